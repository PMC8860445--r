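# The k-gamma model, moment matching, P-P diagnostics, family comparison.

test_that("the k-gamma density matches hand evaluation and normalizes", {
  m <- kgamma_model(v_bar = 1, v_c = 0, sigma2 = 0.5)  # k = 2
  expect_equal(m$k, 2)
  expect_equal(kgamma_pdf(1, m), 4 * exp(-2))
  expect_equal(kgamma_pdf(-0.5, m), 0)
  expect_equal(kgamma_cdf(-0.5, m), 0)
  expect_equal(integrate(kgamma_pdf, 0, Inf, model = m,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  # k = 1 reduces to a shifted exponential
  m1 <- kgamma_model(v_bar = 3, v_c = 1, sigma2 = 4)
  expect_equal(m1$k, 1)
  v <- seq(1, 10, by = 0.5)
  expect_equal(kgamma_pdf(v, m1), dexp(v - 1, rate = 1 / 2), tolerance = 1e-12)
})

test_that("cdf is the integral of the pdf on a grid", {
  m <- kgamma_model(2, 0.5, 0.3)
  v <- seq(0.6, 6, by = 1e-4)
  num <- (kgamma_cdf(v + 5e-5, m) - kgamma_cdf(v - 5e-5, m)) / 1e-4
  expect_equal(num, kgamma_pdf(v, m), tolerance = 1e-5)
})

test_that("moment matching uses the population variance", {
  m <- estimate_kgamma(c(1, 2, 3), v_c = 0)
  expect_equal(m$v_bar, 2)
  expect_equal(m$sigma2, 2 / 3)
  expect_equal(m$k, 6)
  expect_error(estimate_kgamma(c(2, 2, 2), 0), "variance")
  expect_error(estimate_kgamma(c(1, 2, 3), 5), "v_c")
  expect_error(suppressWarnings(estimate_kgamma(c(1, 2, 3), 2.5)), "v_c")
  expect_warning(estimate_kgamma(c(0.1, 1, 2, 3), 0.5), "below")
})

test_that("k is recovered from synthetic draws and is scale invariant", {
  for (k in c(2, 5, 20)) {
    m <- kgamma_model(v_bar = 1 + 1, v_c = 1, sigma2 = 1 / k)
    x <- entropack:::with_seed(101L + k, rkgamma(1e5, m))
    est <- estimate_kgamma(x, 1)
    expect_lt(abs(est$k - k) / k, 0.05)
  }
  x <- entropack:::with_seed(5L, rkgamma(500, kgamma_model(2, 0.5, 0.4)))
  k1 <- estimate_kgamma(x, 0.5)$k
  k2 <- estimate_kgamma(10 * x, 5)$k
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("P-P residuals vanish for model quantiles and match brute force", {
  m <- kgamma_model(1, 0, 1 / 3)
  n <- 200
  q <- m$v_c + qgamma((seq_len(n) - 0.5) / n, shape = m$k,
                      scale = (m$v_bar - m$v_c) / m$k)
  expect_lt(pp_rrms(q, m)$r_rms, 1e-12)
  # 3-point sample against hand-enumerated order statistics
  s <- c(0.3, 1.1, 2.4)
  res <- pp_rrms(s, m)
  hand <- sqrt(mean((c(0.5, 1.5, 2.5) / 3 - kgamma_cdf(sort(s), m))^2))
  expect_equal(res$r_rms, hand)
  expect_true(all(diff(res$empirical) >= 0))
  expect_true(all(diff(res$predicted) >= -1e-12))
  expect_error(pp_rrms(numeric(0), m), "empty")
})

test_that("P-P residuals calibrate to zero for true-model samples", {
  m <- kgamma_model(2, 1, 0.2)
  r <- entropack:::with_seed(9L, {
    vapply(1:20, function(i) pp_rrms(rkgamma(1e4, m), m)$r_rms, numeric(1))
  })
  expect_lt(median(r), 0.01)
})

test_that("fit_min_size recovers a known minimum and ignores clean data", {
  # broad (k ~ 2.4) data: the minimum is sharply identified; for steep
  # shapes the density vanishes too fast at v_c for point identification
  m <- kgamma_model(0.0185, 0.007, (0.0185 - 0.007)^2 / 2.4)
  x <- entropack:::with_seed(31L, rkgamma(4000, m))
  fit <- fit_min_size(x)
  expect_length(fit$removed, 0)
  expect_lt(abs(fit$v_c - 0.007) / 0.007, 0.05)
  # a single extreme low outlier is removed before fitting
  fit2 <- fit_min_size(c(0.0048, x))
  expect_length(fit2$removed, 1)
  expect_lt(abs(fit2$v_c - 0.007) / 0.007, 0.05)
})

test_that("moment-matched families reproduce the requested moments", {
  Vb <- 3.2; s <- 0.9
  bp <- moment_match_family("betaprime", Vb, s)
  a <- bp$params$alpha; b <- bp$params$beta
  expect_equal(a / (b - 1), Vb, tolerance = 1e-12)
  expect_equal(a * (a + b - 1) / ((b - 2) * (b - 1)^2), s^2,
               tolerance = 1e-12)
  ln <- moment_match_family("lognormal", Vb, s)
  mu <- ln$params$mu; sg <- ln$params$sigma
  expect_equal(exp(mu + sg^2 / 2), Vb, tolerance = 1e-12)
  expect_equal((exp(sg^2) - 1) * exp(2 * mu + sg^2), s^2, tolerance = 1e-12)
  no <- moment_match_family("normal", Vb, s)
  expect_equal(unlist(no$params), c(mu = Vb, sigma = s))
  kg <- moment_match_family("kgamma", Vb, s, v_c = 1)
  expect_equal(kg$params$k, (Vb - 1)^2 / s^2)
  expect_error(moment_match_family("kgamma", Vb, s), "v_c")
})

test_that("family CDFs agree with their stats-distribution forms", {
  x <- c(0.5, 1, 2, 5)
  bp <- moment_match_family("betaprime", 2, 1)
  expect_equal(family_cdf(x, bp),
               pbeta(x / (1 + x), bp$params$alpha, bp$params$beta))
  expect_equal(family_cdf(0, bp), 0)
})

test_that("skewness predictions follow the closed forms", {
  x <- entropack:::with_seed(3L, rkgamma(5e4, kgamma_model(2, 0.5, 0.3)))
  expect_equal(skewness_error(x, "normal"), -100)
  # symmetric sample: the k-gamma still predicts positive skewness
  sym <- rep(c(1, 2, 3), 100)
  kg <- moment_match_family("kgamma", mean(sym),
                            sqrt(mean((sym - mean(sym))^2)), v_c = 0)
  expect_gt(predicted_skewness(kg), 0)
  # closed form 2/sqrt(k) near the empirical skewness for true k-gamma data
  err <- skewness_error(x, "kgamma", v_c = 0.5)
  expect_lt(abs(err), 10)
  expect_error(predicted_skewness(
    structure(list(family = "betaprime",
                   params = list(alpha = 5, beta = 2.5)),
              class = "family_params")), "undefined")
})

test_that("subsample comparison is reproducible and consistent at full n", {
  x <- entropack:::with_seed(13L, rkgamma(2000, kgamma_model(2, 0.5, 0.3)))
  a <- subsample_comparison(x, c(200, 2000), reps = 4, seed = 99L, v_c = 0.5)
  b <- subsample_comparison(x, c(200, 2000), reps = 4, seed = 99L, v_c = 0.5)
  expect_identical(a, b)
  full <- pp_rrms(x, estimate_kgamma(x, 0.5))$r_rms
  kg_full <- a$mean_rrms[a$family == "kgamma" & a$n == 2000]
  expect_lt(abs(kg_full - full), 0.01)
})
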