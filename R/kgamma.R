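#' The k-gamma (maximum-entropy) neighborhood-size model
#'
#' The maximum-entropy distribution of cell neighborhood sizes under a
#' total-size constraint is the shifted ("k-gamma") gamma distribution
#' `p(v) = k^k / Gamma(k) * (v - v_c)^(k-1) / (vbar - v_c)^k *
#' exp(-k (v - v_c) / (vbar - v_c))`, where `vbar` is the mean size, `v_c`
#' the minimum size, and `k = (vbar - v_c)^2 / sigma^2` a dimensionless
#' shape parameter set entirely by the first two moments.
#'
#' @param v_bar mean neighborhood size.
#' @param v_c minimum neighborhood size (same units).
#' @param sigma2 variance of the neighborhood sizes.
#' @return an object of class `kgamma_model` with fields `v_bar`, `v_c`,
#'   `sigma2`, `k`.
#' @export
kgamma_model <- function(v_bar, v_c, sigma2) {
  if (!(v_bar > v_c)) stop("v_bar must exceed v_c")
  if (!(sigma2 > 0)) stop("sigma2 must be positive")
  structure(list(v_bar = v_bar, v_c = v_c, sigma2 = sigma2,
                 k = (v_bar - v_c)^2 / sigma2),
            class = "kgamma_model")
}

#' @export
print.kgamma_model <- function(x, ...) {
  cat(sprintf("<kgamma_model> k = %.4g (v_bar = %.4g, v_c = %.4g, sigma2 = %.4g)\n",
              x$k, x$v_bar, x$v_c, x$sigma2))
  invisible(x)
}

#' @rdname kgamma_model
#' @param v neighborhood sizes at which to evaluate.
#' @param model a `kgamma_model`.
#' @export
kgamma_pdf <- function(v, model) {
  scale <- (model$v_bar - model$v_c) / model$k
  out <- numeric(length(v))
  ok <- v >= model$v_c
  out[ok] <- stats::dgamma(v[ok] - model$v_c, shape = model$k, scale = scale)
  out
}

#' @rdname kgamma_model
#' @export
kgamma_cdf <- function(v, model) {
  scale <- (model$v_bar - model$v_c) / model$k
  out <- numeric(length(v))
  ok <- v >= model$v_c
  out[ok] <- pgamma(v[ok] - model$v_c, shape = model$k, scale = scale)
  out
}

#' @rdname kgamma_model
#' @param n number of random draws.
#' @export
rkgamma <- function(n, model) {
  model$v_c + rgamma(n, shape = model$k,
                     scale = (model$v_bar - model$v_c) / model$k)
}

#' Moment-matched k-gamma model of a size sample
#'
#' The model is never fitted by likelihood or least squares: the mean and
#' population (1/n) variance of the sample, together with the supplied
#' minimum size, fully determine it.
#'
#' @param sizes numeric vector of neighborhood sizes (at least 2 distinct).
#' @param v_c minimum neighborhood size. Values below `v_c` are reported via
#'   a warning but retained in the moments.
#' @return a `kgamma_model`.
#' @export
estimate_kgamma <- function(sizes, v_c) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) < 2) stop("need at least 2 sizes")
  m <- mean(sizes)
  s2 <- mean((sizes - m)^2)  # population variance
  if (s2 <= 0) stop("zero variance: k is undefined")
  if (m <= v_c) stop("v_c is not below the sample mean")
  if (any(sizes < v_c))
    warning(sprintf("%d sizes fall below v_c = %.4g", sum(sizes < v_c), v_c))
  kgamma_model(m, v_c, s2)
}

pp_positions <- c("hazen", "weibull", "naive")

#' P-P comparison of a size sample against a model CDF
#'
#' Plots of the empirical CDF at the order statistics against the model CDF
#' quantify goodness of fit; the summary statistic is the root-mean-square
#' residual from the diagonal, `r_RMS = sqrt(mean((F_i - F(v_(i)))^2))`.
#' The empirical CDF uses the Hazen plotting position `(i - 0.5) / n` by
#' default.
#'
#' @param sizes numeric sample.
#' @param model a `kgamma_model` or a [moment_match_family()] result.
#' @param position plotting position convention.
#' @return an object of class `pp_result`: `sizes` (sorted), `empirical`,
#'   `predicted`, `r_rms`.
#' @export
pp_rrms <- function(sizes, model, position = pp_positions) {
  position <- match.arg(position)
  sizes <- sort(sizes[!is.na(sizes)])
  n <- length(sizes)
  if (n == 0) stop("empty size sample")
  emp <- switch(position,
                hazen = (seq_len(n) - 0.5) / n,
                weibull = seq_len(n) / (n + 1),
                naive = seq_len(n) / n)
  pred <- family_cdf(sizes, model)
  structure(list(sizes = sizes, empirical = emp, predicted = pred,
                 r_rms = sqrt(mean((emp - pred)^2))),
            class = "pp_result")
}

#' @export
print.pp_result <- function(x, ...) {
  cat(sprintf("<pp_result> n = %d, r_RMS = %.4g\n", length(x$sizes), x$r_rms))
  invisible(x)
}

#' Fit the minimum size of a k-gamma model by P-P residual minimization
#'
#' For pooled solid-angle data the minimum neighborhood size is not known a
#' priori. After removing extreme low outliers (single values separated
#' from the body of the lower tail by an exceptionally large gap), the
#' minimum size is chosen to minimize the sum of squared P-P residuals of
#' the moment-matched k-gamma model.
#'
#' @param sizes pooled sizes (e.g. solid angles in steradians).
#' @param outlier_gap_factor the smallest value is declared an outlier when
#'   its gap to the next order statistic exceeds this multiple of the span
#'   of the following `n_tail` order statistics. For a k-gamma lower tail
#'   the first gap is a modest fraction of that span, while a detached
#'   outlier dominates it, so the rule separates the two regimes without a
#'   distributional fit.
#' @param n_tail number of low order statistics forming the reference span.
#' @param max_outliers at most this many low outliers are removed.
#' @return list with `v_c` (the fitted minimum), `model`, `removed`
#'   (the removed low values), `objective`.
#' @export
fit_min_size <- function(sizes, outlier_gap_factor = 2, n_tail = 30,
                         max_outliers = 3) {
  x <- sort(sizes[!is.na(sizes)])
  removed <- numeric(0)
  for (r in seq_len(max_outliers)) {
    m <- min(n_tail, length(x) - 1)
    if (m < 5) break
    span <- x[1 + m] - x[2]
    if (span > 0 && (x[2] - x[1]) > outlier_gap_factor * span) {
      removed <- c(removed, x[1])
      x <- x[-1]
    } else break
  }
  obj <- function(vc) {
    m <- estimate_kgamma(x, vc)
    sum((pp_rrms(x, m)$r_rms)^2 * length(x))
  }
  upper <- min(x) * (1 - 1e-9)
  opt <- optimize(obj, interval = c(0, upper))
  if (opt$minimum < 1e-6 * upper || opt$minimum > upper * (1 - 1e-6))
    warning("minimum-size fit at the boundary of its search interval")
  list(v_c = opt$minimum, model = estimate_kgamma(x, opt$minimum),
       removed = removed, objective = opt$objective)
}

#' Moment-match one of the four comparison distributions
#'
#' Given a sample mean `V_bar` and standard deviation `s`, returns the
#' member of the chosen family with exactly that mean and standard
#' deviation: normal `(mu = V_bar, sigma = s)`; log-normal with parameters
#' obtained by inverting its mean/variance relations; beta prime with
#' `alpha = V_bar (V_bar + V_bar^2 + s^2) / s^2` and
#' `beta = (V_bar + V_bar^2 + 2 s^2) / s^2`; k-gamma via moment matching
#' with the supplied minimum size.
#'
#' @param family one of `"kgamma"`, `"normal"`, `"lognormal"`, `"betaprime"`.
#' @param V_bar sample mean.
#' @param s sample standard deviation (> 0).
#' @param v_c minimum size (k-gamma only).
#' @return an object of class `family_params`.
#' @export
moment_match_family <- function(family = c("kgamma", "normal", "lognormal",
                                           "betaprime"),
                                V_bar, s, v_c = NULL) {
  family <- match.arg(family)
  if (!(s > 0)) stop("s must be positive")
  params <- switch(family,
    kgamma = {
      if (is.null(v_c)) stop("k-gamma moment matching requires v_c")
      m <- kgamma_model(V_bar, v_c, s^2)
      list(v_bar = m$v_bar, v_c = m$v_c, k = m$k)
    },
    normal = list(mu = V_bar, sigma = s),
    lognormal = {
      sigma2 <- log(1 + s^2 / V_bar^2)
      list(mu = log(V_bar) - sigma2 / 2, sigma = sqrt(sigma2))
    },
    betaprime = {
      alpha <- V_bar * (V_bar + V_bar^2 + s^2) / s^2
      beta <- (V_bar + V_bar^2 + 2 * s^2) / s^2
      if (beta <= 2) stop("beta prime variance undefined (beta <= 2)")
      list(alpha = alpha, beta = beta)
    })
  structure(list(family = family, params = params, V_bar = V_bar, s = s),
            class = "family_params")
}

#' CDF of a moment-matched model
#'
#' @param x quantiles.
#' @param model a `kgamma_model` or `family_params`.
#' @return vector of probabilities.
#' @export
family_cdf <- function(x, model) {
  if (inherits(model, "kgamma_model")) return(kgamma_cdf(x, model))
  if (!inherits(model, "family_params")) stop("not a model object")
  p <- model$params
  switch(model$family,
         kgamma = kgamma_cdf(x, kgamma_model(p$v_bar, p$v_c,
                                             (p$v_bar - p$v_c)^2 / p$k)),
         normal = pnorm(x, p$mu, p$sigma),
         lognormal = plnorm(x, p$mu, p$sigma),
         betaprime = ifelse(x <= 0, 0, pbeta(x / (1 + x), p$alpha, p$beta)))
}

#' Predicted skewness of a moment-matched family
#'
#' Closed-form standardized third moment implied by the first two moments:
#' `2 / sqrt(k)` for the k-gamma, 0 for the normal,
#' `(exp(sigma^2) + 2) sqrt(exp(sigma^2) - 1)` for the log-normal, and the
#' closed form of the beta prime (defined only for `beta > 3`).
#'
#' @param model a `kgamma_model` or `family_params`.
#' @return the predicted skewness.
#' @export
predicted_skewness <- function(model) {
  if (inherits(model, "kgamma_model")) return(2 / sqrt(model$k))
  p <- model$params
  switch(model$family,
         kgamma = 2 / sqrt(p$k),
         normal = 0,
         lognormal = (exp(p$sigma^2) + 2) * sqrt(exp(p$sigma^2) - 1),
         betaprime = {
           if (p$beta <= 3) stop("beta prime skewness undefined (beta <= 3)")
           2 * (2 * p$alpha + p$beta - 1) / (p$beta - 3) *
             sqrt((p$beta - 2) / (p$alpha * (p$alpha + p$beta - 1)))
         })
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

#' Percent error of a family's skewness prediction
#'
#' Moment-matches the family to the sample, predicts the skewness from the
#' first two moments alone, and reports the percent error relative to the
#' empirical sample skewness.
#'
#' @param sizes numeric sample.
#' @param family family name, as in [moment_match_family()].
#' @param v_c minimum size (k-gamma only).
#' @return percent error, `100 * (predicted - empirical) / empirical`.
#' @export
skewness_error <- function(sizes, family, v_c = NULL) {
  emp <- sample_skewness(sizes)
  fp <- moment_match_family(family, mean(sizes),
                            sqrt(mean((sizes - mean(sizes))^2)), v_c = v_c)
  100 * (predicted_skewness(fp) - emp) / emp
}

#' Bootstrap comparison of the four families across sample sizes
#'
#' Draws `reps` subsamples of each size (with replacement), re-moment-
#' matches every family to each subsample, and records the P-P r_RMS.
#'
#' @param sizes the full data set.
#' @param n_values subsample sizes.
#' @param reps bootstrap repetitions per size.
#' @param seed integer seed.
#' @param v_c minimum size for the k-gamma family.
#' @return a data frame with columns `family`, `n`, `mean_rrms`.
#' @export
subsample_comparison <- function(sizes, n_values, reps = 10, seed = 1L,
                                 v_c = 0) {
  families <- c("kgamma", "normal", "lognormal", "betaprime")
  rows <- list()
  with_seed(seed, {
    for (n in n_values) {
      acc <- matrix(NA_real_, reps, length(families),
                    dimnames = list(NULL, families))
      for (r in seq_len(reps)) {
        sub <- sample(sizes, n, replace = TRUE)
        m <- mean(sub)
        s <- sqrt(mean((sub - m)^2))
        if (s == 0) next
        for (fam in families) {
          fp <- try(moment_match_family(fam, m, s, v_c = v_c), silent = TRUE)
          if (inherits(fp, "try-error")) next
          acc[r, fam] <- pp_rrms(sub, fp)$r_rms
        }
      }
      for (fam in families)
        rows[[length(rows) + 1L]] <-
          data.frame(family = fam, n = n,
                     mean_rrms = mean(acc[, fam], na.rm = TRUE))
    }
  })
  do.call(rbind, rows)
}
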