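# Network shells, size correlations, subregions, hexatic order.

test_that("breadth-first shells enumerate a ring and a hexagonal lattice", {
  adj <- ring_adjacency(6)
  sh <- neighbor_shells(adj, 1)
  expect_equal(lengths(sh), c("1" = 2L, "2" = 2L, "3" = 1L))
  # shells partition the reachable nodes
  expect_setequal(unlist(sh), 2:6)
  hexpos <- hex_lattice(11, 11)
  adjh <- cutoff_adjacency(hexpos, 1.1)
  center <- which.min(rowSums(sweep(hexpos, 2,
                                    colMeans(hexpos))^2))
  shh <- neighbor_shells(adjh, center, q_max = 2)
  expect_equal(length(shh[["1"]]), 6)
  expect_equal(length(shh[["2"]]), 12)
})

test_that("iid sizes are uncorrelated; smooth fields correlate at Q = 1", {
  g <- sample_sphere_poisson(700, d = 0.05, seed = 5L)
  st <- surface_voronoi(g)
  sizes <- entropack:::with_seed(7L, rnorm(700, 10, 1))
  prof <- correlation_function(sizes, st, q_max = 5)
  expect_true(all(abs(prof$C) < 5 / sqrt(700)))
  # sizes equal to a smooth function of position: strong C(1)
  smooth <- cell_centers(g)[, 3]
  prof2 <- correlation_function(smooth, st, q_max = 3)
  expect_gt(prof2$C[1], 0.9)
  expect_error(correlation_function(rep(1, 700), st), "variance")
})

test_that("shuffled size labels give a null correlation profile", {
  g <- sample_sphere_poisson(500, d = 0.05, seed = 15L)
  st <- surface_voronoi(g)
  # average over shuffles: a single permutation's C(Q) fluctuates at the
  # ~1/sqrt(n) scale, the mean over m shuffles at 1/sqrt(m n)
  profs <- entropack:::with_seed(8L, {
    lapply(1:8, function(i)
      correlation_function(sample(st$solid_angles), st, q_max = 6)$C)
  })
  cbar <- rowMeans(do.call(cbind, profs))
  # the null sd of C(Q) is ~1.3-1.6/sqrt(n) (shell members overlap between
  # nodes), so the 3-sigma band is 5/sqrt(m n)
  expect_true(all(abs(cbar) < 5 / sqrt(8 * 500)))
})

test_that("subregions pool to the whole organism at large Q0", {
  g <- sample_sphere_poisson(200, d = 0.05, seed = 6L)
  st <- surface_voronoi(g)
  sub <- extract_subregions(st$solid_angles, st, Q0 = 50)
  expect_equal(sort(unique(unlist(lapply(sub$samples, length)))), 200)
  expect_setequal(round(sub$samples[[1]], 12),
                  round(st$solid_angles, 12))
  # target-mean retention filters subregions
  subt <- extract_subregions(st$solid_angles, st, Q0 = 3,
                             target_mean = mean(st$solid_angles),
                             tolerance = 0.1 * mean(st$solid_angles))
  expect_gt(length(subt$samples), 0)
  expect_error(extract_subregions(st$solid_angles, st, Q0 = 3,
                                  target_mean = 100, tolerance = 1e-6),
               "no subregion")
})

test_that("psi6 is 1 on a hexagonal lattice and small for random points", {
  hexpos <- hex_lattice(13, 13)
  adj <- cutoff_adjacency(hexpos, 1.1)
  interior <- which(lengths(adj) == 6)
  p6 <- psi6(hexpos[interior, ],
             cutoff_adjacency(hexpos[interior, ], 1.1))
  expect_equal(p6, 1, tolerance = 1e-6)
  # invariance under a global rotation
  th <- 0.41
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p6r <- psi6(hexpos[interior, ] %*% t(Rz),
              cutoff_adjacency(hexpos[interior, ] %*% t(Rz), 1.1))
  expect_equal(p6, p6r, tolerance = 1e-9)
  g <- sample_sphere_poisson(600, d = 0.02, seed = 9L)
  st <- surface_voronoi(g)
  expect_lt(psi6(cell_centers(g), st), 0.2)
})
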