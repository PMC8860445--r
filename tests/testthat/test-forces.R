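# Force laws and overdamped relaxation.

cell_at <- function(x, r = 1) list(center = x, radius = r)

test_that("steric force is zero beyond contact, harmonic and antisymmetric inside", {
  cfg <- mechanics_config()
  expect_equal(steric_force(cell_at(c(0, 0, 0)), cell_at(c(3, 0, 0)), cfg),
               c(0, 0, 0))
  f <- steric_force(cell_at(c(0, 0, 0)), cell_at(c(1.5, 0, 0)), cfg)
  expect_equal(sqrt(sum(f^2)), 0.5)
  expect_lt(f[1], 0)  # pushes i away from j
  # antisymmetry for a generic overlapping pair
  a <- cell_at(c(0.2, -0.1, 0.3)); b <- cell_at(c(1.1, 0.7, -0.2))
  expect_equal(steric_force(a, b, cfg), -steric_force(b, a, cfg))
  expect_error(steric_force(a, a, cfg), "coincident")
})

test_that("adhesive force follows the printed three-branch law", {
  cfg <- mechanics_config()  # a = 0.9
  expect_equal(adhesive_force(cell_at(c(0, 0, 0)), cell_at(c(5, 0, 0)), cfg),
               c(0, 0, 0))
  expect_equal(adhesive_force(cell_at(c(0, 0, 0)), cell_at(c(1.9, 0, 0)), cfg),
               c(0, 0, 0))  # overlap branch is identically zero
  f <- adhesive_force(cell_at(c(0, 0, 0)), cell_at(c(2.5, 0, 0)), cfg)
  expect_equal(sqrt(sum(f^2)), 0.7)  # |r| - a (Ri+Rj) = 2.5 - 1.8
  expect_gt(f[1], 0)  # attractive
})

test_that("membrane force matches the exact lens volume", {
  cfg <- mechanics_config()
  expect_equal(membrane_force(cell_at(c(0, 0, 1)), 5, cfg), c(0, 0, 0))
  f_out <- membrane_force(cell_at(c(0, 0, 10)), 5, cfg)
  expect_equal(sqrt(sum(f_out^2)), 4 * pi / 3)
  expect_lt(f_out[3], 0)  # toward the membrane center
  # center on a large membrane: half the cell volume outside
  f_half <- membrane_force(cell_at(c(0, 0, 1000)), 1000, cfg)
  expect_equal(sqrt(sum(f_half^2)), 2 * pi / 3, tolerance = 1e-2)
  expect_error(membrane_force(cell_at(c(0, 0, 0)), -1, cfg), "positive")
})

test_that("lens volume agrees with a Monte-Carlo intersection oracle", {
  r1 <- 1; r2 <- 1.7; d <- 2.1
  set.seed(4)
  pts <- matrix(runif(3 * 2e5, -1, 1), ncol = 3)  # cube around sphere 1
  inside1 <- rowSums(pts^2) <= 1
  inside2 <- (pts[, 1] - d)^2 + pts[, 2]^2 + pts[, 3]^2 <= r2^2
  mc <- 8 * mean(inside1 & inside2)
  expect_equal(entropack:::cpp_lens_volume(r1, r2, d), mc, tolerance = 0.02)
})

test_that("bond force is restoring with the configured rest length", {
  cfg <- mechanics_config(bond_rest_length = 2)
  daughter <- list(birth_scar = c(3, 0, 0))
  mother <- list(bud_scar = c(0, 0, 0))
  f <- bond_force(daughter, mother, cfg)
  expect_equal(sqrt(sum(f^2)), 1)  # |r| = 3, L0 = 2, kappa = 1
  expect_lt(f[1], 0)  # pulls the daughter back toward the scar
  cfg0 <- mechanics_config(bond_rest_length = 0)
  expect_equal(bond_force(list(birth_scar = c(1, 1, 1)),
                          list(bud_scar = c(1, 1, 1)), cfg0), c(0, 0, 0))
  expect_error(bond_force(list(), mother, cfg), "scar")
})

test_that("two-cell adhesive relaxation finds the steric/adhesive crossover", {
  # 1D force balance of the printed laws: zero net force only at contact
  g <- relax_overdamped(two_cell_group(1.5), forces = c("steric", "adhesive"))
  d <- dist(cell_centers(g))[1]
  expect_true(g$converged)
  expect_equal(as.numeric(d), 2, tolerance = 1e-3)
  # separated cells never bonded: adhesion does not act at a distance
  g2 <- relax_overdamped(two_cell_group(2.6), forces = c("steric", "adhesive"))
  expect_equal(as.numeric(dist(cell_centers(g2))[1]), 2.6, tolerance = 1e-9)
})

test_that("an isolated cell does not move and relaxation is deterministic", {
  g <- point_group(matrix(c(1, 2, 3), 1, 3), r = 1)
  r1 <- relax_overdamped(g, forces = c("steric", "adhesive"))
  expect_equal(cell_centers(r1), cell_centers(g))
  expect_true(r1$converged)
  a <- relax_overdamped(two_cell_group(1.2), forces = "steric")
  b <- relax_overdamped(two_cell_group(1.2), forces = "steric")
  expect_identical(cell_centers(a), cell_centers(b))
})
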