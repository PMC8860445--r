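# Convex hulls, clipped 3D Voronoi, surface Voronoi, shells.

test_that("extended hull displaces vertices radially and bounds the centers", {
  # regular tetrahedron, centroid exactly at the origin, vertices at 10
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tet <- 10 * tet / sqrt(3)
  B <- extended_convex_hull(tet, extend = 3)
  expect_equal(sqrt(rowSums(B$vertices^2)), rep(13, 4), tolerance = 1e-9)
  # all original centers strictly inside B
  margins <- apply(B$planes, 1, function(p)
    max(tet %*% p[1:3]) - p[4])
  expect_true(all(margins < -1e-9))
  expect_error(extended_convex_hull(tet[1:3, ]), "4")
})

test_that("hull volume matches a Monte-Carlo inside test", {
  set.seed(8)
  pts <- matrix(rnorm(3 * 40), ncol = 3)
  B <- extended_convex_hull(pts, extend = 0.5)
  lo <- apply(B$vertices, 2, min); hi <- apply(B$vertices, 2, max)
  probes <- cbind(runif(4e4, lo[1], hi[1]), runif(4e4, lo[2], hi[2]),
                  runif(4e4, lo[3], hi[3]))
  inside <- rep(TRUE, nrow(probes))
  for (f in seq_len(nrow(B$planes)))
    inside <- inside & (probes %*% B$planes[f, 1:3] <= B$planes[f, 4])
  mc <- prod(hi - lo) * mean(inside)
  expect_equal(B$volume, mc, tolerance = 0.01)
})

test_that("cube corners give eight equal volumes filling the boundary", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  colnames(cube) <- NULL
  B <- extended_convex_hull(cube, extend = 1)
  tess <- clipped_voronoi_3d(cube, B)
  expect_equal(tess$volumes, rep(tess$volumes[1], 8), tolerance = 1e-9)
  expect_equal(tess$total_volume, B$volume, tolerance = 1e-3)
  # each corner cell touches its three face neighbors
  expect_equal(tess$adjacency[[1]], c(2L, 3L, 5L))
  expect_error(clipped_voronoi_3d(rbind(cube, cube[1, ]), B), "duplicate")
})

test_that("polyhedra obey the nearest-center property (MC probe oracle)", {
  set.seed(21)
  centers <- matrix(rnorm(3 * 40, sd = 3), ncol = 3)
  B <- extended_convex_hull(centers, extend = 1)
  tess <- clipped_voronoi_3d(centers, B)
  # MC volume per cell: nearest-center among probes inside B
  lo <- apply(B$vertices, 2, min); hi <- apply(B$vertices, 2, max)
  probes <- cbind(runif(2e5, lo[1], hi[1]), runif(2e5, lo[2], hi[2]),
                  runif(2e5, lo[3], hi[3]))
  inside <- rep(TRUE, nrow(probes))
  for (f in seq_len(nrow(B$planes)))
    inside <- inside & (probes %*% B$planes[f, 1:3] <= B$planes[f, 4])
  probes <- probes[inside, ]
  d2 <- matrix(0, nrow(probes), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d2[, j] <- (probes[, 1] - centers[j, 1])^2 +
      (probes[, 2] - centers[j, 2])^2 + (probes[, 3] - centers[j, 3])^2
  nearest <- max.col(-d2)
  mc_vol <- tabulate(nearest, nrow(centers)) / nrow(probes) * B$volume
  expect_equal(tess$volumes, mc_vol, tolerance = 0.05)
  expect_equal(tess$total_volume, B$volume, tolerance = 1e-3)
})

test_that("volumes are scale-equivariant", {
  set.seed(5)
  centers <- matrix(rnorm(3 * 25, sd = 2), ncol = 3)
  t1 <- clipped_voronoi_3d(centers, extended_convex_hull(centers, extend = 1))
  s <- 2.5
  t2 <- clipped_voronoi_3d(centers * s,
                           extended_convex_hull(centers * s, extend = s))
  expect_equal(t2$volumes, t1$volumes * s^3, tolerance = 1e-6)
})

test_that("octahedron vertices give six congruent polygons of 4pi/6", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  st <- surface_voronoi(octa)
  expect_equal(st$solid_angles, rep(4 * pi / 6, 6), tolerance = 1e-9)
  expect_equal(st$areas, rep(st$areas[1], 6), tolerance = 1e-9)
})

test_that("surface tessellation closes to 4pi and neighbors are symmetric", {
  g <- sample_sphere_poisson(600, d = 0.05, seed = 3L)
  st <- surface_voronoi(g)
  expect_equal(sum(st$solid_angles), 4 * pi, tolerance = 0.01 * 4 * pi)
  for (i in c(1, 100, 500))
    for (j in st$adjacency[[i]])
      expect_true(i %in% st$adjacency[[j]])
})

test_that("flattened polygon areas approximate spherical patches closely", {
  # on a unit sphere at n = 600 the planar polygon differs from the curved
  # patch by the sagitta only; relative error far below a percent
  g <- sample_sphere_poisson(600, d = 0.05, seed = 6L)
  st <- surface_voronoi(g)
  expect_equal(sum(st$areas), 4 * pi, tolerance = 0.02 * 4 * pi)
})

test_that("gap exclusion masks the polygons around a synthetic gap", {
  g <- sample_sphere_poisson(500, d = 0.05, seed = 8L)
  pos <- cell_centers(g)
  # carve a cap gap around the north pole
  keep <- pos[, 3] < 0.92
  st <- surface_voronoi(pos[keep, ])
  st2 <- exclude_gaps(st, aspect_threshold = 4)
  expect_gt(sum(st2$masked), 0)
  # masked polygons are enriched around the gap (random slivers elsewhere
  # are flagged too, as on real surfaces)
  zmask <- pos[keep, ][st2$masked, 3]
  expect_gt(max(zmask), 0.7)
  expect_gt(mean(zmask), mean(pos[keep, 3]))
  # survivors keep the full-surface normalization: their sum is short of 4pi
  expect_lt(sum(st2$solid_angles[!st2$masked]), 4 * pi * 0.999)
  # without gaps the exclusion is (nearly) the identity
  st3 <- exclude_gaps(surface_voronoi(cell_centers(
    sample_sphere_poisson(500, d = 0.088, seed = 9L))), aspect_threshold = 4)
  expect_lt(mean(st3$masked), 0.02)
  expect_error(exclude_gaps(st, aspect_threshold = 0), "mask")
})

test_that("solid angles respect the masking convention", {
  g <- sample_sphere_poisson(300, d = 0.05, seed = 12L)
  st <- surface_voronoi(g)
  st$masked[1:30] <- TRUE
  full <- solid_angles(st)
  expect_true(all(is.na(full$solid_angles[1:30])))
  expect_lt(sum(full$solid_angles, na.rm = TRUE), 4 * pi)
  renorm <- solid_angles(st, renormalize = TRUE)
  expect_equal(sum(renorm$solid_angles, na.rm = TRUE), 4 * pi,
               tolerance = 1e-9)
})

test_that("shell binning partitions cells by radius", {
  g <- snowflake_ensemble(60)[[1]]
  tess <- tessellate_group(g)
  sp <- shell_bin(tess, c(0, 6.2, 9.7, 20.4))
  n_assigned <- sum(!is.na(sp$membership))
  expect_equal(n_assigned + length(sp$unassigned), length(tess$volumes))
  expect_equal(sum(lengths(sp$volumes)), n_assigned)
  # single all-covering shell
  sp1 <- shell_bin(tess, c(0, 1e6))
  expect_equal(lengths(sp1$volumes), length(tess$volumes))
  expect_error(shell_bin(tess, c(1, 2)), "edges")
  expect_error(shell_bin(tess, c(0, 2, 2)), "edges")
})

test_that("membrane boundary volume approximates the sphere", {
  B <- membrane_boundary(5)
  expect_equal(B$volume, 4 * pi / 3 * 125, tolerance = 0.01)
  # palintomy groups tessellate within it and fill it
  g <- grow_palintomy(seed = 2L)
  tess <- tessellate_group(g)
  expect_equal(tess$total_volume, tess$hull$volume, tolerance = 1e-3)
})
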