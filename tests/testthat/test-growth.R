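# Growth protocols: determinism, tree structure, ensemble statistics.

test_that("identical config and seed give byte-identical cell tables", {
  cfg <- morphology_config()
  a <- grow_snowflake(cfg, seed = 42L)
  b <- grow_snowflake(cfg, seed = 42L)
  expect_identical(a$cells, b$cells)
  c1 <- grow_aggregate(cfg, seed = 7L)
  c2 <- grow_aggregate(cfg, seed = 7L)
  expect_identical(c1$cells, c2$cells)
  expect_false(identical(a$cells, grow_snowflake(cfg, seed = 43L)$cells))
})

test_that("budding groups are trees rooted at cell 0 within the generation cap", {
  for (s in 1:5) {
    g <- grow_snowflake(seed = s)
    n <- nrow(g$cells)
    expect_lte(n, 2^7)
    expect_equal(nrow(g$bonds), n - 1)
    # every non-root cell's mother precedes it: acyclic by construction
    expect_true(all(g$bonds[, "mother"] < g$bonds[, "daughter"]))
    expect_false(0 %in% g$bonds[, "daughter"])
  }
})

test_that("snowflake ensemble cell count matches the published statistics", {
  groups <- snowflake_ensemble(60)
  counts <- vapply(groups, function(g) nrow(g$cells), numeric(1))
  # mean within 2 population-sd of 94.2 (sd 10.9)
  expect_lt(abs(mean(counts) - 94.2), 2 * 10.9)
  expect_gt(sd(counts), 5)
})

test_that("aggregates reach exactly 64 cells with contacts at force balance", {
  g <- grow_aggregate(seed = 3L)
  expect_equal(nrow(g$cells), 64)
  expect_true(g$converged)
  d <- as.matrix(dist(cell_centers(g)))
  nn <- apply(d + diag(1e9, 64), 1, min)
  # every cell rests near contact with its nearest neighbor (small overlap
  # from multi-bond compression, never deep interpenetration)
  expect_gt(min(nn), 1.2)
  expect_lt(max(nn), 2.05)
})

test_that("bidisperse growth respects the inheritance probability", {
  expect_error(morphology_config(polydispersity_xi = 2), "probabilities")
  g1 <- grow_polydisperse(morphology_config(polydispersity_xi = 1), seed = 5L)
  expect_equal(nrow(g1$cells), 64)
  # xi = 1: lineages are size-pure
  cells <- g1$cells
  for (i in which(!is.na(cells$mother_id))) {
    expect_equal(cells$a[i], cells$a[cells$id == cells$mother_id[i]])
  }
  # xi = 0.5: the large-cell fraction is near one half over several runs
  fr <- vapply(1:6, function(s) {
    g <- grow_polydisperse(morphology_config(polydispersity_xi = 0.5),
                           seed = s)
    mean(g$cells$a == 2)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.1)
})

test_that("palintomy holds the packing fraction and keeps cells confined", {
  g <- grow_palintomy(seed = 9L)
  expect_equal(nrow(g$cells), 64)
  vcell <- 4 * pi / 3
  phi <- 64 * vcell / (4 * pi / 3 * g$membrane_radius^3)
  expect_equal(phi, 0.5, tolerance = 0.01)
  r <- sqrt(rowSums(cell_centers(g)^2))
  expect_true(all(r < g$membrane_radius))
})

test_that("sphere-surface sampling is uniform and respects the hard core", {
  g <- sample_sphere_poisson(400, d = 0.088, seed = 2L)
  pos <- cell_centers(g)
  expect_equal(sqrt(rowSums(pos^2)), rep(1, 400), tolerance = 1e-12)
  expect_gte(min(dist(pos)), 0.088)
  # area-uniform sampling: z = cos(theta) is uniform on [-1, 1]
  z <- unlist(lapply(1:5, function(s)
    cell_centers(sample_sphere_poisson(300, 0.02, seed = s))[, 3]))
  h <- hist(z, breaks = seq(-1, 1, length.out = 11), plot = FALSE)$counts
  expect_lt(max(abs(h - length(z) / 10)) / (length(z) / 10), 0.2)
  expect_error(sample_sphere_poisson(200, d = 0.5, seed = 1L, max_tries = 5000),
               "saturated")
})

test_that("patterned growth at zero noise is identical across runs and discrete", {
  g1 <- grow_patterned(seed = 1L)
  g2 <- grow_patterned(seed = 99L)
  # no randomness at eta = 0: structure independent of the seed
  expect_equal(cell_centers(g1), cell_centers(g2), tolerance = 1e-9)
  tess <- tessellate_group(g1)
  # the volume spectrum is visibly discrete: few distinct values
  expect_lt(length(unique(round(tess$volumes, 4))), nrow(g1$cells))
  # noise breaks the degeneracy
  gn <- grow_patterned(morphology_config(noise_eta = 30), seed = 1L)
  gm <- grow_patterned(morphology_config(noise_eta = 30), seed = 2L)
  expect_false(isTRUE(all.equal(cell_centers(gn), cell_centers(gm))))
  expect_equal(nrow(gn$cells), 28)  # no coincident sites once eta > 0
})

test_that("apoptosis removes ten cells, localized when R is small", {
  g <- sample_sphere_poisson(50, d = 2 * 0.198, seed = 4L,
                             cell_radius = 0.198)
  out <- apply_apoptosis(g, R = 2, seed = 1L)
  expect_equal(nrow(out$cells), 40)
  expect_length(attr(out, "removed"), 10)
  # small R: dead cells are spatially clustered relative to survivors
  out_loc <- apply_apoptosis(g, R = 1, seed = 2L)
  dead_ids <- attr(out_loc, "removed")
  pos <- cell_centers(g)
  dead <- pos[g$cells$id %in% dead_ids, ]
  alive <- pos[!g$cells$id %in% dead_ids, ]
  expect_lt(mean(dist(dead)), mean(dist(alive)))
  expect_error(apply_apoptosis(g, R = 0.05, seed = 1L), "flagged")
})
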