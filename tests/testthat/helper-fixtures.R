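# Shared fixtures and small constructors. Expensive ensembles are cached per
# test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

two_cell_group <- function(d, r = 1) {
  pos <- rbind(c(0, 0, 0), c(d, 0, 0))
  entropack:::build_group(pos, c(r, r), c(r, r),
                          list(diag(3), diag(3)), c(NA, NA),
                          matrix(NA_real_, 2, 3), "aggregate", 1L)
}

point_group <- function(pos, r = 0.5, morphology = "aggregate") {
  n <- nrow(pos)
  entropack:::build_group(pos, rep(r, n), rep(r, n),
                          replicate(n, diag(3), simplify = FALSE),
                          rep(NA_integer_, n), matrix(NA_real_, n, 3),
                          morphology, 1L)
}

# planar hexagonal lattice (z = 0), rows of a triangular lattice
hex_lattice <- function(nx = 9, ny = 9, spacing = 1) {
  pts <- list()
  for (j in seq_len(ny)) {
    x <- (seq_len(nx) - 1) * spacing + (j %% 2) * spacing / 2
    y <- rep((j - 1) * spacing * sqrt(3) / 2, nx)
    pts[[j]] <- cbind(x, y, 0)
  }
  do.call(rbind, pts)
}

# adjacency of points closer than cutoff
cutoff_adjacency <- function(pos, cutoff) {
  d <- as.matrix(dist(pos))
  lapply(seq_len(nrow(pos)), function(i)
    which(d[i, ] > 0 & d[i, ] < cutoff))
}

ring_adjacency <- function(n) {
  lapply(seq_len(n), function(i)
    sort(c((i - 2) %% n + 1, i %% n + 1)))
}

snowflake_ensemble <- function(n = 60, seed = 11) {
  cached(sprintf("snow_%d_%d", n, seed),
         simulate_ensemble("snowflake", n, seed = seed))
}

snowflake_volumes <- function(n = 60, seed = 11) {
  cached(sprintf("snowvol_%d_%d", n, seed),
         pool_sizes(snowflake_ensemble(n, seed)))
}

yeast_vc <- 4 * pi / 3 * 2.88 * 2.29^2
unit_vc <- 4 * pi / 3
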