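# Departures from randomness: network-distance shells and correlation of
# neighborhood sizes, correlated-subregion extraction, and the hexatic
# order parameter.

as_adjacency <- function(x) {
  if (inherits(x, "surface_tessellation")) return(x$adjacency)
  if (inherits(x, "tessellation3d")) return(x$adjacency)
  x
}

#' Breadth-first shells of a node in a neighbor graph
#'
#' Shell `Q` holds the nodes at network (graph) distance exactly `Q` from
#' the given node; `J(Q)` is the shell size, with `J(1)` the node degree.
#'
#' @param graph adjacency list (list of integer neighbor vectors), or a
#'   tessellation object carrying one.
#' @param node 1-based node index.
#' @param q_max largest shell to return.
#' @return named list mapping `Q` (as character) to member index vectors.
#' @export
neighbor_shells <- function(graph, node, q_max = Inf) {
  adj <- as_adjacency(graph)
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[node] <- 0L
  frontier <- node
  q <- 0L
  shells <- list()
  while (length(frontier) > 0 && q < q_max) {
    q <- q + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- q
    shells[[as.character(q)]] <- sort(nxt)
    frontier <- nxt
  }
  shells
}

#' Network-distance correlation of neighborhood sizes
#'
#' For each node, `Y_Q` is the mean deviation from the global mean of the
#' sizes in its shell at network distance `Q`; the correlation profile is
#' `C(Q) = <(Omega - <Omega>) Y_Q> / (sigma_Omega sigma_{Y_Q})`, a
#' Pearson-style normalized covariance between a node's own deviation and
#' its shell's mean deviation. Nodes with an empty shell at some `Q` are
#' skipped at that `Q`.
#'
#' @param sizes per-node neighborhood sizes (`NA` for masked nodes, which
#'   are dropped from the statistics).
#' @param graph adjacency list or tessellation.
#' @param q_max largest network distance.
#' @return an object of class `correlation_profile`: data frame with
#'   columns `Q`, `C`, `n_nodes`.
#' @export
correlation_function <- function(sizes, graph, q_max = 10) {
  adj <- as_adjacency(graph)
  ok <- !is.na(sizes)
  mu <- mean(sizes[ok])
  dev <- sizes - mu
  sigma <- sqrt(mean(dev[ok]^2))
  if (sigma == 0) stop("zero size variance: correlation undefined")
  nodes <- which(ok)
  shells_by_node <- lapply(nodes, function(i)
    neighbor_shells(adj, i, q_max = q_max))
  out <- data.frame(Q = seq_len(q_max), C = NA_real_, n_nodes = 0L)
  for (q in seq_len(q_max)) {
    yq <- rep(NA_real_, length(nodes))
    for (t in seq_along(nodes)) {
      sh <- shells_by_node[[t]][[as.character(q)]]
      sh <- sh[!is.na(sizes[sh])]
      if (length(sh) == 0) next
      yq[t] <- mean(dev[sh])
    }
    use <- !is.na(yq)
    if (sum(use) < 2) next
    d0 <- dev[nodes[use]]
    y0 <- yq[use]
    sy <- sqrt(mean((y0 - mean(y0))^2))
    if (sy == 0) next
    out$C[q] <- mean(d0 * y0) / (sigma * sy)
    out$n_nodes[q] <- sum(use)
  }
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Extract subregions of bounded network radius
#'
#' Every unmasked node serves as a candidate center; its subregion collects
#' all cells within network distance `Q0` (center included). When a target
#' mean is supplied, only subregions whose mean size lies within
#' `tolerance` of it are retained. Overlapping subregions are permitted and
#' pooled with multiplicity.
#'
#' @param sizes per-node sizes (`NA` = masked).
#' @param graph adjacency list or tessellation.
#' @param Q0 network radius of the subregions (>= 1).
#' @param target_mean retain only subregions with mean size near this value
#'   (`NULL` retains all).
#' @param tolerance half-width of the retention window.
#' @return list with `samples` (list of per-subregion size vectors),
#'   `pooled` (concatenation), `centers` (retained center nodes).
#' @export
extract_subregions <- function(sizes, graph, Q0, target_mean = NULL,
                               tolerance = NULL) {
  if (Q0 < 1) stop("Q0 must be at least 1")
  adj <- as_adjacency(graph)
  centers <- which(!is.na(sizes))
  samples <- list()
  kept <- integer(0)
  for (i in centers) {
    sh <- neighbor_shells(adj, i, q_max = Q0)
    members <- c(i, unlist(sh, use.names = FALSE))
    vals <- sizes[members]
    vals <- vals[!is.na(vals)]
    if (!is.null(target_mean) &&
        abs(mean(vals) - target_mean) > tolerance) next
    samples[[length(samples) + 1L]] <- vals
    kept <- c(kept, i)
  }
  if (length(samples) == 0)
    stop("no subregion satisfies the target-mean constraint")
  list(samples = samples, pooled = unlist(samples, use.names = FALSE),
       centers = kept)
}

#' Hexatic (six-fold bond-orientational) order parameter
#'
#' For each cell, its Delaunay neighbors are projected onto the local
#' tangent plane spanned by the two leading principal directions of the
#' neighbor point cloud; with polar angles `theta_j` of the neighbors, the
#' cell's order is the complex mean of `exp(6 i theta_j)`. The organism's
#' order parameter is the modulus of the population mean of those complex
#' values: 1 for a perfect hexagonal packing, near 0 for disorder.
#'
#' @param positions n x 3 positions (or a `cell_group`).
#' @param graph adjacency list or tessellation; defaults to the Delaunay
#'   adjacency of [surface_voronoi()] when a tessellation is given.
#' @return the scalar order parameter.
#' @export
psi6 <- function(positions, graph) {
  if (inherits(positions, "cell_group")) positions <- cell_centers(positions)
  positions <- as.matrix(positions)
  adj <- as_adjacency(graph)
  vals <- complex(0)
  for (i in seq_len(nrow(positions))) {
    nb <- adj[[i]]
    if (length(nb) < 3) next  # too few neighbors for a defined orientation
    cloud <- sweep(positions[nb, , drop = FALSE], 2, positions[i, ])
    sv <- svd(cloud, nu = 0, nv = 3)
    nrm <- sv$v[, 3]  # out-of-plane direction from the principal components
    # the in-plane basis must be consistent across cells (the leading
    # principal directions are degenerate for symmetric neighborhoods, which
    # would scramble the phases): project a fixed global axis onto the plane
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unitize(ref - sum(ref * nrm) * nrm)
    e2 <- cross3(nrm, e1)
    theta <- atan2(cloud %*% e2, cloud %*% e1)
    vals <- c(vals, mean(exp(6i * theta)))
  }
  if (length(vals) == 0) stop("no cell has 3 or more neighbors")
  Mod(mean(vals))
}
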