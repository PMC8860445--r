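# 3D Voronoi tessellation clipped to an extended convex hull, and surface
# Voronoi tessellation (solid angles) for cells on closed, star-shaped
# surfaces.

hull_planes <- function(vertices, faces) {
  com <- colMeans(vertices)
  planes <- matrix(NA_real_, nrow(faces), 4)
  for (f in seq_len(nrow(faces))) {
    v1 <- vertices[faces[f, 1], ]
    v2 <- vertices[faces[f, 2], ]
    v3 <- vertices[faces[f, 3], ]
    n <- cross3(v2 - v1, v3 - v1)
    nn <- vnorm(n)
    if (nn < 1e-14) next
    n <- n / nn
    d <- sum(n * v1)
    if (sum(n * com) > d) { n <- -n; d <- -d }
    planes[f, ] <- c(n, d)
  }
  planes[!is.na(planes[, 1]), , drop = FALSE]
}

hull_volume_from_faces <- function(vertices, faces) {
  com <- colMeans(vertices)
  vol <- 0
  for (f in seq_len(nrow(faces))) {
    a <- vertices[faces[f, 1], ] - com
    b <- vertices[faces[f, 2], ] - com
    cc <- vertices[faces[f, 3], ] - com
    vol <- vol + abs(sum(a * cross3(b, cc))) / 6
  }
  vol
}

#' Extended convex hull of a set of cell centers
#'
#' Computes the convex hull of the centers and displaces every hull vertex
#' radially outward from the group center of mass by `extend` (3 micrometres
#' by default), so that the boundary contains the whole of every cell, not
#' just its center.
#'
#' @param centers an n x 3 matrix of cell centers (n >= 4, not coplanar).
#' @param extend radial extension of the hull vertices, in the length unit
#'   of `centers`.
#' @return an object of class `boundary_hull`: list with `vertices`,
#'   `faces` (triangles), `planes` (rows `(nx, ny, nz, d)` with
#'   `n . x <= d` inside), `volume`, and `com`.
#' @export
extended_convex_hull <- function(centers, extend = 3) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 4) stop("need at least 4 cell centers")
  com <- colMeans(centers)
  faces <- cpp_convex_hull(centers)
  vidx <- sort(unique(as.vector(faces)))
  ext <- centers
  for (i in vidx) {
    rvec <- centers[i, ] - com
    rn <- vnorm(rvec)
    if (rn < 1e-12) stop("hull vertex coincides with the center of mass")
    ext[i, ] <- centers[i, ] + extend * rvec / rn
  }
  # re-hull the extended vertex set: radial extension of a non-spherical
  # hull can make individual vertices non-extremal
  everts <- ext[vidx, , drop = FALSE]
  efaces <- cpp_convex_hull(everts)
  structure(list(vertices = everts, faces = efaces,
                 planes = hull_planes(everts, efaces),
                 volume = hull_volume_from_faces(everts, efaces),
                 com = com),
            class = "boundary_hull")
}

#' Voronoi tessellation of cell centers clipped to a boundary hull
#'
#' Each cell's polyhedron is the intersection of its Voronoi half-spaces
#' (perpendicular-bisector planes against all other centers) with the
#' half-spaces of the boundary polyhedron `B`. Volumes come from convex
#' polyhedron decomposition; adjacency records which bisector planes
#' contribute faces.
#'
#' @param centers an n x 3 matrix of cell centers (duplicates are an error).
#' @param B a `boundary_hull` from [extended_convex_hull()]; computed with
#'   default extension when missing.
#' @param pad padding added to the farthest center distance to obtain the
#'   bounded seed radius.
#' @param keep_geometry keep per-cell polyhedron vertices and faces.
#' @return an object of class `tessellation3d`: `volumes`, `adjacency`
#'   (list of neighbor indices), `total_volume`, `hull`, and optionally
#'   `geometry`.
#' @export
clipped_voronoi_3d <- function(centers, B = NULL, pad = 5,
                               keep_geometry = FALSE) {
  centers <- as.matrix(centers)
  if (anyDuplicated(round(centers, 9))) stop("duplicate cell centers")
  if (is.null(B)) B <- extended_convex_hull(centers)
  com <- B$com
  cen0 <- sweep(centers, 2, com)
  bound <- max(sqrt(rowSums(cen0^2))) + pad
  planes <- B$planes
  planes[, 4] <- planes[, 4] - planes[, 1:3] %*% com
  res <- cpp_voronoi_cells(cen0, planes, bound, keep_geometry)
  geom <- res$geometry
  if (keep_geometry) {
    for (i in seq_along(geom))  # shift vertices back to input coordinates
      geom[[i]]$vertices <- sweep(geom[[i]]$vertices, 2, -com)
  }
  structure(list(volumes = as.numeric(res$volumes),
                 adjacency = res$neighbors,
                 total_volume = sum(res$volumes),
                 hull = B,
                 centers = centers,
                 geometry = geom),
            class = "tessellation3d")
}

#' @export
print.tessellation3d <- function(x, ...) {
  cat(sprintf("<tessellation3d> %d cells, total volume %.4g (hull %.4g)\n",
              length(x$volumes), x$total_volume, x$hull$volume))
  invisible(x)
}

#' Polyhedral membrane boundary
#'
#' For membrane-confined (palintomic) groups the natural tessellation
#' boundary is the membrane sphere itself. It is represented by the
#' circumscribed polyhedron of tangent planes at a deterministic Fibonacci
#' lattice of directions; with the default resolution its volume exceeds
#' the sphere's by well under 1 percent.
#'
#' @param radius membrane radius (membrane centered at the origin).
#' @param n_dirs number of tangent planes.
#' @return a `boundary_hull`-compatible object (planes, volume, com).
#' @export
membrane_boundary <- function(radius, n_dirs = 400) {
  stopifnot(radius > 0)
  i <- seq_len(n_dirs) - 1
  z <- 1 - (2 * i + 1) / n_dirs
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  planes <- cbind(dirs, radius)
  vol <- as.numeric(cpp_voronoi_cells(matrix(0, 1, 3), planes,
                                      radius * 1.5, FALSE)$volumes)
  structure(list(vertices = NULL, faces = NULL, planes = planes,
                 volume = vol, com = c(0, 0, 0), radius = radius),
            class = "boundary_hull")
}

#' Tessellate a cell group in one call
#'
#' Convenience wrapper choosing the boundary the way the analysis pipeline
#' does: membrane-confined groups are clipped to their membrane sphere
#' ([membrane_boundary()]); all other volumetric groups are clipped to the
#' extended convex hull of their cell centers. The default extension is
#' 3 micrometres for the budding-yeast-like morphology and 1.5 cell radii
#' otherwise (the same ratio of extension to transverse cell radius, with
#' margin so that the boundary contains the whole of every cell, including
#' cells sitting mid-face where vertex extension moves the boundary out by
#' less than the full extension).
#'
#' @param group a `cell_group`.
#' @param extend hull vertex extension; `NULL` picks the morphology default.
#' @param pad bounded-seed padding.
#' @param keep_geometry keep per-cell polyhedra.
#' @return a `tessellation3d`.
#' @export
tessellate_group <- function(group, extend = NULL, pad = 5,
                             keep_geometry = FALSE) {
  centers <- cell_centers(group)
  if (group$morphology == "palintomy" && !is.null(group$membrane_radius)) {
    B <- membrane_boundary(group$membrane_radius)
  } else {
    if (is.null(extend))
      extend <- if (group$morphology == "snowflake") 3 else
        1.5 * max(group$cells$a)
    B <- extended_convex_hull(centers, extend)
  }
  clipped_voronoi_3d(centers, B, pad = pad, keep_geometry = keep_geometry)
}

triangle_circumcenter <- function(a, b, cc) {
  u <- b - a; v <- cc - a
  e1 <- unitize(u)
  vperp <- v - sum(v * e1) * e1
  e2 <- unitize(vperp)
  bx <- vnorm(u)
  cx <- sum(v * e1); cy <- sum(v * e2)
  ux <- bx / 2
  uy <- (cx^2 + cy^2 - bx * cx) / (2 * cy)
  a + ux * e1 + uy * e2
}

polygon_area_3d <- function(pts) {
  # area of the polygon after projection onto its best-fit plane
  cen <- colMeans(pts)
  p0 <- sweep(pts, 2, cen)
  sv <- svd(p0, nu = 0, nv = 3)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  xy <- cbind(p0 %*% e1, p0 %*% e2)
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Surface Voronoi tessellation of cells on a closed surface
#'
#' Positions on a closed, star-shaped surface are normalized to the unit
#' sphere; the spherical Delaunay triangulation (the convex hull of the
#' normalized points) is mapped back onto the original surface. Voronoi
#' vertices are the circumcenters of the mapped triangles; each cell's
#' polygon collects the circumcenters of its incident triangles, ordered in
#' the cell's tangent frame, and is flattened to its best-fit plane before
#' the area is computed. Solid angles are `4 pi A_i / S` with `S` the total
#' area over unmasked cells.
#'
#' @param positions an n x 3 matrix of cell positions, or a `cell_group`.
#' @return an object of class `surface_tessellation`: `areas`,
#'   `solid_angles`, `polygons`, `adjacency` (Delaunay neighbors),
#'   `triangles`, `circumcenters`, `aspect_ratios` (circumradius over twice
#'   the inradius per triangle), `masked` (all `FALSE` initially),
#'   `total_area`.
#' @export
surface_voronoi <- function(positions) {
  if (inherits(positions, "cell_group")) positions <- cell_centers(positions)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  cen <- colMeans(positions)
  p0 <- sweep(positions, 2, cen)
  rr <- sqrt(rowSums(p0^2))
  if (any(rr < 1e-12)) stop("a position coincides with the surface centroid")
  unit <- p0 / rr
  tri <- cpp_convex_hull(unit)
  m <- nrow(tri)
  ccs <- matrix(NA_real_, m, 3)
  aspect <- numeric(m)
  for (f in seq_len(m)) {
    a <- positions[tri[f, 1], ]
    b <- positions[tri[f, 2], ]
    cc <- positions[tri[f, 3], ]
    ccs[f, ] <- triangle_circumcenter(a, b, cc)
    la <- vnorm(b - cc); lb <- vnorm(a - cc); lc <- vnorm(a - b)
    s <- (la + lb + lc) / 2
    area <- sqrt(max(s * (s - la) * (s - lb) * (s - lc), 0))
    inr <- area / s
    circ <- vnorm(ccs[f, ] - a)
    aspect[f] <- if (inr > 0) circ / (2 * inr) else Inf
  }
  incident <- vector("list", n)
  adjacency <- vector("list", n)
  for (f in seq_len(m)) {
    for (k in 1:3) {
      i <- tri[f, k]
      incident[[i]] <- c(incident[[i]], f)
      adjacency[[i]] <- c(adjacency[[i]], tri[f, -k])
    }
  }
  adjacency <- lapply(adjacency, function(v) sort(unique(v)))
  polygons <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    fs <- incident[[i]]
    if (length(fs) < 3) { areas[i] <- NA_real_; next }
    verts <- ccs[fs, , drop = FALSE]
    # order circumcenters by angle in the cell's tangent frame
    nrm <- unitize(unit[i, ])
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- unitize(cross3(nrm, ref)); t2 <- cross3(nrm, t1)
    rel <- sweep(verts, 2, positions[i, ])
    ang <- atan2(rel %*% t2, rel %*% t1)
    verts <- verts[order(ang), , drop = FALSE]
    polygons[[i]] <- verts
    areas[i] <- polygon_area_3d(verts)
  }
  S <- sum(areas, na.rm = TRUE)
  structure(list(areas = areas,
                 solid_angles = 4 * pi * areas / S,
                 polygons = polygons,
                 adjacency = adjacency,
                 triangles = tri,
                 circumcenters = ccs,
                 aspect_ratios = aspect,
                 masked = rep(FALSE, n),
                 total_area = S,
                 positions = positions),
            class = "surface_tessellation")
}

#' @export
print.surface_tessellation <- function(x, ...) {
  cat(sprintf(
    "<surface_tessellation> %d cells (%d masked), total solid angle %.4f sr\n",
    length(x$areas), sum(x$masked), sum(x$solid_angles[!x$masked],
                                        na.rm = TRUE)))
  invisible(x)
}

#' Mask Voronoi polygons adjacent to surface gaps
#'
#' Gaps in the cell layer (e.g. where interior structures displace surface
#' cells) show up as Delaunay triangles with exceptionally high aspect
#' ratio. Triangles with `circumradius / (2 inradius)` above the threshold
#' are flagged, and every Voronoi polygon touching a flagged triangle is
#' masked out of all downstream statistics. Surviving cells keep their
#' full-surface solid angles (masked cells become `NA`), so the masked sum
#' falls below `4 pi`.
#'
#' @param tess a `surface_tessellation`.
#' @param aspect_threshold flagging threshold (default 4).
#' @return the tessellation with an updated `masked` vector and solid angles.
#' @export
exclude_gaps <- function(tess, aspect_threshold = 4) {
  flagged <- which(tess$aspect_ratios > aspect_threshold)
  masked <- tess$masked
  for (f in flagged) masked[tess$triangles[f, ]] <- TRUE
  masked[is.na(tess$areas)] <- TRUE
  if (all(masked)) stop("aspect threshold masks every polygon")
  tess$masked <- masked
  tess$flagged_triangles <- flagged
  solid_angles(tess)
}

#' Solid angles of a surface tessellation
#'
#' Recomputes `Omega_i = 4 pi A_i / S`. By default `S` is the total area of
#' the closed surface (all polygons, masked or not), so excluding cells
#' leaves the survivors' solid angles unchanged and their sum below `4 pi`;
#' with `renormalize = TRUE` the masked area is dropped from `S` and the
#' surviving solid angles close to `4 pi` again. Masked cells get `NA`.
#'
#' @param tess a `surface_tessellation`.
#' @param renormalize drop masked polygons from the total area.
#' @return the tessellation with updated `solid_angles` and `total_area`.
#' @export
solid_angles <- function(tess, renormalize = FALSE) {
  ok <- !tess$masked & !is.na(tess$areas)
  S <- if (renormalize) sum(tess$areas[ok]) else
    sum(tess$areas, na.rm = TRUE)
  if (S <= 0) stop("total unmasked area is not positive")
  om <- rep(NA_real_, length(tess$areas))
  om[ok] <- 4 * pi * tess$areas[ok] / S
  tess$solid_angles <- om
  tess$total_area <- S
  tess
}

#' Bin cells of a 3D tessellation into radial shells
#'
#' Cells are assigned to spherical shells by the distance of their center
#' from the group center of mass. Cells beyond the last edge are assigned to
#' no shell and reported via the `unassigned` field.
#'
#' @param tess a `tessellation3d`.
#' @param edges strictly increasing shell edges starting at 0.
#' @return an object of class `shell_partition`: `membership` (shell index
#'   per cell, `NA` if beyond the last edge), `volumes` (list of per-shell
#'   Voronoi-volume vectors), `edges`, `unassigned`.
#' @export
shell_bin <- function(tess, edges) {
  if (edges[1] != 0 || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing from 0")
  com <- colMeans(tess$centers)
  r <- sqrt(rowSums(sweep(tess$centers, 2, com)^2))
  idx <- findInterval(r, edges, rightmost.closed = FALSE)
  idx[idx == length(edges)] <- NA  # beyond the last edge
  idx[idx == 0] <- 1
  vols <- lapply(seq_len(length(edges) - 1),
                 function(s) tess$volumes[!is.na(idx) & idx == s])
  structure(list(membership = idx, volumes = vols, edges = edges,
                 unassigned = which(is.na(idx))),
            class = "shell_partition")
}
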