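# Internal helpers: seeded RNG scoping, child-seed derivation, small vector
# algebra used by the growth models.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a root seed
#'
#' Ensembles use one root seed; each replicate `i` runs under
#' `child_seed(root, i)`. The map is a fixed affine counter modulo a prime
#' below 2^31, so ensembles are reproducible and order-independent.
#'
#' @param root integer root seed.
#' @param i replicate counter (1-based).
#' @return an integer seed.
#' @export
child_seed <- function(root, i) {
  as.integer((as.numeric(root) + 104729 * as.numeric(i)) %% 2147483629)
}

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Complete a right-handed orthonormal frame whose first column is e1.
frame_from_axis <- function(e1) {
  e1 <- unitize(e1)
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- unitize(cross3(e1, ref))
  e3 <- cross3(e1, e2)
  cbind(e1, e2, e3, deparse.level = 0)
}

# Uniform random rotation matrix (consumes RNG draws).
random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed, determinant +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

deg2rad <- function(x) x * pi / 180

# Direction on the unit sphere at polar angle theta (from +z) and azimuth phi,
# both in degrees, expressed in the frame given by columns of R (z = col 3).
sphere_dir_z <- function(theta_deg, phi_deg, R = diag(3)) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  as.numeric(R %*% u)
}
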