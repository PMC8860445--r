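# Swimming-speed calculations for spherical microswimmers whose surface
# actuation is expanded in Legendre-derivative modes. Both the slip-velocity
# (squirmer) and the shear-stress/no-slip descriptions make the swimming
# speed depend on the lowest surface mode only.

# P_n(x) and P'_n(x) by the standard three-term recurrence.
legendre_p <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  pm1 <- rep(1, length(x)); p <- x
  if (n == 1) return(p)
  for (m in 2:n) {
    pn <- ((2 * m - 1) * x * p - (m - 1) * pm1) / m
    pm1 <- p; p <- pn
  }
  p
}

legendre_dp <- function(n, x) {
  # (1 - x^2) P'_n = n (P_{n-1} - x P_n); endpoints by the closed form
  pn <- legendre_p(n, x)
  pnm1 <- legendre_p(n - 1, x)
  out <- numeric(length(x))
  interior <- abs(x) < 1 - 1e-12
  out[interior] <- n * (pnm1[interior] - x[interior] * pn[interior]) /
    (1 - x[interior]^2)
  out[!interior] <- sign(x[!interior])^(n + 1) * n * (n + 1) / 2
  out
}

#' Legendre-derivative surface basis functions
#'
#' `V_n(theta) = 2 / (n (n + 1)) * P'_n(cos theta) * sin theta`; the basis
#' for tangential surface fields that vanish at both poles. The lowest mode
#' is `V_1(theta) = sin(theta)`.
#'
#' @param n mode index (>= 1).
#' @param theta polar angle(s) in radians, in `[0, pi]`.
#' @return `V_n` evaluated at `theta`.
#' @export
basis_Vn <- function(n, theta) {
  stopifnot(n >= 1)
  2 / (n * (n + 1)) * legendre_dp(n, cos(theta)) * sin(theta)
}

#' Surface-mode expansion of a swimmer's actuation
#'
#' @param amplitudes mode amplitudes `u_n` (slip velocity, squirmer) or
#'   `f_n` (force density, shear-stress model), starting at `n = 1`.
#' @param model `"squirmer"` or `"shear_stress"`.
#' @param epsilon dimensionless forcing-shell thickness (shear-stress only).
#' @param R colony radius (shear-stress only).
#' @param mu fluid viscosity (shear-stress only).
#' @return an object of class `mode_expansion`.
#' @export
mode_expansion <- function(amplitudes, model = c("squirmer", "shear_stress"),
                           epsilon = NULL, R = NULL, mu = NULL) {
  model <- match.arg(model)
  if (length(amplitudes) < 1) stop("need at least the n = 1 amplitude")
  if (model == "shear_stress") {
    if (is.null(epsilon) || is.null(R) || is.null(mu))
      stop("shear-stress model requires epsilon, R and mu")
    stopifnot(epsilon > 0, R > 0, mu > 0)
  }
  structure(list(amplitudes = amplitudes, model = model,
                 epsilon = epsilon, R = R, mu = mu),
            class = "mode_expansion")
}

#' Swimming speed of a squirmer
#'
#' Computed two ways: the closed form `U = (2/3) u_1` (orthogonality kills
#' every higher mode), and Gauss-Legendre quadrature of
#' `U = (1/2) * integral of sin(theta) u_theta(theta) V_1(theta) dtheta`
#' with the full mode sum. Both are returned along with their difference.
#'
#' @param expansion a [mode_expansion()] with `model = "squirmer"`.
#' @param n_quad quadrature order.
#' @return list with `U` (closed form), `U_quadrature`, `difference`.
#' @export
swimming_speed_squirmer <- function(expansion, n_quad = 64) {
  stopifnot(expansion$model == "squirmer")
  u <- expansion$amplitudes
  U_closed <- 2 / 3 * u[1]
  gl <- pracma::gaussLegendre(n_quad, -1, 1)  # x = cos(theta)
  theta <- acos(gl$x)
  u_theta <- rep(0, length(theta))
  for (n in seq_along(u))
    u_theta <- u_theta + u[n] * basis_Vn(n, theta)
  # sin(theta) dtheta = -dx, so the integral becomes (1/2) int_-1^1 u V_1 dx
  U_quad <- 0.5 * sum(gl$w * u_theta * basis_Vn(1, theta))
  list(U = U_closed, U_quadrature = U_quad,
       difference = U_quad - U_closed)
}

#' Swimming speed in the shear-stress, no-slip model
#'
#' `U = 2 epsilon R f_1 / (3 mu)`: only the lowest mode of the applied
#' tangential force density moves the colony; higher modes contribute
#' nothing to the speed.
#'
#' @param expansion a [mode_expansion()] with `model = "shear_stress"`.
#' @return the swimming speed.
#' @export
swimming_speed_shear <- function(expansion) {
  stopifnot(expansion$model == "shear_stress")
  2 * expansion$epsilon * expansion$R * expansion$amplitudes[1] /
    (3 * expansion$mu)
}

#' Project a sampled tangential surface field onto the V_n basis
#'
#' Least-squares projection of samples `u_theta(theta)` onto
#' `{V_1, ..., V_nmax}`; the reconstruction residual is reported so that
#' under-resolved grids are visible.
#'
#' @param theta sample angles in radians.
#' @param values sampled tangential field.
#' @param n_max number of modes.
#' @return list with `amplitudes`, `residual` (RMS reconstruction error).
#' @export
project_onto_modes <- function(theta, values, n_max) {
  if (length(theta) < n_max)
    stop("grid too coarse for the requested number of modes")
  A <- sapply(seq_len(n_max), function(n) basis_Vn(n, theta))
  qrA <- qr(A)
  if (qrA$rank < n_max) stop("ill-conditioned grid: modes are confounded")
  amps <- qr.coef(qrA, values)
  resid <- sqrt(mean((values - A %*% amps)^2))
  list(amplitudes = as.numeric(amps), residual = resid)
}
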