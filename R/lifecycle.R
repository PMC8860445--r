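# Weakest-link fracture: the k-gamma packing distribution implies a
# geometric group-size survival law, and the fixed-N total-volume ensemble
# shows that whole-group volumes are themselves k-gamma distributed.

#' Probability that a cell is critically confined
#'
#' Under the packing model, a cell causes fracture when its neighborhood
#' volume falls below the critical volume `v_star`; the probability is the
#' lower tail of the k-gamma model, `p* = integral from v_c to v_star of
#' p(v) dv`, evaluated in closed form via the regularized lower incomplete
#' gamma function.
#'
#' @param model a [kgamma_model()].
#' @param v_star critical neighborhood volume (>= `v_c`, same units).
#' @return the probability `p*`.
#' @export
fracture_probability <- function(model, v_star) {
  if (any(v_star < model$v_c)) stop("v_star must be at least v_c")
  kgamma_cdf(v_star, model)
}

#' Weakest-link survival of an N-cell group
#'
#' Each of the N cells is independently confined below the critical volume
#' with probability `p_star`, so the group survives unfractured with
#' probability `P(N) = (1 - p_star)^N`.
#'
#' @param p_star per-cell confinement probability in `[0, 1]`.
#' @param N vector of cell counts.
#' @return `P(N)` for each `N`.
#' @export
survival_curve <- function(p_star, N) {
  stopifnot(p_star >= 0, p_star <= 1)
  (1 - p_star)^N
}

#' Group-size spectrum from measured volumes
#'
#' Converts whole-group volumes to inferred cell counts `N = V / v_c` and
#' bins them into unit-width count bins. Volumes below `debris_threshold`
#' cells are excluded before conversion.
#'
#' @param volumes measured group volumes (e.g. from a particle multisizer).
#' @param v_c single-cell volume in the same units.
#' @param debris_threshold minimum size in cells.
#' @return an object of class `size_spectrum`: data frame with `N` (bin
#'   center) and `count`.
#' @export
size_spectrum <- function(volumes, v_c, debris_threshold = 1) {
  N <- volumes / v_c
  N <- N[N >= debris_threshold]
  bin <- floor(N) + 0.5
  tab <- table(bin)
  out <- data.frame(N = as.numeric(names(tab)), count = as.integer(tab))
  class(out) <- c("size_spectrum", "data.frame")
  out
}

#' Weakest-link prediction of the group-size distribution
#'
#' The predicted counts are log-linear in N with slope `log(1 - p*)` fixed
#' by the packing model; only the amplitude is fitted, by least squares on
#' log counts over the non-empty bins. Returns the prediction and the
#' coefficient of determination of observed vs. predicted log counts.
#'
#' @param model a [kgamma_model()] for single-cell neighborhood volumes.
#' @param v_star critical neighborhood volume.
#' @param spectrum a [size_spectrum()].
#' @param fit_range optional `c(min_N, max_N)` restriction for the fit.
#' @return list with `p_star`, `slope` (`log(1 - p*)`), `amplitude`,
#'   `predicted` (data frame `N`, `log_count`), `r_squared`.
#' @export
predict_size_distribution <- function(model, v_star, spectrum,
                                      fit_range = NULL) {
  p_star <- fracture_probability(model, v_star)
  slope <- log(1 - p_star)
  obs <- spectrum[spectrum$count > 0, ]
  if (!is.null(fit_range))
    obs <- obs[obs$N >= fit_range[1] & obs$N <= fit_range[2], ]
  if (nrow(obs) < 3) stop("too few non-empty bins for a fit")
  y <- log(obs$count)
  amplitude <- mean(y - slope * obs$N)
  pred <- amplitude + slope * obs$N
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(p_star = p_star, slope = slope, amplitude = amplitude,
       predicted = data.frame(N = obs$N, log_count = pred),
       observed = data.frame(N = obs$N, log_count = y),
       r_squared = 1 - ss_res / ss_tot)
}

#' Total-volume ensemble of fixed-size tree-like groups
#'
#' Grows `n_groups` budding groups to exactly `n_cells` cells each,
#' measures each group's total volume as the volume of the convex hull of
#' its cell centers (no tessellation padding: the group volume is the
#' smallest hull), normalizes by the minimum possible volume `N v_c`, and
#' moment-matches a k-gamma model with minimum 1 (in units of `N v_c`).
#'
#' @param n_groups number of groups.
#' @param n_cells cells per group.
#' @param cfg a [morphology_config()].
#' @param seed root seed; groups use [child_seed()] streams. Groups whose
#'   growth saturates before reaching `n_cells` are regrown from a fresh
#'   child seed.
#' @param extend hull extension (micrometres).
#' @return list with `volumes` (normalized total volumes), `model`
#'   (a `kgamma_model`), `v_c` (single-cell volume), `retries`.
#' @export
total_volume_ensemble <- function(n_groups, n_cells = 100,
                                  cfg = morphology_config(), seed = 1L,
                                  extend = 0) {
  v_c <- 4 * pi / 3 * cfg$semi_major * cfg$semi_minor^2
  cfg$target_cells <- n_cells
  volumes <- numeric(n_groups)
  retries <- 0L
  for (g in seq_len(n_groups)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      grp <- grow_snowflake(cfg, seed = child_seed(seed,
                                                   g + retries * n_groups))
      if (nrow(grp$cells) >= n_cells) break
      retries <- retries + 1L
      if (attempt > 20L) stop("growth repeatedly saturated below n_cells")
    }
    hull <- extended_convex_hull(cell_centers(grp), extend = extend)
    volumes[g] <- hull$volume / (n_cells * v_c)
  }
  list(volumes = volumes, model = estimate_kgamma(volumes, 1),
       v_c = v_c, retries = retries)
}
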