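#' Mechanics configuration for overdamped relaxation
#'
#' Spring constants and integration parameters for the harmonic force laws
#' used during mechanical relaxation of growing groups. Only equilibrium
#' geometry matters downstream, so all spring constants default to 1.
#'
#' @param kappa_steric harmonic repulsion constant (force/length).
#' @param kappa_adhesive harmonic adhesion constant.
#' @param kappa_membrane membrane confinement constant (force/volume).
#' @param kappa_bond fixed-bond (chitin-like) spring constant.
#' @param well_position dimensionless adhesive well position `a` in (0, 1];
#'   the adhesive force is `kappa_adhesive * (|r| - a (Ri + Rj))` on the
#'   branch `(Ri+Rj) <= |r| <= 2 (Ri+Rj)`, zero elsewhere.
#' @param bond_rest_length rest length of the scar-to-scar bond spring.
#' @param step_size explicit-Euler time step (mobility is 1).
#' @param displacement_tol convergence threshold on the largest per-cell
#'   displacement in one step.
#' @param max_iters iteration cap; non-convergence is flagged, never silent.
#' @return an object of class `mechanics_config`.
#' @export
mechanics_config <- function(kappa_steric = 1, kappa_adhesive = 1,
                             kappa_membrane = 1, kappa_bond = 1,
                             well_position = 0.9, bond_rest_length = 2,
                             step_size = 0.01, displacement_tol = 1e-4,
                             max_iters = 1e5) {
  stopifnot(kappa_steric > 0, kappa_adhesive > 0, kappa_membrane > 0,
            kappa_bond > 0, step_size > 0, displacement_tol > 0,
            max_iters >= 1)
  if (well_position <= 0 || well_position > 1)
    stop("well_position must lie in (0, 1]")
  structure(list(kappa_steric = kappa_steric,
                 kappa_adhesive = kappa_adhesive,
                 kappa_membrane = kappa_membrane,
                 kappa_bond = kappa_bond,
                 well_position = well_position,
                 bond_rest_length = bond_rest_length,
                 step_size = step_size,
                 displacement_tol = displacement_tol,
                 max_iters = as.integer(max_iters)),
            class = "mechanics_config")
}

check_pair <- function(cell_i, cell_j) {
  r <- cell_j$center - cell_i$center
  d <- vnorm(r)
  if (d < 1e-12) stop("degenerate geometry: coincident cell centers")
  list(r = r, d = d, rhat = r / d, sumR = cell_i$radius + cell_j$radius)
}

#' Harmonic steric repulsion between two spherical cells
#'
#' Zero beyond contact; for overlapping cells the force on `cell_i` has
#' magnitude `kappa_steric * (|r_ij| - (Ri + Rj))` directed along the
#' center-to-center axis (repulsive, antisymmetric between the pair).
#'
#' @param cell_i,cell_j lists with fields `center` (3-vector) and `radius`.
#' @param cfg a [mechanics_config()].
#' @return 3-vector force on `cell_i`.
#' @export
steric_force <- function(cell_i, cell_j, cfg = mechanics_config()) {
  g <- check_pair(cell_i, cell_j)
  if (g$d > g$sumR) return(c(0, 0, 0))
  cfg$kappa_steric * (g$d - g$sumR) * g$rhat
}

#' Harmonic adhesion between two spherical cells
#'
#' Active only on the branch `(Ri+Rj) <= |r_ij| <= 2 (Ri+Rj)`; there the
#' force on `cell_i` is `kappa_adhesive * (|r_ij| - a (Ri+Rj))` directed
#' toward the partner (attractive for separations beyond the well at
#' `a (Ri+Rj)`). The overlap branch is identically zero even though the well
#' position `a < 1` lies inside it; the resulting discontinuity at contact is
#' part of the model definition.
#'
#' @inheritParams steric_force
#' @return 3-vector force on `cell_i`.
#' @export
adhesive_force <- function(cell_i, cell_j, cfg = mechanics_config()) {
  g <- check_pair(cell_i, cell_j)
  if (g$d < g$sumR || g$d > 2 * g$sumR) return(c(0, 0, 0))
  cfg$kappa_adhesive * (g$d - cfg$well_position * g$sumR) * g$rhat
}

#' Membrane confinement force
#'
#' A cell touching or crossing a spherical membrane (centered at the origin)
#' is pushed back toward the membrane center with magnitude proportional to
#' the cell volume lying outside the membrane: `kappa_membrane * (v_c - v_i)`
#' where `v_i` is the exact sphere-sphere intersection (lens) volume of the
#' cell with the membrane interior. Zero for cells fully inside.
#'
#' @param cell list with `center` and `radius`.
#' @param membrane_radius radius of the confining membrane (> 0).
#' @param cfg a [mechanics_config()].
#' @return 3-vector force on the cell.
#' @export
membrane_force <- function(cell, membrane_radius, cfg = mechanics_config()) {
  if (membrane_radius <= 0) stop("membrane_radius must be positive")
  d <- vnorm(cell$center)
  vc <- 4 * pi / 3 * cell$radius^3
  vi <- cpp_lens_volume(cell$radius, membrane_radius, d)
  mag <- cfg$kappa_membrane * (vc - vi)
  if (mag <= 0 || d < 1e-12) return(c(0, 0, 0))
  -mag * cell$center / d
}

#' Fixed-bond (scar-to-scar) force
#'
#' Mother and daughter remain connected by a spring between the mother's bud
#' scar and the daughter's birth scar, both tracked in world coordinates.
#' The force on the daughter has magnitude
#' `kappa_bond * (|r| - bond_rest_length)` along the scar-to-scar vector
#' (restoring), and the mother feels the opposite force.
#'
#' @param cell list with field `birth_scar` (world coordinates), the daughter.
#' @param partner list with field `bud_scar` (world coordinates), the mother.
#' @param cfg a [mechanics_config()].
#' @return 3-vector force on `cell` (the daughter).
#' @export
bond_force <- function(cell, partner, cfg = mechanics_config()) {
  if (is.null(cell$birth_scar) || is.null(partner$bud_scar))
    stop("bond_force requires birth_scar and bud_scar positions")
  r <- cell$birth_scar - partner$bud_scar
  d <- vnorm(r)
  if (d < 1e-12) {
    if (cfg$bond_rest_length == 0) return(c(0, 0, 0))
    stop("degenerate geometry: coincident scars with nonzero rest length")
  }
  -cfg$kappa_bond * (d - cfg$bond_rest_length) * (r / d)
}

#' Relax a cell group under overdamped dynamics
#'
#' Explicit-Euler integration of `x <- x + F dt` (mobility 1) until the
#' largest per-cell displacement in a step falls below
#' `cfg$displacement_tol`, or `cfg$max_iters` steps have run. Deterministic
#' given its inputs. Non-convergence is flagged on the returned group.
#'
#' @param group a `cell_group` (see [grow_aggregate()] and friends).
#' @param cfg a [mechanics_config()].
#' @param forces character vector choosing the active force laws, any of
#'   `"steric"`, `"adhesive"`, `"membrane"`, `"bond"`.
#' @param membrane_radius membrane radius, required when `"membrane"` is
#'   active; defaults to `group$membrane_radius`.
#' @return the group with updated cell centers, plus `converged` and
#'   `iterations` fields.
#' @export
relax_overdamped <- function(group, cfg = mechanics_config(),
                             forces = c("steric", "adhesive"),
                             membrane_radius = group$membrane_radius) {
  pos <- as.matrix(group$cells[, c("x", "y", "z")])
  radii <- group$cells$a  # spherical cells: a = b = c
  use_membrane <- "membrane" %in% forces
  if (use_membrane && (is.null(membrane_radius) || membrane_radius <= 0))
    stop("membrane force requested but no valid membrane_radius")
  bonds <- matrix(integer(0), 0, 2)
  offs <- matrix(numeric(0), 0, 6)
  if ("bond" %in% forces && !is.null(group$bond_offsets)) {
    bonds <- group$bond_offsets$pairs      # columns: mother row, daughter row
    offs <- group$bond_offsets$offsets     # daughter scar xyz, mother scar xyz
  }
  res <- cpp_relax(pos, radii,
                   "steric" %in% forces, cfg$kappa_steric,
                   "adhesive" %in% forces, cfg$kappa_adhesive,
                   cfg$well_position,
                   use_membrane,
                   if (use_membrane) membrane_radius else 1,
                   cfg$kappa_membrane,
                   bonds, offs, cfg$kappa_bond, cfg$bond_rest_length,
                   cfg$step_size, cfg$displacement_tol, cfg$max_iters)
  group$cells$x <- res$positions[, 1]
  group$cells$y <- res$positions[, 2]
  group$cells$z <- res$positions[, 3]
  group$converged <- res$converged
  group$iterations <- res$iterations
  if (!res$converged)
    warning("relaxation did not converge within max_iters (flagged on group)")
  group
}
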