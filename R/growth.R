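#' Morphology configuration for growth simulations
#'
#' One configuration object covers all growth protocols; each grower reads
#' the fields relevant to it. Angles are in degrees, lengths in the model's
#' length unit (micrometres for the budding-yeast-like protocol, cell radii
#' for the unit-sphere protocols).
#'
#' @param generations number of division rounds (grower defaults apply when
#'   `NULL`: 7 for tree-like budding, 6 for aggregates and palintomy, 5 for
#'   patterned growth).
#' @param target_cells grow until exactly this many cells (tree-like budding
#'   only); overrides `generations`-limited growth.
#' @param theta polar angle of the budding ring, degrees.
#' @param theta_spread uniform half-width of the budding-ring angle for
#'   aggregative growth, degrees.
#' @param distal_first_prob probability that a cell's first bud appears at
#'   the distal pole rather than on the budding ring.
#' @param distal_spread polar half-width of the distal-pole bud site, degrees.
#' @param proximal_switch_after number of bud scars after which proximal
#'   (back-)budding becomes possible.
#' @param proximal_prob probability of a proximal bud once enabled.
#' @param bud_exclusion_distance candidate buds whose scar falls within this
#'   distance of an existing scar are eliminated (micrometres).
#' @param semi_major,semi_minor prolate cell semi-axes a and b = c,
#'   micrometres.
#' @param noise_eta placement noise half-width for patterned growth, degrees.
#' @param polydispersity_xi probability that a daughter inherits its mother's
#'   radius in bidisperse aggregative growth.
#' @param radius_small,radius_large the two radii of bidisperse growth.
#' @param cell_radius radius of monodisperse spherical cells.
#' @param packing_fraction palintomy: the membrane radius is reset after each
#'   division round so that `N v_cell / V_membrane` equals this value.
#' @param min_separation minimum chord separation for sphere-surface Poisson
#'   sampling.
#' @param surface_cell_radius cell radius for sphere-surface groups (unit
#'   sphere).
#' @param apoptosis_radius localization radius of the cell-death region.
#' @param apoptosis_deaths number of additional flagged cells that die.
#' @return an object of class `morphology_config`.
#' @export
morphology_config <- function(generations = NULL, target_cells = NULL,
                              theta = 45, theta_spread = 15,
                              distal_first_prob = 0.8, distal_spread = 10,
                              proximal_switch_after = 3, proximal_prob = 0.5,
                              bud_exclusion_distance = 1.2,
                              semi_major = 2.88, semi_minor = 2.29,
                              noise_eta = 0, polydispersity_xi = 1,
                              radius_small = 1, radius_large = 2,
                              cell_radius = 1, packing_fraction = 0.5,
                              min_separation = 0.088,
                              surface_cell_radius = 0.1980,
                              apoptosis_radius = 1, apoptosis_deaths = 9,
                              aggregate_placement = c("uniform", "ring")) {
  aggregate_placement <- match.arg(aggregate_placement)
  probs <- c(distal_first_prob, proximal_prob, polydispersity_xi)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (theta < 0 || theta >= 360) stop("theta must lie in [0, 360)")
  stopifnot(semi_major > 0, semi_minor > 0, cell_radius > 0,
            radius_small > 0, radius_large > 0,
            packing_fraction > 0, packing_fraction < 1)
  structure(as.list(environment()), class = "morphology_config")
}

# Direct interface to the compiled relaxation loop (positions in, positions
# out); used inside the growth loops where relaxation interleaves with cell
# placement.
relax_positions <- function(pos, radii, mech, forces,
                            membrane_radius = NULL,
                            pairs = NULL, offsets = NULL) {
  if (is.null(pairs)) {
    pairs <- matrix(integer(0), 0, 2)
    offsets <- matrix(numeric(0), 0, 6)
  }
  use_membrane <- "membrane" %in% forces
  cpp_relax(pos, radii,
            "steric" %in% forces, mech$kappa_steric,
            "adhesive" %in% forces, mech$kappa_adhesive,
            mech$well_position,
            use_membrane, if (use_membrane) membrane_radius else 1,
            mech$kappa_membrane,
            pairs, offsets, mech$kappa_bond, mech$bond_rest_length,
            mech$step_size, mech$displacement_tol, mech$max_iters)
}

# Assemble the standard cell table from internal growth state.
build_group <- function(pos, radii_a, radii_b, frames, mothers, scars,
                        morphology, seed, bonds = NULL,
                        membrane_radius = NULL, bond_offsets = NULL,
                        cell_volume = NULL, converged = TRUE) {
  n <- nrow(pos)
  rot <- t(vapply(frames, function(R) as.numeric(t(R)), numeric(9)))
  cells <- data.frame(id = seq_len(n) - 1L,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      a = radii_a, b = radii_b, c = radii_b)
  colnames(rot) <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  cells <- cbind(cells, rot)
  cells$mother_id <- mothers
  cells$scar_x <- scars[, 1]
  cells$scar_y <- scars[, 2]
  cells$scar_z <- scars[, 3]
  if (is.null(bonds)) {
    has_mother <- !is.na(mothers)
    bonds <- cbind(mother = mothers[has_mother],
                   daughter = cells$id[has_mother])
  }
  g <- structure(list(cells = cells, bonds = bonds, morphology = morphology,
                      membrane_radius = membrane_radius, seed = seed,
                      bond_offsets = bond_offsets,
                      cell_volume = cell_volume, converged = converged),
                 class = "cell_group")
  if (!converged)
    warning("relaxation failed to converge in at least one round")
  g
}

#' @export
print.cell_group <- function(x, ...) {
  cat(sprintf("<cell_group> %s: %d cells, %d bonds, seed %s\n",
              x$morphology, nrow(x$cells), nrow(x$bonds),
              format(x$seed)))
  invisible(x)
}

#' Cell centers of a group
#' @param group a `cell_group`.
#' @return an n x 3 matrix of Cartesian centers.
#' @export
cell_centers <- function(group) {
  as.matrix(group$cells[, c("x", "y", "z")])
}

#' Simulate tree-like growth by budding with persistent bonds
#'
#' Prolate cells reproduce by budding; mother and daughter stay rigidly
#' attached at the bud site, so the group is a tree frozen in its growth
#' configuration (no mechanical relaxation). Each generation every cell
#' attempts one bud. A cell's first bud appears at the distal pole (polar
#' angle uniform within `distal_spread` of 0) with probability
#' `distal_first_prob`, otherwise on the budding ring at polar angle `theta`;
#' subsequent buds use the ring. Once a cell carries
#' `proximal_switch_after` bud scars, each new bud is reflected to the
#' proximal side (180 - theta) with probability `proximal_prob`. Azimuths
#' are uniform. Candidates that closely overlap existing cells are
#' eliminated: a bud whose scar falls within `bud_exclusion_distance` of an
#' existing scar, or whose center would lie inside an existing cell's
#' ellipsoid, never appears. The
#' daughter's major axis lies along the mother-surface normal at the bud
#' site, attached at the daughter's proximal pole.
#'
#' @param cfg a [morphology_config()].
#' @param seed integer seed; identical `(cfg, seed)` give identical groups.
#' @return a `cell_group` with morphology `"snowflake"`.
#' @export
grow_snowflake <- function(cfg = morphology_config(), seed = 1L) {
  generations <- if (is.null(cfg$generations)) 7L else cfg$generations
  g <- with_seed(seed,
    snowflake_engine(cfg, generations, target_cells = cfg$target_cells))
  build_group(g$pos, rep(cfg$semi_major, nrow(g$pos)),
              rep(cfg$semi_minor, nrow(g$pos)),
              g$frames, g$mothers, g$scars, "snowflake", seed,
              cell_volume = 4 * pi / 3 * cfg$semi_major * cfg$semi_minor^2)
}

snowflake_engine <- function(cfg, generations, target_cells = NULL) {
  a <- cfg$semi_major; b <- cfg$semi_minor
  ax <- c(a, b, b)
  pos <- matrix(0, 1, 3)
  frames <- list(random_rotation())
  mothers <- NA_integer_
  nbuds <- 0L
  scars <- matrix(NA_real_, 1, 3)        # per-cell birth scar (root has none)
  scar_sites <- matrix(numeric(0), 0, 3) # all bud sites, for exclusion
  gen <- 0L
  repeat {
    gen <- gen + 1L
    if (is.null(target_cells) && gen > generations) break
    if (!is.null(target_cells) && gen > 50L) break
    idx <- seq_len(nrow(pos))
    if (!is.null(target_cells)) idx <- sample(idx)
    added <- 0L
    for (i in idx) {
      if (!is.null(target_cells) && nrow(pos) >= target_cells) break
      nb <- nbuds[i]
      if (nb == 0L) {
        theta <- if (runif(1) < cfg$distal_first_prob)
          runif(1, 0, cfg$distal_spread) else cfg$theta
      } else {
        theta <- cfg$theta
      }
      if (nb >= cfg$proximal_switch_after && runif(1) < cfg$proximal_prob)
        theta <- 180 - theta
      phi <- runif(1, 0, 360)
      th <- deg2rad(theta); ph <- deg2rad(phi)
      u <- c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph)) # from major axis
      R <- frames[[i]]
      site <- pos[i, ] + as.numeric(R %*% (ax * u))
      if (nrow(scar_sites) > 0) {
        d2 <- (scar_sites[, 1] - site[1])^2 + (scar_sites[, 2] - site[2])^2 +
          (scar_sites[, 3] - site[3])^2
        if (min(d2) < cfg$bud_exclusion_distance^2) next  # bud eliminated
      }
      normal <- unitize(as.numeric(R %*% (u / ax)))
      newpos <- site + a * normal
      # a bud whose center falls inside an existing cell body is a close
      # overlap and is eliminated as well
      dc2 <- (pos[, 1] - newpos[1])^2 + (pos[, 2] - newpos[2])^2 +
        (pos[, 3] - newpos[3])^2
      inside <- FALSE
      for (j in which(dc2 < a^2)) {
        y <- crossprod(frames[[j]], newpos - pos[j, ])
        if (sum((y / ax)^2) < 1) { inside <- TRUE; break }
      }
      if (inside) next
      pos <- rbind(pos, newpos)
      frames[[length(frames) + 1L]] <- frame_from_axis(normal)
      mothers <- c(mothers, i - 1L)
      nbuds <- c(nbuds, 0L)
      nbuds[i] <- nb + 1L
      scars <- rbind(scars, site)
      scar_sites <- rbind(scar_sites, site)
      added <- added + 1L
    }
    if (!is.null(target_cells)) {
      if (nrow(pos) >= target_cells) break
      if (added == 0L) break  # saturated: caller decides whether to retry
    }
  }
  list(pos = pos, frames = frames, mothers = mothers, scars = scars,
       nbuds = nbuds)
}

frame_with_z <- function(dir) {
  f <- frame_from_axis(dir)
  cbind(f[, 2], f[, 3], f[, 1], deparse.level = 0)
}

# Shared engine for aggregative growth (mono- or bidisperse): one daughter
# per cell per generation, placed in contact on the mother's surface, with a
# quasi-static steric + adhesive relaxation after every single division.
aggregate_engine <- function(cfg, generations, start_radii, mech,
                             daughter_radius = NULL) {
  nseed <- length(start_radii)
  pos <- if (nseed == 1) matrix(0, 1, 3) else
    rbind(c(0, 0, 0), c(sum(start_radii), 0, 0))  # contacting pair
  radii <- start_radii
  frames <- replicate(nseed, random_rotation(), simplify = FALSE)
  mothers <- rep(NA_integer_, nseed)
  scars <- matrix(NA_real_, nseed, 3)
  converged <- TRUE
  for (gen in seq_len(generations)) {
    for (i in seq_len(nrow(pos))) {
      if (cfg$aggregate_placement == "ring") {
        theta <- cfg$theta + runif(1, -cfg$theta_spread, cfg$theta_spread)
        phi <- runif(1, 0, 360)
        dir <- sphere_dir_z(theta, phi, frames[[i]])
      } else {
        z <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
        dir <- c(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
      }
      rd <- if (is.null(daughter_radius)) radii[i] else
        daughter_radius(radii[i])
      scars <- rbind(scars, pos[i, ] + radii[i] * dir)
      pos <- rbind(pos, pos[i, ] + (radii[i] + rd) * dir)
      radii <- c(radii, rd)
      frames[[length(frames) + 1L]] <- frame_with_z(dir)
      mothers <- c(mothers, i - 1L)
      res <- relax_positions(pos, radii, mech, c("steric", "adhesive"))
      pos <- res$positions
      converged <- converged && res$converged
    }
  }
  list(pos = pos, radii = radii, frames = frames, mothers = mothers,
       scars = scars, converged = converged)
}

#' Simulate aggregative growth with sticky, reformable bonds
#'
#' Spherical cells divide once per generation; each daughter appears in
#' contact on its mother's surface, by default at a uniformly random
#' position (set `aggregate_placement = "ring"` to bud at polar angle
#' `theta +/- theta_spread` in the mother's frame instead). After every
#' single division the group relaxes quasi-statically under harmonic
#' steric repulsion and bonded harmonic adhesion ([steric_force()],
#' [adhesive_force()]; adhesive bonds form on contact and break beyond
#' twice the contact distance) in overdamped dynamics.
#'
#' @inheritParams grow_snowflake
#' @param mech a [mechanics_config()].
#' @return a `cell_group` with morphology `"aggregate"`.
#' @export
grow_aggregate <- function(cfg = morphology_config(), seed = 1L,
                           mech = mechanics_config()) {
  generations <- if (is.null(cfg$generations)) 6L else cfg$generations
  r <- cfg$cell_radius
  st <- with_seed(seed,
    aggregate_engine(cfg, generations, start_radii = r, mech = mech))
  build_group(st$pos, st$radii, st$radii, st$frames, st$mothers,
              st$scars, "aggregate", seed,
              cell_volume = 4 * pi / 3 * r^3, converged = st$converged)
}

#' Simulate bidisperse aggregative growth
#'
#' As [grow_aggregate()], but with two cell radii. Growth is seeded with one
#' contacting pair, one cell of each radius. Each daughter inherits its
#' mother's radius with probability `polydispersity_xi`, and takes the other
#' radius otherwise.
#'
#' @inheritParams grow_aggregate
#' @return a `cell_group` with morphology `"aggregate"` and bidisperse radii.
#' @export
grow_polydisperse <- function(cfg = morphology_config(), seed = 1L,
                              mech = mechanics_config()) {
  xi <- cfg$polydispersity_xi
  if (xi < 0 || xi > 1) stop("polydispersity_xi must lie in [0, 1]")
  generations <- if (is.null(cfg$generations)) 5L else cfg$generations
  r1 <- cfg$radius_small; r2 <- cfg$radius_large
  daughter_radius <- function(rm) {
    other <- if (rm == r1) r2 else r1
    if (runif(1) < xi) rm else other
  }
  st <- with_seed(seed,
    aggregate_engine(cfg, generations, start_radii = c(r1, r2), mech = mech,
                     daughter_radius = daughter_radius))
  build_group(st$pos, st$radii, st$radii, st$frames, st$mothers,
              st$scars, "aggregate", seed,
              cell_volume = 4 * pi / 3 * r1^3, converged = st$converged)
}

#' Simulate palintomy: repeated division inside a confining membrane
#'
#' Unit spherical cells divide synchronously inside a spherical membrane.
#' After each division round the membrane radius is reset so that the
#' packing fraction `N v_cell / V_membrane` equals `packing_fraction`, and
#' the group relaxes under steric repulsion plus the membrane confinement
#' force ([membrane_force()]). Daughters are placed half-overlapping their
#' mothers in a uniformly random direction, mimicking division in place.
#'
#' @inheritParams grow_aggregate
#' @return a `cell_group` with morphology `"palintomy"`; the final membrane
#'   radius is stored in `membrane_radius`.
#' @export
grow_palintomy <- function(cfg = morphology_config(), seed = 1L,
                           mech = mechanics_config()) {
  generations <- if (is.null(cfg$generations)) 6L else cfg$generations
  r <- cfg$cell_radius
  phi0 <- cfg$packing_fraction
  st <- with_seed(seed, {
    pos <- matrix(0, 1, 3)
    radii <- r
    frames <- list(random_rotation())
    mothers <- NA_integer_
    scars <- matrix(NA_real_, 1, 3)
    converged <- TRUE
    membrane_radius <- r / phi0^(1 / 3)
    for (gen in seq_len(generations)) {
      for (i in seq_len(nrow(pos))) {
        z <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
        dir <- c(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
        scars <- rbind(scars, pos[i, ] + r * dir / 2)
        pos <- rbind(pos, pos[i, ] + r * dir)  # half-overlap: divide in place
        radii <- c(radii, r)
        frames[[length(frames) + 1L]] <- frame_with_z(dir)
        mothers <- c(mothers, i - 1L)
      }
      # synchronous division round; membrane reset precedes relaxation
      membrane_radius <- r * (nrow(pos) / phi0)^(1 / 3)
      res <- relax_positions(pos, radii, mech, c("steric", "membrane"),
                             membrane_radius = membrane_radius)
      pos <- res$positions
      converged <- converged && res$converged
    }
    list(pos = pos, radii = radii, frames = frames, mothers = mothers,
         scars = scars, converged = converged,
         membrane_radius = membrane_radius)
  })
  build_group(st$pos, st$radii, st$radii, st$frames, st$mothers,
              st$scars, "palintomy", seed,
              membrane_radius = st$membrane_radius,
              cell_volume = 4 * pi / 3 * r^3, converged = st$converged)
}

#' Place cells on the unit sphere by a hard-core Poisson process
#'
#' Uniform random points on the unit sphere are accepted one at a time;
#' a candidate closer (Euclidean chord distance) than `d` to any accepted
#' point is rejected and redrawn, until `n` points are placed.
#'
#' @param n number of cells.
#' @param d minimum chord separation.
#' @param seed integer seed.
#' @param cell_radius nominal cell radius recorded on the group (`d/2` by
#'   default, so accepted cells never overlap).
#' @param max_tries rejection budget per attempt; exceeding it discards the
#'   partial configuration (sequential placement can jam near full
#'   coverage) and restarts.
#' @param max_restarts restart budget; exceeding it signals saturation.
#' @return a `cell_group` with morphology `"sphere_surface"`.
#' @export
sample_sphere_poisson <- function(n, d = 0.088, seed = 1L,
                                  cell_radius = d / 2, max_tries = 1000 * n,
                                  max_restarts = 20L) {
  pos <- with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      pos <- matrix(NA_real_, n, 3)
      placed <- 0L
      tries <- 0L
      while (placed < n && tries <= max_tries) {
        tries <- tries + 1L
        z <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
        p <- c(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
        if (placed > 0L) {
          d2 <- (pos[seq_len(placed), 1] - p[1])^2 +
            (pos[seq_len(placed), 2] - p[2])^2 +
            (pos[seq_len(placed), 3] - p[3])^2
          if (min(d2) < d^2) next
        }
        placed <- placed + 1L
        pos[placed, ] <- p
      }
      if (placed == n) break
      pos <- NULL  # jammed: discard and restart
    }
    if (is.null(pos))
      stop(sprintf(paste0("sphere saturated: could not place %d points at ",
                          "separation %.4g within the restart budget"),
                   n, d))
    pos
  })
  frames <- replicate(n, diag(3), simplify = FALSE)
  build_group(pos, rep(cell_radius, n), rep(cell_radius, n), frames,
              rep(NA_integer_, n), matrix(NA_real_, n, 3),
              "sphere_surface", seed)
}

#' Simulate patterned tree-like growth with placement noise
#'
#' Unit spherical cells bud up to three daughters, one per generation, at
#' prescribed sites in the mother's own frame: the first at polar angle
#' 0 and azimuth 0, the second at (90, 90), the third at (90, 270) degrees,
#' each coordinate perturbed by independent uniform noise of half-width
#' `noise_eta`. Each daughter's frame is its mother's rotated by
#' `Rz(90 + noise)` about the mother's z-axis. Mother-daughter pairs stay
#' connected by chitin-like bond springs holding their centers at the
#' contact distance (a zero-rest-length spring between the coincident bud
#' and birth scars, see [bond_force()]); after every
#' division round the group relaxes under steric plus bond forces. At zero
#' noise some prescribed sites coincide exactly with existing cells; such
#' buds are removed at creation (they are the overlapping cells of the
#' noise-free pattern).
#'
#' @inheritParams grow_aggregate
#' @return a `cell_group` with morphology `"patterned"`.
#' @export
grow_patterned <- function(cfg = morphology_config(), seed = 1L,
                           mech = mechanics_config()) {
  generations <- if (is.null(cfg$generations)) 5L else cfg$generations
  eta <- cfg$noise_eta
  r <- cfg$cell_radius
  site_angles <- list(c(0, 0), c(90, 90), c(90, 270))
  st <- with_seed(seed, {
    pos <- matrix(0, 1, 3)
    frames <- list(diag(3))
    mothers <- NA_integer_
    nbuds <- 0L
    scars <- matrix(NA_real_, 1, 3)
    pairs <- matrix(integer(0), 0, 2)
    offsets <- matrix(numeric(0), 0, 6)
    converged <- TRUE
    for (gen in seq_len(generations)) {
      for (i in seq_len(nrow(pos))) {
        if (nbuds[i] >= 3L) next
        k <- nbuds[i] + 1L
        nn <- runif(3, -eta, eta)  # theta, phi, frame-rotation noise
        ang <- site_angles[[k]]
        dir <- sphere_dir_z(ang[1] + nn[1], ang[2] + nn[2], frames[[i]])
        newpos <- pos[i, ] + 2 * r * dir
        nbuds[i] <- k
        d2 <- (pos[, 1] - newpos[1])^2 + (pos[, 2] - newpos[2])^2 +
          (pos[, 3] - newpos[3])^2
        if (min(d2) < (1e-6 * r)^2) next # coincides with an existing cell
        pos <- rbind(pos, newpos)
        frames[[length(frames) + 1L]] <- frames[[i]] %*% rot_z(90 + nn[3])
        mothers <- c(mothers, i - 1L)
        nbuds <- c(nbuds, 0L)
        scars <- rbind(scars, pos[i, ] + r * dir)
        pairs <- rbind(pairs, c(i, nrow(pos)))
        # chitin bond on the centers: the printed rest length 2 is the
        # contact distance of unit spheres, i.e. a zero-rest-length spring
        # between the coincident bud and birth scars
        offsets <- rbind(offsets, c(0, 0, 0, 0, 0, 0))
      }
      res <- relax_positions(pos, rep(r, nrow(pos)), mech,
                             c("steric", "bond"),
                             pairs = pairs, offsets = offsets)
      pos <- res$positions
      converged <- converged && res$converged
    }
    list(pos = pos, frames = frames, mothers = mothers, scars = scars,
         pairs = pairs, offsets = offsets, converged = converged)
  })
  build_group(st$pos, rep(r, nrow(st$pos)), rep(r, nrow(st$pos)),
              st$frames, st$mothers, st$scars, "patterned", seed,
              bond_offsets = list(pairs = st$pairs, offsets = st$offsets),
              cell_volume = 4 * pi / 3 * r^3, converged = st$converged)
}

#' Apply localized apoptosis to a sphere-surface group
#'
#' One cell is chosen uniformly at random to die; all cells within Euclidean
#' distance `R` of it are flagged, and `n_flagged_deaths` of the flagged
#' cells (9 by default, for 10 deaths in total) are chosen at random to die
#' as well. Dead cells are removed before any tessellation.
#'
#' @param group a sphere-surface `cell_group` (see [sample_sphere_poisson()]).
#' @param R localization radius of the death region.
#' @param seed integer seed for the death draws.
#' @param n_flagged_deaths number of flagged cells that die in addition to
#'   the focal cell.
#' @return the group with dead cells removed; removed ids in
#'   `attr(, "removed")`.
#' @export
apply_apoptosis <- function(group, R, seed = 1L, n_flagged_deaths = 9L) {
  pos <- cell_centers(group)
  n <- nrow(pos)
  dead <- with_seed(seed, {
    focal <- sample.int(n, 1)
    d <- sqrt(colSums((t(pos) - pos[focal, ])^2))
    flagged <- setdiff(which(d <= R), focal)
    if (length(flagged) < n_flagged_deaths)
      stop(sprintf(paste0("only %d cells flagged within R = %.3g; ",
                          "need %d (R too small for this configuration)"),
                   length(flagged), R, n_flagged_deaths))
    extra <- if (length(flagged) == n_flagged_deaths) flagged else
      sample(flagged, n_flagged_deaths)
    c(focal, extra)
  })
  out <- group
  out$cells <- group$cells[-dead, , drop = FALSE]
  out$bonds <- matrix(integer(0), 0, 2)
  attr(out, "removed") <- group$cells$id[dead]
  out
}
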