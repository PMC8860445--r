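# Shared plumbing: the cell-table CSV dialect, deterministic fixtures,
# ensemble helpers and the end-to-end pipeline.

cell_table_columns <- c("id", "x", "y", "z", "a", "b", "c",
                        paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
                        "mother_id", "scar_x", "scar_y", "scar_z")

#' Write and read cell tables
#'
#' One CSV dialect serves all position data: columns `id, x, y, z` are
#' required; `a, b, c` (semi-axes), `r11..r33` (row-major rotation,
#' columns = principal axes), `mother_id` and `scar_x/y/z` are optional and
#' filled with documented defaults on read (unit sphere, identity
#' orientation, no lineage). Units are micrometres (or model units) and are
#' not converted.
#'
#' @param group a `cell_group`.
#' @param path file path.
#' @return `read_cell_table` returns a `cell_group`;
#'   `write_cell_table` returns `path` invisibly.
#' @export
write_cell_table <- function(group, path) {
  df <- group$cells
  df$morphology <- group$morphology
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "z")
  missing_req <- setdiff(required, names(df))
  if (length(missing_req) > 0)
    stop("malformed cell table, missing columns: ",
         paste(missing_req, collapse = ", "))
  bad <- which(!stats::complete.cases(df[, required]))
  if (length(bad) > 0)
    stop("malformed rows (incomplete id/x/y/z) at lines: ",
         paste(bad + 1L, collapse = ", "))
  if (anyDuplicated(df$id)) stop("cell ids are not unique")
  n <- nrow(df)
  if (!"a" %in% names(df)) df$a <- 1
  if (!"b" %in% names(df)) df$b <- df$a
  if (!"c" %in% names(df)) df$c <- df$b
  rotcols <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  if (!all(rotcols %in% names(df)))
    for (rc in rotcols)
      df[[rc]] <- if (substr(rc, 2, 2) == substr(rc, 3, 3)) 1 else 0
  if (!"mother_id" %in% names(df)) df$mother_id <- NA_integer_
  for (sc in c("scar_x", "scar_y", "scar_z"))
    if (!sc %in% names(df)) df[[sc]] <- NA_real_
  morphology <- if ("morphology" %in% names(df)) df$morphology[1] else
    "unknown"
  df <- df[, c(cell_table_columns,
               intersect("morphology", names(df))), drop = FALSE]
  frames <- lapply(seq_len(n), function(i)
    matrix(as.numeric(df[i, rotcols]), 3, 3, byrow = TRUE))
  build_group(as.matrix(df[, c("x", "y", "z")]), df$a, df$b, frames,
              df$mother_id, as.matrix(df[, c("scar_x", "scar_y", "scar_z")]),
              morphology, seed = NA_integer_)
}

#' Write a boundary hull or polyhedron as an OFF mesh
#'
#' @param hull a `boundary_hull` (or any list with `vertices` and `faces`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_off <- function(hull, path) {
  v <- hull$vertices
  f <- hull$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 12),
                                           collapse = " ")), con)
  writeLines(apply(f, 1, function(r)
    paste(c(length(r), r - 1L), collapse = " ")), con)
  invisible(path)
}

#' Small deterministic fixture groups
#'
#' Tiny groups with known tessellation properties, used throughout the test
#' suite: a 2 x 2 x 2 cube lattice (eight congruent Voronoi cells), the six
#' octahedron vertices on the unit sphere (six congruent spherical
#' polygons, solid angle `4 pi / 6` each), a 20-cell budding tree, and a
#' 64-cell aggregate.
#'
#' @param seed integer seed for the stochastic fixtures.
#' @return named list of `cell_group` objects.
#' @export
make_fixtures <- function(seed = 1L) {
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  colnames(cube) <- NULL
  frames <- replicate(8, diag(3), simplify = FALSE)
  cube_group <- build_group(cube, rep(0.5, 8), rep(0.5, 8), frames,
                            rep(NA_integer_, 8), matrix(NA_real_, 8, 3),
                            "aggregate", seed)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  octa_group <- build_group(octa, rep(0.5, 6), rep(0.5, 6),
                            replicate(6, diag(3), simplify = FALSE),
                            rep(NA_integer_, 6), matrix(NA_real_, 6, 3),
                            "sphere_surface", seed)
  snow <- grow_snowflake(morphology_config(target_cells = 20), seed = seed)
  agg <- grow_aggregate(morphology_config(), seed = seed)
  list(cube = cube_group, octahedron = octa_group,
       snowflake20 = snow, aggregate64 = agg)
}

#' Simulate an ensemble of groups
#'
#' Runs `n` independent replicates of one growth protocol under child seeds
#' derived from the root seed ([child_seed()]).
#'
#' @param morphology one of `"snowflake"`, `"aggregate"`, `"polydisperse"`,
#'   `"palintomy"`, `"sphere_surface"`, `"patterned"`.
#' @param n number of replicates.
#' @param cfg a [morphology_config()].
#' @param seed root seed.
#' @param mech a [mechanics_config()].
#' @return list of `cell_group` objects.
#' @export
simulate_ensemble <- function(morphology, n, cfg = morphology_config(),
                              seed = 1L, mech = mechanics_config()) {
  grower <- switch(morphology,
    snowflake = function(s) grow_snowflake(cfg, s),
    aggregate = function(s) grow_aggregate(cfg, s, mech),
    polydisperse = function(s) grow_polydisperse(cfg, s, mech),
    palintomy = function(s) grow_palintomy(cfg, s, mech),
    sphere_surface = function(s)
      sample_sphere_poisson(cfg$target_cells %||% 1000,
                            cfg$min_separation, s,
                            cell_radius = cfg$surface_cell_radius),
    patterned = function(s) grow_patterned(cfg, s, mech),
    stop("unknown morphology: ", morphology))
  lapply(seq_len(n), function(i) grower(child_seed(seed, i)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool Voronoi neighborhood sizes over an ensemble
#'
#' Tessellates each group (clipped 3D Voronoi for volumetric groups,
#' surface Voronoi solid angles for sphere-surface groups) and concatenates
#' the per-cell sizes.
#'
#' @param groups list of `cell_group` objects.
#' @param extend,pad hull parameters for the 3D tessellation (`extend =
#'   NULL` picks the morphology default, see [tessellate_group()]).
#' @return numeric vector of pooled sizes.
#' @export
pool_sizes <- function(groups, extend = NULL, pad = 5) {
  unlist(lapply(groups, function(g) {
    if (g$morphology == "sphere_surface") {
      tess <- surface_voronoi(g)
      tess$solid_angles[!tess$masked]
    } else {
      tessellate_group(g, extend = extend, pad = pad)$volumes
    }
  }), use.names = FALSE)
}

#' Moment-matched packing summary of a pooled size sample
#'
#' @param sizes pooled neighborhood sizes.
#' @param v_c minimum neighborhood size.
#' @return list with `model` (a `kgamma_model`), `k`, `r_rms`, `n`.
#' @export
packing_analysis <- function(sizes, v_c) {
  model <- estimate_kgamma(sizes, v_c)
  pp <- pp_rrms(sizes, model)
  list(model = model, k = model$k, r_rms = pp$r_rms, n = length(sizes))
}

#' Run the full analysis pipeline
#'
#' simulate -> tessellate -> moment-match -> P-P diagnostics, with optional
#' spatial-correlation and fracture stages, from one configuration list.
#' The resolved configuration (all defaults filled in) is part of the
#' report, so every run documents the parameters in effect.
#'
#' @param config list with elements `morphology`, `n_groups`, `seed`, and
#'   optionally `cfg` ([morphology_config()]), `mech`
#'   ([mechanics_config()]), `v_c` (defaults to the simulated cell volume),
#'   `correlate` (logical), `q_max`, `fracture` (list with `v_star_rel`),
#'   `out` (path for a JSON report).
#' @return the report list, invisibly when written to file.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$morphology),
            !is.null(config$n_groups), !is.null(config$seed))
  cfg <- config$cfg %||% morphology_config()
  mech <- config$mech %||% mechanics_config()
  groups <- simulate_ensemble(config$morphology, config$n_groups, cfg,
                              config$seed, mech)
  sizes <- pool_sizes(groups)
  surface <- config$morphology == "sphere_surface"
  v_c <- config$v_c %||%
    (if (surface) fit_min_size(sizes)$v_c else groups[[1]]$cell_volume)
  fit <- packing_analysis(sizes, v_c)
  report <- list(
    config = list(morphology = config$morphology,
                  n_groups = config$n_groups, seed = config$seed,
                  v_c = v_c,
                  morphology_config = unclass(cfg),
                  mechanics_config = unclass(mech)),
    n_sizes = fit$n,
    k = fit$k,
    r_rms = fit$r_rms,
    converged = all(vapply(groups, function(g) isTRUE(g$converged),
                           logical(1))))
  if (isTRUE(config$correlate)) {
    g1 <- groups[[1]]
    tess <- if (surface) surface_voronoi(g1) else tessellate_group(g1)
    szs <- if (surface) tess$solid_angles else tess$volumes
    prof <- correlation_function(szs, tess,
                                 q_max = config$q_max %||% 10)
    report$correlation <- prof
  }
  if (!is.null(config$fracture)) {
    v_star <- config$fracture$v_star_rel * v_c
    report$p_star <- fracture_probability(fit$model, v_star)
  }
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
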