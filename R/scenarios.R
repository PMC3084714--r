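#' Names of the built-in scenario presets
#'
#' Presets cover the study conditions of the model: single gradients at
#' three peak doses for desensitizable and nondesensitizable receptors,
#' opposing competing gradients (both receptor types and the mixed case),
#' angled competing gradients of identical or different ligands, four
#' multi-step navigation layouts with a distant third source, and two
#' orientation-map layouts.
#'
#' @return Character vector of preset names accepted by [build_scenario()].
#' @export
scenario_names <- function() {
  c(paste0("single_", rep(c("2nM", "20nM", "200nM"), each = 2L), "_",
           c("desens", "nondesens")),
    "opposing_desens", "opposing_nondesens", "opposing_mixed",
    "angled_same_desens", "angled_diff_desens",
    "angled_same_nondesens", "angled_diff_nondesens", "angled_mixed",
    "nav_A", "nav_B", "nav_C", "nav_D",
    "orientmap_single", "orientmap_opposing")
}

ring_starts <- function(n, rho, center = c(0, 0)) {
  a <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + rho * cos(a), center[2L] + rho * sin(a))
}

cluster_starts <- function(center = c(0, 0), spacing = 40) {
  g <- expand.grid(x = c(-1, 0, 1) * spacing, y = c(-1, 0, 1) * spacing)
  cbind(center[1L] + g$x, center[2L] + g$y)
}

axis_starts <- function() {
  x <- c(-450, -350, -250, -150, -50, -25, 25, 50, 150, 250, 350, 450)
  cbind(x, 0)
}

des <- function() kinetic_preset("table1_desensitizable")
nondes <- function() kinetic_preset("table1_nondesensitizable")

# angled sources: equilateral triangle of side 800 um with the start
# cluster at the origin, placing the starts inside the sensing annulus of
# both 17.6 nM fields and within a 75-minute reach of the balanced zone
ANGLED_LEFT <- c(-400, 400 * sqrt(3))
ANGLED_RIGHT <- c(400, 400 * sqrt(3))
# distant target of the navigation presets: within sensing reach of the
# angled pair's balanced zone, out of reach (and outside the support) of
# the start cluster at the origin
NAV_TARGET <- c(0, 1100)

scenario_registry <- function(name) {
  # seven representative cells scattered over the mid-to-outer field
  single_starts <- function() {
    rho <- c(600, 700, 750, 800, 850, 875, 900)
    a <- 2 * pi * (seq_along(rho) - 1L) / length(rho)
    cbind(rho * cos(a), rho * sin(a))
  }
  single <- function(L_max, p) list(
    env = ligand_environment(power_field("L", c(0, 0), L_max = L_max)),
    params_by_ligand = list(L = p),
    starts = single_starts(),
    migration = migration_config(total_time = 150))
  opposing <- function(p1, p2) list(
    env = ligand_environment(power_field("L1", c(-500, 0)),
                             power_field("L2", c(500, 0))),
    params_by_ligand = list(L1 = p1, L2 = p2),
    starts = axis_starts(),
    migration = migration_config(total_time = 75))
  angled_same <- function(p) list(
    env = ligand_environment(power_field("L", ANGLED_LEFT),
                             power_field("L", ANGLED_RIGHT)),
    params_by_ligand = list(L = p),
    starts = cluster_starts(),
    migration = migration_config(total_time = 75))
  angled_diff <- function(p1, p2) list(
    env = ligand_environment(power_field("L1", ANGLED_LEFT),
                             power_field("L2", ANGLED_RIGHT)),
    params_by_ligand = list(L1 = p1, L2 = p2),
    starts = cluster_starts(),
    migration = migration_config(total_time = 75))
  nav <- function(fields, params) list(
    env = ligand_environment(fields),
    params_by_ligand = params,
    starts = cluster_starts(),
    migration = migration_config(total_time = 150))
  L3 <- power_field("L3", NAV_TARGET)

  switch(name,
    single_2nM_desens = single(2, des()),
    single_2nM_nondesens = single(2, nondes()),
    single_20nM_desens = single(20, des()),
    single_20nM_nondesens = single(20, nondes()),
    single_200nM_desens = single(200, des()),
    single_200nM_nondesens = single(200, nondes()),
    opposing_desens = opposing(des(), des()),
    opposing_nondesens = opposing(nondes(), nondes()),
    opposing_mixed = opposing(nondes(), des()),
    angled_same_desens = angled_same(des()),
    angled_same_nondesens = angled_same(nondes()),
    angled_diff_desens = angled_diff(des(), des()),
    angled_diff_nondesens = angled_diff(nondes(), nondes()),
    angled_mixed = angled_diff(nondes(), des()),
    nav_A = nav(list(L3), list(L3 = des())),
    nav_B = nav(list(power_field("L1", c(0, 750)), L3),
                list(L1 = des(), L3 = des())),
    nav_C = nav(list(power_field("L1", ANGLED_LEFT),
                     power_field("L1", ANGLED_RIGHT), L3),
                list(L1 = des(), L3 = des())),
    nav_D = nav(list(power_field("L1", ANGLED_LEFT),
                     power_field("L2", ANGLED_RIGHT), L3),
                list(L1 = des(), L2 = des(), L3 = des())),
    orientmap_single = list(
      env = ligand_environment(power_field("L", c(0, 0))),
      params_by_ligand = list(L = des()),
      starts = matrix(numeric(0), ncol = 2L),
      migration = migration_config(total_time = 75)),
    orientmap_opposing = list(
      env = ligand_environment(power_field("L1", c(-500, 0)),
                               power_field("L2", c(500, 0))),
      params_by_ligand = list(L1 = des(), L2 = des()),
      starts = matrix(numeric(0), ncol = 2L),
      migration = migration_config(total_time = 75)),
    NULL)
}

#' Build a named scenario preset
#'
#' @param name a preset name from [scenario_names()].
#' @param overrides named list of replacements, shallow-merged: the keys
#'   \code{env}, \code{params_by_ligand}, \code{geometry}, \code{starts} and
#'   \code{migration} replace the corresponding component wholly, while any
#'   [migration_config()] field name (e.g. \code{seed},
#'   \code{total_time}) is merged into the migration settings.
#' @return An object of class \code{scenario}: \code{name}, \code{env},
#'   \code{params_by_ligand}, \code{geometry}, \code{starts} (matrix) and
#'   \code{migration}.
#' @export
#' @examples
#' sc <- build_scenario("opposing_desens", overrides = list(seed = 7))
build_scenario <- function(name, overrides = list()) {
  sc <- scenario_registry(name)
  if (is.null(sc))
    stop("unknown scenario '", name, "'; valid names:\n  ",
         paste(scenario_names(), collapse = "\n  "), call. = FALSE)
  sc$name <- name
  sc$geometry <- cell_geometry()
  mig_fields <- setdiff(names(formals(migration_config)), "")
  for (key in names(overrides)) {
    if (key %in% c("env", "params_by_ligand", "geometry", "starts",
                   "migration")) {
      sc[[key]] <- overrides[[key]]
    } else if (key %in% mig_fields) {
      m <- unclass(sc$migration)
      m[[key]] <- overrides[[key]]
      sc$migration <- do.call(migration_config, m)
    } else {
      stop("unknown override '", key, "'", call. = FALSE)
    }
  }
  if (!is.matrix(sc$starts)) sc$starts <- as.matrix(sc$starts)
  missing <- setdiff(env_ligands(sc$env), names(sc$params_by_ligand))
  if (length(missing))
    stop("scenario lacks kinetic parameters for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ", length(x$env$fields), " field(s), ",
      nrow(x$starts), " start(s), ", x$migration$total_time,
      " min, seed ", x$migration$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate every cell of a scenario
#'
#' Convenience wrapper running [simulate_population()] with the scenario's
#' starts, environment, parameters and migration settings.
#'
#' @param scenario a [build_scenario()] result.
#' @param base_seed first track's seed (defaults to the scenario seed).
#' @return A \code{cell_track} data frame with a \code{track_id} column.
#' @export
run_scenario <- function(scenario, base_seed = scenario$migration$seed) {
  stopifnot(inherits(scenario, "scenario"))
  if (!nrow(scenario$starts))
    stop("scenario '", scenario$name, "' has no start positions",
         call. = FALSE)
  simulate_population(scenario$starts, scenario$env,
                      scenario$params_by_ligand, scenario$geometry,
                      scenario$migration, base_seed)
}

#' Summary metrics of a simulated track
#'
#' @param track a \code{cell_track} data frame for a single cell (no
#'   \code{track_id} column, or a single unique id).
#' @param scenario the [build_scenario()] scenario the track was run in.
#' @param target the source to measure chemotaxis toward: a ligand label or
#'   a field index into \code{scenario$env$fields}.
#' @return One-row data frame: \code{path_length} (um),
#'   \code{net_displacement} (um), \code{chemotactic_index} (net
#'   displacement projected on the start-to-target direction divided by the
#'   path length, in [-1, 1]) and \code{final_dist_<i>} for every field.
#' @export
track_metrics <- function(track, scenario, target = 1L) {
  stopifnot(inherits(scenario, "scenario"))
  if ("track_id" %in% names(track)) {
    if (length(unique(track$track_id)) != 1L)
      stop("track_metrics expects a single track; split by track_id first",
           call. = FALSE)
  }
  fields <- scenario$env$fields
  if (is.character(target)) {
    idx <- which(vapply(fields, `[[`, character(1L), "ligand") == target)
    if (!length(idx))
      stop("target '", target, "' names no field in the scenario",
           call. = FALSE)
    target <- idx[1L]
  }
  target <- as.integer(target)
  if (target < 1L || target > length(fields))
    stop("target field index out of range", call. = FALSE)

  xy <- as.matrix(track[, c("x_um", "y_um")])
  seg <- diff(xy)
  path_length <- sum(sqrt(rowSums(seg^2)))
  disp <- xy[nrow(xy), ] - xy[1L, ]
  net_displacement <- sqrt(sum(disp^2))
  to_target <- fields[[target]]$center - xy[1L, ]
  nrm <- sqrt(sum(to_target^2))
  ci <- if (path_length == 0 || nrm == 0) 0 else
    sum(disp * to_target / nrm) / path_length
  out <- data.frame(path_length = path_length,
                    net_displacement = net_displacement,
                    chemotactic_index = ci)
  for (i in seq_along(fields))
    out[[paste0("final_dist_", i)]] <-
      sqrt(sum((xy[nrow(xy), ] - fields[[i]]$center)^2))
  out
}

#' Write / read tracks as CSV
#'
#' Tracks are written with a \code{track_id} column (added as 1 for a single
#' track) and the sample columns \code{t_min}, \code{x_um}, \code{y_um},
#' \code{heading_rad}, \code{net_mag}, \code{mode}.
#'
#' @param track a \code{cell_track} data frame.
#' @param path file path.
#' @return \code{write_tracks} returns \code{path} invisibly;
#'   \code{read_tracks} returns a \code{cell_track} data frame.
#' @export
write_tracks <- function(track, path) {
  df <- as.data.frame(track)
  if (!"track_id" %in% names(df)) df <- cbind(track_id = 1L, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cell_track", "data.frame")
  df
}

#' Write / read a scenario configuration as JSON
#'
#' Serializes the full scenario (fields, kinetic parameters, geometry,
#' starts, migration settings) to a single JSON document; all lengths in um,
#' times in min, concentrations in nM, rates in s^-1. Reading the document
#' back reproduces an equivalent scenario.
#'
#' @param scenario a [build_scenario()] scenario.
#' @param path file path.
#' @return \code{write_scenario_config} returns \code{path} invisibly;
#'   \code{read_scenario_config} returns a \code{scenario}.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  doc <- list(
    name = scenario$name,
    fields = lapply(scenario$env$fields, function(f)
      list(ligand = f$ligand, center = f$center, L_max = f$L_max,
           L_0 = f$L_0, A = f$A, n = f$n)),
    params_by_ligand = lapply(scenario$params_by_ligand, unclass),
    geometry = list(unit_radius = scenario$geometry$unit_radius,
                    n_units = scenario$geometry$n_units),
    starts = unname(as.matrix(scenario$starts)),
    migration = unclass(scenario$migration))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- lapply(seq_len(nrow(doc$fields)), function(i) {
    f <- doc$fields[i, ]
    power_field(f$ligand, unlist(f$center), L_max = f$L_max, L_0 = f$L_0,
                A = f$A, n = f$n)
  })
  params <- lapply(doc$params_by_ligand, function(p)
    do.call(kinetic_params, as.list(p)))
  starts <- doc$starts
  if (is.null(starts) || !length(starts))
    starts <- matrix(numeric(0), ncol = 2L)
  structure(list(name = doc$name,
                 env = ligand_environment(fields),
                 params_by_ligand = params,
                 geometry = cell_geometry(doc$geometry$unit_radius,
                                          doc$geometry$n_units),
                 starts = as.matrix(starts),
                 migration = do.call(migration_config,
                                     as.list(doc$migration))),
            class = "scenario")
}
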