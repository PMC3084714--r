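#' Migration simulation settings
#'
#' @param speed migration speed (um/min). Motion never pauses, so every
#'   track's path length is exactly \code{speed * total_time}.
#' @param threshold chemotactic threshold on the orientation magnitude
#'   \code{|dLR*|} (receptor counts); at or above it the cell steps toward
#'   the orientation vector, below it the step direction is random.
#' @param tau_opt optimal (maximum) persistent step time (min).
#' @param tau_min minimum step time (min); also the random-mode step time
#'   when the orientation magnitude is negligible.
#' @param v_sat orientation magnitude (receptor counts) at which the step
#'   time saturates at \code{tau_opt}: the step time is
#'   \code{clamp(tau_opt * |v| / v_sat, tau_min, tau_opt)} and the directed
#'   turning rate is \code{(pi / tau_opt) * (|v| / v_sat)} rad/min, so a
#'   cell at saturation completes a half turn within one optimal step.
#' @param substep_dt sub-step duration (min): motion and receptor
#'   integration advance on this grid; must not exceed \code{tau_min} and
#'   must divide \code{total_time}.
#' @param ode_dt Runge-Kutta step for the receptor kinetics (s).
#' @param total_time simulated migration time (min).
#' @param seed RNG seed for [simulate_track()].
#' @return An object of class \code{migration_config}.
#' @export
migration_config <- function(speed = 10, threshold = 10, tau_opt = 2.5,
                             tau_min = 0.25, v_sat = 100,
                             substep_dt = 0.05, ode_dt = 0.1,
                             total_time = 75, seed = 1L) {
  cfg <- list(speed = speed, threshold = threshold, tau_opt = tau_opt,
              tau_min = tau_min, v_sat = v_sat, substep_dt = substep_dt,
              ode_dt = ode_dt, total_time = total_time,
              seed = as.integer(seed))
  for (nm in setdiff(names(cfg), "seed"))
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]))
      stop("migration setting '", nm, "' must be a finite scalar",
           call. = FALSE)
  if (cfg$speed <= 0) stop("speed must be positive", call. = FALSE)
  if (cfg$threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (!(cfg$tau_min > 0 && cfg$tau_min <= cfg$tau_opt))
    stop("need 0 < tau_min <= tau_opt", call. = FALSE)
  if (cfg$v_sat < cfg$threshold)
    stop("v_sat must be at least the threshold", call. = FALSE)
  if (cfg$substep_dt <= 0 || cfg$substep_dt > cfg$tau_min + 1e-12)
    stop("substep_dt must be positive and no larger than tau_min",
         call. = FALSE)
  if (cfg$ode_dt <= 0) stop("ode_dt must be positive", call. = FALSE)
  if (cfg$total_time <= 0) stop("total_time must be positive", call. = FALSE)
  n_sub <- cfg$total_time / cfg$substep_dt
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("total_time must be an integral number of sub-steps", call. = FALSE)
  structure(cfg, class = "migration_config")
}

#' Migrating cell state
#'
#' @param position cell center \code{c(x, y)} (um).
#' @param heading migration direction (radians, wrapped to [0, 2pi)).
#' @param params_by_ligand named list of [kinetic_params()]; one receptor
#'   state matrix per ligand is created in the all-free initial state.
#' @param geometry a [cell_geometry()].
#' @return An object of class \code{cell_state}: position, heading,
#'   geometry, and per-ligand receptor state matrices (one row per unit,
#'   columns R, LR_act, LR_des, R_int).
#' @export
cell_state <- function(position, heading = 0, params_by_ligand,
                       geometry = cell_geometry()) {
  position <- as.numeric(position)
  if (length(position) != 2L) stop("position must be (x, y)", call. = FALSE)
  states <- lapply(params_by_ligand, function(p) {
    stopifnot(inherits(p, "kinetic_params"))
    m <- matrix(0, nrow = geometry$n_units, ncol = 4,
                dimnames = list(NULL, c("R", "LR_act", "LR_des", "R_int")))
    m[, "R"] <- p$R_u
    m
  })
  structure(list(position = position, heading = heading %% (2 * pi),
                 states = states, geometry = geometry),
            class = "cell_state")
}

track_colnames <- c("t_min", "x_um", "y_um", "heading_rad", "net_mag", "mode")

as_track <- function(samples) {
  df <- as.data.frame(samples)
  names(df) <- track_colnames
  df$mode <- ifelse(df$mode > 0.5, "directed", "random")
  class(df) <- c("cell_track", "data.frame")
  df
}

#' Advance a migrating cell by one step (reference implementation)
#'
#' One migration step of the agent-based model, in pure R. The net
#' orientation vector is computed from the cell's current receptor states;
#' at or above the threshold the cell turns toward it over sub-steps at an
#' angular speed proportional to the magnitude (capped so it never
#' overshoots), below the threshold the cell adopts a uniformly random
#' heading for the step. The step time is
#' \code{clamp(tau_opt |v| / v_sat, tau_min, tau_opt)}. During every
#' sub-step the cell advances \code{speed * substep_dt} along its heading
#' and the receptor pools of all units are integrated against the local
#' ligand concentrations at the unit positions.
#'
#' This is the reference path for the compiled engine used by
#' [simulate_track()]; both consume the R random number stream identically
#' (one uniform draw per sub-threshold step).
#'
#' @param cell a [cell_state()].
#' @param env a [ligand_environment()].
#' @param params_by_ligand named list of [kinetic_params()] covering every
#'   ligand in \code{env}.
#' @param config a [migration_config()].
#' @param t_now current time (min), used only to stamp the returned samples
#'   and cap the step at \code{total_time}.
#' @return List with the updated \code{cell} and a \code{samples} data frame
#'   (one row per sub-step, columns as in [simulate_track()]).
#' @export
advance_step <- function(cell, env, params_by_ligand, config, t_now = 0) {
  stopifnot(inherits(cell, "cell_state"),
            inherits(config, "migration_config"))
  geometry <- cell$geometry
  ligs <- names(cell$states)
  v <- orientation_from_states(cell$states, geometry)
  mag <- v$magnitude
  directed <- mag >= config$threshold
  if (directed) {
    target <- atan2(v$vy, v$vx)
  } else {
    target <- 2 * pi * stats::runif(1L)
    cell$heading <- target %% (2 * pi)
  }
  tau <- min(config$tau_opt,
             max(config$tau_min, config$tau_opt * mag / config$v_sat))
  n_sub <- max(1L, as.integer(round(tau / config$substep_dt)))
  remaining <- as.integer(round((config$total_time - t_now) /
                                  config$substep_dt))
  if (n_sub > remaining) n_sub <- remaining
  omega <- (pi / config$tau_opt) * (mag / config$v_sat)

  n_ode <- as.integer(round(config$substep_dt * 60 / config$ode_dt))
  ode_h <- config$substep_dt * 60 / n_ode

  # flatten states for vectorized RK4: rows = (unit, ligand) pairs
  n_units <- geometry$n_units
  S <- do.call(rbind, cell$states)
  kf <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "k_f"), each = n_units)
  kr <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "k_r"), each = n_units)
  kdes <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "k_des"),
              each = n_units)
  ki <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "k_i"), each = n_units)
  kup <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "k_up"), each = n_units)
  Ru <- rep(vapply(params_by_ligand[ligs], `[[`, 1, "R_u"), each = n_units)
  rhs <- function(M, L) {
    bind <- kf * L * M[, 1L]
    cbind(-bind + kr * M[, 2L] + kup * M[, 4L],
          bind - (kr + kdes) * M[, 2L],
          kdes * M[, 2L] - ki * M[, 3L],
          ki * M[, 3L] - kup * M[, 4L])
  }

  samples <- matrix(NA_real_, nrow = n_sub, ncol = 6L)
  pos <- cell$position
  heading <- cell$heading
  offs <- geometry$directions * geometry$unit_radius
  for (ss in seq_len(n_sub)) {
    if (directed) {
      d <- target - heading
      if (d > pi) d <- d - 2 * pi
      if (d <= -pi) d <- d + 2 * pi
      turn <- min(omega * config$substep_dt, abs(d))
      heading <- (heading + sign(d) * turn) %% (2 * pi)
    }
    pos <- pos + config$speed * config$substep_dt *
      c(cos(heading), sin(heading))
    ux <- pos[1L] + offs[, 1L]
    uy <- pos[2L] + offs[, 2L]
    L <- unlist(lapply(ligs, function(lg)
      ligand_concentration(env, lg, ux, uy)))
    for (i in seq_len(n_ode)) {
      k1 <- rhs(S, L)
      k2 <- rhs(S + ode_h / 2 * k1, L)
      k3 <- rhs(S + ode_h / 2 * k2, L)
      k4 <- rhs(S + ode_h * k3, L)
      S <- S + ode_h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(S < 0)) {
        if (any(S < -1e-9 * Ru))
          stop("RK4 step produced a negative receptor pool: reduce ode_dt",
               call. = FALSE)
        S[S < 0] <- 0
      }
    }
    samples[ss, ] <- c(t_now + ss * config$substep_dt, pos[1L], pos[2L],
                       heading, mag, as.numeric(directed))
  }

  for (j in seq_along(ligs))
    cell$states[[j]][, ] <- S[(j - 1L) * n_units + seq_len(n_units), ]
  cell$position <- pos
  cell$heading <- heading
  list(cell = cell, samples = as_track(samples))
}

#' Simulate the migration track of one cell
#'
#' Runs the threshold-gated biased persistent random walk from a start
#' position: the cell's receptor units begin in the all-free state, the net
#' orientation vector is re-evaluated at every migration step from the
#' dynamically integrated receptor pools (so receptor desensitization
#' carries memory of the concentrations visited), and motion proceeds at
#' constant speed through sub-steps of \code{substep_dt}.
#'
#' @param start starting position \code{c(x, y)} (um).
#' @param env a [ligand_environment()].
#' @param params_by_ligand named list of [kinetic_params()] covering every
#'   ligand in \code{env}.
#' @param geometry a [cell_geometry()].
#' @param config a [migration_config()]; \code{config$seed} seeds the track.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (pure-R
#'   reference path built on [advance_step()]); both consume the random
#'   number stream identically and agree to floating-point accuracy.
#' @return A \code{cell_track} data frame with one row per sub-step:
#'   \code{t_min}, \code{x_um}, \code{y_um}, \code{heading_rad},
#'   \code{net_mag} (orientation magnitude at the enclosing step's start)
#'   and \code{mode} ("directed"/"random"). Attributes:
#'   \code{final_states} (per-ligand receptor matrices) and
#'   \code{max_conservation_error}.
#' @export
simulate_track <- function(start, env, params_by_ligand,
                           geometry = cell_geometry(), config,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(env, "ligand_environment"),
            inherits(config, "migration_config"))
  ligs <- env_ligands(env)
  missing <- setdiff(ligs, names(params_by_ligand))
  if (length(missing))
    stop("no kinetic parameters for ligand(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  params_by_ligand <- params_by_ligand[ligs]
  set.seed(config$seed)

  if (engine == "cpp") {
    fm <- do.call(rbind, lapply(env$fields, function(f)
      c(f$center, f$L_max, f$L_0, f$A, f$n, match(f$ligand, ligs))))
    pm <- do.call(rbind, lapply(params_by_ligand, function(p)
      unlist(p[c("k_f", "k_r", "k_des", "k_i", "k_up", "R_u")])))
    # initial states: all receptors free, laid out unit-fastest
    n_units <- geometry$n_units
    states0 <- matrix(0, nrow = 4L, ncol = n_units * nrow(pm))
    states0[1L, ] <- rep(pm[, "R_u"], each = n_units)
    res <- simulate_track_cpp(start[1L], start[2L], fm, pm,
                              geometry$directions, geometry$unit_radius,
                              states0,
                              config$speed, config$threshold, config$tau_opt,
                              config$tau_min, config$v_sat,
                              config$substep_dt, config$ode_dt,
                              config$total_time)
    track <- as_track(res$samples)
    st <- res$states
    final_states <- lapply(seq_along(ligs), function(j)
      t(matrix(st[, , j], nrow = 4L,
               dimnames = list(c("R", "LR_act", "LR_des", "R_int"), NULL))))
    names(final_states) <- ligs
    attr(track, "final_states") <- final_states
    attr(track, "max_conservation_error") <- res$max_conservation_error
    return(track)
  }

  # pure-R reference path
  cell <- cell_state(start, heading = 0, params_by_ligand, geometry)
  cell$heading <- 2 * pi * stats::runif(1L)
  v0 <- orientation_from_states(cell$states, geometry)
  first <- data.frame(t_min = 0, x_um = start[1L], y_um = start[2L],
                      heading_rad = cell$heading, net_mag = v0$magnitude,
                      mode = "random")
  pieces <- list(first)
  t_now <- 0
  max_err <- 0
  Ru <- vapply(params_by_ligand, `[[`, 1, "R_u")
  while (t_now < config$total_time - 1e-9) {
    stp <- advance_step(cell, env, params_by_ligand, config, t_now)
    cell <- stp$cell
    pieces[[length(pieces) + 1L]] <- stp$samples
    t_now <- stp$samples$t_min[nrow(stp$samples)]
    err <- max(abs(vapply(seq_along(cell$states), function(j)
      max(abs(rowSums(cell$states[[j]]) - Ru[j])), numeric(1L))))
    max_err <- max(max_err, err)
  }
  track <- do.call(rbind, pieces)
  class(track) <- c("cell_track", "data.frame")
  attr(track, "final_states") <- cell$states
  attr(track, "max_conservation_error") <- max_err
  track
}

#' Simulate a cohort of independent cell tracks
#'
#' Track \code{i} (1-based) is simulated with seed \code{base_seed + i - 1},
#' so the first track reproduces \code{simulate_track} at \code{base_seed}
#' and cohorts are reproducible as a whole.
#'
#' @param starts matrix (or list) of starting positions, one per track.
#' @inheritParams simulate_track
#' @param base_seed seed of the first track.
#' @return A \code{cell_track} data frame with a leading \code{track_id}
#'   column; attribute \code{max_conservation_error} is the cohort maximum.
#' @export
simulate_population <- function(starts, env, params_by_ligand,
                                geometry = cell_geometry(), config,
                                base_seed = config$seed) {
  if (is.list(starts)) starts <- do.call(rbind, starts)
  starts <- as.matrix(starts)
  if (!nrow(starts)) stop("starts must be non-empty", call. = FALSE)
  if (ncol(starts) != 2L) stop("starts must be (x, y) rows", call. = FALSE)
  out <- vector("list", nrow(starts))
  max_err <- 0
  for (i in seq_len(nrow(starts))) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    tr <- simulate_track(starts[i, ], env, params_by_ligand, geometry, cfg)
    max_err <- max(max_err, attr(tr, "max_conservation_error"))
    tr <- cbind(track_id = i, as.data.frame(tr))
    out[[i]] <- tr
  }
  res <- do.call(rbind, out)
  class(res) <- c("cell_track", "data.frame")
  attr(res, "max_conservation_error") <- max_err
  res
}
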