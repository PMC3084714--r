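#' Multi-unit model cell geometry
#'
#' The model cell consists of \code{n_units} receptor-expressing units evenly
#' spaced on a circle of radius \code{unit_radius} around the cell center,
#' the first unit on the +x axis. With the default four units the units lie
#' exactly on the positive and negative x and y axes, matching a 10-um cell
#' whose front-back receptor occupancy difference is read along each axis.
#'
#' @param unit_radius distance of each unit from the cell center (um).
#' @param n_units number of units; at least 4 and a multiple of 4 so that
#'   the x/y axis pairs are always present.
#' @return An object of class \code{cell_geometry} with the unit direction
#'   matrix in \code{$directions} (exact zeros on the axes).
#' @export
cell_geometry <- function(unit_radius = 5, n_units = 4L) {
  if (!is.numeric(unit_radius) || unit_radius <= 0)
    stop("unit_radius must be positive (um)", call. = FALSE)
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 4L || n_units %% 4L != 0L)
    stop("n_units must be an integer >= 4 and a multiple of 4",
         call. = FALSE)
  frac <- 2 * (seq_len(n_units) - 1L) / n_units
  # cospi/sinpi are exact at half-integer multiples, so axis units land on
  # (+-1, 0) and (0, +-1) without rounding error
  dirs <- cbind(cospi(frac), sinpi(frac))
  structure(list(unit_radius = unit_radius, n_units = n_units,
                 directions = dirs),
            class = "cell_geometry")
}

#' Positions of the receptor-expressing units of a cell
#'
#' @param center cell center \code{c(x, y)} (um).
#' @param geometry a [cell_geometry()].
#' @return A numeric matrix with \code{n_units} rows and columns
#'   \code{x}, \code{y}.
#' @export
unit_positions <- function(center, geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be (x, y)", call. = FALSE)
  pos <- geometry$directions * geometry$unit_radius
  pos[, 1L] <- pos[, 1L] + center[1L]
  pos[, 2L] <- pos[, 2L] + center[2L]
  colnames(pos) <- c("x", "y")
  pos
}

orientation_vector <- function(vx, vy) {
  structure(list(vx = vx, vy = vy, magnitude = sqrt(vx^2 + vy^2)),
            class = "orientation_vector")
}

#' @export
print.orientation_vector <- function(x, ...) {
  cat(sprintf("Orientation vector (%.4g, %.4g), |dLR*| = %.4g\n",
              x$vx, x$vy, x$magnitude))
  invisible(x)
}

# Combine per-unit active-complex counts into the orientation vector.
# For n_units = 4 this is exactly the axis-difference definition
# (LR[+x] - LR[-x], LR[+y] - LR[-y]); for finer unit rings the unit-sum
# sum_j LR_j * d_j is normalized by n_units/4 so it reduces to the 4-unit
# definition and the two discretizations are directly comparable.
combine_units <- function(lr_act, geometry) {
  v <- crossprod(geometry$directions, lr_act) * (4 / geometry$n_units)
  orientation_vector(v[1L], v[2L])
}

#' Steady-state orientation vector toward one ligand
#'
#' Evaluates the closed-form steady state of the active complexes at every
#' receptor-expressing unit, at that unit's local concentration of the given
#' ligand, and combines the per-unit counts into the front-back
#' receptor-occupancy difference vector.
#'
#' @param position cell center \code{c(x, y)} (um).
#' @param env a [ligand_environment()].
#' @param ligand ligand label.
#' @param params [kinetic_params()] of the receptor for this ligand.
#' @param geometry a [cell_geometry()].
#' @return An \code{orientation_vector} (fields \code{vx}, \code{vy},
#'   \code{magnitude}, all in receptor counts).
#' @export
ligand_orientation_steady <- function(position, env, ligand, params,
                                      geometry = cell_geometry()) {
  pos <- unit_positions(position, geometry)
  L <- ligand_concentration(env, ligand, pos[, 1L], pos[, 2L])
  combine_units(steady_lr_act(L, params), geometry)
}

#' Net steady-state orientation vector over all ligands
#'
#' Component-wise sum of [ligand_orientation_steady()] over every ligand
#' present in the environment; each ligand is sensed by its own receptor
#' species with its own kinetic parameters.
#'
#' @param position cell center \code{c(x, y)} (um).
#' @param env a [ligand_environment()].
#' @param params_by_ligand named list mapping every ligand label in
#'   \code{env} to its [kinetic_params()].
#' @param geometry a [cell_geometry()].
#' @return An \code{orientation_vector}.
#' @export
net_orientation_steady <- function(position, env, params_by_ligand,
                                   geometry = cell_geometry()) {
  ligs <- env_ligands(env)
  missing <- setdiff(ligs, names(params_by_ligand))
  if (length(missing))
    stop("no kinetic parameters supplied for ligand(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vx <- 0; vy <- 0
  for (lig in ligs) {
    v <- ligand_orientation_steady(position, env, lig,
                                   params_by_ligand[[lig]], geometry)
    vx <- vx + v$vx; vy <- vy + v$vy
  }
  orientation_vector(vx, vy)
}

#' Orientation vector from dynamically integrated receptor states
#'
#' Applies the same combination rule as the steady-state variants to
#' supplied per-unit receptor states, e.g. those carried along a migrating
#' cell.
#'
#' @param per_unit_states named list: for each ligand, either a list of
#'   [receptor_state()] objects (one per unit, in unit order) or a numeric
#'   matrix with one row per unit whose second column is \code{LR_act}.
#' @param geometry a [cell_geometry()].
#' @return An \code{orientation_vector}.
#' @export
orientation_from_states <- function(per_unit_states,
                                    geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  vx <- 0; vy <- 0
  for (states in per_unit_states) {
    lr <- if (is.matrix(states)) {
      if (nrow(states) != geometry$n_units)
        stop("state matrix must have one row per unit", call. = FALSE)
      states[, 2L]
    } else {
      if (length(states) != geometry$n_units)
        stop("need one receptor state per unit", call. = FALSE)
      vapply(states, function(s) unclass(s)[[2L]], numeric(1L))
    }
    v <- combine_units(lr, geometry)
    vx <- vx + v$vx; vy <- vy + v$vy
  }
  orientation_vector(vx, vy)
}

#' Steady-state orientation map on a grid
#'
#' Tabulates the net orientation vector over a rectangular grid of cell
#' positions, flagging positions whose magnitude reaches the chemotactic
#' threshold.
#'
#' @param env a [ligand_environment()].
#' @param params_by_ligand named list of [kinetic_params()] per ligand.
#' @param geometry a [cell_geometry()].
#' @param bbox bounding box \code{c(x0, y0, x1, y1)} (um).
#' @param step grid spacing (um).
#' @param threshold chemotactic threshold on \code{|dLR*|} (receptor
#'   counts); positions at or above it count as directed.
#' @return Data frame with columns \code{x_um}, \code{y_um}, \code{vx},
#'   \code{vy}, \code{directed}.
#' @export
orientation_map <- function(env, params_by_ligand,
                            geometry = cell_geometry(),
                            bbox, step, threshold = 10) {
  if (!is.numeric(step) || step <= 0) stop("step must be positive",
                                           call. = FALSE)
  xs <- seq(bbox[1L], bbox[3L], by = step)
  ys <- seq(bbox[2L], bbox[4L], by = step)
  g <- expand.grid(x_um = xs, y_um = ys, KEEP.OUT.ATTRS = FALSE)
  vx <- numeric(nrow(g)); vy <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    v <- net_orientation_steady(c(g$x_um[i], g$y_um[i]), env,
                                params_by_ligand, geometry)
    vx[i] <- v$vx; vy[i] <- v$vy
  }
  g$vx <- vx; g$vy <- vy
  g$directed <- sqrt(vx^2 + vy^2) >= threshold
  g
}

#' Parametric sweep of the steady-state orientation
#'
#' Re-evaluates the net orientation at a set of cell positions while one
#' recycling rate is swept, reporting the signed component of the vector
#' along a reference axis (positive toward the \code{toward} point). Sweeping
#' \code{"k_des"}, \code{"k_i"} or \code{"k_up"} overrides that rate for
#' every receptor species; \code{"k_des1"} overrides the desensitization
#' rate of the first ligand only, leaving the other receptors untouched.
#'
#' @param param one of \code{"k_des"}, \code{"k_i"}, \code{"k_up"},
#'   \code{"k_des1"}.
#' @param values rate values to sweep (s^-1).
#' @param positions cell positions: a 2-column matrix of (x, y) points, or a
#'   numeric vector of x-coordinates taken on the axis y = 0.
#' @param env a [ligand_environment()].
#' @param params_by_ligand named list of base [kinetic_params()] per ligand.
#' @param geometry a [cell_geometry()].
#' @param toward point (um) defining the positive direction of the reported
#'   component; defaults to the center of the environment's first field
#'   (so a single-gradient sweep reports the up-gradient component and a
#'   two-ligand sweep reports "positive toward ligand 1").
#' @return Data frame with columns \code{param}, \code{value},
#'   \code{position_id}, \code{x_um}, \code{y_um}, \code{component}.
#' @export
sweep_orientation <- function(param, values, positions, env,
                              params_by_ligand,
                              geometry = cell_geometry(),
                              toward = NULL) {
  param <- match.arg(param, c("k_des", "k_i", "k_up", "k_des1"))
  if (param != "k_des1" && any(values < 0))
    stop("rate values must be non-negative", call. = FALSE)
  if (is.null(dim(positions))) positions <- cbind(positions, 0)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("positions must be (x, y) points or x-coordinates", call. = FALSE)
  if (is.null(toward)) toward <- env$fields[[1L]]$center
  ligs <- env_ligands(env)

  override <- function(ps, value) {
    target <- if (param == "k_des1") ligs[1L] else ligs
    rate <- if (param == "k_des1") "k_des" else param
    for (lig in target) {
      p <- ps[[lig]]
      p[[rate]] <- value
      ps[[lig]] <- do.call(kinetic_params, unclass(p))
    }
    ps
  }

  rows <- vector("list", length(values) * nrow(positions))
  k <- 0L
  for (value in values) {
    ps <- override(params_by_ligand, value)
    for (i in seq_len(nrow(positions))) {
      pos <- positions[i, ]
      v <- net_orientation_steady(pos, env, ps, geometry)
      ax <- toward - pos
      nrm <- sqrt(sum(ax^2))
      comp <- if (nrm == 0) 0 else (v$vx * ax[1L] + v$vy * ax[2L]) / nrm
      k <- k + 1L
      rows[[k]] <- data.frame(param = param, value = value,
                              position_id = i, x_um = pos[1L],
                              y_um = pos[2L], component = comp)
    }
  }
  do.call(rbind, rows)
}
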