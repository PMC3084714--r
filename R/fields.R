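#' Fixed nonlinear power-gradient ligand field
#'
#' A radially symmetric, time-invariant concentration profile
#' \deqn{L(\rho) = L_0 + (L_{max} - L_0)(1 - \rho/A)^n \quad (\rho \le A)}
#' and \eqn{L_0} beyond the field radius \eqn{A}, where \eqn{\rho} is the
#' Euclidean distance from the gradient center. With the default power
#' \code{n = 3} this is the standard fixed nonlinear approximation to a
#' point-source chemoattractant profile.
#'
#' @param ligand ligand identity label (e.g. \code{"L1"}). Fields with the
#'   same label superpose; distinct ligands never sum.
#' @param center gradient center, numeric \code{c(x, y)} in um.
#' @param L_max peak concentration at the center (nM).
#' @param L_0 basal concentration outside the field (nM).
#' @param A field radius (um).
#' @param n power of the gradient function (dimensionless).
#' @return An object of class \code{power_field}.
#' @export
#' @examples
#' f <- power_field("IL8", c(0, 0), L_max = 17.6)
#' field_concentration(f, 500, 0)   # 17.6 * 0.5^3 = 2.2 nM
power_field <- function(ligand, center = c(0, 0), L_max = 17.6, L_0 = 0,
                        A = 1000, n = 3) {
  if (!is.character(ligand) || length(ligand) != 1L || !nzchar(ligand))
    stop("ligand must be a non-empty label", call. = FALSE)
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be a finite (x, y) point in um", call. = FALSE)
  if (!(L_max > L_0)) stop("L_max must exceed L_0", call. = FALSE)
  if (L_0 < 0) stop("L_0 must be non-negative", call. = FALSE)
  if (A <= 0) stop("field radius A must be positive", call. = FALSE)
  if (n <= 0) stop("power n must be positive", call. = FALSE)
  structure(list(ligand = ligand, center = center, L_max = L_max,
                 L_0 = L_0, A = A, n = n),
            class = "power_field")
}

#' @export
print.power_field <- function(x, ...) {
  cat(sprintf(
    "Power gradient of '%s': center (%g, %g) um, L_max %g nM, L_0 %g nM, A %g um, n %g\n",
    x$ligand, x$center[1L], x$center[2L], x$L_max, x$L_0, x$A, x$n))
  invisible(x)
}

#' Concentration of a single field at points in the plane
#'
#' @param field a [power_field()].
#' @param x,y coordinates (um); vectorized.
#' @return Concentrations in nM, within \code{[L_0, L_max]}.
#' @export
field_concentration <- function(field, x, y) {
  stopifnot(inherits(field, "power_field"))
  rho <- sqrt((x - field$center[1L])^2 + (y - field$center[2L])^2)
  inside <- rho <= field$A
  out <- rep_len(field$L_0, length(rho))
  out[inside] <- field$L_0 +
    (field$L_max - field$L_0) * (1 - rho[inside] / field$A)^field$n
  out
}

#' Ligand environment: a collection of power-gradient fields
#'
#' Fields carrying the same ligand label superpose additively (two sources of
#' one chemoattractant); fields of distinct ligands coexist and are sensed by
#' their own receptor species.
#'
#' @param ... [power_field()] objects (or a single list of them).
#' @return An object of class \code{ligand_environment}.
#' @export
ligand_environment <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && !inherits(fields[[1L]], "power_field"))
    fields <- fields[[1L]]
  if (!length(fields)) stop("environment needs at least one field",
                            call. = FALSE)
  if (!all(vapply(fields, inherits, logical(1L), "power_field")))
    stop("all members must be power_field objects", call. = FALSE)
  structure(list(fields = fields), class = "ligand_environment")
}

#' @export
print.ligand_environment <- function(x, ...) {
  cat("Ligand environment with", length(x$fields), "field(s):\n")
  for (f in x$fields) print(f)
  invisible(x)
}

#' Ligand identities present in an environment
#' @param env a [ligand_environment()].
#' @return Character vector of unique ligand labels, in field order.
#' @export
env_ligands <- function(env) {
  stopifnot(inherits(env, "ligand_environment"))
  unique(vapply(env$fields, `[[`, character(1L), "ligand"))
}

#' Total concentration of one ligand at points in the plane
#'
#' Sums [field_concentration()] over every field carrying the requested
#' label; returns 0 where no such field exists.
#'
#' @param env a [ligand_environment()].
#' @param ligand ligand label.
#' @param x,y coordinates (um); vectorized.
#' @return Concentrations in nM.
#' @export
ligand_concentration <- function(env, ligand, x, y) {
  stopifnot(inherits(env, "ligand_environment"))
  out <- numeric(max(length(x), length(y)))
  x <- rep_len(x, length(out)); y <- rep_len(y, length(out))
  for (f in env$fields)
    if (f$ligand == ligand) out <- out + field_concentration(f, x, y)
  out
}

#' Sample one ligand's concentration on a rectangular grid
#'
#' @param env a [ligand_environment()].
#' @param ligand ligand label.
#' @param bbox bounding box \code{c(x0, y0, x1, y1)} in um.
#' @param step grid spacing (um).
#' @return A data frame with columns \code{x_um}, \code{y_um}, \code{L_nM};
#'   one row per grid node (x varying fastest).
#' @export
grid_sample <- function(env, ligand, bbox, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive grid spacing in um", call. = FALSE)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || bbox[3L] < bbox[1L] || bbox[4L] < bbox[2L])
    stop("bbox must be c(x0, y0, x1, y1) with x1 >= x0 and y1 >= y0",
         call. = FALSE)
  xs <- seq(bbox[1L], bbox[3L], by = step)
  ys <- seq(bbox[2L], bbox[4L], by = step)
  g <- expand.grid(x_um = xs, y_um = ys, KEEP.OUT.ATTRS = FALSE)
  g$L_nM <- ligand_concentration(env, ligand, g$x_um, g$y_um)
  g
}
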