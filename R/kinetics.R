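#' Kinetic parameters for one ligand-receptor pair
#'
#' Bundles the five mass-action rate constants of ligand-induced receptor
#' modulation together with the receptor endowment of one receptor-expressing
#' unit. The kinetic scheme has four pools: free surface receptors \code{R},
#' active ligand-receptor complexes \code{LR_act}, desensitized surface
#' complexes \code{LR_des}, and an internalized pool \code{R_int} that is
#' recycled back to the surface. Ligand dissociation from desensitized
#' receptors is neglected.
#'
#' Defaults are the measured human neutrophil formyl-peptide-receptor rates;
#' time is in seconds and concentrations in nM throughout, so the association
#' rate 8.4e7 M^-1 s^-1 is stored as 0.084 nM^-1 s^-1.
#'
#' @param k_f ligand-receptor association rate (nM^-1 s^-1).
#' @param k_r low-affinity dissociation rate of the active complex (s^-1).
#' @param k_des homologous desensitization rate (s^-1); 0 gives a
#'   nondesensitizable receptor.
#' @param k_i internalization rate of desensitized complexes (s^-1).
#' @param k_up up-regulation (re-expression) rate of internalized receptors
#'   (s^-1).
#' @param R_u receptor endowment of one receptor-expressing unit (continuous
#'   receptor count). The default gives each unit the full cellular complement
#'   of 25,000 receptors, so that a front-back unit pair reproduces the
#'   receptor-occupancy difference of a two-compartment cell.
#' @return An object of class \code{kinetic_params}.
#' @seealso [kinetic_preset()] for the named desensitizable /
#'   nondesensitizable parameter sets.
#' @export
#' @examples
#' kinetic_params()                 # desensitizable defaults
#' kinetic_params(k_des = 0)        # nondesensitizable variant
kinetic_params <- function(k_f = 0.084, k_r = 0.37, k_des = 0.065,
                           k_i = 0.0033, k_up = 0.004, R_u = 25000) {
  p <- list(k_f = k_f, k_r = k_r, k_des = k_des, k_i = k_i, k_up = k_up,
            R_u = R_u)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("kinetic parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  if (any(unlist(p[c("k_f", "k_r", "k_des", "k_i", "k_up")]) < 0))
    stop("kinetic rates must be non-negative", call. = FALSE)
  if (p$R_u <= 0) stop("R_u must be positive", call. = FALSE)
  if (p$k_des > 0 && (p$k_i <= 0 || p$k_up <= 0))
    stop("k_des > 0 requires k_i > 0 and k_up > 0: otherwise the ",
         "desensitized/internalized pools are absorbing and no recycling ",
         "steady state exists", call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' Named kinetic parameter presets
#'
#' @param name one of \code{"table1_desensitizable"} (k_des = 0.065 s^-1) or
#'   \code{"table1_nondesensitizable"} (k_des = 0, all other rates equal).
#' @return A [kinetic_params()] object.
#' @export
kinetic_preset <- function(name = c("table1_desensitizable",
                                    "table1_nondesensitizable")) {
  name <- match.arg(name)
  switch(name,
         table1_desensitizable = kinetic_params(),
         table1_nondesensitizable = kinetic_params(k_des = 0))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (s^-1 except k_f in nM^-1 s^-1):\n")
  cat(sprintf("  k_f = %g, k_r = %g, k_des = %g, k_i = %g, k_up = %g\n",
              x$k_f, x$k_r, x$k_des, x$k_i, x$k_up))
  cat(sprintf("  R_u = %g receptors per unit\n", x$R_u))
  invisible(x)
}

#' Receptor pool state of one receptor-expressing unit
#'
#' @param R free surface receptors.
#' @param LR_act active receptor-ligand complexes.
#' @param LR_des desensitized surface complexes.
#' @param R_int internalized receptors awaiting re-expression.
#' @return A named numeric vector of class \code{receptor_state}.
#' @export
receptor_state <- function(R, LR_act, LR_des, R_int) {
  s <- c(R = R, LR_act = LR_act, LR_des = LR_des, R_int = R_int)
  if (!all(is.finite(s))) stop("receptor state must be finite", call. = FALSE)
  structure(s, class = "receptor_state")
}

#' Initial receptor state: all receptors free on the surface
#'
#' @param params a [kinetic_params()] object.
#' @return A [receptor_state()] with \code{R = R_u} and empty bound,
#'   desensitized and internalized pools.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  receptor_state(R = params$R_u, LR_act = 0, LR_des = 0, R_int = 0)
}

#' Time derivative of the receptor pools
#'
#' Mass-action rate laws of the recycling scheme:
#' \deqn{dR/dt = -k_f L R + k_r LR_{act} + k_{up} R_{int}}
#' \deqn{dLR_{act}/dt = k_f L R - (k_r + k_{des}) LR_{act}}
#' \deqn{dLR_{des}/dt = k_{des} LR_{act} - k_i LR_{des}}
#' \deqn{dR_{int}/dt = k_i LR_{des} - k_{up} R_{int}}
#' The four components always sum to zero (receptor conservation).
#'
#' @param state a [receptor_state()] (non-negative components).
#' @param L local ligand concentration (nM, non-negative).
#' @param params a [kinetic_params()] object.
#' @return Named numeric vector of rates of change (per second).
#' @export
receptor_derivative <- function(state, L, params) {
  stopifnot(inherits(params, "kinetic_params"))
  s <- unclass(state)
  if (length(s) != 4L) stop("state must have four components", call. = FALSE)
  if (any(s < 0)) stop("receptor state components must be non-negative",
                       call. = FALSE)
  if (!is.numeric(L) || length(L) != 1L || L < 0)
    stop("ligand concentration L must be a non-negative scalar (nM)",
         call. = FALSE)
  bind <- params$k_f * L * s[[1L]]
  c(R      = -bind + params$k_r * s[[2L]] + params$k_up * s[[4L]],
    LR_act =  bind - (params$k_r + params$k_des) * s[[2L]],
    LR_des =  params$k_des * s[[2L]] - params$k_i * s[[3L]],
    R_int  =  params$k_i * s[[3L]] - params$k_up * s[[4L]])
}

#' Integrate the receptor pools with fixed-step 4th-order Runge-Kutta
#'
#' Advances one receptor-expressing unit through a (possibly time-varying)
#' ligand exposure. Components are clamped to zero when a step produces a
#' negative overshoot smaller than \code{1e-9 * R_u}; a larger overshoot
#' aborts with advice to reduce \code{dt}.
#'
#' @param state0 starting [receptor_state()].
#' @param ligand either a single non-negative concentration (nM, held
#'   constant) or a function of time (seconds) returning nM.
#' @param params a [kinetic_params()] object.
#' @param dt Runge-Kutta step (s). The default 0.1 s is comfortably stable
#'   for the default rates; binding rates k_f*L above ~25 s^-1 need a
#'   smaller step.
#' @param duration total integration time (s).
#' @return The final [receptor_state()]. Attribute
#'   \code{max_conservation_error} records the largest deviation of the pool
#'   sum from \code{R_u} seen at any accepted step.
#' @export
integrate_receptors <- function(state0, ligand, params, dt = 0.1, duration) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration < 0)
    stop("duration must be non-negative", call. = FALSE)
  s <- as.numeric(unclass(state0))
  if (length(s) != 4L || any(s < 0))
    stop("state0 must be a non-negative 4-component receptor state",
         call. = FALSE)
  if (duration == 0) return(state0)

  if (is.numeric(ligand) && length(ligand) == 1L) {
    if (ligand < 0) stop("ligand concentration must be non-negative",
                         call. = FALSE)
    out <- integrate_pool_cpp(s, ligand,
                              unlist(params[c("k_f", "k_r", "k_des",
                                              "k_i", "k_up")]),
                              params$R_u, dt, duration)
    res <- receptor_state(out[1L], out[2L], out[3L], out[4L])
    attr(res, "max_conservation_error") <- attr(out, "max_conservation_error")
    return(res)
  }

  if (!is.function(ligand))
    stop("ligand must be a concentration (nM) or a function of time",
         call. = FALSE)
  n_steps <- ceiling(duration / dt - 1e-9)
  kf <- params$k_f; kr <- params$k_r; kdes <- params$k_des
  ki <- params$k_i; kup <- params$k_up; Ru <- params$R_u
  tol <- 1e-9 * Ru
  rhs <- function(s, L) {
    bind <- kf * L * s[1L]
    c(-bind + kr * s[2L] + kup * s[4L],
      bind - (kr + kdes) * s[2L],
      kdes * s[2L] - ki * s[3L],
      ki * s[3L] - kup * s[4L])
  }
  t <- 0
  max_err <- 0
  for (i in seq_len(n_steps)) {
    h <- min(dt, duration - t)
    L1 <- ligand(t); L2 <- ligand(t + h / 2); L3 <- ligand(t + h)
    if (min(L1, L2, L3) < 0)
      stop("ligand trace returned a negative concentration", call. = FALSE)
    k1 <- rhs(s, L1)
    k2 <- rhs(s + h / 2 * k1, L2)
    k3 <- rhs(s + h / 2 * k2, L2)
    k4 <- rhs(s + h * k3, L3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(s < 0)) {
      if (min(s) < -tol)
        stop("RK4 step produced a negative receptor pool (", min(s),
             "): reduce dt", call. = FALSE)
      s[s < 0] <- 0
    }
    max_err <- max(max_err, abs(sum(s) - Ru))
    t <- t + h
  }
  res <- receptor_state(s[1L], s[2L], s[3L], s[4L])
  attr(res, "max_conservation_error") <- max_err
  res
}

#' Closed-form steady state of the receptor pools
#'
#' Setting the four rate laws to zero under total receptor conservation gives
#' \deqn{LR_{act} = \frac{R_u k_f L}{(k_r + k_{des}) + k_f L (1 + k_{des}/k_i
#'   + k_{des}/k_{up})}}
#' with \eqn{LR_{des} = (k_{des}/k_i) LR_{act}},
#' \eqn{R_{int} = (k_{des}/k_{up}) LR_{act}} and the free pool as the
#' conserved remainder. For \code{k_des = 0} the ratio terms vanish and the
#' expression reduces exactly to the Langmuir isotherm
#' \eqn{LR_{act} = R_u L / (k_r/k_f + L)}.
#'
#' @param L ligand concentration (nM); may be a vector.
#' @param params a [kinetic_params()] object.
#' @return For scalar \code{L} a [receptor_state()]; for vector \code{L} a
#'   matrix with one row per concentration.
#' @export
steady_state <- function(L, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(L < 0)) stop("L must be non-negative", call. = FALSE)
  rdes_i  <- if (params$k_des == 0) 0 else params$k_des / params$k_i
  rdes_up <- if (params$k_des == 0) 0 else params$k_des / params$k_up
  lr <- params$R_u * params$k_f * L /
    ((params$k_r + params$k_des) + params$k_f * L * (1 + rdes_i + rdes_up))
  lrd <- rdes_i * lr
  rint <- rdes_up * lr
  r <- params$R_u - lr - lrd - rint
  if (length(L) == 1L) return(receptor_state(r, lr, lrd, rint))
  cbind(R = r, LR_act = lr, LR_des = lrd, R_int = rint)
}

#' Steady-state active complexes only
#'
#' Convenience accessor used throughout the orientation maps: the
#' \code{LR_act} component of [steady_state()], vectorized over \code{L}.
#'
#' @inheritParams steady_state
#' @return Numeric vector of active-complex counts.
#' @export
steady_lr_act <- function(L, params) {
  stopifnot(inherits(params, "kinetic_params"))
  rdes_i  <- if (params$k_des == 0) 0 else params$k_des / params$k_i
  rdes_up <- if (params$k_des == 0) 0 else params$k_des / params$k_up
  params$R_u * params$k_f * L /
    ((params$k_r + params$k_des) + params$k_f * L * (1 + rdes_i + rdes_up))
}
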