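#' Per-cell growth rate of the basal progenitor compartment
#'
#' Evaluates \eqn{u_P(t) = c (1 + D/P)^k e^{-t^2/s}}: proliferation is
#' amplified by the suprabasal-to-basal ratio (the expanding gland surface
#' demands more basal cells) and damped by a Gaussian decay over
#' developmental time, so growth is maximal at onset and ceases thereafter.
#'
#' @param p Basal (progenitor) cell count; must be > 0.
#' @param d Suprabasal (differentiated) cell count; must be >= 0.
#' @param t Model time in days since developmental onset; >= 0.
#' @param params An [sg_params()] object.
#' @return The per-cell division rate in 1/day (vectorized over `p`, `d`, `t`).
#' @examples
#' growth_rate(11, 0, 0, sg_params(c = 1, k = 2, f_p = 0.8))  # = c
#' @export
growth_rate <- function(p, d, t, params) {
  stopifnot(inherits(params, "sg_params"))
  if (any(!is.finite(p)) || any(p <= 0))
    stop("'p' must be positive: the D/P feedback ratio is undefined otherwise")
  if (any(!is.finite(d)) || any(d < 0)) stop("'d' must be >= 0")
  if (any(t < 0)) stop("'t' is model time since onset and must be >= 0")
  s <- .decay_scale(params)
  params$c * (1 + d / p)^params$k * exp(-t^2 / s)
}

#' Right-hand side of the two-compartment rate equations
#'
#' The basal compartment P is the only proliferating one; each division
#' self-renews with probability `f_p`, otherwise the offspring detaches into
#' the suprabasal compartment D:
#' \deqn{dP/dt = (2 f_P - 1) u_P P, \qquad dD/dt = (1 - f_P) u_P P.}
#'
#' @param t Model time (days since onset).
#' @param state Numeric vector `c(P = , D = )`.
#' @param params An [sg_params()] object.
#' @return A list whose first element is `c(dP, dD)` (the signature
#'   expected by [deSolve::ode()]).
#' @export
sg_rhs <- function(t, state, params) {
  p <- state[[1L]]
  d <- state[[2L]]
  u <- growth_rate(p, d, t, params)
  list(c((2 * params$f_p - 1) * u * p,
         (1 - params$f_p) * u * p))
}

# Guarded rates for use inside the solver only. Tiny negative excursions
# of d from solver probing are clamped; non-finite states short-circuit.
.sg_rates_guarded <- function(t, p, d, params) {
  if (!is.finite(p) || !is.finite(d) || p <= 0) return(c(0, 0, 0))
  d <- max(d, 0)
  u <- params$c * (1 + d / p)^params$k * exp(-t^2 / .decay_scale(params))
  flux <- u * p
  c((2 * params$f_p - 1) * flux, (1 - params$f_p) * flux, flux)
}

# Integration stops, and the state is held constant, when either
# - the basal layer is exhausted (P below .p_floor cells): for f_p < 0.5
#   and k >= 1 the true solution reaches P = 0 in finite time with
#   unbounded slope, and the D/P feedback leaves its domain; with no
#   dividing cells left, development has halted anyway; or
# - the population exceeds .pop_cap cells: runaway growth at extreme
#   (c, k) combinations far outside the biological regime (real glands
#   hold a few hundred cells), frozen so that calibration sees a finite,
#   very poor fit instead of an integrator collapse.
# Root-finding (lsodar) locates either event precisely, which keeps the
# solver from collapsing its step size against the singularity.
.p_floor <- 1e-3
.pop_cap <- 1e6

# Solve the (optionally division-augmented) system on `times`, stopping at
# the exhaustion/runaway roots and padding the remaining output times with
# the frozen terminal state.
.integrate_sg <- function(params, times, rtol, atol, maxsteps,
                          with_divisions = FALSE) {
  y <- c(P = params$p0, D = params$d0)
  if (with_divisions) y <- c(y, I = 0)
  nstate <- length(y)
  rhs <- function(t, state, parms) {
    r <- .sg_rates_guarded(t, state[[1L]], state[[2L]], parms)
    list(r[seq_len(nstate)])
  }
  root <- function(t, state, parms)
    c(state[[1L]] - .p_floor, state[[1L]] + state[[2L]] - .pop_cap)
  sol <- suppressWarnings(
    deSolve::ode(y = y, times = times, func = rhs, parms = params,
                 method = "lsodar", rootfun = root,
                 rtol = rtol, atol = atol, maxsteps = maxsteps))
  sol <- as.data.frame(sol)
  if (nrow(sol) < 1L || anyNA(sol[nrow(sol), ]))
    stop("integration failed for parameters: c = ", params$c, ", k = ",
         params$k, ", f_p = ", params$f_p,
         " (solver returned NaN or stopped early)")
  if (!all(times %in% sol$time)) {
    # terminated at a root: hold the terminal (frozen) state on the rest
    # of the requested grid
    last <- sol[nrow(sol), -1L, drop = FALSE]
    sol <- sol[sol$time %in% times, , drop = FALSE]
    miss <- setdiff(times, sol$time)
    sol <- rbind(sol, cbind(time = miss,
                            last[rep(1L, length(miss)), , drop = FALSE]))
    sol <- sol[order(sol$time), ]
  }
  rownames(sol) <- NULL
  sol
}

#' Integrate the sebaceous-gland development model
#'
#' Solves the two-compartment system from onset (`t = 0`, postnatal day
#' `t_onset`) to `t_end - t_onset` with an adaptive solver
#' ([deSolve::ode()], `lsodar`, rtol 1e-8 / atol 1e-10). Output is sampled
#' on a uniform fine grid that always contains the whole postnatal days.
#'
#' Two terminal events are located by root-finding, after which the state
#' is held constant on the remaining grid: exhaustion of the basal layer
#' (P below 0.001 cells — reachable when `f_p < 0.5`, where the true
#' solution hits P = 0 in finite time and the D/P feedback leaves its
#' domain) and runaway growth beyond 1e6 total cells at extreme parameter
#' combinations. Both are far outside the biological regime and are
#' treated as "development halted".
#'
#' @param params An [sg_params()] object.
#' @param times Optional numeric vector of output times (days since onset)
#'   within `[0, t_end - t_onset]`; the default is a uniform grid of step
#'   `dt` including every whole day.
#' @param dt Output grid step in days when `times` is not given. Default 0.02.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `"sg_trajectory"`: a data frame with columns
#'   `t_model` (days since onset), `postnatal_day`, `P`, `D` and `total`,
#'   with the generating parameters attached as attribute `"params"`.
#' @examples
#' traj <- simulate_sg(sg_params(c = 1.5, k = 2, f_p = 0.8))
#' endpoint(traj)
#' @export
simulate_sg <- function(params, times = NULL, dt = 0.02,
                        rtol = 1e-8, atol = 1e-10, maxsteps = 5000) {
  stopifnot(inherits(params, "sg_params"))
  horizon <- params$t_end - params$t_onset
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, horizon, by = dt), 0:floor(horizon), horizon)))
  } else {
    times <- sort(unique(as.numeric(times)))
    if (any(times < 0) || any(times > horizon + 1e-9))
      stop("output times must lie within [0, t_end - t_onset]")
    if (times[1L] > 0) times <- c(0, times)
  }
  sol <- .integrate_sg(params, times, rtol, atol, maxsteps)
  # clamp solver round-off excursions below zero
  sol$P <- pmax(sol$P, 0)
  sol$D <- pmax(sol$D, 0)
  out <- data.frame(t_model = sol$time,
                    postnatal_day = sol$time + params$t_onset,
                    P = sol$P, D = sol$D, total = sol$P + sol$D)
  structure(out, class = c("sg_trajectory", "data.frame"), params = params)
}

#' @export
print.sg_trajectory <- function(x, ...) {
  e <- endpoint(x)
  cat(sprintf("SG trajectory: %d samples over P%g-P%g; endpoint P = %.2f, D = %.2f, total = %.2f\n",
              nrow(x), x$postnatal_day[1L], x$postnatal_day[nrow(x)],
              e[["p_end"]], e[["d_end"]], e[["total"]]))
  invisible(x)
}

#' @export
plot.sg_trajectory <- function(x, ...) {
  graphics::matplot(x$postnatal_day, cbind(x$P, x$D, x$total), type = "l",
                    lty = c(1, 1, 2), col = c("#1b9e77", "#d95f02", "grey30"),
                    xlab = "postnatal day", ylab = "cells", ...)
  graphics::legend("topleft", c("basal P", "suprabasal D", "total"),
                   lty = c(1, 1, 2), col = c("#1b9e77", "#d95f02", "grey30"),
                   bty = "n")
  invisible(x)
}

#' Endpoint cell counts of a simulated trajectory
#'
#' @param traj An `sg_trajectory` from [simulate_sg()].
#' @return Named numeric vector `c(p_end, d_end, total)` taken at the last
#'   output time.
#' @export
endpoint <- function(traj) {
  stopifnot(inherits(traj, "sg_trajectory"))
  if (nrow(traj) < 1L) stop("empty trajectory")
  n <- nrow(traj)
  c(p_end = traj$P[n], d_end = traj$D[n], total = traj$total[n])
}

#' Cumulative-division bookkeeping along a trajectory
#'
#' Every division produces `f_p` net new cells in expectation, so the model
#' satisfies the identity
#' \eqn{P(t) + D(t) - P_0 - D_0 = f_P \int_0^t u_P P \, d\tau}.
#' The integral of \eqn{u_P P} is accumulated as an auxiliary state of the
#' same solver run (so it carries the integrator tolerance, not a coarser
#' grid quadrature error) and both sides are reported at the trajectory's
#' output times — a consistency check on the integration.
#'
#' @param traj An `sg_trajectory`.
#' @param params The generating [sg_params()]; defaults to the parameters
#'   attached to `traj`.
#' @return A data frame with columns `t_model`, `net_gain`
#'   (`P + D - P0 - D0`), `cum_divisions` (`f_p` times the accumulated
#'   `u_P P`) and `residual` (their difference).
#' @export
division_bookkeeping <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "sg_trajectory"), inherits(params, "sg_params"))
  sol <- .integrate_sg(params, traj$t_model, rtol = 1e-10, atol = 1e-12,
                       maxsteps = 5000, with_divisions = TRUE)
  gain <- traj$P + traj$D - params$p0 - params$d0
  data.frame(t_model = traj$t_model, net_gain = gain,
             cum_divisions = params$f_p * sol$I,
             residual = gain - params$f_p * sol$I)
}

#' Write a trajectory to CSV
#'
#' Columns: `postnatal_day, t_model, P, D, total`.
#'
#' @param traj An `sg_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sg_trajectory"))
  utils::write.csv(traj[, c("postnatal_day", "t_model", "P", "D", "total")],
                   path, row.names = FALSE)
  invisible(path)
}
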