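#' Integrate the homeostasis model
#'
#' Adaptive-step numerical integration of the two-compartment system from an
#' arbitrary initial condition, with constant or time-varying thymic output.
#' Integration runs internally in model units of `cell_unit` cells with
#' relative tolerance `rtol` and absolute tolerance `atol` (model units),
#' via [deSolve::ode()] (lsoda). The output is resampled onto a daily grid,
#' with the first `fine_until` days additionally resolved at `fine_step`
#' days so that the fast transient of the dividing compartment (timescale
#' `1/r`, about 6 h at defaults) is captured.
#'
#' @param params A [model_params()] object.
#' @param init_resting,init_dividing Initial resting and dividing cells.
#' @param t_end End time, days.
#' @param theta_fn Optional function of time (days) returning thymic output
#'   in cells/day; default `NULL` uses the constant `params$theta`.
#' @param fine_until,fine_step Extent (days) and step of the fine initial
#'   grid (defaults 10 and 0.01).
#' @param rtol,atol Solver tolerances (defaults 1e-8 relative, 1e-12
#'   absolute in model units).
#' @return A tibble of class `cd4_trajectory` with columns `time_days`,
#'   `X_cells`, `Y_cells`, `N_cells`, `ratio` (Y/X). The parameters and
#'   tolerances are attached as attributes.
#' @examples
#' traj <- simulate_homeostasis(model_params(), init_resting = 1e9,
#'                              t_end = 400)
#' tail(traj)
#' @export
simulate_homeostasis <- function(params, init_resting, init_dividing = 0,
                                 t_end = 1000, theta_fn = NULL,
                                 fine_until = 10, fine_step = 0.01,
                                 rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  check_nonneg(init_resting, "init_resting")
  check_nonneg(init_dividing, "init_dividing")
  if (!is.numeric(t_end) || t_end <= 0) {
    stop("'t_end' must be positive", call. = FALSE)
  }
  cu <- params$cell_unit
  pu <- as_model_units(params)
  times <- trajectory_grid(t_end, fine_until, fine_step)
  deriv <- if (is.null(theta_fn)) {
    function(t, s, parms) list(unlist(rhs_core(s[1], s[2], pu$theta, pu)))
  } else {
    function(t, s, parms) {
      list(unlist(rhs_core(s[1], s[2], theta_fn(t) / cu, pu)))
    }
  }
  sol <- deSolve::ode(y = c(X = init_resting / cu, Y = init_dividing / cu),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    last <- sol[nrow(sol), ]
    stop("ODE solver failed at t = ", last[1], " days, state (",
         last[2] * cu, ", ", last[3] * cu, ") cells", call. = FALSE)
  }
  X <- pmax(sol[, "X"], 0) * cu   # clip solver noise at the atol level
  Y <- pmax(sol[, "Y"], 0) * cu
  out <- tibble::tibble(time_days = sol[, "time"], X_cells = X, Y_cells = Y,
                        N_cells = X + Y, ratio = Y / X)
  class(out) <- c("cd4_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  attr(out, "time_varying_theta") <- !is.null(theta_fn)
  out
}

trajectory_grid <- function(t_end, fine_until, fine_step) {
  fine_until <- min(fine_until, t_end)
  g <- round(c(seq(0, fine_until, by = fine_step),
               if (t_end > fine_until) {
                 seq(ceiling(fine_until), floor(t_end), by = 1)
               }), 10)
  sort(unique(c(g[g < t_end], t_end)))
}

#' Time to reach the homeostatic set point
#'
#' The earliest time after which the total cell number stays within a
#' relative `band` of its asymptotic (final) value for the rest of the
#' trajectory. The trajectory must itself have converged: its last 5% of
#' time points must already sit inside the band, otherwise an error is
#' raised.
#'
#' @param traj A `cd4_trajectory` from [simulate_homeostasis()].
#' @param band Relative half-width of the equilibrium band (default 0.05).
#' @return Days (0 if the whole trajectory is inside the band).
#' @examples
#' traj <- simulate_homeostasis(model_params(), 1e9, t_end = 1000)
#' convergence_time(traj)
#' @export
convergence_time <- function(traj, band = 0.05) {
  stopifnot(inherits(traj, "cd4_trajectory"), band > 0)
  N <- traj$N_cells
  t <- traj$time_days
  Nf <- N[length(N)]
  inside <- abs(N / Nf - 1) <= band
  tail_idx <- which(t >= t[length(t)] - 0.05 * (t[length(t)] - t[1]))
  if (!all(inside[tail_idx])) {
    stop("trajectory has not converged: total cell number still moves by ",
         "more than ", 100 * band, "% of its final value near t_end",
         call. = FALSE)
  }
  if (all(inside)) return(0)
  t[max(which(!inside)) + 1L]
}

#' Peak dividing-to-resting ratio of a trajectory
#'
#' Maximum of Y/X over the trajectory. From a lymphopenic start the ratio
#' shoots up on the fast timescale (quasi-steady value about
#' `lambda(N0) / r`) and then relaxes slowly to the equilibrium fraction.
#'
#' @param traj A `cd4_trajectory`.
#' @return Dimensionless peak ratio.
#' @export
peak_ratio <- function(traj) {
  stopifnot(inherits(traj, "cd4_trajectory"))
  if (any(traj$X_cells == 0)) {
    stop("ratio undefined: trajectory contains X = 0", call. = FALSE)
  }
  max(traj$ratio)
}

#' Ratio at a given time
#'
#' Linear interpolation of Y/X at time `t` days; used to read off the
#' slow-drift shoulder after the fast transient.
#'
#' @param traj A `cd4_trajectory`.
#' @param t Time, days, within the trajectory range.
#' @return Dimensionless ratio.
#' @export
ratio_at <- function(traj, t) {
  stopifnot(inherits(traj, "cd4_trajectory"))
  if (t < min(traj$time_days) || t > max(traj$time_days)) {
    stop("'t' outside trajectory range", call. = FALSE)
  }
  stats::approx(traj$time_days, traj$ratio, xout = t)$y
}

#' @method glance cd4_trajectory
#' @export
glance.cd4_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(t_end = x$time_days[n], N_final = x$N_cells[n],
                 ratio_final = x$ratio[n], peak_ratio = max(x$ratio),
                 n_points = n)
}
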