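#' Analytic Jacobian of the model
#'
#' Partial derivatives of `(dX/dt, dY/dt)` with respect to `(X, Y)`,
#' including the dependence of the competition rates on the total pool
#' (`d lambda / dN = -lambda / epsilon`, `d delta / dN = delta / rho`).
#' Entries are in /day and independent of the cell unit.
#'
#' @param X Resting cells, cells.
#' @param Y Dividing cells, cells.
#' @param params A [model_params()] object.
#' @return A 2x2 numeric matrix, rows (dX/dt, dY/dt), columns (X, Y).
#' @examples
#' model_jacobian(1e11, 5e8, model_params())
#' @export
model_jacobian <- function(X, Y, params) {
  check_nonneg(X, "X")
  check_nonneg(Y, "Y")
  stopifnot(length(X) == 1L, length(Y) == 1L)
  N <- X + Y
  lam <- params$lambda0 * exp(-N / params$epsilon)
  del <- params$delta0 * exp(N / params$rho)
  lam_p <- -lam / params$epsilon   # d lambda / dN
  del_p <- del / params$rho        # d delta / dN
  matrix(c(-(lam + del) - X * (lam_p + del_p),
           2 * params$r - X * (lam_p + del_p),
           lam + X * lam_p,
           X * lam_p - params$r - 2 * params$mu_prime * Y),
         nrow = 2, ncol = 2, byrow = TRUE,
         dimnames = list(c("dX", "dY"), c("X", "Y")))
}

#' Nontrivial steady state of the homeostasis model
#'
#' Finds the equilibrium `(X*, Y*)` of the two-compartment system and
#' classifies its linear stability from the analytic Jacobian. The search
#' reduces the fixed-point conditions to a scalar root in the total pool
#' size `N`: for given `N` the dividing-compartment balance
#' `lambda(N) (N - Y) = r Y + mu' Y^2` has a unique non-negative root
#' `Y(N)` (a quadratic), and the remaining condition
#' `theta + r Y - delta(N) (N - Y) - mu' Y^2 = 0` is monotone from
#' `theta > 0` at `N = 0` to negative values at large `N`, so bracketing
#' and [stats::uniroot()] locate the physiological root robustly. A Newton
#' refinement on the full two-dimensional system polishes the result.
#'
#' @param params A [model_params()] object.
#' @param tol Relative tolerance of the scalar root search (default 1e-12).
#' @return An object of class `cd4_equilibrium`: a list with `X`, `Y`, `N`
#'   (cells), `ratio` (Y/X), `residual` (max |rhs|, cells/day),
#'   `jacobian`, `eigenvalues`, `leading_eigen_real` (/day), `stable`
#'   (TRUE/FALSE, or NA when |Re| < 1e-10 /day, reported as marginal), and
#'   the `params` used. Use [tidy()] / [glance()] for tibble views.
#' @examples
#' eq <- steady_state(model_params())
#' glance(eq)
#' @export
steady_state <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  pu <- as_model_units(params)
  f <- function(N) {
    Y <- dividing_branch(N, pu)
    pu$theta + pu$r * Y - pu$delta0 * exp(N / pu$rho) * (N - Y) -
      pu$mu_prime * Y^2
  }
  lo <- 1e-12
  while (f(lo) <= 0 && lo > 1e-250) lo <- lo / 100
  if (f(lo) <= 0) {
    stop("steady_state: no positive equilibrium detected; f(N) <= 0 down to ",
         "N = ", lo * params$cell_unit, " cells (theta = ", params$theta, ")",
         call. = FALSE)
  }
  hi <- 1
  it <- 0
  while (f(hi) > 0) {
    hi <- hi * 2
    it <- it + 1
    if (it > 200) {
      stop("steady_state: failed to bracket the equilibrium; ",
           "f(N) still positive at N = ", hi * params$cell_unit,
           " cells with parameters theta=", params$theta,
           ", lambda0=", params$lambda0, call. = FALSE)
    }
  }
  Ns <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  Ys <- dividing_branch(Ns, pu)
  st <- newton_refine(c(Ns - Ys, Ys), pu)
  X <- st[1] * params$cell_unit
  Y <- st[2] * params$cell_unit
  res <- rhs_core(X, Y, params$theta, params)
  J <- model_jacobian(X, Y, params)
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  stable <- if (abs(lead) < 1e-10) NA else lead < 0
  structure(list(X = X, Y = Y, N = X + Y, ratio = Y / X,
                 residual = max(abs(res[[1]]), abs(res[[2]])),
                 jacobian = J, eigenvalues = ev,
                 leading_eigen_real = lead, stable = stable,
                 params = params),
            class = "cd4_equilibrium")
}

# unique non-negative root Y of mu' Y^2 + (r + lambda) Y - lambda N = 0
dividing_branch <- function(N, pu) {
  lam <- pu$lambda0 * exp(-N / pu$epsilon)
  b <- pu$r + lam
  (-b + sqrt(b^2 + 4 * pu$mu_prime * lam * N)) / (2 * pu$mu_prime)
}

newton_refine <- function(s, pu, n_iter = 50) {
  for (i in seq_len(n_iter)) {
    d <- rhs_core(s[1], s[2], pu$theta, pu)
    g <- c(d[[1]], d[[2]])
    N <- s[1] + s[2]
    lam <- pu$lambda0 * exp(-N / pu$epsilon)
    del <- pu$delta0 * exp(N / pu$rho)
    lam_p <- -lam / pu$epsilon
    del_p <- del / pu$rho
    J <- matrix(c(-(lam + del) - s[1] * (lam_p + del_p),
                  2 * pu$r - s[1] * (lam_p + del_p),
                  lam + s[1] * lam_p,
                  s[1] * lam_p - pu$r - 2 * pu$mu_prime * s[2]),
                2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, -g), error = function(e) c(0, 0))
    s <- s + step
    if (max(abs(step)) < 1e-15) break
  }
  s
}

#' @export
print.cd4_equilibrium <- function(x, ...) {
  cat("<cd4_equilibrium>\n")
  cat(sprintf("  X* (resting)  %.6g cells\n", x$X))
  cat(sprintf("  Y* (dividing) %.6g cells\n", x$Y))
  cat(sprintf("  N* (total)    %.6g cells   Y/X = %.4g (%.3g%%)\n",
              x$N, x$ratio, 100 * x$ratio))
  cat(sprintf("  residual %.3g cells/day, leading eigenvalue Re %.4g /day (%s)\n",
              x$residual, x$leading_eigen_real,
              if (is.na(x$stable)) "marginal" else if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' @method tidy cd4_equilibrium
#' @export
tidy.cd4_equilibrium <- function(x, ...) {
  tibble::tibble(compartment = c("resting", "dividing"),
                 cells = c(x$X, x$Y))
}

#' @method glance cd4_equilibrium
#' @export
glance.cd4_equilibrium <- function(x, ...) {
  tibble::tibble(N = x$N, X = x$X, Y = x$Y, ratio = x$ratio,
                 residual = x$residual,
                 leading_eigen_real = x$leading_eigen_real,
                 stable = x$stable,
                 interdivision_days = interdivision_time(x$N, x$params))
}

#' Critical parameter value for loss of linear stability
#'
#' Bisects one model parameter over a bracket, recomputing the steady state
#' and the sign of the leading Jacobian eigenvalue's real part at every
#' trial value, and returns the critical value at which stability changes.
#' If the equilibrium has the same stability at both endpoints there is no
#' threshold inside the bracket and `critical_value` is `NA` with
#' `stable_side = "both"` (or `"neither"`); for this model that is the
#' finding for every parameter over physiological brackets — the adult
#' equilibrium is linearly stable throughout (see the package vignette).
#'
#' @param params A [model_params()] object (the non-scanned values).
#' @param param_name One of `"r"`, `"mu_prime"`, `"epsilon"`, `"lambda0"`,
#'   `"theta"`, `"delta0"`, `"rho"`.
#' @param lower,upper Bracket endpoints, in the same absolute units as the
#'   corresponding `model_params` field.
#' @param tol Relative tolerance of the bisection (default 1e-4).
#' @return A one-row tibble: `parameter`, `bracket_lo`, `bracket_hi`,
#'   `critical_value` (NA when stability does not change), `stable_side`
#'   (`"lower"`, `"upper"`, `"both"`, or `"neither"`), and
#'   `lead_lo`/`lead_hi`, the leading eigenvalue real parts at the
#'   endpoints.
#' @examples
#' stability_threshold(model_params(), "r", 0.01, 4)
#' @export
stability_threshold <- function(params, param_name, lower, upper, tol = 1e-4) {
  stopifnot(inherits(params, "model_params"))
  param_name <- match.arg(param_name,
                          c("r", "mu_prime", "epsilon", "lambda0",
                            "theta", "delta0", "rho"))
  stopifnot(is.numeric(lower), is.numeric(upper), lower > 0, upper > lower)
  lead_at <- function(v) {
    steady_state(do.call(update_params,
                         stats::setNames(list(params, v), c("params", param_name)))
    )$leading_eigen_real
  }
  lead_lo <- lead_at(lower)
  lead_hi <- lead_at(upper)
  row <- function(crit, side) {
    tibble::tibble(parameter = param_name, bracket_lo = lower,
                   bracket_hi = upper, critical_value = crit,
                   stable_side = side, lead_lo = lead_lo, lead_hi = lead_hi)
  }
  if (sign(lead_lo) == sign(lead_hi)) {
    return(row(NA_real_, if (lead_lo < 0) "both" else "neither"))
  }
  a <- lower
  b <- upper
  fa <- lead_lo
  while ((b - a) / ((a + b) / 2) > tol) {
    m <- (a + b) / 2
    fm <- lead_at(m)
    if (sign(fm) == sign(fa)) {
      a <- m
      fa <- fm
    } else {
      b <- m
    }
  }
  row((a + b) / 2, if (lead_lo < 0) "lower" else "upper")
}

#' Scan all model parameters for stability thresholds
#'
#' Runs [stability_threshold()] for each kinetic parameter over a default
#' (overridable) bracket and binds the results. Brackets are in absolute
#' units; the defaults correspond to r in \[0.01, 4\] /day, mu_prime in
#' \[15, 500\] and epsilon in \[0.5, 2\] model units of `cell_unit` cells,
#' lambda0 in \[1e-6, 0.11\] /day, theta in \[1e6, 1e10\] cells/day,
#' delta0 in \[0.002, 0.2\] /day and rho in \[10, 1000\] model units.
#'
#' @param params A [model_params()] object.
#' @param brackets Optional named list of `c(lower, upper)` overrides,
#'   absolute units.
#' @param tol Bisection relative tolerance.
#' @return A tibble with one row per parameter (columns as in
#'   [stability_threshold()]).
#' @export
stability_scan <- function(params, brackets = NULL, tol = 1e-4) {
  cu <- params$cell_unit
  def <- list(r = c(0.01, 4),
              mu_prime = c(15, 500) / cu,
              epsilon = c(0.5, 2) * cu,
              lambda0 = c(1e-6, 0.11),
              theta = c(1e6, 1e10),
              delta0 = c(0.002, 0.2),
              rho = c(10, 1000) * cu)
  if (!is.null(brackets)) def[names(brackets)] <- brackets
  purrr::map_dfr(names(def), function(nm) {
    stability_threshold(params, nm, def[[nm]][1], def[[nm]][2], tol = tol)
  })
}
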