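#' Per-cell rates of the homeostasis model
#'
#' `division_rate()` is the per-cell rate at which resting cells enter cell
#' division, `lambda0 * exp(-N / epsilon)`: competition of the whole naive
#' pool for proliferative signals (IL-7, self-peptide MHC) makes it decay
#' exponentially with total cell number. `resting_death_rate()` is the
#' per-cell death rate of resting cells, `delta0 * exp(N / rho)`: survival
#' signals become scarce as the pool grows. `dividing_death_rate()` is the
#' per-cell activation-induced death rate of dividing cells, `mu_prime * Y`,
#' proportional to the dividing-cell density (Fas-Fas ligand mediated).
#'
#' @param N Total naive CD4 cells (resting plus dividing), cells. Vectorised.
#' @param Y Dividing naive CD4 cells, cells. Vectorised.
#' @param params A [model_params()] object.
#' @return Per-cell rate(s), /day.
#' @examples
#' p <- model_params()
#' division_rate(c(0, 1e11), p)
#' resting_death_rate(1e13, p)
#' dividing_death_rate(5e8, p)
#' @export
division_rate <- function(N, params) {
  check_nonneg(N, "N")
  params$lambda0 * exp(-N / params$epsilon)
}

#' @rdname division_rate
#' @export
resting_death_rate <- function(N, params) {
  check_nonneg(N, "N")
  params$delta0 * exp(N / params$rho)
}

#' @rdname division_rate
#' @export
dividing_death_rate <- function(Y, params) {
  check_nonneg(Y, "Y")
  params$mu_prime * Y
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'", name, "' must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Right-hand side of the two-compartment model
#'
#' Time derivatives of the resting (`X`) and dividing (`Y`) compartments:
#' \deqn{dX/dt = \theta + 2 r Y - \lambda(N) X - \delta(N) X}
#' \deqn{dY/dt = \lambda(N) X - r Y - \mu' Y^2}
#' with \eqn{N = X + Y}. The factor 2 encodes that one division returns two
#' resting daughter cells; homeostatic divisions return cells to rest after
#' a single division.
#'
#' @param X Resting cells, cells. Vectorised.
#' @param Y Dividing cells, cells. Vectorised with `X`.
#' @param params A [model_params()] object.
#' @param theta Thymic output to use, cells/day; defaults to `params$theta`.
#'   May be a vector matching `X` for time-varying scenarios.
#' @return A tibble with columns `dX` and `dY`, cells/day.
#' @examples
#' model_rhs(0, 0, model_params())
#' @export
model_rhs <- function(X, Y, params, theta = params$theta) {
  check_nonneg(X, "X")
  check_nonneg(Y, "Y")
  check_nonneg(theta, "theta")
  d <- rhs_core(X, Y, theta, params)
  tibble::tibble(dX = d[[1]], dY = d[[2]])
}

# unchecked vectorised core, shared by the integrator and the tidy wrapper;
# works in whatever cell unit X, Y, theta, epsilon, rho, mu_prime share
rhs_core <- function(X, Y, theta, p) {
  N <- X + Y
  lam <- p$lambda0 * exp(-N / p$epsilon)
  del <- p$delta0 * exp(N / p$rho)
  list(theta + 2 * p$r * Y - (lam + del) * X,
       lam * X - p$r * Y - p$mu_prime * Y^2)
}

#' Mean interdivision time of resting cells
#'
#' The waiting time of a resting cell before its next entry into division at
#' total pool size `N` is exponential with rate `division_rate(N)`; its mean
#' is the reciprocal, `1 / lambda(N)`. At the adult equilibrium this is the
#' model's average time between divisions (about 55 days at defaults).
#'
#' @inheritParams division_rate
#' @return Days (Inf where the division rate underflows to zero).
#' @examples
#' interdivision_time(0, model_params()) # 1 / lambda0
#' @export
interdivision_time <- function(N, params) {
  lam <- division_rate(N, params)
  ifelse(lam > 0, 1 / lam, Inf)
}
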