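#' Kinetic parameters of the two-compartment naive CD4 T cell model
#'
#' Constructs the full parameter set of the homeostasis model: thymic input,
#' resource-competition kinetics of division entry and resting-cell survival,
#' return from division, and density-dependent death of dividing cells.
#' All values are in absolute cells and days. The defaults describe a healthy
#' young adult and correspond, after rescaling cell numbers by `cell_unit`
#' (10^11 cells), to the dimensionless parameterisation theta = 0.003,
#' lambda0 = 0.055, epsilon = 1, delta0 = 0.02, rho = 100, r = 4,
#' mu_prime = 15.
#'
#' The per-cell rates built from these parameters are
#' \deqn{\lambda(N) = \lambda_0 e^{-N/\epsilon}, \quad
#'       \delta(N) = \delta_0 e^{N/\rho}, \quad
#'       \mu(Y) = \mu' Y,}
#' where \eqn{N = X + Y} is the total naive pool competing for IL-7 and
#' self-peptide MHC signals.
#'
#' @param theta Thymic output, cells/day (adult default 3e8).
#' @param lambda0 Intrinsic division-entry rate with unlimited resource, /day.
#' @param epsilon Resource scale for division entry, cells (default 1e11).
#' @param delta0 Intrinsic resting-cell death rate with unlimited resource, /day.
#' @param rho Resource scale for resting-cell survival, cells (default 1e13).
#' @param r Rate of return from the dividing to the resting state, /day
#'   (default 4, i.e. one division completed in about 6 h).
#' @param mu_prime Activation-induced cell death coefficient, /day per cell;
#'   the per-cell death rate of dividing cells is `mu_prime * Y`.
#' @param cell_unit Cells per internal model unit (default 1e11). Only sets
#'   the internal scaling of the integrator and solver tolerances; all inputs
#'   and outputs stay in absolute cells.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' division_rate(1e11, p)
#' @export
model_params <- function(theta = 3e8,
                         lambda0 = 0.055,
                         epsilon = 1e11,
                         delta0 = 0.02,
                         rho = 1e13,
                         r = 4,
                         mu_prime = 15 / 1e11,
                         cell_unit = 1e11) {
  p <- list(theta = theta, lambda0 = lambda0, epsilon = epsilon,
            delta0 = delta0, rho = rho, r = r, mu_prime = mu_prime,
            cell_unit = cell_unit)
  validate_model_params(p)
  structure(p, class = "model_params")
}

param_fields <- c("theta", "lambda0", "epsilon", "delta0", "rho",
                  "r", "mu_prime", "cell_unit")

validate_model_params <- function(p) {
  miss <- setdiff(param_fields, names(p))
  if (length(miss) > 0) {
    stop("missing model parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in param_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model parameter '", f, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> naive CD4 homeostasis kinetics (cells, days)\n")
  cat(sprintf("  theta    %.4g cells/day   thymic output\n", x$theta))
  cat(sprintf("  lambda0  %.4g /day        division entry, no competition\n", x$lambda0))
  cat(sprintf("  epsilon  %.4g cells       division resource scale\n", x$epsilon))
  cat(sprintf("  delta0   %.4g /day        resting death, no competition\n", x$delta0))
  cat(sprintf("  rho      %.4g cells       survival resource scale\n", x$rho))
  cat(sprintf("  r        %.4g /day        return from division\n", x$r))
  cat(sprintf("  mu_prime %.4g /day/cell   AICD coefficient\n", x$mu_prime))
  cat(sprintf("  cell_unit %.4g cells per model unit\n", x$cell_unit))
  invisible(x)
}

# parameters rescaled to model units (cells measured in cell_unit);
# used internally for well-conditioned integration and root-finding
as_model_units <- function(p) {
  cu <- p$cell_unit
  list(theta = p$theta / cu, lambda0 = p$lambda0, epsilon = p$epsilon / cu,
       delta0 = p$delta0, rho = p$rho / cu, r = p$r,
       mu_prime = p$mu_prime * cu, cell_unit = 1)
}

#' @method tidy model_params
#' @export
tidy.model_params <- function(x, ...) {
  tibble::tibble(
    term = param_fields,
    value = vapply(param_fields, function(f) x[[f]], numeric(1)),
    units = c("cells/day", "/day", "cells", "/day", "cells", "/day",
              "/day/cell", "cells")
  )
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#'
#' @param params A [model_params()] object.
#' @param ... Named scalar replacements, e.g. `r = 0.5`.
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), param_fields)
  if (length(bad) > 0) {
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_model_params(p)
  structure(p, class = "model_params")
}
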