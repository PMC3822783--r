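#' Generate a synthetic cross-sectional pediatric cohort
#'
#' Samples subject ages uniformly over `age_range`, evaluates the model's
#' pediatric concentration curve at each age, and multiplies by median-1
#' lognormal noise with coefficient of variation `noise_cv`
#' (`sdlog = sqrt(log(1 + noise_cv^2))`). This emulates the statistical
#' structure of a cross-sectional child cohort (one blood naive CD4 count
#' per subject) for pipeline testing; it carries no within-subject
#' correlation and makes no claim about any real cohort's dispersion.
#'
#' @param params A [model_params()] object.
#' @param cfg An [ontogeny_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns the model curve exactly).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param age_range Two ages, years (default `c(0, 3)`).
#' @return A tibble of class `cd4_cohort` with columns `subject_id`,
#'   `age_years`, `naive_cd4_cells_per_ul`.
#' @examples
#' coh <- generate_cohort(model_params(), ontogeny_config(),
#'                        n_subjects = 20, noise_cv = 0.3, seed = 1)
#' @export
generate_cohort <- function(params, cfg, n_subjects = 500, noise_cv = 0.3,
                            seed = 1, age_range = c(0, 3)) {
  stopifnot(n_subjects >= 1, noise_cv >= 0, length(age_range) == 2,
            age_range[1] >= 0, age_range[2] > age_range[1])
  pred <- simulate_childhood(params, cfg, age_end = age_range[2],
                             age_step = 0.01)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  ages <- stats::runif(n_subjects, age_range[1], age_range[2])
  mu <- stats::approx(pred$age_years, pred$concentration_cells_per_ul,
                      xout = ages)$y
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- if (noise_cv > 0) stats::rlnorm(n_subjects, 0, sdlog) else 1
  out <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n_subjects)),
    age_years = ages,
    naive_cd4_cells_per_ul = mu * noise
  )
  class(out) <- c("cd4_cohort", class(out))
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Compare a cohort against a predicted concentration curve
#'
#' Interpolates the predicted age-concentration curve at each subject's age
#' and summarises the log-scale residuals `log(observed / predicted)`.
#'
#' @param cohort A cohort table with columns `age_years` and
#'   `naive_cd4_cells_per_ul` (e.g. from [generate_cohort()]).
#' @param predicted A `cd4_childhood` tibble (or any data frame with
#'   `age_years` and `concentration_cells_per_ul`) covering the cohort's
#'   age range.
#' @return A one-row tibble: `n`, `rms_log_error` (root mean square of the
#'   log-residuals) and `bias` (their mean; 0 means no systematic over- or
#'   under-prediction).
#' @examples
#' p <- model_params(); cfg <- ontogeny_config()
#' coh <- generate_cohort(p, cfg, 50, noise_cv = 0, seed = 1)
#' compare_cohort(coh, simulate_childhood(p, cfg, age_step = 0.01))
#' @export
compare_cohort <- function(cohort, predicted) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(all(c("age_years", "naive_cd4_cells_per_ul") %in% names(cohort)),
            all(c("age_years", "concentration_cells_per_ul") %in%
                  names(predicted)))
  if (min(cohort$age_years) < min(predicted$age_years) ||
      max(cohort$age_years) > max(predicted$age_years)) {
    stop("prediction does not cover the cohort age range", call. = FALSE)
  }
  mu <- stats::approx(predicted$age_years,
                      predicted$concentration_cells_per_ul,
                      xout = cohort$age_years)$y
  res <- log(cohort$naive_cd4_cells_per_ul / mu)
  tibble::tibble(n = length(res),
                 rms_log_error = sqrt(mean(res^2)),
                 bias = mean(res))
}

#' Recover model parameters from a cohort
#'
#' Minimises the RMS log-error of the pediatric prediction against the
#' cohort over a chosen subset of parameters. Optimisation is on the log
#' scale (positivity enforced by construction) with [stats::optim()]
#' L-BFGS-B, bounded a factor of 10 either side of the initial values.
#'
#' @param cohort A cohort table (see [compare_cohort()]).
#' @param free Character vector naming the free parameters, a subset of
#'   `c("lambda0", "epsilon", "delta0", "blood_fraction")`.
#' @param params Initial [model_params()].
#' @param cfg Initial [ontogeny_config()].
#' @param age_step Prediction grid step used inside the objective, years.
#' @return An object of class `cd4_fit`: estimates (absolute units),
#'   objective value, convergence flag and evaluation count. Use [tidy()]
#'   and [glance()].
#' @examples
#' \donttest{
#' p <- model_params(); cfg <- ontogeny_config()
#' coh <- generate_cohort(p, cfg, 100, noise_cv = 0, seed = 7)
#' fit <- fit_cohort(coh, free = "lambda0",
#'                   params = update_params(p, lambda0 = 0.04), cfg = cfg)
#' tidy(fit)
#' }
#' @export
fit_cohort <- function(cohort, free = "lambda0", params = model_params(),
                       cfg = ontogeny_config(), age_step = 0.05) {
  allowed <- c("lambda0", "epsilon", "delta0", "blood_fraction")
  stopifnot(length(free) >= 1, all(free %in% allowed), nrow(cohort) >= 2)
  init <- vapply(free, function(f) {
    if (f == "blood_fraction") cfg$blood_fraction else params[[f]]
  }, numeric(1))
  age_end <- max(cohort$age_years)
  objective <- function(logv) {
    v <- exp(logv)
    p2 <- params
    c2 <- cfg
    for (i in seq_along(free)) {
      if (free[i] == "blood_fraction") {
        c2$blood_fraction <- v[i]
      } else {
        p2 <- do.call(update_params,
                      c(list(p2), stats::setNames(list(v[i]), free[i])))
      }
    }
    pred <- simulate_childhood(p2, c2, age_end = age_end,
                               age_step = age_step)
    compare_cohort(cohort, pred)$rms_log_error
  }
  opt <- stats::optim(log(init), objective, method = "L-BFGS-B",
                      lower = log(init) - log(10),
                      upper = log(init) + log(10),
                      control = list(factr = 1e9))
  structure(list(estimates = stats::setNames(exp(opt$par), free),
                 objective = opt$value,
                 converged = opt$convergence == 0,
                 n_evals = opt$counts[["function"]],
                 message = opt$message,
                 free = free, init = init),
            class = "cd4_fit")
}

#' @export
print.cd4_fit <- function(x, ...) {
  cat("<cd4_fit> RMS log-error", format(x$objective, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  for (f in x$free) {
    cat(sprintf("  %-14s %.6g (from %.6g)\n", f, x$estimates[[f]],
                x$init[[f]]))
  }
  invisible(x)
}

#' @method tidy cd4_fit
#' @export
tidy.cd4_fit <- function(x, ...) {
  tibble::tibble(term = x$free,
                 estimate = unname(x$estimates),
                 init = unname(x$init))
}

#' @method glance cd4_fit
#' @export
glance.cd4_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_evals = x$n_evals)
}
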