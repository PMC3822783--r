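#' Read and write run configuration files
#'
#' A run configuration is a YAML file with a `model` section (keys exactly
#' `theta`, `lambda0`, `epsilon`, `delta0`, `rho`, `r`, `mu_prime`,
#' `cell_unit`, absolute-cell units) and an optional `ontogeny` section
#' (`theta_birth`, `theta_peak`, `age_peak`, `theta_adult`, `age_adult`,
#' `blood_fraction`, `initial_total`, and a `blood_volume_table` with
#' `age_years` / `volume_litres` vectors), plus free-form `scenario`,
#' `seed` and `outdir` entries used by the command-line driver.
#'
#' @param path File path.
#' @return `read_run_config()` returns a list with elements `params`
#'   ([model_params()]), `ontogeny` ([ontogeny_config()]) and the raw
#'   remaining entries; `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- if (is.null(raw$model)) model_params() else {
    do.call(model_params, raw$model)
  }
  ontogeny <- if (is.null(raw$ontogeny)) ontogeny_config() else {
    o <- raw$ontogeny
    if (!is.null(o$blood_volume_table)) {
      o$blood_volume_table <- tibble::as_tibble(o$blood_volume_table)
    }
    do.call(ontogeny_config, o)
  }
  list(params = params, ontogeny = ontogeny,
       extra = raw[setdiff(names(raw), c("model", "ontogeny"))])
}

#' @rdname read_run_config
#' @param params A [model_params()] object.
#' @param cfg An [ontogeny_config()] object.
#' @param extra Named list of additional top-level entries (scenario, seed,
#'   outdir, ...).
#' @export
write_run_config <- function(path, params = model_params(),
                             cfg = ontogeny_config(), extra = list()) {
  stopifnot(inherits(params, "model_params"),
            inherits(cfg, "ontogeny_config"))
  x <- c(list(
    model = unclass(params),
    ontogeny = list(
      theta_birth = cfg$theta_birth, theta_peak = cfg$theta_peak,
      age_peak = cfg$age_peak, theta_adult = cfg$theta_adult,
      age_adult = cfg$age_adult,
      blood_volume_table = as.list(cfg$blood_volume_table),
      blood_fraction = cfg$blood_fraction,
      initial_total = cfg$initial_total
    )
  ), extra)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a trajectory, prediction, cohort or threshold scan as CSV
#'
#' Plain comma-separated output with a header row; trajectories get a YAML
#' sidecar (same path with extension `.meta.yaml`) recording the parameters
#' and solver tolerances.
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "cd4_trajectory"))
  readr::write_csv(tibble::as_tibble(x), path)
  p <- attr(x, "params")
  yaml::write_yaml(list(params = unclass(p),
                        rtol = attr(x, "rtol"), atol = attr(x, "atol"),
                        time_varying_theta = attr(x, "time_varying_theta")),
                   paste0(tools::file_path_sans_ext(path), ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(all(c("subject_id", "age_years", "naive_cd4_cells_per_ul")
                %in% names(x)))
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV with header `subject_id, age_years,
#'   naive_cd4_cells_per_ul`.
#' @return A `cd4_cohort` tibble.
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           age_years = readr::col_double(),
                           naive_cd4_cells_per_ul = readr::col_double()
                         ))
  class(out) <- c("cd4_cohort", class(out))
  out
}

#' Adult homeostasis scenario
#'
#' Runs the two canonical adult scenarios — a lymphopenic start at 0.01 and
#' an excess start at 2 times 10^11 resting cells, no dividing cells,
#' constant adult thymic output — plus the steady-state analysis, and
#' optionally writes trajectory CSVs and an equilibrium report.
#'
#' @param params A [model_params()] object.
#' @param outdir Optional output directory (created if missing).
#' @param t_end Integration horizon, days.
#' @return A list with `trajectories` (named list of `cd4_trajectory`),
#'   `equilibrium` (a `cd4_equilibrium`) and `summary` (a tibble with one
#'   row per start: final N, convergence time, peak and final ratio).
#' @export
run_adult_scenario <- function(params = model_params(), outdir = NULL,
                               t_end = 1000) {
  cu <- params$cell_unit
  inits <- c(lymphopenic = 0.01 * cu, excess = 2 * cu)
  trajs <- purrr::imap(inits, function(x0, nm) {
    simulate_homeostasis(params, init_resting = x0, t_end = t_end)
  })
  eq <- steady_state(params)
  summary <- purrr::imap_dfr(trajs, function(tr, nm) {
    tibble::tibble(start = nm,
                   init_resting = inits[[nm]],
                   N_final = tr$N_cells[nrow(tr)],
                   convergence_days = convergence_time(tr),
                   peak_ratio = peak_ratio(tr),
                   final_ratio = tr$ratio[nrow(tr)])
  })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(trajs)) {
      write_trajectory_csv(trajs[[nm]],
                           file.path(outdir, paste0("adult_", nm, ".csv")))
    }
    readr::write_csv(summary, file.path(outdir, "adult_summary.csv"))
    readr::write_csv(glance(eq), file.path(outdir, "equilibrium.csv"))
  }
  list(trajectories = trajs, equilibrium = eq, summary = summary)
}

#' Stability threshold scan scenario
#'
#' Runs [stability_scan()] and optionally writes the CSV table
#' (`parameter, bracket_lo, bracket_hi, critical_value, stable_side`).
#'
#' @inheritParams run_adult_scenario
#' @param brackets Optional bracket overrides, see [stability_scan()].
#' @return The scan tibble.
#' @export
run_stability_scan <- function(params = model_params(), outdir = NULL,
                               brackets = NULL) {
  scan <- stability_scan(params, brackets = brackets)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scan, file.path(outdir, "stability_scan.csv"))
  }
  scan
}

#' Pediatric scenario
#'
#' Runs [simulate_childhood()] and, when `n_subjects > 0`, generates a
#' synthetic cohort and the comparison summary.
#'
#' @inheritParams run_adult_scenario
#' @param cfg An [ontogeny_config()].
#' @param age_end Final age, years.
#' @param n_subjects Cohort size (0 skips cohort generation).
#' @param noise_cv Cohort noise coefficient of variation.
#' @param seed Cohort seed.
#' @return A list with `prediction` (a `cd4_childhood`), and when a cohort
#'   is generated, `cohort` and `comparison`.
#' @export
run_child_scenario <- function(params = model_params(),
                               cfg = ontogeny_config(), outdir = NULL,
                               age_end = 3, n_subjects = 0, noise_cv = 0.3,
                               seed = 1) {
  pred <- simulate_childhood(params, cfg, age_end = age_end)
  out <- list(prediction = pred)
  if (n_subjects > 0) {
    out$cohort <- generate_cohort(params, cfg, n_subjects = n_subjects,
                                  noise_cv = noise_cv, seed = seed,
                                  age_range = c(0, age_end))
    fine <- simulate_childhood(params, cfg, age_end = age_end,
                               age_step = 0.01)
    out$comparison <- compare_cohort(out$cohort, fine)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(pred, file.path(outdir, "child_prediction.csv"))
    if (!is.null(out$cohort)) {
      write_cohort_csv(out$cohort, file.path(outdir, "cohort.csv"))
      readr::write_csv(out$comparison,
                       file.path(outdir, "cohort_comparison.csv"))
    }
  }
  out
}
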