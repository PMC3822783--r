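#' Age-dependent configuration for the pediatric scenario
#'
#' Bundles the thymic-output ontogeny curve, the blood-volume curve and the
#' blood compartment fraction used to convert whole-body naive CD4 numbers
#' into blood concentrations (cells/ul) in children.
#'
#' Thymic output rises from `theta_birth` at birth to its lifetime maximum
#' `theta_peak` at `age_peak` (about 1 year), then declines to the adult
#' value `theta_adult` by `age_adult` (20 years). Blood volume is linearly
#' interpolated from `blood_volume_table`; the shipped default table is a
#' synthetic fixture built from roughly 80 ml of blood per kg of body
#' weight against a standard weight-for-age curve (neonate about 0.3 L,
#' adult about 5 L) — replace it with measured volumes where available.
#'
#' @param theta_birth Thymic output at age 0, cells/day (default 4e8).
#' @param theta_peak Peak thymic output, cells/day (default 2e9).
#' @param age_peak Age of the peak, years (default 1).
#' @param theta_adult Adult thymic output, cells/day (default 3e8).
#' @param age_adult Age at which the adult value is reached, years (20).
#' @param blood_volume_table Data frame with numeric columns `age_years`
#'   and `volume_litres`, both strictly increasing.
#' @param blood_fraction Fraction of whole-body naive CD4 cells circulating
#'   in blood (default 0.02).
#' @param initial_total Whole-body naive CD4 cells at birth (default 1e10).
#' @return An object of class `ontogeny_config`.
#' @examples
#' cfg <- ontogeny_config()
#' theta_of_age(c(0, 1, 20), cfg)
#' @export
ontogeny_config <- function(theta_birth = 4e8,
                            theta_peak = 2e9,
                            age_peak = 1,
                            theta_adult = 3e8,
                            age_adult = 20,
                            blood_volume_table = default_blood_volume_table(),
                            blood_fraction = 0.02,
                            initial_total = 1e10) {
  stopifnot(theta_birth > 0, theta_peak > 0, theta_adult > 0,
            age_peak > 0, age_adult > age_peak,
            blood_fraction > 0, blood_fraction <= 1, initial_total >= 0)
  if (theta_peak < theta_birth || theta_peak < theta_adult) {
    stop("'theta_peak' must be the global maximum of the ontogeny curve",
         call. = FALSE)
  }
  tb <- blood_volume_table
  if (!all(c("age_years", "volume_litres") %in% names(tb)) ||
      any(diff(tb$age_years) <= 0) || any(diff(tb$volume_litres) <= 0)) {
    stop("'blood_volume_table' needs strictly increasing columns ",
         "'age_years' and 'volume_litres'", call. = FALSE)
  }
  structure(list(theta_birth = theta_birth, theta_peak = theta_peak,
                 age_peak = age_peak, theta_adult = theta_adult,
                 age_adult = age_adult,
                 blood_volume_table = tibble::as_tibble(tb),
                 blood_fraction = blood_fraction,
                 initial_total = initial_total),
            class = "ontogeny_config")
}

#' Default pediatric blood-volume table (synthetic fixture)
#'
#' A monotone age-to-blood-volume table constructed from ~80 ml/kg against
#' a standard weight-for-age reference; not a measured dataset.
#'
#' @return A tibble with columns `age_years` and `volume_litres`.
#' @export
default_blood_volume_table <- function() {
  tibble::tibble(
    age_years = c(0, 0.25, 0.5, 1, 2, 3, 5, 10, 15, 20),
    volume_litres = c(0.30, 0.45, 0.60, 0.76, 0.96, 1.12, 1.45, 2.50,
                      4.00, 5.00)
  )
}

#' Thymic output as a function of age
#'
#' Continuous curve anchored at `theta(0) = theta_birth`,
#' `theta(age_peak) = theta_peak` (global maximum) and
#' `theta(age_adult) = theta_adult`: a smooth cubic (Hermite smoothstep,
#' zero slope at both ends) rises to the peak, an exponential decay with
#' rate `log(theta_peak / theta_adult) / (age_adult - age_peak)`
#' (about 0.0998 /year at defaults) reaches the adult value, and output is
#' held at `theta_adult` thereafter.
#'
#' @param age Age(s), years, non-negative.
#' @param cfg An [ontogeny_config()].
#' @return Thymic output, cells/day.
#' @export
theta_of_age <- function(age, cfg) {
  stopifnot(inherits(cfg, "ontogeny_config"))
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("'age' must be finite and non-negative", call. = FALSE)
  }
  k <- log(cfg$theta_peak / cfg$theta_adult) / (cfg$age_adult - cfg$age_peak)
  s <- pmin(age / cfg$age_peak, 1)
  rise <- cfg$theta_birth + (cfg$theta_peak - cfg$theta_birth) *
    (3 * s^2 - 2 * s^3)
  decay <- cfg$theta_peak * exp(-k * (pmin(age, cfg$age_adult) - cfg$age_peak))
  ifelse(age <= cfg$age_peak, rise, decay)
}

#' Blood volume as a function of age
#'
#' Linear interpolation of the configured blood-volume table. Ages outside
#' the table range are rejected rather than extrapolated.
#'
#' @inheritParams theta_of_age
#' @return Blood volume, litres.
#' @export
blood_volume <- function(age, cfg) {
  stopifnot(inherits(cfg, "ontogeny_config"))
  tb <- cfg$blood_volume_table
  if (any(age < min(tb$age_years)) || any(age > max(tb$age_years))) {
    stop("'age' outside the blood-volume table range [",
         min(tb$age_years), ", ", max(tb$age_years), "] years",
         call. = FALSE)
  }
  stats::approx(tb$age_years, tb$volume_litres, xout = age)$y
}

#' Blood naive CD4 concentration from whole-body numbers
#'
#' Converts a whole-body naive CD4 cell count to a blood concentration:
#' `blood_fraction * N_total / blood_volume(age)` with the volume in
#' microlitres.
#'
#' @param N_total Whole-body naive CD4 cells.
#' @param age Age, years.
#' @param cfg An [ontogeny_config()].
#' @return Concentration, cells/ul.
#' @examples
#' cd4_concentration(1.1e11, 20, ontogeny_config())
#' @export
cd4_concentration <- function(N_total, age, cfg) {
  check_nonneg(N_total, "N_total")
  vol_ul <- blood_volume(age, cfg) * 1e6
  if (any(vol_ul <= 0)) stop("blood volume must be positive", call. = FALSE)
  cfg$blood_fraction * N_total / vol_ul
}

#' Pediatric scenario: naive CD4 concentration over childhood
#'
#' Integrates the homeostasis model from birth with the age-dependent
#' thymic output `theta_of_age()` and fixed adult kinetic parameters,
#' starting from `cfg$initial_total` resting cells and no dividing cells,
#' and converts whole-body totals to blood concentrations with the
#' age-dependent blood volume. Only thymic output and body growth vary
#' with age; the homeostatic mechanism itself is unchanged.
#'
#' @param params A [model_params()] object (adult kinetics).
#' @param cfg An [ontogeny_config()].
#' @param age_end Final age, years (default 3; must lie inside the
#'   blood-volume table).
#' @param age_step Output grid step, years (default 0.05).
#' @return A tibble of class `cd4_childhood` with columns `age_years`,
#'   `N_total_cells`, `concentration_cells_per_ul`.
#' @examples
#' ped <- simulate_childhood(model_params(), ontogeny_config())
#' head(ped)
#' @export
simulate_childhood <- function(params, cfg, age_end = 3, age_step = 0.05) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "ontogeny_config"),
            age_end > 0, age_step > 0)
  if (age_end > max(cfg$blood_volume_table$age_years)) {
    stop("'age_end' exceeds the blood-volume table range", call. = FALSE)
  }
  ages <- seq(0, age_end, by = age_step)
  if (ages[length(ages)] < age_end) ages <- c(ages, age_end)
  traj <- simulate_homeostasis(
    params,
    init_resting = cfg$initial_total, init_dividing = 0,
    t_end = age_end * 365.25,
    theta_fn = function(t) theta_of_age(t / 365.25, cfg)
  )
  N <- stats::approx(traj$time_days, traj$N_cells,
                     xout = ages * 365.25)$y
  out <- tibble::tibble(age_years = ages, N_total_cells = N,
                        concentration_cells_per_ul =
                          cd4_concentration(N, ages, cfg))
  class(out) <- c("cd4_childhood", class(out))
  attr(out, "params") <- params
  attr(out, "config") <- cfg
  out
}
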