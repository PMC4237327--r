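#' NSC population parameters
#'
#' The neural stem cell pool is modelled as exponentially declining from
#' its size at birth: `N(t) = N0 * exp(-k t)`. `N0` has no default - it
#' must be supplied from an empirical estimate of the proliferative pool
#' at birth. The decay constant `k` is in principle measurable, but in
#' practice is calibrated against demographic incidence data (see
#' [fit_incidence_model()]); note that in the small-probability regime
#' only the product `N0 * S` is identified, so calibration holds `N0`
#' fixed.
#'
#' @param N0 NSC count at birth (cells, `> 0`).
#' @param k Exponential decay constant (per year, `>= 0`).
#' @return An object of class `population_params`.
#' @examples
#' population_params(N0 = 1e5, k = 0.04)
#' @export
population_params <- function(N0, k) {
  check_number(N0, "N0")
  if (N0 <= 0) abort("`N0` must be positive.")
  check_number(k, "k", lower = 0)
  structure(list(N0 = N0, k = k), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> N0 = %g cells, k = %g per year\n",
              x$N0, x$k))
  invisible(x)
}

#' Division-rate schedule
#'
#' Per-cell division rate across the lifespan. Rodent-derived estimates
#' indicate that actively-cycling NSCs divide about 251 times per year in
#' the young adult and 318 times per year in the aged adult; the default
#' schedule interpolates linearly between these anchors from age 0 to age
#' 85 and clamps to the endpoint values outside that window. The
#' `"constant"` mode holds the rate at `r_young` everywhere, for scenario
#' comparisons of what the age-related rate increase contributes.
#'
#' @param mode `"linear"` (default) or `"constant"`.
#' @param r_young Divisions per cell per year at `t_start` (default 251).
#' @param r_aged Divisions per cell per year at `t_end` (default 318).
#' @param t_start,t_end Age anchors in years (defaults 0 and 85).
#' @return An object of class `division_schedule`.
#' @examples
#' division_schedule()
#' division_schedule("constant")
#' @export
division_schedule <- function(mode = c("linear", "constant"),
                              r_young = 251, r_aged = 318,
                              t_start = 0, t_end = 85) {
  mode <- match.arg(mode)
  check_number(r_young, "r_young")
  check_number(r_aged, "r_aged")
  if (r_young <= 0 || r_aged <= 0) abort("division rates must be positive.")
  check_number(t_start, "t_start", lower = 0)
  check_number(t_end, "t_end")
  if (t_start >= t_end) abort("`t_start` must be below `t_end`.")
  structure(
    list(mode = mode, r_young = r_young, r_aged = r_aged,
         t_start = t_start, t_end = t_end),
    class = "division_schedule"
  )
}

#' @export
print.division_schedule <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<division_schedule> constant %g divisions/cell/year\n",
                x$r_young))
  } else {
    cat(sprintf(
      "<division_schedule> linear %g -> %g divisions/cell/year over ages %g-%g\n",
      x$r_young, x$r_aged, x$t_start, x$t_end))
  }
  invisible(x)
}

#' Division rate at a given age
#'
#' @param t Age in years (vectorised, `>= 0`).
#' @param schedule A [division_schedule()].
#' @return Divisions per cell per year at each age.
#' @examples
#' division_rate(c(0, 42.5, 85), division_schedule())
#' @export
division_rate <- function(t, schedule = division_schedule()) {
  stopifnot(inherits(schedule, "division_schedule"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.")
  }
  if (schedule$mode == "constant") {
    return(rep(schedule$r_young, length(t)))
  }
  frac <- pmin(pmax((t - schedule$t_start) /
                      (schedule$t_end - schedule$t_start), 0), 1)
  schedule$r_young + (schedule$r_aged - schedule$r_young) * frac
}

#' Cumulative divisions by a given age
#'
#' Integral of the division rate from birth to age `t`, computed from
#' the closed-form piecewise-linear antiderivative (no quadrature error).
#' This is the expected number of divisions a single NSC surviving to age
#' `t` has undergone, and sets the Poisson mutation intensity
#' `lambda = u_o * D(t)`.
#'
#' @inheritParams division_rate
#' @return Cumulative division count `D(t)` at each age; `D(0) = 0`.
#' @examples
#' cumulative_divisions(85, division_schedule())  # (251 + 318)/2 * 85
#' @export
cumulative_divisions <- function(t, schedule = division_schedule()) {
  stopifnot(inherits(schedule, "division_schedule"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.")
  }
  if (schedule$mode == "constant") {
    return(schedule$r_young * t)
  }
  t0 <- schedule$t_start
  t1 <- schedule$t_end
  slope <- (schedule$r_aged - schedule$r_young) / (t1 - t0)
  tc <- pmin(pmax(t, t0), t1)
  # flat at r_young before t0, linear ramp on [t0, t1], flat at r_aged after
  schedule$r_young * pmin(t, t0) +
    (schedule$r_young * (tc - t0) + 0.5 * slope * (tc - t0)^2) +
    schedule$r_aged * pmax(t - t1, 0)
}

#' NSC pool size at a given age
#'
#' @param t Age in years (vectorised, `>= 0`).
#' @param params A [population_params()].
#' @return `N0 * exp(-k t)` at each age.
#' @examples
#' population_size(c(0, 40, 80), population_params(N0 = 1e5, k = 0.04))
#' @export
population_size <- function(t, params) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.")
  }
  params$N0 * exp(-params$k * t)
}

#' Empirical-derivation constants
#'
#' Scaling constants used to convert the published histology counts into
#' model parameters: the number of 48-hour periods per year used to
#' annualise time-lapse division counts, the per-millimetre scaling of a
#' tissue-section count (1000 / section thickness in microns), and the
#' length of the proliferative tract in millimetres.
#'
#' `periods_per_year` defaults to 183 (= 366/2), the value under which
#' both published time-lapse rates annualise to the printed integers
#' (1.37 -> 251 and 1.74 -> 318); with 182.5 the former would round to
#' 250.
#'
#' @param periods_per_year 48-hour periods per year (default 183).
#' @param tract_length_mm Proliferative tract length in mm (default 10).
#' @return A named list of class `derivation_constants`.
#' @export
derivation_constants <- function(periods_per_year = 183,
                                 tract_length_mm = 10) {
  check_number(periods_per_year, "periods_per_year")
  if (periods_per_year <= 0) abort("`periods_per_year` must be positive.")
  check_number(tract_length_mm, "tract_length_mm")
  if (tract_length_mm <= 0) abort("`tract_length_mm` must be positive.")
  structure(list(periods_per_year = periods_per_year,
                 tract_length_mm = tract_length_mm),
            class = "derivation_constants")
}

#' Annualise a 48-hour division count
#'
#' Converts a division count observed over a 48-hour live-imaging window
#' into divisions per cell per year, rounding to the nearest integer as
#' the published rates do.
#'
#' @param divisions_per_48h Divisions per cell in 48 hours (`>= 0`).
#' @param constants A [derivation_constants()].
#' @return Integer divisions per cell per year.
#' @examples
#' annual_rate_from_48h(1.37)  # 251
#' annual_rate_from_48h(1.74)  # 318
#' @export
annual_rate_from_48h <- function(divisions_per_48h,
                                 constants = derivation_constants()) {
  stopifnot(inherits(constants, "derivation_constants"))
  if (!is.numeric(divisions_per_48h) || any(!is.finite(divisions_per_48h)) ||
      any(divisions_per_48h < 0)) {
    abort("`divisions_per_48h` must be non-negative and finite.")
  }
  round(divisions_per_48h * constants$periods_per_year)
}

#' Scale a tissue-section cell count to cells per millimetre
#'
#' Converts a count of immunolabelled cells in a section of known
#' thickness into cells per millimetre of tract
#' (`count * 1000 / thickness_um`), the first step of the scaling chain
#' that estimates the proliferative NSC pool from histology.
#'
#' @param count Cells counted per section (`>= 0`).
#' @param thickness_um Section thickness in microns (`> 0`).
#' @return Cells per millimetre.
#' @examples
#' cells_per_mm_from_section(144, 200)  # ~720 DCX+ cells per mm
#' cells_per_mm_from_section(22, 30)    # ~733, consistent
#' @export
cells_per_mm_from_section <- function(count, thickness_um) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0)) {
    abort("`count` must be non-negative and finite.")
  }
  check_number(thickness_um, "thickness_um")
  if (thickness_um <= 0) abort("`thickness_um` must be positive.")
  count * 1000 / thickness_um
}
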