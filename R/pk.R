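#' In-vitro MPS pharmacokinetics
#'
#' Dose-translation toolkit for organ-on-chip studies: non-specific-binding
#' recovery, rapid-equilibrium-dialysis protein binding, log-linear
#' half-life estimation, simulation of the daily spike-to-nominal dosing
#' regimen with periodic full media changes, and anchoring of MPS dose
#' levels to clinical exposures.  Units are hours and micromolar
#' throughout.
#'
#' @name pk
NULL

#' Concentration time series
#'
#' @param analyte Compound name.
#' @param times_h Strictly increasing sampling times, hours.
#' @param conc_uM Measured concentrations, micromolar (non-negative).
#' @param input_conc_uM Nominal input (dosed) concentration.
#' @return A `conc_series` data frame with attributes `analyte` and
#'   `input_conc_uM`.
#' @export
conc_series <- function(analyte, times_h, conc_uM, input_conc_uM = NA) {
  if (length(times_h) != length(conc_uM))
    abort_input("times_h and conc_uM differ in length")
  if (is.unsorted(times_h, strictly = TRUE) || any(times_h < 0))
    abort_input("times_h must be non-negative and strictly increasing")
  if (any(conc_uM < 0)) abort_input("concentrations must be >= 0")
  structure(data.frame(time_h = times_h, conc_uM = conc_uM),
            analyte = analyte, input_conc_uM = input_conc_uM,
            class = c("conc_series", "data.frame"))
}

#' Percent recovery relative to input concentration
#'
#' The device-binding check: the final measured concentration after a blank
#' (cell-free) incubation as a percentage of the input concentration.
#' Scale-invariant: multiplying all concentrations by a constant changes
#' nothing.
#'
#' @param series A [conc_series()] with a known `input_conc_uM`.
#' @return List: `percent_recovery`, `n_points`.
#' @export
estimate_recovery <- function(series) {
  input <- attr(series, "input_conc_uM")
  if (is.null(input) || is.na(input) || input <= 0)
    abort_input("series carries no positive input_conc_uM")
  if (nrow(series) < 1L) abort_input("series has no measurements")
  final <- series$conc_uM[nrow(series)]
  list(percent_recovery = 100 * final / input, n_points = nrow(series))
}

#' Fraction unbound from rapid equilibrium dialysis
#'
#' `fu = buffer / chamber`, clipped into `[0, 1]` with a flag when
#' clipping was needed; `percent_bound = 100 * (1 - fu)`.
#'
#' @param buffer_conc_uM Concentration in the (protein-free) buffer
#'   chamber.
#' @param chamber_conc_uM Concentration in the protein (media) chamber.
#' @return List: `fu`, `percent_bound`, `clipped`.
#' @export
estimate_fu <- function(buffer_conc_uM, chamber_conc_uM) {
  if (!is_number(chamber_conc_uM) || chamber_conc_uM <= 0)
    abort_input("chamber concentration must be > 0")
  if (!is_number(buffer_conc_uM) || buffer_conc_uM < 0)
    abort_input("buffer concentration must be >= 0")
  fu_raw <- buffer_conc_uM / chamber_conc_uM
  fu <- min(1, max(0, fu_raw))
  list(fu = fu, percent_bound = 100 * (1 - fu), clipped = fu != fu_raw)
}

#' Fit a first-order elimination half-life by log-linear regression
#'
#' Ordinary least squares of `ln(conc)` on time; `k = -slope`,
#' `t_half = ln 2 / k`.  Non-positive concentrations are excluded (with a
#' message); fewer than 3 usable points is an error.  A non-negative
#' fitted slope flags the series as non-eliminating with an undefined
#' half-life.
#'
#' @param series A [conc_series()].
#' @return A `pk_fit`: `k_per_h`, `t_half_h`, `c0_uM`, `r_squared`,
#'   `se_k`, `n_used`, `n_dropped`, `non_eliminating`.
#' @export
fit_halflife <- function(series) {
  ok <- series$conc_uM > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("excluding ", n_dropped, " non-positive concentration(s)")
  if (sum(ok) < 3L)
    abort_input("need >= 3 positive measurements, have %d", sum(ok))
  t <- series$time_h[ok]
  y <- log(series$conc_uM[ok])
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2])
  # noise-free fixtures fit perfectly; the summary() warning is expected
  sm <- suppressWarnings(summary(fit))
  se_k <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  k <- -slope
  non_elim <- k <= 0
  structure(list(
    k_per_h = k,
    t_half_h = if (non_elim) NA_real_ else log(2) / k,
    c0_uM = exp(unname(coef(fit)[1])),
    r_squared = r2, se_k = se_k,
    n_used = sum(ok), n_dropped = n_dropped,
    non_eliminating = non_elim), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  if (x$non_eliminating) {
    cat("PK fit: non-eliminating (k <= 0)\n")
  } else {
    cat(sprintf("PK fit: k = %.4g /h, t1/2 = %.3g h, r^2 = %.4f (n = %d)\n",
                x$k_per_h, x$t_half_h, x$r_squared, x$n_used))
  }
  invisible(x)
}

#' Dosing regimen of media changes and spikes
#'
#' Event kinds: `full_change_redose` (complete media change, redosed to
#' nominal) and `spike_to_nominal` (compound spiked in to restore the
#' nominal concentration; never above it).
#'
#' @param nominal_dose_uM Target concentration restored at every event.
#' @param events Data frame with `time_h` (strictly increasing, within
#'   `(0, duration_h]`) and `kind`.
#' @param duration_h Total simulated duration, hours.
#' @return A `dose_regimen`.
#' @export
dose_regimen <- function(nominal_dose_uM, events, duration_h) {
  if (nominal_dose_uM <= 0) abort_input("nominal_dose_uM must be > 0")
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(time_h = numeric(0), kind = character(0))
  } else {
    if (!all(events$kind %in% c("full_change_redose", "spike_to_nominal")))
      abort_input("unknown event kind")
    if (is.unsorted(events$time_h, strictly = TRUE))
      abort_input("event times must be strictly increasing")
    if (any(events$time_h <= 0) || any(events$time_h > duration_h))
      abort_input("event times must lie in (0, duration_h]")
  }
  structure(list(nominal_dose_uM = nominal_dose_uM, events = events,
                 duration_h = duration_h), class = "dose_regimen")
}

#' Daily spike-to-nominal regimen with 48-h full media changes
#'
#' The standard protocol: compound added at time zero, a full media change
#' with redose every `full_change_every_h`, and on intervening days a
#' spike back to the nominal concentration.
#'
#' @param nominal_dose_uM Nominal dose, micromolar.
#' @param duration_h Total duration, hours.
#' @param interval_h Dosing interval (default daily).
#' @param full_change_every_h Full media change period (default 48 h).
#' @return A [dose_regimen()].
#' @export
daily_regimen <- function(nominal_dose_uM, duration_h = 240,
                          interval_h = 24, full_change_every_h = 48) {
  times <- seq(interval_h, duration_h, by = interval_h)
  kind <- ifelse(times %% full_change_every_h == 0,
                 "full_change_redose", "spike_to_nominal")
  dose_regimen(nominal_dose_uM,
               data.frame(time_h = times, kind = kind), duration_h)
}

#' Simulate the exposure profile under a dosing regimen
#'
#' Between events the concentration decays as
#' `C(t) = C(t_e) * exp(-k (t - t_e))`; at every event it is reset exactly
#' to the nominal dose (both event kinds restore nominal).  The AUC is
#' computed by exact piecewise integration, `cmin` is the lowest
#' pre-event/terminal trough and `cmax` the nominal dose.
#'
#' @param k_per_h Elimination rate (>= 0).
#' @param regimen A [dose_regimen()].
#' @param grid_step_h Reporting grid step for the dense profile.
#' @return An `exposure_profile`: `times_h`, `conc_uM`, `cmax_uM`,
#'   `cmin_uM`, `c_avg_uM`, `auc_uM_h`, `troughs` (per-event pre-event
#'   concentrations).
#' @export
simulate_regimen <- function(k_per_h, regimen, grid_step_h = 0.25) {
  if (k_per_h < 0) abort_input("k_per_h must be >= 0")
  stopifnot(inherits(regimen, "dose_regimen"))
  D <- regimen$nominal_dose_uM
  bounds <- c(0, regimen$events$time_h, regimen$duration_h)
  bounds <- unique(bounds)
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  seg_auc <- numeric(length(seg_start))
  troughs <- numeric(length(seg_start))
  times <- numeric(0); conc <- numeric(0)
  for (i in seq_along(seg_start)) {
    dt <- seg_end[i] - seg_start[i]
    seg_auc[i] <- if (k_per_h > 0) D * (-expm1(-k_per_h * dt)) / k_per_h
                  else D * dt
    troughs[i] <- D * exp(-k_per_h * dt)
    tt <- seq(seg_start[i], seg_end[i], by = grid_step_h)
    if (tt[length(tt)] < seg_end[i]) tt <- c(tt, seg_end[i])
    times <- c(times, tt)
    conc <- c(conc, D * exp(-k_per_h * (tt - seg_start[i])))
  }
  structure(list(times_h = times, conc_uM = conc,
                 cmax_uM = D, cmin_uM = min(troughs),
                 auc_uM_h = sum(seg_auc),
                 c_avg_uM = sum(seg_auc) / regimen$duration_h,
                 troughs = troughs), class = "exposure_profile")
}

#' Clinical exposure anchor
#'
#' @param plasma_cmax_uM Clinical plasma Cmax, micromolar.
#' @param liver_cmax_uM Optional liver Cmax.
#' @param plasma_protein_binding Optional percent bound in plasma.
#' @return A `clinical_anchor`.
#' @export
clinical_anchor <- function(plasma_cmax_uM, liver_cmax_uM = NULL,
                            plasma_protein_binding = NULL) {
  if (plasma_cmax_uM <= 0) abort_input("plasma_cmax_uM must be > 0")
  if (!is.null(liver_cmax_uM) && liver_cmax_uM <= 0)
    abort_input("liver_cmax_uM must be > 0")
  structure(list(plasma_cmax_uM = plasma_cmax_uM,
                 liver_cmax_uM = liver_cmax_uM,
                 plasma_protein_binding = plasma_protein_binding),
            class = "clinical_anchor")
}

#' Translate clinical exposure anchors into MPS dose levels
#'
#' Each dose level is `anchor concentration x multiplier`; levels are
#' returned sorted ascending with their provenance.
#'
#' @param anchor A [clinical_anchor()].
#' @param multipliers Data frame with columns `anchor` (`"plasma"` or
#'   `"liver"`) and `multiplier` (> 0).
#' @return Data frame: `dose_uM`, `anchor`, `multiplier`, ascending in
#'   dose.
#' @export
translate_dose <- function(anchor, multipliers) {
  stopifnot(inherits(anchor, "clinical_anchor"))
  if (!all(multipliers$anchor %in% c("plasma", "liver")))
    abort_input("anchor must be 'plasma' or 'liver'")
  if (any(multipliers$multiplier <= 0))
    abort_input("multipliers must be > 0")
  if (any(multipliers$anchor == "liver") && is.null(anchor$liver_cmax_uM))
    abort_input("liver anchor requested but liver_cmax_uM is absent")
  base <- ifelse(multipliers$anchor == "plasma",
                 anchor$plasma_cmax_uM,
                 anchor$liver_cmax_uM %||% NA_real_)
  out <- data.frame(dose_uM = base * multipliers$multiplier,
                    anchor = multipliers$anchor,
                    multiplier = multipliers$multiplier)
  out[order(out$dose_uM), , drop = FALSE]
}
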