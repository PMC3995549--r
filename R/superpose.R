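# Nonparametric superposition: predict concentration profiles and AUC_last
# at untested doses/regimens from a single low-dose profile, assuming
# dose-linearity.  Model-free by construction: the reference profile is
# interpolated within the observed range and extended mono-exponentially
# beyond it, then shifted, dose-scaled copies are summed.

#' Dosing regimen
#'
#' @param times Dose times, hr (non-negative, strictly increasing).
#' @param amounts Dose amounts, mg (> 0), recycled to `length(times)`.
#' @param t_end End of the observation window, hr (> last dose time).
#' @return An object of class `regimen`.
#' @export
regimen <- function(times = 0, amounts = 1, t_end = 72) {
  amounts <- rep_len(amounts, length(times))
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE),
            all(amounts > 0), t_end > times[length(times)])
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 t_end = as.numeric(t_end)), class = "regimen")
}

#' Extend a profile beyond its last observed sample
#'
#' Beyond the last quantifiable time `t_last`, the concentration follows the
#' fitted terminal phase: `C(t) = C(t_last) * exp(-lambda_z * (t - t_last))`.
#' The observed segment is unchanged (linear interpolation between samples).
#'
#' @param profile A [conc_profile()] dosed at t = 0.
#' @param terminal A `terminal_phase` from [fit_lambda_z()]; fitted from
#'   `profile` when omitted.
#' @param t_end Nominal extension horizon, hr (>= last sample time).
#'   Evaluation beyond `t_end` remains possible; the terminal phase simply
#'   continues.
#' @return An object of class `extended_profile`.
#' @export
extend_profile <- function(profile, terminal = NULL, t_end = NULL) {
  if (is.null(terminal)) terminal <- fit_lambda_z(profile)
  stopifnot(inherits(terminal, "terminal_phase"), terminal$lambda_z > 0)
  pts <- usable_points(profile)
  t_last <- max(pts$time)
  if (is.null(t_end)) t_end <- t_last
  if (t_end < t_last) stop("t_end must be >= the last observed time")
  structure(list(profile = profile, points = pts, terminal = terminal,
                 t_last = t_last, c_last = pts$conc[which.max(pts$time)],
                 t_end = t_end),
            class = "extended_profile")
}

#' Evaluate an extended profile at arbitrary times
#'
#' Zero before the first sample shifted to dosing (t < 0), linear
#' interpolation within the observed range, mono-exponential terminal decay
#' beyond it.
#'
#' @param extended An [extend_profile()] result.
#' @param t Times, hr (any real vector).
#' @return Concentrations, ng/mL.
#' @export
conc_at <- function(extended, t) {
  stopifnot(inherits(extended, "extended_profile"))
  pts <- extended$points
  out <- numeric(length(t))
  t0 <- min(pts$time)
  obs <- t >= t0 & t <= extended$t_last
  if (any(obs))
    out[obs] <- stats::approx(pts$time, pts$conc, xout = t[obs], rule = 1)$y
  tail <- t > extended$t_last
  if (any(tail))
    out[tail] <- extended$c_last *
      exp(-extended$terminal$lambda_z * (t[tail] - extended$t_last))
  out  # t < t0 (pre-dose of a shifted copy): zero
}

#' Superpose a reference profile over a dosing regimen
#'
#' Predicted concentration at time t is the sum over dose events k of
#' `(D_k / D_ref) * C_ref(t - t_k)`, terms vanishing before each dose.
#' Evaluation uses a dense grid (default 0.1 hr) augmented with every
#' reference sample time shifted to every dose event, so piecewise-linear
#' segments are represented exactly.
#'
#' @param reference An [extend_profile()] result whose underlying profile
#'   was dosed at t = 0.
#' @param regimen A [regimen()].
#' @param grid_step Dense grid spacing, hr.
#' @return An object of class `superposed_profile` with fields `time`,
#'   `conc`, `regimen`, `reference_dose`.
#' @export
superpose <- function(reference, regimen, grid_step = 0.1) {
  stopifnot(inherits(reference, "extended_profile"),
            inherits(regimen, "regimen"))
  d_ref <- reference$profile$dose$amount
  shifted <- unlist(lapply(regimen$times,
                           function(tk) tk + reference$points$time))
  grid <- sort(unique(c(seq(0, regimen$t_end, by = grid_step),
                        regimen$t_end, regimen$times, shifted)))
  grid <- grid[grid >= 0 & grid <= regimen$t_end]
  conc <- numeric(length(grid))
  for (k in seq_along(regimen$times)) {
    conc <- conc + (regimen$amounts[k] / d_ref) *
      conc_at(reference, grid - regimen$times[k])
  }
  structure(list(time = grid, conc = conc, regimen = regimen,
                 reference_dose = d_ref),
            class = "superposed_profile")
}

#' AUC of a superposed profile over a window
#'
#' Linear trapezoid on the superposed evaluation grid.
#'
#' @param sp A [superpose()] result.
#' @param t_start,t_end Window, hr; defaults to the full grid.
#' @return AUC in ng.hr/mL.
#' @export
superposed_auc <- function(sp, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(sp, "superposed_profile"))
  if (is.null(t_start)) t_start <- min(sp$time)
  if (is.null(t_end)) t_end <- max(sp$time)
  .trapz_window(sp$time, sp$conc, t_start, t_end)
}

#' Predict AUC_last as a function of dose
#'
#' For each dose D on the grid, the regimen template's amounts are scaled so
#' that the total administered dose is D, the reference profile is
#' superposed over the scaled regimen, and AUC is computed over the
#' template's observation window.  With the default single-dose template
#' this reduces to linear scaling through the reference point.
#'
#' @param reference A [conc_profile()] or [extend_profile()] result.
#' @param terminal Optional `terminal_phase` (fitted from the profile when
#'   needed and omitted).
#' @param regimen_template A [regimen()]; default a single dose observed
#'   over 0-72 hr.
#' @param doses Dose grid, mg (positive).
#' @param grid_step Dense evaluation grid spacing, hr.
#' @return An object of class `dose_exposure_curve`: a list with a
#'   data.frame `curve` (`dose_mg`, `predicted_auc`), `reference_dose` and
#'   `reference_auc`.
#' @export
predict_auc_vs_dose <- function(reference, terminal = NULL,
                                regimen_template = regimen(0, 1, t_end = 72),
                                doses = seq(2.5, 150, by = 2.5),
                                grid_step = 0.1) {
  stopifnot(all(doses > 0))
  if (inherits(reference, "conc_profile"))
    reference <- extend_profile(reference, terminal,
                                t_end = regimen_template$t_end)
  stopifnot(inherits(reference, "extended_profile"))
  total <- sum(regimen_template$amounts)
  auc <- vapply(doses, function(D) {
    reg <- regimen(regimen_template$times,
                   regimen_template$amounts * D / total,
                   regimen_template$t_end)
    superposed_auc(superpose(reference, reg, grid_step = grid_step))
  }, numeric(1))
  ref_auc <- auc_linear_trapezoid(reference$profile)
  structure(list(curve = data.frame(dose_mg = doses, predicted_auc = auc),
                 reference_dose = reference$profile$dose$amount,
                 reference_auc = ref_auc),
            class = "dose_exposure_curve")
}

#' Invert a dose-exposure curve at a target AUC
#'
#' Monotone linear interpolation of dose against predicted AUC; exact for
#' the linear single-dose case, where `D* = D_ref * target / AUC_ref`.
#'
#' @param curve A [predict_auc_vs_dose()] result, or a data.frame with
#'   columns `dose_mg` and `predicted_auc`.
#' @param target Target AUC_last, ng.hr/mL, within the predicted range.
#' @return The dose in mg achieving the target.
#' @export
invert_dose <- function(curve, target) {
  df <- if (inherits(curve, "dose_exposure_curve")) curve$curve else curve
  stopifnot(is.data.frame(df), all(c("dose_mg", "predicted_auc") %in%
                                     names(df)))
  df <- df[order(df$dose_mg), , drop = FALSE]
  if (is.unsorted(df$predicted_auc))
    stop("predicted AUC must be non-decreasing in dose")
  if (target > max(df$predicted_auc))
    stop(sprintf(paste0("target %g above the maximum predicted AUC %g; ",
                        "extend the dose grid"),
                 target, max(df$predicted_auc)))
  if (target < min(df$predicted_auc))
    stop("target below the minimum predicted AUC; extend the dose grid down")
  stats::approx(df$predicted_auc, df$dose_mg, xout = target, ties = "ordered",
                rule = 1)$y
}
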