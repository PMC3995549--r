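# Pipeline orchestration of the three-step dose-selection method, the
# dose-rounding policy, and simulated-vs-observed validation.

#' Round an exact dose up to a practical increment
#'
#' The smallest multiple of `increment` that is at least `exact` (ceiling
#' mode); a dose already on the grid is returned unchanged.
#'
#' @param exact Exact dose, mg (> 0).
#' @param increment Practical increment, mg (> 0); default 5.
#' @param mode Rounding mode; only `"ceil"` is defined.
#' @return Practical dose, mg.
#' @export
round_dose <- function(exact, increment = 5, mode = c("ceil")) {
  mode <- match.arg(mode)
  stopifnot(all(exact > 0), increment > 0)
  increment * ceiling(exact / increment - 1e-9)
}

#' Compare observed and simulated concentration profiles
#'
#' Metrics are computed on paired values at the observed quantifiable
#' sampling times: mean absolute percentage error (MAPE), average fold
#' error `AFE = 10^mean(|log10(pred/obs)|)` and the fraction of points
#' within 2-fold (boundary inclusive).
#'
#' @param observed A [conc_profile()] of observations.
#' @param simulated A [superpose()] result or a [conc_profile()]; must be
#'   evaluable (by linear interpolation) at every observed quantifiable
#'   time.
#' @return An object of class `validation_report` with fields `mape`,
#'   `afe`, `frac_within_2fold`, `n`, and the paired series `pairs`.
#' @export
validate_prediction <- function(observed, simulated) {
  obs <- usable_points(observed)
  obs <- obs[obs$conc > 0, , drop = FALSE]
  if (inherits(simulated, "superposed_profile")) {
    sx <- simulated$time; sy <- simulated$conc
  } else {
    sp <- usable_points(simulated)
    sx <- sp$time; sy <- sp$conc
  }
  obs <- obs[obs$time >= min(sx) & obs$time <= max(sx), , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no overlapping quantifiable points between observed and simulated")
  pred <- stats::approx(sx, sy, xout = obs$time, rule = 1)$y
  keep <- is.finite(pred) & pred > 0
  if (!any(keep)) stop("simulated profile is zero at every observed time")
  pairs <- data.frame(time = obs$time[keep], observed = obs$conc[keep],
                      simulated = pred[keep])
  ratio <- pairs$simulated / pairs$observed
  structure(list(
    mape = 100 * mean(abs(pairs$simulated - pairs$observed) /
                        pairs$observed),
    afe = 10^mean(abs(log10(ratio))),
    frac_within_2fold = mean(ratio >= 0.5 - 1e-12 & ratio <= 2 + 1e-12),
    n = nrow(pairs), pairs = pairs),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> n = %d, MAPE = %.1f%%, ",
                     "AFE = %.3f, within 2-fold = %.0f%%\n"),
              x$n, x$mape, x$afe, 100 * x$frac_within_2fold))
  invisible(x)
}

# Pool paired series from several validation reports into one set of
# aggregate metrics.
.pool_validation <- function(reports) {
  pairs <- do.call(rbind, lapply(reports, `[[`, "pairs"))
  ratio <- pairs$simulated / pairs$observed
  structure(list(
    mape = 100 * mean(abs(pairs$simulated - pairs$observed) /
                        pairs$observed),
    afe = 10^mean(abs(log10(ratio))),
    frac_within_2fold = mean(ratio >= 0.5 - 1e-12 & ratio <= 2 + 1e-12),
    n = nrow(pairs), pairs = pairs),
    class = "validation_report")
}

.profile_key <- function(p) paste(p$analyte, p$matrix, sep = "/")

#' Run the three-step dose-selection pipeline
#'
#' Step 1 runs NCA on the pilot dose-escalation data and applies the
#' dose-proportionality gate (power-model 95% CI containing 1.0 for every
#' parameter); a gate failure halts the pipeline with the Step-1 report
#' unless `force_gate = TRUE`.  Step 2 runs NCA on the low-dose study,
#' builds the per-subject dose-exposure curves by nonparametric
#' superposition, averages them across subjects, and inverts the mean curve
#' at the target AUC; the exact dose is rounded up to the practical
#' increment.  Step 3 superposes each subject's low-dose reference at the
#' validation dose and compares the prediction with the observed validation
#' profiles (matched by subject) for every analyte/matrix series present.
#'
#' The pipeline is deterministic: identical inputs and configuration give
#' identical reports.
#'
#' @param pilot_data,lowdose_data,validation_data Lists of
#'   [conc_profile()] objects (as from [load_profiles()] or
#'   [simulate_study()]); `validation_data` may be `NULL` or empty, in
#'   which case Step 3 is skipped with a notice.
#' @param config A [study_config()].
#' @param force_gate Proceed past a failed proportionality gate (with a
#'   warning)?
#' @param dose_grid Dose grid for the exposure curve, mg.
#' @param outdir Optional directory; when given, NCA tables, the
#'   dose-exposure curve and the validation pairs are written there as CSV.
#' @return An object of class `pk_dose_pipeline` with elements `step1`,
#'   `step2`, `step3`, `recommendation` and `halted`.
#' @export
run_pipeline <- function(pilot_data, lowdose_data, validation_data = NULL,
                         config = study_config(), force_gate = FALSE,
                         dose_grid = seq(2.5, 150, by = 2.5),
                         outdir = NULL) {
  ## Step 1: pilot escalation, NCA + proportionality gate
  nca_pilot <- run_nca(pilot_data, config)
  prop <- dose_proportionality_report(nca_pilot)
  step1 <- list(nca = nca_pilot, summary = nca_summary(nca_pilot),
                proportionality = prop)
  if (!prop$verdict$passes) {
    if (!force_gate) {
      warning("dose-proportionality gate failed; pipeline halted at Step 1",
              call. = FALSE)
      return(structure(list(step1 = step1, step2 = NULL, step3 = NULL,
                            recommendation = NULL, halted = TRUE),
                       class = "pk_dose_pipeline"))
    }
    warning("dose-proportionality gate failed; continuing (force_gate)",
            call. = FALSE)
  }

  ## Step 2: low-dose NCA, dose-exposure curve, recommendation
  nca_low <- run_nca(lowdose_data, config)
  is_ref <- vapply(lowdose_data, function(p)
    p$analyte == "metabolite" && p$matrix == "plasma", logical(1))
  refs <- lowdose_data[is_ref]
  t_end <- max(config$sampling_times)
  per_subject <- list()
  for (p in refs) {
    curve <- tryCatch(
      predict_auc_vs_dose(p, regimen_template = regimen(0, 1, t_end = t_end),
                          doses = dose_grid),
      error = function(e) NULL)
    if (!is.null(curve)) per_subject[[p$subject]] <- curve
  }
  if (!length(per_subject))
    stop("no low-dose metabolite profile supports superposition")
  mat <- vapply(per_subject, function(cv) cv$curve$predicted_auc,
                numeric(length(dose_grid)))
  mat <- matrix(mat, nrow = length(dose_grid))
  mean_curve <- data.frame(
    dose_mg = dose_grid,
    predicted_auc = rowMeans(mat),
    se = apply(mat, 1L, stats::sd) / sqrt(ncol(mat)))
  exact <- invert_dose(mean_curve, config$target_auc)
  practical <- round_dose(exact, config$rounding_increment)
  recommendation <- list(exact_dose = exact, practical_dose = practical,
                         target_auc = config$target_auc, curve = mean_curve)
  step2 <- list(nca = nca_low, summary = nca_summary(nca_low),
                per_subject_curves = per_subject, curve = mean_curve)

  ## Step 3: simulated-vs-observed validation at the practical dose
  step3 <- NULL
  if (is.null(validation_data) || length(validation_data) == 0L) {
    step3 <- list(skipped = TRUE,
                  notice = "no validation data supplied; Step 3 skipped")
  } else {
    by_key <- split(validation_data,
                    vapply(validation_data, .profile_key, character(1)))
    ref_by_subj <- list()
    for (p in lowdose_data)
      ref_by_subj[[.profile_key(p)]][[p$subject]] <- p
    reports <- list()
    for (key in names(by_key)) {
      per <- list()
      for (obs in by_key[[key]]) {
        ref <- ref_by_subj[[key]][[obs$subject]]
        if (is.null(ref)) next
        pred <- tryCatch({
          ext <- extend_profile(ref, t_end = t_end)
          sp <- superpose(ext, regimen(0, obs$dose$amount, t_end = t_end))
          validate_prediction(obs, sp)
        }, error = function(e) NULL)
        if (!is.null(pred)) per[[obs$subject]] <- pred
      }
      if (length(per))
        reports[[key]] <- list(pooled = .pool_validation(per),
                               per_subject = per)
    }
    if (!length(reports))
      stop("no validation profile could be paired with a low-dose reference")
    step3 <- list(skipped = FALSE, reports = reports)
  }

  out <- structure(list(step1 = step1, step2 = step2, step3 = step3,
                        recommendation = recommendation, halted = FALSE),
                   class = "pk_dose_pipeline")
  if (!is.null(outdir)) .write_pipeline_artifacts(out, outdir)
  out
}

.write_pipeline_artifacts <- function(pipeline, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pipeline$step1$nca, file.path(outdir, "nca_pilot.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$step1$proportionality$verdict$reasons,
                   file.path(outdir, "proportionality_gate.csv"),
                   row.names = FALSE)
  if (!is.null(pipeline$step2)) {
    utils::write.csv(pipeline$step2$nca, file.path(outdir, "nca_lowdose.csv"),
                     row.names = FALSE)
    utils::write.csv(pipeline$step2$curve,
                     file.path(outdir, "dose_exposure_curve.csv"),
                     row.names = FALSE)
  }
  if (!is.null(pipeline$step3) && isFALSE(pipeline$step3$skipped)) {
    pairs <- do.call(rbind, lapply(names(pipeline$step3$reports), function(k) {
      cbind(series = k, pipeline$step3$reports[[k]]$pooled$pairs)
    }))
    utils::write.csv(pairs, file.path(outdir, "validation_pairs.csv"),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.pk_dose_pipeline <- function(x, ...) {
  cat("<pk_dose_pipeline>\n")
  cat(sprintf("  Step 1 gate: %s\n",
              if (x$step1$proportionality$verdict$passes) "PASS" else "FAIL"))
  if (x$halted) {
    cat("  halted at Step 1\n")
    return(invisible(x))
  }
  cat(sprintf("  Step 2: exact dose %.2f mg -> practical %.0f mg (target %g)\n",
              x$recommendation$exact_dose, x$recommendation$practical_dose,
              x$recommendation$target_auc))
  if (isTRUE(x$step3$skipped)) {
    cat("  Step 3: skipped\n")
  } else {
    for (k in names(x$step3$reports)) {
      p <- x$step3$reports[[k]]$pooled
      cat(sprintf("  Step 3 %s: AFE %.3f, %.0f%% within 2-fold (n = %d)\n",
                  k, p$afe, 100 * p$frac_within_2fold, p$n))
    }
  }
  invisible(x)
}
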