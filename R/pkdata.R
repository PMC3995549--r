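# Domain objects and tabular I/O for concentration-time data.
#
# All times are hours since dosing (dose at t = 0, immediately after the end
# of a dialysis session), concentrations are ng/mL, doses are mg.  The
# mg -> ng conversion factor 1e6 is applied only inside clearance
# computations, never stored in the data.

.ANALYTES <- c("parent", "metabolite")
.MATRICES <- c("plasma", "dialysate")

#' Dose event
#'
#' A single oral dose, given as an amount in mg at a time in hours on the
#' study clock (the reference dose is always at t = 0).
#'
#' @param amount Dose amount in mg (> 0).
#' @param time Dosing time in hours (>= 0); default 0.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(amount, time = 0) {
  stopifnot(is.numeric(amount), length(amount) == 1L, is.finite(amount),
            is.numeric(time), length(time) == 1L, is.finite(time))
  if (amount <= 0) stop("dose amount must be > 0")
  if (time < 0) stop("dose time must be >= 0")
  structure(list(time = as.numeric(time), amount = as.numeric(amount)),
            class = "dose_event")
}

#' Hemodialysis session window
#'
#' Describes one intermittent dialysis session on the study clock.  Defaults
#' are a 4-hr high-flux session starting 44 hr after dosing with dialysate
#' flow 500 mL/min and blood flow 250 mL/min.
#'
#' @param start,end Session start/end in hours since dosing (`end > start`).
#' @param dialysate_flow Dialysate flow rate, mL/min.
#' @param blood_flow Blood flow rate, mL/min (descriptive; not used in
#'   recovery-method computations).
#' @return An object of class `dialysis_window`.
#' @export
dialysis_window <- function(start = 44, end = 48, dialysate_flow = 500,
                            blood_flow = 250) {
  stopifnot(is.numeric(start), is.numeric(end), end > start,
            dialysate_flow > 0, blood_flow > 0)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 dialysate_flow = as.numeric(dialysate_flow),
                 blood_flow = as.numeric(blood_flow)),
            class = "dialysis_window")
}

#' Study configuration
#'
#' Assay limits, dialysis schedule, sampling design, the target metabolite
#' exposure and the dose-rounding increment used by the pipeline.
#'
#' Defaults mirror a single-dose design in anuric hemodialysis patients:
#' plasma sampling at 0, 1, 1.5, 2, 2.5, 3, 6, 12, 24, 44 (dialysis start),
#' 48 (dialysis end) and 72 hr; LLOQ 0.2 ng/mL for the parent drug and
#' 2 ng/mL for the metabolite; target metabolite AUC_last 60,000 ng.hr/mL;
#' doses rounded up to 5-mg increments.
#'
#' @param lloq_parent,lloq_metabolite Lower limits of quantification, ng/mL.
#' @param dialysis A [dialysis_window()].
#' @param target_auc Target metabolite AUC_last, ng.hr/mL.
#' @param sampling_times Plasma sampling times, hr.
#' @param rounding_increment Practical dose increment, mg.
#' @return An object of class `study_config`.
#' @export
study_config <- function(lloq_parent = 0.2, lloq_metabolite = 2,
                         dialysis = dialysis_window(), target_auc = 60000,
                         sampling_times = c(0, 1, 1.5, 2, 2.5, 3, 6, 12, 24,
                                            44, 48, 72),
                         rounding_increment = 5) {
  stopifnot(lloq_parent > 0, lloq_metabolite > 0, target_auc > 0,
            rounding_increment > 0,
            inherits(dialysis, "dialysis_window"),
            is.numeric(sampling_times), !is.unsorted(sampling_times,
                                                     strictly = TRUE))
  structure(list(lloq_parent = lloq_parent, lloq_metabolite = lloq_metabolite,
                 dialysis = dialysis, target_auc = target_auc,
                 sampling_times = as.numeric(sampling_times),
                 rounding_increment = rounding_increment),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognised keys mirror the [study_config()] arguments; `dialysis` is a
#' mapping with keys `start`, `end`, `dialysate_flow`, `blood_flow`.
#' Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dial <- do.call(dialysis_window, raw$dialysis %||% list())
  args <- raw[setdiff(names(raw), "dialysis")]
  do.call(study_config, c(args, list(dialysis = dial)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concentration-time profile
#'
#' One subject/analyte/matrix time series.  Times must be strictly
#' increasing; non-BLOQ concentrations must be finite and non-negative.
#' BLOQ records carry the applicable LLOQ in the `conc` column (never a
#' measured concentration) and are flagged in `bloq`.
#'
#' @param subject Subject identifier.
#' @param analyte `"parent"` or `"metabolite"`.
#' @param matrix `"plasma"` or `"dialysate"`.
#' @param time Sampling times, hr since dosing (finite, >= 0, strictly
#'   increasing).
#' @param conc Concentrations, ng/mL.
#' @param bloq Logical below-LLOQ flags (default all `FALSE`).
#' @param dose A [dose_event()] or a dose amount in mg (dosed at t = 0).
#' @param lloq Assay LLOQ for this analyte, ng/mL.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject, analyte, matrix, time, conc,
                         bloq = rep(FALSE, length(time)), dose, lloq) {
  analyte <- match.arg(analyte, .ANALYTES)
  matrix <- match.arg(matrix, .MATRICES)
  if (is.numeric(dose)) dose <- dose_event(dose)
  stopifnot(inherits(dose, "dose_event"), is.numeric(lloq), lloq > 0,
            length(time) == length(conc), length(bloq) == length(time))
  time <- as.numeric(time); conc <- as.numeric(conc); bloq <- as.logical(bloq)
  if (length(time) == 0L) stop("profile must contain at least one record")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(!bloq & (!is.finite(conc) | conc < 0)))
    stop("non-BLOQ concentrations must be finite and non-negative")
  conc[bloq] <- lloq  # BLOQ records carry the LLOQ, not a concentration
  structure(list(subject = as.character(subject), analyte = analyte,
                 matrix = matrix,
                 data = data.frame(time = time, conc = conc, bloq = bloq),
                 dose = dose, lloq = lloq),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s, %s %s, dose %g mg, %d records\n",
              x$subject, x$matrix, x$analyte, x$dose$amount,
              nrow(x$data)))
  print(x$data, ...)
  invisible(x)
}

#' Apply the BLOQ censoring rule to a profile
#'
#' Under the default rule, below-LLOQ records before the first quantifiable
#' concentration are set to zero (the pre-absorption phase), while embedded
#' and trailing BLOQ records are dropped so that AUC_last ends at the last
#' quantifiable time.  The operation is idempotent.
#'
#' @param profile A [conc_profile()].
#' @param rule Censoring rule; only `"default"` is defined.
#' @return A censored `conc_profile` with no remaining BLOQ flags.
#' @export
censor_bloq <- function(profile, rule = c("default")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "conc_profile"))
  d <- profile$data
  if (!any(d$bloq)) return(profile)
  quant <- which(!d$bloq)
  if (length(quant) == 0L) {
    stop(structure(class = c("hdpk_unusable_profile", "error", "condition"),
                   list(message = sprintf(
                     "profile %s/%s/%s has no quantifiable records",
                     profile$subject, profile$analyte, profile$matrix),
                     call = NULL)))
  }
  first_q <- quant[1L]
  lead <- d$bloq & seq_len(nrow(d)) < first_q
  d$conc[lead] <- 0
  d$bloq[lead] <- FALSE
  d <- d[!d$bloq, , drop = FALSE]
  rownames(d) <- NULL
  profile$data <- d
  profile
}

# Quantifiable (censored) points of a profile as a data.frame(time, conc).
usable_points <- function(profile) {
  d <- censor_bloq(profile)$data
  d[, c("time", "conc")]
}

#' Interpolate a concentration within the observed range
#'
#' Linear interpolation between the bracketing quantifiable samples; exact
#' sample values are returned when `t` coincides with a sampling time.
#' Extrapolation outside the observed range is an error (profile extension
#' beyond the last sample is the job of [extend_profile()]).
#'
#' @param profile A [conc_profile()].
#' @param t Time(s), hr, within the observed quantifiable range.
#' @param method Interpolation method; only `"linear"` is defined.
#' @return Concentration(s), ng/mL.
#' @export
interpolate_conc <- function(profile, t, method = c("linear")) {
  method <- match.arg(method)
  pts <- usable_points(profile)
  if (nrow(pts) < 2L) stop("need at least two quantifiable points")
  if (any(t < min(pts$time) - 1e-12) || any(t > max(pts$time) + 1e-12))
    stop(sprintf("t outside observed range [%g, %g]",
                 min(pts$time), max(pts$time)))
  stats::approx(pts$time, pts$conc, xout = t, rule = 1)$y
}

.required_cols <- c("subject", "analyte", "matrix", "time_hr", "conc_ng_ml",
                    "bloq")

#' Load concentration-time profiles from a long-format CSV
#'
#' The file must carry a header with columns `subject`, `analyte`, `matrix`,
#' `time_hr`, `conc_ng_ml`, `bloq`, and either a `dose_mg` column or a
#' `dose` argument.  One profile is built per (subject, analyte, matrix) --
#' and per dose level when `dose_mg` is present, so crossover dose-escalation
#' data load naturally.  Malformed rows are reported with their line numbers
#' (header = line 1).
#'
#' @param path CSV path.
#' @param config A [study_config()] supplying analyte LLOQs.
#' @param dose Dose in mg applying to all rows; only used when the file has
#'   no `dose_mg` column.
#' @return A list of [conc_profile()] objects.
#' @export
load_profiles <- function(path, config = study_config(), dose = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"dose_mg" %in% names(df)) {
    if (is.null(dose)) stop("no dose_mg column and no dose argument given")
    df$dose_mg <- dose
  }
  df$bloq <- as.logical(df$bloq)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !is.finite(df$time_hr) | df$time_hr < 0 |
    (!df$bloq & (!is.finite(df$conc_ng_ml) | df$conc_ng_ml < 0)) |
    is.na(df$bloq) | !df$analyte %in% .ANALYTES | !df$matrix %in% .MATRICES
  if (any(bad))
    stop("malformed rows at line(s): ", paste(line[bad], collapse = ", "))
  key <- interaction(df$subject, df$analyte, df$matrix, df$dose_mg,
                     drop = TRUE)
  dup <- duplicated(data.frame(key, df$time_hr))
  if (any(dup))
    stop("duplicate (subject, analyte, matrix, time) at line(s): ",
         paste(line[dup], collapse = ", "))
  profiles <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_hr), , drop = FALSE]
    lloq <- if (g$analyte[1L] == "parent") config$lloq_parent
            else config$lloq_metabolite
    conc_profile(subject = g$subject[1L], analyte = g$analyte[1L],
                 matrix = g$matrix[1L], time = g$time_hr,
                 conc = g$conc_ng_ml, bloq = g$bloq,
                 dose = dose_event(g$dose_mg[1L]), lloq = lloq)
  })
  names(profiles) <- NULL
  profiles
}

#' Write concentration-time profiles to the long CSV dialect
#'
#' @param profiles A list of [conc_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject = p$subject, analyte = p$analyte, matrix = p$matrix,
               time_hr = p$data$time, conc_ng_ml = p$data$conc,
               bloq = p$data$bloq, dose_mg = p$dose$amount)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
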