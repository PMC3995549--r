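# Non-compartmental analysis: linear trapezoidal AUC, Cmax/Tmax, terminal
# slope, apparent oral clearance and recovery-method dialytic clearance.

# Trapezoid over [a, b] on knots (x, y), with linear interpolation at
# non-sampled boundaries.  Exact for piecewise-linear curves, hence exactly
# additive over adjacent windows.
.trapz_window <- function(x, y, a, b) {
  if (b < a) stop("t_end must be >= t_start")
  if (a < min(x) - 1e-12 || b > max(x) + 1e-12)
    stop(sprintf("window [%g, %g] outside observed range [%g, %g]",
                 a, b, min(x), max(x)))
  if (b == a) return(0)
  ya <- stats::approx(x, y, xout = a, rule = 1)$y
  yb <- stats::approx(x, y, xout = b, rule = 1)$y
  inner <- x > a & x < b
  xs <- c(a, x[inner], b)
  ys <- c(ya, y[inner], yb)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Linear trapezoidal AUC over a time window
#'
#' Sum of `(t[i+1] - t[i]) * (C[i] + C[i+1]) / 2` over the quantifiable
#' samples in the window, with linear interpolation at non-sampled window
#' boundaries.  BLOQ handling follows [censor_bloq()]: leading BLOQ records
#' enter as zeros, embedded/trailing BLOQ records are excluded.
#'
#' @param profile A [conc_profile()].
#' @param t_start,t_end Window bounds, hr; default the full quantifiable
#'   range (giving AUC_last when `t_start` is the first sample).
#' @return AUC in ng.hr/mL.
#' @export
auc_linear_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  pts <- usable_points(profile)
  if (nrow(pts) < 2L) stop("need at least two quantifiable points")
  if (is.null(t_start)) t_start <- min(pts$time)
  if (is.null(t_end)) t_end <- max(pts$time)
  .trapz_window(pts$time, pts$conc, t_start, t_end)
}

#' Maximum observed concentration and its time
#'
#' Determined directly from the quantifiable samples; ties are broken by
#' the earliest time.
#'
#' @param profile A [conc_profile()].
#' @return Named numeric `c(cmax = , tmax = )`.
#' @export
cmax_tmax <- function(profile) {
  pts <- usable_points(profile)
  if (nrow(pts) == 0L) stop("no quantifiable points")
  i <- which.max(pts$conc)  # which.max returns the first (earliest) maximum
  c(cmax = pts$conc[i], tmax = pts$time[i])
}

#' Fit the terminal log-linear phase
#'
#' Log-linear least squares over candidate terminal windows: every suffix of
#' at least `min_points` positive quantifiable samples ending at the last
#' quantifiable time, excluding the Tmax sample (extravascular dosing).
#' Candidates with non-negative slope are discarded; among the rest the
#' window with the largest adjusted R-squared wins, ties (within 1e-4) going
#' to the longer window.
#'
#' @param profile A [conc_profile()].
#' @param min_points Minimum points per candidate window (>= 3).
#' @return An object of class `terminal_phase` with fields `lambda_z`
#'   (1/hr), `intercept` (ln ng/mL), `n_points`, `adj_r2`, `t_first`,
#'   `t_last`.
#' @export
fit_lambda_z <- function(profile, min_points = 3L) {
  stopifnot(min_points >= 3L)
  pts <- usable_points(profile)
  pts <- pts[pts$conc > 0, , drop = FALSE]
  if (nrow(pts) < 2L) stop("too few positive quantifiable points")
  i_tmax <- which.max(pts$conc)
  pool <- pts[seq_len(nrow(pts)) > i_tmax, , drop = FALSE]
  n <- nrow(pool)
  if (n < min_points)
    stop(sprintf("only %d post-Tmax points; need >= %d", n, min_points))
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    w <- pool[start:n, , drop = FALSE]
    x <- w$time; y <- log(w$conc); m <- nrow(w)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
    sst <- sum((y - mean(y))^2)
    # adjusted R^2 computed directly (robust to numerically exact fits)
    adj_r2 <- 1 - (rss / sst) * (m - 1) / (m - 2)
    if (is.null(best) || adj_r2 > best$adj_r2 + 1e-4) {
      best <- list(lambda_z = -slope,
                   intercept = mean(y) - slope * mean(x),
                   n_points = m, adj_r2 = adj_r2,
                   t_first = x[1L], t_last = x[m])
    }
  }
  if (is.null(best)) stop("no candidate terminal window with negative slope")
  structure(best, class = "terminal_phase")
}

#' Partial AUC over the dialysis session (AUC_HD)
#'
#' The area under the plasma concentration-time curve during hemodialysis,
#' computed with the linear trapezoid over `[window$start, window$end]`.
#'
#' @param profile A plasma [conc_profile()] whose samples bracket the window.
#' @param window A [dialysis_window()].
#' @return AUC_HD in ng.hr/mL.
#' @export
partial_auc_dialysis <- function(profile, window) {
  stopifnot(inherits(window, "dialysis_window"))
  auc_linear_trapezoid(profile, window$start, window$end)
}

#' Apparent oral clearance, CL/F = dose / AUC_last
#'
#' @param dose Dose in mg.
#' @param auc_last AUC_last in ng.hr/mL (> 0).
#' @return CL/F in L/hr.
#' @export
oral_clearance <- function(dose, auc_last) {
  stopifnot(dose > 0)
  if (any(auc_last <= 0)) stop("auc_last must be > 0")
  dose * 1e6 / auc_last / 1000  # mg -> ng, then mL/hr -> L/hr
}

#' Amount recovered in dialysate during a session
#'
#' Trapezoidal integral of the dialysate concentration times the dialysate
#' flow over the session window (flow converted mL/min -> mL/hr).
#'
#' @param dialysate_profile A dialysate [conc_profile()].
#' @param window A [dialysis_window()].
#' @return Recovered amount R in ng.
#' @export
recovered_amount <- function(dialysate_profile, window) {
  stopifnot(inherits(window, "dialysis_window"))
  if (!inherits(dialysate_profile, "conc_profile") ||
      dialysate_profile$matrix != "dialysate")
    stop("dialysate concentration data required")
  flow_ml_hr <- window$dialysate_flow * 60
  auc_d <- auc_linear_trapezoid(dialysate_profile, window$start, window$end)
  auc_d * flow_ml_hr
}

#' Dialytic clearance by the recovery method, CL_HD = R / AUC_HD
#'
#' @param recovered Amount recovered in dialysate, ng (>= 0).
#' @param auc_hd Plasma AUC over the dialysis session, ng.hr/mL (> 0).
#' @return CL_HD in mL/hr.
#' @export
dialysis_clearance <- function(recovered, auc_hd) {
  stopifnot(recovered >= 0)
  if (any(auc_hd <= 0)) stop("auc_hd must be > 0")
  recovered / auc_hd
}

#' Percentage of the dose excreted by dialysis
#'
#' @param recovered Amount recovered in dialysate, ng.
#' @param dose Dose in mg (> 0).
#' @return Percent of dose.
#' @export
percent_excreted <- function(recovered, dose) {
  stopifnot(dose > 0)
  100 * recovered / (dose * 1e6)
}

#' Run non-compartmental analysis over a profile collection
#'
#' Produces one row per (subject, dose, analyte) from the plasma profiles:
#' Cmax, Tmax, AUC_last, terminal slope when estimable, AUC_HD over the
#' configured dialysis window (when bracketed by samples), CL/F for the
#' parent, and -- when a matching dialysate profile exists -- the recovered
#' amount, recovery-method CL_HD and percent of dose excreted for the
#' metabolite.  Per-profile failures are flagged in the `flag` column
#' rather than aborting the run.
#'
#' @param profiles List of [conc_profile()] objects.
#' @param config A [study_config()].
#' @return A data.frame of per-subject NCA parameters.
#' @export
run_nca <- function(profiles, config = study_config()) {
  is_plasma <- vapply(profiles, function(p) p$matrix == "plasma", logical(1))
  dialysate <- profiles[!is_plasma]
  rows <- lapply(profiles[is_plasma], function(p) {
    out <- data.frame(subject = p$subject, dose_mg = p$dose$amount,
                      analyte = p$analyte, cmax = NA_real_, tmax = NA_real_,
                      auc_last = NA_real_, auc_hd = NA_real_,
                      cl_f = NA_real_, recovered_ng = NA_real_,
                      cl_hd = NA_real_, pct_excreted = NA_real_,
                      lambda_z = NA_real_, lambda_z_n = NA_integer_,
                      lambda_z_adj_r2 = NA_real_, flag = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      ct <- cmax_tmax(p)
      out$cmax <- ct[["cmax"]]; out$tmax <- ct[["tmax"]]
      out$auc_last <- auc_linear_trapezoid(p)
      pts <- usable_points(p)
      if (min(pts$time) <= config$dialysis$start &&
          max(pts$time) >= config$dialysis$end) {
        out$auc_hd <- partial_auc_dialysis(p, config$dialysis)
      }
      if (p$analyte == "parent")
        out$cl_f <- oral_clearance(p$dose$amount, out$auc_last)
      term <- tryCatch(fit_lambda_z(p), error = function(e) NULL)
      if (!is.null(term)) {
        out$lambda_z <- term$lambda_z
        out$lambda_z_n <- term$n_points
        out$lambda_z_adj_r2 <- term$adj_r2
      }
      if (p$analyte == "metabolite" && is.finite(out$auc_hd) &&
          out$auc_hd > 0) {
        dia <- Filter(function(q) q$subject == p$subject &&
                        q$analyte == p$analyte &&
                        q$dose$amount == p$dose$amount, dialysate)
        if (length(dia)) {
          R <- recovered_amount(dia[[1L]], config$dialysis)
          out$recovered_ng <- R
          out$cl_hd <- dialysis_clearance(R, out$auc_hd)
          out$pct_excreted <- percent_excreted(R, p$dose$amount)
        }
      }
      out
    }, error = function(e) {
      out$flag <- conditionMessage(e)
      out
    })
    res
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Group summary of NCA results
#'
#' Mean (SD) of each continuous parameter by analyte and dose; Tmax is
#' summarised as median [min, max], the conventional presentation.
#'
#' @param nca_table Output of [run_nca()].
#' @return A data.frame with one row per (analyte, dose).
#' @export
nca_summary <- function(nca_table) {
  groups <- split(nca_table, list(nca_table$analyte, nca_table$dose_mg),
                  drop = TRUE)
  msd <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_character_)
    sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  }
  rows <- lapply(groups, function(g) {
    tmax <- g$tmax[is.finite(g$tmax)]
    data.frame(analyte = g$analyte[1L], dose_mg = g$dose_mg[1L], n = nrow(g),
               cmax_mean = mean(g$cmax, na.rm = TRUE),
               cmax_sd = stats::sd(g$cmax[is.finite(g$cmax)]),
               tmax_median = stats::median(tmax),
               tmax_range = sprintf("[%.2f, %.2f]", min(tmax), max(tmax)),
               auc_last_mean = mean(g$auc_last, na.rm = TRUE),
               auc_last_sd = stats::sd(g$auc_last[is.finite(g$auc_last)]),
               auc_hd_mean = mean(g$auc_hd, na.rm = TRUE),
               cl_f_mean = mean(g$cl_f, na.rm = TRUE),
               cl_hd_mean = mean(g$cl_hd, na.rm = TRUE),
               pct_excreted_mean = mean(g$pct_excreted, na.rm = TRUE),
               cmax_summary = msd(g$cmax),
               auc_last_summary = msd(g$auc_last),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$analyte, res$dose_mg), , drop = FALSE]
}
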