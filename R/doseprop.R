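# Dose-linearity assessment: dose-normalized parameters, Kruskal-Wallis
# comparison across dose levels, and the power-model proportionality gate.

#' Dose-normalize a PK parameter
#'
#' @param value Parameter value(s) in native units.
#' @param dose Dose in mg (> 0).
#' @return `value / dose` (per-mg value).
#' @export
dose_normalize <- function(value, dose) {
  if (any(dose <= 0)) stop("dose must be > 0")
  value / dose
}

#' Kruskal-Wallis comparison of dose groups
#'
#' Rank-based H statistic with tie correction and a chi-squared p-value on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]).  When every value
#' in every group is identical, H = 0 and p = 1 by convention.
#'
#' @param groups A list (>= 2 elements) of non-empty numeric vectors, one
#'   per dose level.
#' @return List with elements `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) > 0L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Fit the dose-proportionality power model
#'
#' Ordinary least squares of `ln(value)` on `ln(dose)`:
#' `ln(y) = alpha + beta * ln(D)`.  The slope beta estimates the
#' dose-proportionality exponent; its 95% CI is
#' `beta +/- t(0.975, n - 2) * se(beta)`.
#'
#' @param dose Doses in mg (>= 3 observations spanning >= 2 distinct doses).
#' @param value Positive parameter values, same length as `dose`.
#' @param parameter_name Label carried into reports.
#' @return An object of class `power_model` with fields `beta`, `se_beta`,
#'   `ci95` (length-2), `n_obs`, `parameter_name`.
#' @export
power_model_fit <- function(dose, value, parameter_name = "") {
  stopifnot(length(dose) == length(value))
  keep <- is.finite(dose) & is.finite(value)
  dose <- dose[keep]; value <- value[keep]
  if (length(dose) < 3L) stop("need at least 3 observations")
  if (length(unique(dose)) < 2L) stop("need at least 2 distinct doses")
  if (any(value <= 0) || any(dose <= 0))
    stop("doses and values must be positive")
  x <- log(dose); y <- log(value); n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  tq <- stats::qt(0.975, df = n - 2L)
  structure(list(beta = beta, se_beta = se,
                 ci95 = c(beta - tq * se, beta + tq * se),
                 n_obs = length(dose), parameter_name = parameter_name),
            class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("<power_model> %s: beta = %.3f (95%% CI %.3f-%.3f, n = %d)\n",
              x$parameter_name, x$beta, x$ci95[1L], x$ci95[2L], x$n_obs))
  invisible(x)
}

#' Dose-proportionality gate
#'
#' A parameter passes when its 95% CI for the power-model slope contains
#' 1.0 (closed interval: the boundary counts as containing).  The study
#' passes when every parameter passes.
#'
#' @param results A `power_model` or list of `power_model` objects.
#' @return An object of class `proportionality_verdict` with fields
#'   `passes` (logical) and `reasons` (per-parameter data.frame).
#' @export
proportionality_gate <- function(results) {
  if (inherits(results, "power_model")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "power_model")))
  reasons <- do.call(rbind, lapply(results, function(r) {
    data.frame(parameter = r$parameter_name, beta = r$beta,
               ci_low = r$ci95[1L], ci_high = r$ci95[2L],
               pass = r$ci95[1L] <= 1 && 1 <= r$ci95[2L],
               stringsAsFactors = FALSE)
  }))
  structure(list(passes = all(reasons$pass), reasons = reasons),
            class = "proportionality_verdict")
}

#' @export
print.proportionality_verdict <- function(x, ...) {
  cat(sprintf("<proportionality_verdict> %s\n",
              if (x$passes) "PASS" else "FAIL"))
  print(x$reasons, ...)
  invisible(x)
}

#' Full dose-proportionality report from an NCA table
#'
#' Builds the per-parameter power models (parent Cmax and AUC_last;
#' metabolite Cmax, AUC_last and AUC_HD when available), applies the CI
#' gate, and runs the Kruskal-Wallis test on dose-normalized Cmax and
#' AUC_last per analyte.
#'
#' @param nca_table Output of [run_nca()] across the escalation doses.
#' @return List with elements `power` (list of `power_model`), `verdict`
#'   (a `proportionality_verdict`), and `kruskal` (data.frame of H and p per
#'   analyte/parameter).
#' @export
dose_proportionality_report <- function(nca_table) {
  tab <- nca_table[is.na(nca_table$flag), , drop = FALSE]
  fits <- list()
  specs <- list(
    list(analyte = "parent", col = "cmax", name = "parent Cmax"),
    list(analyte = "parent", col = "auc_last", name = "parent AUC_last"),
    list(analyte = "metabolite", col = "cmax", name = "metabolite Cmax"),
    list(analyte = "metabolite", col = "auc_last",
         name = "metabolite AUC_last"),
    list(analyte = "metabolite", col = "auc_hd", name = "metabolite AUC_HD"))
  for (s in specs) {
    sub <- tab[tab$analyte == s$analyte & is.finite(tab[[s$col]]) &
                 tab[[s$col]] > 0, , drop = FALSE]
    if (nrow(sub) >= 3L && length(unique(sub$dose_mg)) >= 2L)
      fits[[s$name]] <- power_model_fit(sub$dose_mg, sub[[s$col]], s$name)
  }
  if (!length(fits)) stop("no parameter usable for the power model")
  kw <- do.call(rbind, lapply(c("parent", "metabolite"), function(an) {
    do.call(rbind, lapply(c("cmax", "auc_last"), function(col) {
      sub <- tab[tab$analyte == an & is.finite(tab[[col]]), , drop = FALSE]
      if (length(unique(sub$dose_mg)) < 2L) return(NULL)
      groups <- split(dose_normalize(sub[[col]], sub$dose_mg), sub$dose_mg)
      res <- kruskal_wallis(groups)
      data.frame(analyte = an, parameter = col, H = res$statistic,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    }))
  }))
  list(power = fits, verdict = proportionality_gate(fits), kruskal = kw)
}

#' Coverage of the power-model CI under dose-linear kinetics
#'
#' Simulates replicate dose-escalation studies in which exposure is exactly
#' proportional to dose up to log-normal between-subject variability (the
#' exposure-level consequence of linear kinetics with log-normal IIV), fits
#' the power model to each, and reports how often the 95% CI covers the
#' true slope of 1.
#'
#' @param n_replicates Number of replicate studies.
#' @param doses Escalation dose levels, mg.
#' @param n_subjects Subjects per dose level.
#' @param cv Log-normal coefficient of variation of exposure.
#' @param seed RNG seed.
#' @return Fraction of replicates whose 95% CI contains 1.0.
#' @export
simulate_beta_coverage <- function(n_replicates = 2000, doses = c(2.5, 5, 10),
                                   n_subjects = 4, cv = 0.3, seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  d <- rep(doses, each = n_subjects)
  ld <- log(d)
  n <- length(d)
  tq <- stats::qt(0.975, df = n - 2L)
  covered <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    ly <- ld + stats::rnorm(n, sd = sdlog)  # true beta = 1, intercept 0
    fit <- stats::lm.fit(cbind(1, ld), ly)
    rss <- sum(fit$residuals^2)
    sxx <- sum((ld - mean(ld))^2)
    se <- sqrt(rss / (n - 2L) / sxx)
    beta <- fit$coefficients[2L]
    covered[r] <- beta - tq * se <= 1 && 1 <= beta + tq * se
  }
  mean(covered)
}
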