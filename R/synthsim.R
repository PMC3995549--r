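# Synthetic hemodialysis-patient PK study generator.
#
# Structural model: oral prodrug absorbed first-order from the gut, parent
# eliminated by a clearance of which a fraction fm appears as the active
# metabolite; the metabolite has a small interdialytic clearance (anuric
# patients) plus a dialytic clearance active only during dialysis sessions.
# One-compartment disposition for both species.  Internal units: amounts in
# ng, volumes in mL, clearances in mL/hr, concentrations ng/mL.

#' Simulation parameters (population typical values)
#'
#' Defaults describe an oseltamivir-like prodrug in anuric hemodialysis
#' patients: fast absorption and very high apparent parent clearance (the
#' parent is quantifiable only for a few hours), ~80% of the dose reaching
#' the circulation as active metabolite, a small interdialytic metabolite
#' clearance and a much larger clearance during dialysis.  The typical
#' values are tuned so that a single 2.5-mg dose yields a metabolite
#' AUC_last near 5,600 ng.hr/mL and Cmax near 130 ng/mL.
#'
#' @param ka First-order absorption rate, 1/hr.
#' @param F Bioavailable fraction of the dose (0-1).
#' @param fm Fraction of parent clearance converted to metabolite (0-1).
#' @param V_p,V_m Apparent volumes of distribution, L.
#' @param CL_p Parent (conversion + elimination) clearance, L/hr.
#' @param CL_m_inter Interdialytic metabolite clearance, L/hr (near 0 for
#'   anuric patients).
#' @param CL_hd Dialytic metabolite clearance, L/hr, active only during
#'   dialysis windows.
#' @param Q_d Dialysate flow, mL/min.
#' @param iiv_cv Log-normal between-subject CV applied to `ka`, `CL_p`,
#'   `V_p`, `V_m`, `CL_m_inter` and `CL_hd`; a single number or a named
#'   vector over those parameters.
#' @param residual_cv Proportional (log-normal) residual error CV.
#' @param km Michaelis constant, ng/mL, for saturable parent elimination;
#'   `Inf` (the default) gives linear kinetics.  See [saturable_variant()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(ka = 1.5, F = 1, fm = 0.8, V_p = 620, V_m = 14,
                       CL_p = 620, CL_m_inter = 0.18, CL_hd = 3, Q_d = 500,
                       iiv_cv = 0.3, residual_cv = 0.15, km = Inf) {
  stopifnot(ka > 0, F > 0, F <= 1, fm >= 0, fm <= 1, V_p > 0, V_m > 0,
            CL_p >= 0, CL_m_inter >= 0, CL_hd >= 0, Q_d > 0, km > 0,
            all(iiv_cv >= 0), residual_cv >= 0)
  structure(list(ka = ka, F = F, fm = fm, V_p = V_p, V_m = V_m, CL_p = CL_p,
                 CL_m_inter = CL_m_inter, CL_hd = CL_hd, Q_d = Q_d,
                 iiv_cv = iiv_cv, residual_cv = residual_cv, km = km),
            class = "sim_params")
}

#' Saturable (Michaelis-Menten) variant of a parameter set
#'
#' Replaces the linear parent clearance with Michaelis-Menten elimination
#' `Vmax * C / (km + C)` where `Vmax = CL_p * km`, so the `km -> Inf` limit
#' recovers the linear kinetics and exposure grows super-linearly with dose
#' at concentrations approaching `km`.
#'
#' @param params A [sim_params()].
#' @param km Michaelis constant, ng/mL (> 0).
#' @return A `sim_params` with saturable parent elimination.
#' @export
saturable_variant <- function(params, km) {
  stopifnot(inherits(params, "sim_params"), km > 0)
  params$km <- km
  params
}

#' Study scenario for the synthetic generator
#'
#' @param params Typical [sim_params()].
#' @param doses Dose levels, mg; in a crossover design every subject
#'   receives every dose (independent occasions after washout).
#' @param n_subjects Number of subjects.
#' @param sampling_times Plasma sampling times, hr.
#' @param dialysis A [dialysis_window()].
#' @param lloq_parent,lloq_metabolite Assay LLOQs, ng/mL.
#' @param dialysate_times Dialysate sampling times, hr; default hourly
#'   across the dialysis session.
#' @param seed Default RNG seed for [simulate_study()].
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(params = sim_params(), doses = 2.5, n_subjects = 10,
                         sampling_times = c(0, 1, 1.5, 2, 2.5, 3, 6, 12, 24,
                                            44, 48, 72),
                         dialysis = dialysis_window(), lloq_parent = 0.2,
                         lloq_metabolite = 2, dialysate_times = NULL,
                         seed = 1) {
  stopifnot(inherits(params, "sim_params"), all(doses > 0), n_subjects >= 1)
  if (is.null(dialysate_times))
    dialysate_times <- seq(dialysis$start, dialysis$end, by = 1)
  structure(list(params = params, doses = doses, n_subjects = n_subjects,
                 sampling_times = sampling_times, dialysis = dialysis,
                 lloq_parent = lloq_parent, lloq_metabolite = lloq_metabolite,
                 dialysate_times = dialysate_times, seed = seed),
            class = "sim_scenario")
}

# Piecewise ODE solve of the gut/parent/metabolite system at `times`,
# splitting the timeline at dialysis boundaries (clearance discontinuity).
# Returns a data.frame with amounts (ng), the running dialysate recovery,
# interdialytic metabolite elimination and non-metabolite parent loss.
.simulate_amounts <- function(params, dose_mg, times, dialysis) {
  p <- params
  Vp <- p$V_p * 1000; Vm <- p$V_m * 1000          # L -> mL
  CLp <- p$CL_p * 1000; CLint <- p$CL_m_inter * 1000
  CLhd <- p$CL_hd * 1000
  rhs <- function(t, y, parms) {
    Cp <- y[2L] / Vp
    elim_p <- if (is.finite(p$km)) CLp * p$km * Cp / (p$km + Cp) else CLp * Cp
    clm <- CLint + if (parms$hd) CLhd else 0
    Cm <- y[3L] / Vm
    list(c(-p$ka * y[1L],
           p$ka * y[1L] - elim_p,
           p$fm * elim_p - clm * Cm,
           if (parms$hd) CLhd * Cm else 0,   # cumulative dialysate recovery
           CLint * Cm,                        # cumulative interdialytic loss
           (1 - p$fm) * elim_p))              # parent loss not to metabolite
  }
  times <- sort(unique(c(0, times)))
  bounds <- sort(unique(c(0, dialysis$start, dialysis$end, max(times))))
  bounds <- bounds[bounds <= max(times)]
  y <- c(gut = p$F * dose_mg * 1e6, A_p = 0, A_m = 0, cum_hd = 0,
         cum_int = 0, cum_lost = 0)
  out <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    hd <- a >= dialysis$start && b <= dialysis$end
    seg_times <- sort(unique(c(a, times[times >= a & times <= b], b)))
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = list(hd = hd),
                          rtol = 1e-9, atol = 1e-6)
    if (attr(sol, "istate")[1L] < 0)
      stop("stiff integration failure; params: ",
           paste(sprintf("%s=%g", names(p)[1:9], unlist(p[1:9])),
                 collapse = ", "))
    y <- sol[nrow(sol), -1L]
    out <- rbind(out, sol[-1L, , drop = FALSE])
  }
  out <- rbind(matrix(c(0, p$F * dose_mg * 1e6, 0, 0, 0, 0, 0), nrow = 1,
                      dimnames = list(NULL, c("time", names(y)))), out)
  out <- as.data.frame(out)
  out <- out[!duplicated(out$time) & out$time %in% times, , drop = FALSE]
  out$C_p <- out$A_p / Vp
  out$C_m <- out$A_m / Vm
  in_hd <- out$time >= dialysis$start & out$time <= dialysis$end
  out$C_dial <- ifelse(in_hd, CLhd * out$C_m / (p$Q_d * 60), NA_real_)
  rownames(out) <- NULL
  out
}

#' Simulate one subject's concentration profiles
#'
#' Numerically integrates the gut/parent/metabolite system with an
#' event-aware piecewise scheme (the dialytic clearance switches on and off
#' at the session boundaries), applies proportional log-normal residual
#' error, flags values below the LLOQ as BLOQ, and returns plasma parent,
#' plasma metabolite and dialysate metabolite profiles.  Dialysate
#' concentration during dialysis is `CL_hd * C_m / Q_d`.
#'
#' @param params Individual [sim_params()].
#' @param dose Dose, mg (0 allowed: all-zero profiles).
#' @param scenario A [sim_scenario()] supplying the design (sampling times,
#'   dialysis window, LLOQs).
#' @param subject Subject identifier for the emitted profiles.
#' @param noise Apply residual error?  Uses the current RNG state.
#' @return List with elements `parent`, `metabolite`, `dialysate`
#'   ([conc_profile()] objects) and `truth`, the noiseless concentrations at
#'   the design times.  For `dose = 0` the profile elements are `NULL`
#'   (there is no dose event) and `truth` is identically zero.
#' @export
simulate_subject <- function(params, dose, scenario = sim_scenario(),
                             subject = "S1", noise = TRUE) {
  stopifnot(inherits(params, "sim_params"), dose >= 0)
  all_t <- sort(unique(c(scenario$sampling_times, scenario$dialysate_times)))
  sim <- .simulate_amounts(params, dose, all_t, scenario$dialysis)
  truth <- sim[, c("time", "C_p", "C_m", "C_dial")]
  if (dose == 0)
    return(list(parent = NULL, metabolite = NULL, dialysate = NULL,
                truth = truth))
  perturb <- function(x) {
    if (!noise || params$residual_cv == 0) return(x)
    sdlog <- sqrt(log(1 + params$residual_cv^2))
    x * exp(stats::rnorm(length(x), sd = sdlog))
  }
  mk <- function(tt, conc, analyte, matrix, lloq) {
    conc <- pmax(perturb(conc), 0)
    bloq <- conc < lloq
    conc_profile(subject, analyte, matrix, tt, conc, bloq = bloq,
                 dose = dose_event(dose), lloq = lloq)
  }
  samp <- sim[sim$time %in% scenario$sampling_times, , drop = FALSE]
  dial <- sim[sim$time %in% scenario$dialysate_times & !is.na(sim$C_dial), ,
              drop = FALSE]
  list(parent = mk(samp$time, samp$C_p, "parent", "plasma",
                   scenario$lloq_parent),
       metabolite = mk(samp$time, samp$C_m, "metabolite", "plasma",
                       scenario$lloq_metabolite),
       dialysate = mk(dial$time, dial$C_dial, "metabolite", "dialysate",
                      scenario$lloq_metabolite),
       truth = truth)
}

#' Ground-truth metabolite AUC_last by fine-grid integration
#'
#' Integrates the noiseless metabolite concentration on a <= 0.01-hr grid
#' over the window with the trapezoid rule; serves as the oracle for NCA
#' accuracy checks.
#'
#' @param params A [sim_params()].
#' @param dose Dose, mg.
#' @param window Integration window `c(start, end)`, hr.
#' @param dialysis A [dialysis_window()].
#' @param step Grid step, hr (<= 0.01).
#' @return True AUC_last, ng.hr/mL.
#' @export
true_auc_last <- function(params, dose, window = c(0, 72),
                          dialysis = dialysis_window(), step = 0.01) {
  stopifnot(step <= 0.01)
  tt <- seq(window[1L], window[2L], by = step)
  if (tt[length(tt)] < window[2L]) tt <- c(tt, window[2L])
  sim <- .simulate_amounts(params, dose, tt, dialysis)
  .trapz_window(sim$time, sim$C_m, window[1L], window[2L])
}

# Draw one individual parameter set around the typical values.
.draw_individual <- function(params, iiv_names = c("ka", "CL_p", "V_p",
                                                   "V_m", "CL_m_inter",
                                                   "CL_hd")) {
  cv <- params$iiv_cv
  if (length(cv) == 1L) cv <- stats::setNames(rep(cv, length(iiv_names)),
                                              iiv_names)
  ind <- params
  for (nm in iiv_names) {
    cvi <- if (nm %in% names(cv)) cv[[nm]] else 0
    if (cvi > 0 && ind[[nm]] > 0) {
      sdlog <- sqrt(log(1 + cvi^2))
      ind[[nm]] <- ind[[nm]] * exp(stats::rnorm(1, sd = sdlog))
    }
  }
  ind
}

#' Simulate a complete study
#'
#' Draws per-subject parameters log-normally around the scenario's typical
#' values, simulates every subject at every dose level (crossover), applies
#' residual error and LLOQ censoring, and returns the profiles together
#' with a ground-truth sidecar of the individual parameters.
#'
#' @param scenario A [sim_scenario()].
#' @param seed RNG seed; default the scenario's.
#' @param truth_auc Also compute each subject's true (noiseless, fine-grid)
#'   metabolite AUC_last per dose?  Slower; off by default.
#' @return List with `profiles` (flat list of [conc_profile()]), `data`
#'   (long data.frame in the CSV dialect), and `truth` (per-subject
#'   parameters, plus `true_auc_last` when requested).
#' @export
simulate_study <- function(scenario, seed = scenario$seed,
                           truth_auc = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  profiles <- list()
  truth <- NULL
  for (i in seq_len(scenario$n_subjects)) {
    sid <- sprintf("S%02d", i)
    ind <- .draw_individual(scenario$params)
    for (d in scenario$doses) {
      prof <- simulate_subject(ind, d, scenario, subject = sid, noise = TRUE)
      profiles <- c(profiles,
                    list(prof$parent, prof$metabolite, prof$dialysate))
      row <- data.frame(subject = sid, dose_mg = d, ka = ind$ka,
                        CL_p = ind$CL_p, V_p = ind$V_p, V_m = ind$V_m,
                        CL_m_inter = ind$CL_m_inter, CL_hd = ind$CL_hd,
                        stringsAsFactors = FALSE)
      if (truth_auc)
        row$true_auc_last <- true_auc_last(ind, d,
                                           dialysis = scenario$dialysis)
      truth <- rbind(truth, row)
    }
  }
  data <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject = p$subject, analyte = p$analyte, matrix = p$matrix,
               time_hr = p$data$time, conc_ng_ml = p$data$conc,
               bloq = p$data$bloq, dose_mg = p$dose$amount,
               stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(profiles = profiles, data = data, truth = truth)
}
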