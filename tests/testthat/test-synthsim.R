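test_that("a zero dose yields identically zero true concentrations", {
  s <- simulate_subject(sim_params(), 0, sim_scenario())
  expect_null(s$parent)
  expect_true(all(s$truth$C_p == 0))
  expect_true(all(s$truth$C_m == 0))
  expect_true(all(s$truth$C_dial == 0, na.rm = TRUE))
})

test_that("fm = 0 cuts all mass flow to metabolite and dialysate", {
  p <- sim_params(fm = 0, residual_cv = 0)
  s <- simulate_subject(p, 2.5, sim_scenario(), noise = FALSE)
  expect_true(all(s$truth$C_m == 0))
  expect_true(all(s$truth$C_dial == 0, na.rm = TRUE))
  expect_gt(max(s$truth$C_p), 0)
})

test_that("the integrator matches the closed-form cascade solution", {
  # no dialysis effect (CL_hd = 0), no noise: three-rate Bateman cascade
  p <- sim_params(ka = 1.2, V_p = 600, CL_p = 540, V_m = 15,
                  CL_m_inter = 0.3, CL_hd = 0, residual_cv = 0)
  sc <- sim_scenario(params = p, sampling_times = c(0.5, 1, 2, 4, 8, 16, 24,
                                                    36, 48, 60, 72))
  s <- simulate_subject(p, 2.5, sc, noise = FALSE)
  kp <- 540 / 600                 # CL_p / V_p, 1/hr
  ke <- 0.3 / 15                  # CL_m_inter / V_m, 1/hr
  oracle <- cascade_metabolite_conc(s$truth$time, 2.5e6, 1.2, kp, ke,
                                    fm = 0.8, Vm_ml = 15000)
  expect_equal(s$truth$C_m, oracle, tolerance = 1e-6)
})

test_that("true AUC is linear in dose and decreased by dialysis", {
  p <- sim_params()
  a1 <- true_auc_last(p, 2.5)
  a2 <- true_auc_last(p, 5)
  expect_equal(a2, 2 * a1, tolerance = 1e-6)
  no_hd <- sim_params(CL_hd = 0)
  expect_gt(true_auc_last(no_hd, 2.5), a1)
})

test_that("NCA on dense noiseless output recovers the true AUC within 0.5%
           and Cmax within one grid step", {
  p <- sim_params()
  sc <- sim_scenario(params = p, sampling_times = seq(0, 72, by = 0.1))
  s <- simulate_subject(p, 2.5, sc, noise = FALSE)
  truth <- true_auc_last(p, 2.5)
  expect_equal(auc_linear_trapezoid(s$metabolite), truth,
               tolerance = 0.005)
  # Cmax: within one grid step of the fine-grid maximum
  fine <- s$truth
  ct <- cmax_tmax(s$metabolite)
  expect_lte(abs(ct[["tmax"]] - fine$time[which.max(fine$C_m)]), 0.1)
})

test_that("recovery-method CL_HD matches the programmed dialytic clearance
           on dense noiseless data", {
  p <- sim_params()
  sc <- sim_scenario(params = p, sampling_times = seq(0, 72, by = 0.1),
                     dialysate_times = seq(44, 48, by = 0.05))
  s <- simulate_subject(p, 2.5, sc, noise = FALSE)
  R <- recovered_amount(s$dialysate, sc$dialysis)
  auc_hd <- partial_auc_dialysis(s$metabolite, sc$dialysis)
  cl_hd_mlhr <- dialysis_clearance(R, auc_hd)
  expect_equal(cl_hd_mlhr / 1000, p$CL_hd, tolerance = 1e-3)
})

test_that("mass balance closes at every design time", {
  p <- sim_params()
  sim <- hdpkdose:::.simulate_amounts(p, 2.5, seq(0, 72, by = 2),
                                      dialysis_window())
  total <- sim$gut + sim$A_p + sim$A_m + sim$cum_hd + sim$cum_int +
    sim$cum_lost
  expect_equal(total, rep(2.5e6, nrow(sim)), tolerance = 1e-6)
})

test_that("study simulation is seed-reproducible with log-normal IIV", {
  sc <- sim_scenario(n_subjects = 3, doses = c(2.5, 5), seed = 4)
  s1 <- simulate_study(sc)
  s2 <- simulate_study(sc)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(sc, seed = 5)
  expect_false(identical(s1$data, s3$data))
  # degenerate variability: all subjects identical
  sc0 <- sim_scenario(params = sim_params(iiv_cv = 0, residual_cv = 0),
                      n_subjects = 3, seed = 4)
  s0 <- simulate_study(sc0)
  per <- split(s0$data[s0$data$analyte == "metabolite" &
                         s0$data$matrix == "plasma",
                       c("time_hr", "conc_ng_ml")],
               s0$data$subject[s0$data$analyte == "metabolite" &
                                 s0$data$matrix == "plasma"])
  for (i in seq_along(per)) rownames(per[[i]]) <- NULL
  expect_identical(per[[1]], per[[2]])
  expect_identical(per[[1]], per[[3]])
})

test_that("at the low dose the parent is predominantly BLOQ after 6 hr", {
  sc <- sim_scenario(n_subjects = 10, doses = 2.5, seed = 12)
  s <- simulate_study(sc)
  parent <- s$data[s$data$analyte == "parent" & s$data$time_hr > 6, ]
  expect_gt(mean(parent$bloq), 0.9)
  # but quantifiable around its early Tmax
  early <- s$data[s$data$analyte == "parent" & s$data$time_hr >= 1 &
                    s$data$time_hr <= 2, ]
  expect_lt(mean(early$bloq), 0.2)
})

test_that("saturable elimination makes parent exposure super-linear", {
  base <- sim_params(iiv_cv = 0, residual_cv = 0)
  sat <- saturable_variant(base, km = 2)
  # km -> Inf limit recovers the linear kinetics
  near_linear <- saturable_variant(base, km = 1e9)
  sc <- sim_scenario(params = base, doses = 2.5)
  s_lin <- simulate_subject(base, 2.5, sc, noise = FALSE)
  s_lim <- simulate_subject(near_linear, 2.5, sc, noise = FALSE)
  expect_equal(s_lim$truth$C_p, s_lin$truth$C_p, tolerance = 1e-6)

  # parent AUC/dose strictly increasing across the escalation doses
  auc_parent <- function(params, dose) {
    scd <- sim_scenario(params = params,
                        sampling_times = seq(0, 24, by = 0.01))
    s <- simulate_subject(params, dose, scd, noise = FALSE)
    trapz_oracle(s$truth$time, s$truth$C_p)
  }
  ratios <- sapply(c(2.5, 5, 10), function(d) auc_parent(sat, d) / d)
  expect_true(all(diff(ratios) > 0))
})
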