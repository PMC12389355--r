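test_that("single-dose profile approaches the IV bolus closed form as ka grows", {
  cmp <- test_perpetrator()
  cmp$pk$ka <- 200
  sim <- simulate_perpetrator(cmp, regimen(800, n_doses = 1), t_end = 24,
                              grid_h = 0.05)
  ke <- cmp$pk$cl_L_h / cmp$pk$v_L
  d_umol <- 800 * 1000 / cmp$pk$mw
  tt <- sim$time[sim$time >= 0.2]
  pred <- (d_umol / cmp$pk$v_L) * exp(-ke * tt)
  obs <- sim$conc[sim$time >= 0.2]
  expect_lt(max(abs(obs - pred) / pred), 0.005)
})

test_that("zero dose gives an identically zero series", {
  sim <- simulate_perpetrator("rifampicin", regimen(0, n_doses = 3))
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$inlet_u == 0))
})

test_that("mass balance and superposition hold for multiple dosing", {
  reg <- regimen(600, n_doses = 5)
  sim <- simulate_perpetrator("rifampicin", reg, t_end = 96 + 48)
  absorbed <- attr(sim, "absorbed_umol")
  dosed <- attr(sim, "dosed_umol") * attr(sim, "fa")
  expect_lt(abs(absorbed - dosed) / dosed, 0.005)

  # n-dose profile equals the sum of shifted single-dose profiles
  multi <- simulate_perpetrator("rifampicin", regimen(600, n_doses = 3),
                                t_end = 96)
  single <- simulate_perpetrator("rifampicin", regimen(600, n_doses = 1),
                                 t_end = 96)
  f <- approxfun(single$time, single$conc, rule = 2, yleft = 0)
  recon <- f(multi$time) + f(multi$time - 24) + f(multi$time - 48)
  recon[multi$time < 24] <- f(multi$time[multi$time < 24])
  expect_equal(multi$conc, recon, tolerance = 1e-8)
})

test_that("steady-state exposure of the rifampicin fixture matches its literature AUC", {
  rif <- load_compound("rifampicin")
  sim <- simulate_perpetrator(rif, regimen(600, n_doses = 5), t_end = 120)
  w <- sim$time >= 96
  auc_tau <- trapezoid_auc(sim$time[w], sim$conc[w])
  ratio <- auc_tau / rif$lit_auc_tau_uMh
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("enzyme turnover follows the linear-ODE closed forms", {
  tt <- seq(0, 400, 0.05)
  kdeg <- 0.0193
  # no induction
  expect_equal(enzyme_dynamics(tt, rep(3, length(tt)), emax = 1, ec50 = 1,
                               kdeg = kdeg),
               rep(1, length(tt)))
  # constant Cu = EC50, Emax = 5: E(t) = 3 - 2 exp(-kdeg t)
  e <- enzyme_dynamics(tt, rep(1, length(tt)), emax = 5, ec50 = 1, kdeg = kdeg)
  expect_lt(max(abs(e - (3 - 2 * exp(-kdeg * tt)))), 1e-3)
  expect_true(all(e >= 1 - 1e-9 & e <= 5 + 1e-9))
  # washout: half the excess is gone after ln2/kdeg
  e0 <- 4
  ew <- enzyme_dynamics(tt, rep(0, length(tt)), emax = 5, ec50 = 1,
                        kdeg = kdeg, e0 = e0)
  at_half <- approxfun(tt, ew)(log(2) / kdeg)
  expect_lt(abs(at_half - (1 + (e0 - 1) / 2)) / (1 + (e0 - 1) / 2), 0.01)
  # return to baseline within 0.1% after 7 degradation half-lives
  at7 <- approxfun(tt, ew)(7 * log(2) / kdeg)
  expect_lt(abs(at7 - 1), 0.001 + (e0 - 1) * 2^-7)
  expect_error(enzyme_dynamics(tt, rep(1, length(tt)), 5, 1, kdeg = 0),
               class = "cypind_input_error")
})

test_that("well-stirred victim clearance behaves in both extraction limits", {
  base <- victim_clearance(c(CYP3A4 = 1), c(CYP3A4 = 1), cl_int0 = 10,
                           fu = 0.01, q_h = 90)
  expect_equal(base$cl_int, 10)
  # low extraction: doubling the enzyme doubles CLh within 5%
  dbl <- victim_clearance(c(CYP3A4 = 1), c(CYP3A4 = 2), cl_int0 = 10,
                          fu = 0.01, q_h = 90)
  expect_lt(abs(dbl$cl_h / base$cl_h - 2), 0.05 * 2)
  # flow limit: CLh -> Qh regardless of induction
  hi <- victim_clearance(c(CYP3A4 = 1), c(CYP3A4 = 5), cl_int0 = 1e6,
                         fu = 0.5, q_h = 90)
  expect_lt(abs(hi$cl_h - 90) / 90, 0.01)
  expect_lt(hi$cl_h, 90)
  expect_error(victim_clearance(c(A = 0.7, B = 0.5), c(A = 1, B = 1), 10,
                                0.1, 90),
               class = "cypind_input_error")
})

test_that("zero-dose or non-inducing perpetrators leave the victim untouched", {
  perp <- test_perpetrator()
  vic <- test_victim(fm = c(CYP3A4 = 0.8))
  out <- run_ddi(perp, vic, perp_regimen = regimen(0, n_doses = 3),
                 victim_dose_mg = 10, victim_offset_h = 49)
  expect_identical(out$aucr, 1)
  expect_identical(out$pct_reduction, 0)

  # all victim fm on an enzyme the perpetrator does not induce
  vic2 <- test_victim(fm = c(CYP2C9 = 0.8))
  expect_message(
    out2 <- run_ddi(perp, vic2, perp_regimen = regimen(600, n_doses = 3),
                    victim_dose_mg = 10, victim_offset_h = 49),
    "induces none")
  expect_equal(out2$aucr, 1, tolerance = 1e-9)
})

test_that("AUCR is invariant to victim dose (linear PK)", {
  perp <- test_perpetrator()
  vic <- test_victim(fm = c(CYP3A4 = 0.8))
  a <- run_ddi(perp, vic, perp_regimen = regimen(600, n_doses = 3),
               victim_dose_mg = 10, victim_offset_h = 49)
  b <- run_ddi(perp, vic, perp_regimen = regimen(600, n_doses = 3),
               victim_dose_mg = 20, victim_offset_h = 49)
  expect_equal(a$aucr, b$aucr, tolerance = 1e-6)
})

test_that("dynamic model agrees with the static model under constant exposure", {
  # constant unbound perpetrator exposure, low-extraction victim, enzymes
  # run in to steady state: AUCR must match the fm-weighted static model
  cu <- 0.5
  perp <- test_perpetrator(emax = 7.15, ec50 = 0.0796)
  vic <- test_victim(fm = c(CYP3A4 = 0.8), cl = 0.85, fu = 0.07, v = 9)
  out <- run_ddi(perp, vic, perp_regimen = constant_regimen(cu),
                 victim_dose_mg = 100, victim_offset_h = 420,
                 victim_window_h = 96, grid_h = 0.1)
  fc <- 1 / r3(7.15, 0.0796, cu, multiplier = 1)
  static <- net_auc_ratio(c(CYP3A4 = 0.8), c(CYP3A4 = fc))
  expect_lt(abs(out$aucr - static) / static, 0.02)
})

test_that("reported AUCR is robust to halving the solver tolerances", {
  base <- run_ddi("rifampicin", "midazolam")
  tight <- run_ddi("rifampicin", "midazolam", rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(base$aucr - tight$aucr) / base$aucr, 0.005)
  expect_true(all(base$extrap_frac < 0.2))
})

test_that("enzyme trajectories stay within [1, Emax] during a full design", {
  out <- run_ddi("rifampicin", "omeprazole")
  rif <- load_compound("rifampicin")
  for (enz in c("CYP2C19", "CYP3A4")) {
    e <- out$enzymes[[enz]]
    expect_true(all(e >= 1 - 1e-9))
    expect_true(all(e <= rif$induction[[enz]]$emax_fold + 1e-9))
  }
})

test_that("sensitivity scan reproduces the base case and is monotone", {
  perp <- test_perpetrator()
  vic <- test_victim(fm = c(CYP3A4 = 0.8))
  args <- list(perp_regimen = regimen(600, n_doses = 3),
               victim_dose_mg = 10, victim_offset_h = 49)
  base <- do.call(run_ddi, c(list(perp, vic), args))
  scan <- do.call(sensitivity_scan,
                  c(list(perp, vic, parameter = "emax",
                         factors = c(0.5, 1, 2)), args))
  expect_identical(scan$aucr[scan$factor == 1], base$aucr)
  expect_true(all(diff(scan$aucr) < 0))     # AUCR non-increasing in Emax

  scan_ec <- do.call(sensitivity_scan,
                     c(list(perp, vic, parameter = "ec50",
                            factors = c(0.5, 1, 2)), args))
  expect_true(all(diff(scan_ec$aucr) > 0))  # AUCR non-decreasing in EC50

  # joint worst case strictly below base
  perp2 <- perp
  perp2$induction$CYP3A4$emax_fold <- 1 + 2 * (perp$induction$CYP3A4$emax_fold - 1)
  perp2$induction$CYP3A4$ec50_uM <- perp$induction$CYP3A4$ec50_uM / 2
  worst <- do.call(run_ddi, c(list(perp2, vic), args))
  expect_lt(worst$aucr, base$aucr)

  scan_cl <- do.call(sensitivity_scan,
                     c(list(perp, vic, parameter = "cl_int",
                            factors = c(0.5, 1, 2)), args))
  # ordering must match brute-force reruns with scaled victim clearance
  for (f in c(0.5, 2)) {
    v2 <- vic; v2$pk$cl_L_h <- vic$pk$cl_L_h * f
    ref <- do.call(run_ddi, c(list(perp, v2), args))
    expect_equal(scan_cl$aucr[scan_cl$factor == f], ref$aucr)
  }
})

test_that("gut CYP3A4 induction deepens the interaction for gut substrates", {
  perp <- load_compound("rifampicin")
  vic <- load_compound("midazolam")
  with_gut <- run_ddi(perp, vic)
  vic_nogut <- vic
  vic_nogut$pk$gut_cyp3a4 <- FALSE
  vic_nogut$pk$fg0 <- 1
  no_gut <- run_ddi(perp, vic_nogut)
  expect_lt(with_gut$aucr, no_gut$aucr)
  expect_true("CYP3A4_gut" %in% names(with_gut$enzymes))
  expect_false("CYP3A4_gut" %in% names(no_gut$enzymes))
})
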