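test_that("R3 matches hand-computed values and limits", {
  expect_equal(r3(emax = 4, ec50 = 1, imax_u = 1, multiplier = 10), 11 / 41)
  expect_equal(r3(emax = 1, ec50 = 1, imax_u = 10), 1)
  # zero-exposure limit
  expect_equal(r3(emax = 10, ec50 = 1, imax_u = 1e-9), 1, tolerance = 1e-6)
  # convention switch: amplitude supplied directly
  expect_equal(r3(emax = 3, ec50 = 1, imax_u = 1, multiplier = 1,
                  emax_convention = "fold_minus_one"),
               r3(emax = 4, ec50 = 1, imax_u = 1, multiplier = 1))
})

test_that("R3 is bounded and monotone in its inputs", {
  set.seed(7)
  for (i in 1:50) {
    emax <- runif(1, 1, 25); ec50 <- 10^runif(1, -2, 2)
    i_u <- 10^runif(1, -2, 1); d <- runif(1, 0.5, 2)
    v <- r3(emax, ec50, i_u, d = d)
    expect_gt(v, 0); expect_lte(v, 1)
    expect_lte(r3(emax * 1.5, ec50, i_u, d = d), v)       # decreasing in Emax
    expect_lte(r3(emax, ec50, i_u * 2, d = d), v)         # decreasing in I
    expect_gte(r3(emax, ec50 * 2, i_u, d = d), v)         # increasing in EC50
  }
})

test_that("fold-CL change is the reciprocal of R3", {
  expect_equal(fold_cl_change(emax = 4, ec50 = 1, imax_u = 1), 41 / 11)
  expect_equal(fold_cl_change(emax = 1, ec50 = 1, imax_u = 5), 1)
  blk <- induction_blocks("rifampicin", donors = "donor2")$CYP3A4
  expect_equal(fold_cl_change(blk$emax_fold, blk$ec50_uM, 2),
               1 / r3(blk$emax_fold, blk$ec50_uM, 2))
})

test_that("net AUC ratio weights fold changes by fm", {
  expect_equal(net_auc_ratio(c(CYP3A4 = 0.94), c(CYP3A4 = 1)), 1)
  expect_equal(net_auc_ratio(c(A = 0.5, B = 0.5), c(A = 2, B = 2)), 0.5)
  expect_equal(net_auc_ratio(c(CYP2C9 = 0.85), c(CYP2C9 = 4)),
               1 / (3.4 + 0.15))
  # single enzyme at fm = 1 collapses to R3
  fc <- fold_cl_change(emax = 4, ec50 = 1, imax_u = 1)
  expect_equal(net_auc_ratio(c(CYP3A4 = 1), c(CYP3A4 = fc)),
               r3(emax = 4, ec50 = 1, imax_u = 1))
  # permutation invariance
  fm <- c(CYP3A4 = 0.5, CYP2C9 = 0.3, CYP2C8 = 0.1)
  fc <- c(CYP2C9 = 2, CYP2C8 = 5, CYP3A4 = 3)
  expect_equal(net_auc_ratio(fm, fc), net_auc_ratio(rev(fm), rev(fc)))
  # enzymes without a fold change are uninduced, with a warning
  expect_warning(v <- net_auc_ratio(c(CYP3A4 = 0.5, CYP2C9 = 0.4),
                                    c(CYP3A4 = 2)),
                 "treated as uninduced")
  expect_equal(v, 1 / (0.5 * 2 + 0.4 + 0.1))
  expect_error(net_auc_ratio(c(A = 0.7, B = 0.5), c(A = 2, B = 2)),
               class = "cypind_input_error")
})

test_that("static pipeline reproduces per-donor hand arithmetic", {
  m <- msm("rifampicin", "midazolam", imax_u = 2)
  rif <- subset(induction_registry(), compound == "rifampicin" &
                  enzyme == "CYP3A4")
  for (d in 1:3) {
    row <- rif[rif$donor == d, ]
    fc <- 1 / (1 / (1 + (row$emax_fold - 1) * 20 / (row$ec50_uM + 20)))
    expect_equal(m$per_donor$aucr[m$per_donor$donor == d],
                 1 / (0.94 * fc + 0.06))
  }
  expect_equal(m$summary$aucr_mean, mean(m$per_donor$aucr))
  expect_equal(m$summary$pct_reduction_mean,
               100 * (1 - m$summary$aucr_mean))
  expect_output(print(m), "mean AUCR")
})

test_that("all-no-call donors yield a no-call static report", {
  fits <- data.frame(enzyme = "CYP2C9", donor = 1:3, ec50_uM = NA_real_,
                     emax_fold = NA_real_, nc = TRUE)
  vic <- test_victim(fm = c(CYP2C9 = 0.85))
  m <- msm("rifampicin", vic, fits = fits)
  expect_true(m$summary$no_call)
  expect_output(print(m), "no-call")
})

test_that("per-enzyme multiplier overrides are honoured", {
  fits <- data.frame(enzyme = c("CYP3A4", "CYP2C9"), donor = 1,
                     ec50_uM = c(0.1, 0.1), emax_fold = c(5, 5), nc = FALSE)
  vic <- test_victim(fm = c(CYP3A4 = 0.5, CYP2C9 = 0.5))
  m10 <- msm("rifampicin", vic, fits = fits, imax_u = 1, multiplier = 10)
  mmix <- msm("rifampicin", vic, fits = fits, imax_u = 1,
              multiplier = c(CYP3A4 = 10, CYP2C9 = 1))
  fc10 <- 1 / r3(5, 0.1, 1, multiplier = 10)
  fc1 <- 1 / r3(5, 0.1, 1, multiplier = 1)
  expect_equal(mmix$per_donor$aucr,
               net_auc_ratio(vic$fm, c(CYP3A4 = fc10, CYP2C9 = fc1)))
  expect_lt(m10$per_donor$aucr, mmix$per_donor$aucr)
})
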