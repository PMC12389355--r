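test_that("no-call rule is strict at 2-fold and drives the fit path", {
  flat <- data.frame(conc_uM = rep(c(0.1, 1, 10, 100), each = 2),
                     fold_change = 1)
  expect_true(apply_nc_rule(flat))
  f <- fit_induction(flat)
  expect_true(f$nc)
  expect_true(is.na(f$ec50_uM))

  below <- data.frame(conc_uM = c(0.1, 1, 10, 100),
                      fold_change = c(1, 1.2, 1.6, 1.9))
  at <- data.frame(conc_uM = c(0.1, 1, 10, 100),
                   fold_change = c(1, 1.2, 1.6, 2.0))
  expect_true(apply_nc_rule(below))
  expect_false(apply_nc_rule(at))   # exactly 2-fold is not a no-call
})

test_that("no-call is monotone under response scaling", {
  for (seed in 1:5) {
    d <- sim_induction_response(ec50 = 1, emax = 3, seed = seed, cv = 0.15)
    if (!apply_nc_rule(d)) {
      for (k in c(1, 1.5, 4)) {
        d2 <- d
        d2$fold_change <- d2$fold_change * k
        expect_false(apply_nc_rule(d2))
      }
    }
  }
})

test_that("noiseless Hill data are recovered to 1e-4 relative error", {
  d <- hill_data(ec50 = 0.0655, emax = 5.60)
  f <- fit_induction(d, form = "hill")
  expect_true(f$converged)
  expect_lt(abs(f$ec50_uM - 0.0655) / 0.0655, 1e-4)
  expect_lt(abs(f$emax_fold - 5.60) / 5.60, 1e-4)
  expect_lt(abs(f$slope - 1), 1e-4)
  # the log-concentration logistic is the same curve family: identical optimum
  g <- fit_induction(d, form = "logistic_logC")
  expect_lt(abs(g$ec50_uM - 0.0655) / 0.0655, 1e-4)
  expect_lt(abs(g$emax_fold - 5.60) / 5.60, 1e-4)
})

test_that("recovery holds across random truths inside the tested range", {
  set.seed(42)
  conc <- 10^seq(-2, 1.5, length.out = 8)
  for (i in 1:8) {
    truth <- c(ec50 = 10^runif(1, -1.5, 1), emax = runif(1, 2.5, 15),
               hill = runif(1, 0.6, 2.5))
    d <- sim_induction_response(truth["ec50"], truth["emax"], truth["hill"],
                                conc = conc, cv = 0, seed = i)
    f <- fit_induction(d, form = "hill")
    expect_true(f$converged)
    expect_lt(abs(f$ec50_uM - truth["ec50"]) / truth["ec50"], 1e-4)
    expect_lt(abs(f$emax_fold - truth["emax"]) / truth["emax"], 1e-4)
    expect_lt(abs(f$slope - truth["hill"]) / truth["hill"], 1e-4)
  }
})

test_that("fitted Emax never exceeds twice the maximum observed mean fold", {
  # truth EC50 at the top of the tested range: the plateau is unobserved
  conc <- 10^seq(-2, 0.5, length.out = 6)
  d <- sim_induction_response(ec50 = 3, emax = 12, conc = conc, cv = 0.1,
                              seed = 11)
  f <- fit_induction(d, form = "hill")
  agg_max <- max(f$agg$mean_fold)
  if (!f$nc && !is.na(f$emax_fold)) {
    expect_lte(f$emax_fold, 2 * agg_max + 1e-8)
  }
})

test_that("fit bookkeeping: weights, duplicates, refusals", {
  # noiseless quadruplicates have zero SD -> unweighted path
  expect_false(fit_induction(hill_data(0.5, 5))$weighted)
  noisy <- sim_induction_response(0.5, 5, seed = 3, cv = 0.1)
  expect_true(fit_induction(noisy)$weighted)

  # duplicate concentration entries are averaged before fitting
  dup <- rbind(noisy, noisy)
  f <- fit_induction(dup)
  expect_equal(nrow(f$agg), length(unique(noisy$conc_uM)))

  few <- data.frame(conc_uM = c(0.1, 1, 10), fold_change = c(1, 3, 5))
  expect_error(fit_induction(few), class = "cypind_input_error")
  expect_error(validate_induction_data(
    data.frame(conc_uM = c(0.1, 1, 10, 100), fold_change = c(1, 2, -1, 3))),
    class = "cypind_input_error")
})

test_that("model methods behave like a fitted model object", {
  d <- hill_data(0.5, 6)
  f <- fit_induction(d, form = "hill")
  expect_named(coef(f), c("ec50_uM", "emax_fold", "slope"))
  expect_equal(predict(f, conc = 0), 1)                  # vehicle baseline
  expect_equal(predict(f, conc = f$ec50_uM), 1 + 5 / 2, tolerance = 1e-4)
  expect_lt(max(abs(residuals(f))), 1e-6)
  expect_output(print(f), "EC50")
  expect_output(print(summary(f)), "residual sum of squares")
  nc_fit <- fit_induction(data.frame(conc_uM = c(0.1, 1, 10, 100),
                                     fold_change = 1.1))
  expect_error(predict(nc_fit, 1), class = "cypind_input_error")
})

test_that("moderate replicate noise still centres the EC50 estimate", {
  errs <- vapply(1:40, function(s) {
    d <- sim_induction_response(0.803, 8.45, seed = s, cv = 0.1, n = 4)
    f <- fit_induction(d, form = "hill")
    if (!f$converged) return(NA_real_)
    abs(f$ec50_uM - 0.803) / 0.803
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("donor summaries exclude no-calls and report ranges", {
  rif <- subset(induction_registry(), compound == "rifampicin")
  s <- summarize_donors(rif)
  cyp3a4 <- s[s$enzyme == "CYP3A4", ]
  expect_equal(cyp3a4$ec50_min, 0.0602)
  expect_equal(cyp3a4$ec50_max, 0.128)
  expect_equal(cyp3a4$nc_count, 0)

  one <- rif[rif$enzyme == "CYP3A4" & rif$donor == 1, ]
  s1 <- summarize_donors(one)
  expect_equal(s1$ec50_mean, s1$ec50_min)
  expect_equal(s1$ec50_mean, s1$ec50_max)

  cbz <- subset(induction_registry("activity"),
                compound == "carbamazepine" & enzyme == "CYP2C9")
  s2 <- summarize_donors(cbz)
  expect_false(s2$all_nc)           # donor 1 is estimable
  expect_equal(s2$nc_count, 2)
  allnc <- cbz[cbz$donor != 1, ]
  expect_true(summarize_donors(allnc)$all_nc)
})

test_that("long-table fitting covers every group and the CSV round-trips", {
  d1 <- sim_induction_response(0.1, 5, seed = 1, cv = 0.05,
                               compound = "a", enzyme = "CYP3A4")
  d2 <- sim_induction_response(1, 1.5, seed = 2, cv = 0.05,
                               compound = "a", enzyme = "CYP2C9")
  tab <- fit_induction_all(rbind(d1, d2), form = "hill")
  expect_equal(nrow(tab), 2)
  expect_false(tab$nc[tab$enzyme == "CYP3A4"])
  expect_true(tab$nc[tab$enzyme == "CYP2C9"])

  path <- withr::local_tempfile(fileext = ".csv")
  write_induction_csv(d1, path)
  back <- read_induction_csv(path)
  expect_equal(back$fold_change, d1$fold_change)
})
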