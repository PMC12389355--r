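# Minimal dynamic DDI engine. The perpetrator follows linear
# one-compartment first-order oral kinetics, so multiple-dose profiles are
# evaluated by closed-form Bateman superposition (exact; no integrator
# error, superposition and mass balance hold by construction). The
# perpetrator's unbound hepatic-inlet concentration drives per-enzyme
# turnover
#
#   dE/dt = kdeg * [1 + (Emax - 1) * Cu / (EC50 + Cu)] - kdeg * E,  E(0)=1,
#
# a linear ODE in E integrated with an exact exponential step on the output
# grid. The victim is simulated twice (enzymes at baseline vs under the
# perpetrator regimen) with fm-partitioned intrinsic clearance in a
# well-stirred liver,
#
#   CLint(t) = CLint0 * [sum_i fm_i E_i(t) + (1 - sum fm_i)],
#   CLh(t)   = Qh fu CLint / (Qh + fu CLint),
#
# and, for gut CYP3A4 substrates, a first-pass gut extraction
# Fg(t) = 1 / (1 + (1/Fg0 - 1) * Eg(t)) driven by an enterocyte pool with
# its own (faster) kdeg.

.perp_forcings <- function(pk, reg, phys) {
  if (reg$type == "constant") {
    cu <- reg$conc_u_uM
    return(list(
      conc = function(t) rep(cu / pk$fu, length(t)),
      conc_u = function(t) rep(cu, length(t)),
      inlet_u = function(t) rep(cu, length(t)),
      c_ent = function(t) rep(cu, length(t)),
      agut = function(t) rep(0, length(t)),
      dose_times = numeric(0), dose_umol = 0
    ))
  }
  dose_umol <- reg$dose_mg * 1000 / pk$mw
  td <- reg$start_h + (seq_len(reg$n_doses) - 1) * reg$interval_h
  ka <- pk$ka
  ke <- pk$cl_L_h / pk$v_L
  one_gut <- function(tau) ifelse(tau < 0, 0, dose_umol * exp(-ka * tau))
  one_conc <- if (abs(ka - ke) > 1e-8) {
    function(tau) {
      ifelse(tau < 0, 0,
             (pk$fa * dose_umol / pk$v_L) * ka / (ka - ke) *
               (exp(-ke * tau) - exp(-ka * tau)))
    }
  } else {
    function(tau) {
      ifelse(tau < 0, 0, (pk$fa * dose_umol / pk$v_L) * ka * tau *
               exp(-ka * tau))
    }
  }
  sup <- function(f) {
    function(t) {
      out <- rep(0, length(t))
      for (t0 in td) out <- out + f(t - t0)
      out
    }
  }
  agut <- sup(one_gut)
  conc <- sup(one_conc)
  list(
    conc = conc,
    conc_u = function(t) pk$fu * conc(t),
    inlet_u = function(t) pk$fu * (conc(t) + ka * pk$fa * agut(t) / phys$q_h),
    c_ent = function(t) ka * pk$fa * agut(t) / phys$q_gut,
    agut = agut,
    dose_times = td, dose_umol = dose_umol
  )
}

#' Simulate multiple-dose perpetrator pharmacokinetics
#'
#' Closed-form one-compartment first-order oral kinetics with dose
#' superposition: total and unbound plasma concentration and the unbound
#' hepatic-inlet concentration (systemic plus absorption-rate/Qh term) on a
#' regular grid.
#'
#' @param compound perpetrator name or `"compound_model"`.
#' @param reg a [regimen()].
#' @param t_end end of the simulated window, h (default: one interval past
#'   the final dose).
#' @param grid_h output time step, h.
#' @param physiology see [default_physiology()].
#' @return Object of class `"perp_sim"`: data frame with columns `time`,
#'   `conc` (total uM), `conc_u`, `inlet_u`, `gut_amount` (umol), with the
#'   compound/regimen and the analytic cumulative-absorbed fraction as
#'   attributes.
#' @export
#' @examples
#' sim <- simulate_perpetrator("rifampicin", regimen(600, n_doses = 5))
#' max(sim$conc)                   # ~ 10 uM total Cmax
simulate_perpetrator <- function(compound, reg, t_end = NULL, grid_h = 0.05,
                                 physiology = default_physiology()) {
  cmp <- if (is.character(compound)) load_compound(compound) else compound
  if (reg$type == "oral" && grid_h > 0.1) {
    stop_input("grid_h must be <= 0.1 h to resolve absorption phases")
  }
  pk <- cmp$pk
  frc <- .perp_forcings(pk, reg, physiology)
  if (is.null(t_end)) {
    t_end <- if (reg$type == "oral") max(frc$dose_times) + reg$interval_h
    else 24
  }
  tt <- seq(0, t_end, by = grid_h)
  out <- data.frame(
    time = tt, conc = frc$conc(tt), conc_u = frc$conc_u(tt),
    inlet_u = frc$inlet_u(tt), gut_amount = frc$agut(tt)
  )
  total_dosed <- frc$dose_umol * length(frc$dose_times)
  absorbed <- if (reg$type == "oral" && total_dosed > 0) {
    pk$fa * sum(frc$dose_umol * (1 - exp(-pk$ka * pmax(0, t_end - frc$dose_times))))
  } else {
    0
  }
  structure(out, class = c("perp_sim", "data.frame"),
            compound = cmp$name, regimen = reg,
            absorbed_umol = absorbed,
            dosed_umol = total_dosed,
            fa = pk$fa)
}

#' Enzyme turnover under a time-varying inducer concentration
#'
#' Integrates the synthesis/degradation turnover model
#' `dE/dt = kdeg * S(Cu(t)) - kdeg * E` with stimulation
#' `S = 1 + (Emax - 1) * Cu / (EC50 + Cu)` and baseline `E(0) = 1`
#' (relative abundance). The linear ODE is advanced with an exact
#' exponential step per grid interval (trapezoidal forcing), which is
#' unconditionally stable for any `kdeg`.
#'
#' @param times strictly increasing time grid, h.
#' @param cu unbound inducer concentration at `times`, uM (vector) or a
#'   function of time.
#' @param emax maximal fold induction (baseline 1).
#' @param ec50 unbound EC50, uM.
#' @param kdeg enzyme degradation rate constant, 1/h; must be positive.
#' @param e0 initial relative abundance (default 1).
#' @return Numeric vector of relative enzyme abundance `E(t)` at `times`.
#' @export
#' @examples
#' tt <- seq(0, 240, 0.1)
#' e <- enzyme_dynamics(tt, cu = rep(1, length(tt)), emax = 5, ec50 = 1,
#'                      kdeg = 0.0193)
#' tail(e, 1)    # approaches Ess = 1 + 4 * 1/(1 + 1) = 3
enzyme_dynamics <- function(times, cu, emax, ec50, kdeg, e0 = 1) {
  if (kdeg <= 0) stop_input("kdeg must be positive")
  if (emax < 1) stop_input("emax (fold) must be >= 1")
  if (ec50 <= 0) stop_input("ec50 must be positive")
  if (is.function(cu)) cu <- cu(times)
  if (any(cu < -1e-12)) stop_input("inducer concentrations must be >= 0")
  cu <- pmax(cu, 0)
  s <- 1 + (emax - 1) * cu / (ec50 + cu)
  n <- length(times)
  dt <- diff(times)
  if (any(dt <= 0)) stop_input("times must be strictly increasing")
  e <- numeric(n)
  e[1] <- e0
  sbar <- (s[-n] + s[-1]) / 2
  decay <- exp(-kdeg * dt)
  for (i in seq_len(n - 1)) {
    e[i + 1] <- sbar[i] + (e[i] - sbar[i]) * decay[i]
  }
  e
}

#' Instantaneous well-stirred hepatic clearance under induction
#'
#' @param fm named fm vector of the victim (`"other"` treated as uninduced
#'   residual).
#' @param e named vector (or single-row assignment) of relative enzyme
#'   abundances; enzymes absent from `e` are at baseline 1.
#' @param cl_int0 baseline intrinsic clearance, L/h.
#' @param fu victim unbound fraction in plasma.
#' @param q_h hepatic blood flow, L/h.
#' @return List with `cl_int` (L/h), `cl_h` (L/h, always < `q_h`) and `f_h`
#'   (hepatic availability).
#' @export
#' @examples
#' victim_clearance(c(CYP3A4 = 1), c(CYP3A4 = 2), cl_int0 = 10,
#'                  fu = 0.05, q_h = 90)
victim_clearance <- function(fm, e, cl_int0, fu, q_h) {
  if (sum(fm) > 1 + 1e-9) stop_input("fm sum exceeds 1")
  if (q_h <= 0) stop_input("q_h must be positive")
  induc <- setdiff(names(fm), "other")
  e_used <- setNames(rep(1, length(induc)), induc)
  hit <- intersect(induc, names(e))
  e_used[hit] <- e[hit]
  mult <- sum(fm[induc] * e_used) + (1 - sum(fm[induc]))
  cl_int <- cl_int0 * mult
  cl_h <- q_h * fu * cl_int / (q_h + fu * cl_int)
  list(cl_int = cl_int, cl_h = cl_h, f_h = q_h / (q_h + fu * cl_int))
}

.clint0_from_cl <- function(cl, fu, q_h) {
  if (cl >= q_h) {
    stop_input("systemic clearance (", cl, " L/h) must be below hepatic flow (",
               q_h, " L/h)")
  }
  q_h * cl / (fu * (q_h - cl))
}

# terminal log-linear slope over the trailing part of a profile;
# returns NA when no reliable negative slope is found
.terminal_kel <- function(time, conc, tail_frac = 0.25) {
  n <- length(time)
  keep <- time >= time[n] - tail_frac * (time[n] - time[1]) & conc > 0
  if (sum(keep) < 5) return(NA_real_)
  fit <- lm(log(conc[keep]) ~ time[keep])
  sl <- unname(coef(fit)[2])
  if (!is.finite(sl) || sl >= -1e-6) NA_real_ else -sl
}

.victim_arm <- function(pk, dose_umol, window_h, grid_h, mfun, fgfun,
                        phys, rtol, atol) {
  clint0 <- .clint0_from_cl(pk$cl_L_h, pk$fu, phys$q_h)
  parms <- list(ka = pk$ka, fa = pk$fa, v = pk$v_L, fu = pk$fu,
                qh = phys$q_h, clint0 = clint0, mfun = mfun, fgfun = fgfun)
  deriv <- function(t, y, p) {
    clint <- p$clint0 * p$mfun(t)
    fuclint <- p$fu * clint
    clh <- p$qh * fuclint / (p$qh + fuclint)
    fh <- p$qh / (p$qh + fuclint)   # hepatic first pass of absorbed drug
    dgut <- -p$ka * y[1]
    dcen <- p$ka * p$fa * p$fgfun(t) * fh * y[1] - clh * y[2] / p$v
    list(c(dgut, dcen, y[2] / p$v))
  }
  tt <- seq(0, window_h, by = grid_h)
  sol <- deSolve::lsoda(c(gut = dose_umol, cen = 0, auc = 0), tt, deriv,
                        parms, rtol = rtol, atol = atol)
  conc <- unname(sol[, "cen"]) / pk$v_L
  auc_last <- unname(sol[nrow(sol), "auc"])
  kel <- .terminal_kel(tt, conc)
  if (is.na(kel)) {
    list(time = tt, conc = conc, auc = auc_last, auc_inf = auc_last,
         extrap_frac = NA_real_, auc_flag = "auc_last_only")
  } else {
    extra <- conc[length(conc)] / kel
    list(time = tt, conc = conc, auc = auc_last, auc_inf = auc_last + extra,
         extrap_frac = extra / (auc_last + extra), auc_flag = "ok")
  }
}

#' Simulate an induction DDI between a perpetrator and a victim drug
#'
#' Runs the full dynamic workflow: multiple-dose perpetrator PK, per-enzyme
#' hepatic (and, for gut CYP3A4 substrates, enterocyte) turnover induction,
#' then the victim arm twice -- enzymes at baseline versus under the
#' perpetrator regimen -- with AUC to infinity by trapezoid plus terminal
#' extrapolation. The victim dose cancels from the AUC ratio (linear PK).
#'
#' @param perpetrator perpetrator name or `"compound_model"` (with
#'   induction blocks).
#' @param victim victim name or `"compound_model"` (with an fm block).
#' @param design optional packaged design from [ddi_design()]; defaults to
#'   the packaged design for the victim. Fields can be overridden with
#'   `perp_regimen`, `victim_dose_mg`, `victim_offset_h`.
#' @param perp_regimen,victim_dose_mg,victim_offset_h design overrides.
#' @param readout,donors induction parameter selection when `perpetrator`
#'   is given by name (see [induction_blocks()]).
#' @param victim_window_h length of the simulated victim window, h.
#' @param grid_h output/forcing grid step, h (<= 0.1).
#' @param kdeg named kdeg vector, see [kdeg_defaults()].
#' @param physiology see [default_physiology()].
#' @param driver induction driving concentration: `"inlet"` (unbound
#'   hepatic inlet, default) or `"systemic"` (unbound plasma).
#' @param rtol,atol integrator tolerances for the victim arm.
#' @return Object of class `"ddi_outcome"`: `auc_alone_uMh`,
#'   `auc_with_uMh` (dose-normalized victim AUCs), `aucr`,
#'   `pct_reduction = 100 (1 - aucr)`, victim concentration series for both
#'   arms, enzyme abundance trajectories, and AUC-extrapolation
#'   diagnostics.
#' @export
#' @examples
#' \donttest{
#' out <- run_ddi("rifampicin", "midazolam")
#' out$pct_reduction
#' }
run_ddi <- function(perpetrator, victim, design = NULL,
                    perp_regimen = NULL, victim_dose_mg = NULL,
                    victim_offset_h = NULL, readout = "mrna",
                    donors = "geomean", victim_window_h = 96,
                    grid_h = 0.05, kdeg = kdeg_defaults(),
                    physiology = default_physiology(),
                    driver = c("inlet", "systemic"),
                    rtol = 1e-8, atol = 1e-10) {
  driver <- match.arg(driver)
  perp <- if (is.character(perpetrator)) {
    load_compound(perpetrator, readout = readout, donors = donors)
  } else perpetrator
  vic <- if (is.character(victim)) load_compound(victim) else victim
  if (is.null(perp$induction)) {
    stop_input("perpetrator '", perp$name, "' has no induction blocks")
  }
  if (is.null(vic$fm)) stop_input("victim '", vic$name, "' has no fm map")
  if (grid_h > 0.1) stop_input("grid_h must be <= 0.1 h")

  if (is.null(design) && is.null(perp_regimen)) {
    design <- tryCatch(ddi_design(vic$name), error = function(e) NULL)
  }
  reg <- perp_regimen %||% design$perp_regimen
  if (is.null(reg)) stop_input("no perpetrator regimen supplied")
  victim_dose_mg <- victim_dose_mg %||% design$victim_dose_mg %||% 1
  victim_offset_h <- victim_offset_h %||% design$victim_offset_h %||%
    (if (reg$type == "oral") (reg$n_doses - 1) * reg$interval_h + 1 else 48)

  t_end <- victim_offset_h + victim_window_h
  frc <- .perp_forcings(perp$pk, reg, physiology)
  tt <- seq(0, t_end, by = grid_h)
  cu_liver <- if (driver == "inlet") frc$inlet_u(tt) else frc$conc_u(tt)

  fm_enz <- setdiff(names(vic$fm), "other")
  induced <- intersect(fm_enz, names(perp$induction))
  uninduced <- setdiff(fm_enz, induced)
  if (length(induced) == 0) {
    message("perpetrator induces none of the victim's enzymes; AUCR = 1 expected")
  }

  e_mat <- sapply(induced, function(enz) {
    blk <- perp$induction[[enz]]
    kd <- kdeg[[enz]]
    if (is.null(kd) || is.na(kd)) stop_input("no kdeg for enzyme ", enz)
    enzyme_dynamics(tt, cu_liver, blk$emax_fold, blk$ec50_uM, kd)
  })
  if (length(induced) > 0) e_mat <- matrix(e_mat, ncol = length(induced),
                                           dimnames = list(NULL, induced))

  resid <- 1 - sum(vic$fm[fm_enz])
  fmv <- vic$fm[fm_enz]
  mult_t <- rep(resid + sum(fmv[uninduced]), length(tt))
  for (enz in induced) mult_t <- mult_t + fmv[[enz]] * e_mat[, enz]

  use_gut <- isTRUE(vic$pk$gut_cyp3a4) && "CYP3A4" %in% names(perp$induction) &&
    vic$pk$fg0 < 1
  if (use_gut) {
    blk <- perp$induction$CYP3A4
    eg <- enzyme_dynamics(tt, frc$c_ent(tt), blk$emax_fold, blk$ec50_uM,
                          kdeg[["CYP3A4_gut"]])
    fg_t <- 1 / (1 + (1 / vic$pk$fg0 - 1) * eg)
  } else {
    eg <- NULL
    fg_t <- rep(vic$pk$fg0, length(tt))
  }

  # forcings restricted to the victim window (time measured from victim dose)
  win <- tt >= victim_offset_h - grid_h
  shift <- function(y) approxfun(tt[win] - victim_offset_h, y[win], rule = 2)
  mfun <- shift(mult_t)
  fgfun <- shift(fg_t)
  base_m <- function(t) rep(1, length(t))
  base_fg <- function(t) rep(vic$pk$fg0, length(t))

  dose_umol <- victim_dose_mg * 1000 / vic$pk$mw
  alone <- .victim_arm(vic$pk, dose_umol, victim_window_h, grid_h,
                       base_m, base_fg, physiology, rtol, atol)
  with_p <- .victim_arm(vic$pk, dose_umol, victim_window_h, grid_h,
                        mfun, fgfun, physiology, rtol, atol)

  for (arm in list(alone, with_p)) {
    if (identical(arm$auc_flag, "ok") && is.finite(arm$extrap_frac) &&
        arm$extrap_frac > 0.2) {
      warning("extrapolated AUC fraction exceeds 20% (",
              sprintf("%.1f%%", 100 * arm$extrap_frac), ")")
    }
  }

  aucr <- with_p$auc_inf / alone$auc_inf
  series <- rbind(
    data.frame(arm = "alone", time = alone$time, conc_uM = alone$conc),
    data.frame(arm = "with_perpetrator", time = with_p$time,
               conc_uM = with_p$conc)
  )
  enzymes <- data.frame(time = tt, check.names = FALSE)
  for (enz in induced) enzymes[[enz]] <- e_mat[, enz]
  if (!is.null(eg)) enzymes[["CYP3A4_gut"]] <- eg

  structure(
    list(
      perpetrator = perp$name, victim = vic$name,
      regimen = reg, victim_dose_mg = victim_dose_mg,
      victim_offset_h = victim_offset_h,
      auc_alone_uMh = alone$auc_inf, auc_with_uMh = with_p$auc_inf,
      aucr = aucr, pct_reduction = 100 * (1 - aucr),
      extrap_frac = c(alone = alone$extrap_frac, with = with_p$extrap_frac),
      auc_flags = c(alone = alone$auc_flag, with = with_p$auc_flag),
      series = series, enzymes = enzymes, fm = vic$fm,
      driver = driver, grid_h = grid_h
    ),
    class = "ddi_outcome"
  )
}

#' @export
print.ddi_outcome <- function(x, ...) {
  cat("Dynamic induction DDI: ", x$perpetrator, " -> ", x$victim, "\n",
      sep = "")
  if (x$regimen$type == "oral") {
    cat(sprintf("  perpetrator %g mg x %d q%gh; victim %g mg at %g h\n",
                x$regimen$dose_mg, x$regimen$n_doses, x$regimen$interval_h,
                x$victim_dose_mg, x$victim_offset_h))
  } else {
    cat(sprintf("  constant unbound exposure %g uM; victim %g mg at %g h\n",
                x$regimen$conc_u_uM, x$victim_dose_mg, x$victim_offset_h))
  }
  cat(sprintf("  AUC alone %.4g uM*h, with perpetrator %.4g uM*h\n",
              x$auc_alone_uMh, x$auc_with_uMh))
  cat(sprintf("  AUCR %.3f -> %.1f%% AUC reduction\n", x$aucr,
              x$pct_reduction))
  invisible(x)
}

#' @export
summary.ddi_outcome <- function(object, ...) {
  e <- object$enzymes
  emax_reached <- vapply(names(e)[-1], function(n) max(e[[n]]), numeric(1))
  cat("Enzyme induction at victim dose time and trajectory maxima:\n")
  at_dose <- vapply(names(e)[-1], function(n) {
    approxfun(e$time, e[[n]])(object$victim_offset_h)
  }, numeric(1))
  print(round(rbind(at_victim_dose = at_dose, maximum = emax_reached), 3))
  print(object)
  invisible(object)
}

#' @export
plot.ddi_outcome <- function(x, which = c("victim", "enzymes"), ...) {
  which <- match.arg(which)
  if (which == "victim") {
    s <- x$series
    a <- s[s$arm == "alone", ]
    b <- s[s$arm == "with_perpetrator", ]
    plot(a$time, a$conc_uM, type = "l", lwd = 2,
         xlab = "Time after victim dose (h)", ylab = "Victim conc (uM)", ...)
    lines(b$time, b$conc_uM, col = "red3", lwd = 2)
    legend("topright", c("alone", "with perpetrator"),
           col = c("black", "red3"), lwd = 2, bty = "n")
  } else {
    e <- x$enzymes
    matplot(e$time, as.matrix(e[, -1, drop = FALSE]), type = "l", lty = 1,
            lwd = 2, xlab = "Time (h)", ylab = "Relative enzyme abundance",
            ...)
    abline(v = x$victim_offset_h, lty = 3)
    legend("topleft", names(e)[-1], col = seq_len(ncol(e) - 1), lty = 1,
           lwd = 2, bty = "n")
  }
  invisible(x)
}

#' One-at-a-time sensitivity scan of the dynamic DDI model
#'
#' Reruns [run_ddi()] with the chosen parameter scaled by each factor:
#' `"emax"` scales the induction amplitude (Emax - 1) of every perpetrator
#' enzyme block, `"ec50"` scales every EC50, `"cl_int"` scales the victim's
#' baseline clearance.
#'
#' @param perpetrator,victim compound names or models.
#' @param parameter `"emax"`, `"ec50"` or `"cl_int"`.
#' @param factors numeric perturbation factors (1 = base case).
#' @param ... passed to [run_ddi()].
#' @return Data frame with `factor`, `aucr`, `pct_reduction`.
#' @export
sensitivity_scan <- function(perpetrator, victim,
                             parameter = c("emax", "ec50", "cl_int"),
                             factors = c(0.5, 1, 2), ...) {
  parameter <- match.arg(parameter)
  perp <- if (is.character(perpetrator)) load_compound(perpetrator)
  else perpetrator
  vic <- if (is.character(victim)) load_compound(victim) else victim
  rows <- lapply(factors, function(f) {
    p <- perp; v <- vic
    if (parameter == "emax") {
      p$induction <- lapply(p$induction, function(b) {
        b$emax_fold <- 1 + (b$emax_fold - 1) * f; b
      })
    } else if (parameter == "ec50") {
      p$induction <- lapply(p$induction, function(b) {
        b$ec50_uM <- b$ec50_uM * f; b
      })
    } else {
      v$pk$cl_L_h <- v$pk$cl_L_h * f
    }
    out <- run_ddi(p, v, ...)
    data.frame(factor = f, aucr = out$aucr,
               pct_reduction = out$pct_reduction)
  })
  do.call(rbind, rows)
}
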