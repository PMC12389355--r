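# Mechanistic static model for induction DDIs. The basic induction model
# (ICH M12) predicts the ratio of victim AUC with/without the perpetrator
# for a single fully-responsible enzyme as
#
#   R3 = 1 / (1 + d * (Emax - 1) * I / (EC50 + I)),   I = multiplier * Imax,u
#
# with scaling factor d (default 1) and a 10x concentration correction
# calibrated for CYP3A4 mRNA induction. Because victims of CYP2C induction
# are multi-enzyme substrates, the net AUC ratio weights the per-enzyme
# fold-change in intrinsic clearance by the victim's fraction metabolized:
#
#   AUCR = 1 / (sum_i fm_i * FC_i + (1 - sum_i fm_i)),  FC_i = 1 / R3_i.

#' Basic static induction model R3
#'
#' @param emax maximal fold induction. Under the default
#'   `emax_convention = "fold"` this is total fold induction with baseline 1
#'   (the convention of [fit_induction()] and the registry), and the
#'   induction amplitude entering the model is `emax - 1`; under
#'   `"fold_minus_one"` the supplied value is already the maximal increase
#'   over baseline.
#' @param ec50 concentration of half-maximal induction, uM.
#' @param imax_u perpetrator maximal unbound plasma concentration, uM.
#' @param d empirical scaling factor (default 1).
#' @param multiplier concentration correction multiplying `imax_u` (default
#'   10, the CYP3A4-calibrated correction; supply per-enzyme values to
#'   override).
#' @param emax_convention `"fold"` or `"fold_minus_one"`.
#' @return R3, a ratio in (0, 1].
#' @export
#' @examples
#' r3(emax = 4, ec50 = 1, imax_u = 1, multiplier = 10)   # 11/41
#' r3(emax = 1, ec50 = 1, imax_u = 5)                    # no induction: 1
r3 <- function(emax, ec50, imax_u, d = 1, multiplier = 10,
               emax_convention = c("fold", "fold_minus_one")) {
  emax_convention <- match.arg(emax_convention)
  if (any(imax_u <= 0)) stop_input("imax_u must be positive")
  if (any(d <= 0)) stop_input("d must be positive")
  if (any(multiplier <= 0)) stop_input("multiplier must be positive")
  if (any(ec50 <= 0)) stop_input("ec50 must be positive")
  amp <- if (emax_convention == "fold") emax - 1 else emax
  if (any(amp < 0)) stop_input("emax below baseline")
  i_eff <- multiplier * imax_u
  1 / (1 + d * amp * i_eff / (ec50 + i_eff))
}

#' Fold-change in enzyme-mediated intrinsic clearance implied by R3
#'
#' The reciprocal of [r3()]: the factor by which the perpetrator multiplies
#' the victim's intrinsic clearance through the induced enzyme.
#'
#' @inheritParams r3
#' @return Fold change >= 1.
#' @export
fold_cl_change <- function(emax, ec50, imax_u, d = 1, multiplier = 10,
                           emax_convention = "fold") {
  1 / r3(emax, ec50, imax_u, d = d, multiplier = multiplier,
         emax_convention = emax_convention)
}

#' fm-weighted net AUC ratio
#'
#' Combines per-enzyme fold-changes in intrinsic clearance into the victim
#' AUC ratio using the fraction metabolized by each enzyme; unlisted
#' clearance (`1 - sum(fm)`) is uninduced. Enzymes present in `fm` but
#' absent from `fc` are treated as uninduced with a warning (e.g. no-call
#' enzymes); the `"other"` fm entry is always uninduced.
#'
#' @param fm named numeric vector of fractions metabolized (each in
#'   \[0, 1\], sum at most 1).
#' @param fc named numeric vector of fold-changes in intrinsic clearance
#'   (each >= 1), named by enzyme.
#' @return AUC ratio in (0, 1].
#' @export
#' @examples
#' net_auc_ratio(c(CYP2C9 = 0.85), c(CYP2C9 = 4))   # 1/(3.4 + 0.15)
net_auc_ratio <- function(fm, fc) {
  if (any(fm < 0 | fm > 1)) stop_input("fm values must lie in [0, 1]")
  if (sum(fm) > 1 + 1e-9) stop_input("fm sum exceeds 1")
  if (any(fc < 1 - 1e-12)) stop_input("fold changes must be >= 1")
  fc_used <- setNames(rep(1, length(fm)), names(fm))
  induc <- setdiff(names(fm), "other")
  missing <- setdiff(induc, names(fc))
  if (length(missing) > 0) {
    warning("no fold-change for enzyme(s) ", paste(missing, collapse = ", "),
            "; treated as uninduced (FC = 1)")
  }
  hit <- intersect(induc, names(fc))
  fc_used[hit] <- fc[hit]
  1 / (sum(fm * fc_used) + (1 - sum(fm)))
}

#' Mechanistic static model for a perpetrator-victim pair
#'
#' Runs the full static pipeline: per-donor induction parameters of the
#' perpetrator (from the registry or supplied fits), per-enzyme R3 and
#' fold-CL change at `I = multiplier x Imax,u`, fm-weighted net AUC ratio
#' per donor, and the donor mean and range. Donors that are no-call on
#' every enzyme of the victim's fm map yield a no-call report.
#'
#' @param perpetrator perpetrator name, or a `"compound_model"`.
#' @param victim victim name, or a `"compound_model"` with an `fm` block.
#' @param donors donor selection: `"all"` (default; per-donor results) or
#'   one of `1:3`.
#' @param readout `"mrna"` (default) or `"activity"`.
#' @param imax_u perpetrator unbound Cmax, uM; defaults to the packaged
#'   fixture value.
#' @param d,multiplier,emax_convention passed to [r3()]; `multiplier` may
#'   be a single value or a named per-enzyme vector.
#' @param fits optional data frame of induction fits (columns `enzyme`,
#'   `donor`, `ec50_uM`, `emax_fold`, `nc`) overriding the registry.
#' @return Object of class `"msm_ddi"`: per-donor table (`donor`, `aucr`,
#'   `pct_reduction`), summary (`aucr_mean`, `aucr_min`, `aucr_max`,
#'   `pct_reduction_mean`), and the per-donor per-enzyme detail.
#' @export
#' @examples
#' msm("rifampicin", "midazolam")
msm <- function(perpetrator, victim, donors = "all", readout = "mrna",
                imax_u = NULL, d = 1, multiplier = 10,
                emax_convention = "fold", fits = NULL) {
  if (is.character(perpetrator)) {
    perp_name <- perpetrator
    perp <- load_compound(perpetrator, readout = readout)
  } else {
    perp <- perpetrator
    perp_name <- perp$name
  }
  vic <- if (is.character(victim)) load_compound(victim) else victim
  if (is.null(vic$fm)) stop_input("victim '", vic$name, "' has no fm map")
  imax_u <- imax_u %||% perp$imax_u_uM
  if (is.null(imax_u)) stop_input("imax_u not supplied and not in fixture")

  if (is.null(fits)) {
    fits <- induction_registry(readout)
    fits <- fits[fits$compound == perp_name, , drop = FALSE]
  }
  donor_set <- if (identical(donors, "all")) sort(unique(fits$donor)) else donors
  enz <- setdiff(names(vic$fm), "other")
  mult_for <- function(e) {
    if (length(multiplier) == 1 && is.null(names(multiplier))) multiplier
    else multiplier[[e]] %||% 10
  }

  detail <- list(); per_donor <- list()
  for (dn in donor_set) {
    rows <- fits[fits$donor == dn & fits$enzyme %in% enz, , drop = FALSE]
    usable <- rows[!rows$nc, , drop = FALSE]
    if (nrow(usable) == 0) {
      per_donor[[length(per_donor) + 1]] <-
        data.frame(donor = dn, aucr = NA_real_, pct_reduction = NA_real_,
                   nc = TRUE)
      next
    }
    fc <- setNames(vapply(seq_len(nrow(usable)), function(i) {
      fold_cl_change(usable$emax_fold[i], usable$ec50_uM[i], imax_u,
                     d = d, multiplier = mult_for(usable$enzyme[i]),
                     emax_convention = emax_convention)
    }, numeric(1)), usable$enzyme)
    aucr <- suppressWarnings(net_auc_ratio(vic$fm, fc))
    per_donor[[length(per_donor) + 1]] <-
      data.frame(donor = dn, aucr = aucr, pct_reduction = 100 * (1 - aucr),
                 nc = FALSE)
    detail[[length(detail) + 1]] <-
      data.frame(donor = dn, enzyme = names(fc), fold_cl = unname(fc))
  }
  per_donor <- do.call(rbind, per_donor)
  ok <- per_donor[!per_donor$nc, , drop = FALSE]
  if (nrow(ok) == 0) {
    summary <- list(no_call = TRUE)
  } else {
    summary <- list(
      no_call = FALSE,
      aucr_mean = mean(ok$aucr), aucr_min = min(ok$aucr),
      aucr_max = max(ok$aucr),
      pct_reduction_mean = 100 * (1 - mean(ok$aucr))
    )
  }
  structure(
    list(perpetrator = perp_name, victim = vic$name, readout = readout,
         imax_u_uM = imax_u, d = d, multiplier = multiplier,
         fm = vic$fm, per_donor = per_donor,
         detail = if (length(detail)) do.call(rbind, detail) else NULL,
         summary = summary),
    class = "msm_ddi"
  )
}

#' @export
print.msm_ddi <- function(x, ...) {
  cat("Mechanistic static model: ", x$perpetrator, " -> ", x$victim,
      " (", x$readout, ", Imax,u ", format(x$imax_u_uM), " uM)\n", sep = "")
  cat("  fm: ", paste(sprintf("%s %.2f", names(x$fm), x$fm), collapse = ", "),
      "\n", sep = "")
  if (isTRUE(x$summary$no_call)) {
    cat("  no-call: no donor has estimable induction on the victim's enzymes\n")
    return(invisible(x))
  }
  pd <- x$per_donor
  for (i in seq_len(nrow(pd))) {
    if (pd$nc[i]) {
      cat(sprintf("  donor %s: no-call\n", pd$donor[i]))
    } else {
      cat(sprintf("  donor %s: AUCR %.3f (%.1f%% reduction)\n",
                  pd$donor[i], pd$aucr[i], pd$pct_reduction[i]))
    }
  }
  cat(sprintf("  mean AUCR %.3f [%.3f, %.3f]; mean reduction %.1f%%\n",
              x$summary$aucr_mean, x$summary$aucr_min, x$summary$aucr_max,
              x$summary$pct_reduction_mean))
  invisible(x)
}
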