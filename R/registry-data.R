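# Typed parameter registry: induction parameters measured in the all-human
# hepatocyte triculture (HTC) assay (three donors, mRNA and activity
# readouts), the clinical trial designs with victim fraction-metabolized
# maps, and literature base-PK fixtures for the simulator. Matching
# plain-text transcriptions of the assay tables are vendored under
# inst/extdata/tables/ and checked cell-for-cell against this registry.

.ind_row <- function(compound, enzyme, donor, ec50, emax) {
  data.frame(
    compound = compound, enzyme = enzyme, donor = donor,
    ec50_uM = ec50, emax_fold = emax,
    nc = is.na(ec50),
    stringsAsFactors = FALSE
  )
}

.ind_block <- function(enzyme, readout, ap, cb, ef, rf) {
  one <- function(compound, v) {
    do.call(rbind, lapply(1:3, function(d) {
      .ind_row(compound, enzyme, d, v[[d]][1], v[[d]][2])
    }))
  }
  out <- rbind(
    one("apalutamide", ap), one("carbamazepine", cb),
    one("efavirenz", ef), one("rifampicin", rf)
  )
  out$readout <- readout
  out
}

NC <- c(NA_real_, NA_real_)

#' Induction parameter registry (EC50, Emax per donor)
#'
#' Sigmoidal induction parameters measured in the all-human hepatocyte
#' triculture system for four clinical inducers across three hepatocyte
#' donors. `EC50` is the nominal concentration (uM) eliciting half-maximal
#' induction and `Emax` the maximal fold induction relative to vehicle
#' (baseline 1). Cells below the 2-fold induction threshold are no-call
#' (`nc = TRUE`, parameters `NA`). The `mrna` readout covers CYP3A4, CYP2C8,
#' CYP2C9, CYP2C19 and CYP2B6; the `activity` readout covers CYP3A4, CYP2C9
#' and CYP2C19.
#'
#' @param readout `"mrna"` or `"activity"`.
#' @return A data frame with columns `compound`, `enzyme`, `donor`,
#'   `ec50_uM`, `emax_fold`, `nc`, `readout`.
#' @export
#' @examples
#' subset(induction_registry(), compound == "rifampicin" & enzyme == "CYP3A4")
induction_registry <- function(readout = c("mrna", "activity")) {
  readout <- match.arg(readout)
  if (readout == "mrna") {
    rbind(
      .ind_block("CYP3A4", "mrna",
        ap = list(c(0.690, 6.12), c(1.61, 20.8), c(1.08, 7.45)),
        cb = list(c(23.6, 4.09), c(61.2, 9.93), c(28.5, 3.53)),
        ef = list(c(2.61, 5.32), c(4.38, 11.3), c(3.04, 5.31)),
        rf = list(c(0.0655, 5.60), c(0.128, 13.4), c(0.0602, 4.87))
      ),
      .ind_block("CYP2C8", "mrna",
        ap = list(c(1.68, 8.36), c(1.22, 4.55), c(1.26, 7.20)),
        cb = list(c(35.6, 3.21), c(20.0, 2.26), c(40.2, 5.07)),
        ef = list(c(4.48, 5.22), c(1.97, 2.85), c(2.95, 5.11)),
        rf = list(c(0.504, 6.89), c(0.260, 4.51), c(0.307, 7.36))
      ),
      .ind_block("CYP2C9", "mrna",
        ap = list(c(0.794, 3.50), c(0.419, 3.63), c(0.474, 2.73)),
        cb = list(c(9.86, 2.44), NC, NC),
        ef = list(c(0.455, 2.46), NC, NC),
        rf = list(c(0.0876, 3.23), c(0.0784, 2.87), c(0.149, 2.57))
      ),
      .ind_block("CYP2C19", "mrna",
        ap = list(c(4.01, 8.42), c(5.22, 7.70), c(6.04, 14.6)),
        cb = list(c(124, 5.11), c(186, 4.48), c(182, 7.22)),
        ef = list(c(8.30, 4.79), NC, c(2.91, 3.56)),
        rf = list(c(1.64, 19.9), c(0.803, 8.45), c(1.47, 17.9))
      ),
      .ind_block("CYP2B6", "mrna",
        ap = list(c(4.44, 10.2), c(2.98, 6.71), c(2.96, 9.06)),
        cb = list(c(46.9, 5.74), c(41.9, 4.84), c(59.0, 6.93)),
        ef = list(c(2.76, 6.46), c(3.67, 6.61), c(4.01, 9.44)),
        rf = list(c(0.415, 6.71), c(0.53, 5.91), c(0.399, 8.44))
      )
    )
  } else {
    rbind(
      .ind_block("CYP3A4", "activity",
        ap = list(c(0.686, 2.96), c(0.709, 3.03), c(1.50, 10.6)),
        cb = list(c(6.40, 2.31), c(2.70, 3.38), c(17.8, 4.44)),
        ef = list(c(1.43, 5.07), c(0.259, 2.79), c(4.54, 16.3)),
        rf = list(c(0.0509, 2.84), c(0.0652, 3.45), c(0.0897, 7.74))
      ),
      .ind_block("CYP2C9", "activity",
        ap = list(c(13.1, 2.79), NC, c(23.7, 3.25)),
        cb = list(c(41.4, 2.52), NC, NC),
        ef = list(c(4.29, 2.40), NC, NC),
        rf = list(c(0.469, 2.44), NC, NC)
      ),
      .ind_block("CYP2C19", "activity",
        ap = list(c(0.455, 3.38), c(1.03, 3.62), c(0.865, 9.66)),
        cb = list(c(8.14, 2.48), c(2.05, 3.63), c(18, 4.54)),
        ef = list(c(0.946, 3.04), c(0.297, 3.52), c(2.48, 6.87)),
        rf = list(c(0.0438, 3.48), c(0.0816, 4.09), c(0.105, 9.32))
      )
    )
  }
}

#' Clinical DDI trial designs
#'
#' Dosing regimens of the rifampicin DDI studies used for simulation: daily
#' perpetrator doses followed by a single victim dose at a study-specific
#' time. `victim_offset_h` is the victim dose time in hours after the first
#' perpetrator dose (perpetrator doses at 0, 24, ... h); victims dosed
#' "after the perpetrator on day N" are placed 1 h after that day's dose,
#' and the glyburide/repaglinide designs place the victim 12.5 h after the
#' final perpetrator dose. Bupropion was taken on the morning of day 8 of
#' evening rifampicin dosing (12 h offset from the dosing grid). The
#' warfarin design uses weight-based dosing (1.5 mg/kg; a 70 kg subject is
#' assumed for the fixture) and ships as experimental.
#'
#' @return Data frame, one row per victim drug.
#' @export
trial_designs <- function() {
  data.frame(
    victim = c("midazolam", "alfentanil", "atorvastatin", "omeprazole",
               "pioglitazone", "tolbutamide", "glyburide", "bupropion",
               "repaglinide", "warfarin"),
    perpetrator = "rifampicin",
    perp_dose_mg = c(600, 600, 600, 450, 600, 600, 600, 600, 600, 600),
    perp_n_doses = c(5, 5, 5, 6, 6, 14, 5, 10, 10, 3),
    perp_interval_h = 24,
    victim_dose_mg = c(3, 4, 40, 20, 30, 500, 1.75, 150, 0.5, 105),
    victim_offset_h = c(97, 97, 97, 121, 97, 313, 108.5, 156, 228.5, 96),
    timing = c("after perpetrator on day 5", "after perpetrator on day 5",
               "after perpetrator on day 5", "after perpetrator on day 6",
               "after perpetrator on day 5", "after perpetrator on day 14",
               "12.5 h after final perpetrator dose",
               "on day 8 of evening perpetrator dosing",
               "12.5 h after final perpetrator dose",
               "on day 4 after perpetrator dosing"),
    stringsAsFactors = FALSE
  )
}

#' Victim fraction-metabolized (fm) map
#'
#' Fraction of each victim drug's clearance mediated by specific CYP
#' enzymes, as used in the clinical DDI designs. Qualified entries (">0.9",
#' ">=0.8") carry the stated bound in `fm_reported` and the point value
#' adopted by the packaged fixture in `fm`. Tolbutamide's remaining 0.15 is
#' attributed to "other" (uninduced) CYPs. The bupropion fixture adds a
#' minor CYP3A4 pathway (fm 0.10) from the in vitro metabolism literature
#' (Hesse et al. 2000); this entry is fixture-added, not part of the study
#' design table (`source = "fixture"`).
#'
#' @param victim optional victim name to filter on.
#' @return Data frame with columns `victim`, `enzyme`, `fm`, `fm_reported`,
#'   `source`.
#' @export
fm_registry <- function(victim = NULL) {
  fm <- rbind(
    data.frame(victim = "midazolam", enzyme = "CYP3A4", fm = 0.94,
               fm_reported = ">0.9", source = "design"),
    data.frame(victim = "alfentanil", enzyme = "CYP3A4", fm = 0.90,
               fm_reported = ">=0.8", source = "design"),
    data.frame(victim = "atorvastatin", enzyme = "CYP3A4", fm = 0.90,
               fm_reported = ">0.9", source = "design"),
    data.frame(victim = "omeprazole", enzyme = c("CYP2C19", "CYP3A4"),
               fm = c(0.68, 0.32), fm_reported = c("0.68", "0.32"),
               source = "design"),
    data.frame(victim = "pioglitazone", enzyme = c("CYP2C8", "CYP3A4"),
               fm = c(0.56, 0.37), fm_reported = c("0.56", "0.37"),
               source = "design"),
    data.frame(victim = "tolbutamide", enzyme = c("CYP2C9", "other"),
               fm = c(0.85, 0.15), fm_reported = c("0.85", "0.15"),
               source = "design"),
    data.frame(victim = "glyburide", enzyme = c("CYP3A4", "CYP2C9", "CYP2C8"),
               fm = c(0.53, 0.35, 0.12),
               fm_reported = c("0.53", "0.35", "0.12"), source = "design"),
    data.frame(victim = "bupropion", enzyme = c("CYP2B6", "CYP2C19", "CYP3A4"),
               fm = c(0.21, 0.18, 0.10),
               fm_reported = c("0.21", "0.18", "0.10"),
               source = c("design", "design", "fixture")),
    data.frame(victim = "repaglinide", enzyme = c("CYP3A4", "CYP2C8"),
               fm = c(0.74, 0.26), fm_reported = c("0.74", "0.26"),
               source = "design"),
    data.frame(victim = "warfarin", enzyme = c("CYP2C9", "CYP3A4", "CYP2B6"),
               fm = c(0.64, 0.05, 0.12),
               fm_reported = c("0.64", "0.05", "0.12"), source = "design")
  )
  if (!is.null(victim)) {
    keep <- fm$victim == victim
    if (!any(keep)) stop_input("no fm entries for victim '", victim, "'")
    fm <- fm[keep, , drop = FALSE]
  }
  rownames(fm) <- NULL
  fm
}

# Literature base-PK fixtures. These stand in for proprietary simulator
# compound files: a deliberately minimal one-compartment oral backbone per
# compound, with parameter values and citations from the primary clinical
# pharmacokinetics literature. Victim `cl_h` is systemic (hepatic) plasma
# clearance in L/h; `fg0` is the baseline fraction escaping gut-wall CYP3A4
# metabolism (1 = no gut extraction modelled); `gut_cyp3a4` marks victims
# whose first-pass gut extraction is CYP3A4-mediated and therefore
# inducible.
.base_pk <- function() {
  list(
    rifampicin = list(
      role = "perpetrator", mw = 822.94, ka = 1.15, v_L = 55, cl_L_h = 8,
      fu = 0.20, fa = 1, imax_u_uM = 2.0,
      lit_auc_tau_uMh = 86,
      citation = paste(
        "Acocella 1978 Clin Pharmacokinet 3:108 (600 mg oral: Cmax ~7-10",
        "ug/mL, AUC ~58-86 uM*h, t1/2 3-5 h); Regazzi 1992 (fu ~0.2);",
        "unbound Cmax ~2 uM at 600 mg qd")
    ),
    efavirenz = list(
      role = "perpetrator", mw = 315.67, ka = 0.4, v_L = 250, cl_L_h = 9,
      fu = 0.01, fa = 1, imax_u_uM = 0.13,
      lit_auc_tau_uMh = 184,
      citation = "Csajka 2003 Clin Pharmacol Ther 73:20 (600 mg qd steady state)"
    ),
    carbamazepine = list(
      role = "perpetrator", mw = 236.27, ka = 0.5, v_L = 98, cl_L_h = 3.7,
      fu = 0.25, fa = 1, imax_u_uM = 9.5,
      lit_auc_tau_uMh = 860,
      citation = "Bertilsson 1978 Clin Pharmacokinet 3:128 (autoinduced steady state)"
    ),
    apalutamide = list(
      role = "perpetrator", mw = 477.43, ka = 0.5, v_L = 276, cl_L_h = 1.3,
      fu = 0.04, fa = 1, imax_u_uM = 0.5,
      lit_auc_tau_uMh = 212,
      citation = "Erleada FDA clinical pharmacology review 2018 (240 mg qd steady state)"
    ),
    midazolam = list(
      role = "victim", mw = 325.77, ka = 3, v_L = 77, cl_L_h = 27,
      fu = 0.03, fg0 = 0.51, gut_cyp3a4 = TRUE,
      citation = paste(
        "Thummel 1996 Clin Pharmacol Ther 59:491 (CL ~25-30 L/h, Fg ~0.51);",
        "Smith 1981 (V ~1.1 L/kg)")
    ),
    alfentanil = list(
      role = "victim", mw = 416.52, ka = 2, v_L = 27, cl_L_h = 21,
      fu = 0.10, fg0 = 0.60, gut_cyp3a4 = TRUE,
      citation = paste(
        "Kharasch 2004 Clin Pharmacol Ther 76:452 (hepatic extraction ~0.24,",
        "oral F ~0.43 implying Fg ~0.6); Bower 1984 (V 0.4 L/kg, fu 0.1)")
    ),
    atorvastatin = list(
      role = "victim", mw = 558.64, ka = 1.5, v_L = 380, cl_L_h = 37,
      fu = 0.02, fg0 = 0.83, gut_cyp3a4 = TRUE,
      citation = paste(
        "Lennernas 2003 Clin Pharmacokinet 42:1141 (CL 625 mL/min, Vss 381 L);",
        "Gertz 2010 Drug Metab Dispos 38:1147 (predicted Fg ~0.83)")
    ),
    omeprazole = list(
      role = "victim", mw = 345.42, ka = 2, v_L = 20, cl_L_h = 30,
      fu = 0.05, fg0 = 1, gut_cyp3a4 = FALSE,
      citation = "Andersson 1990 Ther Drug Monit (CL ~500-600 mL/min, t1/2 ~1 h, V 0.3 L/kg)"
    ),
    pioglitazone = list(
      role = "victim", mw = 356.44, ka = 1, v_L = 17, cl_L_h = 2.3,
      fu = 0.01, fg0 = 1, gut_cyp3a4 = FALSE,
      citation = "Budde 2003 Br J Clin Pharmacol 55:368 (CL/F ~2-3 L/h, V 0.25 L/kg, fu <0.02)"
    ),
    tolbutamide = list(
      role = "victim", mw = 270.35, ka = 1, v_L = 9, cl_L_h = 0.85,
      fu = 0.07, fg0 = 1, gut_cyp3a4 = FALSE,
      citation = "Miners & Birkett 1998 Br J Clin Pharmacol 45:525 (CL ~0.8-1 L/h, t1/2 ~7 h)"
    ),
    glyburide = list(
      role = "victim", mw = 494.00, ka = 1.2, v_L = 13, cl_L_h = 2.2,
      fu = 0.01, fg0 = 0.93, gut_cyp3a4 = TRUE,
      citation = "Pearson 1985 Clin Pharmacokinet 10:100 (CL ~2-3 L/h, V ~0.2 L/kg, t1/2 ~4 h)"
    ),
    bupropion = list(
      role = "victim", mw = 239.74, ka = 1.5, v_L = 140, cl_L_h = 40,
      fu = 0.16, fg0 = 1, gut_cyp3a4 = FALSE,
      citation = "Lai 1983; Findlay 1981 (V ~2 L/kg, t1/2 ~12-21 h, fu ~0.16)"
    ),
    repaglinide = list(
      role = "victim", mw = 452.59, ka = 2, v_L = 31, cl_L_h = 33,
      fu = 0.015, fg0 = 0.95, gut_cyp3a4 = TRUE,
      citation = "Hatorp 2002 Clin Pharmacokinet 41:471 (CL ~33-38 L/h, t1/2 ~1 h)"
    ),
    warfarin = list(
      role = "victim", mw = 308.33, ka = 1, v_L = 10, cl_L_h = 0.2,
      fu = 0.01, fg0 = 1, gut_cyp3a4 = FALSE, experimental = TRUE,
      citation = paste(
        "Holford 1986 Clin Pharmacokinet 11:483 (racemic CL ~0.2 L/h, V 10 L);",
        "experimental: enantiomer-specific kinetics not modelled")
    )
  )
}

#' Full registry dump as fixture records
#'
#' Flattens every registered value (induction parameters per donor and
#' readout, trial-design fields, fm entries, base-PK parameters) into one
#' long table of typed fixture records with provenance: `"assay-mrna"` /
#' `"assay-activity"` for triculture measurements, `"clinical-design"` for
#' trial-design and fm values, and `"literature"` for base-PK fixtures
#' (these carry the citation string).
#'
#' @return Data frame with columns `compound`, `parameter`, `value`,
#'   `units`, `provenance`, `citation`.
#' @export
registry_dump <- function() {
  rows <- list()
  add <- function(compound, parameter, value, units, provenance, citation = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      compound = compound, parameter = parameter, value = value,
      units = units, provenance = provenance, citation = citation,
      stringsAsFactors = FALSE
    )
  }
  for (rd in c("mrna", "activity")) {
    tab <- induction_registry(rd)
    prov <- paste0("assay-", rd)
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      key <- paste0(r$enzyme, ".donor", r$donor, ".", rd)
      if (r$nc) {
        add(r$compound, paste0(key, ".nc"), 1, "flag", prov)
      } else {
        add(r$compound, paste0(key, ".ec50"), r$ec50_uM, "uM", prov)
        add(r$compound, paste0(key, ".emax"), r$emax_fold, "fold", prov)
      }
    }
  }
  td <- trial_designs()
  for (i in seq_len(nrow(td))) {
    r <- td[i, ]
    add(r$victim, "design.perp_dose", r$perp_dose_mg, "mg", "clinical-design")
    add(r$victim, "design.perp_n_doses", r$perp_n_doses, "doses", "clinical-design")
    add(r$victim, "design.victim_dose", r$victim_dose_mg, "mg", "clinical-design")
    add(r$victim, "design.victim_offset", r$victim_offset_h, "h", "clinical-design")
  }
  fm <- fm_registry()
  for (i in seq_len(nrow(fm))) {
    r <- fm[i, ]
    prov <- if (r$source == "design") "clinical-design" else "literature"
    add(r$victim, paste0("fm.", r$enzyme), r$fm, "fraction", prov,
        if (r$source == "fixture") "Hesse 2000 Br J Clin Pharmacol 49:72" else "")
  }
  pk <- .base_pk()
  for (nm in names(pk)) {
    p <- pk[[nm]]
    for (field in c("mw", "ka", "v_L", "cl_L_h", "fu", "fg0", "imax_u_uM")) {
      if (!is.null(p[[field]])) {
        units <- switch(field, mw = "g/mol", ka = "1/h", v_L = "L",
                        cl_L_h = "L/h", fu = "fraction", fg0 = "fraction",
                        imax_u_uM = "uM")
        add(nm, paste0("pk.", field), p[[field]], units, "literature", p$citation)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
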