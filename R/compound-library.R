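#' List compounds available in the packaged registry
#'
#' @return Data frame with compound names and roles.
#' @export
list_compounds <- function() {
  pk <- .base_pk()
  data.frame(
    compound = names(pk),
    role = vapply(pk, function(p) p$role, character(1)),
    experimental = vapply(pk, function(p) isTRUE(p$experimental), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Aggregate per-donor induction parameters
#'
#' Collapses the three-donor induction parameters of a perpetrator into the
#' per-enzyme blocks used by the simulator. No-call donors are excluded; an
#' enzyme is no-call overall when every donor is. The default `"geomean"`
#' aggregation takes geometric means of EC50 and Emax across non-no-call
#' donors; `"donor1"`/`"donor2"`/`"donor3"` select a single donor (for
#' donor-range runs).
#'
#' @param compound perpetrator name.
#' @param readout `"mrna"` (default) or `"activity"`.
#' @param donors `"geomean"`, `"donor1"`, `"donor2"` or `"donor3"`.
#' @return Named list (by enzyme) of lists with `ec50_uM`, `emax_fold`,
#'   `n_donors`; no-call enzymes are omitted.
#' @export
#' @examples
#' induction_blocks("rifampicin")$CYP3A4
induction_blocks <- function(compound, readout = "mrna", donors = "geomean") {
  tab <- induction_registry(readout)
  tab <- tab[tab$compound == compound, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop_input("no induction data for '", compound, "'; available: ",
               paste(unique(induction_registry(readout)$compound), collapse = ", "))
  }
  if (donors != "geomean") {
    d <- as.integer(sub("donor", "", donors))
    if (!d %in% 1:3) stop_input("donors must be 'geomean' or 'donor1'..'donor3'")
    tab <- tab[tab$donor == d, , drop = FALSE]
  }
  out <- list()
  for (enz in unique(tab$enzyme)) {
    sub <- tab[tab$enzyme == enz & !tab$nc, , drop = FALSE]
    if (nrow(sub) == 0) next
    out[[enz]] <- list(
      ec50_uM = exp(mean(log(sub$ec50_uM))),
      emax_fold = exp(mean(log(sub$emax_fold))),
      n_donors = nrow(sub)
    )
  }
  out
}

#' Load a compound model from the registry
#'
#' Builds a validated compound model: base PK plus, for perpetrators, the
#' per-enzyme induction blocks (aggregated across donors) and the unbound
#' maximal plasma concentration used by the static model; for victims, the
#' per-enzyme fraction-metabolized map and gut-extraction settings.
#'
#' @param name compound name (see [list_compounds()]).
#' @param readout induction readout for perpetrators, `"mrna"` or
#'   `"activity"`.
#' @param donors donor aggregation for perpetrators (see
#'   [induction_blocks()]).
#' @return An object of class `"compound_model"`: a list with `name`,
#'   `role`, `pk` (mw, ka, v_L, cl_L_h, fu, fa, fg0, gut_cyp3a4), and
#'   `induction`/`imax_u_uM` (perpetrators) or `fm` (victims, named numeric
#'   vector; the `"other"` entry denotes uninduced pathways).
#' @export
#' @examples
#' rif <- load_compound("rifampicin")
#' rif$induction$CYP3A4
#' load_compound("omeprazole")$fm
load_compound <- function(name, readout = "mrna", donors = "geomean") {
  pk <- .base_pk()
  if (!name %in% names(pk)) {
    stop_input("unknown compound '", name, "'; available: ",
               paste(names(pk), collapse = ", "))
  }
  p <- pk[[name]]
  model <- list(
    name = name,
    role = p$role,
    experimental = isTRUE(p$experimental),
    pk = list(
      mw = p$mw, ka = p$ka, v_L = p$v_L, cl_L_h = p$cl_L_h, fu = p$fu,
      fa = p$fa %||% 1, fg0 = p$fg0 %||% 1,
      gut_cyp3a4 = isTRUE(p$gut_cyp3a4)
    ),
    citation = p$citation
  )
  if (p$role == "perpetrator") {
    model$induction <- induction_blocks(name, readout = readout, donors = donors)
    model$imax_u_uM <- p$imax_u_uM
    model$lit_auc_tau_uMh <- p$lit_auc_tau_uMh
    model$readout <- readout
    model$donors <- donors
  } else {
    fm <- fm_registry(name)
    model$fm <- setNames(fm$fm, fm$enzyme)
  }
  class(model) <- "compound_model"
  rep <- validate_compound(model)
  if (nrow(rep) > 0) {
    stop_input("invalid compound model '", name, "': ",
               paste(rep$message, collapse = "; "))
  }
  model
}

#' Validate a compound model
#'
#' Checks the type invariants of a compound model: positivity of PK
#' parameters, fractions within (0, 1], fm entries in \[0, 1\] summing to at
#' most 1, and induction blocks with positive EC50 and Emax >= 1.
#'
#' @param model a `"compound_model"` object (or a bare list with the same
#'   fields).
#' @return Data frame of violations with columns `field` and `message`
#'   (zero rows when the model is valid).
#' @export
#' @examples
#' m <- load_compound("omeprazole")
#' validate_compound(m)            # clean
#' m$fm["CYP2C19"] <- 0.80
#' validate_compound(m)            # fm sum now exceeds 1
validate_compound <- function(model) {
  bad <- list()
  flag <- function(field, message) {
    bad[[length(bad) + 1]] <<- data.frame(field = field, message = message,
                                          stringsAsFactors = FALSE)
  }
  pk <- model$pk
  for (f in c("mw", "ka", "v_L", "cl_L_h")) {
    if (is.null(pk[[f]]) || !is.finite(pk[[f]]) || pk[[f]] <= 0) {
      flag(f, paste0("pk parameter '", f, "' must be positive"))
    }
  }
  for (f in c("fu", "fa", "fg0")) {
    v <- pk[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0 || v > 1) {
      flag(f, paste0("fraction '", f, "' must be in (0, 1]"))
    }
  }
  if (!is.null(model$fm)) {
    if (any(model$fm < 0 | model$fm > 1)) {
      flag("fm", "each fm must lie in [0, 1]")
    }
    if (sum(model$fm) > 1 + 1e-9) {
      flag("fm", sprintf("fm sum exceeds 1 (%.3f)", sum(model$fm)))
    }
  }
  if (!is.null(model$induction)) {
    for (enz in names(model$induction)) {
      blk <- model$induction[[enz]]
      if (!is.finite(blk$ec50_uM) || blk$ec50_uM <= 0) {
        flag(paste0("induction.", enz), "EC50 must be positive")
      }
      if (!is.finite(blk$emax_fold) || blk$emax_fold < 1) {
        flag(paste0("induction.", enz), "Emax (fold) must be >= 1")
      }
    }
  }
  if (length(bad) == 0) {
    data.frame(field = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Write / read a compound model as JSON
#'
#' Serializes the full compound model (PK, induction or fm blocks,
#' provenance) so that user-modified compound files can be round-tripped
#' through plain text.
#'
#' @param model a `"compound_model"`.
#' @param path file path.
#' @return `write_compound_json` returns `path` invisibly;
#'   `read_compound_json` returns the validated `"compound_model"`.
#' @export
write_compound_json <- function(model, path) {
  stopifnot(inherits(model, "compound_model"))
  x <- unclass(model)
  if (!is.null(x$fm)) x$fm <- as.list(x$fm)   # keep enzyme names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_compound_json
#' @export
read_compound_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.numeric(v)) as.numeric(v) else v
  x$pk <- lapply(x$pk, num)
  if (!is.null(x$fm)) x$fm <- vapply(x$fm, as.numeric, numeric(1))
  if (!is.null(x$induction)) {
    x$induction <- lapply(x$induction, function(b) {
      b <- lapply(as.list(b), num)
      if (!is.null(b$n_donors)) b$n_donors <- as.integer(b$n_donors)
      b
    })
  }
  class(x) <- "compound_model"
  rep <- validate_compound(x)
  if (nrow(rep) > 0) {
    stop_input("invalid compound file '", path, "': ",
               paste(rep$message, collapse = "; "))
  }
  x
}

#' @export
print.compound_model <- function(x, ...) {
  cat("<compound_model> ", x$name, " (", x$role,
      if (x$experimental) ", experimental" else "", ")\n", sep = "")
  pk <- x$pk
  cat(sprintf("  PK: MW %.1f g/mol, ka %.2f 1/h, V %.0f L, CL %.2f L/h, fu %.3f\n",
              pk$mw, pk$ka, pk$v_L, pk$cl_L_h, pk$fu))
  if (pk$gut_cyp3a4) {
    cat(sprintf("  gut CYP3A4 substrate, baseline Fg %.2f\n", pk$fg0))
  }
  if (!is.null(x$induction)) {
    cat("  induction blocks (", x$readout, ", ", x$donors, "):\n", sep = "")
    for (enz in names(x$induction)) {
      b <- x$induction[[enz]]
      cat(sprintf("    %-8s EC50 %.4g uM, Emax %.3g-fold (n=%d donors)\n",
                  enz, b$ec50_uM, b$emax_fold, b$n_donors))
    }
  }
  if (!is.null(x$fm)) {
    cat("  fm: ", paste(sprintf("%s %.2f", names(x$fm), x$fm), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Build a dosing regimen
#'
#' Describes a repeated-dose oral regimen (`type = "oral"`) or a constant
#' unbound-exposure regimen (`type = "constant"`, used for dynamic-static
#' equivalence analyses).
#'
#' @param dose_mg dose per administration, mg (oral regimens).
#' @param n_doses number of doses.
#' @param interval_h dosing interval, h.
#' @param start_h time of the first dose, h.
#' @param conc_u_uM constant unbound plasma concentration, uM (constant
#'   regimens).
#' @return A list of class `"regimen"`.
#' @export
#' @examples
#' regimen(600, n_doses = 5)               # 600 mg daily x 5
#' constant_regimen(2.0)                   # fixed 2 uM unbound exposure
regimen <- function(dose_mg, n_doses = 1, interval_h = 24, start_h = 0) {
  if (dose_mg < 0) stop_input("dose must be non-negative")
  if (n_doses < 1 || interval_h <= 0) stop_input("invalid regimen")
  structure(list(type = "oral", dose_mg = dose_mg, n_doses = n_doses,
                 interval_h = interval_h, start_h = start_h),
            class = "regimen")
}

#' @rdname regimen
#' @export
constant_regimen <- function(conc_u_uM) {
  if (conc_u_uM < 0) stop_input("concentration must be non-negative")
  structure(list(type = "constant", conc_u_uM = conc_u_uM), class = "regimen")
}

#' Retrieve a packaged DDI study design
#'
#' Returns the perpetrator regimen, victim dose and victim dose time for one
#' of the packaged clinical trial designs (see [trial_designs()]).
#'
#' @param victim victim drug name.
#' @return List with `perpetrator`, `victim`, `perp_regimen` (a
#'   `"regimen"`), `victim_dose_mg`, `victim_offset_h`.
#' @export
#' @examples
#' ddi_design("midazolam")
ddi_design <- function(victim) {
  td <- trial_designs()
  row <- td[td$victim == victim, , drop = FALSE]
  if (nrow(row) == 0) {
    stop_input("no packaged design for '", victim, "'; available: ",
               paste(td$victim, collapse = ", "))
  }
  list(
    perpetrator = row$perpetrator,
    victim = victim,
    perp_regimen = regimen(row$perp_dose_mg, row$perp_n_doses,
                           row$perp_interval_h),
    victim_dose_mg = row$victim_dose_mg,
    victim_offset_h = row$victim_offset_h
  )
}
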