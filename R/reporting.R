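# Reporting helpers: DDI classification bands and side-by-side comparison
# of the dynamic (PBPK), static (MSM) and clinically observed % AUC
# reductions per victim drug.

#' Classify an AUC ratio against the regulatory DDI bands
#'
#' AUC ratios within \[0.8, 1.25\] fall in the average-bioequivalence band
#' (`"bioequivalent"`); ratios within \[0.5, 2.0\] but outside the
#' bioequivalence band are `"non-significant"`; anything beyond is a
#' `"significant"` DDI. Band edges are closed on the inside.
#'
#' @param aucr numeric vector of AUC ratios (> 0).
#' @return Character vector of classifications.
#' @export
#' @examples
#' classify_band(c(1, 0.6, 0.13, 2.5))
classify_band <- function(aucr) {
  if (any(aucr <= 0)) stop_input("AUC ratios must be positive")
  ifelse(aucr >= 0.8 & aucr <= 1.25, "bioequivalent",
         ifelse(aucr >= 0.5 & aucr <= 2.0, "non-significant", "significant"))
}

#' Assemble a dynamic / static / observed comparison table
#'
#' Joins per-victim results of the dynamic simulator and the static model
#' with optional user-supplied clinically observed AUC ratios, computes
#' % AUC reductions (`100 (1 - AUCR)`), band classifications per method,
#' and -- when observations are present -- the fold error of the dynamic
#' prediction (`max(pred, obs)/min(pred, obs)`, always >= 1).
#'
#' Observed values must be supplied as AUC ratios (`aucr` column) or
#' percent reductions (`pct_reduction` column); any other layout is
#' rejected so the AUC convention is never guessed.
#'
#' @param outcomes list of `"ddi_outcome"` objects (one per victim).
#' @param msm_results optional list of `"msm_ddi"` objects.
#' @param observed optional data frame with `victim` plus `aucr` or
#'   `pct_reduction`.
#' @return Data frame of class `"ddi_comparison"`, one row per victim.
#' @export
build_comparison <- function(outcomes, msm_results = NULL, observed = NULL) {
  if (length(outcomes) == 0) stop_input("need at least one outcome")
  rows <- lapply(outcomes, function(o) {
    data.frame(victim = o$victim,
               fm = paste(sprintf("%s %.2f", names(o$fm), o$fm),
                          collapse = ", "),
               aucr_dynamic = o$aucr,
               pct_reduction_dynamic = o$pct_reduction,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$band_dynamic <- classify_band(tab$aucr_dynamic)

  tab$aucr_static <- NA_real_
  tab$pct_reduction_static <- NA_real_
  tab$band_static <- NA_character_
  if (!is.null(msm_results)) {
    for (m in msm_results) {
      i <- match(m$victim, tab$victim)
      if (is.na(i) || isTRUE(m$summary$no_call)) next
      tab$aucr_static[i] <- m$summary$aucr_mean
      tab$pct_reduction_static[i] <- m$summary$pct_reduction_mean
      tab$band_static[i] <- classify_band(m$summary$aucr_mean)
    }
  }

  tab$aucr_observed <- NA_real_
  tab$fold_error_dynamic <- NA_real_
  tab$band_observed <- NA_character_
  if (!is.null(observed)) {
    if (!"victim" %in% names(observed)) {
      stop_input("observed data must carry a 'victim' column")
    }
    if ("aucr" %in% names(observed)) {
      obs_aucr <- observed$aucr
    } else if ("pct_reduction" %in% names(observed)) {
      obs_aucr <- 1 - observed$pct_reduction / 100
    } else {
      stop_input("observed data must supply 'aucr' or 'pct_reduction' ",
                 "(AUC-ratio convention must be explicit)")
    }
    for (j in seq_len(nrow(observed))) {
      i <- match(observed$victim[j], tab$victim)
      if (is.na(i)) next
      tab$aucr_observed[i] <- obs_aucr[j]
      tab$band_observed[i] <- classify_band(obs_aucr[j])
      tab$fold_error_dynamic[i] <-
        max(tab$aucr_dynamic[i], obs_aucr[j]) /
        min(tab$aucr_dynamic[i], obs_aucr[j])
    }
  }
  class(tab) <- c("ddi_comparison", "data.frame")
  tab
}

#' @export
print.ddi_comparison <- function(x, ...) {
  cat("Induction DDI comparison (% AUC reduction; bands on the AUC ratio)\n")
  show <- data.frame(
    victim = x$victim,
    dynamic = sprintf("%.1f%% [%s]", x$pct_reduction_dynamic,
                      x$band_dynamic),
    static = ifelse(is.na(x$aucr_static), "-",
                    sprintf("%.1f%% [%s]", x$pct_reduction_static,
                            x$band_static)),
    observed = ifelse(is.na(x$aucr_observed), "-",
                      sprintf("%.1f%%", 100 * (1 - x$aucr_observed))),
    fold_error = ifelse(is.na(x$fold_error_dynamic), "-",
                        sprintf("%.2f", x$fold_error_dynamic))
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' AUC-ratio dot plot with regulatory bands
#'
#' Plots dynamic, static and observed AUC ratios per victim on a log scale
#' with the 0.8-1.25 bioequivalence band (dashed) and the 0.5-2.0
#' no-significant-DDI band (dotted).
#'
#' @param x a `"ddi_comparison"`.
#' @param ... further graphical arguments.
#' @export
plot.ddi_comparison <- function(x, ...) {
  n <- nrow(x)
  ylim <- range(c(x$aucr_dynamic, x$aucr_static, x$aucr_observed, 0.8, 1.25),
                na.rm = TRUE)
  plot(seq_len(n), x$aucr_dynamic, log = "y", pch = 16, col = "forestgreen",
       xaxt = "n", xlab = "", ylab = "AUC ratio", ylim = ylim, ...)
  axis(1, at = seq_len(n), labels = x$victim, las = 2, cex.axis = 0.8)
  points(seq_len(n), x$aucr_static, pch = 16, col = "red3")
  points(seq_len(n), x$aucr_observed, pch = 16, col = "blue3")
  abline(h = c(0.8, 1.25), lty = 2, col = "red")
  abline(h = c(0.5, 2.0), lty = 3, col = "blue")
  legend("bottomleft", c("dynamic", "static", "observed"), pch = 16,
         col = c("forestgreen", "red3", "blue3"), bty = "n")
  invisible(x)
}

#' Load the packaged clinically observed AUC reductions
#'
#' Transcribed summary values (% AUC reduction of each victim when
#' co-administered with rifampicin) from the primary clinical DDI
#' literature, shipped for comparison plots and tests. Full observed PK
#' profiles are deliberately not vendored; supply digitized profiles as
#' user input where needed.
#'
#' @return Data frame with `victim`, `pct_reduction`, `citation`.
#' @export
observed_reductions <- function() {
  path <- system.file("extdata", "observed", "clinical_auc_reductions.csv",
                      package = "cypind")
  read.csv(path, stringsAsFactors = FALSE)
}
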