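# Sigmoidal concentration-response fitting for CYP induction fold-change
# data. Two model forms are supported, both anchored at the vehicle
# baseline (fold change 1 at zero concentration):
#
#   logistic_logC:  Y = 1 + (Emax - 1) / (1 + exp(-(x - log10 EC50) / s)),
#                   x = log10(C)   (GraphPad-style three-parameter sigmoid)
#   hill:           Y = 1 + (Emax - 1) * C^h / (EC50^h + C^h)
#
# The forms coincide when h = 1/(s * ln 10); the logistic slope s and the
# Hill exponent h are both reported under `slope`.

.curve_fun <- function(form) {
  switch(form,
    logistic_logC = function(conc, ec50, emax, slope) {
      1 + (emax - 1) / (1 + exp(-(log10(conc) - log10(ec50)) / slope))
    },
    hill = function(conc, ec50, emax, slope) {
      1 + (emax - 1) * conc^slope / (ec50^slope + conc^slope)
    },
    stop_input("unknown form '", form, "'")
  )
}

#' Check induction data against the assay-table invariants
#'
#' @param data data frame with at least `conc_uM` and `fold_change` columns
#'   (long format, one row per replicate measurement).
#' @param min_conc minimum number of distinct non-zero concentrations
#'   required for fitting.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_induction_data <- function(data, min_conc = 4) {
  if (!all(c("conc_uM", "fold_change") %in% names(data))) {
    stop_input("data must have columns conc_uM and fold_change")
  }
  if (any(!is.finite(data$conc_uM)) || any(data$conc_uM < 0)) {
    stop_input("concentrations must be finite and non-negative")
  }
  if (any(!is.finite(data$fold_change)) || any(data$fold_change <= 0)) {
    stop_input("fold-change values must be positive")
  }
  n_conc <- length(unique(data$conc_uM[data$conc_uM > 0]))
  if (n_conc < min_conc) {
    stop_input("need at least ", min_conc,
               " distinct non-zero concentrations, got ", n_conc)
  }
  invisible(TRUE)
}

.aggregate_response <- function(data) {
  data <- data[data$conc_uM > 0, , drop = FALSE]
  conc <- sort(unique(data$conc_uM))
  agg <- do.call(rbind, lapply(conc, function(cc) {
    y <- data$fold_change[data$conc_uM == cc]
    data.frame(conc_uM = cc, mean_fold = mean(y),
               sd_fold = if (length(y) > 1) sd(y) else NA_real_,
               n = length(y))
  }))
  rownames(agg) <- NULL
  agg
}

#' No-call rule for induction datasets
#'
#' A compound/enzyme/donor response is a no-call (NC) when the maximum over
#' concentrations of the mean fold change is below 2: induction parameters
#' are then not estimable with regulatory meaning. The threshold is strict
#' (a maximum mean fold of exactly 2 is *not* a no-call).
#'
#' @inheritParams validate_induction_data
#' @return `TRUE` if the dataset is a no-call.
#' @export
#' @examples
#' d <- data.frame(conc_uM = rep(c(0.1, 1, 10, 100), each = 2),
#'                 fold_change = rep(c(1.0, 1.2, 1.6, 1.9), each = 2))
#' apply_nc_rule(d)   # TRUE: tops out below 2-fold
apply_nc_rule <- function(data) {
  validate_induction_data(data)
  agg <- .aggregate_response(data)
  max(agg$mean_fold) < 2
}

#' Fit a sigmoidal induction concentration-response curve
#'
#' Estimates `EC50` (uM, reported on the linear scale), `Emax` (maximal fold
#' induction, baseline 1) and a slope parameter from fold-change data by
#' weighted nonlinear least squares on replicate means. The no-call rule
#' ([apply_nc_rule()]) is checked first; no parameters are estimated for
#' no-call datasets. When every concentration has `n >= 2` replicates, the
#' replicate scatter is pooled into a single relative SD (fold-change noise
#' is multiplicative, so SD scales with the mean) and means are weighted by
#' `1/(pooled CV x mean)^2`; without replicate scatter the fit is
#' unweighted. Duplicate concentrations are averaged before fitting.
#'
#' Optimizer initialization follows standard dose-response practice:
#' `Emax` starts at the maximum mean fold, `EC50` at the concentration
#' nearest the half-maximal response, slope at 1 (Hill) or `1/ln 10`
#' (logistic). Box bounds keep `Emax` in `[1, 2 x max mean fold]`, the
#' slope in `[0.3, 5]` (Hill exponent; the logistic slope bound is mapped
#' through `h = 1/(s ln 10)`), and `EC50` within
#' `[min tested conc / 10, max tested conc x 10]`; a fit that lands on the
#' EC50 bounds is flagged non-converged.
#'
#' @param data data frame with columns `conc_uM` and `fold_change` (long
#'   format; optional metadata columns `compound`, `enzyme`, `donor`,
#'   `readout` are carried along).
#' @param form `"logistic_logC"` (default) or `"hill"`; see Details above.
#' @return An object of class `"induction_fit"` with components `ec50_uM`,
#'   `emax_fold`, `slope`, `nc`, `converged`, `rss`, `form`, `agg` (the
#'   replicate-mean table), `meta`, and (when fitted) the underlying `nls`
#'   object in `fit`. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot`.
#' @export
#' @examples
#' d <- sim_induction_response(ec50 = 0.5, emax = 6, seed = 1, cv = 0)
#' f <- fit_induction(d, form = "hill")
#' coef(f)
#' predict(f, conc = c(0.1, 0.5, 5))
fit_induction <- function(data, form = c("logistic_logC", "hill")) {
  form <- match.arg(form)
  validate_induction_data(data)
  agg <- .aggregate_response(data)
  meta <- lapply(data[intersect(c("compound", "enzyme", "donor", "readout"),
                                names(data))], function(x) unique(x)[1])

  obj <- structure(
    list(ec50_uM = NA_real_, emax_fold = NA_real_, slope = NA_real_,
         nc = FALSE, converged = FALSE, rss = NA_real_, form = form,
         agg = agg, meta = meta, weighted = FALSE, fit = NULL),
    class = "induction_fit"
  )

  if (max(agg$mean_fold) < 2) {
    obj$nc <- TRUE
    return(obj)
  }

  max_fold <- max(agg$mean_fold)
  conc_rng <- range(agg$conc_uM)
  half <- 1 + (max_fold - 1) / 2
  m0 <- log10(agg$conc_uM[which.min(abs(agg$mean_fold - half))])

  # replicate SDs from n = 4 are too noisy to use point-wise; under the
  # multiplicative error model SD is proportional to the mean, so the
  # replicate scatter is pooled into one relative SD and the weights are
  # 1/(pooled_cv * mean)^2 (relative weighting). Without replicate scatter
  # the fit is unweighted.
  pooled_cv <- if (all(agg$n >= 2) && all(is.finite(agg$sd_fold))) {
    sqrt(mean((agg$sd_fold / agg$mean_fold)^2))
  } else 0
  use_w <- pooled_cv > 0
  w <- if (use_w) 1 / (pooled_cv * agg$mean_fold)^2 else rep(1, nrow(agg))
  obj$weighted <- use_w

  # internal slope parameter is always the Hill exponent; the logistic
  # slope of the printed model is 1/(h ln 10)
  h_lo <- if (form == "hill") 0.3 else 1 / (5 * log(10))
  h_hi <- if (form == "hill") 5 else 1 / (0.3 * log(10))
  fun <- .curve_fun("hill")
  start <- c(lec50 = m0, emax = max_fold, h = 1)
  lower <- c(log10(conc_rng[1] / 10), 1, h_lo)
  upper <- c(log10(conc_rng[2] * 10), 2 * max_fold, h_hi)
  start <- pmin(pmax(start, lower), upper)

  df <- data.frame(conc = agg$conc_uM, y = agg$mean_fold)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 + (emax - 1) * conc^h / ((10^lec50)^h + conc^h),
      data = df, start = as.list(start), lower = lower, upper = upper,
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(obj)

  cf <- coef(fit)
  ec50 <- 10^cf[["lec50"]]
  h <- cf[["h"]]
  obj$fit <- fit
  obj$ec50_uM <- ec50
  obj$emax_fold <- cf[["emax"]]
  obj$slope <- if (form == "hill") h else 1 / (h * log(10))
  obj$rss <- sum((agg$mean_fold - fun(agg$conc_uM, ec50, cf[["emax"]], h))^2)
  at_bound <- abs(cf[["lec50"]] - lower[1]) < 1e-8 ||
    abs(cf[["lec50"]] - upper[1]) < 1e-8
  obj$converged <- !at_bound
  obj
}

.fit_hill_exponent <- function(object) {
  if (object$form == "hill") object$slope else 1 / (object$slope * log(10))
}

#' @export
coef.induction_fit <- function(object, ...) {
  c(ec50_uM = object$ec50_uM, emax_fold = object$emax_fold,
    slope = object$slope)
}

#' @export
predict.induction_fit <- function(object, conc, ...) {
  if (object$nc || !isTRUE(object$converged)) {
    stop_input("no fitted parameters (no-call or non-converged fit)")
  }
  if (missing(conc)) conc <- object$agg$conc_uM
  h <- .fit_hill_exponent(object)
  ifelse(conc <= 0, 1,
         .curve_fun("hill")(conc, object$ec50_uM, object$emax_fold, h))
}

#' @export
fitted.induction_fit <- function(object, ...) predict(object)

#' @export
residuals.induction_fit <- function(object, ...) {
  object$agg$mean_fold - predict(object)
}

#' @export
print.induction_fit <- function(x, ...) {
  hdr <- paste(unlist(x$meta), collapse = " / ")
  if (nzchar(hdr)) cat(hdr, "\n")
  if (x$nc) {
    cat("No-call (maximum mean fold change ",
        sprintf("%.2f", max(x$agg$mean_fold)), " < 2)\n", sep = "")
  } else if (!x$converged) {
    cat("Fit did not converge (form ", x$form, ")\n", sep = "")
  } else {
    cat(sprintf("EC50 %.4g uM, Emax %.3g-fold, slope %.3g  [%s%s]\n",
                x$ec50_uM, x$emax_fold, x$slope, x$form,
                if (x$weighted) ", SD-weighted" else ""))
  }
  invisible(x)
}

#' @export
summary.induction_fit <- function(object, ...) {
  out <- list(
    meta = object$meta, form = object$form, nc = object$nc,
    converged = object$converged, coef = coef(object), rss = object$rss,
    agg = object$agg, weighted = object$weighted,
    se = if (!is.null(object$fit)) {
      tryCatch(coef(summary(object$fit))[, "Std. Error"],
               error = function(e) NULL)
    }
  )
  class(out) <- "summary.induction_fit"
  out
}

#' @export
print.summary.induction_fit <- function(x, ...) {
  hdr <- paste(unlist(x$meta), collapse = " / ")
  if (nzchar(hdr)) cat(hdr, "\n")
  cat("form:", x$form, if (x$weighted) "(SD-weighted)" else "(unweighted)",
      "\n")
  if (x$nc) {
    cat("No-call: maximum mean fold change below 2\n")
  } else if (!x$converged) {
    cat("Non-converged fit; parameters not reported\n")
  } else {
    print(x$coef)
    cat(sprintf("residual sum of squares: %.4g over %d concentrations\n",
                x$rss, nrow(x$agg)))
  }
  invisible(x)
}

#' @export
plot.induction_fit <- function(x, ...) {
  agg <- x$agg
  xr <- range(agg$conc_uM)
  plot(agg$conc_uM, agg$mean_fold, log = "x", pch = 16,
       xlab = "Concentration (uM)", ylab = "Fold change vs vehicle",
       ylim = c(0, max(agg$mean_fold + ifelse(is.na(agg$sd_fold), 0,
                                              agg$sd_fold)) * 1.1),
       ...)
  ok <- is.finite(agg$sd_fold)
  if (any(ok)) {
    segments(agg$conc_uM[ok], agg$mean_fold[ok] - agg$sd_fold[ok],
             agg$conc_uM[ok], agg$mean_fold[ok] + agg$sd_fold[ok])
  }
  abline(h = 2, lty = 3, col = "grey40")
  if (!x$nc && x$converged) {
    cc <- 10^seq(log10(xr[1] / 3), log10(xr[2] * 3), length.out = 200)
    lines(cc, predict(x, cc), col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Fit every compound x enzyme x donor x readout group in a long table
#'
#' Applies [fit_induction()] across the grouping columns of a long-format
#' induction table (the standard assay CSV layout:
#' `compound,enzyme,donor,readout,conc_uM,fold_change,replicate`).
#'
#' @param data long-format induction data.
#' @param form passed to [fit_induction()].
#' @return Data frame with one row per group: parameters, `nc`,
#'   `converged`, `rss`.
#' @export
fit_induction_all <- function(data, form = "logistic_logC") {
  for (col in c("compound", "enzyme", "donor", "readout")) {
    if (!col %in% names(data)) data[[col]] <- "all"
  }
  key <- interaction(data$compound, data$enzyme, data$donor, data$readout,
                     drop = TRUE)
  out <- lapply(split(data, key), function(d) {
    f <- fit_induction(d, form = form)
    data.frame(
      compound = d$compound[1], enzyme = d$enzyme[1], donor = d$donor[1],
      readout = d$readout[1], ec50_uM = f$ec50_uM, emax_fold = f$emax_fold,
      slope = f$slope, nc = f$nc, converged = f$converged, rss = f$rss,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize induction fits across donors
#'
#' Aggregates per-donor fits of one compound into per-enzyme summaries:
#' mean, minimum and maximum of EC50 and Emax across donors with estimable
#' parameters, and the count of no-call donors. All-no-call enzymes are
#' reported with `NA` statistics and `all_nc = TRUE`.
#'
#' @param fits either a data frame as returned by [fit_induction_all()] /
#'   [induction_registry()] (columns `enzyme`, `ec50_uM`, `emax_fold`,
#'   `nc`), or a list of `"induction_fit"` objects with `enzyme` metadata.
#' @return Data frame with one row per enzyme.
#' @export
#' @examples
#' rif <- subset(induction_registry(), compound == "rifampicin")
#' summarize_donors(rif)
summarize_donors <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f) {
      data.frame(enzyme = f$meta$enzyme %||% "all", ec50_uM = f$ec50_uM,
                 emax_fold = f$emax_fold, nc = f$nc,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(fits) == 0) stop_input("need at least one fit")
  out <- lapply(split(fits, fits$enzyme), function(d) {
    ok <- d[!d$nc & is.finite(d$ec50_uM), , drop = FALSE]
    if (nrow(ok) == 0) {
      data.frame(enzyme = d$enzyme[1], n = 0, nc_count = sum(d$nc),
                 all_nc = TRUE, ec50_mean = NA_real_, ec50_min = NA_real_,
                 ec50_max = NA_real_, emax_mean = NA_real_,
                 emax_min = NA_real_, emax_max = NA_real_)
    } else {
      data.frame(
        enzyme = d$enzyme[1], n = nrow(ok), nc_count = sum(d$nc),
        all_nc = FALSE,
        ec50_mean = mean(ok$ec50_uM), ec50_min = min(ok$ec50_uM),
        ec50_max = max(ok$ec50_uM), emax_mean = mean(ok$emax_fold),
        emax_min = min(ok$emax_fold), emax_max = max(ok$emax_fold)
      )
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write long-format induction CSV files
#'
#' The standard assay exchange layout:
#' `compound,enzyme,donor,readout,conc_uM,fold_change,replicate`.
#'
#' @param path file path.
#' @param data long-format induction data frame.
#' @return `read_induction_csv` returns the validated data frame.
#' @export
read_induction_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_induction_data(d, min_conc = 1)
  d
}

#' @rdname read_induction_csv
#' @export
write_induction_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
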