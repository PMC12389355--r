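#' Linear trapezoidal area under a concentration-time series
#'
#' @param time sampling times, h; strictly increasing, at least 2 points.
#' @param conc concentrations, uM; non-negative.
#' @return AUC in uM*h.
#' @export
#' @examples
#' trapezoid_auc(c(0, 96), c(1, 1))        # 96
#' trapezoid_auc(0:2, c(0, 2, 0))          # 2
trapezoid_auc <- function(time, conc) {
  if (length(time) < 2) stop_input("need at least 2 points for trapezoid AUC")
  if (length(time) != length(conc)) stop_input("time and conc lengths differ")
  if (any(diff(time) <= 0)) stop_input("times must be strictly increasing")
  if (any(conc < 0)) stop_input("concentrations must be non-negative")
  sum((conc[-length(conc)] + conc[-1]) * diff(time) / 2)
}

#' Dosing-interval stability metrics for an in vitro incubation
#'
#' Summarizes compound depletion over the incubation window from observed
#' medium concentrations: AUC over the window (linear trapezoid), the
#' average concentration (AUC / window), and the extent of loss relative to
#' the nominal dosing concentration, `1 - avg/nominal`, clipped at 0.
#'
#' @param time sampling times, h.
#' @param conc observed concentrations, uM.
#' @param nominal nominal dosing concentration, uM; must be positive.
#' @param window_h duration of the incubation window, h (default 96).
#' @return List of class `"stability_result"` with `auc_uMh`,
#'   `avg_concentration_uM`, `extent_of_loss`.
#' @export
#' @examples
#' stability_metrics(c(0, 96), c(5, 5), nominal = 5)    # no loss
#' stability_metrics(c(0, 96), c(2.5, 2.5), nominal = 5) # 50% loss
stability_metrics <- function(time, conc, nominal, window_h = 96) {
  if (nominal <= 0) stop_input("nominal concentration must be positive")
  if (window_h <= 0) stop_input("window must be positive")
  auc <- trapezoid_auc(time, conc)
  avg <- auc / window_h
  structure(
    list(
      auc_uMh = auc,
      avg_concentration_uM = avg,
      extent_of_loss = max(0, 1 - avg / nominal)
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("AUC %.3g uM*h; average %.3g uM; extent of loss %.1f%%\n",
              x$auc_uMh, x$avg_concentration_uM, 100 * x$extent_of_loss))
  invisible(x)
}
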