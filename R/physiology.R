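#' Physiological constants for the minimal DDI simulator
#'
#' Default system parameters used by [run_ddi()] and [victim_clearance()].
#' The values describe a single representative adult subject:
#' hepatic blood flow `q_h` of 90 L/h (~1.5 L/min) and a villous/enterocyte
#' blood flow `q_gut` of 18 L/h as used in minimal gut-extraction models.
#' Blood and plasma are treated as equivalent (blood:plasma ratio handled at
#' the compound level).
#'
#' @param q_h hepatic blood flow, L/h.
#' @param q_gut enterocyte (villous) blood flow, L/h.
#' @return A named list with components `q_h` and `q_gut`.
#' @export
#' @examples
#' default_physiology()
default_physiology <- function(q_h = 90, q_gut = 18) {
  if (q_h <= 0 || q_gut <= 0) stop_input("physiological flows must be positive")
  list(q_h = q_h, q_gut = q_gut)
}

#' Enzyme degradation rate constants (kdeg)
#'
#' First-order degradation rate constants (1/h) of the hepatic CYP pools,
#' plus the faster enterocyte CYP3A4 pool, taken from the enzyme-turnover
#' literature (Obach et al. 2007; Yang et al. 2008; Rowland Yeo et al. 2011).
#' These set the onset/offset timescale of induction: the liver CYP3A4
#' half-life of ~36 h means ~90% of steady-state induction is reached after
#' 5 days of daily perpetrator dosing.
#'
#' The values are editable configuration, not constants wired into the
#' simulator: pass a modified copy to [run_ddi()] via its `kdeg` argument.
#'
#' @return Named numeric vector of kdeg values in 1/h. The enterocyte pool is
#'   named `"CYP3A4_gut"`.
#' @export
#' @examples
#' kdeg_defaults()
#' log(2) / kdeg_defaults()   # enzyme half-lives, h
kdeg_defaults <- function() {
  c(
    CYP3A4 = 0.0193,
    CYP2C8 = 0.030,
    CYP2C9 = 0.0067,
    CYP2C19 = 0.026,
    CYP2B6 = 0.022,
    CYP3A4_gut = 0.030
  )
}
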