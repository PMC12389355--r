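# Synthetic-data generators emulating the study's data-generating
# processes: quadruplicate sigmoidal fold-change responses with
# multiplicative (log-normal) replicate noise, and noisy PK observations
# sampled from the simulator. All generators are pure functions of their
# arguments and a mandatory seed.

#' Simulate a quadruplicate induction concentration-response dataset
#'
#' Draws replicate fold-change values around a true sigmoid. Noise is
#' multiplicative log-normal by default (fold changes are strictly
#' positive), parameterized by the coefficient of variation and
#' mean-corrected so the expected value of each replicate equals the truth
#' curve; `cv = 0` returns the exact truth.
#'
#' @param ec50,emax,hill true curve parameters (uM; fold; Hill exponent).
#' @param conc tested concentrations, uM; default 8-point 3-fold dilution
#'   series from 30 uM, matching a typical induction assay plate design.
#' @param n replicates per concentration (default 4, quadruplicate).
#' @param cv replicate coefficient of variation (default 0.1).
#' @param seed mandatory RNG seed.
#' @param form truth curve form, `"hill"` (default) or `"logistic_logC"`
#'   (in which case `hill` is the logistic slope).
#' @param compound,enzyme,donor,readout metadata carried into the output.
#' @return Long-format data frame with columns `compound`, `enzyme`,
#'   `donor`, `readout`, `conc_uM`, `fold_change`, `replicate`.
#' @export
#' @examples
#' d <- sim_induction_response(ec50 = 0.0655, emax = 5.60, seed = 7)
#' fit_induction(d, form = "hill")
sim_induction_response <- function(ec50, emax, hill = 1,
                                   conc = 30 / 3^(7:0), n = 4, cv = 0.1,
                                   seed, form = "hill",
                                   compound = "synthetic", enzyme = "CYP",
                                   donor = 1, readout = "mrna") {
  if (missing(seed)) stop_input("seed is mandatory for stochastic generation")
  if (cv < 0) stop_input("cv must be >= 0")
  if (n < 1) stop_input("need at least 1 replicate")
  truth <- .curve_fun(form)(conc, ec50, emax, hill)
  set.seed(seed)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(rlnorm(length(conc) * n, meanlog = -sdlog^2 / 2,
                           sdlog = sdlog), nrow = length(conc))
  } else {
    noise <- matrix(1, nrow = length(conc), ncol = n)
  }
  data.frame(
    compound = compound, enzyme = enzyme, donor = donor, readout = readout,
    conc_uM = rep(conc, each = n),
    fold_change = as.vector(t(truth * noise)),
    replicate = rep(seq_len(n), times = length(conc)),
    stringsAsFactors = FALSE
  )
}

#' Simulate noisy PK observations of a perpetrator regimen
#'
#' Samples the closed-form multiple-dose profile of
#' [simulate_perpetrator()] at the requested times and applies residual
#' error: multiplicative log-normal (default, mean-corrected) or additive
#' Gaussian on the concentration scale.
#'
#' @param compound perpetrator name or `"compound_model"`.
#' @param reg a [regimen()].
#' @param times sampling times, h.
#' @param cv residual coefficient of variation (default 0: noiseless).
#' @param seed mandatory when `cv > 0`.
#' @param noise `"multiplicative"` or `"additive"` (additive SD =
#'   `cv * conc` at each point, truncated at 0).
#' @return Data frame with `time` and observed `conc` (total plasma uM).
#' @export
sim_pk_observations <- function(compound, reg, times, cv = 0, seed = NULL,
                                noise = c("multiplicative", "additive")) {
  noise <- match.arg(noise)
  cmp <- if (is.character(compound)) load_compound(compound) else compound
  frc <- .perp_forcings(cmp$pk, reg, default_physiology())
  conc <- frc$conc(times)
  if (cv > 0) {
    if (is.null(seed)) stop_input("seed is mandatory for stochastic generation")
    set.seed(seed)
    if (noise == "multiplicative") {
      sdlog <- sqrt(log(1 + cv^2))
      conc <- conc * rlnorm(length(conc), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
    } else {
      conc <- pmax(0, conc + rnorm(length(conc), sd = cv * conc))
    }
  }
  data.frame(time = times, conc = conc)
}
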