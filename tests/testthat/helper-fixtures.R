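# Shared fixtures built in code.

# noiseless quadruplicate Hill-curve dataset
hill_data <- function(ec50, emax, hill = 1, conc = 10^seq(-2, 1, length.out = 8),
                      n = 4) {
  sim_induction_response(ec50 = ec50, emax = emax, hill = hill, conc = conc,
                         n = n, cv = 0, seed = 1)
}

# minimal custom compound models for engine tests
test_perpetrator <- function(emax = 7.15, ec50 = 0.0796, enzyme = "CYP3A4",
                             fu = 0.2) {
  structure(list(
    name = "test_perp", role = "perpetrator", experimental = FALSE,
    pk = list(mw = 800, ka = 1, v_L = 50, cl_L_h = 8, fu = fu, fa = 1,
              fg0 = 1, gut_cyp3a4 = FALSE),
    induction = setNames(list(list(ec50_uM = ec50, emax_fold = emax,
                                   n_donors = 1)), enzyme),
    imax_u_uM = 2
  ), class = "compound_model")
}

test_victim <- function(fm = c(CYP3A4 = 0.8), cl = 0.85, fu = 0.07,
                        v = 9, ka = 1, fg0 = 1, gut = FALSE) {
  structure(list(
    name = "test_victim", role = "victim", experimental = FALSE,
    pk = list(mw = 300, ka = ka, v_L = v, cl_L_h = cl, fu = fu, fa = 1,
              fg0 = fg0, gut_cyp3a4 = gut),
    fm = fm
  ), class = "compound_model")
}
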