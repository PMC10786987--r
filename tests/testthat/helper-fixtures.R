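# Shared fixtures: canonical rate sets from the wild-type and truncated
# receptors, standard protocols, and small builders used across tests.

wt_2a_rates <- list(k_d = 0.47, k_r = 0.59, P_o = 19.1)   # GluN2A wild type
wt_2b_rates <- list(k_d = 0.52, k_r = 1.75, P_o = 9.2)    # GluN2B wild type
tr_2a_rates <- list(k_d = 2.50, k_r = 1.37, P_o = 5.8)    # GluN2A full truncation
tr_2b_rates <- list(k_d = 4.23, k_r = 4.57, P_o = 2.5)    # GluN2B juxtamembrane fs

params_for <- function(r, k_c = 200, k_b = 25) {
  kinetic_params(k_d = r$k_d, k_r = r$k_r,
                 k_o = ko_from_po(r$P_o, k_c), k_c = k_c, k_b = k_b)
}

control_protocol <- function(t_app = 5)
  glu_step_protocol(t_pre = 0.1, t_app = t_app, glutamate = 1000,
                    glycine = 30, mk801 = 0)

mk_protocol <- function(t_app = 10, mk801 = 1)
  glu_step_protocol(t_pre = 0.1, t_app = t_app, glutamate = 1000,
                    glycine = 30, mk801 = mk801)

# pure single-exponential decay trace (two-state desensitization limit)
two_state_trace <- function(k_d, k_r, gain = 500, t_end = NULL, fs = 5000) {
  tau <- 1 / (k_d + k_r)
  if (is.null(t_end)) t_end <- 8 * tau
  iss <- k_r / (k_d + k_r)
  t <- seq(0, t_end, by = 1 / fs)
  new_trace(t, -gain * (iss + (1 - iss) * exp(-t / tau)), fs)
}
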