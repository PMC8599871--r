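# Independent oracles, kept free of the package's own numerical paths.

# Direct transcription of the WLC interpolation formula (force from relative
# extension), written independently of wlc_force().
oracle_wlc_force <- function(x, L_p, kT) {
  (kT / L_p) * (-1 / 4 + 1 / (4 * (1 - x)^2) + x)
}

# Pure bisection inverse of the WLC formula; no Brent, no Newton.
oracle_bisect_rel_ext <- function(force, L_p, kT, iters = 200) {
  lo <- 0
  hi <- 1 - 1e-9
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_wlc_force(mid, L_p, kT) < force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

wt_config <- function() {
  bl_config(phase_B = phase_params(50, 0.34),
            phase_L = phase_params(3.8, 0.34 * 1.4),
            tether = tether_spec(4642))
}

dap_config <- function() {
  bl_config(phase_B = phase_params(50, 0.34),
            phase_L = phase_params(6.0, 0.476),
            tether = tether_spec(4642))
}
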