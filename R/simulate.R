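#' Generate a synthetic extension-versus-turns trace
#'
#' Emulates a magnetic-tweezers twist experiment at fixed force: a piecewise
#' extension-versus-turns curve built from the same model operations the
#' analysis pipeline later fits, plus seeded Gaussian axial tracking noise.
#' At forces at or above `bl_min_force` the three regimes are
#'
#' * B plectonemic (`n_t > n_b_max`): extension shortens linearly from the
#'   pure-B WLC extension at the plectonemic slope of the B phase;
#' * mixed BL (`n_t_max <= n_t <= n_b_max`): the two-phase extension of
#'   [mixed_extension()], linear in `n_t`;
#' * L plectonemic (`n_t < n_t_max`): extension shortens from the pure-L WLC
#'   extension at the plectonemic slope of the L phase.
#'
#' Segment junctions are continuous by construction.  Below `bl_min_force`
#' the molecule buckles instead of denaturing and negative turns are
#' generated as a symmetric (hat-curve) plectonemic branch.  After adding
#' noise, extensions are clipped at zero and flagged in the `clipped` column.
#'
#' @param force Applied force in pN (single positive value).
#' @param n_t_range Length-2 numeric `c(min, max)` of imposed turns.
#' @param config A [bl_config()].
#' @param plect A [plectoneme_params()].
#' @param noise_sd Gaussian axial noise standard deviation in nm
#'   (default 10, the typical axial tracking precision).
#' @param seed Optional integer seed; with a seed the trace is fully
#'   reproducible.
#' @param by Turn step between consecutive points (default 1).
#' @param trace_id,dna_label Identifier strings stored with the trace.
#' @param bl_min_force Force threshold in pN below which negative turns are
#'   plectonemic rather than BL (default 0.5).
#' @param regime Either `"auto"` (regimes decided by the force, the default)
#'   or `"BL"` to insist on mixed-phase generation, which is a configuration
#'   error below `bl_min_force`.
#' @return A data frame with columns `trace_id`, `dna_label`, `force_pN`,
#'   `n_turns`, `extension_nm`, `clipped`.
#' @examples
#' cfg <- bl_config(phase_L = phase_params(3.8, 0.34 * 1.4))
#' tr <- gen_twist_trace(2.3, c(-700, -100), cfg, noise_sd = 0)
#' @export
gen_twist_trace <- function(force, n_t_range, config,
                            plect = plectoneme_params(),
                            noise_sd = 10, seed = NULL, by = 1,
                            trace_id = "trace1", dna_label = "WT",
                            bl_min_force = 0.5, regime = c("auto", "BL")) {
  .check_config(config)
  regime <- match.arg(regime)
  if (!is.numeric(force) || length(force) != 1L || !is.finite(force) ||
      force <= 0) {
    stop("`force` must be a single positive value (pN)", call. = FALSE)
  }
  if (length(n_t_range) != 2L || n_t_range[1] >= n_t_range[2]) {
    stop("`n_t_range` must be c(min, max) with min < max", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0 nm", call. = FALSE)
  }
  if (regime == "BL" && force < bl_min_force) {
    stop("inconsistent regime request: mixed BL generation at F = ", force,
         " pN, below the plectonemic threshold of ", bl_min_force, " pN",
         call. = FALSE)
  }
  n_t <- seq(n_t_range[1], n_t_range[2], by = by)
  n_t_max <- turns_from_sigma(config$sigma_max, config$tether)
  nb <- config$n_b_max
  LeB <- wlc_extension(force, config$phase_B, config$tether, config$kT)
  slope_B <- plectoneme_slope(force, config$phase_B, config$kT, plect)
  ext <- numeric(length(n_t))
  if (force < bl_min_force) {
    # hat curve: buckling on both sides, symmetric about n_b_max
    ext <- LeB - slope_B * abs(n_t - nb)
  } else {
    LeL <- wlc_extension(force, config$phase_L, config$tether, config$kT)
    slope_L <- plectoneme_slope(force, config$phase_L, config$kT, plect)
    in_B <- n_t > nb
    in_L <- n_t < n_t_max
    in_BL <- !in_B & !in_L
    ext[in_B] <- LeB - slope_B * (n_t[in_B] - nb)
    if (any(in_BL)) ext[in_BL] <- mixed_extension(force, n_t[in_BL], config)
    ext[in_L] <- LeL + slope_L * (n_t[in_L] - n_t_max)
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) ext <- ext + stats::rnorm(length(ext), sd = noise_sd)
  clipped <- as.integer(ext < 0)
  ext[ext < 0] <- 0
  data.frame(trace_id = trace_id, dna_label = dna_label, force_pN = force,
             n_turns = n_t, extension_nm = ext, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic force-extension curve
#'
#' Produces a WLC force-extension table (the zero-turns characterisation of
#' a tether) with seeded Gaussian noise on the extensions, suitable as input
#' for [fit_wlc()].
#'
#' @param forces Applied forces in pN, all positive.
#' @param phase A [phase_params()].
#' @param tether A [tether_spec()].
#' @param kT Thermal energy in pN nm (default 4.28).
#' @param noise_sd Gaussian noise standard deviation in nm (default 10).
#' @param seed Optional integer seed.
#' @return A data frame with columns `force_pN`, `extension_nm`.
#' @examples
#' gen_force_extension(c(0.5, 1, 2, 4), phase_params(50, 0.34),
#'                     tether_spec(4642), noise_sd = 0)
#' @export
gen_force_extension <- function(forces, phase, tether, kT = 4.28,
                                noise_sd = 10, seed = NULL) {
  .check_phase(phase)
  .check_tether(tether)
  if (any(!is.finite(forces)) || any(forces <= 0)) {
    stop("all forces must be positive (pN)", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0 nm", call. = FALSE)
  }
  ext <- wlc_extension(forces, phase, tether, kT)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) ext <- ext + stats::rnorm(length(ext), sd = noise_sd)
  data.frame(force_pN = forces, extension_nm = ext)
}

#' Generate a family of twist traces across forces
#'
#' Convenience wrapper around [gen_twist_trace()] producing `reps` traces at
#' each force in `forces`, with per-trace seeds derived deterministically
#' from `seed`, bound into one data frame in the trace CSV schema.
#'
#' @param forces Vector of forces in pN.
#' @param reps Traces per force (default 3).
#' @param n_t_range Turn range per trace (default `c(-880, 60)`, spanning
#'   the L, BL and B regimes of a ~4.6 kbp tether).
#' @param config A [bl_config()].
#' @param plect A [plectoneme_params()].
#' @param noise_sd Axial noise sd in nm (default 10).
#' @param seed Integer seed for the family (default 1).
#' @param by Turn step (default 1).
#' @param dna_label Label stored with every trace.
#' @return A data frame of stacked traces.
#' @export
gen_trace_family <- function(forces, reps = 3, n_t_range = c(-880, 60),
                             config = bl_config(), plect = plectoneme_params(),
                             noise_sd = 10, seed = 1, by = 1,
                             dna_label = "WT") {
  out <- vector("list", length(forces) * reps)
  k <- 0L
  for (i in seq_along(forces)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      out[[k]] <- gen_twist_trace(
        forces[i], n_t_range, config, plect, noise_sd,
        seed = if (is.null(seed)) NULL else (seed * 1000L + k) %% 2147483647L,
        by = by,
        trace_id = sprintf("F%g_r%d", forces[i], r),
        dna_label = dna_label)
    }
  }
  do.call(rbind, out)
}
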