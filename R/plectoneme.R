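#' Plectoneme slope surrogate
#'
#' Simplified loop-balance estimate of the tether length sequestered per
#' imposed turn once the molecule is writhing plectonemically.  Balancing
#' bending energy against tension gives a superhelical gyre of radius
#' `sqrt(kT * L_p / (2 F))`; the length stored per turn is the circumference
#' of that loop scaled by a calibration factor `c`:
#'
#'   |dL_e/dn_t| = c * 2 * pi * sqrt(kT * L_p / (2 F))
#'
#' The surrogate reproduces the two qualitative facts full electrostatic
#' plectoneme models supply - the slope magnitude decreases with force and
#' increases with persistence length - but it is not a quantitative model:
#' it ignores electrostatics entirely (`ionic_strength` is accepted for
#' interface parity only) and should not be compared numerically against
#' measured plectonemic slopes.
#'
#' @param force Applied force(s) in pN; must be positive.
#' @param phase A [phase_params()] supplying the persistence length of the
#'   writhing phase.
#' @param kT Thermal energy in pN nm (default 4.28).
#' @param params A [plectoneme_params()] supplying the calibration factor.
#' @return Slope magnitude(s) in nm/turn.
#' @examples
#' plectoneme_slope(0.2, phase_params(50, 0.34))  # about 58 nm/turn
#' @export
plectoneme_slope <- function(force, phase, kT = 4.28,
                             params = plectoneme_params()) {
  .check_phase(phase)
  .check_kT(kT)
  if (!is_plectoneme_params(params)) {
    stop("`params` must be created with plectoneme_params()", call. = FALSE)
  }
  bad <- !is.finite(force) | force <= 0
  if (any(bad)) {
    stop("`force` must be positive (pN); offending value(s): ",
         paste(format(force[bad]), collapse = ", "), call. = FALSE)
  }
  params$efficiency * 2 * pi *
    sqrt(kT * phase$persistence_length / (2 * force))
}
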