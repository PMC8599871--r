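#' Fraction of L-form DNA at a given number of imposed turns
#'
#' In the mixed BL regime the fraction of the molecule converted to the
#' L-form grows linearly with the imposed (negative) turns:
#'
#'   chi = (n_t - n_b_max) / (n_t_max - n_b_max)
#'
#' where `n_b_max` is the buckling-transition edge of the regime (0 by
#' default) and `n_t_max = turns_from_sigma(sigma_max)` is the turn count at
#' which conversion is complete.
#'
#' @param n_t Imposed turns; must lie between `n_t_max` and `n_b_max`
#'   (inclusive).
#' @param config A [bl_config()].
#' @return The L-fraction chi in \[0, 1\], linear in `n_t`.
#' @examples
#' cfg <- bl_config()
#' l_fraction(-400, cfg)
#' @export
l_fraction <- function(n_t, config) {
  .check_config(config)
  n_t_max <- turns_from_sigma(config$sigma_max, config$tether)
  n_b_max <- config$n_b_max
  below <- n_t < n_t_max
  above <- n_t > n_b_max
  if (any(below | above)) {
    offender <- n_t[below | above][1]
    regime <- if (offender < n_t_max) "L-plectonemic" else "B-plectonemic"
    stop("n_t = ", format(offender), " lies outside the BL range [",
         format(n_t_max), ", ", format(n_b_max), "] (", regime, " regime)",
         call. = FALSE)
  }
  (n_t - n_b_max) / (n_t_max - n_b_max)
}

#' Extension of the mixed BL phase
#'
#' Extension of a tether partially converted to the L-form, modelled as two
#' worm-like chains in series: the convex combination of the pure-phase
#' extensions weighted by the L-fraction,
#' `L_eBL = L_eB * (1 - chi) + L_eL * chi`.
#'
#' @param force Applied force in pN (single positive value).
#' @param n_t Imposed turns (vectorised); must lie in the BL validity range
#'   of [l_fraction()].
#' @param config A [bl_config()].
#' @return Extension(s) in nm.
#' @examples
#' cfg <- bl_config()
#' mixed_extension(2.3, c(-600, -400, -200), cfg)
#' @export
mixed_extension <- function(force, n_t, config) {
  .check_config(config)
  chi <- l_fraction(n_t, config)
  LeB <- wlc_extension(force, config$phase_B, config$tether, config$kT)
  LeL <- wlc_extension(force, config$phase_L, config$tether, config$kT)
  LeB * (1 - chi) + LeL * chi
}

#' Slope of extension versus turns in the mixed BL regime
#'
#' The exact n_t-derivative of the mixed-phase extension.  Because the
#' L-fraction is linear in `n_t`, the derivative is constant in `n_t`:
#'
#'   dL_eBL/dn_t = (L_eL(F) - L_eB(F)) / (n_t_max - n_b_max)
#'
#' The slope is positive below the inversion force (where the shorter,
#' floppier L-form dominates the balance), zero at the inversion force, and
#' negative above it.
#'
#' @param force Applied force(s) in pN.
#' @param config A [bl_config()].
#' @return Slope(s) in nm/turn.
#' @examples
#' cfg <- bl_config()
#' bl_slope(c(1.1, 2.3), cfg)
#' @export
bl_slope <- function(force, config) {
  .check_config(config)
  n_t_max <- turns_from_sigma(config$sigma_max, config$tether)
  LeB <- wlc_extension(force, config$phase_B, config$tether, config$kT)
  LeL <- wlc_extension(force, config$phase_L, config$tether, config$kT)
  (LeL - LeB) / (n_t_max - config$n_b_max)
}

#' Inversion force of the two-phase model
#'
#' Solves for the force F* at which the pure-B and pure-L worm-like-chain
#' extensions are equal, so that the mixed-phase extension is independent of
#' the imposed turns and the BL slope vanishes.  Below F* the stiff B-form is
#' longer; above F* the longer contour of the L-form wins.  A crossing exists
#' when the L-form has a larger rise per bp and a smaller persistence length
#' than the B-form; under those preconditions it is unique and is found by
#' Brent bracketing on the force.
#'
#' @param config A [bl_config()].
#' @param bracket Force bracket in pN (default `c(0.01, 50)`).
#' @param tol Absolute force tolerance in pN (default 1e-10).
#' @return An object of class `"inversion_result"`: a list with `f_star`
#'   (pN), `bracket`, and `converged`.
#' @examples
#' cfg <- bl_config(phase_L = phase_params(3.8, 0.34 * 1.4))
#' inversion_force(cfg)
#' @export
inversion_force <- function(config, bracket = c(0.01, 50), tol = 1e-10) {
  .check_config(config)
  B <- config$phase_B
  L <- config$phase_L
  if (identical(B$persistence_length, L$persistence_length) &&
      identical(B$rise_per_bp, L$rise_per_bp)) {
    stop("degenerate model: B and L phases are identical, the extension ",
         "curves coincide at every force", call. = FALSE)
  }
  diff_ext <- function(f) {
    wlc_extension(f, B, config$tether, config$kT) -
      wlc_extension(f, L, config$tether, config$kT)
  }
  d_lo <- diff_ext(bracket[1])
  d_hi <- diff_ext(bracket[2])
  if (sign(d_lo) == sign(d_hi)) {
    stop("no inversion force in [", bracket[1], ", ", bracket[2], "] pN: ",
         "extension difference (B - L) is ", format(d_lo, digits = 4),
         " nm at the lower end and ", format(d_hi, digits = 4),
         " nm at the upper end (no sign change)", call. = FALSE)
  }
  root <- stats::uniroot(diff_ext, bracket, tol = tol,
                         f.lower = d_lo, f.upper = d_hi)
  structure(list(f_star = root$root,
                 bracket = bracket,
                 converged = abs(root$f.root) < 1e-6 ||
                   root$estim.prec <= 10 * tol),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("Inversion force F* = %.6g pN (bracket [%g, %g] pN, %s)\n",
              x$f_star, x$bracket[1], x$bracket[2],
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Infer the L-form persistence length from a measured inversion force
#'
#' Closed-form inverse of [inversion_force()] for the L-phase persistence
#' length at a fixed contour ratio.  At the inversion force the pure-phase
#' extensions are equal, so the relative extensions satisfy
#' `x_L = x_B / ratio_L0`; `x_B` is obtained by inverting the WLC relation
#' for the B phase at `f_star`, and the L persistence length follows from the
#' WLC formula evaluated at `x_L`:
#'
#'   L_pL = (kT / F*) * ( -1/4 + 1 / (4 (1 - x_L)^2) + x_L )
#'
#' @param f_star Measured inversion force in pN (> 0).
#' @param ratio_L0 Contour ratio L_0L / L_0B (> 1).
#' @param config A [bl_config()]; only its B phase and kT are used.
#' @return The L-form persistence length in nm.  Round-trips through
#'   [inversion_force()] to better than 1e-6 pN.
#' @examples
#' lpl_from_inversion(2.7, 1.4, bl_config())  # about 3.9 nm
#' lpl_from_inversion(1.6, 1.4, bl_config())  # about 5.9 nm
#' @export
lpl_from_inversion <- function(f_star, ratio_L0, config) {
  .check_config(config)
  if (!is.numeric(f_star) || length(f_star) != 1L || !is.finite(f_star) ||
      f_star <= 0) {
    stop("`f_star` must be a single positive force (pN); got ",
         deparse(f_star), call. = FALSE)
  }
  if (!is.numeric(ratio_L0) || length(ratio_L0) != 1L ||
      !is.finite(ratio_L0) || ratio_L0 <= 1) {
    stop("`ratio_L0` must be a single number > 1; got ", deparse(ratio_L0),
         call. = FALSE)
  }
  kT <- config$kT
  x_B <- .wlc_rel_ext(f_star, config$phase_B$persistence_length, kT)
  x_L <- x_B / ratio_L0
  if (x_L >= 1) {
    stop("infeasible geometry: x_B / ratio_L0 = ", format(x_L),
         " >= 1, the L phase cannot match the B extension", call. = FALSE)
  }
  (kT / f_star) * (-0.25 + 1 / (4 * (1 - x_L)^2) + x_L)
}

#' Map the (contour ratio, L-form persistence length) plane compatible with
#' a measured inversion force
#'
#' Evaluates the model inversion force on a Cartesian grid of contour ratios
#' `L_0L / L_0B` and L-form persistence lengths, and masks the points whose
#' predicted F* falls within `delta_f` of the measured value - the locus of
#' L-form parameters compatible with the measurement.  Grid points at which
#' the inversion-force preconditions fail (no crossing in the bracket) are
#' masked `FALSE` and counted in `n_failed`, never raised as errors, so the
#' map is total by construction.
#'
#' @param f_star Measured inversion force in pN.
#' @param delta_f Half-width of the compatibility band in pN (>= 0).
#' @param ratio_grid Ascending grid of contour ratios L_0L / L_0B.
#' @param lpl_grid Ascending grid of L-form persistence lengths in nm.
#' @param config A [bl_config()]; its B phase, tether and kT frame the model.
#' @return An object of class `"compatibility_region"`: `ratio_axis`,
#'   `lpl_axis`, `f_star_grid` (matrix, rows = ratios, cols = persistence
#'   lengths; NA where the model has no crossing), `mask` (logical matrix),
#'   `f_star`, `delta_f`, `n_failed`.
#' @examples
#' reg <- compatibility_region(2.7, 0.3, seq(1.2, 1.6, by = 0.1),
#'                             seq(2, 8, by = 1), bl_config())
#' @export
compatibility_region <- function(f_star, delta_f, ratio_grid, lpl_grid,
                                 config) {
  .check_config(config)
  if (!is.numeric(delta_f) || length(delta_f) != 1L || !is.finite(delta_f) ||
      delta_f < 0) {
    stop("`delta_f` must be a single non-negative force (pN)", call. = FALSE)
  }
  if (length(ratio_grid) < 1L || is.unsorted(ratio_grid, strictly = TRUE)) {
    stop("`ratio_grid` must be non-empty and strictly ascending",
         call. = FALSE)
  }
  if (length(lpl_grid) < 1L || is.unsorted(lpl_grid, strictly = TRUE)) {
    stop("`lpl_grid` must be non-empty and strictly ascending", call. = FALSE)
  }
  rise_B <- config$phase_B$rise_per_bp
  fgrid <- matrix(NA_real_, nrow = length(ratio_grid),
                  ncol = length(lpl_grid),
                  dimnames = list(format(ratio_grid), format(lpl_grid)))
  for (i in seq_along(ratio_grid)) {
    for (j in seq_along(lpl_grid)) {
      cfg_ij <- tryCatch(
        bl_config(phase_B = config$phase_B,
                  phase_L = phase_params(lpl_grid[j],
                                         ratio_grid[i] * rise_B),
                  tether = config$tether, kT = config$kT,
                  sigma_max = config$sigma_max, n_b_max = config$n_b_max),
        error = function(e) NULL)
      if (is.null(cfg_ij)) next
      fgrid[i, j] <- tryCatch(inversion_force(cfg_ij)$f_star,
                              error = function(e) NA_real_)
    }
  }
  mask <- !is.na(fgrid) & abs(fgrid - f_star) <= delta_f
  structure(list(ratio_axis = ratio_grid, lpl_axis = lpl_grid,
                 f_star_grid = fgrid, mask = mask,
                 f_star = f_star, delta_f = delta_f,
                 n_failed = sum(is.na(fgrid))),
            class = "compatibility_region")
}

#' @export
print.compatibility_region <- function(x, ...) {
  cat(sprintf(
    "Compatibility region for F* = %g +/- %g pN\n  grid %d ratios x %d L_pL values; %d compatible, %d infeasible\n",
    x$f_star, x$delta_f, length(x$ratio_axis), length(x$lpl_axis),
    sum(x$mask), x$n_failed))
  invisible(x)
}

#' @export
plot.compatibility_region <- function(x, ...) {
  graphics::image(x$ratio_axis, x$lpl_axis, 1 * x$mask,
                  col = c("grey92", "steelblue"),
                  xlab = "contour ratio L_0L / L_0B",
                  ylab = "L-form persistence length (nm)",
                  main = sprintf("F* = %g +/- %g pN", x$f_star, x$delta_f),
                  ...)
  invisible(x)
}

#' L-to-B contour ratio from the transition-completion threshold
#'
#' Geometric reconstruction of the contour-length increment of the L-form
#' from the supercoiling density at which the conversion completes.  All
#' helical DNA phases share the same backbone length, so the arc length of
#' backbone per base pair,
#' `s = sqrt(rise_B^2 + (2 pi r / bp_per_turn_B)^2)`, is conserved.  At the
#' completion threshold the residual twist per bp of the L-form is
#' `|1 + sigma_max| / bp_per_turn_B` turns (left-handed for sigma < -1), so
#' its rise follows from Pythagoras:
#' `rise_L = sqrt(s^2 - (2 pi r |1 + sigma_max| / bp_per_turn_B)^2)`.
#'
#' @param sigma_max Supercoiling threshold at which the L-form conversion is
#'   complete; must lie in (-2, 0\].
#' @param geometry A [helix_geometry()].
#' @return The contour ratio `rise_L / rise_B` (dimensionless); 1 exactly at
#'   `sigma_max = 0`.
#' @examples
#' contour_ratio_from_sigma(-1.8, helix_geometry())  # about 1.40
#' @export
contour_ratio_from_sigma <- function(sigma_max, geometry = helix_geometry()) {
  if (!is_helix_geometry(geometry)) {
    stop("`geometry` must be created with helix_geometry()", call. = FALSE)
  }
  if (!is.numeric(sigma_max) || length(sigma_max) != 1L ||
      !is.finite(sigma_max) || sigma_max <= -2 || sigma_max > 0) {
    stop("`sigma_max` must lie in (-2, 0]; got ", deparse(sigma_max),
         call. = FALSE)
  }
  twist_ratio <- abs(1 + sigma_max)   # L-form turns per bp / B-form turns per bp
  if (twist_ratio == 1) return(1)     # identical helix, exactly
  circ_B <- 2 * pi * geometry$radius / geometry$bp_per_turn_B
  # conserved arc length s^2 = rise_B^2 + circ_B^2; rise_L^2 = s^2 - (t*circ_B)^2
  under <- geometry$rise_B^2 + circ_B^2 * (1 - twist_ratio^2)
  if (under < 0) {
    stop("infeasible geometry: the circumferential backbone path (",
         format(circ_B * twist_ratio, digits = 4), " nm/bp) exceeds the ",
         "conserved arc length (",
         format(sqrt(geometry$rise_B^2 + circ_B^2), digits = 4), " nm/bp)",
         call. = FALSE)
  }
  sqrt(under) / geometry$rise_B
}
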