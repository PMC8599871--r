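#' Mechanical parameters of one helical DNA phase
#'
#' Bundles the two quantities that characterise the elasticity of a single
#' helical form (B or L) in the worm-like-chain description: the persistence
#' length and the axial rise per base pair.
#'
#' @param persistence_length Persistence length in nm (about 50 nm for B-DNA,
#'   a few nm for L-DNA).
#' @param rise_per_bp Axial rise per base pair in nm (0.34 nm for B-DNA,
#'   about 0.48 nm for L-DNA).
#' @return An object of class `"phase_params"`.
#' @examples
#' phase_params(50, 0.34)   # canonical B-form
#' phase_params(3, 0.48)    # L-form
#' @export
phase_params <- function(persistence_length, rise_per_bp) {
  if (!is.numeric(persistence_length) || length(persistence_length) != 1L ||
      !is.finite(persistence_length) || persistence_length <= 0) {
    stop("`persistence_length` must be a single positive number (nm); got ",
         deparse(persistence_length), call. = FALSE)
  }
  if (!is.numeric(rise_per_bp) || length(rise_per_bp) != 1L ||
      !is.finite(rise_per_bp) || rise_per_bp <= 0) {
    stop("`rise_per_bp` must be a single positive number (nm); got ",
         deparse(rise_per_bp), call. = FALSE)
  }
  structure(list(persistence_length = as.numeric(persistence_length),
                 rise_per_bp = as.numeric(rise_per_bp)),
            class = "phase_params")
}

#' @export
print.phase_params <- function(x, ...) {
  cat(sprintf("DNA phase: L_p = %g nm, rise = %g nm/bp\n",
              x$persistence_length, x$rise_per_bp))
  invisible(x)
}

is_phase_params <- function(x) inherits(x, "phase_params")

.check_phase <- function(phase, arg = "phase") {
  if (!is_phase_params(phase)) {
    stop("`", arg, "` must be created with phase_params()", call. = FALSE)
  }
  invisible(phase)
}

#' DNA tether specification
#'
#' Describes the torsionally constrained molecule held in the magnetic
#' tweezers: its length in base pairs and the relaxed helical repeat used to
#' convert imposed turns into supercoiling density.
#'
#' @param n_bp Number of base pairs of the construct (e.g. 4642 or 6258).
#' @param bp_per_turn Base pairs per helical turn of relaxed B-DNA
#'   (default 10.4).
#' @return An object of class `"tether_spec"`.
#' @examples
#' tether_spec(4642)
#' @export
tether_spec <- function(n_bp, bp_per_turn = 10.4) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) || n_bp < 1) {
    stop("`n_bp` must be a single number >= 1; got ", deparse(n_bp),
         call. = FALSE)
  }
  if (!is.numeric(bp_per_turn) || length(bp_per_turn) != 1L ||
      !is.finite(bp_per_turn) || bp_per_turn <= 0) {
    stop("`bp_per_turn` must be a single positive number; got ",
         deparse(bp_per_turn), call. = FALSE)
  }
  structure(list(n_bp = as.numeric(n_bp),
                 bp_per_turn = as.numeric(bp_per_turn)),
            class = "tether_spec")
}

#' @export
print.tether_spec <- function(x, ...) {
  cat(sprintf("DNA tether: %g bp, %g bp/turn (%.1f natural turns)\n",
              x$n_bp, x$bp_per_turn, x$n_bp / x$bp_per_turn))
  invisible(x)
}

is_tether_spec <- function(x) inherits(x, "tether_spec")

.check_tether <- function(tether, arg = "tether") {
  if (!is_tether_spec(tether)) {
    stop("`", arg, "` must be created with tether_spec()", call. = FALSE)
  }
  invisible(tether)
}

.check_kT <- function(kT) {
  if (!is.numeric(kT) || length(kT) != 1L || !is.finite(kT) || kT <= 0) {
    stop("`kT` must be a single positive energy in pN nm; got ", deparse(kT),
         call. = FALSE)
  }
  invisible(kT)
}

#' Two-phase B/L model configuration
#'
#' Assembles the full configuration of the two-phase worm-like-chain model:
#' the mechanical parameters of the pure B and pure L phases, the tether, the
#' thermal energy, and the topology thresholds that delimit the mixed BL
#' regime.  The supercoiling density `sigma_max` is the threshold at which the
#' conversion to the L-form is complete; `n_b_max` is the (small) number of
#' turns absorbed elastically before buckling, negligible against the total
#' twist imposed in the BL regime and therefore 0 by default.
#'
#' @param phase_B,phase_L [phase_params()] objects for the pure phases.  The
#'   L-form rise per bp must be at least the B-form rise.
#' @param tether A [tether_spec()].
#' @param kT Thermal energy in pN nm (default 4.28).
#' @param sigma_max Supercoiling density at which conversion to the L-form is
#'   complete; must be negative (default -1.8).
#' @param n_b_max Buckling-transition turns treated as the upper edge of the
#'   BL regime; |n_b_max| <= 30 (default 0).
#' @return An object of class `"bl_config"`.
#' @examples
#' bl_config()
#' @export
bl_config <- function(phase_B = phase_params(50, 0.34),
                      phase_L = phase_params(3, 0.48),
                      tether = tether_spec(4642),
                      kT = 4.28,
                      sigma_max = -1.8,
                      n_b_max = 0) {
  .check_phase(phase_B, "phase_B")
  .check_phase(phase_L, "phase_L")
  .check_tether(tether)
  .check_kT(kT)
  if (!is.numeric(sigma_max) || length(sigma_max) != 1L ||
      !is.finite(sigma_max) || sigma_max >= 0) {
    stop("`sigma_max` must be a single negative number; got ",
         deparse(sigma_max), call. = FALSE)
  }
  if (!is.numeric(n_b_max) || length(n_b_max) != 1L || !is.finite(n_b_max) ||
      abs(n_b_max) > 30) {
    stop("`n_b_max` must satisfy |n_b_max| <= 30 turns; got ",
         deparse(n_b_max), call. = FALSE)
  }
  if (phase_L$rise_per_bp < phase_B$rise_per_bp) {
    stop("L-form rise per bp (", phase_L$rise_per_bp,
         " nm) must be >= B-form rise per bp (", phase_B$rise_per_bp, " nm)",
         call. = FALSE)
  }
  structure(list(phase_B = phase_B, phase_L = phase_L, tether = tether,
                 kT = as.numeric(kT), sigma_max = as.numeric(sigma_max),
                 n_b_max = as.numeric(n_b_max)),
            class = "bl_config")
}

#' @export
print.bl_config <- function(x, ...) {
  cat("Two-phase B/L model configuration\n")
  cat(sprintf("  B phase : L_p = %g nm, rise = %g nm/bp\n",
              x$phase_B$persistence_length, x$phase_B$rise_per_bp))
  cat(sprintf("  L phase : L_p = %g nm, rise = %g nm/bp\n",
              x$phase_L$persistence_length, x$phase_L$rise_per_bp))
  cat(sprintf("  tether  : %g bp (%g bp/turn)\n",
              x$tether$n_bp, x$tether$bp_per_turn))
  cat(sprintf("  kT = %g pN nm, sigma_max = %g, n_b_max = %g turns\n",
              x$kT, x$sigma_max, x$n_b_max))
  invisible(x)
}

is_bl_config <- function(x) inherits(x, "bl_config")

.check_config <- function(config, arg = "config") {
  if (!is_bl_config(config)) {
    stop("`", arg, "` must be created with bl_config()", call. = FALSE)
  }
  invisible(config)
}

#' Helical backbone geometry of B-DNA
#'
#' Geometric description of the B-form double helix used by the
#' backbone-conservation derivation of the L-to-B contour ratio
#' ([contour_ratio_from_sigma()]): the radius at which the sugar-phosphate
#' backbone winds around the helical axis, the helical repeat, and the axial
#' rise per base pair.
#'
#' @param radius Backbone helix radius in nm (default 0.92, within the
#'   accepted 0.9-1.0 nm range for B-DNA).
#' @param bp_per_turn_B Base pairs per turn of B-DNA (default 10.4).
#' @param rise_B Axial rise per base pair of B-DNA in nm (default 0.34).
#' @return An object of class `"helix_geometry"`.
#' @export
helix_geometry <- function(radius = 0.92, bp_per_turn_B = 10.4,
                           rise_B = 0.34) {
  for (nm in c("radius", "bp_per_turn_B", "rise_B")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number; got ", deparse(v),
           call. = FALSE)
    }
  }
  structure(list(radius = as.numeric(radius),
                 bp_per_turn_B = as.numeric(bp_per_turn_B),
                 rise_B = as.numeric(rise_B)),
            class = "helix_geometry")
}

is_helix_geometry <- function(x) inherits(x, "helix_geometry")

#' Plectoneme slope surrogate parameters
#'
#' Parameters of the simplified loop-balance surrogate for the slope of
#' extension versus turns in a plectonemic regime (see [plectoneme_slope()]).
#' `ionic_strength` is accepted for interface parity with full electrostatic
#' plectoneme models but is not used by the surrogate.
#'
#' @param ionic_strength Monovalent salt concentration in mM (default 150).
#' @param efficiency Dimensionless calibration factor in (0, 1] scaling the
#'   ideal loop circumference down to an effective length sequestered per
#'   turn (default 0.4).
#' @return An object of class `"plectoneme_params"`.
#' @export
plectoneme_params <- function(ionic_strength = 150, efficiency = 0.4) {
  if (!is.numeric(ionic_strength) || length(ionic_strength) != 1L ||
      !is.finite(ionic_strength) || ionic_strength <= 0) {
    stop("`ionic_strength` must be a single positive number (mM); got ",
         deparse(ionic_strength), call. = FALSE)
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be a single number in (0, 1]; got ",
         deparse(efficiency), call. = FALSE)
  }
  structure(list(ionic_strength = as.numeric(ionic_strength),
                 efficiency = as.numeric(efficiency)),
            class = "plectoneme_params")
}

is_plectoneme_params <- function(x) inherits(x, "plectoneme_params")
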