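---
title: "Modelling the B-to-L transition of unwound DNA under tension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the B-to-L transition of unwound DNA under tension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bldna)
```

## The physical picture

A torsionally constrained DNA tether in magnetic tweezers is stretched at a
fixed force *F* while the magnets impose *n_t* turns.  Wound positively, or
unwound at low force, B-DNA buckles and stores turns in plectonemic loops,
so extension falls steeply with |n_t|.  Unwound at forces above roughly
1 pN, the molecule instead converts locally into a left-handed L-form.  The
conversion grows with unwinding until, at a supercoiling density of about
σ = -1.8 (σ = n_t/(N_b/10.4) for N_b base pairs), the whole tether is
L-form; beyond that the L-form writhes plectonemically in turn.  An
extension-versus-turns trace therefore shows three linear regimes — B, mixed
BL, and L — and the package models, simulates, and fits exactly that
structure.

## The two-phase model and its assumptions

Each pure phase is a classical worm-like chain.  With relative extension
`x = L_e/(N_b L_0)`:

$$F = \frac{k_BT}{L_p}\left(-\frac14 + \frac{1}{4(1-x)^2} + x\right)$$

`wlc_force()` evaluates this; `wlc_extension()` inverts it numerically.
The mixed phase is two WLCs in series.  Writing χ for the L-fraction,

$$L_{eBL} = L_{eB}(1-\chi) + L_{eL}\,\chi,\qquad
  \chi = \frac{n_t - n_{b,max}}{n_{t,max} - n_{b,max}},$$

with `n_t_max` the turn count at which conversion completes (derived from
`sigma_max` and the tether, about -803 turns for 4642 bp rather than a
hard-coded -800, so different tether lengths stay consistent under one
rule) and `n_b_max` the few turns absorbed elastically before buckling.

The model assumes: (i) the L-fraction is strictly linear in imposed turns;
(ii) both phases keep force-independent mechanical parameters; (iii) in the
BL regime no plectonemes form, which empirically holds at the forces where
the BL slope changes sign; (iv) torque is not modelled at all.  These are
the same assumptions under which the inversion-force analysis is meaningful.

Because the B-form is stiff but short per base pair and the L-form floppy
but long, the pure-phase extension curves cross at a single force, the
inversion force F\*, where `bl_slope()` vanishes:

```{r}
cfg <- bl_config(phase_B = phase_params(50, 0.34),
                 phase_L = phase_params(3.8, 0.34 * 1.4),
                 tether = tether_spec(4642))
inversion_force(cfg)
```

At F\* the mixed extension is independent of n_t, which is what makes F\*
cleanly measurable: it is the force at which the BL segment of a trace goes
flat.  `lpl_from_inversion()` is the closed-form inverse: at F\* the
relative extensions satisfy `x_L = x_B / (L_0L/L_0B)`, and the WLC formula
evaluated at `x_L` returns the L-form persistence length.  Both directions
round-trip to numerical tolerance, and `compatibility_region()` maps the
full `(L_0L/L_0B, L_pL)` locus compatible with a measured F\* ± ΔF when
neither parameter is fixed.

## Parameters, units, defaults

Units are fixed package-wide: nm, pN, pN·nm, turns; σ dimensionless.  No
unit inference is attempted.

| parameter | default | meaning |
|---|---|---|
| `L_pB`, `L_0B` | 50 nm, 0.34 nm | B-form persistence length and rise |
| `L_pL`, `L_0L` | 3 nm, 0.48 nm | L-form defaults (every value overridable) |
| `kT` | 4.28 pN·nm | thermal energy (T = 310 K) |
| `sigma_max` | -1.8 | completion threshold of the conversion |
| `n_b_max` | 0 turns | buckling edge of the BL regime |
| `bp_per_turn` | 10.4 | relaxed helical repeat |
| `noise_sd` | 10 nm | axial tracking noise of the generator |
| `radius` | 0.92 nm | backbone helix radius (geometry) |
| `efficiency` | 0.4 | plectoneme-surrogate calibration factor |

Design choices that were genuinely open:

* **kT = 4.28 pN·nm (310 K).**  The experiments this model describes do not
  fix a temperature; 310 K makes the inferred L-form persistence lengths
  land on the reported ≈3.8/6.0 nm values, and `kT` is an explicit argument
  everywhere, never a hidden constant.
* **`n_b_max = 0`.**  The buckling transition absorbs |n_b,max| ≈ 20–30
  turns, negligible against the ≈800 turns of the BL regime; it remains
  configurable up to ±30 for sensitivity checks.
* **Inversion of the B-phase WLC used `L_pB = 50 nm`** (the canonical
  value) rather than the tether-specific fitted 44.3/48.2 nm; `phase_B` is
  an argument, so either choice is one keystroke.
* **Geometry radius 0.92 nm.**  The backbone-conservation derivation of the
  contour ratio needs the radius at which the backbone winds around the
  axis; 0.92 nm sits inside the accepted 0.9–1.0 nm range for B-DNA and
  reproduces the ratio 1.40 at σ = -1.8.  It is a visible knob of
  `helix_geometry()`, never silent.  Note one property of this
  reconstruction: since the residual twist factor |1+σ| is below 1
  everywhere in (-2, 0), the ratio *increases* with radius, and the
  argument under the square root can never go negative in that domain.

## What the synthetic generator emulates — and what it does not

`gen_twist_trace()` builds a trace piecewise from the same model operations
the analysis later fits: B-plectonemic shortening at positive turns (slope
from the surrogate below), the mixed-phase extension in the BL range, and
L-plectonemic shortening beyond `n_t_max`; junctions are continuous by
construction.  Below 0.5 pN the B-form buckles on both sides, so negative
turns are generated as a symmetric hat-curve branch instead of a BL branch.
Between 0.5 and 1 pN the experimental behaviour is genuinely mixed; the
generator uses the B→L branch from 0.5 pN upward (`bl_min_force`,
configurable) since partial conversion is already detectable there, and
requesting BL generation below that threshold is an error.

Noise is i.i.d. Gaussian on extension with sd 10 nm — the typical axial
tracking precision of bead imaging — added after the deterministic curve,
then clipped at zero with a per-point `clipped` flag.  All randomness is a
pure function of (seed, configuration).

Deliberately **not** modelled: drift, bead-size variability, correlated
(Allan-type) noise, camera blur, torque signals, force-dependence of the
plectoneme slope beyond the surrogate's power law, partial Z-DNA content.
Consequently, passing recovery tests demonstrate the pipeline's
correctness *under the stated noise model*, not robustness to every
instrumental artefact of real traces.

The plectoneme slope itself uses a simplified loop-balance surrogate,
`c·2π·sqrt(kT·L_p/(2F))` with calibration factor c = 0.4 chosen so
low-force B slopes land in the tens of nm/turn typical of tweezers data.
It reproduces only the two qualitative facts the analysis needs — slope
decreasing in force, increasing in persistence length — and must not be
compared quantitatively with measured plectonemic slopes or with full
electrostatic energy-minimisation models; published measurements in the L
regime in fact fall well below such model predictions, which no surrogate
can arbitrate.

## The fitting pipeline

`fit_bl_transition()` chains three declared, deterministic steps:

1. **Segmentation** (`segment_trace()`): exhaustive search over ordered
   breakpoint pairs on the observed turn values; for each candidate, three
   independent least-squares lines via exact prefix-sum algebra; global SSE
   minimiser wins; ties go to the longest middle segment, then the smaller
   first breakpoint.  Candidates leaving fewer than 4 points per segment
   are skipped.  The innermost 10% of points adjacent to each breakpoint
   are excluded from the final slope fits (not from the search) to reduce
   junction-curvature bias; both the minimum segment size and the trim are
   configurable.  A trace whose three-segment fit barely improves on a
   single line is flagged `single_regime_suspected`.
2. **Slope collection** (`slope_vs_force()`): one BL slope per trace, or a
   fixed-window line fit when a published-figure-style window such as
   [-700, -100] turns is supplied; every estimate carries its turn window.
   B-regime slopes are also reported as absolute values, the plotting
   convention for plectonemic slopes.
3. **Inversion-force estimation** (`estimate_f_star()`): per-force mean
   slopes, linear interpolation across the sign change, and a bootstrap
   that resamples whole traces (not points, respecting within-trace
   correlation; 1999 replicates by default) for the confidence interval.
   `lpl_from_inversion()` then converts F\* — and its CI endpoints, since
   the map is monotone decreasing — into the L-form persistence length.

The slope-fitting windows and regime-boundary procedure are this package's
own declared algorithm; the published analyses this mirrors do not specify
theirs.

## Numerical choices

* WLC inversion: Brent bracketing on x ∈ [0, 1 - 1e-9] (`uniroot`, tol
  1e-12) plus three Newton polish steps; the formula is strictly monotone,
  so convergence is guaranteed and round trips hold to ~1e-12 relative.
* Inversion force: Brent on F ∈ [0.01, 50] pN, tolerance 1e-10 pN, after an
  explicit sign-change check that reports the extension differences at both
  bracket ends when no crossing exists; identical phases raise a degeneracy
  error instead of a spurious root.
* `fit_wlc()`: Levenberg–Marquardt (`minpack.lm::nls.lm`) on extension
  residuals, start `(max extension/0.95, 50 nm)`, standard errors from the
  Jacobian; fewer than 4 distinct forces, or a force span under 3×, is a
  precondition error, and non-convergence reports the best-so-far state.
* Negative or zero forces are rejected, not extrapolated: the model is only
  used under tension.
* Grid evaluation in `compatibility_region()` never fails: grid points
  violating the crossing preconditions are masked `FALSE` and counted, so
  parameter maps always render.

## Problem sizes

The shipped tests and the reproduction script run on deliberately modest
sizes chosen as realistic desk-scale analyses: traces of ~150–940 points
(turn steps of 1–5 over [-880, 60]), families of 9 forces × 3 traces,
50-seed recovery studies, and 100-seed WLC-fit studies.  The segmentation
search is O(n²) with O(1) per candidate, so a 240-point trace costs a few
milliseconds and a full 50-seed recovery study runs in well under a minute.

## Known limitations

* The two-phase balance fixes the contour ratio when inferring `L_pL`; if
  the ratio is misspecified the persistence length absorbs the error (the
  compatibility region shows exactly how).
* No torque, no twist-stretch coupling, no extensible-WLC correction, no
  overstretching: the model is for the 0.2–5 pN, negative-σ window.
* The L-regime plectonemic description is the weakest link — the surrogate
  is qualitative, and even full models overpredict measured L slopes — so
  L-segment slopes from the generator carry no quantitative meaning.
* A small Z-DNA fraction (persistence length two orders larger) cannot be
  excluded in real molecules and is not modelled.
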