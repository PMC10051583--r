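---
title: "Membrane topology of helical peptides from NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane topology of helical peptides from NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtopo)
```

# Scope and scientific background

`memtopo` determines how an amphipathic helical peptide sits in a lipid
membrane from three independent classes of NMR observables, using the
24-residue antimicrobial peptide SAAP-148
(`LKRVWKRVFKLLKRYWRQLKKPVR`) as its worked example:

1. **Oriented-sample ¹⁵N chemical shifts.** In mechanically aligned
   bilayers whose normal is parallel to the magnetic field, the amide
   ¹⁵N shift of a labeled residue depends on the orientation of its
   chemical shift anisotropy (CSA) tensor relative to the field, and
   therefore on the helix *tilt* (angle between the helix long axis and
   the membrane normal) and *pitch* (rotation about the helix axis).
   Inverting measured shifts over a tilt/pitch grid yields the
   compatible orientations.
2. **Solution-state secondary shifts and paramagnetic attenuation.**
   Chemical shift deviations (CSDs) from random-coil references detect
   the helix itself; the loss of cross-peak intensity caused by a
   paramagnetic agent buried in the micelle core reports which helix
   face is buried, with the ~3.6-residue periodicity of an α-helix.
3. **Deuterium order parameters of the lipids.** Quadrupolar splittings
   of a perdeuterated acyl chain give per-carbon order parameters
   S~CD~; their with/without-peptide ratios quantify how deeply the
   peptide perturbs the bilayer core.

# The forward model for oriented-sample ¹⁵N shifts

## Geometry

An ideal α-helix is generated by chain extension in internal
coordinates with uniform dihedrals (default φ = −65°, ψ = −45°,
ω = 180°) and fixed backbone bond lengths and angles (N–Cα 1.458 Å,
Cα–C′ 1.525 Å, C′–N 1.329 Å, C′=O 1.231 Å, N–H 1.02 Å; angles
N–Cα–C′ 111.0°, Cα–C′–N 117.2°, C′–N–Cα 121.7°). The amide proton is
placed in the peptide plane trans to the carbonyl oxygen, and a single
Cβ per residue is placed with standard L-amino-acid geometry (improper
dihedral N–C′–Cα–Cβ = +122.6°); the Cβ direction defines each
residue's azimuth about the helix axis and the pitch-angle zero
(residue 1). These constants live in one configuration block
(`memtopo_config()$helix`) so the model is reproducible bit-exactly.

The **helix axis** is obtained from the Cα trace. We deliberately do
not fit a straight line through the Cα positions: for a finite helix
with a fractional number of turns such a fit is biased by its ends by
up to about a degree, which is enough to destroy the exact per-residue
azimuth progression. Instead we use the fact that for an ideal helix
the second differences of consecutive Cα positions lie exactly in the
plane perpendicular to the axis; the axis is the total-least-squares
normal of that plane (smallest right singular vector of the
second-difference matrix). This estimator is exact for an ideal helix
and agrees with a screw-transform fit between consecutive backbone
triads to machine precision, which the test suite verifies
independently. With the defaults the helix has 3.76 residues per turn
(twist 95.76°/residue, rise 1.45 Å); the classic (−57°, −47°)
dihedrals give 3.62.

## CSA tensor and motional averaging

The amide ¹⁵N CSA tensor is expressed in each residue's amide frame:
σ₃₃ lies in the peptide plane at β = 17° from the N–H bond, rotated
towards the N–C′ bond (this puts σ₃₃ about 12.7° from the helix axis,
the standard amide geometry — the opposite rotation direction, ~27°
from the axis, is inconsistent with transmembrane helices resonating
near σ₃₃); σ₂₂ is perpendicular to the peptide plane. The principal
values default to (57, 81, 227) ppm. These are literature consensus
values for backbone amides: no experiment-specific values are
available, so they are exposed in `memtopo_config()$tensor` and every
topology result should be read as conditional on them.

For a rigid helix at orientation (τ, ρ) the observed shift is the
quadratic form **b**ᵀσ**b** of the field direction with the tensor.
Molecular motion is modeled as two independent Gaussian fluctuations,
following the dynamics established for surface-bound amphipathic
helices: *wobble* of the tilt angle (SD 10°) and *azimuthal*
fluctuation about the helix long axis (SD 18°). The observed shift is
the Gaussian-weighted mean of the *resonance values* (not of the
tensor), computed by two-dimensional Gauss–Hermite quadrature with 21
nodes per dimension. Quadrature was chosen over Monte-Carlo
integration because it is deterministic and converges fast: doubling
the node count changes results by < 10⁻³ ppm, and the suite checks
agreement with a 10⁶-draw Monte-Carlo oracle to better than 0.05 ppm.

## Restriction analysis

`scan_restraint()` forward-computes the averaged shift on a regular
tilt/pitch grid (default 1°; tilt ∈ [0°, 180°], pitch periodic in
[0°, 360°)) and marks orientations whose shift falls within the
measured value ± its half-width. Maps for several restraints are
intersected cell-wise, and `find_regions()` labels the connected
components (8-connectivity with pitch wrap-around, via a graph
component search) with at least `min_area` = 3 cells, sorted by area
and labeled I, II, …. Centroid pitch uses the circular mean. Regions
are classified *in-plane* (centroid tilt in [75°, 105°]),
*transmembrane* (within 30° of either pole) or *tilted*.

Because the static shift is invariant under reversal of the field
direction, every solution has a mirror image at
(180° − τ, ρ + 180°) that no oriented-sample measurement can
distinguish. The package reports all regions rather than collapsing
the degeneracy, since the two members correspond to physically
different peptide arrangements (N-terminus dipping into versus rising
out of the membrane).

With the measured SAAP-148 restraints (Leu11 80.0 ± 2.5 ppm, Leu12
70.0 ± 4.0 ppm) and all defaults, the analysis returns the two large
mirror-related in-plane solutions (centroid tilts 86.5° and 93.5°,
~160 deg² each) — the surface-parallel topology — plus a second,
smaller pair of grazing band crossings (~44 deg² each, also in-plane).
Whether this secondary pair appears depends sensitively on the
(experimentally undetermined) tensor principal values and on how much
line broadening is folded into the acceptance band; with the defaults
documented here it is present and reported. All solutions are
in-plane, and the forward-computed shifts at the main centroids
reproduce both measurements well within their errors (80.15 and
70.93 ppm).

# Solution-state analyses

**CSDs and helix calling.** Deviations are observed minus a static
embedded random-coil reference table (Wishart-style Hα/Cα consensus
values). A residue supports helix when ΔHα ≤ −0.1 ppm or
ΔCα ≥ +0.7 ppm, provided the two atoms do not disagree beyond their
thresholds in opposite directions; helix segments are maximal runs of
at least `min_run` = 4 supporting residues. The OR-with-agreement rule
and the run length are package choices: the experimental literature
requires "persistent" deviations without defining persistence, and
four residues is one full helical turn. Absolute CSDs computed against
the embedded table can differ by a few hundredths of a ppm from
condition-corrected predictors (pH, temperature, neighbor effects), so
the validation surface uses synthetic tables rather than re-deriving
published per-residue values.

**Amide dispersion.** `amide_dispersion()` is simply max − min of the
HN shifts; it is reported as a coarse structure indicator only.

**PRE percentage loss.** With B the cross-peak intensity without and C
with the paramagnetic agent, the retained fraction is A = C/B, the
loss is 100·(1 − A), and the error is propagated linearly,
ΔA = A(ΔB/B + ΔC/C), from the spectral-noise estimates. The linear
(worst-case) form is implemented deliberately; it upper-bounds the
quadrature-sum propagation, and the suite pins it to hand arithmetic
(B = 100, C = 50, ΔB = ΔC = 2 → 50% ± 3%). Negative losses are
reported as-is and flagged rather than clipped.

**Periodicity and faces.** `fit_periodicity()` fits
a + b·cos(2π(i − i₀)/P) with the period seeded from a grid over
[3.0, 4.5] residues (step 0.05; at each candidate the remaining
parameters are linear) and refined by BFGS. A fit is flagged aperiodic
when the amplitude is below twice the residual SD. `classify_faces()`
compares cationic (K/R) against remaining residues with a one-sided
Wilcoxon rank-sum test (cationic less attenuated).

# Deuterium order parameters

S~CD~ = (4/3)·Δν/QCC with the static quadrupole coupling constant
QCC = 167 kHz; the published form of this relation is typeset
ambiguously, and the implementation uses the standard de-Paking
relation for C–D bonds, which is the only dimensionally consistent
reading. CD₃ groups are converted identically (no 3-fold correction),
which is documented rather than hidden because assignments of terminal
methyl splittings vary between studies. `profile_ratio()` reports
per-carbon with/without-peptide ratios and the maximal percentage
reduction with its carbon position.

# Synthetic data: what it emulates and what it does not

All inputs can be generated by `gen_shift_table()`,
`gen_pre_profile()`, `gen_15n_restraints()` and `gen_scd_tables()`,
each seed-controlled and emitting its ground truth. The scenarios
reproduce the *statistical structure* each analysis assumes —

* coil/helix shift tables: reference ± Gaussian noise (SD 0.02 ppm Hα,
  0.1 ppm Cα), helix deviations ΔHα = −0.25, ΔCα = +2.0 ppm over the
  true span, optionally zeroed at a proline-like break; HN shifts get
  a 0.45-ppm helical modulation so structured tables disperse more;
* PRE profiles: loss = 50 + 30·cos(2π(i − 1)/3.6) %, cationic residues
  scaled by 0.7, Gaussian noise SD 3% (10% of the amplitude) — chosen
  to match the visual scatter of published per-residue attenuation
  plots;
* ¹⁵N restraints: forward-computed at a known orientation with noise
  SD of half the quoted error;
* S~CD~ profiles: plateau 0.20 (carbons 2–8) decaying to 0.05 at C16,
  with a linear perturbation ramp reaching 30% at the chain terminus.

They do *not* emulate peak overlap, assignment ambiguity, baseline or
phasing artifacts, conformational exchange broadening, or
condition-dependent random-coil corrections. Passing recovery tests on
these generators therefore demonstrates that the *inference chain* is
correct and well-conditioned at realistic noise levels, not that any
particular experimental spectrum would be reproduced.

# Numerical choices and edge cases

* Gauss–Hermite quadrature: 21 nodes/dimension by default; fewer nodes
  (11) are used in some tests where 0.1-ppm accuracy suffices.
* Grids: 1° default; a full two-restraint scan takes a few seconds.
  Property tests verify that region counts survive grid halving and
  that centroids move < 2°.
* Degenerate inputs: sequences shorter than 4 residues have no defined
  axis; splittings implying S~CD~ > 1 are rejected as unphysical;
  zero-amplitude profiles are flagged aperiodic instead of returning a
  meaningless period; S~CD~ ratios with a zero denominator are flagged
  undefined.
* Tie-breaks: solution regions of equal area (the mirror pairs) are
  ordered by the component enumeration; their forward shifts are
  identical by symmetry, so downstream results do not depend on the
  order.

# Known limitations

* The ¹⁵N tensor principal values and β are literature defaults, not
  measured for this peptide; the solution-region *count* (though not
  the in-plane classification) is sensitive to them, as discussed
  above.
* Motional averaging treats wobble and azimuthal fluctuation as
  independent one-dimensional Gaussians; correlated or anisotropic
  motions are out of scope.
* No dipolar couplings or separated-local-field (PISEMA-type)
  observables are simulated, and no line shapes are synthesized.
* The random-coil reference is static; no pH/temperature/sequence
  corrections are applied.

# A compact worked example

```{r example, eval = FALSE}
res <- run_topology_analysis(list(shift_restraint(11, 80.0, 2.5),
                                  shift_restraint(12, 70.0, 4.0)))
res$table

g <- gen_pre_profile(seed = 11)
fit_periodicity(pre_attenuation(g$data))$period

rat <- profile_ratio(build_profile(gen_scd_tables(seed = 1)$data))
rat$max_reduction_pct
```
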