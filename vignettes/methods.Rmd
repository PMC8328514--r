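---
title: "Methods: quantifying receptor oligomerization from SEC, densitometry and dimer geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying receptor oligomerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptorOligo)
```

This vignette documents the models behind `receptorOligo`, the parameters
that matter, the numerical choices made where the procedures are
conventionally interactive, and what the synthetic-data tests do and do
not establish about real data.

## The oligomer-level statistic

On size-exclusion chromatography a receptor population separates by
hydrodynamic size: high-molecular-weight (HMW) oligomer first, then
dimer, then monomer. The A280 trace is modelled, after baseline
correction, as a sum of Gaussians

$$A(v) \;=\; \sum_k a_k \exp\!\left(-\frac{(v-\mu_k)^2}{2\sigma_k^2}\right)
\;+\; c_0 + c_1\,(v-\bar v),$$

where each component's area $A_k = a_k \sigma_k \sqrt{2\pi}$ measures the
population of one species, and $c_0, c_1$ are small free residual-baseline
terms (below). The *oligomer level* of a species is its pooled area
divided by the monomer area — a dimensionless, monomer-equivalent
concentration ratio that is invariant to detector gain, injection amount
and uniform rescaling of the absorbance axis. Uncertainties are
propagated from the least-squares parameter covariance through the area
ratios by the delta method and reported as 95% half-widths; they describe
fit variance only, never biological replication.

Assumptions: peaks are adequately Gaussian (true for well-behaved SEC
peaks; strongly tailing peaks violate it), species elute in the size
order above, and the monomer peak area is strictly positive (a zero
monomer area raises an error rather than returning an arbitrary level).

### Baseline correction

The baseline method is a genuinely open choice, since integration is
conventionally done interactively. The default here is a straight line
anchored on the **median** signal of two flanking windows
(`flankFraction = 0.05` of the trace at each end) where no peaks elute.
The median was chosen over a low quantile deliberately: on a peak-free
flank the median estimates the baseline without bias, whereas an
aggressive low quantile sits systematically below it by a multiple of the
noise standard deviation, and that residual offset is absorbed
preferentially by the broadest fitted peak — in our synthetic benchmarks
it inflated the (broad, small) HMW area by tens of percent. An iterative
asymmetric-least-squares baseline (second-difference penalty,
`lambda = 1e5`, asymmetry `p = 0.01`) is available for curvature that a
line cannot follow.

### The free baseline terms in the fit

Interactive chromatography Gaussian fitting conventionally includes a
baseline term in the model itself. `fitPeaks()` therefore adds a free
constant and slope (`fitOffset = TRUE`) so that whatever small residual
the explicit baseline step leaves behind is absorbed by two dedicated
parameters instead of biasing the broad peaks. The species-area
covariance marginalizes these terms out (areas do not depend on them);
they are reported in the `offset` slot.

### Initialization, restarts, determinism

Centers start at local maxima of a Savitzky-Golay-smoothed trace
(quadratic, window about 1/20 of the trace), de-duplicated at 2% of the
elution range; amplitudes from the smoothed height; widths from the
half-width at half-maximum. On non-convergence the fit restarts up to 5
times with *deterministically* jittered centers (fixed multiples of the
initial width), so identical inputs always give identical fits — there is
no RNG anywhere in the fitting path. Manual elution windows and fixed
widths (`window = list(range=, sigma=)`) reproduce the interactive
practice of constraining fits on low-SNR traces; `nPeaks = NULL` adds
peaks while the BIC improves, capped at 6.

### Species assignment

The default ordinal rule maps peaks from the latest-eluting backwards:
last = monomer, second-last = dimer, everything earlier pools into HMW.
This reproduces both the 3-peak case and the convention that a broad HMW
feature may be fitted with two Gaussians, and gives 2-peak traces a
dimer/monomer reading. It cannot interpret a single peak, so single-peak
traces require the window policy (calibrated elution ranges per species);
under that policy a peak whose center falls in two windows is an error,
and one in no window is flagged unassigned rather than silently dropped.

## Lane densitometry

Blot lanes are 1-D intensity profiles; bands are integrated by the
trapezoidal rule over user-supplied windows (band selection is
interactive in practice; `proposeBandWindows()` offers an automatic
local-maxima proposal) and the dimer level is the same monomer-equivalent
ratio as in the SEC analysis. Background subtraction defaults to a
straight line through the median intensity of the lane ends — exact for
constant or linearly drifting backgrounds. The rolling-minimum
alternative is a morphological opening of a lightly smoothed profile; its
structuring element must be wider than the bands, and on tilted
backgrounds it can overestimate the background under a band by up to the
slope times the window half-width, which is why it is not the default.
Ladder calibration interpolates log molecular weight against position and
is used for labeling only.

## Dimer-interface geometry

All contact operations are cross-protomer only and purely geometric, with
the boundary conventions fixed and tested:

| operation | criterion | boundary |
|---|---|---|
| dimer detection | min residue-COM distance, 5 A | strict `<` |
| electrostatic contact | opposite charges, 5.0 A | inclusive `<=` |
| hydrogen bond | donor-acceptor 3.5 A and <= 20 deg off linear | inclusive |
| non-polar contact | non-polar sites, 5.0 A | inclusive `<=` |
| interacting helices | min inter-site distance, 7 A | strict `<` |

"Minimum centre-of-mass distance" is read as the minimum over
cross-protomer *residue* COM pairs: a whole-protomer COM distance can
never reach 5 A for intact receptors, so the residue-level minimum is the
only operative interpretation. The non-polar cutoff has no stated
literature value for this analysis; 5.0 A matches the electrostatic
criterion and is configurable. Hydrogen bonds require explicit hydrogen
positions (atomistic-style input) and are restricted to C-terminal
residues by default; coarse-grained coordinates raise an explicit
unsupported-input error rather than silently returning nothing. The
H-bond angle is the deviation of the donor-hydrogen-acceptor angle from
180 degrees, with the distance measured donor-to-acceptor. When a
periodic box is supplied, the orthorhombic minimum-image convention is
applied to every distance.

Helical tilt is the angle between the helix principal axis and the
membrane normal (the fixed z-axis by default; the instantaneous bilayer
normal is not available to a geometry-only analysis), folded into
[0, 90] degrees. Per-residue backbone positions are first averaged over a
sliding four-residue window — about one alpha-helical turn — because the
principal axis of a raw, finite helix is biased a degree or two away from
the geometric axis by the winding itself; the one-turn average removes
that bias and was what brought planted-tilt recovery inside 1 degree.

Interface classification: *none* iff there are no cross-protomer
contacts; *symmetric* when C-terminus-to-C-terminus contacts exist and
are at least a plurality against each one-sided C-terminus-to-other
tally; otherwise *asymmetric*. The rule is invariant under swapping the
protomer labels. Interfaces whose contacts involve no C-terminus at all
are called asymmetric by this rule; they do not occur in the scenarios
the package models, and the supporting tallies are always returned for
inspection.

Daura clustering computes pairwise RMSD on backbone sites of the whole
dimer after optimal least-squares superposition (a no-fit mode exists),
then iteratively extracts the frame with the most neighbours within the
1.5 A cutoff plus those neighbours as a cluster. Ties in neighbour count
break to the lowest frame index; clusters are ordered by decreasing size,
then smallest member. Both choices make the result deterministic; the
representatives of distinct clusters are necessarily non-neighbours, so
re-clustering representatives yields singletons (tested). Frames from
multiple replicas can simply be pooled into one list.

Per-segment contact averaging counts, per frame, the *distinct residues*
of a segment participating in at least one contact (a residue on either
protomer counts once per frame) and averages over frames; counting
contact events instead is exposed via `mode = "events"`, since either
reading of "average number of residues" is defensible.

## Solution biophysics

Ionic strength is $I = \tfrac12 \sum_i c_i z_i^2$ under full dissociation,
with phosphates taken as drawn (H2PO4- monovalent, HPO4^2- divalent) and
no acid-base speciation. For 49 mM Na2HPO4 this gives 147 mM; one may
encounter 146 mM in tabulations (rounding or a slightly different
concentration), and the computed value is reported as computed. The three
reference buffers (0/300/800 mM NaCl + 4 mM NaH2PO4 + 49 mM Na2HPO4)
land on 151/451/951 mM, i.e. 0.15/0.45/0.95 M at two decimals.

The Debye length is
$\kappa^{-1} = \sqrt{\varepsilon_0 \varepsilon_r(T) k_B T / (2 N_A e^2 I \cdot 10^3)}$
with $\varepsilon_r(T)$ from the Malmberg-Maryott pure-water polynomial
(a constant override is available). At 25 C this reproduces the familiar
$\kappa^{-1}(\mathrm{nm}) = 0.304/\sqrt{I}$ within 1%; at 0.34 M and 4 C
it gives 5.27 A, i.e. 5 A at the precision such statements are quoted.
`isScreened()` is a strict comparison of a distance against
$\kappa^{-1}$.

DSF melt curves are differentiated by central differences after a 5-point
moving average. Tm is the temperature of the global derivative maximum,
refined by a local quadratic fit over a +-2 C window (this averages out
grid discretization and point noise; the raw argmax alone jittered by up
to 0.75 C at the default noise). A minimum prominence
(`minProminence = 0.01` fluorescence-amplitudes per degree) suppresses
transitions on featureless curves; it is deliberately permissive and a
noise-only curve with no signal amplitude can still defeat it — callers
with pathological inputs should raise it. The aggregation quench is the
onset of a sustained fluorescence collapse after Tm: the first
temperature where the derivative stays below
`-quenchFraction * max(derivative)` (default fraction 0.25) for at least
`k = 3` consecutive points. Turbidity classification maps A450 through
two configurable thresholds (defaults 0.05 / 0.3 absorbance units) onto
soluble / slight / aggregated, monotone in A450 by construction. The
standard DSF ramp metadata (20 to 85 C at 0.5 C per 30 s) shapes the
generator's default grid but enters no computation.

## What the synthetic generators emulate — and what they do not

Every generator is a pure function of `(seed, parameters)`; the global
RNG stream is saved and restored, and each output carries a ground-truth
manifest sufficient to recompute the expected analysis result.

* `genChromatogram()`: Gaussian peaks over a linear baseline with
  additive i.i.d. Gaussian noise. Defaults are the wild-type-like study
  conditions: areas 0.20 / 1.14 / 1.00 (HMW / dimer / monomer), centers
  9.8 / 11.8 / 13.5 mL, SNR 50. **SNR is defined against the smallest
  planted peak amplitude**: the weakest peak is what limits
  deconvolution, and under a tallest-peak definition a small HMW peak
  would sit at a local SNR where no fitter recovers its area to a few
  percent — the weakest-peak definition makes "a trace at SNR 50"
  meaningful for every species.
* `genLaneProfile()`: two Gaussian bands (dimer at the smaller position)
  over a linear background; default areas 1.14 / 1.00.
* `genDimerConfiguration()`: two labeled point scaffolds — ideal helices
  (2.3 A radius, 1.5 A rise, 100 deg/residue; 18 residues by default so
  the principal axis is well conditioned) for TM regions, clustered loop
  sites, a confined random chain for the C-terminus — separated across an
  interface plane, with requested contact pairs planted at exact
  distances and angles. Planted pairs (and attached hydrogens) translate
  rigidly under per-frame noise, so planted predicates hold in every
  frame; all non-planted cross-protomer pairs stay beyond every cutoff
  plus a 1 A margin by construction.
* `genMeltCurve()`: a logistic melt (width 2 C) with optional exponential
  post-quench collapse (tau 1.5 C); `genTurbiditySeries()`: a step to an
  aggregated plateau above 1 M with a slight-aggregation window at
  0.25-0.5 M.

Passing the recovery suites therefore shows that the *algorithms* invert
their own generative models at realistic noise — it does not show that
real chromatograms are Gaussian, that real backgrounds are linear, that
real interfaces are made of point sites, or anything about detector
artifacts, blot saturation, peak tailing or lipid environments. The
deposited raw data of the underlying study are not bundled here; the
benchmark traces used in tests and in `scripts/acceptance.R` are
synthetic stand-ins generated at the printed compositions, and are
labelled as such.

## Problem sizes and runtime

The test and acceptance workloads are sized for a laptop-class single
core: 600-point chromatograms, 25-50 seeded replicates per recovery
suite, protomers of ~160 residues, frame series of up to 8 frames for
clustering. All are package choices and scale linearly (quadratically in
frames for the RMSD matrix) if increased.

## Known limitations

* Peak shapes are strictly Gaussian; tailing or fronting peaks bias the
  areas, and the only remedies offered are manual windows and widths.
* The window assignment policy needs calibrated elution ranges; the
  package does no column calibration against standards and no molar-mass
  estimation (SEC-MALS is out of scope).
* Contact analysis is geometry only — no energetics, no force field, no
  trajectory propagation, no coarse-grain/atomistic conversion.
* The dielectric model is pure water; high-salt or crowded solutions
  deviate, and no activity corrections beyond the Debye length are made.
* Interface classification is a contact-count plurality rule; sparse
  contact sets near a tie flip between calls legitimately, and the
  supporting tallies should be inspected in such cases.
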