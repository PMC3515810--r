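---
title: "Quantifying steroid-receptor translocation screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying steroid-receptor translocation screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translocscreen)
```

## The assay and its readout

Unliganded glucocorticoid and androgen receptors (GR, AR) reside mostly in
the cytoplasm; hormone binding drives them into the nucleus. A GFP-tagged
receptor therefore turns receptor activation into an imaging readout: in a
two-channel micrograph (DNA stain + GFP receptor), the fraction of GFP
signal inside the nucleus rises with ligand activity. The per-cell
statistic is the **N/C ratio**

$$ R = \frac{\bar I_{\mathrm{nuc}}}{\bar I_{\mathrm{cyt}}}, $$

the mean background-corrected GFP intensity over nucleus pixels divided by
the mean over cytoplasm pixels. Per well, the mean ratio over QC-passing
cells is normalized to the plate's vehicle (DMSO) controls, so vehicle
wells average exactly 1 and "2.0" means twice the basal translocation.
Environmental water samples with steroid-like activity shift this value
upward; a plate of samples is scored by a one-way ANOVA gate followed by
Dunnett's many-to-one comparison against the vehicle group.

`translocscreen` implements this chain end to end on synthetic data:
because the original screens' raw images are not deposited, a simulator
with exact per-cell ground truth stands in for the microscope, and every
downstream stage is validated against quantities the simulator knows
exactly.

## The synthetic-data generator

`simulate_field()` renders one two-channel field:

* **Geometry.** Cells are irregular ellipse-like nuclei nested in larger
  cell footprints. Outlines are circles modulated by low-order Fourier
  terms with amplitude `shape_irregularity` (default 0.08); the nuclear
  outline is constrained to lie strictly inside the cell outline, and
  footprints never overlap (rejection sampling of centres, with a density
  error when placement fails). This keeps the ground-truth label maps
  unambiguous so segmentation can be scored by intersection-over-union.
* **Dose response.** The nuclear fraction of each cell's total GFP
  follows a Hill curve
  $f(d) = f_{\min} + (f_{\max}-f_{\min})\,d^h/(\mathrm{EC}_{50}^h + d^h)$.
  The functional form is a package choice: the screen literature shows
  concentration-dependent, saturating translocation but no parametric
  model, and receptor-occupancy phenomenology is the standard default.
  `f(0) = f_min` and monotonicity hold for every valid parameter set and
  are asserted property-style in the tests.
* **Photometry.** A cell with total GFP $G$ and planted fraction $f$
  carries $fG$ spread uniformly over its $A_n$ nucleus pixels and
  $(1-f)G$ over its $A_c$ cytoplasm pixels, so the ground-truth ratio is
  $(f/A_n)\,/\,((1-f)/A_c)$ and, in a noise-free rendering, summed GFP
  over the cell equals $G$ exactly (conservation is a unit test).
* **Noise ladder.** Gaussian PSF blur, additive background, Poisson shot
  noise on expected counts, and Gaussian read noise are independently
  switchable, giving a path from analytically exact images
  (`noise_free()`) to realistic ones. "SNR $s$" in the tests means the
  dominant signal level is $s^2$ counts, so Poisson noise alone gives
  signal-to-noise $s$.

Defaults emulate the acquisition described for automated confocal
screening — 300 nm pixels after 2×2 binning, 16-bit range, 512×512
fields, roughly 50 adherent cells per field, 2 fields per well, 4
replicate wells per condition, ≥4 vehicle and ≥4 positive-control
(100 nM hormone) wells per plate. Default cell brightness puts the mean
in-cell GFP signal near 400 counts; at much lower exposures the cytoplasm
of strongly translocated cells falls to single-digit counts and its mean
becomes heavy-tailed, which destabilizes well-level statistics — a real
effect worth simulating, but not a sensible default.

What the generator does **not** emulate: optics-accurate PSFs,
autofluorescence, photobleaching, cell-cycle or morphology heterogeneity
beyond the stated jitter, mitotic/apoptotic figures, illumination
shading, or plate-edge effects. Passing tests therefore demonstrate that
the analysis chain is correct and well calibrated on images whose
difficulty is controlled — not that the segmenter would transfer
unchanged to arbitrary real screens.

## Segmentation

The commercial analysis SDK used in the original screens is not
described, so the package uses a standard, fully testable recipe
(EBImage primitives):

1. **Nuclei** (`segment_nuclei`): Gaussian smoothing (σ = 1 px) → global
   Otsu threshold on the DNA channel → hole filling → area gate
   (60–2000 px by default) → optional distance-transform watershed for
   touching nuclei. The watershed `tolerance` (default 2) is the minimum
   distance-map depth between objects before they are split; it guards
   against over-splitting irregular single nuclei. Border-touching nuclei
   are removed by default because truncated compartments bias the ratio.
   A blank image yields an empty labeling with a warning, not an error.
2. **Cells/cytoplasm** (`segment_cytoplasm`): each nucleus seeds a region
   grown over the GFP foreground by seeded propagation (geodesic nearest
   seed), hard-capped at `cyto_max_expand_px` (default 12 px) beyond the
   nuclear boundary. The foreground is Otsu on the **log-compressed** GFP
   channel: with a bright nuclear pool, linear Otsu separates nucleus
   from everything else and discards the dim cytoplasm entirely; log
   compression restores the background/cell bimodality. If the GFP
   channel has no usable foreground the cell degenerates to a one-pixel
   ring (flagged downstream). Contested pixels go to the nearest seed;
   the assignment is deterministic, and a permutation test asserts that
   relabeling seeds changes assignments only at exact-tie pixels.

## Measurement and QC

`measure_cells()` computes compartment means with a **boundary guard**
(default 2 px): the nuclear mean is taken over the nucleus eroded by the
guard, and the cytoplasmic mean over cytoplasm pixels at least the guard
away from both the nuclear and outer cell boundary. PSF blur mixes
signal across boundaries in both directions; without the guard the
measured ratio is biased low at high nuclear fractions (blurred nuclear
signal contaminates the perinuclear ring) and high at low fractions (the
dim halo outside the true cell edge drags the cytoplasmic mean down).
With the guard, median recovered ratios sit within ~3% of ground truth
across planted fractions 0.3–0.9 at shot-noise SNR 20, and exactly on it
in the noise-free limit. Background is the median intensity outside all
cells, subtracted from both means (a constant offset added to both
channels then cancels to machine precision, which is a test).

QC flags: `too_small`, `border`, `degenerate_cyto`, `saturated`
(bit-depth maximum reached), `low_signal`. Flagged cells are emitted but
excluded from aggregation; a cytoplasm of zero area yields an `NA` ratio,
never a division error.

## Plate statistics

Per well, kept cells from all fields are pooled and averaged (the mean
matches the assay's per-well value; a median option exists). Wells below
`min_cells_per_well` kept cells are excluded. Each well's mean ratio is
divided by the mean of vehicle-well means on the same plate, making the
vehicle group average exactly 1 by construction; plates are normalized
independently.

Hit calling follows the gate-then-compare convention: a classical one-way
fixed-effects ANOVA on per-well values must reach $P < 0.05$ before any
post-hoc comparison is made. Dunnett's many-to-one statistics are

$$ T_i = \frac{\bar x_i - \bar x_0}{s_p \sqrt{1/n_i + 1/n_0}},\qquad
   \mathrm{corr}(T_i, T_j) = \lambda_i \lambda_j,\quad
   \lambda_i = \sqrt{n_i/(n_i+n_0)}, $$

with $s_p^2$ the pooled one-way variance on $\nu = \sum n_i - (k+1)$
degrees of freedom. `dunnett_critical()` solves
$P(\max_i |T_i| \le d) = 1-\alpha$ for the equicorrelated multivariate
$t$ by double Gauss–Legendre quadrature over the shared control variate
$Z_0$ and the studentizing scale $S = \sqrt{\chi^2_\nu/\nu}$, which
factorizes the joint probability into a product of univariate normal
probabilities. Quadrature orders (128 nodes for $Z_0$ over $[-9, 9]$, 96
for $S$ over essentially the full support of its density) give absolute
accuracy well below the $10^{-4}$ requirement: at $k = 1$ the critical
value matches the Student-$t$ quantile to $\sim 10^{-9}$, and for
$k \in \{2,4,8\}$, $\nu \in \{6,12,30\}$ it agrees with an independent
$10^6$-draw Monte-Carlo max-$|T|$ oracle within its Monte-Carlo error.
Adjusted p-values are single-step, $p_i = P(\max_j |T_j| \ge |t_i|)$.
Tiers follow the screening convention — `p05` (adjusted $P<0.05$) and
`p01` (adjusted $P<0.01$) — and are assigned only when the gate passes;
otherwise every treatment is `negative` with `NA` (not evaluated)
adjusted p-values. The comparison is two-sided by default (suppression
is biologically possible) with an upper-tailed mode; tiers are invariant
to plate-constant rescaling, so normalized and raw units call identical
hits (asserted as a test). Statistics operate on normalized values by
default, and each plate is its own family — no cross-plate correction,
mirroring per-plate screen analysis.

`dose_response_summary()` reports per-dose normalized translocation with
SEM, the Spearman rank correlation of dose versus group mean, and the
lowest dose whose Dunnett-adjusted p-value (in the increasing direction)
falls below α — the detection-threshold dose.

## Statistical design of the validation suite

Two acceptance properties need care because they are themselves random:

* **Exact hit recovery vs. familywise error.** With 8 strong actives
  planted among 69 samples, single-step Dunnett at $\alpha = 0.05$
  controls the familywise error *per plate*; across 20 independent
  plates the expected number of plates with at least one false call is
  $20 \times 0.05 = 1$ ($P(\text{none}) = 0.95^{20} \approx 0.36$).
  Demanding zero false positives in all 20 plates would contradict the
  test's own guarantee. The suite therefore asserts what the design can
  deliver: every planted active recovered at the `p01` tier in every
  plate (power at 5 pooled-SD effects is effectively 1), and the count
  of plates with any false call within its binomial bound (≤3 of 20;
  $P[X>3] < 2\%$ under the nominal rate).
* **qPCR fold recovery.** At Cq noise 0.15 cycles, the noise enters a
  fold estimate through the target gene, the reference gene, and the
  vehicle normalizer; a single $n = 4$ experiment estimates a fold with
  ≈8% relative standard error, so "within 10%" holds only ~16% of the
  time on one draw. The suite instead bounds the **mean** absolute
  recovery error per planted fold across 60 independent simulated
  experiments (expected ≈8.5%, standard error <1%), which is the
  stable version of the same accuracy claim.

Problem sizes used by the tests and the acceptance script — 512×512
noise-free and SNR-10 fields for segmentation (10 each), three 50-cell
fields per planted fraction for ratio recovery, 1000 well-level null
plates for the familywise rate, 20 well-level plates for hit recovery,
and a 24-well image-based dose ladder — were chosen so each property is
measured with adequate Monte-Carlo precision while the whole suite stays
fast; large replication studies run on well-level summaries
(`simulate_well_values()`), since the quantity under test there is the
plate statistics, not the imaging chain, which the image-based pipeline
tests cover separately.

The dose-ladder validation keeps normalized translocation within the
assay's realistic ~1–3.5× range. This is deliberate: the classical
one-way layout pools variance across groups, and planting effects far
outside the observed dynamic range makes high-dose wells dominate the
pooled variance (multiplicative noise), masking real low-dose effects —
a heteroscedasticity caveat that applies to real screens as well.

## qPCR quantification

`simulate_qpcr()` generates Cq values from
$C_q = C_q^{\mathrm{base}} - \log(\text{quantity})/\log(1+E)$ plus
Gaussian cycle noise, with the reference gene fixed at fold 1, plus a
10-fold serial-dilution series per gene. `fit_standard_curve()` fits Cq
on $\log_{10}$(quantity) (≥3 points spanning ≥2 decades required) and
derives the efficiency $E = 10^{-1/\text{slope}} - 1$; perfect doubling
gives slope $-\log(10)/\log(2) = -3.3219$. `relative_expression()`
interpolates quantities from the curve (flagging Cq values outside the
calibrated range), normalizes each replicate to its reference-gene
quantity, and expresses conditions as fold change over the mean vehicle
value with mean ± SEM across replicates; a plate-wide Cq offset cancels
exactly. Significance versus vehicle reuses the Dunnett machinery on
log2 fold changes, one family per gene. Standard-curve interpolation is
the primary mode because it is the assay's stated method; per-condition
fold-change profiles may be nonmonotonic (rise-then-fall induction is
representable and recovered in rank order — no mechanistic inhibition
model is attempted).

## Numerical and degenerate-input conventions

* Critical-value search: bisection-bracketed `uniroot` to $10^{-6}$;
  quadrature accuracy verified against closed forms at $k=1$.
* Zero within-group variance with separated means: the ANOVA gate
  returns $F = \infty$, $p = 0$ with a `zero_variance` flag rather than
  failing.
* Tie-breaking: contested pixels in seeded growth go to the nearest seed
  deterministically; label maps are relabeled 1..K in first-use order.
* Determinism: every stochastic stage takes a seed; per-well/field seeds
  are derived from the master seed by integer mixing (kept below
  $2^{31}$), so identical configurations reproduce identical rasters,
  tables, and manifest checksums.
* Images round-trip as multi-page TIFF (page 1 DNA, page 2 GFP) at the
  acquisition bit depth; label maps as 16-bit TIFF (≤65535 objects).

## Known limitations

* The segmentation recipe is intensity-threshold-based; crowded or
  low-contrast real images would need tuned parameters or a learned
  segmenter, which is out of scope.
* The simulator's uniform compartment intensities make the guard-ring
  correction nearly exact; real cells have textured signal, so ratio
  accuracy there depends on texture scale relative to the guard.
* Heteroscedasticity across dose groups is not modeled in the ANOVA
  (classical pooled-variance layout, as in the original analysis); a
  variance-stabilizing log transform of ratios is a reasonable user
  choice but is not the default.
* Each plate is analyzed as its own family; multi-plate campaigns get no
  additional multiplicity correction.
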