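---
title: "EPID-based in vivo dosimetry: models, tolerances and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPID-based in vivo dosimetry: models, tolerances and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidivd)
```

## The problem

During intensity-modulated (IMRT) and volumetric-arc (VMAT) radiotherapy,
pre-treatment verification cannot catch errors that arise *during* the
treatment course: setup errors, unintended attenuators in the beam, output
drifts, or morphological changes of the patient (weight loss, tumour
shrinkage). In vivo dosimetry (IVD) with an electronic portal imaging device
(EPID) monitors every fraction using the transit signal behind the patient.
`epidivd` implements a complete per-beam IVD test of this kind and the
decision and aggregation logic around it, plus a forward simulator that
generates synthetic cohorts with known injected errors so every stage can be
validated against ground truth.

Each IVD test for one beam of one fraction consists of three indices:

* $R = D_{iso} / D_{tps}$ — the ratio of the isocentre dose reconstructed
  from the transit signal to the planned isocentre dose; in tolerance when
  $0.95 \le R \le 1.05$ (inclusive).
* $\gamma\%$ — the percentage of evaluated pixels with $\gamma < 1$ in a
  global 2D gamma comparison of the current portal image against the
  reference image of the first (reference) fraction; in tolerance when
  $\gamma\% \ge 90$.
* $\gamma_{mean}$ — the mean gamma over the evaluated pixels; in tolerance
  when $\gamma_{mean} \le 0.4$.

A *warning* is raised as soon as at least one index is out of tolerance.
The gamma criteria are site specific: $\Delta S\% = 3\%$, $\Delta d = 3$ mm
for head-and-neck, $5\%/5$ mm for breast, thorax, abdomen and pelvis — the
distance criterion deliberately equal to the maximum clinically accepted
setup displacement per site.

## The gamma engine

For each evaluated reference pixel $r$,

$$\gamma(r) = \min_{|d| \le R_s}
  \sqrt{\left(\frac{\Delta S(r, d)}{S_{tol}}\right)^2 +
        \left(\frac{|d|}{\Delta d}\right)^2},$$

with $S_{tol}$ equal to $\Delta S\%$ of the *global* normalisation value,
taken as the maximum reference signal over the evaluated area — the standard
global-gamma convention. The evaluated ("irradiated") area is the set of
reference pixels at or above a low-signal cutoff, 10 % of the normalisation
value by default; the pass test $\gamma < 1$ is strict, so a pixel at
exactly 1 fails but does not appear in the $\gamma > 1$ failure map.

Numerically the minimisation proceeds in two phases. A circular lattice of
pitch $\Delta d / 10$ and radius $3 \Delta d$ is scanned in order of growing
$|d|$, with the current image interpolated bilinearly on its own grid at the
displaced query points (so reference and current grids only need to overlap,
not to match); the scan stops once the bare distance term exceeds every
pixel's running minimum, which makes near-agreeing images — the common case
in routine QA — cheap. A local pattern search then refines each pixel's
minimum with halved steps down to $\Delta d / 80$. The refinement matters:
without it the lattice quantisation alone leaves per-pixel errors of a few
hundredths, which would dominate the comparison against the exhaustive
oracle below. Setting `refine = FALSE` together with a pitch equal to the
pixel spacing restricts the search to pixel centres (no interpolation), a
mode used to pin boundary cases such as a one-pixel step shift giving
$\gamma$ exactly 1.

`brute_force_gamma()` is an independent oracle: a dense exhaustive scan
(default pitch $\Delta d / 20$) with its own interpolation code and no
pruning. The test suite requires per-pixel agreement within 0.02 on 100
random band-limited fields. The field class is chosen from an explicit
error analysis: both estimators quantise the displacement search, with a
per-pixel error bounded by $|\nabla S| \cdot \text{pitch} / S_{tol}$, so the
validation fields are low-pass-filtered random textures whose gradient is
normalised to make the oracle's own bound about 0.01 — on unconstrained
rough textures the *oracle's* quantisation error alone exceeds the
comparison tolerance (dense sub-lattice scans confirm that at near-zero
minima the refined engine sits closer to the continuum minimum than the
$\Delta d/20$ oracle). Transit portal images are physically smooth
(detector blur, scatter), so this regime is also the realistic one. Ties on
the lattice are irrelevant (a minimum over a finite set).

Two symmetry properties are enforced as tests: enlarging either criterion
(on a fixed search lattice) can only lower pixel gammas, and multiplying
*both* images by a constant leaves the gamma map unchanged (global
normalisation scales with the images).

## Transit dose reconstruction

The clinical reconstruction algorithm of the commercial IVD system is not
public; `epidivd` defines a minimal mid-plane transit model chosen to be
exactly invertible against its own simulator, which makes correctness
testable end to end. It is a deliberately simple surrogate, not a claim of
equivalence to any commercial system. The detector signal is converted to
in-air dose through the EPID calibration factor $k_s$, corrected for MU
linearity, backprojected to the patient mid-plane through half the
radiological path, and rescaled by the detector-to-isocentre inverse square:

$$D_{iso} = \frac{s_t}{k_s}\, L(MU)\, e^{+\mu_{eff} w_{cax}/2}
            \left(\frac{sdd}{sid}\right)^2 .$$

$w_{cax}$ is the radiological thickness actually crossed along the central
axis that day — in clinic derived from the registered planning CT/CBCT, in
simulations taken from the ground-truth phantom. With the actual $w_{cax}$
the formula recovers the dose truly delivered at the mid-plane point, so
$R$ compares delivered against planned dose. Two consequences fix the
closed forms used in the tests: a pure output drift of $+3\%$ gives
$R = 1.03$ exactly, and a uniform thickness loss $\Delta w$ (for example
10 % of 20 cm) gives $R = e^{+\mu_{eff} \Delta w / 2} = e^{0.05} \approx
1.051$ — just beyond the 1.05 tolerance, which is precisely the kind of
slow morphological drift the R index is meant to catch.

$\mu_{eff}$ follows from the beam quality index TPR20/10 through a small
monotone lookup (0.67 → 0.050 cm$^{-1}$, typical of 6 MV in water), with a
direct override available. The central ROI for $s_t$ has a 5 mm radius by
default.

## The synthetic cohort

The simulator stands in for the patients of a clinical cohort. Anatomy is a
2D water-equivalent thickness map in beam's-eye view — the transit chain
only needs attenuation and geometry, so no CT volume is involved. The
noise-free forward model per pixel is
$S = s_0\, MU\, e^{-\mu_{eff} w'(x,y)}$, followed by an optional Gaussian
point-spread blur and i.i.d. multiplicative Gaussian noise (1 % relative by
default). $s_0$, the in-air signal per MU, is tied to the calibration so
that the reconstruction above is the exact inverse of the forward model at
the central axis when noise and blur are off.

Default geometry: 128 × 128 pixels at 2 mm (the cohort simulator uses
64 × 64 to keep full-cohort runs tractable; all sizes are configurable),
source-isocentre distance 1000 mm, source-detector 1600 mm. No public
datasheet fixes the panel pitch used clinically; these are package choices.
Site-typical phantoms combine an elliptical dome (body contour) with
sinusoidal ridges (internal heterogeneity); breast and thorax get the
strongest gradients, which is what makes those sites the most sensitive to
setup errors — the same ranking reported clinically.

Perturbation kinds map to the two clinical error classes: `setup_shift`,
`attenuator` and `output_drift` are class 1 (setup/delivery causes),
`morphologic_change` is class 2, and `partial_acquisition` (a blanked
trailing row band, 40 % by default) models an acquisition artifact. One
perturbation is drawn per *fraction*, since a setup error affects every
beam of a session; morphological changes persist across fractions until the
correction loop (enabled by default) clears them after the first warned
fraction. Default rates encode the study conditions the simulator emulates:
15 % artifact images; dose-affecting errors at 25 % per fraction for breast
and thorax versus 10 % elsewhere, split 9:1 between class-1 kinds and
morphological change. Magnitudes are drawn once per event: shifts 3–8 mm,
thickness losses 5–15 %, 2 cm attenuator patches, ±3–6 % output drifts.
These rates were chosen as the generator's fixed conditions; measured T%/P%
emerge from the physics and are *not* calibrated to reproduce any published
table.

VMAT arcs are simulated as the sum of at least eight sub-beam images
through the rotated phantom, mirroring the fact that the analysed arc image
integrates many beam entries — which also reproduces the clinical
observation that arcs tolerate single-entry discrepancies better than fixed
beams. Rotation about the central axis leaves $w_{cax}$ unchanged, so arcs
and static beams share the same dose chain.

What the simulator does *not* model: MLC/fluence structure, scatter kernels
beyond a Gaussian blur, CT/DICOM geometry, couch and imaging-system
mechanics. Passing tests therefore demonstrate the correctness of the
indices, decision rules and aggregation on attenuation-driven images — not
the clinical accuracy of any specific commercial reconstruction on real
anatomy.

## Decision rules and aggregation

Tolerance comparisons are inclusive at every boundary (the tolerance
definitions are written with ≤/≥ throughout). Tests whose images fail the
acquisition sanity rule — more than 5 % blanked rows or integral signal
below 50 % of the reference — are excluded before any averaging; the
thresholds are package choices (clinically such images are identified by
inspection, being grossly off scale). Artifact records carry no pass flags.

Per-patient summaries use a two-stage unweighted mean: each beam's index is
averaged over the days it was tested, then the patient mean averages the
beam means; the same rule applies to all three indices. Cohort aggregation
reports, per (site, technique) group and per index, T% — the percentage of
retained tests in tolerance — and P% — the percentage of patients whose
mean index is in tolerance. Because isolated off-tolerance tests average
out and corrections re-align subsequent fractions, P% systematically
dominates T%, a property the test suite checks on simulated cohorts.
Display values are rounded half-up to integers; because the rounding
convention of published integer tables is not self-evident, the recompute
path reports a truncated variant alongside.

`classify_error()` returns the simulator's injected class verbatim when
ground truth is present. Without ground truth it gives an *advisory*
rule-based suggestion from the beam's R trend: a slow monotone drift ending
beyond tolerance suggests class 2, an isolated jump suggests class 1,
anything else is left unexplained — in clinic this attribution is a human
decision by physicist and oncologist, and the rule only ranks hypotheses.

## Index tables and the recompute path

Per-beam records travel as a nine-column table (patient, reference plan,
pathology, machine, beam, fraction label, R, γ%, γ_mean). CSV is the
canonical format; XLSX ingestion is supported through a minimal reader of
the workbook's XML parts (shared strings plus the first worksheet), since
no installed R package reads the format. Unparseable or out-of-range rows
are routed to a rejects table and counted — never silently dropped — and
row conservation (records in = records kept + rejects) is tested. Site
labels normalize through a documented synonym map; the technique, which the
table does not document, is inferred from the reference-plan label by a
configurable regular expression. `recompute_cohort_summary()` re-derives all counts,
flags, patient summaries and both aggregate tables from such a file, and
the suite verifies that exporting a simulated cohort and recomputing from
the file reproduces the in-memory aggregation exactly.

## Problem sizes and numerical choices

The validation suite uses 16 × 16 grids for oracle comparisons (100
instances), 64 × 64 grids for cohort simulation, an error-free 100-patient
cohort for the false-warning rate in the test suite (50 patients in
`scripts/acceptance.R`), 100 seeded replicates for the 6 mm
shift-sensitivity check, and a half-scale version of a 147-patient cohort
(same site/technique proportions) for the full emulation run in
`scripts/acceptance.R`. Degenerate inputs fail loudly: empty irradiated
areas, non-finite signals, zero transit signal, shifts beyond the grid,
negative thicknesses and invalid configuration keys all raise errors before
any computation.

## Known limitations

* The transit model is 0-D at the isocentre plus a 2D signal comparison; no
  off-axis dose reconstruction and no 3D dose is attempted.
* The gamma analysis offers global normalisation only (no local mode).
* Cause classification without ground truth is heuristic and advisory.
* Published aggregate tables from a real cohort can only be recomputed from
  the corresponding per-beam record file; the package ships the machinery
  but, deliberately, no third-party data.
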