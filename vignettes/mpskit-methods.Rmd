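---
title: "Methods: quantifying fibrosis, exposure and molecular concordance in a liver MPS NASH model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fibrosis, exposure and molecular concordance in a liver MPS NASH model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpskit)
```

# Scope and model

`mpskit` implements the quantitative machinery of a liver
microphysiological-system (MPS) NASH study in which 3-D microtissues grow
on collagen-coated scaffolds, develop a fibrotic phenotype (α-SMA
expression in activated stellate cells, collagen-I deposition), and are
treated with anti-NASH compounds. Four analysis families are covered:
confocal image quantification, in-vitro pharmacokinetics, transcriptomic
concordance/enrichment scoring, and soluble-biomarker panel analytics. A
fixture module generates every input synthetically with exact ground
truth, which is what makes the pipeline testable at desk scale: the
headline biological effect sizes (6-fold α-SMA and 8-fold collagen-I
increases, the drug-induced reductions, the patient-signature overlap
percentages) were measured on real images, LC-MS runs and RNA-seq data
that this package does not ship, so they are covered here as
*parameter-recovery* properties — the pipeline must recover what the
generator put in — not as reproductions of the published values.

# The imaging pipeline

**Acquisition model.** A slide is scanned at low magnification on the
nuclei channel as an overlapping tile grid; scaffolds appear as bright
circular regions. Eight regions of interest (ROIs) are placed on each
scaffold in a fixed array (the same array for every scaffold — this is
what makes the quantification unbiased), and each ROI is imaged as a
multi-channel z-stack, by default 25 planes over 120 µm at a 5 µm
interval. Each imaged ROI is treated as one field of view (FOV); the
FOV-per-scaffold count is configurable because published figure legends
report between two and eight per scaffold depending on the experiment.

**Stitching.** Nominal offsets are the grid strides,
`round((1 − overlap) × tile)`. They are refined by maximising the Pearson
correlation of the overlap strips against the already placed left (or
top) neighbour over a ±10%-of-tile-size search window; featureless
(numerically constant) strips, or zero configured overlap, fall back to
the nominal offsets — with a warning in the latter case. Overlaps are
blended by linear feathering, which is value-preserving when the two
tiles agree. On noise-free fixtures the refined offsets equal the
generator's offsets exactly.

**Scaffold detection and ROI placement.** Detection thresholds a heavily
smoothed mosaic (Gaussian sigma = radius/4) with Otsu's method, keeps
blobs of plausible scaffold area (¼× to 4× the expected circle), refines
each centre by a small circular-template shift search and re-estimates
the radius from the half-height crossing of the radial intensity profile
on a lightly smoothed image (the heavy detection blur would bias the
crossing inward). Detections are ordered row-major by centre so
downstream identifiers are deterministic. ROI centres are the scaffold
centre plus the fixed template offsets; out-of-bounds ROIs raise an error
naming the ROI index.

**Focus selection.** The sharpness score is the variance of the
4-neighbour Laplacian of the nuclei channel, the classic autofocus
metric; the source protocol names the channel but not the metric, so the
metric is a package choice. It is invariant to positive affine intensity
rescaling, ties break to the lowest plane index, and an all-constant
stack returns plane 0 with a degenerate flag.

**Segmentation and measurement.** Microtissues are segmented on the
in-focus nuclei plane: Gaussian smooth (sigma 2 px), Otsu threshold,
4-connected components, minimum area 100 px. The protocol gives no
operator detail here; these are the simplest standard choices. Total
marker intensity per microtissue is the pixel sum inside the object mask
at the selected plane minus `area × background`, with the background
estimated as the median outside all masks dilated by a guard band. Two
numerical details matter: the measurement mask is dilated by 3 px to
recover the soft tapered edge of the objects (pixels claimed by two
dilated masks are excluded from both), and negative totals are clamped to
zero and flagged. The phrase "total intensity throughout" an object is
ambiguous between the selected plane and the whole stack; plane mode is
the default and `mode = "stack"` sums across planes.

**Aggregation.** FOV summaries average over the FOV's microtissues;
scaffold summaries are the *unweighted* mean of FOV means, so unevenly
populated FOVs carry equal weight — this matches per-FOV averaging
before per-scaffold averaging in the source workflow. Fold-change
between conditions is the ratio of condition means of scaffold
summaries; percent change is `(1 − treated/control) × 100`. A zero
reference mean yields a flagged `NA`, never a division error.

# Pharmacokinetics

Recovery is the final measured concentration over the input
concentration, in percent. Fraction unbound is the rapid-equilibrium-
dialysis ratio `fu = C_buffer / C_chamber`, clipped to [0, 1] with a
flag. The half-life fit is ordinary least squares on `ln C` versus time
— chosen over weighted nonlinear fitting because an 8-point single-phase
decay is exactly the situation where the log-linear fit is standard
practice; non-positive concentrations are excluded with a count, fewer
than three usable points is an error, and a non-negative slope flags the
series as non-eliminating rather than reporting a nonsense half-life.

The dosing-regimen simulator models the protocol of a full media change
with redose every 48 h and spikes back to the nominal concentration on
intervening days. Spikes restore the concentration *exactly to* nominal,
never above — that is what "back to the desired concentration" implies —
so both event kinds reset to the same level and differ only in the media-
reset annotation. Between events the decay is exact
(`C(t) = C_e e^{−k(t−t_e)}`), AUC uses `expm1` per segment so the k → 0
limit is numerically clean, troughs are the pre-event concentrations
(sampling immediately before an event; the protocol does not state the
sampling order, so the convention is explicit), and residual-volume
carryover at media changes is idealised as a perfect reset because the
residual volume is unknown. Dose translation multiplies a clinical
plasma or liver Cmax anchor by configured multipliers and reports
provenance. A free-drug comparison (`C × fu`) is available but off by
default, since published dose tables anchor on total concentrations.

# Omics scoring

"Top 300 DEGs ranked by p value" is contradictory wording in the source
material (highest *expressed* vs ranked by *p*); ranking by p is the
implemented default because it is the explicitly stated rule, with an
expression-ranked option. The tie-break (descending |log2FC|, then gene
id) makes the order total, hence permutation-stable.

Concordance against a signed marker set reports both readings of
"also differentially expressed": `pct_overlap` (FDR < α regardless of
sign) and `pct_directional` (FDR < α and matching sign), because the
source usage is ambiguous between them. Denominators use the reference
genes actually present in the table — absent genes are unknowable — and
a set with no measured member returns flagged `NA`s.

Enrichment is the one-sided (over-representation) Fisher's exact test,
i.e. the hypergeometric upper tail, Bonferroni-corrected over the sets
tested in the call; gene-level calls use Benjamini–Hochberg FDR. The two
corrections deliberately mirror the two tools this module stands in for.
The tests verify the tail against exhaustive enumeration for universes
up to 25 genes.

The stand-in DE test is a per-gene Welch t on log-scale values with BH
correction — the count-model machinery it replaces is out of scope, and
for lognormal synthetic matrices the Welch test is the appropriate
simple surrogate. The batch simulator draws, per repeat, one offset per
plate shared across genes (groups confounded with plates — the layout
under which batch effects actually inflate error), adds per-gene
residual noise under a null effect, and counts miscalls at α. Its
default test is the *pooled* t, which has exactly nominal level under
the simulator's equal-variance null; the Welch option matches
`simple_de` but is conservative at three replicates. The published
per-gene error figure (≈5%) depends on unstated test details, so it is
treated as a calibration property (error ≈ α under the pure null,
non-decreasing in batch spread), not a number to reproduce. The
"median per-gene error rate" is the median across genes of each gene's
error rate over the simulation repeats (default 20).

# Panels

Analytes are retained when detected in ≥ 50% of samples of at least one
condition — the source states the outcome (15 of 42 excluded), not the
rule, so the rule is a package choice and the threshold is a parameter.
The optional "no significant group difference" screen reuses the same
one-way ANOVA at α = 0.05 and is off by default because it mixes
inference into filtering. Sampling day is folded into the grouping key
(condition.day) since panels are reported per day. Pairwise comparisons
against the reference use the pooled ANOVA mean-square error with the
Sidak adjustment `1 − (1 − p)^m`. Oil-Red-O normalisation is absorbance
per mg protein; the recorded wavelength defaults to 515 nm (the methods
value; one figure legend says 510 nm, so it is a config field).

# The synthetic world

The generators state a world once and the tests measure recovery from
it; none of their parameters were adjusted to make a test pass.

- **Geometry**: 8 ROIs per scaffold; 8–12 microtissues per FOV (the
  published per-FOV range), radii 6–9 px at the rendered scale; 25-plane
  stacks (120 µm / 5 µm) where stack geometry matters, shallow 3-plane
  stacks where it does not and runtime does.
- **Optics**: microtissues are Gaussian-tapered disks (flat core, soft
  1.2 px edge) so blur and focus metrics respond smoothly; defocus is a
  Gaussian blur with sigma proportional to the plane distance from
  focus, the simplest monotone sharpness model; intensities are
  quantised to 16-bit like confocal data.
- **Noise**: multiplicative lognormal with unit mean; 5% CV for pixel
  and LC-MS noise (the decay protocol's stated measurement noise level),
  10% for panels.
- **Effects**: disease folds 6 (α-SMA) and 8 (collagen-I); drug decay
  from 1 µM over 48 h; expression batch spread 0.1 and residual 0.5 on
  the log2 scale — values a transcriptomics practitioner would call
  typical plate-level and replicate-level variability.
- **Layout**: objects are placed on a jittered grid rather than by
  rejection sampling, which *guarantees* a minimum separation
  (deterministic object counts, no merged components) at the cost of
  never producing touching microtissues — a real-data failure mode the
  fixtures deliberately do not model.
- **Seeding**: every generator draws from named sub-streams of its spec
  seed. Condition sets that share a seed share layouts and base
  amplitudes, so their truth intensity ratio equals the configured fold
  *exactly*; the demo experiment uses this paired design, which means
  its fold-recovery test isolates pipeline bias from sampling noise.

What a green suite does establish: the pipeline is deterministic,
coordinate-exact on stitching, count-exact on well-separated objects,
within 1% on noise-free intensity truth and within 10% on fold recovery
under moderate noise; the statistical operators agree with enumeration
and hand computation. What it does not establish: performance on real
confocal data — uneven illumination, touching or out-of-plane objects,
autofluorescence and optical PSFs are all outside the rendered world.

# Known limitations

- Images live in memory as plain R arrays with CSV/JSON side outputs; no
  TIFF reader/writer is bundled because the supported R stack has none,
  and hand-rolling one was judged out of scope. Configs are JSON (not
  YAML) for the same reason.
- Segmentation is 2-D at the selected plane; there is no 3-D merging of
  objects across planes.
- The stitcher refines against a single anchor neighbour (left, else
  top); it does not do global bundle adjustment, which real mosaics with
  drift would want.
- `simple_de` is a surrogate, not a replacement, for count-based DE
  models; it is only meant for the lognormal synthetic matrices.
- The batch simulator's error criterion is a plain two-group test at α;
  the exact criterion behind the published error-rate figure is
  unstated, so agreement with it is not claimed.

# Session example

```{r example}
fit <- fit_halflife(gen_decay(decay_spec(
  c0_uM = 1, t_half_h = 12,
  sample_times_h = seq(0, 48, length.out = 8),
  noise_cv = 0.05, seed = 42)))
fit$t_half_h

prof <- simulate_regimen(log(2) / 12, daily_regimen(0.5, duration_h = 240))
c(cmax = prof$cmax_uM, cmin = prof$cmin_uM)
```
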