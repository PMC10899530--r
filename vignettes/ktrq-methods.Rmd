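---
title: "Methods: KTR trace analysis and histology quantification in ktrq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KTR trace analysis and histology quantification in ktrq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktrq)
```

## Overview

`ktrq` analyzes two kinds of data. First, live-cell kinase translocation
reporter (KTR) imaging: an H2B channel marks nuclei, and the ERKTR channel
reports ERK activity through the reporter's nucleus-to-cytoplasm shuttling
— active ERK phosphorylates the reporter and pushes it into the cytoplasm,
so the background-corrected cytoplasm/nucleus intensity ratio rises with
pathway activity. Second, fluorescent histology of lung sections stained
for DAPI (tissue), vimentin (tumor) and a marker of interest, from which
tumor counts, metastatic burden and within-tumor marker intensities are
quantified.

Because real imaging data are large and noisy, every analysis stage is
paired with a synthetic generator that produces data with *exact* ground
truth. The generators are first-class, tested code: the package's
correctness claims are statements about recovery of that truth.

## The acquisition schedule

`acquisition_schedule()` encodes the experimental timeline: one frame
every 6 minutes, a 4 h ligand-free baseline, growth-factor addition at the
end of the baseline, a 15 h response window, then MEK inhibitor (MEKi)
addition with a 60-minute imaged tail. Event times snap to the frame grid.
The MEKi tail defines the per-cell activity floor used for normalization.

## The trace generative model

`simulate_trace_ensemble()` draws each cell as a responder with
probability

$$p(\mathrm{dose}) = \frac{p_{max}}{1 + (EC_{50}/\mathrm{dose})^{h}},$$

the standard Hill/logistic pharmacology form; a class-0 "non-inducer"
forces $p = 0$. A responder's noiseless activity is
$b + A\,f_c(t - t_{tx})$ with per-cell amplitude $A$ drawn from a gamma
distribution (mean `amplitude_mean`, CV `amplitude_cv`) and one of three
unit-peak kinetic shapes:

- class 1, transient: $f_1(t) = (t/\tau_r)\,e^{1 - t/\tau_r}$ — a pulse
  peaking at $\tau_r$;
- class 2, prolonged but waning:
  $f_2(t) = e^{-t/\tau_d}(1 - e^{-t/\tau_r})$;
- class 3, sustained: $f_3(t) = 1 - e^{-t/\tau_r}$ — a plateau.

These are the simplest smooth shapes matching the three qualitative
response categories; their asymptotes and integrals are available in
closed form, which the tests exploit. After MEKi addition all traces relax
exponentially to `meki_floor` with $\tau = 12$ min — fast enough to be
biologically sensible, continuous enough to avoid discontinuity artifacts
in AUC computations. Per-frame noise is additive Gaussian, iid by default;
an AR(1) option exists because real reporter noise is autocorrelated, and
the paired test below is *not* corrected for autocorrelation — with AR(1)
noise its type-I rate inflates, which the iid default makes visible rather
than hiding.

Defaults (`sim_params()`): baseline 1.0 ratio units, amplitude mean 1.5
(CV 0.2), $\tau_r = 12$ min, $\tau_d = 300$ min, noise SD 0.05, floor 0.6,
$p_{max} = 0.8$, $EC_{50} = 10$ ng/mL, Hill 1, doses in the 1–100 ng/mL
range typical of growth-factor titrations. The per-ligand kinetics of any
real experiment are unknown to this package; these defaults are
illustrative magnitudes chosen once for realism (ratio changes of 2–3x
baseline, frame-to-frame jitter of a few percent), not estimates of any
particular ligand's biology. $\tau_d = 300$ min specifically keeps the
waning class kinetically intermediate between the pulse and the plateau
under the classification indices described below; a much faster decay
would make classes 1 and 2 genuinely indistinguishable on a 12 h horizon.

## The movie and tissue renderers

`simulate_timelapse()` renders each cell as a uniform nuclear disk
(radius 6 px) inside a cytoplasmic disk (radius 11 px). The ERKTR
cytoplasm is drawn at `erktr_nuclear * activity`, so the
background-corrected compartment ratio equals the cell's true activity
*exactly* before pixel noise — the renderer is definitionally consistent
with the extraction it tests. Nuclei perform reflected random walks in a
box centred on their initial position. The default box half-width is
`min((min_spacing - 2*cell_radius)/2 - 1, min_spacing/3)`: the first term
guarantees two cells placed at the minimum spacing can never overlap (so
rendered ground truth stays exact), the second keeps the worst-case
inter-cell distance large relative to the per-frame step (so ground-truth
tracks are unambiguous). There are no divisions, deaths, textures, PSFs or
illumination gradients — the renderer tests geometry and arithmetic, not
robustness to optical artifacts, and passing its tests says nothing about
deep-noise regimes real microscopes can produce.

`simulate_tissue_section()` renders the lung as a centred ellipse
occupying `lung_fill_fraction` of the field (the whole field at fraction
1), tumors as vimentin-positive disks placed fully inside the lung with a
minimum edge-to-edge separation, and a marker channel with one
normally-drawn intensity per tumor. All ground-truth areas are pixel
counts of the rendered masks, so discretization never causes truth and
mask to disagree. Default scale 0.32 µm/px at 16-bit depth matches a 20x
whole-section scan.

## Live-cell segmentation, tracking and extraction

The segmentation chain is deliberately classical and fully specified:
median background subtraction, Otsu threshold, hole filling,
distance-transform watershed to split touching nuclei, minimum-area filter
(30 px², matched to the default rendered nucleus). Cytoplasmic rings are
annuli within 3 px (Euclidean) of each nucleus, excluding all nuclear
pixels; a contested pixel goes to the nearer nucleus, ties to the lower
label. Tracking is greedy nearest-neighbor linking, closest pairs first,
with a hard displacement gate and no gap closing. These choices trade
sophistication for testability: on rendered movies the whole chain is
checked against exact truth (trace error below 2% at every valid frame on
noiseless input; identity agreement 100% when drift is bounded as above).

Activity extraction uses compartment *means* (the choice between mean and
median is exposed nowhere because the renderer makes them identical; on
real data mean is the common convention) and a per-frame background equal
to the median intensity outside all nuclei and rings — robust and
parameter-free. Frames with too few compartment pixels or a non-positive
denominator are flagged invalid rather than propagating NaNs. The default
ratio orientation is cytoplasm/nucleus so that activity *increases* with
ERK activity; the reciprocal orientation is available, and the two are
exact reciprocals on the same valid frames.

## Responder analysis

Traces are first normalized per cell to the MEKi floor: divide mode
(default) scales by the cell's mean activity over the floor window, so the
floor maps exactly to 1; subtract mode shifts it to exactly 0. The floor
window defaults to the final 40% of the MEKi tail, skipping the initial
relaxation transient.

The responder test pairs the $k$ valid frames ending at treatment time
with the $k$ valid frames starting right after it ($k$ = the smaller
window count, windows of 1 h each), matched by order, and applies a
two-sided paired t-test to the differences. A cell is a responder when
$p < 0.005$ *and* the post-window mean exceeds the pre-window mean
(`increase_only` policy; configurable to `any`). The pairing construction
is a design choice — "paired pre versus post" admits several concrete
constructions, and order-matching equal-length windows is the simplest one
that is exactly calibrated under iid noise: under the null the call rate
is $\alpha/2 \approx 0.0025$ (two-sided test, one accepted direction),
verified on 2,000 simulated null cells. No multiplicity correction is
applied across cells; the fixed $\alpha = 0.005$ *is* the operating point.
Zero-variance differences yield $p = 1$; under 3 valid pairs the call is
indeterminate and excluded from fractions.

Responders — and only responders — receive two features: the maximum
baseline-subtracted amplitude within 1 h of treatment (baseline $b_0$ =
mean over the 1 h pre-window, symmetric with the pairing window), and the
trapezoidal AUC of $activity - b_0$ over 12 h, in activity·hours, with
invalid frames linearly interpolated and no clipping at zero (a value with
more than 25% interpolated frames is flagged low-confidence). Amplitude is
baseline-subtracted by default; an absolute variant would differ only by
$b_0$.

Responder fractions carry Wilson 95% score intervals. Dose-response
summaries fit the same Hill form used by the generator via bounded
Levenberg-Marquardt least squares; identical fractions at all doses yield
a flagged degenerate fit with unidentifiable $EC_{50}$, and non-monotone
data are fitted but flagged.

### Class assignment

On the ensemble mean baseline-subtracted response $r(t)$ over the 12 h
window, two scale-free indices are computed: persistence
$P = r(12\,\mathrm{h}) / \max r$ and normalized duration
$D = \mathrm{AUC} / (\max r \cdot 12\,\mathrm{h})$. Class 3 when
$P \ge 0.5$ (the response holds at least half its peak), class 1 when
$D \le 0.25$ (the response occupies at most a quarter of its bounding
rectangle), class 2 otherwise. The thresholds are an operationalization of
the qualitative transient/waning/sustained distinction, chosen at the
midpoints of the analytic index values of the three default kinetic shapes
($D \approx 0.05$, $0.43$; $P \approx 0.1$, $1.0$), not a claim about any
published procedure. An ensemble with a non-positive peak is
unclassifiable.

## Tissue quantification

Tissue segmentation: Otsu threshold on DAPI, morphological closing
(disc, 5 px), hole filling (vessels and airways count as lung), minimum
component area 500 px². "Auto-threshold" in vendor software is
unspecified; Otsu is the standard reproducible stand-in, which also means
published limits of agreement obtained with vendor tooling are not
expected to transfer. Optional manual-correction masks are applied
explicitly (union / subtraction), never silently. Tumor segmentation:
Otsu computed over vimentin intensities *inside* the tissue mask,
8-connected components, minimum area 50 px² at working resolution.
8-connectivity is implemented as a union-find diagonal merge over a
4-connected labeling.

Burden is $100 \cdot \text{tumor area} / \text{lung area}$ — the bounded
form of the percentage; with tumors constrained inside the lung it lies in
$[0, 100]$ and equals 100 when tumor covers the lung. Marker intensity is
summarized as the 90th percentile within the vimentin mask, using linear
interpolation between order statistics (R's type-7 quantile) — the
convention is fixed because bit-reproducibility requires one, and both
pooled-mask and per-tumor scopes are provided since either aggregation is
defensible. Bland-Altman agreement reports bias and
$\text{bias} \pm 1.96\,SD$ limits with the $n-1$ SD denominator.

Fixed-cell immunostain quantification reuses the live-cell masks: per-cell
mean intensity in the nuclear or cytoplasmic compartment (e.g. nuclear for
an AP-1 factor like Fra-1, cytoplasmic for MCL1 given its localization),
normalized to a control-condition mean.

## Reporting statistics

Fold increase is experimental/control means; fold decrease is
control/experimental — so the two directions multiply to 1 for the same
pair. Organoid percent survival is post/pre counts × 100.
Benjamini-Hochberg adjustment is the original step-up procedure
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1, input order
restored); note the step-up procedure is not idempotent in general —
re-adjusting adjusted values can change them — so only order-monotonicity
and capping are invariant properties. Group summaries report mean ± SEM
with $SEM = SD/\sqrt{n}$.

## Numerical choices and degenerate inputs

- Coordinates are 1-based (row, col) matrix indices; disk membership is by
  pixel-center distance; areas are pixel counts, with µm² derived via
  `pixel_size^2`.
- Constant frames segment to empty masks without error; empty masks yield
  `NA` percentiles and empty label tables; zero lung area is an error.
- A divide-mode floor that is non-positive drops the cell with a counted
  warning rather than producing infinities.
- Trapezoidal integration on the 6-min grid makes step-discontinuous
  integrands lose half a frame interval relative to their continuous
  integral (a rectangle of height 1 over 12 h integrates to 11.95); for
  the smooth kinetic shapes quadrature error is below 1%.
- All generators are bit-reproducible under a fixed seed; `run_pipeline()`
  derives every stream from one master seed and writes byte-identical
  summaries on reruns.

## Problem sizes

The validation suite and `scripts/acceptance.R` use desk-scale problems
chosen to give tight binomial/oracle checks while completing in minutes:
2,000 null cells for calibration, 1,000-cell ensembles (100 replicates)
for fraction recovery and CI coverage, a 20-cell 190-frame 300×300 px
movie for imaging fidelity, 300 ensembles of 25 cells for class
assignment, and 30 rendered 512×512 px sections with 0–40 tumors for
tissue metrics.

## Known limitations

- The segmentation/tracking chain targets well-separated, disk-like nuclei;
  no mitosis handling, lineage reconstruction, gap closing, or
  learned segmentation.
- The paired t-test assumes exchangeable iid frame noise within windows;
  autocorrelated noise inflates its type-I rate (the AR(1) generator
  option exists to demonstrate exactly this).
- The renderers omit optical realism (PSF, shading, texture, 3D), so
  passing recovery tests bounds algorithmic error, not robustness on real
  microscopes.
- Group-comparison inference beyond the implemented formulas (ANOVA
  families, post-hoc tests) is intentionally delegated to standard R
  routines.
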