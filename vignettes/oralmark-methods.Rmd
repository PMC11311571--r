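---
title: "Methods: quantitative OCT biomarkers of oral mucosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative OCT biomarkers of oral mucosa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralmark)
```

## The measurement problem

Endoscopic OCT of the oral cavity produces long cylindrical volumes —
hundreds of longitudinal frames (rotation angle $\theta$), each a depth
($z$) by pullback ($y$) image — that are too large for frame-by-frame
expert reading. Given per-frame segmentations of the epithelium top and
the epithelial–stromal boundary (produced upstream by a segmentation
network, or by this package's phantom ground truth), `oralmark` reduces
each volume to seven per-A-line biomarkers:

* **morphology** — epithelial depth (µm) and the percentage of tissue
  A-lines with loss of the epithelial–stromal boundary;
* **attenuation** — mean depth-resolved attenuation coefficient
  $\mu$ (mm$^{-1}$) over the whole visualized depth, the epithelium, and
  the stroma;
* **stratification** — the normalized contrasts
  $(\mu_E - \mu_S)/(\mu_E + \mu_S)$ (epithelial–stromal) and
  $(\mu_{UE} - \mu_{LE})/(\mu_{UE} + \mu_{LE})$ (intraepithelial, upper
  vs lower epithelium halves), each in $[-1, 1]$.

Each biomarker is an en face map over (frame, pullback); a volume is
summarized by the median of each map over the retained A-lines.

## Geometry and conventions

Volumes are stored in calibrated dB, one 32-bit float TIFF page per
longitudinal frame (rows = depth, columns = pullback) with a JSON
metadata sidecar. Because TIFF float storage covers $[0, 1]$, intensities
are written through an affine map recorded in the sidecar; round-trips are
exact to 32-bit float precision (about $10^{-6}$ of the dynamic range),
which is far below any feature scale used here.

All computation happens on a 10 µm isotropic grid. Axial optical-path
spacing is divided by the immersion-medium refractive index
(`n_medium = 1.333`, water, configurable) before resampling, which uses
separable cubic-convolution (bicubic, Keys $a=-0.5$) interpolation
applied to the stored dB values — the scale the images are presented
in — with replicate borders. Spacings already within 0.05% of 10 µm are
passed through untouched. Depth intervals are half-open `[top, bottom)`;
the JSON surface format is 0-based with `-1` as the missing sentinel,
mapped to R's 1-based indices on read.

## Regions: noise floor, visualized depth, layer masks

The **noise floor** of a frame is computed from its bottom 25 rows
(250 µm): A-lines with no epithelium surface are excluded first, the
remaining region is smoothed with a 2-D 5×5 Gaussian kernel, and the
floor is the mean of the smoothed region. The kernel's $\sigma = 1$ px
puts ~99% of its mass inside the 5-px support; whether the smoothing is
1-D or 2-D is not fixed by the protocol we follow, so the 2-D choice is
flagged here as ours.

The **visualized region** of an A-line runs from the epithelium top to
the depth where the signal falls to within 6 dB of the floor. The
threshold is applied to the smoothed frame (the same kernel as the floor,
so both sides of the comparison see the same filtering), and a drop only
terminates the region when it is sustained for $k = 3$ consecutive
pixels, which rejects single-pixel speckle dips. The bottom is capped 25
pixels above the end of the A-line so the visualized region can never
overlap the noise-floor estimation window.

**Layer masks** follow the segmentation: epithelium `E = [top, boundary)`
and stroma `S = [boundary, bottom)`. Where the boundary is missing —
loss of the epithelial–stromal boundary, itself a biomarker — the entire
visualized depth is treated as epithelium and the A-line is flagged; its
stroma-dependent features are missing. The upper/lower epithelium split
gives the extra pixel of an odd-height epithelium to the upper half
(arbitrary but fixed).

**Edge erosion.** Where the catheter grazes tissue tangentially at the
azimuthal limits of contact, depth and attenuation are distorted. Before
summarizing, each azimuthal run of contact frames of length $L$ is
replaced by its central $\lfloor L/2 \rfloor$ frames (ties resolved
toward the run start; runs of one frame are kept, so thin contact strips
still contribute).

## Depth-resolved attenuation

The attenuation coefficient is estimated from the single-scattering
relation between the signal at a pixel and the energy remaining below
it. We use the exact discrete form

$$\hat\mu_i \;=\; \frac{1}{2\Delta}\,
  \log\!\left(1 + \frac{I_i}{\sum_{j>i} I_j + T}\right),$$

with $\Delta = 0.01$ mm and $I$ in linear power. The commonly quoted
ratio form $I_i / (2\Delta \sum_{j>i} I_j)$ is its first-order expansion
and carries an intrinsic relative bias of about $\mu\Delta$ (2% at
4 mm$^{-1}$ on this grid); the log form is exact on a noiseless
exponential at every pixel. The tail term $T$ compensates the energy
below the last measured pixel: an exponential is fitted by log-linear
least squares to the last $m = 10$ pixels (100 µm, configurable) and
summed in closed form, $T = I_N\, r/(1-r)$ with
$r = e^{-2\hat\mu_{tail}\Delta}$, which reduces to the familiar boundary
estimate $I_N / (2\hat\mu_{tail})$ as $\Delta \to 0$. A non-decaying
tail fit falls back to the uncompensated sum and is recorded in a
per-A-line quality flag. The estimator is invariant to rescaling the
profile, so catheter-to-catheter intensity calibration does not affect
it. No confocal/PSF correction is applied.

Two pipeline choices matter for accuracy near the bottom of the
visualized region:

* the per-frame noise floor (mean level, linear power) is subtracted
  before estimation — additive detector noise otherwise flattens the
  apparent decay where the signal approaches the floor;
* region means exclude the deepest $m$ pixels of each A-line
  (`tail_trim`): estimates inside the tail-fit window reflect the fitted
  boundary condition rather than data, and under speckle the window end
  is located where the smoothed signal happens to dip, which couples the
  truncation point to the noise. The pure per-region operation
  `region_mean_mu()` defaults to no trimming; `compute_biomarkers()`
  applies `tail_trim = m`.

Per-A-line region values are aggregated by *mean* over the region's
pixels (matching the mean en face projection of the 3-D attenuation
volume); stratification is computed per A-line from these means and only
then summarized by the median — not as a ratio of summary medians.

## The phantom: what it emulates, and what it does not

`phantom_spec()` renders a two-layer mucosa: a darker epithelium of
configurable depth over a brighter stroma, each with its own attenuation
coefficient, plus a contact sector (two-thirds of the revolution by
default, as for a catheter lying on a non-luminal surface), optional
loss-of-boundary regions, elliptical bubble artifacts that shadow whole
A-lines, and a linear dB roll-off taper at contact-run ends standing in
for edge effects.

The generative law is round-trip single-scattering decay in linear
power, $P(z) = B(z)\, e^{-2\int \mu\, dz}$, *averaged over each 10 µm
pixel* — detectors integrate the decay across a pixel, and the integral
form also makes the discrete estimator consistent with the generator on
noiseless inputs, so recovery tests measure pipeline error rather than
sampling artifacts. Speckle is multiplicative unit-mean exponential in
intensity (fully developed speckle), which preserves the expected decay
so attenuation recovery is unbiased to first order; the noise floor is
additive in linear power (exponentially distributed when speckle is on),
making the 6 dB rule meaningful. By default backscatter amplitudes are
proportional to the attenuation coefficients (constant backscatter
efficiency), the standard single-scattering tissue model and the regime
in which the depth-resolved estimator is exact; both can be overridden
to study model mismatch, at the cost of a known boundary bias in the
estimator.

Preset profiles encode the study conditions: the `"contralateral"`
preset uses the reference-tissue medians (depth 160 µm,
$\mu_E = 1.20$ mm$^{-1}$, $\mu_S = 3.97$ mm$^{-1}$, no loss); the
`"intervention_lesion"` preset carries a 77% loss fraction as reported
for carcinoma; the `"observation_lesion"` preset is an intermediate
lesion (depth 300 µm, 5% loss) with bubbles and a central lesion label.
Remaining free parameters were fixed once at values a practitioner would
call realistic for a 1310 nm endoscopic system — noise floor 40 dB below
the stroma backscatter level, tissue surface at 100 µm, a 2 mm deep
frame — and are not tuned per experiment.

The phantom deliberately omits rete pegs/papillae texture, keratin
layers, catheter sheath rings, and non-uniform rotational distortion.
Passing recovery tests therefore demonstrates that the pipeline measures
what it claims on layered attenuating media with speckle — not that the
biomarkers separate disease states in patients, which only clinical data
can show.

## Statistical protocol

`route_test()` reproduces the study's routing: a Shapiro–Wilk test
(α = 0.05) on the feature's pooled per-volume medians chooses parametric
vs nonparametric; paired designs then use the t-test on paired
differences or the Wilcoxon signed-rank test, unpaired designs use
Welch's t or the Mann–Whitney U. Two naming choices are deliberate: the
protocol's "Welch's paired t-test" is implemented as the one-sample t on
paired differences (an unequal-variance correction is undefined for a
single difference sample), and "Wilcoxon rank-sum" for paired data is
implemented as the signed-rank test, rank-sum being its unpaired
counterpart. Whether normality should be assessed on lesions, on
contralaterals, or pooled is not fixed by the protocol; we pool, which
matches feature-level routing. Missing values are dropped pairwise;
paired data with all-zero differences return p = 1. Lesions are
normalized within-patient by subtracting the median contralateral
measurement (`normalize_to_contralateral()`; unmatched patients are
excluded with a message). Supporting tests — Spearman's rank correlation
against age, Levene's variance-homogeneity test, and a closed-form
two-sided Grubbs outlier test — are reported without correction for
multiple comparisons, as in the protocol. Significance is fixed at
p < 0.05.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to exercise every
code path while keeping a full run around half a minute: estimator
oracles on 100-pixel A-lines; noiseless phantoms of 1–8 frames; speckled
recovery at the full working geometry of 64 frames × 512 A-lines ×
200 depth samples (about 7 s per volume on one core); speckle-ensemble
convergence over 6000 seeds of a 12 × 4 × 1 grid; and null calibration
of the routed tests over 500 replicates of n = 15 per group.

## Known limitations

* Surfaces are inputs: segmentation error (e.g. keratin labelled as
  epithelium) propagates into every downstream feature.
* The attenuation model assumes single scattering with
  backscatter-proportional attenuation; confocal effects are not
  corrected, so absolute values depend on catheter optics.
* The loss-of-boundary rule intentionally treats the whole visualized
  depth as epithelium; in heavy-loss volumes the epithelium biomarkers
  measure the visualized region, not the anatomical layer.
* Stored intensity is assumed log-compressed (dB); linear-scale inputs
  are supported via the sidecar `scale` field, converted on load.
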