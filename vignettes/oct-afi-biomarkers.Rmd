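---
title: "Quantitative OCT-AFI biomarkers for tubal imaging: models and methods"
author: "tubavision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative OCT-AFI biomarkers for tubal imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubavision)
```

## The problem

Endoscopic optical coherence tomography with co-registered autofluorescence
imaging (OCT-AFI) images the fallopian tube lumen through a rotating
catheter in a helical pullback: each revolution yields one cross-section
(B-frame) of depth-resolved backscatter profiles (A-lines), while a single
fluorescence value per A-line forms an en face map. From such volumes,
eleven quantitative biomarkers are extracted per specimen — calibrated
autofluorescence, four attenuation-derived measures, and six texture
measures — and compared across diagnoses, anatomical regions
(isthmus/ampulla/fimbriae), paired left/right tubes, and patient
covariates.

`tubavision` implements that entire pipeline, together with a synthetic
phantom generator that provides ground truth for every stage. Clinical
OCT-AFI datasets of this kind are not publicly distributed, so the phantom
is the package's test bed: every quantitative claim in the test suite is a
claim about recovery of known truth.

## Conventions

Volumes are `[frame, azimuth, depth]` arrays; indices are 1-based with
closed ranges (the native R convention). Depth increases away from the
catheter core; the azimuth wraps (`wrapAzimuth()` is the single shared
helper, and azimuthal equivariance is property-tested); frames run proximal
to distal. Intensity is stored in decibels, `dB = 10*log10(I_linear)`;
attenuation, speckle, and calibration convert to linear intensity at the
point of use, while co-occurrence texture consumes the log-transformed data
directly. En face maps are `[frame, azimuth]` matrices with `NA` marking
invalid pixels; invalid pixels are excluded from every downstream median,
never interpolated.

## The phantom

`phantomConfig()` / `generatePhantom()` render a cylindrical two-layer
tissue tube with full ground-truth sidecars. The image-formation model is
single scattering on linear intensity,

$$\mathbb{E}[I(z)] \;=\; A\,\mu(z)\,\exp\!\Big(-2\sum_{s \le z}\mu(s)\,\Delta\Big),$$

multiplied by unit-mean gamma speckle (shape $\alpha$, rate $\alpha$) and
with an additive gamma-distributed noise floor. This is exactly the model
under which the depth-resolved attenuation estimator's target quantity is
well defined, so recovery tests are meaningful. The phantom emulates:

* a sinusoidal lumen radius over azimuth and pullback (endosalpinx folds at
  a caricature level);
* a superficial layer of lower attenuation (default 2 mm$^{-1}$, 150 µm
  thick) over a deeper layer of higher attenuation (default 4 mm$^{-1}$),
  standing in for endosalpinx over myosalpinx;
* an en face fluorophore concentration field (default 1 µM fluorescein)
  read out through a monotone depth-decay model
  $a e^{-b d} + c$ plus a background offset — the calibration fitter shares
  only the monotone-decay property with this model, never its parameters;
* bright (0.98 µM fluorescein) and dark (water) calibration standards with
  an eccentric sheath so the standards span a usable depth range;
* the catheter artifact catalogue: core (PET) and sheath reflections, a
  test-tube wall reflection at 900 µm in standards, an attenuated axially
  smeared multipath ghost band at the end of the A-line, four azimuthal
  birefringence suppression bands, bubbles and a sheath marker;
* air frames beyond the distal specimen end (the AFI background region),
  and pathology metadata (specimen length, fimbriae length, 2 mm diagnosis
  blocks) in the bundle sidecar.

What it does **not** emulate: physically rigorous coherent speckle (spatial
correlation, confocal gating), refractive distortions, real plica geometry,
mucous, or hemosiderin-type fluorophores. Passing tests therefore
demonstrate correctness of the measurement chain under the stated model,
not clinical performance on tissue.

Default sizes are desk-scale (60 frames; tests use 10–36 frames and 48–360
A-lines per revolution rather than the native 1792) so that the full suite
runs in under a minute; all structural parameters are otherwise the
geometry the pipeline expects (10 µm pixels at the window tube, 0.98 µM
positive standard, 6 dB margins and so on). Determinism: every generator
call seeds R's RNG from `config@seed` and restores the caller's stream.

## Segmentation

Surface detection substitutes a classical detector for a pretrained
network whose weights are not distributable: per A-line, the first
sustained crossing (3 consecutive pixels) of noise floor + 6 dB below the
sheath, refined to the strongest intensity edge nearby. The published
post-processing chain is retained: azimuthal outlier replacement against a
wrapped running median ("thresholding"), morphological closing of the
valid mask with neighbour fill ("morphologic linking"), and median
combination with ±2 adjacent frames. Replacement only fires when the
detected value deviates by more than `maxJump` pixels, so on clean data
post-processing never degrades a pixel-accurate detection — that is what
makes the ≤1 px criterion on noiseless phantoms attainable. The detector
inherits the documented bias toward including air or mucous above the
plicae rather than cutting into them.

The noise floor is per A-line: the mean of a Gaussian-smoothed (length 5,
$\sigma = 1$) 25-pixel window at the end of the A-line, or immediately
before the multipath band when one is present. Padding for the smoothing
kernel is half-sample symmetric, which preserves the window mean exactly —
so the choice of $\sigma$ cannot bias the floor.

Sheath segmentation for standards thresholds at 3 dB above the floor,
discards pixels more than 750 µm from the core (excluding the test-tube
wall), and takes the deepest retained pixel per column. Two numerical
choices matter here: the volume is smoothed out-of-plane first (a raw
speckle excursion crosses a 3 dB threshold with probability ~4% per pixel,
which would otherwise corrupt nearly every column), and the line is then
snapped back to the unsmoothed frame's reflection peak so that averaging
across a wobbling sheath cannot drag the line off by the wobble amplitude.

## AFI calibration

Raw fluorescence is converted to µM fluorescein by

$$c = 0.98\,\mu M \cdot \frac{I_{tissue}(d) - \bar I_{background}}
{I_{bright}(d) - I_{dark}(d)},$$

with $d$ the core-to-tissue distance and the bright/dark curves fitted to
the standards as a three-parameter exponential-plus-offset by least
squares (`minpack.lm`), constrained monotone non-increasing, with a flat
fallback for data with no resolvable decay. Background is subtracted from
the tissue term only, exactly as the formula is printed. Pixels deeper
than 700 µm are not calibrated (they go to the uncalculated mask), and
negative calibrated values are retained so that region medians stay
unbiased. The operation is invariant to a common detector gain — scaling
tissue and both standards leaves the output unchanged — and recovery of a
constant-concentration phantom is depth-flat when judged against the
generated truth geometry; judged against the estimated surface, the ±1 px
segmentation jitter enters both coordinates of the correlation and
dominates the rank statistic long before any calibration defect would.

## Depth-resolved attenuation

The per-voxel attenuation estimate divides each linear intensity sample by
the tail sum below it,

$$\mu(z) \approx \frac{I(z)}{2\Delta \sum_{i=z+1}^{N} I(i) + I(N)/\mu(N)},$$

where $N$ is the deepest retained pixel and the boundary term $I(N)/\mu(N)$
accounts for the truncated tail; $\mu(N)$ comes from a log-linear fit over
the last 10 pixels (slope $-2\mu\Delta$). Two numerical choices:

* **Discretization.** The linearized form above carries a first-order bias
  of about $\mu\Delta$ (3% at 3 mm$^{-1}$ and 10 µm pitch — measurable on
  exact discrete exponentials). The package therefore defaults to the
  exact discrete inversion of the same model,
  $\mu(z) = \log(1 + 2\Delta I(z)/\text{denom})/(2\Delta)$, which is exact
  on discrete exponentials up to the boundary term; `linearized = TRUE`
  reproduces the printed form, and `groupedTail` exposes the alternative
  denominator grouping (off by default: the printed grouping is the
  dimensionally consistent one).
* **Noise floor.** The pipeline subtracts the measured per-A-line noise
  floor from the linear intensities before estimation. Without this, the
  additive floor flattens the apparent decay approaching the truncation
  depth and biases the deep-band attenuation low, washing out the
  stratification contrast. Retained pixels sit ≥6 dB (4×) above the floor,
  so subtraction keeps them positive.

Estimates are floored at 0.1 mm$^{-1}$ and capped at 50 mm$^{-1}$ with the
column flagged, never silently clipped. Band projections are per-column:
with $n$ retained pixels the superficial band is the shallowest
$\lfloor n/2 \rfloor$, the deep band the rest; stratification is
$(\mu_{sup}-\mu_{deep})/(\mu_{sup}+\mu_{deep}) \in [-1, 1]$, negative when
the deep band attenuates more.

## Texture

**Speckle.** Per A-line, retained tissue pixels from the 11-A-line
azimuthal window (5 each side, wrapping) are pooled and fitted to a gamma
distribution by maximum likelihood (method-of-moments start, `uniroot` on
the profile equation), on linear, unsmoothed intensity — out-of-plane
averaging would destroy the statistics. The biomarker is the distribution
mean $\alpha/\beta$ with $\beta$ the rate; at the MLE this equals the
sample mean exactly, which resolves the shape/scale naming ambiguity in
favour of the printed $\alpha/\beta$ formula. A-lines with fewer than 10
tissue pixels are excluded; degenerate fits are invalid pixels.

**Co-occurrence features.** Per cross-section, dB intensities are
normalized to [0, 1] by the volume-wide 5th/95th quantiles of masked
voxels (values clipped), binned to 32 gray levels, and ordered pixel pairs
one azimuthal step apart — both members inside the tissue mask, wrapping
at the seam to match the cylindrical topology — populate an asymmetric
joint probability matrix $p(i,j)$. Five Haralick features follow the
printed formulas: contrast $\sum (i-j)^2 p$, correlation (undefined and
flagged when a marginal is constant), energy $\sum p^2$, homogeneity
$\sum p/(1+|i-j|)$, and Shannon entropy $-\sum p \log_2 p$ over the GLCM
(the homogeneity formula gives 1, not 0, for identical neighbours; the
formula wins over the prose gloss). Pairs straddling a masked pixel are
dropped entirely so artifact borders cannot dominate the statistics. A
brute-force pair-counting oracle pins the implementation to 1e-12.

## Labels, resampling, medians

Pathology lengths are scaled linearly to the imaged extent when the imaged
specimen is longer and the sample was fully imaged; otherwise they are
used directly. The fimbriated region runs from the distal tissue end over
the (scaled) fimbriae length, the ampulla covers 50% of the (scaled)
specimen length proximal to it, and the remainder is isthmus; diagnosis
blocks are exact 2 mm before scaling (the histology sectioning interval),
and frames are assigned by their midpoints. En face maps are resampled to
the common 10 µm-square grid by area weighting with strict `NA`
propagation; per-cross-section features are replicated across the azimuth
for the en face reinterpretation. The region median is taken over pixels
that are kept, not removed, valid, and members of the scope — and rows
with zero eligible pixels are omitted rather than reported as NaN.

## Statistics

The battery is gated by Shapiro–Wilk per group (parametric only when every
group passes at 0.05 — the conservative joint reading): unpaired questions
use the unpaired t-test or Mann–Whitney U; paired questions the paired
t-test or the Wilcoxon signed-rank test (the paired analogue, despite the
"rank sum" label that sometimes travels with it), with pairwise deletion.
Levene and Grubbs diagnostics accompany unpaired parametric runs; Grubbs
outliers are reported, never removed. Fully tied rank tests report p = 1;
a paired t-test on exactly constant differences falls back to the rank
branch. No multiple-comparison correction is applied, by design. Bilateral
left/right differences use the symmetric percentage
$100\,|L-R| / ((L+R)/2)$ averaged over complete pairs — the denominator is
a package choice (the symmetric form makes L/R order irrelevant). The
type-I error of the full gated procedure is calibration-tested to
[0.03, 0.07] under Gaussian and exponential nulls, with ≥80% power at a
2σ shift with 20 per group.

## Orchestration

`computeBiomarkerMaps()` runs one acquisition through segmentation,
calibration and all biomarkers; `runPipeline()` wraps it end to end from a
phantom configuration, writes maps/tables to an output directory, and is
deterministic per seed. The stage functions are the public interface — a
thin Rscript wrapper (`inst/scripts/run_pipeline.R`) exists for shell use.
Problem sizes in the shipped tests (10–36 frames, 48–360 A-lines,
120–140 depth pixels, 20-seed replications) were chosen so the whole suite
exercises every stage in well under a minute of compute while keeping
every statistical bound comfortably away from its sampling noise.

## Known limitations

* The classical surface detector is a stand-in validated on phantoms; on
  real tissue a retrained network would be expected to outperform it.
* Confocal-gate and multiple-scattering corrections are out of scope, as
  is polarization-diverse artifact removal; birefringence bands are
  handled by masking, not correction.
* The phantom's AFI noise model is a simple relative-Gaussian on signal
  plus background; detector-specific noise (PMT shot noise statistics) is
  not modelled.
* Tissue-specific median values from clinical material are not
  reproducible here, since no public dataset exists; the package's claims
  are recovery claims on synthetic truth.
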