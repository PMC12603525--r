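---
title: "Methods: single-synapse puncta quantification with synmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-synapse puncta quantification with synmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

## The problem

Synaptic proteins labelled by immunofluorescence appear in high-resolution
confocal images as diffraction-limited bright spots ("puncta"), one per
labelled synaptic terminal. Quantifying a marker across brain regions means
(i) detecting the puncta in each channel, (ii) normalising counts to region
area (puncta per 100 µm²) and averaging punctum intensities (arbitrary
units), (iii) asking how often two markers occupy the same terminal
(colocalization) or adjacent pre/postsynaptic terminals (juxtaposition),
and (iv) condensing marker-by-region tables into fraction tables and
clustered heatmaps. `synmapr` implements this pipeline and, because raw
image archives are bulky, ships a synthetic micrograph generator with exact
ground truth so every stage can be validated end to end.

## Image model and coordinates

Images are single-channel matrices of arbitrary-unit intensities with a
physical pixel size (default 68 nm) and a bit depth (default 12-bit data in
a 16-bit container, so values are clipped to [0, 4095] and written as
uint16 TIFF). All functions share one coordinate convention: continuous
micrometres, origin at the top-left pixel corner, the centre of matrix
pixel (i, j) at ((j − 0.5)·s, (i − 0.5)·s) for pixel size s.

Acquisition by mosaic tiling without overlap is mirrored exactly:
`tile_montage()` cuts an image into a dense grid of fixed-shape tiles
(default 942 × 920 px) and `stitch_tiles()` abuts them back in row-major
order. No registration, blending or flat-field correction is applied, so
the round trip is bit-exact — a property the tests assert rather than
assume.

## The synthetic generator

`generate_field()` draws, per channel, a Poisson number of puncta with mean
ρ·area/100 for a configured density ρ (puncta per 100 µm²), places them
uniformly, and renders each as an isotropic Gaussian A·exp(−r²/2σ²) on a
flat background. Defaults, with units and reasoning:

* **Punctum width** `sigma_um = 0.12` (FWHM ≈ 0.28 µm ≈ 4 px). At
  NA 1.45 with far-red emission the point-spread sigma is ≈ 0.21·λ/NA ≈
  0.10 µm; a synaptic terminal adds a little physical extent. Per-punctum
  widths are log-normal (`sigma_sdlog = 0.15`) to emulate the wide range of
  punctum sizes seen in tissue; the generator does not attempt per-marker
  size distributions because no numeric ones are available — only
  qualitative statements (e.g. unusually large SV2A puncta in thalamic and
  dentate regions).
* **Amplitude** `amplitude_mean = 400`, `amplitude_sd = 80` a.u. over a
  background of 100 a.u., chosen so that disc-mean punctum intensities land
  in the few-hundred a.u. range reported for real markers.
* **Noise**: optional Poisson shot noise on signal + background followed by
  Gaussian read noise (`read_noise_sd = 37`), giving a signal-to-noise
  ratio of ≈ 10 for an average punctum — the regime the detection
  validation targets. Noise-free renders stay un-quantised so that the
  integral identity (image sum = background·area + Σ 2πσ²A) is testable.
* **Cross-channel structure**: a fraction f of channel-B puncta are placed
  at a distinct channel-A centroid plus at most one pixel of jitter
  (colocalized) or displaced by a fixed offset, default 200 nm, in a random
  direction (juxtaposed). 200 nm ≈ 3 px keeps pre/post pairs resolvable yet
  adjacent; no measured pre/post centroid separation was available to
  calibrate against. Pairing is one-to-one per channel pair and recorded in
  the ground truth.

A single integer seed drives one generator stream; identical seeds give
bit-identical fields. What the simulation deliberately omits: 3D structure,
tissue autofluorescence texture, chromatic aberration, optical PSF tails.
Passing tests therefore demonstrate algorithmic correctness at realistic
densities and SNR, not robustness to every artefact of real tissue.

## Detection

`detect_puncta()` is a TrackMate-style spot detector with the three
familiar knobs: punctum radius, quality threshold, intensity threshold.
The image is filtered with the negated scale-normalised
Laplacian-of-Gaussian at σ = radius/√2 (`log_response()`); the kernel is
discretised on ±4σ and recentred to exact zero sum, so constant images map
to zero and the filter is linear. For a Gaussian punctum of amplitude A
matched to the filter the peak response is A/2, which makes quality
thresholds interpretable on the amplitude scale (the default absolute
threshold of 60 a.u. used in the validation sits ≈ 10 response-noise
standard deviations above the noise floor at default noise settings, and
accepts puncta down to ≈ 30% of the mean amplitude).

Candidates are local maxima with minimum separation of one radius
(grey-scale dilation with a disc structuring element; a relative tolerance
of 1e-9 guards the equality against floating-point round-off). Suppression
keeps the higher-quality member of any conflicting pair, breaking exact
ties by scan order, so output is deterministic and ordered by descending
quality. Sub-pixel refinement fits a separable parabola to the response
peak (offsets clamped to ±0.5 px); maxima within one radius of the border
are discarded to avoid truncated-disc intensity bias, and an ROI mask
restricts both the detections and the area used for densities. "Auto"
quality mode sets the cutoff to the mean quality of all candidate maxima —
the "mean quality threshold" — which is useful on sparse images but mixes
noise maxima into the mean on dense ones, so the validation uses the
absolute threshold. Punctum intensity is the disc-mean pixel value;
whether the original workflow used peak or disc-mean intensity is not
stated, and disc-mean was chosen as the less noise-sensitive option.

## Quantification and replicates

Densities are 100·count/area with area from the ROI mask pixel count.
Replicate aggregation (`aggregate_replicates()`) treats the biological
subject — animal or case — as the unit, reporting mean ± SEM (sd/√n, 0 and
flagged for n = 1); values from multiple images of one subject should be
pooled before aggregation, the conservative reading of subject-level
mean ± SEM. Printed-table reproduction rounds half away from zero;
machine-readable outputs keep full precision.

## Colocalization

`match_puncta()` matches centroids across channels one-to-one: candidate
pairs within the distance criterion are accepted greedily in ascending
distance, then the matching is augmented along alternating paths to
maximum cardinality among distance-feasible matchings. The augmentation
exists because plain greedy matching can strand matchable puncta (its
count can fall below the maximum); with it, the matched count provably
equals the exhaustive maximum, which the tests verify against a
brute-force oracle on small instances. One-to-one matching caps the
percentage of partner puncta containing the reference at 100 and prevents
double counting at high density — note that a published per-region SEM
exceeding 100% suggests the original per-subject ratios could exceed 100,
which this design intentionally does not reproduce.

Distance criteria: 300 nm for same-terminal (presynaptic–presynaptic)
colocalization, about one punctum radius at the diffraction limit; 500 nm
for pre/post juxtaposition across the synaptic cleft. Both are
configurable; the two modes differ only in this default.

The chance that an unrelated reference punctum falls within d of a partner
punctum under spatial independence is 1 − exp(−(ρ/100)·πd²)
(`expected_chance_percent()`). Recovery experiments correct observed
percentages with this formula evaluated at the density of reference puncta
not consumed by true pairs; the null-calibration experiment uses modest
densities (ρ_A = 10, ρ_B = 5 per 100 µm²) because at high partner density
the one-to-one constraint begins to compete with the "any neighbour"
counting behind the analytic formula (a 30-seed audit at these densities
showed no detectable bias: per-criterion z scores mean ≈ 0, sd ≈ 1).

## Fraction tables and heatmaps

`build_fraction_table()` stacks reference density, summed comparison
densities, and their percentage. In reproduction mode all inputs are first
rounded to integers and the trailing "Mean" column is computed from the
rounded per-region values — the arithmetic a reader can verify against a
printed table; analysis mode keeps full precision. On the bundled mouse
reference densities this reconstructs the published presynaptic share
(60–83% across regions) and postsynaptic share (29–40%) cell for cell; on
the human densities the outer layers reproduce exactly while two cells
(one layer and the mean) land within one percentage point, because the
published versions of those cells were evidently derived from unrounded
source data.

Heatmaps (`plot_marker_heatmap()`) min–max normalise each marker row —
constant rows map to 0.5 and are flagged — and order both axes by
average-linkage hierarchical clustering on Euclidean distances of the
normalised rows. The published figures state only "clustered by
similarity"; average/Euclidean on normalised values is this package's
documented choice and is configurable. Normalisation is idempotent, and
leaf orders are deterministic.

## Validation experiments and problem sizes

The shipped experiments (also run by `scripts/acceptance.R`) use:

* **Density recovery**: one 35 × 35 µm field per cell of the 7-marker ×
  9-region design with ground-truth densities set to the mouse reference
  means (5–39 per 100 µm²), SNR ≈ 10, matched-filter radius, interior ROI
  inset 0.5 µm. Detected density is compared with the realised (not
  nominal) in-mask truth density, so Poisson realisation noise does not
  enter the per-cell 10% comparison. Pooled over the design this yields
  ≈ 12,000 true puncta, recall and precision above 0.95, localisation RMSE
  ≈ 0.02 µm.
* **Paired-fraction recovery**: 7 replicate 120 × 120 µm point-pattern
  fields per marker pair (mirroring n = 7 subjects), pooled counts,
  chance-corrected estimate compared with the configured fraction at the
  binomial 95% CI. Point patterns rather than rendered images isolate the
  matching statistics from detection error.
* **Null calibration**: one 300 × 300 µm field, distance criteria 0.2,
  0.3 and 0.5 µm, observed minus analytic chance within 3 Monte-Carlo
  standard errors.

These sizes were chosen to give each check adequate statistical power
while keeping a full validation run in the low minutes on one CPU.

## Known limitations

* 2D only; no 3D stacks or axial blur.
* Detection cannot split two puncta closer than roughly twice the punctum
  sigma — at the highest study densities a few percent of puncta sit in
  such pairs, which is the dominant contribution to the residual recall
  gap and density underestimate.
* The generator's amplitude and width distributions are calibrated only
  qualitatively; absolute intensity values are not comparable to any
  particular instrument.
* Inferential statistics across groups or species are out of scope; the
  package produces descriptive tables only.
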