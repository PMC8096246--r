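---
title: "Quantifying locus-level epigenetic marks from two-channel EVA images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus-level epigenetic marks from two-channel EVA images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

The Epigenetic Visualization Assay (EVA) reports the density of an
epigenetic mark (for instance 5-methylcytosine) at a single gene locus in a
single nucleus as a fluorescence ratio. Two oligo probes hybridize to the
locus: a *detector* oligo (red, Ch1) that marks the locus regardless of its
epigenetic state, and a *sensor* oligo (green, Ch2) whose retention depends
on the mark, because a mark-bound alkaline phosphatase protects the probe
complex from lambda-exonuclease digestion. The readout per locus is the
rim-corrected intensity ratio

$$
G/R \;=\; \frac{I_{\mathrm{Locus,Ch2}} - I_{\mathrm{Rim,Ch2}}}
               {I_{\mathrm{Locus,Ch1}} - I_{\mathrm{Rim,Ch1}}},
$$

where $I_{\mathrm{Locus}}$ is the mean intensity over the locus mask and
$I_{\mathrm{Rim}}$ the mean over a concentric 5-pixel band around it. The
rim subtraction removes the local diffuse background under each locus, so
no global flat-field correction is needed. `evaquant` implements the whole
chain from raw multi-channel TIFFs to these ratios and the statistics built
on them, plus a synthetic-specimen generator that makes every stage
verifiable against known ground truth.

Two properties of the formula are worth making explicit, because the test
suite leans on them:

* adding a constant to every pixel of a channel leaves $G/R$ unchanged
  (the rim mean absorbs the constant), and
* multiplying the sensor (detector) channel by a gain $k$ multiplies
  (divides) $G/R$ by exactly $k$.

Both hold exactly because locus and rim intensities are per-pixel *means*,
not sums: means over masks of different areas are directly subtractable,
which is what makes the formula well-posed. Whether the original assay
software used means or integrated intensities is not documented; means are
this package's declared choice.

## Pipeline stages and their parameters

1. **Registration** (`estimate_shift()`, `apply_shift()`). Chromatic
   aberration displaces the sensor channel relative to the detector channel
   by a field-wide translation. The shift is estimated once per field on
   maximum-intensity projections by normalized cross-correlation (FFT-based,
   subpixel refinement by a separable quadratic fit around the integer
   peak), with the detector channel fixed as reference, and undone by
   bilinear resampling. Shifts above `max_shift` (default 10 px) abort
   loudly: they indicate an acquisition problem, not something to correct
   silently. Pixels resampled from outside the frame are filled with the
   channel median and flagged; any locus or rim touching them is invalidated
   rather than measured on made-up data.

2. **Nucleus segmentation** (`segment_nuclei()`). The diffuse intranuclear
   signal of the detector channel, smoothed with a Gaussian
   (`smooth_sigma`, default 5 px), is thresholded by Otsu's method on the
   image's own intensity range (hence invariance to constant offsets),
   holes are filled, and objects outside `[min_area, max_area]` (default
   500 px to unlimited) are discarded. Watershed splitting of touching
   nuclei exists but is off by default: the assay images sparse,
   well-spread fixed cells. Border-touching nuclei are removed by default
   since their loci and rims may be truncated. The smoothing scale was
   chosen against the generator's nucleus geometry (semi-axes 18-30 px, the
   size of a ~10 um nucleus at a 100x/1.3 oil objective): heavier smoothing
   visibly inflates areas and can bridge neighbouring nuclei.

3. **Locus detection** (`detect_spots()`, `match_loci()`,
   `assign_to_nuclei()`). Foci are diffraction-limited, so a single-scale
   Laplacian-of-Gaussian filter at $\sigma = d/(2\sqrt{2})$ for an expected
   spot diameter $d$ (default 5 px) is used instead of a multi-scale blob
   search. Local maxima of the scale-normalized response above
   `min_snr` (default 5) times a robust noise level are kept; the noise
   level is the median absolute deviation of the response map, floored at
   2% of the peak response. The floor is a numerical guard: on noise-free
   synthetic images the MAD vanishes and, without it, arbitrarily faint
   smooth texture would be "detected". On noisy images the MAD dominates
   and the floor is inert. Each spot's mask is the connected response
   region above half its peak. The detector channel is authoritative for
   locus existence: sensor spots are greedily matched to detector spots
   within `match_radius` (default 3 px, ties broken by distance then
   index), unmatched detector spots are kept as `detector_only` (their
   sensor intensity is still measured on the detector-defined mask — this
   is precisely what makes cells with *no* visible sensor signal
   quantifiable as negative rather than missing), and unmatched sensor
   spots are discarded with a logged count. Loci take the nucleus label
   under their detector center; background loci are dropped.

4. **Ratio quantification** (`make_rim()`, `measure_locus()`,
   `compute_ratio()`). The rim is the disc-dilation of the locus mask by
   `rim_width` (default 5 px) minus the locus, clipped to the nucleus and
   excluding all other loci dilated by 1 px, so neighbouring foci never
   leak into a background estimate. The corrected sensor signal is floored
   at zero (a locus cannot carry negative mark density); a corrected
   detector signal below `epsilon` — by default three standard errors of
   the detector rim — invalidates the locus, because the detector signal
   is what defines it. z-stacks are measured on the maximum projection by
   default; `z_mode = "per_slice"` instead measures the `k_slices`
   brightest slices and averages the per-slice ratios weighted by each
   slice's corrected detector signal. The weighting matters: an unweighted
   average lets dim out-of-focus slices, whose ratio estimates are nearly
   unconstrained, inflate the variance, defeating the purpose of using
   more slices to stabilize the measurement.

5. **Statistics** (`normalize_to_control()`, `calibrate_dynamic_range()`,
   `classify_cells()`, `allelic_fold_ratio()`, `wilcoxon_rank_sum()`,
   `sample_size_two_groups()`). Ratios are normalized by the mean G/R of
   the no-exonuclease negative controls, so the control mean is exactly 1.
   The mixing-series calibration expresses any G/R as a percent of the
   attainable range, $100\,(x - \mathrm{floor})/(\mathrm{ceiling} -
   \mathrm{floor})$, with the fraction-0 and fraction-1 conditions defining
   floor and ceiling, and reports per-condition CVs as the technical-noise
   estimate. Two-locus cells are classified di+/+, mono+/- or di-/- by a
   positivity threshold, defaulting to mean + 3 SD of the normalized floor
   controls (no rule is documented for the original assay, so this is an
   explicit config value). Allelic analysis keeps only nuclei with exactly
   two valid loci — nuclei with more (typically replicated loci) or fewer
   are excluded — and reports per-cell RNA-/RNA+ ratios with both median
   and mean, since the available description does not say which was used.
   Group comparisons use the Wilcoxon rank-sum test (exact null for
   combined n of at most 12 without ties, otherwise the normal
   approximation with tie and continuity corrections); the sample-size
   estimate uses the two-sample normal-approximation formula
   $n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 \sigma^2 / \delta^2
   \rceil$ rather than a t-based iteration, because that closed form is
   what reproduces the assay's published planning number ($n = 16$ for a
   1.5-fold difference at $\sigma = 0.5$, power 0.8, $\alpha = 0.05$).

## The synthetic-specimen generator

`generate_specimen()` renders fields with known ground truth: elliptical
nuclei (random semi-axes 18-30 px, random orientation, non-overlapping)
carrying a smooth multiplicative intranuclear texture over a linear
background gradient; 0-4 foci per nucleus as isotropic Gaussians
(`psf_sigma` 1.7 px laterally, 1 slice axially) of detector amplitude 3000
counts over a ~400-count diffuse level; the sensor channel as the same foci
scaled per-focus by the true ratio on a diffuse level 0.3 times the
detector's; a global translation of the sensor channel (default (2, -3)
px); and, last, Poisson shot noise plus Gaussian read noise (sigma 10
counts, clipped at zero) — together an SNR around 50 at the focus peak.
Defaults frame a 512x512, 5-slice field on the nominal 16-bit scale. Foci
keep at least `6 * psf_sigma` apart so rims stay clean, and a focus set
that cannot satisfy the separation constraint is rejected with an explicit
"focus placement impossible" error rather than silently bent.

`generate_mixing_series()` emulates the dynamic-range experiment (labeled
sensor oligo mixed with unlabeled at known fractions: every focus in a
condition has true ratio `fraction * ratio_scale`), and
`generate_allelic_specimen()` emulates heterozygous cells: two foci per
nucleus, the RNA+ allele at `base_ratio / fold_difference`, marked by a
diffuse blob in an auxiliary RNA FISH channel from which the pipeline
derives positivity (mask-overlap fraction above 0.5 by default).

What the generator deliberately does **not** emulate: real PSF structure
beyond a Gaussian, 3D chromatic aberration, hybridization chemistry and
amplification trees, probe-size effects, cell-cycle structure, or any real
distribution of methylation across cells. Passing recovery tests therefore
demonstrates that the *measurement chain* is unbiased and correctly wired
under controlled imaging physics — not that any biological claim about real
specimens is reproduced. Bit depth, exposure and the true SNR of the
original acquisitions are not documented; the generator's defaults were
chosen once for testability, not fidelity to a particular microscope.

## Verification setup

The test suite checks each stage against independent oracles: constructed
circular shifts for registration (plus a brute-force correlation grid);
the generator's truth masks for segmentation and detection (noise-free:
100% recall, 0% false positives; noisy: >= 95% / <= 5%); hand-substituted
intensities and exact set-algebra for the rim and ratio; full enumeration
of rank assignments for the Wilcoxon test; and closed forms for tiling
counts and sample sizes.

The two end-to-end recovery studies run at sizes chosen to balance
statistical resolution against desk-scale runtime, and are stated here as
the package's own study conditions: the mixing series uses four conditions
(fractions 0, 0.33, 0.67, 1) of 55 nuclei x 2 foci each (110 foci per
condition) on 768x768 px, 3-slice stacks; the allelic study uses 25 nuclei
with a 2-fold allelic difference on 640x640 px stacks. Under these
conditions the pipeline recovers the first nonzero mixing fraction within
a few thousandths (tolerance 0.05) and the allelic fold within ~1%
(tolerance 15%), with rank-sum P far below 0.05. `scripts/acceptance.R`
re-runs both studies from scratch at any seed.

## Probe design

`tile_probes()` places 30-mer probes left to right with an exact 20-bp gap
(the "~20 bp" of the assay's description is resolved to a fixed stride so
counts are reproducible): an N-free 2.5-kb target yields exactly 50
probes, and windows containing N are skipped without moving the grid.
Coordinates are 0-based half-open on the given strand (the original
probes' strand is not documented; it is a flag here). `filter_probes()`
removes low-complexity probes (dinucleotide entropy < 1.5 bits or a
homopolymer run > 8) and probes sharing an exact 16-mer with a second site
in a user-supplied background — a deterministic, dependency-free
approximation of the original (unspecified) repeat/similarity filter, not
a re-implementation of it; published probe counts for real genes (96 over
5 kb, 85 over ~4.5 kb) reflect that unknown filter and are intentionally
not targets. `append_common_tail()` adds the shared 3' detection tail
(default `TAGTTTCAGCTTTCCGCAAC`), giving 50-nt oligos.

## Known limitations

* Detection is 2D (projections); overlapping foci separated only in z are
  merged. Per-slice *measurement* is supported, per-slice detection is not.
* The greedy nearest-neighbour pairing is not globally optimal; at the
  enforced focus separations it is exact, and ties are deterministic.
* Registration covers translation only — no rotation, scaling, or z
  registration — matching the optics it corrects.
* The k-mer uniqueness filter sees only the background it is given and
  only exact matches; it is not an aligner.
* Technical-vs-biological CV decomposition is reported descriptively; no
  mixed-effects modelling of cell heterogeneity is attempted.

## A minimal session

```{r example}
library(evaquant)

p <- sim_params(image_shape = c(512L, 512L), n_z_slices = 3L,
                n_nuclei = 25L, true_ratio = 0.6, seed = 1L)
sp <- generate_specimen(p)
q <- quantify_stack(sp$stack)
head(q$measurements)

agg <- aggregate_cells(q$measurements, mode = "population")
summary(agg$cells$mean_GR)
```
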