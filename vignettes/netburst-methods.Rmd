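---
title: "Methods: Pol II pausing profiles and transcriptional burst quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pol II pausing profiles and transcriptional burst quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netburst)
```

# Scope

`netburst` quantifies nascent transcription of a single gene from two
complementary data types: locus-targeted NET-seq read 3′ ends (RNA
polymerase II positions at single-nucleotide resolution) and 3D smFISH
image stacks (single-transcript foci, transcription sites, burst sizes).
Upstream steps — read alignment and UMI deduplication, manual cell
segmentation — are taken as given; their outputs (single-nucleotide BED
records, 2D cell outlines) are the package's inputs.

# The NET-seq density model

## Coordinates and filters

All positions are 1-based distances from the TSS in transcription
direction, introns included, which removes strand branching everywhere
downstream of `genomic_to_relative()`. BED input is 0-based half-open and
converted on load; GFF3 is 1-based inclusive.

Two read filters precede tallying:

* **Splicing intermediates.** 3′-end sequencing of chromatin-associated RNA
  also captures RNAs engaged with the transcription machinery but not
  attached to Pol II; the dominant class are intermediates of splicing
  after 5′-splice-site cleavage, whose 3′ ends sit exactly at the last
  nucleotide of the upstream exon. `donor_sites()` returns those positions
  (terminal exon excluded; a single-exon gene yields none) and
  `filter_splice_intermediates()` drops reads ending precisely there. This
  also discards genuine polymerases that happen to occupy the donor
  nucleotide — an unavoidable cost of the positional filter, shared by any
  analysis of this data type.
* **Primer windows.** Each sequencing primer reports reliably only over a
  limited downstream range; reads are kept when the 3′ end lies in
  `[primer_last_nt + 1, primer_last_nt + window_len]`, both bounds
  inclusive, with `window_len = 600` nt by default.

## Normalization and smoothing

Per primer, replicate and genotype, read ends are tallied per nucleotide;
empty positions receive a pseudocount of 0.1 so ratios and fold-changes
stay finite. Each position is divided by the primer's *raw* filtered read
count — pseudocounts contribute to the numerator only. Under this
convention the ratios over covered positions sum to exactly 1 (each
pseudocounted position adds `0.1/N`), and the track reads as the fraction
of observed polymerases dwelling at each nucleotide, independent of library
depth. The alternative convention (pseudocounts in the denominator too) is
available via `pseudo_in_denominator = TRUE`; the two differ by at most
`0.1 * n_zero / N` and the choice does not affect any binned statistic
materially.

Display smoothing is a centered rolling median of 11 nt. At the track
edges the window shrinks symmetrically to the positions available — no
padding, so no signal is invented and the output keeps the input length.
The first and last values are therefore plain copies, positions 2 and
n − 1 use 3-nt windows, and so on.

## Binned statistics

Statistics are computed on the *unsmoothed* ratios: a rolling median
correlates neighbouring positions, which would break the independence
assumptions of a per-bin test. Each primer window is tiled into 25-nt bins
from its first position (a trailing partial bin is allowed); a replicate's
bin value is the mean of its per-nucleotide ratios in the bin. Genotypes
are compared per bin with a two-tailed Student's pooled-variance t-test
(two replicates minimum per genotype; the equal-variance form is the
convention throughout this kind of analysis), and Bonferroni correction is
applied over all bins of all primers in one invocation — one corrected
track per run. Fold-changes are `log2(mean_alt / mean_ref)` of
cross-replicate bin means.

Degenerate bins are handled explicitly, since `stats::t.test()` errors on
constant input: when both genotype groups have zero variance, p is 1 for
equal means and 0 otherwise (the pooled t statistic is infinite).

# The smFISH branch

## Image model and preprocessing

Stacks are `[z, y, x]` arrays, two channels (DAPI, FISH), with a default
voxel size of 0.3 µm axially (the z-step of the widefield series the
simulator emulates). Denoising is separable 3D Gaussian smoothing
(default sigma 0.5 voxel axially, 1 voxel in-plane — narrow enough to
preserve diffraction-limited spots) with reflective borders.

Brightness is then normalized across depth. The default estimates each
slice's spread as its median absolute deviation and rescales the slice by
`reference / slice_MAD`, with the reference the median of the per-slice
MADs. Two deliberate robustness choices here:

* MAD rather than standard deviation, because a slice's sd is dominated by
  the few bright spots it happens to contain; equalizing raw sds dims
  spot-rich slices relative to spot-poor ones and distorts relative focus
  intensities, whereas the background-driven MAD tracks the depth
  attenuation itself.
* The per-slice spread profile is median-filtered along z (window 5)
  before use, because attenuation varies smoothly with depth while
  individual slice estimates jitter; this prevents a spot-containing slice
  from partially dimming itself.

Plain per-slice sd equalization (`method = "slice"`, after which every
non-degenerate slice has exactly the reference sd) and global-sd scaling
(`method = "global"`) remain selectable. Slices with zero spread are left
untouched, and an all-constant stack passes through unchanged.

## Segmentation and compartments

Nuclei are segmented from denoised DAPI by a global Otsu threshold,
3D 6-connected component labelling, and removal of components below a
minimum volume (default 50 voxels, against debris). Cells come from manual
2D outlines extruded over the slices each cell spans; overlapping cell
masks are rejected so no focus can ever be counted twice. Each cell is
partitioned exactly into nucleus, nuclear periphery and cytoplasm: the
periphery is an in-plane dilation shell of the nucleus (default width 2
voxels, outside the nuclear boundary), clipped to the cell. The shell
geometry is a package choice — nothing in the underlying assay defines
whether the periphery lies inside or outside the boundary — and the width
is configurable.

## Spot detection

Candidate foci are 3D local maxima (26-connectivity) of the denoised,
normalized FISH channel above a threshold. Because image intensities are
arbitrary units, the default threshold is a robust z-score: a peak
qualifies when it exceeds `median + detect_threshold × MAD` of the channel
(default 5), which adapts to high and variable background; an absolute
mode exists for calibrated data. Peaks closer than `min_separation_vox`
(default 2) are resolved greedily in favour of the brighter one, with
exact ties broken by voxel index so results are deterministic. Peaks
outside every cell are discarded.

A focus's intensity is the integrated signal over an ellipsoidal patch
(default semi-axes 1×2×2 voxels, matching the PSF anisotropy) minus the
local median background (a surrounding box of twice the patch size, patch
excluded) times the patch volume, floored at a small positive epsilon.
This deliberately avoids full Gaussian PSF fitting: integrated
background-subtracted intensity is linear in spot brightness, which is all
the downstream fold-change analysis requires.

## Transcription sites and burst size

Per cell, foci in nucleus and periphery are pooled ("nuclear-region").
With at least four of them, the two brightest are set aside (a diploid
cell has at most two active alleles) and the mean of the rest is the
single-transcript unit intensity. Every nuclear-region focus then gets a
fold-change to this unit; foci at or above 1.6 (inclusive — the boundary
case is TS-qualifying) are transcription-site candidates, capped at the
two brightest. The TS fold-change is the burst-size proxy: the number of
transcript-equivalents of fluorescence at the site.

Active-transcription frequency divides total TS calls by total alleles,
`2 × n_cells`, over *all* analyzed cells by default; a variant restricted
to eligible cells is exposed (`eligible_only = TRUE`) and both are
reported per embryo when embryos are annotated, since which convention the
per-embryo analysis should use is genuinely open. Cells with ≥ 4 nuclear
foci but a non-positive unit intensity are flagged and excluded from TS
calling. Genotype comparisons report means, two-tailed pooled t-tests and
Tukey box statistics (whiskers at the most extreme values within 1.5 IQR)
for cytoplasmic counts per cell, TS fold-changes and per-embryo
frequencies, skipping any quantity with fewer than two values in a group.

# Simulators

The simulators are first-class, tested code: they define the conditions
under which the pipelines are validated.

* `simulate_netseq()` draws read 3′ ends multinomially over a primer
  window with baseline dwell weight 1 and genotype-specific multipliers
  over pause ranges; defaults are 19,000 reads per replicate and 3
  replicates per genotype (the replicate count is a simulator default, as
  typical for this assay scale). Contamination places an exact count
  (`round(contamination × n)`) of reads uniformly on donor sites, so the
  splice filter can be scored exactly. The truth object carries closed-form
  expected per-bin fold-changes — e.g. an 8× multiplier over one 25-nt bin
  of a 600-nt window gives `log2((8·25/775)/(25/600)) ≈ 2.63`, which is
  why a dwell multiplier of 8 appears as a fold-change near 2.6, not 3:
  normalization redistributes the added dwell mass.
* `simulate_cells()` emulates diploid cells with Poisson(20) mature
  transcripts (the typical per-cell focus count in the data this mirrors),
  a 0.3 probability of a mature transcript being nuclear-region (split
  evenly between nucleus and periphery), per-allele activity probability
  0.5 by default, and multiplicative lognormal intensity noise
  parameterized by CV with mean exactly 1, so a noise-free simulation
  recovers burst sizes exactly. TS foci are placed in the nucleus proper,
  since transcription is chromatin-bound. Burst-size parameter-recovery
  runs use `p_allele_on = 1`: with both alleles active the two discarded
  brightest foci are exactly the two TS, making the unit-intensity
  estimator unbiased — the clean condition for testing the estimator
  itself rather than the allele-activity process.
* `render_image()` renders spots as 3D Gaussians (peak amplitude
  proportional to truth intensity) over a flat background, with Poisson
  shot noise plus Gaussian read noise, and an optional per-slice gain
  applied to the *recorded* slice — modelling slice-wise brightness
  attenuation, which per-slice spread normalization can undo exactly.

What the simulators do **not** emulate: optical aberrations and empirical
PSFs, chromatic shifts, autofluorescent debris, tissue-level background
gradients within a slice, partial-length nascent transcripts at the TS
(probe occupancy is modelled as complete, so TS intensity is exactly
burst size × unit), segmentation errors in the manual outlines, and
kinetic (time-resolved) bursting. Passing the synthetic benchmarks
therefore demonstrates correctness of the quantification logic under the
stated noise model, not robustness to every artefact of real microscopy.

# Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately modest
scale — 600-nt windows with 19,000 reads × 3 replicates × 2 genotypes,
200-cell simulations, and 20 × 64 × 64 voxel stacks with ~13 spots — which
this package's authors consider representative for validating the
statistics while keeping a full validation run under a minute of compute.
Every stochastic step takes an explicit seed; identical seeds and
parameters give byte-identical outputs, and the table writers format
numbers deterministically so repeated pipeline runs are file-identical.

# Known limitations

* The splice-intermediate filter removes genuine Pol II density at donor
  nucleotides; profiles are blind at exactly those positions.
* The Bonferroni family is all bins of one invocation; re-running primers
  separately changes the correction, deliberately mirroring one corrected
  track per run.
* Unit intensity is estimated per cell from few foci (≥ 2 after
  discarding), so single-cell burst sizes are noisy; population means are
  the intended readout.
* With fewer than two TS per cell active, the discard-two-brightest rule
  removes the brightest mature foci, biasing the unit slightly downward
  and burst-size proxies upward; the effect is small at realistic CVs and
  vanishes in the recovery condition described above.
* Compartment assignment happens at the peak voxel only; a focus
  straddling a boundary is attributed wholly to one compartment.
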