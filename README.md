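# netburst

Quantification pipelines for nascent transcription at a single locus,
for researchers combining locus-targeted NET-seq with single-molecule RNA
FISH (smFISH) to dissect how a gene is transcribed — where RNA polymerase II
pauses along the gene body, and how often and in what burst sizes its
alleles fire.

The package implements two independent analysis branches plus seeded
simulators that generate ground-truthed inputs for both:

## The NET-seq branch: Pol II density profiles

Targeted NET-seq sequences nascent RNAs primed at fixed positions along one
gene; each read's 3′ end marks the active site of a transcribing Pol II.
The pipeline:

1. drops reads whose 3′ end falls exactly on a 5′ splice site (donor) of
   the gene — these are splicing intermediates released by 5′ss cleavage,
   not polymerases;
2. keeps reads ending within 600 nt downstream of each sequencing primer's
   last nucleotide;
3. tallies ends per nucleotide, substitutes a pseudocount of 0.1 at empty
   positions, and normalizes each position by the primer's raw read total,
   so the profile reads as the *fraction* of polymerases observed per
   nucleotide — a dwell-time (pausing) signal independent of overall
   transcription level:

   r_i = max(c_i, 0.1) / N,   with c_i the read-end count at nucleotide i
   and N the primer's filtered read total;

4. smooths for display with an 11-nt centered rolling median;
5. for statistics, tiles each window into 25-nt bins, takes per-replicate
   bin means of the unsmoothed ratios, and compares genotypes per bin with
   a two-tailed Student's (pooled-variance) t-test, Bonferroni-corrected
   over all bins of all primers; fold-changes are log2(alt/ref) of the
   cross-replicate bin means.

## The smFISH branch: transcription sites and burst size

From two-channel 3D stacks (DAPI + FISH) with manual 2D cell outlines:
Gaussian denoising, per-slice brightness normalization across depth, Otsu
nucleus segmentation, partition of each cell into nucleus / nuclear
periphery / cytoplasm, and threshold-based 3D spot detection with
background-subtracted integrated intensities. Per cell, with n ≥ 4
nuclear-region foci:

* unit intensity u = mean intensity of nuclear-region foci after discarding
  the two brightest (a diploid cell has at most two transcription sites);
* every nuclear focus gets a fold-change f = I/u; foci with f ≥ 1.6 are
  transcription sites (TS), at most the two brightest;
* burst-size proxy = TS fold-change; active-transcription frequency =
  n_TS / (2 × n_cells).

## Worked example

```r
library(netburst)

model <- gene_model("geneA", "chr5", "+",
                    exons = cbind(c(1L, 801L), c(700L, 1400L)))
win <- primer_window("exon1", primer_last_nt = 50L, window_len = 600L)

# 19,000 reads x 3 replicates per genotype; an 8x Pol II dwell multiplier
# over 301-325 in the mutant only; 5% splicing-intermediate contamination
sim <- simulate_netseq(model, win, n_reads = 19000, n_replicates = 3,
                       pause_sites = list(list(start = 301, end = 325,
                                               multiplier = c(WT = 1, mut = 8))),
                       contamination = 0.05, seed = 1)
res <- run_netseq(sim$reads, model, list(win),
                  ref_genotype = "WT", alt_genotype = "mut")
res$summary$n_splice_intermediates_removed
#> [1] 5700
res$bins[which.min(res$bins$p_raw), ]
#>  primer_id bin_start bin_end mean_ref mean_alt log2_fc    p_raw   p_bonf n_ref n_alt
#>      exon1       301     325  0.00176   0.0102    2.54 4.22e-08 1.01e-06     3     3
```

All 5,700 planted splicing intermediates (5% of 114,000 reads) are removed,
and the pause bin 301–325 is recovered as the most significant bin with
log2 fold-change 2.54 — close to its closed-form expectation
log2((8·25/775)/(25/600)) ≈ 2.63 under the multinomial dwell model.

```r
cells <- simulate_cells(200, p_allele_on = 1, burst_size = 5,
                        intensity_cv = 0.1, seed = 1)
summarize_genotype(cells$foci)
#> <burst_summary> genotype WT: 200 cells (199 eligible), 398 TS
#>   active-transcription frequency: 0.995 TS/allele
#>   mean TS fold-change (burst-size proxy): 5.04
#>   mean cytoplasmic foci per cell: 13.75
```

A simulated burst size of 5 is recovered as mean TS fold-change 5.04; with
both alleles forced on, 398 TS across 400 alleles give a frequency of
0.995 (one cell drew too few nuclear foci to be eligible).

Thin command-line wrappers over these functions live in `inst/cli/`
(`netseq.R`, `fish-detect.R`, `burst.R`, `simulate.R`).

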