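Package: netburst
Title: Pol II Pausing Profiles from Targeted NET-Seq and Transcriptional
    Burst Quantification from smFISH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for locus-targeted nascent
    transcription data. Converts UMI-deduplicated nascent-RNA 3' end
    positions into normalized per-nucleotide RNA polymerase II density
    profiles with splicing-intermediate filtering, rolling-median
    smoothing and binned between-genotype testing. Detects fluorescent
    foci in two-channel 3D smFISH image stacks, classifies them into
    nucleus, nuclear periphery and cytoplasm, calls transcription sites
    as foci brighter than a per-cell single-transcript intensity, and
    estimates burst-size proxies and active-transcription frequencies.
    Includes seeded simulators for reads, cells and microscopy stacks
    that provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    mgcv,
    EBImage,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
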