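#' Load nascent-RNA 3' end positions from BED
#'
#' Each BED record is a single-nucleotide interval marking the 3' end of one
#' UMI-deduplicated nascent RNA (the Pol II active site). The record's name
#' field identifies the sequencing library; the manifest maps it to the
#' targeting primer, biological replicate and genotype. Coordinates are
#' converted from BED (0-based, half-open) to 1-based gene-relative positions
#' in the direction of transcription. Records outside the gene span (or on
#' another chromosome) are dropped and counted.
#'
#' @param bed_source Path to a BED file of single-nucleotide intervals with a
#'   name field, or a `GRanges` already imported.
#' @param manifest Data frame (or TSV path) with columns
#'   `source, primer_id, replicate_id, genotype`; `source` is matched against
#'   the BED name field.
#' @param model A [gene_model()].
#' @return A data frame of class `read_ends` with columns
#'   `rel_pos, primer_id, replicate_id, genotype`; the number of dropped
#'   out-of-span records is attached as attribute `n_dropped`.
#' @export
load_read_ends <- function(bed_source, manifest, model) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  need <- c("source", "primer_id", "replicate_id", "genotype")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  gr <- if (methods::is(bed_source, "GRanges")) bed_source else {
    rtracklayer::import(bed_source, format = "BED")
  }
  if (length(gr) && any(GenomicRanges::width(gr) != 1L)) {
    bad <- sum(GenomicRanges::width(gr) != 1L)
    stop(bad, " BED record(s) are not single-nucleotide intervals")
  }
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("BED records lack the name field keying the manifest")
  miss <- setdiff(unique(nm), manifest$source)
  if (length(miss)) {
    stop("BED sources absent from the manifest: ", paste(miss, collapse = ", "))
  }
  sp <- gene_span(model)
  pos <- GenomicRanges::start(gr)   # rtracklayer returns 1-based starts
  keep <- as.character(GenomicRanges::seqnames(gr)) == model$chrom &
    pos >= sp[1L] & pos <= sp[2L]
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " read end(s) outside the gene span dropped")
  }
  gr <- gr[keep]
  idx <- match(S4Vectors::mcols(gr)$name, manifest$source)
  out <- data.frame(
    rel_pos = if (length(gr)) genomic_to_relative(GenomicRanges::start(gr), model) else integer(0),
    primer_id = manifest$primer_id[idx],
    replicate_id = manifest$replicate_id[idx],
    genotype = manifest$genotype[idx],
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_ends", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Define a primer read window
#'
#' Reads retained for a primer are those whose 3' end lies within
#' `window_len` nucleotides after the last nucleotide of the sequencing
#' primer, i.e. in `[primer_last_nt + 1, primer_last_nt + window_len]`
#' (both bounds inclusive).
#'
#' @param primer_id Primer identifier.
#' @param primer_last_nt Gene-relative position of the primer's last
#'   nucleotide.
#' @param window_len Window length in nt (default 600).
#' @return An object of class `primer_window`.
#' @export
primer_window <- function(primer_id, primer_last_nt, window_len = 600L) {
  if (window_len < 1L) stop("window_len must be >= 1")
  if (primer_last_nt < 0L) stop("primer_last_nt must be >= 0")
  structure(
    list(primer_id = primer_id,
         primer_last_nt = as.integer(primer_last_nt),
         window_len = as.integer(window_len),
         positions = seq.int(primer_last_nt + 1L,
                             primer_last_nt + window_len)),
    class = "primer_window"
  )
}

#' Read a primer panel from TSV
#'
#' @param path TSV with columns `primer_id, primer_last_nt`.
#' @param window_len Window length applied to every primer.
#' @return Named list of [primer_window()] objects.
#' @export
read_primer_panel <- function(path, window_len = 600L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("primer_id", "primer_last_nt") %in% names(tab))) {
    stop("primer panel TSV must have columns primer_id, primer_last_nt")
  }
  ws <- lapply(seq_len(nrow(tab)), function(i) {
    primer_window(tab$primer_id[i], tab$primer_last_nt[i], window_len)
  })
  names(ws) <- tab$primer_id
  ws
}
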