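#' Construct a gene model
#'
#' A minimal single-gene model holding the exon/intron structure needed to
#' interpret nascent-RNA 3' end positions: chromosome, strand, exon intervals
#' and the transcription start site. All downstream coordinates are expressed
#' 1-based relative to the TSS in the direction of transcription, introns
#' included, so that "position 1" is the first transcribed nucleotide on
#' either strand.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of genomic exon intervals
#'   (1-based, inclusive). Order is irrelevant; exons are sorted into
#'   transcription direction and must not overlap.
#' @param length Gene length in nt from the TSS to the annotated 3' end,
#'   introns included. Defaults to the genomic span of the exons.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, length = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("gene model needs at least one exon")
  if (any(exons[, "start"] > exons[, "end"])) {
    stop("exon start > end in gene model for ", gene_id)
  }
  # sort into transcription direction
  ord <- order(exons[, "start"], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  # overlap check on genomically sorted intervals
  gs <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(gs) > 1L && any(gs[-1L, "start"] <= gs[-nrow(gs), "end"])) {
    stop("overlapping exons in gene model for ", gene_id)
  }
  tss <- if (strand == "+") exons[1L, "start"] else exons[1L, "end"]
  span <- max(exons[, "end"]) - min(exons[, "start"]) + 1L
  if (is.null(length)) length <- span
  if (length < span) stop("gene length shorter than the exon span")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         tss_genomic = as.integer(tss), exons = exons,
         length = as.integer(length)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s), length %d nt\n",
              x$gene_id, x$chrom, min(x$exons), max(x$exons), x$strand,
              nrow(x$exons), x$length))
  invisible(x)
}

#' Load a gene model from GFF3 or TSV annotation
#'
#' For GFF3 input the `exon` features belonging to `gene_id` (matched against
#' the `gene_id`, `Parent` or `ID` attributes) are collected and overlapping
#' intervals merged, so multi-isoform annotations collapse to the exonic
#' union. A plain TSV with columns `chrom, strand, exon_start, exon_end`
#' (one row per exon) is accepted for fixtures.
#'
#' @param path Path to a GFF3 (`.gff`/`.gff3`) or TSV file.
#' @param gene_id Identifier of the gene to load.
#' @return A [gene_model()].
#' @export
load_gene_model <- function(path, gene_id) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    load_gene_model_gff(path, gene_id)
  } else {
    load_gene_model_tsv(path, gene_id)
  }
}

load_gene_model_gff <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  hit <- rep(FALSE, length(gr))
  for (col in c("gene_id", "ID", "Parent")) {
    if (col %in% names(meta)) {
      v <- meta[[col]]
      if (methods::is(v, "List")) {
        hit <- hit | vapply(v, function(p) any(grepl(gene_id, p, fixed = TRUE)),
                            logical(1))
      } else {
        hit <- hit | (!is.na(v) & grepl(gene_id, v, fixed = TRUE))
      }
    }
  }
  sub <- gr[hit]
  if (length(sub) == 0L) stop("gene '", gene_id, "' not found in ", path)
  ex <- sub[tolower(as.character(meta$type[hit])) == "exon"]
  if (length(ex) == 0L) {
    stop("gene '", gene_id, "' has no exon features in ", path)
  }
  strand <- unique(as.character(GenomicRanges::strand(ex)))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    stop("gene '", gene_id, "' has no single well-defined strand")
  }
  ex <- GenomicRanges::reduce(ex)
  gene_model(gene_id,
             chrom = as.character(GenomicRanges::seqnames(ex))[1L],
             strand = strand,
             exons = cbind(GenomicRanges::start(ex), GenomicRanges::end(ex)))
}

load_gene_model_tsv <- function(path, gene_id) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(tab))) {
    stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
  }
  if ("gene_id" %in% names(tab)) {
    tab <- tab[tab$gene_id == gene_id, , drop = FALSE]
    if (nrow(tab) == 0L) stop("gene '", gene_id, "' not found in ", path)
  }
  gene_model(gene_id, chrom = tab$chrom[1L], strand = tab$strand[1L],
             exons = cbind(tab$exon_start, tab$exon_end))
}

gene_span <- function(model) {
  c(min(model$exons[, "start"]), max(model$exons[, "end"]))
}

#' Convert genomic to gene-relative coordinates
#'
#' Gene-relative positions are 1-based distances from the TSS in the
#' direction of transcription, introns included (position 1 = TSS).
#'
#' @param pos_genomic Integer vector of genomic positions (1-based).
#' @param model A [gene_model()].
#' @return Integer vector of gene-relative positions.
#' @export
genomic_to_relative <- function(pos_genomic, model) {
  sp <- gene_span(model)
  if (any(pos_genomic < sp[1L] | pos_genomic > sp[2L])) {
    stop("position outside the gene span [", sp[1L], ", ", sp[2L], "]")
  }
  if (model$strand == "+") {
    as.integer(pos_genomic - model$tss_genomic + 1L)
  } else {
    as.integer(model$tss_genomic - pos_genomic + 1L)
  }
}

#' Convert gene-relative back to genomic coordinates
#'
#' Inverse of [genomic_to_relative()].
#'
#' @inheritParams genomic_to_relative
#' @param pos_rel Integer vector of gene-relative positions (>= 1).
#' @return Integer vector of genomic positions.
#' @export
relative_to_genomic <- function(pos_rel, model) {
  if (any(pos_rel < 1L)) stop("gene-relative positions are >= 1")
  if (model$strand == "+") {
    as.integer(model$tss_genomic + pos_rel - 1L)
  } else {
    as.integer(model$tss_genomic - pos_rel + 1L)
  }
}

#' Donor (5' splice) sites of a gene model
#'
#' Splicing intermediates generated by 5' splice-site cleavage end at the last
#' nucleotide of the upstream exon, so their 3' ends contaminate nascent-RNA
#' 3'-end maps precisely at those nucleotides. This returns the gene-relative
#' position of the last nucleotide of every exon that is followed by an
#' intron; the terminal exon contributes nothing. A single-exon model yields
#' an empty set.
#'
#' @param model A [gene_model()].
#' @return Sorted integer vector of gene-relative donor positions.
#' @export
donor_sites <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) return(integer(0))
  ex <- model$exons[-n, , drop = FALSE]   # transcription order, drop terminal
  last_nt <- if (model$strand == "+") ex[, "end"] else ex[, "start"]
  sort(genomic_to_relative(last_nt, model))
}
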