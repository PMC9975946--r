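#' Simulate targeted nascent 3'-end reads with known ground truth
#'
#' Draws read 3'-end positions for one primer window under a multinomial
#' dwell model: every position has baseline weight 1, and each configured
#' pause range multiplies the weights of its positions by a genotype-specific
#' factor (a dwell-time multiplier; Pol II is observed more often where it
#' dwells longer). A fixed fraction of reads is planted uniformly on the
#' gene's donor sites to emulate splicing-intermediate contamination; the
#' split between signal and contaminant reads is exact
#' (`round(contamination * n_reads)` per replicate), only the placement is
#' stochastic.
#'
#' @param model A [gene_model()]; supplies the donor sites.
#' @param window A [primer_window()].
#' @param n_reads Reads per replicate (default 19000).
#' @param n_replicates Replicates per genotype (default 3).
#' @param genotypes Character vector of genotype labels, reference first
#'   (default `c("WT", "mut")`).
#' @param pause_sites List of pause specifications, each a list with
#'   `start`, `end` (gene-relative, inside the window) and `multiplier` — a
#'   named numeric vector of per-genotype dwell multipliers (unnamed single
#'   value = same multiplier for all genotypes).
#' @param contamination Fraction of reads placed at donor sites (default 0).
#' @param seed Integer seed; the same seed and parameters give identical
#'   output.
#' @return List with `reads` (a `read_ends` data frame with an extra
#'   `origin` column, `"signal"` or `"splice_intermediate"`) and `truth`
#'   (per-genotype position weights, expected per-bin log2 fold-changes for
#'   25-nt tiles, and the planted contaminant count per replicate).
#' @export
simulate_netseq <- function(model, window, n_reads = 19000L,
                            n_replicates = 3L,
                            genotypes = c("WT", "mut"),
                            pause_sites = list(),
                            contamination = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (contamination < 0 || contamination >= 1) {
    stop("contamination must be in [0, 1)")
  }
  pos <- window$positions
  donors <- donor_sites(model)
  n_contam <- as.integer(round(contamination * n_reads))
  if (n_contam > 0L && length(donors) == 0L) {
    stop("contamination > 0 requires a gene model with donor sites")
  }
  weights <- sapply(genotypes, function(g) {
    w <- rep(1, length(pos))
    for (ps in pause_sites) {
      if (ps$start < pos[1L] || ps$end > pos[length(pos)]) {
        stop("pause range [", ps$start, ", ", ps$end, "] outside the window")
      }
      m <- ps$multiplier
      mg <- if (is.null(names(m))) unname(m)[1L] else {
        if (!g %in% names(m)) 1 else unname(m[g])
      }
      w[pos >= ps$start & pos <= ps$end] <- w[pos >= ps$start & pos <= ps$end] * mg
    }
    w
  })
  reads <- list()
  for (g in genotypes) {
    for (r in seq_len(n_replicates)) {
      main <- sample(pos, n_reads - n_contam, replace = TRUE,
                     prob = weights[, g])
      cont <- if (n_contam > 0L) {
        donors[sample.int(length(donors), n_contam, replace = TRUE)]
      } else integer(0)
      reads[[paste(g, r)]] <- data.frame(
        rel_pos = c(main, cont),
        primer_id = window$primer_id,
        replicate_id = paste0("rep", r),
        genotype = g,
        origin = c(rep("signal", length(main)),
                   rep("splice_intermediate", length(cont))),
        stringsAsFactors = FALSE
      )
    }
  }
  reads <- do.call(rbind, reads)
  rownames(reads) <- NULL
  class(reads) <- c("read_ends", "data.frame")

  # closed-form expectations for 25-nt tiles: bin probability ratio alt/ref
  probs <- sweep(weights, 2, colSums(weights), "/")
  idx <- (pos - pos[1L]) %/% 25L
  bin_prob <- apply(probs, 2, function(p) as.numeric(tapply(p, idx, sum)))
  truth <- list(
    weights = weights,
    positions = pos,
    bin_start = bin_starts(pos[1L], length(pos), 25L),
    expected_log2_fc = if (length(genotypes) >= 2L) {
      log2(bin_prob[, genotypes[2L]] / bin_prob[, genotypes[1L]])
    } else NULL,
    n_contaminant_per_replicate = n_contam,
    donor_sites = donors
  )
  list(reads = reads, truth = truth)
}

#' Run the full targeted NET-seq density pipeline
#'
#' End-to-end orchestration: load (or accept) read ends, drop
#' splicing-intermediate 3' ends at donor sites, restrict to each primer's
#' window, build pseudocounted normalized density profiles per replicate,
#' average replicates per genotype, and test 25-nt bins between genotypes
#' with Bonferroni correction across all primers. Output tables are written
#' with a byte-stable format so identical inputs give identical files.
#'
#' @param reads A `read_ends` data frame (e.g. from [load_read_ends()] or
#'   [simulate_netseq()]).
#' @param model A [gene_model()].
#' @param windows List of [primer_window()] objects (the primer panel).
#' @param ref_genotype,alt_genotype Genotype labels to compare.
#' @param bin_nt,smooth_window,pseudocount Tuning parameters of the profile
#'   and bin comparison steps.
#' @param out_dir Optional output directory; when given, per-profile TSVs,
#'   the bin-comparison TSV and a JSON run summary are written there.
#' @return List with `profiles`, `averaged`, `bins`, `summary`.
#' @export
run_netseq <- function(reads, model, windows, ref_genotype, alt_genotype,
                       bin_nt = 25L, smooth_window = 11L, pseudocount = 0.1,
                       out_dir = NULL) {
  n_in <- nrow(reads)
  reads <- filter_splice_intermediates(reads, model)
  n_splice <- attr(reads, "n_removed")
  profiles <- list()
  for (w in windows) {
    in_win <- filter_primer_window(reads, w)
    for (g in unique(in_win$genotype)) {
      for (r in unique(in_win$replicate_id[in_win$genotype == g])) {
        sub <- in_win[in_win$genotype == g & in_win$replicate_id == r, ]
        sub <- sub[order(sub$rel_pos), , drop = FALSE]
        profiles[[paste(w$primer_id, g, r, sep = "|")]] <-
          build_profile(sub, w, pseudocount = pseudocount,
                        smooth_window = smooth_window)
      }
    }
  }
  genos <- vapply(profiles, profile_meta, character(1), what = "genotype")
  averaged <- do.call(rbind, lapply(windows, function(w) {
    prims <- vapply(profiles, profile_meta, character(1), what = "primer_id")
    av <- average_replicates(profiles[prims == w$primer_id])
    av$primer_id <- w$primer_id
    av
  }))
  bins <- compare_bins(profiles[genos == ref_genotype],
                       profiles[genos == alt_genotype], bin_nt = bin_nt)
  summary <- list(
    gene_id = model$gene_id,
    n_reads_in = n_in,
    n_splice_intermediates_removed = n_splice,
    n_profiles = length(profiles),
    primers = vapply(windows, `[[`, character(1), "primer_id"),
    ref_genotype = ref_genotype, alt_genotype = alt_genotype,
    n_bins = nrow(bins),
    n_significant_bins = sum(bins$p_bonf < 0.05)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(profiles)) {
      p <- profiles[[nm]]
      write_tsv_stable(
        data.frame(position = p$position, count = p$count,
                   ratio = p$ratio, smoothed = p$smoothed),
        file.path(out_dir, paste0("profile_", gsub("[|]", "_", nm), ".tsv")))
    }
    write_tsv_stable(as.data.frame(bins), file.path(out_dir, "bins.tsv"))
    write_tsv_stable(averaged, file.path(out_dir, "averaged_profiles.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(profiles = profiles, averaged = averaged, bins = bins,
       summary = summary)
}
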