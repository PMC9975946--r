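#' Nuclear-region foci of one cell
#'
#' Foci in the nucleus or nuclear periphery (the two compartments pooled for
#' transcription-site analysis), sorted by decreasing intensity with ties
#' broken by `focus_id` for determinism.
#'
#' @param cell A `foci` data frame restricted to one cell.
#' @return The nuclear-region subset, sorted.
#' @export
nuclear_foci <- function(cell) {
  nf <- cell[cell$compartment %in% c("nucleus", "periphery"), , drop = FALSE]
  nf <- nf[order(-nf$intensity, nf$focus_id), , drop = FALSE]
  rownames(nf) <- NULL
  nf
}

#' Single-transcript unit intensity of one cell
#'
#' Up to two nuclear foci of a diploid cell can be transcription sites, so
#' the two brightest nuclear-region foci are discarded and the mean
#' intensity of the remainder is the proxy for the brightness of one mature
#' transcript. Requires more than three nuclear-region foci (at least one
#' focus must remain after discarding two).
#'
#' @param cell A `foci` data frame restricted to one cell.
#' @return Unit intensity (arbitrary units).
#' @export
unit_intensity <- function(cell) {
  nf <- nuclear_foci(cell)
  if (nrow(nf) < 4L) {
    stop("cell ineligible for TS calling: ", nrow(nf),
         " nuclear-region foci (need >= 4)")
  }
  mean(nf$intensity[-(1:2)])
}

#' Call transcription sites in one cell
#'
#' Every nuclear-region focus (including the two brightest) gets a
#' fold-change relative to the cell's unit intensity; foci at or above
#' `ts_threshold` are transcription-site candidates, and when more than two
#' qualify only the two brightest are kept (a diploid cell has two alleles).
#'
#' @param cell A `foci` data frame restricted to one cell.
#' @param ts_threshold Fold-change threshold (default 1.6, inclusive).
#' @return Data frame `focus_id, fold_change` with at most two rows, sorted
#'   by decreasing fold-change. Cells whose unit intensity is not positive
#'   are flagged: an empty result with attribute `flag = "zero_unit"`.
#' @export
call_ts <- function(cell, ts_threshold = 1.6) {
  nf <- nuclear_foci(cell)
  unit <- unit_intensity(cell)   # errors on ineligible cells
  if (unit <= 0) {
    out <- data.frame(focus_id = integer(0), fold_change = numeric(0))
    attr(out, "flag") <- "zero_unit"
    return(out)
  }
  fc <- nf$intensity / unit
  cand <- which(fc >= ts_threshold)
  if (length(cand) > 2L) cand <- cand[1:2]   # nf sorted brightest-first
  data.frame(focus_id = nf$focus_id[cand], fold_change = fc[cand])
}

#' Summarize transcription-site calls for one genotype
#'
#' Per cell: eligibility (>= 4 nuclear-region foci), unit intensity and TS
#' calls; aggregated: total TS count, active-transcription frequency
#' (TS per allele, i.e. `n_ts / (2 * n_cells)` over all analyzed cells by
#' default), the TS fold-change values (the burst-size proxy), and per-cell
#' cytoplasmic focus counts. When `embryo_id` is present, per-embryo
#' frequencies are also computed.
#'
#' @param foci A `foci` data frame for one genotype (several cells).
#' @param ts_threshold Fold-change threshold (default 1.6).
#' @param eligible_only If `TRUE`, the frequency denominator counts only
#'   eligible cells. Default `FALSE`: all analyzed cells, matching the
#'   definition "number of TS / (2 x total number of cells)".
#' @return Object of class `burst_summary`: list with `genotype`,
#'   `n_cells`, `n_eligible`, `n_ts`, `ts_frequency`, `ts_fc_values`,
#'   `mean_ts_fc`, `cyto_counts`, `per_cell` (per-cell table), and
#'   `embryo_frequency` when embryos are annotated.
#' @export
summarize_genotype <- function(foci, ts_threshold = 1.6,
                               eligible_only = FALSE) {
  if (nrow(foci) == 0L) stop("empty foci table")
  genotype <- if ("genotype" %in% names(foci)) {
    unique(foci$genotype)
  } else NA_character_
  if (length(genotype) > 1L) {
    stop("foci table mixes genotypes; summarize one at a time")
  }
  cells <- split(as.data.frame(foci), foci$cell_id)
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    nf <- nuclear_foci(cell)
    eligible <- nrow(nf) >= 4L
    unit <- NA_real_; n_ts <- 0L; fcs <- numeric(0); flag <- ""
    if (eligible) {
      unit <- unit_intensity(cell)
      ts <- call_ts(cell, ts_threshold)
      if (identical(attr(ts, "flag"), "zero_unit")) flag <- "zero_unit"
      n_ts <- nrow(ts)
      fcs <- ts$fold_change
    }
    data.frame(cell_id = cell$cell_id[1L],
               embryo_id = if ("embryo_id" %in% names(cell))
                 cell$embryo_id[1L] else NA,
               n_foci = nrow(cell),
               n_nuclear = nrow(nf),
               n_cyto = sum(cell$compartment == "cytoplasm"),
               eligible = eligible,
               unit_intensity = unit,
               n_ts = n_ts,
               ts_fc = I(list(fcs)),
               flag = flag,
               stringsAsFactors = FALSE)
  }))
  rownames(per_cell) <- NULL
  n_cells <- nrow(per_cell)
  n_elig <- sum(per_cell$eligible)
  n_ts <- sum(per_cell$n_ts)
  denom_cells <- if (eligible_only) n_elig else n_cells
  ts_fc_values <- unlist(per_cell$ts_fc)
  out <- list(
    genotype = genotype,
    n_cells = n_cells,
    n_eligible = n_elig,
    n_ts = n_ts,
    ts_frequency = if (denom_cells > 0L) n_ts / (2 * denom_cells) else 0,
    ts_fc_values = ts_fc_values,
    mean_ts_fc = if (length(ts_fc_values)) mean(ts_fc_values) else NA_real_,
    no_ts_flag = length(ts_fc_values) == 0L,
    cyto_counts = per_cell$n_cyto,
    per_cell = per_cell
  )
  if (!all(is.na(per_cell$embryo_id))) {
    emb <- split(per_cell, per_cell$embryo_id)
    out$embryo_frequency <- vapply(emb, function(e) {
      d <- if (eligible_only) sum(e$eligible) else nrow(e)
      if (d > 0L) sum(e$n_ts) / (2 * d) else 0
    }, numeric(1))
  }
  class(out) <- "burst_summary"
  out
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<burst_summary> genotype %s: %d cells (%d eligible), %d TS\n",
    "  active-transcription frequency: %.3f TS/allele\n",
    "  mean TS fold-change (burst-size proxy): %s\n",
    "  mean cytoplasmic foci per cell: %.2f\n"),
    x$genotype, x$n_cells, x$n_eligible, x$n_ts, x$ts_frequency,
    if (is.na(x$mean_ts_fc)) "NA (no TS)" else sprintf("%.2f", x$mean_ts_fc),
    mean(x$cyto_counts)))
  invisible(x)
}

tukey_box <- function(v) {
  st <- grDevices::boxplot.stats(v)$stats
  list(lower_whisker = st[1L], q1 = st[2L], median = st[3L], q3 = st[4L],
       upper_whisker = st[5L])
}

#' Compare two genotype summaries
#'
#' For each of: per-cell cytoplasmic focus counts, TS fold-change values,
#' and per-embryo active-transcription frequencies — reports group means,
#' a two-tailed Student's (pooled-variance) t-test p-value, and Tukey
#' box-plot statistics (whiskers at the most extreme values within 1.5 IQR
#' of the box). A quantity with fewer than two values in either group is
#' skipped with a flag instead of tested.
#'
#' @param summary_a,summary_b [summarize_genotype()] outputs.
#' @return List of class `genotype_comparison`, one entry per quantity with
#'   `mean_a`, `mean_b`, `p_value` (or `skipped = TRUE`), and `box_a`/`box_b`.
#' @export
compare_genotypes <- function(summary_a, summary_b) {
  quantities <- list(
    cytoplasmic_counts = list(a = summary_a$cyto_counts,
                              b = summary_b$cyto_counts),
    ts_fold_change = list(a = summary_a$ts_fc_values,
                          b = summary_b$ts_fc_values),
    embryo_ts_frequency = list(a = summary_a$embryo_frequency,
                               b = summary_b$embryo_frequency)
  )
  out <- lapply(quantities, function(q) {
    if (is.null(q$a) || is.null(q$b) || length(q$a) < 2L || length(q$b) < 2L) {
      return(list(skipped = TRUE,
                  reason = "fewer than 2 values in at least one group",
                  n_a = length(q$a), n_b = length(q$b)))
    }
    list(skipped = FALSE,
         n_a = length(q$a), n_b = length(q$b),
         mean_a = mean(q$a), mean_b = mean(q$b),
         p_value = pooled_t_p(q$a, q$b),
         box_a = tukey_box(q$a), box_b = tukey_box(q$b))
  })
  out$genotype_a <- summary_a$genotype
  out$genotype_b <- summary_b$genotype
  class(out) <- "genotype_comparison"
  out
}

#' Run the burst-quantification pipeline on a foci table
#'
#' Splits a foci table by genotype, summarizes each, and (for exactly two
#' genotypes) compares them. When `out_dir` is given, writes a per-cell TS
#' table TSV, a per-genotype summary JSON and a comparison JSON.
#'
#' @param foci Foci data frame (or TSV path) with a `genotype` column.
#' @param ts_threshold Fold-change threshold (default 1.6).
#' @param eligible_only Frequency denominator restricted to eligible cells.
#' @param out_dir Optional output directory.
#' @return List with `summaries` (per genotype) and `comparison` (or NULL).
#' @export
run_burst <- function(foci, ts_threshold = 1.6, eligible_only = FALSE,
                      out_dir = NULL) {
  if (is.character(foci)) {
    foci <- utils::read.table(foci, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  if (!"genotype" %in% names(foci)) stop("foci table lacks a genotype column")
  summaries <- lapply(split(foci, foci$genotype), summarize_genotype,
                      ts_threshold = ts_threshold,
                      eligible_only = eligible_only)
  comparison <- if (length(summaries) == 2L) {
    compare_genotypes(summaries[[1L]], summaries[[2L]])
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    percell <- do.call(rbind, lapply(names(summaries), function(g) {
      pc <- summaries[[g]]$per_cell
      data.frame(genotype = g,
                 pc[, c("cell_id", "embryo_id", "n_foci", "n_nuclear",
                        "n_cyto", "eligible", "unit_intensity", "n_ts")],
                 stringsAsFactors = FALSE)
    }))
    write_tsv_stable(percell, file.path(out_dir, "cells.tsv"))
    jsonlite::write_json(
      lapply(summaries, function(s) s[setdiff(names(s), "per_cell")]),
      file.path(out_dir, "summaries.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(comparison)) {
      jsonlite::write_json(unclass(comparison),
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  list(summaries = summaries, comparison = comparison)
}
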