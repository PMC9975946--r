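#' Simulate per-cell smFISH foci tables with ground truth
#'
#' Emulates the statistical structure of single-molecule FISH data from
#' diploid cells: each cell carries a Poisson number of mature transcripts
#' of unit brightness (multiplicative lognormal noise with the given CV,
#' mean exactly 1), distributed between the nuclear region and the
#' cytoplasm; each of the two alleles is independently active with
#' probability `p_allele_on` and, when active, contributes one
#' transcription-site focus in the nucleus whose brightness is the burst
#' size (number of nascent transcripts) times the unit intensity, with the
#' same multiplicative noise. Nuclear-region mature transcripts split evenly
#' between nucleus and periphery; TS foci sit in the nucleus proper
#' (transcription is chromatin-bound).
#'
#' @param n_cells Number of cells.
#' @param mature_count_mean Poisson mean of mature transcripts per cell
#'   (default 20, the typical per-cell focus count in salt-stressed
#'   wild-type embryos).
#' @param p_nuclear Probability a mature transcript is nuclear-region
#'   (default 0.3).
#' @param p_allele_on Per-allele activity probability (default 0.5).
#' @param burst_size Burst size `b` (>= 1): fixed value, or the mean of a
#'   geometric distribution when `burst_dist = "geometric"`.
#' @param burst_dist `"fixed"` (default) or `"geometric"`.
#' @param unit_intensity_mean Mean single-transcript intensity, a.u.
#' @param intensity_cv Lognormal coefficient of variation of intensities
#'   (default 0.1).
#' @param genotype,embryo_ids Labels written into the table; cells are
#'   assigned to embryos round-robin.
#' @param seed Integer seed.
#' @return List with `foci` (a `foci`-style data frame with `genotype`,
#'   `embryo_id` columns) and `truth` (one row per focus: `type`
#'   "mature"/"TS" and the drawn burst size).
#' @export
simulate_cells <- function(n_cells, mature_count_mean = 20,
                           p_nuclear = 0.3, p_allele_on = 0.5,
                           burst_size = 5, burst_dist = c("fixed", "geometric"),
                           unit_intensity_mean = 1, intensity_cv = 0.1,
                           genotype = "WT", embryo_ids = "embryo1",
                           seed = NULL) {
  burst_dist <- match.arg(burst_dist)
  for (p in c(p_nuclear, p_allele_on)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (burst_size < 1) stop("burst_size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  foci <- list(); truth <- list()
  for (ci in seq_len(n_cells)) {
    n_mat <- stats::rpois(1L, mature_count_mean)
    comp <- character(0); intens <- numeric(0); type <- character(0)
    b_out <- numeric(0)
    if (n_mat > 0L) {
      nuclear <- stats::runif(n_mat) < p_nuclear
      comp <- ifelse(nuclear,
                     ifelse(stats::runif(n_mat) < 0.5, "nucleus", "periphery"),
                     "cytoplasm")
      intens <- unit_intensity_mean * lognormal_noise(n_mat, intensity_cv)
      type <- rep("mature", n_mat)
      b_out <- rep(NA_real_, n_mat)
    }
    for (allele in 1:2) {
      if (stats::runif(1L) < p_allele_on) {
        b <- if (burst_dist == "fixed") burst_size else {
          stats::rgeom(1L, prob = 1 / burst_size) + 1L
        }
        comp <- c(comp, "nucleus")
        intens <- c(intens,
                    b * unit_intensity_mean * lognormal_noise(1L, intensity_cv))
        type <- c(type, "TS")
        b_out <- c(b_out, b)
      }
    }
    if (length(comp) == 0L) next
    foci[[ci]] <- data.frame(
      genotype = genotype,
      embryo_id = embryo_ids[(ci - 1L) %% length(embryo_ids) + 1L],
      cell_id = ci,
      focus_id = seq_along(comp),
      compartment = comp,
      intensity = intens,
      stringsAsFactors = FALSE
    )
    truth[[ci]] <- data.frame(cell_id = ci, focus_id = seq_along(comp),
                              type = type, burst_size = b_out,
                              stringsAsFactors = FALSE)
  }
  foci <- do.call(rbind, foci)
  rownames(foci) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  class(foci) <- c("foci", "data.frame")
  list(foci = foci, truth = truth)
}
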