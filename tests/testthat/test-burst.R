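test_that("nuclear foci pool nucleus and periphery, sorted deterministically", {
  cell <- data.frame(focus_id = 1:3, cell_id = 1,
                     compartment = c("nucleus", "cytoplasm", "periphery"),
                     intensity = c(5, 9, 7))
  nf <- nuclear_foci(cell)
  expect_equal(nf$focus_id, c(3L, 1L))
  expect_equal(nrow(nuclear_foci(make_cell(c(1, 2), "cytoplasm"))), 0L)
  # exact intensity tie: ordered by focus_id
  tie <- make_cell(c(3, 3))
  expect_equal(nuclear_foci(tie)$focus_id, c(1L, 2L))
})

test_that("unit intensity discards the two brightest and needs > 3 nuclear foci", {
  expect_equal(unit_intensity(make_cell(c(16, 10, 10, 10, 10))), 10)
  expect_equal(unit_intensity(make_cell(c(20, 10, 8, 6))), 7)
  expect_error(unit_intensity(make_cell(c(5, 5, 5))), "ineligible")
  # cytoplasmic foci never enter the unit intensity
  cell <- rbind(make_cell(c(20, 10, 8, 6)),
                data.frame(focus_id = 5L, cell_id = 1L,
                           compartment = "cytoplasm", intensity = 1000))
  expect_equal(unit_intensity(cell), 7)
})

test_that("TS calls honour the inclusive 1.6x threshold and the two-allele cap", {
  ts <- call_ts(make_cell(c(16, 10, 10, 10, 10)))
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$fold_change, 1.6)       # boundary is TS-qualifying
  # just below threshold: no TS
  expect_equal(nrow(call_ts(make_cell(c(15.9, 10, 10, 10, 10)))), 0L)
  # more than two candidates: the two brightest win
  cell <- make_cell(c(20, 18, 17, 8, 9, 8, 8, 9, 9, 9))
  u <- unit_intensity(cell)
  expect_true(all(c(20, 18, 17) / u >= 1.6))   # three candidates
  ts3 <- call_ts(cell)
  expect_equal(nrow(ts3), 2L)
  expect_equal(ts3$focus_id, c(1L, 2L))
  expect_equal(ts3$fold_change, c(20, 18) / u)
  expect_error(call_ts(make_cell(c(5, 5, 5))), "ineligible")
})

test_that("TS calling is invariant to intensity rescaling", {
  base <- c(18, 11, 10, 9, 10, 8)
  for (c_mult in c(0.01, 1, 250)) {
    ts <- call_ts(make_cell(base * c_mult))
    expect_equal(ts$fold_change, call_ts(make_cell(base))$fold_change)
  }
})

test_that("raising the TS threshold never increases the number of calls", {
  set.seed(13)
  sim <- simulate_cells(50, p_allele_on = 0.7, burst_size = 3,
                        intensity_cv = 0.15, seed = 13)
  n_ts <- vapply(c(1.2, 1.6, 2, 3, 5), function(th) {
    summarize_genotype(sim$foci, ts_threshold = th)$n_ts
  }, numeric(1))
  expect_true(all(diff(n_ts) <= 0))
})

test_that("genotype summaries count TS per allele over all cells", {
  # 10 cells, all eligible, one forced TS in 4 of them
  foci <- do.call(rbind, lapply(1:10, function(i) {
    ints <- if (i <= 4) c(20, 10, 10, 10, 10) else c(10, 10, 10, 10, 10)
    cbind(make_cell(ints, cell_id = i), genotype = "WT")
  }))
  s <- summarize_genotype(foci)
  expect_equal(s$n_cells, 10L)
  expect_equal(s$n_ts, 4L)
  expect_equal(s$ts_frequency, 4 / 20)
  expect_equal(s$mean_ts_fc, 2)
  # no eligible cells: zero frequency, flagged undefined mean
  tiny <- cbind(make_cell(c(5, 5)), genotype = "WT")
  s0 <- summarize_genotype(tiny)
  expect_equal(s0$n_ts, 0L)
  expect_equal(s0$ts_frequency, 0)
  expect_true(s0$no_ts_flag)
  expect_true(is.na(s0$mean_ts_fc))
})

test_that("ts_frequency stays in [0, 1] and equals n_ts / (2 n_cells)", {
  set.seed(77)
  for (i in 1:8) {
    sim <- simulate_cells(40, mature_count_mean = sample(5:30, 1),
                          p_nuclear = runif(1, 0.1, 0.9),
                          p_allele_on = runif(1),
                          burst_size = sample(2:8, 1),
                          intensity_cv = runif(1, 0, 0.3))
    s <- summarize_genotype(sim$foci)
    expect_gte(s$ts_frequency, 0)
    expect_lte(s$ts_frequency, 1)
    expect_equal(s$ts_frequency, s$n_ts / (2 * s$n_cells))
    expect_lte(s$n_ts, 2L * s$n_eligible)
  }
  # silent alleles give frequency 0
  off <- simulate_cells(50, p_allele_on = 0, seed = 1)
  expect_equal(summarize_genotype(off$foci)$ts_frequency, 0)
  # two active alleles per cell, noise-free, abundant nuclear foci: frequency 1
  on <- simulate_cells(50, mature_count_mean = 30, p_nuclear = 0.9,
                       p_allele_on = 1, burst_size = 5, intensity_cv = 0,
                       seed = 2)
  expect_equal(summarize_genotype(on$foci)$ts_frequency, 1)
})

test_that("burst size is recovered by the mean TS fold-change", {
  # noise-free: exact
  sim0 <- simulate_cells(100, p_allele_on = 1, burst_size = 4,
                         intensity_cv = 0, seed = 3)
  expect_equal(summarize_genotype(sim0$foci)$mean_ts_fc, 4)
  # 10% intensity CV: within 15% relative error for every burst size
  for (b in 2:8) {
    sim <- simulate_cells(200, p_allele_on = 1, burst_size = b,
                          intensity_cv = 0.1, seed = 100 + b)
    fc <- summarize_genotype(sim$foci)$mean_ts_fc
    expect_lt(abs(fc - b) / b, 0.15)
  }
})

test_that("genotype comparison tests the right quantities and flags small groups", {
  sim_a <- simulate_cells(80, p_allele_on = 0.8, burst_size = 5,
                          embryo_ids = paste0("e", 1:4), seed = 41)
  sim_b <- simulate_cells(80, p_allele_on = 0.3, burst_size = 2,
                          embryo_ids = paste0("e", 5:8), seed = 42)
  cmp <- compare_genotypes(summarize_genotype(sim_a$foci),
                           summarize_genotype(sim_b$foci))
  expect_false(cmp$ts_fold_change$skipped)
  expect_gt(cmp$ts_fold_change$mean_a, cmp$ts_fold_change$mean_b)
  expect_lt(cmp$ts_fold_change$p_value, 0.01)
  expect_false(cmp$embryo_ts_frequency$skipped)
  # boxplot stats follow the 1.5 IQR whisker convention
  box <- cmp$cytoplasmic_counts$box_a
  expect_lte(box$q1, box$median)
  expect_lte(box$median, box$q3)
  st <- grDevices::boxplot.stats(sim_a$foci$intensity)$stats
  tb <- netburst:::tukey_box(sim_a$foci$intensity)
  expect_equal(unlist(tb, use.names = FALSE), st)
  # identical groups: mean difference 0, p = 1
  same <- compare_genotypes(summarize_genotype(sim_a$foci),
                            summarize_genotype(sim_a$foci))
  expect_equal(same$cytoplasmic_counts$p_value, 1)
  # fewer than two values: skipped with a flag
  s_small <- summarize_genotype(cbind(make_cell(c(5, 5)), genotype = "WT"))
  cmp2 <- compare_genotypes(s_small, summarize_genotype(sim_b$foci))
  expect_true(cmp2$ts_fold_change$skipped)
})

test_that("the comparison t-test keeps its nominal type-I error and power", {
  set.seed(55)
  fake_summary <- function(counts) {
    structure(list(genotype = "g", cyto_counts = counts,
                   ts_fc_values = NULL, embryo_frequency = NULL),
              class = "burst_summary")
  }
  # null: both groups from one distribution
  p_null <- replicate(100, {
    compare_genotypes(fake_summary(rpois(200, 20)),
                      fake_summary(rpois(200, 20)))$cytoplasmic_counts$p_value
  })
  frac <- mean(p_null < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
  # strong effect: 20 vs 10 counts, n = 150
  p_eff <- replicate(20, {
    compare_genotypes(fake_summary(rpois(150, 20)),
                      fake_summary(rpois(150, 10)))$cytoplasmic_counts$p_value
  })
  expect_gte(mean(p_eff < 0.001), 0.95)
})
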