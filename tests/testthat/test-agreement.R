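test_that("group summaries report mean, SD, SD% and t-based confidence limits", {
  x <- c(-16.2, -13.1, -7.9, -11.4, -9.8, -14.5, -10.4)
  gs <- group_summary(x)
  expect_equal(gs$mean, mean(x))
  expect_equal(gs$sd, sd(x))
  expect_equal(gs$sd_pct, 100 * sd(x) / abs(mean(x)))
  expect_equal(gs$ci_low, mean(x) - qt(0.975, 6) * sd(x) / sqrt(7))
  expect_equal(gs$ci_high, mean(x) + qt(0.975, 6) * sd(x) / sqrt(7))
  const <- group_summary(rep(3.2, 5))
  expect_equal(const$sd, 0)
  expect_equal(const$sd_pct, 0)
  expect_equal(const$ci_low, 3.2)
  expect_equal(const$ci_high, 3.2)
  expect_error(group_summary(5), "at least 2")
})

test_that("SD as a percentage of the mean reproduces printed summary columns", {
  expect_equal(round(sd_percent_of_mean(4.1, -11.9), 1), 34.5)
  expect_equal(round(sd_percent_of_mean(7.8, 123.8), 1), 6.3)
})

test_that("paired comparisons match the closed-form paired t-test", {
  a <- c(1, 2, 3); b <- c(2, 3, 5)
  pc <- paired_comparison(a, b)
  expect_equal(pc$mean_difference, -4 / 3)
  expect_equal(pc$sd_difference, sd(a - b))
  expect_equal(pc$sd_difference, 0.577, tolerance = 1e-3)
  # independent oracle: t = mean(d) / (sd(d) / sqrt(n)), two-sided p from pt()
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(pc$p, 2 * pt(-abs(t_stat), 2))
  expect_lt(abs(pc$p - 0.0572), 1e-4)
  expect_equal(pc$mean_of_attempts, mean((a + b) / 2))
  # identical groups: zero difference, p undefined and flagged
  same <- paired_comparison(a, a)
  expect_equal(same$mean_difference, 0)
  expect_false(same$p_defined)
  expect_true(is.na(same$p))
  expect_error(paired_comparison(1:3, 1:4), "same length")
})

test_that("pairing identity holds to machine precision", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(7, 100, 10); b <- rnorm(7, 95, 10)
    pc <- paired_comparison(a, b)
    expect_equal(pc$mean_difference, mean(a) - mean(b), tolerance = 1e-12)
    # antisymmetry under group swap, p unchanged
    rev_pc <- paired_comparison(b, a)
    expect_equal(rev_pc$mean_difference, -pc$mean_difference)
    expect_equal(rev_pc$p, pc$p)
  }
})

test_that("derived paired columns follow from group means alone", {
  pm <- paired_means(-11.9, -10.5)
  expect_equal(pm$mean_of_attempts, -11.2)
  expect_equal(pm$mean_difference, -1.4)
})

test_that("Bonferroni threshold divides alpha and reports at 3 decimals", {
  expect_equal(bonferroni_threshold(0.05, 7), 0.05 / 7)
  expect_equal(bonferroni_threshold(0.05, 7, report = TRUE), 0.007)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  for (m in c(2, 5, 7, 28)) expect_equal(bonferroni_threshold(0.05, m) * m, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.2, 7), "alpha")
})

test_that("Bland-Altman bias and limits follow the paired-difference model", {
  x <- c(10, 11, 12, 13)
  ident <- bland_altman(x, x)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_low, 0)
  expect_equal(ident$loa_high, 0)
  shift <- bland_altman(x, x - 1.9)
  expect_equal(shift$bias, -1.9)
  expect_equal(shift$loa_high - shift$loa_low, 0)
  expect_error(bland_altman(1:3, 1:4), "paired")
  # Monte-Carlo against the normal model for the differences
  set.seed(8)
  sigma <- 0.5
  base <- rnorm(1000, 14, 1)
  ba <- bland_altman(base, base + rnorm(1000, 0.6, sigma))
  expect_lt(abs(ba$bias - 0.6), 3 * sigma / sqrt(1000))
  expect_equal(ba$loa_low, 0.6 - 1.96 * sigma, tolerance = 0.05)
  expect_equal(ba$loa_high, 0.6 + 1.96 * sigma, tolerance = 0.05)
})

test_that("single-run duplication produces two flagged, identical repetitions", {
  rows <- tibble::tibble(reader = 0L, repetition = 1L, value = c(4.2, 4.4))
  dup <- duplicate_single_run(rows)
  expect_equal(nrow(dup), 4L)
  expect_equal(sort(unique(dup$repetition)), c(1L, 2L))
  expect_true(all(dup$duplicated_run))
  expect_equal(dup$value[dup$repetition == 1], dup$value[dup$repetition == 2])
  # paired comparison of the duplicated groups is forced to zero difference
  pc <- paired_comparison(dup$value[dup$repetition == 1],
                          dup$value[dup$repetition == 2])
  expect_equal(pc$mean_difference, 0)
  expect_false(pc$p_defined)
  expect_error(duplicate_single_run(dup), "more than one repetition")
})

test_that("summary and comparison tables have the designed shape and flags", {
  cfg <- small_config()
  met <- study_metrics(measure_study(generate_study(cfg)))
  t1 <- build_table1(met)
  expect_equal(nrow(t1), 7 * 2 * 2)  # 7 metrics x 2 software x 2 repetitions
  expect_true(all(t1$ci_low <= t1$mean & t1$mean <= t1$ci_high))
  expect_true(all(t1$sd >= 0))
  t2 <- build_table2(met)
  expect_equal(nrow(t2), 7 * 4)  # 7 metrics x (2 intra + 2 inter)
  expect_equal(unique(t2$p_threshold), 0.05 / 7)
  # the injected inter-software volume bias must fire the significance flag
  edv_inter <- t2[t2$kind == "inter" & t2$metric == "EDV", ]
  expect_true(all(edv_inter$significant))
  # intra-software comparisons carry no injected bias
  expect_true(all(abs(t2$mean_difference[t2$kind == "intra" & t2$metric == "EDV"]) < 1))
  # alpha = 1 - epsilon flags every defined comparison
  t2_all <- build_table2(met, alpha = 0.999, m = 1)
  expect_true(all(t2_all$significant[t2_all$p_defined]))
})

test_that("swapping the software group order negates differences, keeps p", {
  cfg <- small_config()
  met <- study_metrics(measure_study(generate_study(cfg, include_automated = FALSE)))
  met_swapped <- met
  met_swapped$software <- factor(met$software, levels = c("ScanIP", "OsiriX"))
  met_swapped <- met_swapped[order(met_swapped$software), ]
  met_swapped$software <- as.character(met_swapped$software)
  t2a <- build_table2(met)
  t2b <- build_table2(met_swapped)
  inter_a <- t2a[t2a$kind == "inter", ]
  inter_b <- t2b[t2b$kind == "inter", ]
  ord <- order(inter_a$comparison, inter_a$metric)
  ordb <- order(inter_b$comparison, inter_b$metric)
  expect_equal(inter_b$mean_difference[ordb], -inter_a$mean_difference[ord])
  expect_equal(inter_b$p[ordb], inter_a$p[ord])
})

test_that("study-level Bland-Altman recovers injected software offsets", {
  cfg <- small_config()
  meas <- measure_study(generate_study(cfg))
  ba <- bland_altman_study(meas)
  expect_setequal(unique(ba$comparison),
                  c("ScanIP vs OsiriX", "OsiriX vs CVI42", "ScanIP vs CVI42"))
  expect_setequal(unique(ba$repetition), c("1", "2", "pooled"))
  sc_os <- ba[ba$comparison == "ScanIP vs OsiriX" & ba$repetition == "pooled", ]
  expect_equal(sc_os$bias, -1.9, tolerance = 0.05)
  expect_false(sc_os$uses_duplicated_run)
  expect_true(all(ba$uses_duplicated_run[grepl("CVI42", ba$comparison)]))
  expect_true(all(ba$loa_low <= ba$bias & ba$bias <= ba$loa_high))
  # per-repetition n: readers x slices x frames
  expect_equal(sc_os$n, 2 * cfg$n_readers * cfg$n_slices * cfg$n_frames)
})

test_that("type-I error rate of the corrected comparison table stays below alpha", {
  # null studies: default reader noise, no software bias anywhere
  n_studies <- 20
  flags <- logical(0)
  for (i in seq_len(n_studies)) {
    cfg <- phantom_config(n_frames = 6, seed = 1000 + i,
                          software_length_bias = c(A = 0, B = 0))
    met <- study_metrics(measure_study(generate_study(cfg, include_automated = FALSE),
                                       samples_per_segment = 60))
    t2 <- build_table2(met)
    flags <- c(flags, t2$significant)
  }
  expect_lte(mean(flags), 0.05)
})
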