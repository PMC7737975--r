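# Agreement-statistics layer: group summaries, paired intra-/inter-software
# comparisons with Bonferroni correction, Bland-Altman analysis of contour
# lengths, and the single-run duplication rule for automated software.

METRIC_LEVELS <- c("ACS", "MCS", "BCS", "GCS", "EDV", "ESV", "LVEF")

#' Standard deviation as a percentage of the mean
#'
#' `100 * sd / |mean|`, the dispersion measure reported alongside group means.
#'
#' @param sd Standard deviation.
#' @param mean Mean (its sign is ignored).
#' @return SD as percent of the absolute mean (`NaN` when the mean is 0).
#' @export
sd_percent_of_mean <- function(sd, mean) {
  100 * sd / abs(mean)
}

#' Summarise one metric for one group of readers
#'
#' Sample mean, sample SD (n - 1 denominator), SD as a percentage of the mean,
#' and a t-based 95 percent confidence interval
#' `mean +/- t(0.975, n - 1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector, one value per reader (n >= 2).
#' @return A one-row tibble: `n`, `mean`, `sd`, `sd_pct`, `ci_low`, `ci_high`.
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("group_summary needs at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s,
                 sd_pct = sd_percent_of_mean(s, m),
                 ci_low = m - half, ci_high = m + half)
}

#' Paired comparison of one metric between two groups
#'
#' Reader-paired differences `d_i = a_i - b_i` with the two-sided paired
#' t-test. `mean_of_attempts` is the mean over readers of the two-group
#' average `(a_i + b_i) / 2`; by pairing, `mean_difference` equals the
#' difference of the two group means exactly. When the differences have zero
#' variance the t statistic is undefined and `p` is reported as `NA` with
#' `p_defined = FALSE`.
#'
#' @param a,b Numeric vectors of per-reader values, same readers in the same
#'   order, length >= 2.
#' @return A one-row tibble: `n`, `mean_of_attempts`, `mean_difference`,
#'   `sd_difference`, `sd_pct` (SD of differences as percent of
#'   `|mean_of_attempts|`), `p`, `p_defined`.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("paired groups must have the same length")
  if (length(a) < 2) stop("paired_comparison needs at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired groups")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    p <- NA_real_
    p_defined <- FALSE
  } else {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    p_defined <- TRUE
  }
  moa <- mean((a + b) / 2)
  tibble::tibble(n = length(a), mean_of_attempts = moa,
                 mean_difference = mean(d), sd_difference = sd_d,
                 sd_pct = sd_percent_of_mean(sd_d, moa),
                 p = p, p_defined = p_defined)
}

#' Paired-comparison columns implied by two group means
#'
#' Because pairing makes the mean paired difference equal the difference of
#' group means, the `mean_difference` and `mean_of_attempts` columns of a
#' paired-comparison table are determined by the two group means alone. This
#' helper reproduces those derived columns from published group means.
#'
#' @param mean_a,mean_b Group means (first and second group).
#' @return A one-row tibble: `mean_of_attempts`, `mean_difference`.
#' @export
paired_means <- function(mean_a, mean_b) {
  tibble::tibble(mean_of_attempts = (mean_a + mean_b) / 2,
                 mean_difference = mean_a - mean_b)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @param report Round the threshold to 3 decimals for reporting?
#' @return `alpha / m` (rounded if `report = TRUE`).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 7, report = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  thr <- alpha / m
  if (report) round(thr, 3) else thr
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement of two sets of measurements of the same
#' quantity. Differences are `d = y - x` (second argument minus first), so for
#' a comparison read as "A vs B" pass `x = B`, `y = A`: a negative bias is then
#' a bias "towards" A (A reads lower). The limits of agreement are
#' `bias +/- multiplier * sd(d)` with the 95 percent multiplier 1.96.
#'
#' @param x,y Paired numeric vectors (same length, n >= 2).
#' @param loa_multiplier Limits-of-agreement multiplier (1.96 for 95 percent).
#' @return A list of class `bland_altman`: `n`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, and a `points` tibble of per-pair (`mean`, `difference`).
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("bland_altman needs at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements")
  d <- y - x
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(n = length(d), bias = bias, sd_diff = sd_d,
                 loa_low = bias - loa_multiplier * sd_d,
                 loa_high = bias + loa_multiplier * sd_d,
                 loa_multiplier = loa_multiplier,
                 points = tibble::tibble(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  bias %.3f, limits of agreement [%.3f, %.3f] (bias +/- %.2f SD)\n",
              x$bias, x$loa_low, x$loa_high, x$loa_multiplier))
  invisible(x)
}

#' Duplicate a single-repetition session's rows
#'
#' Automated contouring performed once is treated as perfectly repeatable: its
#' rows are entered as both repetition 1 and repetition 2, flagged with
#' `duplicated_run = TRUE` so reports can surface the convention.
#'
#' @param rows A tibble carrying a `repetition` column with a single value.
#' @return The rows duplicated under repetitions 1 and 2.
#' @export
duplicate_single_run <- function(rows) {
  stopifnot("repetition" %in% names(rows))
  if (length(unique(rows$repetition)) != 1)
    stop("session already has more than one repetition")
  out <- dplyr::bind_rows(
    dplyr::mutate(rows, repetition = 1L),
    dplyr::mutate(rows, repetition = 2L))
  out$duplicated_run <- TRUE
  out
}

metrics_long <- function(metrics) {
  tidyr::pivot_longer(metrics, cols = dplyr::all_of(METRIC_LEVELS),
                      names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = METRIC_LEVELS))
}

#' Group summary table (per metric, software and repetition)
#'
#' One summary row per (metric, software, repetition) over the manual
#' sessions: means, SDs, SD as a percentage of the mean, and 95 percent
#' confidence intervals.
#'
#' @param metrics A per-session metrics tibble from [study_metrics()]; rows
#'   with `type != "manual"` are excluded (single-run automated software has no
#'   reader spread to summarise).
#' @return A tibble: `metric`, `software`, `repetition`, `n`, `mean`, `sd`,
#'   `sd_pct`, `ci_low`, `ci_high`.
#' @export
build_table1 <- function(metrics) {
  if ("type" %in% names(metrics)) metrics <- metrics[metrics$type == "manual", ]
  metrics_long(metrics) |>
    dplyr::group_by(.data$metric, .data$software, .data$repetition) |>
    dplyr::group_modify(function(d, key) group_summary(d$value)) |>
    dplyr::ungroup()
}

#' Paired-comparison table (intra- and inter-software)
#'
#' For every metric: the two within-software comparisons (repetition 1 minus
#' repetition 2, per software) and the two between-software comparisons at
#' each repetition (first configured software minus second), paired by reader,
#' flagged significant at the Bonferroni-corrected threshold `alpha / m`.
#'
#' @param metrics A per-session metrics tibble from [study_metrics()] (manual
#'   sessions; needs exactly two repetitions and at least two software labels;
#'   the first two labels, in order of appearance, form the inter-software
#'   comparisons).
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons for the Bonferroni correction; defaults to
#'   the number of metrics.
#' @return A tibble: `comparison`, `kind` (`intra`/`inter`), `metric`, the
#'   [paired_comparison()] columns, `p_threshold`, `significant`.
#' @export
build_table2 <- function(metrics, alpha = 0.05, m = NULL) {
  if ("type" %in% names(metrics)) metrics <- metrics[metrics$type == "manual", ]
  long <- metrics_long(metrics)
  softwares <- unique(long$software)
  reps <- sort(unique(long$repetition))
  if (length(softwares) < 2) stop("need at least two software groups")
  if (length(reps) != 2) stop("need exactly two repetitions")
  if (is.null(m)) m <- length(unique(long$metric))
  thr <- bonferroni_threshold(alpha, m)
  cell <- function(soft, rep) {
    d <- long[long$software == soft & long$repetition == rep, ]
    d[order(d$reader), c("reader", "metric", "value")]
  }
  compare <- function(da, db, label, kind) {
    dplyr::bind_rows(lapply(levels(long$metric), function(met) {
      a <- da[da$metric == met, ]
      b <- db[db$metric == met, ]
      if (!identical(a$reader, b$reader)) stop("reader sets differ between groups")
      out <- paired_comparison(a$value, b$value)
      dplyr::bind_cols(tibble::tibble(comparison = label, kind = kind,
                                      metric = met), out)
    }))
  }
  rows <- list()
  for (soft in softwares[1:2]) {
    rows[[length(rows) + 1L]] <- compare(
      cell(soft, reps[1]), cell(soft, reps[2]),
      sprintf("%s: T%d vs T%d", soft, reps[1], reps[2]), "intra")
  }
  for (rep in reps) {
    rows[[length(rows) + 1L]] <- compare(
      cell(softwares[1], rep), cell(softwares[2], rep),
      sprintf("T%d: %s vs %s", rep, softwares[1], softwares[2]), "inter")
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(metric = factor(.data$metric, levels = METRIC_LEVELS),
                  p_threshold = thr,
                  significant = !is.na(.data$p) & .data$p <= thr)
}

#' Bland-Altman analysis of contour lengths across a study
#'
#' Pools the per-slice perimeter lengths and runs [bland_altman()] for each
#' software pairing, per repetition and pooled over repetitions. Manual-manual
#' pairings are matched on (reader, slice, frame, repetition); pairings against
#' the automated software first apply the single-run duplication rule
#' ([duplicate_single_run()]) and match each reader's lengths to the automated
#' lengths on (slice, frame, repetition). Comparisons are labelled "A vs B"
#' with differences A minus B, so a negative bias is a bias towards A.
#'
#' @param measurements Output of [measure_study()].
#' @param pairings A list of 2-element character vectors `c(A, B)`; defaults to
#'   second-manual vs first-manual plus each manual vs the automated label when
#'   present.
#' @param loa_multiplier Limits-of-agreement multiplier.
#' @return A tibble: `comparison`, `repetition` (`"1"`, `"2"` or `"pooled"`),
#'   `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`, `uses_duplicated_run`.
#' @export
bland_altman_study <- function(measurements, pairings = NULL,
                               loa_multiplier = 1.96) {
  manual <- measurements[measurements$type == "manual", ]
  auto <- measurements[measurements$type == "automated", ]
  softwares <- unique(manual$software)
  if (is.null(pairings)) {
    pairings <- list()
    if (length(softwares) >= 2)
      pairings[[1]] <- c(softwares[2], softwares[1])
    if (nrow(auto) > 0) {
      auto_label <- unique(auto$software)
      for (soft in softwares)
        pairings[[length(pairings) + 1L]] <- c(soft, auto_label)
    }
  }
  if (nrow(auto) > 0) auto_dup <- duplicate_single_run(auto)
  one <- function(pair) {
    a_label <- pair[1]; b_label <- pair[2]
    pick <- function(label) {
      if (nrow(auto) > 0 && label %in% auto$software) auto_dup
      else dplyr::mutate(manual[manual$software == label, ],
                         duplicated_run = FALSE)
    }
    da <- pick(a_label); db <- pick(b_label)
    a_auto <- any(da$duplicated_run); b_auto <- any(db$duplicated_run)
    key <- if (a_auto || b_auto) c("slice", "frame", "repetition")
           else c("reader", "slice", "frame", "repetition")
    joined <- dplyr::inner_join(
      da[, unique(c(key, "perimeter_cm"))],
      db[, unique(c(key, "perimeter_cm"))],
      by = key, suffix = c("_a", "_b"),
      relationship = "many-to-many")
    per_rep <- lapply(sort(unique(joined$repetition)), function(rep) {
      j <- joined[joined$repetition == rep, ]
      ba <- bland_altman(j$perimeter_cm_b, j$perimeter_cm_a, loa_multiplier)
      tibble::tibble(comparison = sprintf("%s vs %s", a_label, b_label),
                     repetition = as.character(rep), n = ba$n, bias = ba$bias,
                     sd_diff = ba$sd_diff, loa_low = ba$loa_low,
                     loa_high = ba$loa_high,
                     uses_duplicated_run = a_auto || b_auto)
    })
    ba <- bland_altman(joined$perimeter_cm_b, joined$perimeter_cm_a,
                       loa_multiplier)
    dplyr::bind_rows(c(per_rep, list(
      tibble::tibble(comparison = sprintf("%s vs %s", a_label, b_label),
                     repetition = "pooled", n = ba$n, bias = ba$bias,
                     sd_diff = ba$sd_diff, loa_low = ba$loa_low,
                     loa_high = ba$loa_high,
                     uses_duplicated_run = a_auto || b_auto))))
  }
  dplyr::bind_rows(lapply(pairings, one))
}
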