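# The nine-test feature/model assessment: seven regression tests, two
# classification tests, median-rank aggregation within and across datasets,
# subsample robustness, and the shuffled-mean cell-specificity control.

cor_or_flag <- function(x, y, method) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(statistic = 0, p = 1, flagged = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(statistic = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

# quintile index of y by empirical quantiles, ties to the lower bin
quintile_index <- function(y) {
  brk <- quantile(y, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  # bin = 1 + number of breakpoints strictly below y
  vapply(y, function(v) 1L + sum(v > brk), integer(1))
}

#' The seven regression tests of one predictor against quantitative activity
#'
#' Pearson, Spearman and Kendall correlation of `x` with `y` over all
#' regions; the same three restricted to regions in the top quartile of `y`;
#' and Spearman of `x` against the quintile index of `y` (empirical
#' quintiles, ties to the lower bin). A constant predictor (or constant
#' restricted subset) yields statistic 0, p 1 and `flagged = TRUE`.
#'
#' @param x Numeric predictor (a feature or model predictions).
#' @param y Quantitative activity.
#'
#' @return A tibble with columns `test`, `statistic`, `p`, `flagged`.
#' @export
regression_tests <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 8) abort("regression tests need n >= 8")
  if (length(unique(y)) < 2) abort("`y` must have at least 2 distinct values")
  top <- y >= quantile(y, 0.75, names = FALSE)
  qi <- quintile_index(y)
  specs <- list(
    pearson      = list(x, y, "pearson"),
    spearman     = list(x, y, "spearman"),
    kendall      = list(x, y, "kendall"),
    pearson_top25  = list(x[top], y[top], "pearson"),
    spearman_top25 = list(x[top], y[top], "spearman"),
    kendall_top25  = list(x[top], y[top], "kendall"),
    spearman_quintile = list(x, qi, "spearman")
  )
  purrr::imap(specs, function(s, nm) {
    r <- cor_or_flag(s[[1]], s[[2]], s[[3]])
    tibble::tibble(test = nm, statistic = r$statistic, p = r$p,
                   flagged = r$flagged)
  }) |> dplyr::bind_rows()
}

#' Area under the ROC curve (rank statistic with tie correction)
#'
#' @param scores Numeric scores; higher means more likely positive.
#' @param labels Binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step-wise integration)
#'
#' Ranks scores descending, processes ties as blocks, and integrates
#' precision over recall increments.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || sum(labels == 0) == 0) abort("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  blocks <- rle(s)
  tp <- 0
  n_seen <- 0
  ap <- 0
  i <- 1
  for (len in blocks$lengths) {
    idx <- seq.int(i, i + len - 1)
    tp_new <- tp + sum(l[idx])
    n_new <- n_seen + len
    recall_inc <- (tp_new - tp) / n_pos
    precision <- tp_new / n_new
    ap <- ap + recall_inc * precision
    tp <- tp_new
    n_seen <- n_new
    i <- i + len
  }
  ap
}

#' The two classification tests plus their Kolmogorov-Smirnov significance
#'
#' AUROC and AUPRC of the scores against the binary labels; significance is
#' the two-sample KS test comparing score distributions of positive versus
#' negative regions.
#'
#' @inheritParams auroc
#' @return A tibble with columns `test` (`auroc`, `auprc`), `statistic`, `p`
#'   (the shared KS p-value) and `flagged`.
#' @export
classification_tests <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  ks <- suppressWarnings(ks.test(scores[labels == 1], scores[labels == 0]))
  tibble::tibble(
    test = c("auroc", "auprc"),
    statistic = c(auroc(scores, labels), auprc(scores, labels)),
    p = ks$p.value,
    flagged = FALSE
  )
}

#' Run the test suite for every feature of a dataset
#'
#' Applies the seven regression tests (when `y` is given) and the two
#' classification tests (when `labels` are given) to every feature column,
#' then adjusts p-values by Benjamini-Hochberg within each test.
#'
#' @param features Tibble with `region_id` plus numeric feature columns.
#' @param y Optional quantitative activity, aligned with `features` rows.
#' @param labels Optional binary labels, aligned likewise.
#'
#' @return A long tibble: `feature`, `test`, `statistic`, `p`, `q`,
#'   `flagged`.
#' @export
test_suite <- function(features, y = NULL, labels = NULL) {
  stopifnot(is.data.frame(features))
  if (is.null(y) && is.null(labels)) abort("supply `y` and/or `labels`")
  feats <- setdiff(names(features), "region_id")
  res <- purrr::map(feats, function(f) {
    x <- features[[f]]
    parts <- list()
    if (!is.null(y)) parts$reg <- regression_tests(x, y)
    if (!is.null(labels)) parts$cls <- classification_tests(x, labels)
    dplyr::bind_rows(parts) |> dplyr::mutate(feature = f, .before = 1)
  }) |> dplyr::bind_rows()
  res |>
    dplyr::group_by(.data$test) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
}

#' Within-dataset feature ranking (median of the nine per-test ranks)
#'
#' Per test, features are ranked descending by `|statistic|` for the
#' regression tests and by AUROC/AUPRC for the classification tests, with
#' average ranks for ties; the within-dataset rank of a feature is the
#' median of its per-test ranks.
#'
#' @param suite A [test_suite()] result.
#' @return A tibble `feature`, `rank`, sorted by rank.
#' @export
within_dataset_rank <- function(suite) {
  stopifnot(all(c("feature", "test", "statistic") %in% names(suite)))
  if (length(unique(suite$feature)) < 2) abort("ranking needs >= 2 features")
  ranked <- suite |>
    dplyr::group_by(.data$test) |>
    dplyr::mutate(per_test_rank = rank(-abs(.data$statistic),
                                       ties.method = "average")) |>
    dplyr::ungroup()
  ranked |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(rank = median(.data$per_test_rank), .groups = "drop") |>
    dplyr::arrange(.data$rank)
}

#' Comprehensive feature ranking across datasets
#'
#' The comprehensive rank of a feature is the median of its within-dataset
#' ranks over the datasets in which it is present; features absent from all
#' datasets are dropped with a warning.
#'
#' @param rank_tables Named list of [within_dataset_rank()] tibbles.
#' @return A tibble `feature`, one `rank_<dataset>` column per dataset, and
#'   `comprehensive_rank`, sorted ascending.
#' @export
comprehensive_rank <- function(rank_tables) {
  stopifnot(is.list(rank_tables), length(rank_tables) >= 1)
  if (is.null(names(rank_tables))) {
    names(rank_tables) <- paste0("dataset_", seq_along(rank_tables))
  }
  wide <- purrr::imap(rank_tables, function(tb, nm) {
    dplyr::select(tb, "feature", !!paste0("rank_", nm) := "rank")
  }) |> purrr::reduce(dplyr::full_join, by = "feature")
  rank_cols <- setdiff(names(wide), "feature")
  wide$comprehensive_rank <- apply(wide[rank_cols], 1, median, na.rm = TRUE)
  empty <- is.na(wide$comprehensive_rank)
  if (any(empty)) {
    warn(sprintf("%d feature(s) absent from all datasets were dropped",
                 sum(empty)))
    wide <- wide[!empty, ]
  }
  dplyr::arrange(wide, .data$comprehensive_rank)
}

#' Subsample robustness of the test statistics
#'
#' Repeats the feature tests `n_rep` times on random subsamples of
#' `frac * n` regions (without replacement) and reports the mean and
#' standard deviation of each statistic.
#'
#' @param x Feature values.
#' @param y Optional quantitative activity.
#' @param labels Optional binary labels.
#' @param n_rep Number of repetitions.
#' @param frac Subsample fraction.
#' @param seed Integer seed.
#'
#' @return A tibble `test`, `mean`, `sd`.
#' @export
subsample_robustness <- function(x, y = NULL, labels = NULL, n_rep = 100,
                                 frac = 0.8, seed = 1L) {
  n <- length(x)
  m <- round(frac * n)
  if (m < 8) abort("frac * n must be at least 8")
  with_seed(seed, {
    reps <- purrr::map(seq_len(n_rep), function(i) {
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      parts <- list()
      if (!is.null(y)) parts$reg <- regression_tests(x[idx], y[idx])
      if (!is.null(labels) && length(unique(labels[idx])) == 2) {
        parts$cls <- classification_tests(x[idx], labels[idx])
      }
      dplyr::bind_rows(parts)
    }) |> dplyr::bind_rows()
    reps |>
      dplyr::group_by(.data$test) |>
      dplyr::summarise(mean = mean(.data$statistic),
                       sd = stats::sd(.data$statistic), .groups = "drop")
  })
}

#' Empirical control for cell-type-specific track aggregates
#'
#' Tests whether a cell-type-restricted mean-overlap feature is more
#' predictive than random sets of non-cell-type tracks of the same size:
#' for each of `n_draws` draws, `n_tracks` columns of `pool` are drawn at
#' random, their row mean is scored with `stat_fn` against `y`, and the
#' empirical p-value is the fraction of draws whose statistic is at least
#' the cell feature's statistic.
#'
#' @param pool Matrix or tibble of candidate track binaries (regions x
#'   tracks), excluding the cell-type's own tracks.
#' @param n_tracks Number of tracks per draw (the cell-mean member count).
#' @param y Quantitative activity (or any response accepted by `stat_fn`).
#' @param cell_feature The cell-type-restricted aggregate feature values.
#' @param n_draws Number of random draws.
#' @param seed Integer seed.
#' @param stat_fn Predictivity statistic; default absolute Spearman.
#'
#' @return A list with `empirical_p`, `cell_statistic` and `draw_statistics`.
#' @export
shuffled_mean_control <- function(pool, n_tracks, y, cell_feature,
                                  n_draws = 100, seed = 1L,
                                  stat_fn = function(f, y) abs(spearman(f, y))) {
  pool <- as.matrix(pool)
  if (ncol(pool) < n_tracks) {
    abort("pool has fewer tracks than the requested draw size")
  }
  cell_stat <- stat_fn(cell_feature, y)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      cols <- sample.int(ncol(pool), n_tracks)
      stat_fn(rowMeans(pool[, cols, drop = FALSE]), y)
    }, numeric(1))
  })
  list(empirical_p = mean(draws >= cell_stat),
       cell_statistic = cell_stat,
       draw_statistics = draws)
}
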