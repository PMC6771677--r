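# Predictive transcription factors per dataset, overlap enrichment between
# datasets, and the association between TF predictivity and expression.

#' Identify TFs whose predicted binding correlates with MPRA activity
#'
#' Computes, per TF, the Spearman correlation of its per-region binding
#' score with activity, adjusts the two-sided p-values by
#' Benjamini-Hochberg across TFs, and assigns membership:
#' `predictive` (q < 0.05), `high_confidence` (q < 0.01, a subset of
#' predictive), `nonpredictive` (q > 0.1), `indeterminate` otherwise.
#' A constant score column has undefined correlation and is marked
#' indeterminate.
#'
#' @param tf_scores Tibble: `region_id` plus one numeric column per TF.
#' @param activity Tibble with `region_id` and `activity` (or `alpha`), or a
#'   numeric vector aligned with `tf_scores` rows.
#' @param q_predictive,q_high,q_nonpredictive Membership thresholds.
#'
#' @return A tibble: `tf`, `rho`, `p`, `q`, `predictive`,
#'   `high_confidence`, `nonpredictive`, `membership`.
#' @export
predictive_tfs <- function(tf_scores, activity, q_predictive = 0.05,
                           q_high = 0.01, q_nonpredictive = 0.1) {
  stopifnot(is.data.frame(tf_scores), "region_id" %in% names(tf_scores))
  if (is.data.frame(activity)) {
    col <- intersect(c("activity", "alpha"), names(activity))[1]
    if (is.na(col)) abort("`activity` needs an `activity` or `alpha` column")
    y <- activity[[col]][match(tf_scores$region_id, activity$region_id)]
  } else {
    y <- activity
  }
  if (length(y) < 8) abort("need at least 8 regions")
  if (anyNA(y)) abort("activity does not cover all scored regions")
  tfs <- setdiff(names(tf_scores), "region_id")
  res <- purrr::map(tfs, function(tf) {
    x <- tf_scores[[tf]]
    if (length(unique(x)) < 2) {
      return(tibble::tibble(tf = tf, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(tf = tf, rho = unname(ct$estimate), p = ct$p.value)
  }) |> dplyr::bind_rows()
  res$q <- p.adjust(res$p, method = "BH")
  res$predictive <- !is.na(res$q) & res$q < q_predictive
  res$high_confidence <- !is.na(res$q) & res$q < q_high
  res$nonpredictive <- !is.na(res$q) & res$q > q_nonpredictive
  res$membership <- dplyr::case_when(
    is.na(res$q) ~ "indeterminate",
    res$high_confidence ~ "high_confidence",
    res$predictive ~ "predictive",
    res$nonpredictive ~ "nonpredictive",
    TRUE ~ "indeterminate"
  )
  res
}

#' Overlap enrichment between two predictive-TF sets
#'
#' Fold enrichment is `overlap * N / (|A| * |B|)` over a universe of `N`
#' TFs; significance is the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when sampling
#' `|B|` elements from a universe containing `|A|` marked ones.
#'
#' @param set_a,set_b Character vectors of TF identifiers.
#' @param universe Character vector of all TFs scored in both datasets.
#'
#' @return A one-row tibble: `n_a`, `n_b`, `universe_size`, `overlap`,
#'   `fold_enrichment`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  N <- length(universe)
  a <- length(set_a)
  b <- length(set_b)
  ov <- length(intersect(set_a, set_b))
  if (a == 0 || b == 0) {
    return(tibble::tibble(n_a = a, n_b = b, universe_size = N, overlap = ov,
                          fold_enrichment = NA_real_, p = NA_real_,
                          flagged = TRUE))
  }
  fold <- ov * N / (a * b)
  p <- phyper(ov - 1, a, N - a, b, lower.tail = FALSE)
  tibble::tibble(n_a = a, n_b = b, universe_size = N, overlap = ov,
                 fold_enrichment = fold, p = p, flagged = FALSE)
}

#' Overlap enrichment across all dataset pairs
#'
#' Applies [overlap_enrichment()] to every pair of predictive-TF sets, using
#' as universe the TFs scored in both datasets of each pair, and adjusts the
#' hypergeometric p-values by Benjamini-Hochberg across pairs.
#'
#' @param tf_sets Named list of [predictive_tfs()] tibbles.
#' @return A tibble with one row per unordered pair, including `q`.
#' @export
pairwise_overlap <- function(tf_sets) {
  stopifnot(is.list(tf_sets), length(tf_sets) >= 2, !is.null(names(tf_sets)))
  pairs <- utils::combn(names(tf_sets), 2, simplify = FALSE)
  res <- purrr::map(pairs, function(pr) {
    ta <- tf_sets[[pr[1]]]
    tb <- tf_sets[[pr[2]]]
    universe <- intersect(ta$tf, tb$tf)
    out <- overlap_enrichment(ta$tf[ta$predictive & ta$tf %in% universe],
                              tb$tf[tb$predictive & tb$tf %in% universe],
                              universe)
    dplyr::bind_cols(tibble::tibble(dataset_a = pr[1], dataset_b = pr[2]),
                     out)
  }) |> dplyr::bind_rows()
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Association between TF predictivity rank and expression
#'
#' Two-sided Wilcoxon rank-sum test comparing the expression (TPM) of the
#' `k` best-ranked TFs against the `k` worst-ranked. TFs without expression
#' are dropped with a diagnostic and `k` is reduced symmetrically if needed.
#'
#' @param tf_ranks Tibble with `tf` and a rank column (`comprehensive_rank`
#'   or `rank`); smaller rank = more predictive.
#' @param tpm Tibble with `tf` (or `factor`) and `tpm`.
#' @param k Number of TFs per tail.
#'
#' @return A list with `statistic`, `p`, `k`, `top_tfs`, `bottom_tfs`.
#' @export
expression_association <- function(tf_ranks, tpm, k = 50) {
  stopifnot(is.data.frame(tf_ranks))
  rank_col <- intersect(c("comprehensive_rank", "rank"), names(tf_ranks))[1]
  if (is.na(rank_col)) abort("`tf_ranks` needs a rank column")
  tf_col <- intersect(c("tf", "feature"), names(tf_ranks))[1]
  names(tpm)[names(tpm) == "factor"] <- "tf"
  merged <- dplyr::inner_join(
    tibble::tibble(tf = tf_ranks[[tf_col]], rank = tf_ranks[[rank_col]]),
    tpm[c("tf", "tpm")], by = "tf")
  dropped <- setdiff(tf_ranks[[tf_col]], merged$tf)
  if (length(dropped)) {
    warn(sprintf("%d TF(s) without expression dropped", length(dropped)))
  }
  merged <- merged[!is.na(merged$tpm), ]
  k <- min(k, floor(nrow(merged) / 2))
  if (k < 1) abort("not enough TFs with expression for the rank-sum test")
  ord <- order(merged$rank)
  top <- merged[head(ord, k), ]
  bottom <- merged[tail(ord, k), ]
  wt <- suppressWarnings(wilcox.test(top$tpm, bottom$tpm,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value, k = k,
       top_tfs = top$tf, bottom_tfs = bottom$tf)
}

#' TFs predictive in one dataset but not the other
#'
#' Returns the TFs that are high-confidence predictive (`q < 0.01`) in one
#' dataset while nonpredictive (`q > 0.1`) in the other, in both directions.
#'
#' @param set_a,set_b [predictive_tfs()] tibbles over the same TF universe.
#' @return A list with `a_specific` and `b_specific` character vectors.
#' @export
difference_tfs <- function(set_a, set_b) {
  if (!setequal(set_a$tf, set_b$tf)) {
    abort("the two sets must cover the same TF universe")
  }
  b_at <- match(set_a$tf, set_b$tf)
  a_specific <- set_a$tf[set_a$high_confidence & set_b$nonpredictive[b_at]]
  a_at <- match(set_b$tf, set_a$tf)
  b_specific <- set_b$tf[set_b$high_confidence & set_a$nonpredictive[a_at]]
  list(a_specific = a_specific, b_specific = b_specific)
}
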