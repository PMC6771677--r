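# Region categories shared between two datasets, and the hardness statistic
# quantifying cross-dataset prediction difficulty.

#' Categorize regions shared by two datasets by their activity pattern
#'
#' The 2x2 of (active in A, active in B) gives four categories:
#' `common_active`, `specific_to_a`, `specific_to_b`, `inactive_both`.
#' Labels may come from the FDR-based call ([call_active()]) or from the
#' log2-cutoff rule ([threshold_active()]); this function only combines
#' them.
#'
#' @param labels_a,labels_b Tibbles with `region_id` and a binary label
#'   column (`label`, or `active`), over identical region id sets.
#'
#' @return A tibble `region_id`, `active_a`, `active_b`, `category`.
#' @export
categorize_regions <- function(labels_a, labels_b) {
  la <- extract_labels(labels_a, "labels_a")
  lb <- extract_labels(labels_b, "labels_b")
  only_a <- setdiff(la$region_id, lb$region_id)
  only_b <- setdiff(lb$region_id, la$region_id)
  if (length(only_a) || length(only_b)) {
    abort(sprintf(
      "region id sets differ (only in A: %s; only in B: %s)",
      paste(head(only_a, 3), collapse = ","),
      paste(head(only_b, 3), collapse = ",")))
  }
  merged <- dplyr::inner_join(la, lb, by = "region_id",
                              suffix = c("_a", "_b"))
  merged$category <- dplyr::case_when(
    merged$label_a == 1 & merged$label_b == 1 ~ "common_active",
    merged$label_a == 1 & merged$label_b == 0 ~ "specific_to_a",
    merged$label_a == 0 & merged$label_b == 1 ~ "specific_to_b",
    TRUE ~ "inactive_both"
  )
  dplyr::rename(merged, active_a = "label_a", active_b = "label_b")
}

extract_labels <- function(df, name) {
  stopifnot(is.data.frame(df), "region_id" %in% names(df))
  col <- intersect(c("label", "active"), names(df))[1]
  if (is.na(col)) abort(sprintf("`%s` needs a `label` or `active` column", name))
  tibble::tibble(region_id = df$region_id, label = as.integer(df[[col]]))
}

#' Hardness of regions: rank-normalized prediction error
#'
#' The raw hardness of a region is `|label - predicted probability|`; the
#' hardness is its rank-normalization `(average rank - 1) / (n - 1)` in
#' `[0, 1]` (average ranks for ties), so hardness is invariant to any
#' strictly increasing transform of the raw differences.
#'
#' @param pred_prob Predicted probabilities in `[0, 1]`.
#' @param labels Binary 0/1 labels.
#' @param region_id Optional region ids.
#'
#' @return A tibble `region_id`, `raw`, `hardness`.
#' @export
hardness <- function(pred_prob, labels, region_id = NULL) {
  if (any(pred_prob < 0 | pred_prob > 1)) {
    abort("predicted probabilities must lie in [0, 1]")
  }
  n <- length(pred_prob)
  if (n < 2) abort("hardness needs at least 2 regions")
  stopifnot(length(labels) == n)
  raw <- abs(as.numeric(labels) - pred_prob)
  h <- (rank(raw, ties.method = "average") - 1) / (n - 1)
  tibble::tibble(
    region_id = region_id %||% sprintf("region_%04d", seq_len(n)),
    raw = raw, hardness = h
  )
}

#' Compare hardness distributions across region categories
#'
#' Computes each category's empirical CDF of hardness (sampled at all
#' observed hardness values) and the pairwise two-sample Kolmogorov-Smirnov
#' statistics between categories. Categories with fewer than `min_size`
#' regions are excluded with a warning.
#'
#' @param hardness_table Tibble with `hardness` and `category` (e.g. the
#'   join of [hardness()] and [categorize_regions()]).
#' @param min_size Minimum category size.
#'
#' @return A list with `ecdf` (tibble `category`, `hardness`, `cdf`) and
#'   `ks` (tibble `category_1`, `category_2`, `statistic`, `p`).
#' @export
compare_hardness <- function(hardness_table, min_size = 10) {
  stopifnot(all(c("hardness", "category") %in% names(hardness_table)))
  sizes <- table(hardness_table$category)
  small <- names(sizes)[sizes < min_size]
  if (length(small)) {
    warn(paste0("excluding categor(ies) below minimum size: ",
                paste(small, collapse = ", ")))
    hardness_table <- hardness_table[!hardness_table$category %in% small, ]
  }
  cats <- sort(unique(hardness_table$category))
  if (length(cats) < 2) abort("need at least 2 categories of sufficient size")
  grid <- sort(unique(hardness_table$hardness))
  ecdf_tb <- purrr::map(cats, function(cc) {
    F_ <- stats::ecdf(hardness_table$hardness[hardness_table$category == cc])
    tibble::tibble(category = cc, hardness = grid, cdf = F_(grid))
  }) |> dplyr::bind_rows()
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  ks_tb <- purrr::map(pairs, function(pr) {
    a <- hardness_table$hardness[hardness_table$category == pr[1]]
    b <- hardness_table$hardness[hardness_table$category == pr[2]]
    kt <- suppressWarnings(ks.test(a, b))
    tibble::tibble(category_1 = pr[1], category_2 = pr[2],
                   statistic = unname(kt$statistic), p = kt$p.value)
  }) |> dplyr::bind_rows()
  list(ecdf = ecdf_tb, ks = ks_tb)
}
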