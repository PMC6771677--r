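# Sequence, interval and score-table featurization producing a categorized
# feature matrix (categories: experimental / predicted / kmer / locus).

#' k-mer presence features of a sequence
#'
#' @param seq ACGT string of length >= `k`.
#' @param k Word length (the assessed feature set uses k = 5).
#' @return A list with `presence` — a named 0/1 integer vector over all `4^k`
#'   k-mers in lexicographic order — and `n_distinct`, the number of distinct
#'   k-mers present.
#' @export
#' @examples
#' kmer_features("ACGTACGTA")$n_distinct
kmer_features <- function(seq, k = 5) {
  assert_dna(seq)
  k <- assert_count(k, "k")
  if (nchar(seq) < k) abort(sprintf("sequence shorter than k = %d", k))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  presence <- as.integer(counts > 0)
  names(presence) <- names(counts)
  list(presence = presence, n_distinct = sum(presence))
}

#' Base-composition features of a sequence
#'
#' @param seq ACGT string.
#' @return A list with `n_gc` (count of G/C bases), `poly_a` and `poly_t`
#'   (lengths of the longest A and T runs).
#' @export
composition_features <- function(seq) {
  assert_dna(seq)
  chars <- strsplit(seq, "")[[1]]
  n_gc <- sum(chars %in% c("G", "C"))
  longest_run <- function(base) {
    r <- rle(chars == base)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  list(n_gc = n_gc, poly_a = longest_run("A"), poly_t = longest_run("T"))
}

#' Featurize sequences with all sequence-intrinsic features
#'
#' Computes, per sequence: the `4^k` k-mer presence features (columns
#' prefixed `kmer_`), the distinct-k-mer count, base composition, and — when
#' motifs are supplied — the significant motif-hit count and motif density
#' from [scan_motifs()]. These features depend only on the sequence, never on
#' the genomic interval.
#'
#' @param sequences Tibble with `seq_id` (or `region_id`) and `sequence`.
#' @param pwms Optional list of `pwm` objects.
#' @param k k-mer length.
#' @param p_threshold,window Passed to [scan_motifs()].
#'
#' @return A tibble with one row per sequence.
#' @export
featurize_sequences <- function(sequences, pwms = NULL, k = 5,
                                p_threshold = 1e-4, window = 20) {
  stopifnot(is.data.frame(sequences), "sequence" %in% names(sequences))
  id_col <- if ("region_id" %in% names(sequences)) "region_id" else "seq_id"
  tabs <- if (!is.null(pwms)) {
    lapply(pwms, pwm_score_table)
  }
  rows <- purrr::map(seq_len(nrow(sequences)), function(i) {
    s <- sequences$sequence[i]
    km <- kmer_features(s, k)
    comp <- composition_features(s)
    row <- c(as.list(setNames(km$presence, paste0("kmer_", names(km$presence)))),
             list(n_kmers = km$n_distinct, n_gc = comp$n_gc,
                  poly_a = comp$poly_a, poly_t = comp$poly_t))
    if (!is.null(pwms)) {
      sc <- scan_motifs(s, pwms, p_threshold = p_threshold, window = window)
      row$n_motifs <- sc$n_motifs
      row$motif_density <- sc$motif_density
    }
    tibble::as_tibble(row)
  })
  dplyr::bind_cols(tibble::tibble(region_id = sequences[[id_col]]),
                   dplyr::bind_rows(rows))
}

# binary >=1 bp overlap of each region against one interval set
# (0-based half-open coordinates on both sides)
interval_overlap_binary <- function(regions, track) {
  out <- integer(nrow(regions))
  if (!nrow(track)) return(out)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    ti <- track$chrom == ch
    if (!any(ti)) next
    q <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    s <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    hits <- IRanges::overlapsAny(q, s, minoverlap = 1L)
    out[ri] <- as.integer(hits)
  }
  out
}

#' Binary track-overlap features and their per-factor aggregates
#'
#' For each track, the feature is 1 iff the region's genomic interval shares
#' at least one base with any interval of the track (0-based half-open
#' coordinates). Aggregates summarise groups of tracks: `<factor>_mean` is
#' the mean of member binaries over all tracks of that factor;
#' `<factor>_cell_mean` restricts members to tracks assayed in `cell_type`;
#' `tfbs_shuffled_mean` draws, `n_draws` times, as many random non-cell-type
#' TFBS tracks as there are members of `tfbs_cell_mean`, and averages the
#' mean binaries over the draws.
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param tracks Tibble of intervals with `track_id`, `chrom`, `start`, `end`.
#' @param track_meta Tibble with `track_id`, `factor`, `cell_type`.
#' @param cell_type Cell type of the assay (used for the cell-restricted
#'   aggregates); `NULL` skips them.
#' @param n_draws Number of random draws for the shuffled mean.
#' @param seed Seed for the shuffled-mean draws.
#'
#' @return A tibble: `region_id`, one binary column per track, and the
#'   aggregate columns.
#' @export
overlap_features <- function(regions, tracks, track_meta, cell_type = NULL,
                             n_draws = 100, seed = 1L) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)),
            all(c("track_id", "chrom", "start", "end") %in% names(tracks)),
            all(c("track_id", "factor", "cell_type") %in% names(track_meta)))
  if (any(tracks$end <= tracks$start)) {
    abort("track interval with end <= start")
  }
  ids <- track_meta$track_id
  bin <- sapply(ids, function(tid) {
    interval_overlap_binary(regions, tracks[tracks$track_id == tid, , drop = FALSE])
  })
  bin <- matrix(bin, nrow = nrow(regions),
                dimnames = list(NULL, ids))
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = regions$region_id),
    tibble::as_tibble(as.data.frame(bin))
  )
  for (fac in unique(track_meta$factor)) {
    members <- track_meta$track_id[track_meta$factor == fac]
    out[[paste0(tolower(fac), "_mean")]] <-
      rowMeans(bin[, members, drop = FALSE])
    if (!is.null(cell_type)) {
      cell_members <- track_meta$track_id[track_meta$factor == fac &
                                            track_meta$cell_type == cell_type]
      if (length(cell_members)) {
        out[[paste0(tolower(fac), "_cell_mean")]] <-
          rowMeans(bin[, cell_members, drop = FALSE])
      }
    }
  }
  if (!is.null(cell_type)) {
    tfbs_cell <- track_meta$track_id[track_meta$factor == "TFBS" &
                                       track_meta$cell_type == cell_type]
    pool <- track_meta$track_id[track_meta$factor == "TFBS" &
                                  track_meta$cell_type != cell_type]
    n_cell <- length(tfbs_cell)
    if (n_cell > 0 && length(pool) >= n_cell) {
      draws <- with_seed(seed, {
        replicate(n_draws, {
          chosen <- sample(pool, n_cell)
          rowMeans(bin[, chosen, drop = FALSE])
        })
      })
      out$tfbs_shuffled_mean <- rowMeans(draws)
    }
  }
  out
}

#' Counts of high-scoring factors from a precomputed score table
#'
#' Consumes a pluggable regions-by-factors score table (e.g. predicted TF
#' binding from an external model). For each factor the reference level is
#' its `percentile`-th percentile across all regions; a region "has" the
#' factor when its score is strictly above that level. `n_top` counts the
#' factors a region has; when an expression table is supplied, `n_tf_high`,
#' `n_tf_med` and `n_tf_low` intersect that count with the factors ranked in
#' the top, middle and bottom `stratum_size` by TPM.
#'
#' @param scores Tibble: `region_id` plus one numeric column per factor.
#' @param expression Optional tibble with `factor` and `tpm`.
#' @param percentile Reference percentile (0-100 scale).
#' @param stratum_size Size of each expression stratum.
#' @param prefix Name prefix of the count column (e.g. `"deepbind"` gives
#'   `n_deepbind_top`).
#'
#' @return A tibble of per-region counts.
#' @export
score_table_features <- function(scores, expression = NULL, percentile = 90,
                                 stratum_size = 100, prefix = "score") {
  stopifnot(is.data.frame(scores), "region_id" %in% names(scores))
  factors <- setdiff(names(scores), "region_id")
  if (!length(factors)) abort("score table has no factor columns")
  mat <- as.matrix(scores[factors])
  thr <- apply(mat, 2, quantile, probs = percentile / 100, names = FALSE)
  above <- sweep(mat, 2, thr, ">")
  out <- tibble::tibble(region_id = scores$region_id)
  out[[paste0("n_", prefix, "_top")]] <- as.integer(rowSums(above))
  if (!is.null(expression)) {
    stopifnot(all(c("factor", "tpm") %in% names(expression)))
    missing_expr <- setdiff(factors, expression$factor)
    if (length(missing_expr)) {
      abort(paste0("factor(s) missing expression: ",
                   paste(head(missing_expr, 5), collapse = ", ")))
    }
    tpm <- expression$tpm[match(factors, expression$factor)]
    ord <- order(-tpm)        # factors sorted by TPM descending
    m <- length(factors)
    ssz <- min(stratum_size, m)
    top <- factors[ord][seq_len(ssz)]
    bottom <- factors[ord][seq(m - ssz + 1L, m)]
    mid_start <- ceiling((m - ssz) / 2) + 1L
    middle <- factors[ord][seq(mid_start, length.out = ssz)]
    for (nm in c("high", "med", "low")) {
      set <- switch(nm, high = top, med = middle, low = bottom)
      out[[paste0("n_tf_", nm)]] <-
        as.integer(rowSums(above[, set, drop = FALSE]))
    }
  }
  out
}

#' Locus annotation features
#'
#' Binary promoter/exon/intron overlap (>= 1 shared base, half-open
#' coordinates), `distal = 1 - max(promoter, exon, intron)`, mean per-base
#' conservation over the interval, and the expression of the closest gene
#' (consumed from a provided table).
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param promoters,exons,introns Interval tibbles (`chrom`, `start`, `end`).
#' @param conservation Optional per-base score tibble (`chrom`, `pos`
#'   0-based, `score`); an interval not fully covered yields `NA`
#'   (flagged missing), never silently 0.
#' @param closest_gene_tpm Optional tibble (`region_id`, `tpm`).
#'
#' @return A tibble of per-region locus features.
#' @export
locus_features <- function(regions, promoters = NULL, exons = NULL,
                           introns = NULL, conservation = NULL,
                           closest_gene_tpm = NULL) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  prom <- interval_overlap_binary(regions, promoters %||% empty)
  exon <- interval_overlap_binary(regions, exons %||% empty)
  intr <- interval_overlap_binary(regions, introns %||% empty)
  out <- tibble::tibble(
    region_id = regions$region_id,
    promoter = prom, exon = exon, intron = intr,
    distal = 1L - pmax(prom, exon, intr)
  )
  if (!is.null(conservation)) {
    out$conservation <- vapply(seq_len(nrow(regions)), function(i) {
      sel <- conservation$chrom == regions$chrom[i] &
        conservation$pos >= regions$start[i] &
        conservation$pos < regions$end[i]
      width <- regions$end[i] - regions$start[i]
      if (sum(sel) < width) NA_real_ else mean(conservation$score[sel])
    }, numeric(1))
  }
  if (!is.null(closest_gene_tpm)) {
    out$closest_gene_expression <-
      closest_gene_tpm$tpm[match(regions$region_id, closest_gene_tpm$region_id)]
  }
  out
}

#' Assemble categorized feature blocks into a feature matrix
#'
#' Column-binds named feature blocks (each a tibble with `region_id`) over a
#' common region set, tagging every feature with its block's category. The
#' result is an ordinary tibble carrying a `categories` attribute (tibble of
#' `feature`, `category`, `block`) consulted by [select_features()].
#'
#' @param blocks Named list of feature tibbles, each with `region_id`.
#' @param categories Named character vector mapping block name to a category
#'   in `c("experimental", "predicted", "kmer", "locus")`.
#'
#' @return A `feature_matrix` tibble.
#' @export
assemble_feature_matrix <- function(blocks, categories) {
  stopifnot(is.list(blocks), length(blocks) > 0, !is.null(names(blocks)))
  if (!all(names(blocks) %in% names(categories))) {
    abort("every block needs a category tag")
  }
  ids <- blocks[[1]]$region_id
  cat_rows <- list()
  out <- tibble::tibble(region_id = ids)
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    stopifnot("region_id" %in% names(blk))
    if (!identical(sort_ids(blk$region_id), sort_ids(ids))) {
      abort(sprintf("block `%s` indexes a different region set", nm))
    }
    blk <- blk[match(ids, blk$region_id), ]
    feats <- setdiff(names(blk), "region_id")
    clash <- intersect(feats, setdiff(names(out), "region_id"))
    if (length(clash)) {
      abort(paste0("duplicate feature name(s) across blocks: ",
                   paste(head(clash, 5), collapse = ", ")))
    }
    out <- dplyr::bind_cols(out, blk[feats])
    cat_rows[[nm]] <- tibble::tibble(feature = feats,
                                     category = unname(categories[[nm]]),
                                     block = nm)
  }
  attr(out, "categories") <- dplyr::bind_rows(cat_rows)
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Select a feature subset from a feature matrix
#'
#' @param fm A `feature_matrix` from [assemble_feature_matrix()].
#' @param subset `"Full"` for all features, or a vector of block names
#'   and/or categories.
#' @return A `feature_matrix` restricted to the selected columns.
#' @export
select_features <- function(fm, subset = "Full") {
  cats <- attr(fm, "categories")
  if (is.null(cats)) abort("`fm` lacks a categories attribute")
  keep <- if (identical(subset, "Full")) {
    cats$feature
  } else {
    cats$feature[cats$block %in% subset | cats$category %in% subset]
  }
  if (!length(keep)) abort("feature subset is empty")
  out <- fm[c("region_id", keep)]
  attr(out, "categories") <- cats[cats$feature %in% keep, ]
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Write a feature matrix with its category sidecar
#' @param fm A `feature_matrix`.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".categories.tsv")`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write_tsv_table(fm, path)
  cats <- attr(fm, "categories")
  if (!is.null(cats)) write_tsv_table(cats, paste0(path, ".categories.tsv"))
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Input TSV path.
#' @return A `feature_matrix` tibble.
#' @export
read_feature_matrix <- function(path) {
  out <- read_tsv_table(path)
  sidecar <- paste0(path, ".categories.tsv")
  if (file.exists(sidecar)) {
    attr(out, "categories") <- read_tsv_table(sidecar)
  }
  class(out) <- c("feature_matrix", class(out))
  out
}
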