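# Saturation-mutagenesis variant-effect prediction: sequence-feature
# differencing between variant and wild type, the discrete (-1/0/+1) and
# continuous ensembles, evaluation, and cross-element transfer.

# Variant features use k-mer frequencies (counts), not binary presence:
# a substitution then shifts exactly the counts of the words it destroys
# and creates, which is the signal the effect models learn from.
variant_sequence_features <- function(seq, pwms = NULL, k = 5,
                                      providers = NULL,
                                      p_threshold = 1e-4, window = 20) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  comp <- composition_features(seq)
  out <- c(setNames(as.numeric(counts), paste0("kmer_", names(counts))),
           n_kmers = sum(counts > 0), n_gc = comp$n_gc,
           poly_a = comp$poly_a, poly_t = comp$poly_t)
  if (!is.null(pwms)) {
    sc <- scan_motifs(seq, pwms, p_threshold = p_threshold, window = window)
    out <- c(out, n_motifs = sc$n_motifs, motif_density = sc$motif_density)
  }
  if (!is.null(providers)) {
    for (nm in names(providers)) {
      v <- providers[[nm]](seq)
      names(v) <- paste0(nm, "_", names(v))
      out <- c(out, v)
    }
  }
  out
}

#' Featurize a single-nucleotide variant against its wild-type sequence
#'
#' Builds the variant sequence, computes all sequence-intrinsic features
#' (k-mer presence, composition, motif features when PWMs are given, and
#' any pluggable per-sequence score providers) for both alleles, and returns
#' the difference `variant - wild-type` (and optionally the concatenation).
#' Positional features are excluded by construction: they cannot differ
#' between alleles of the same element.
#'
#' @param wt_seq Wild-type ACGT sequence.
#' @param position 0-based variant position; `wt_seq` must carry `ref`
#'   there.
#' @param ref,alt Reference and alternate bases.
#' @param pwms Optional list of `pwm` objects.
#' @param k k-mer length.
#' @param providers Optional named list of functions `f(seq) ->` named
#'   numeric vector (pluggable predicted-score models).
#' @param p_threshold,window Motif-hit threshold and density window, passed
#'   to [scan_motifs()].
#' @param mode `"difference"` (default) or `"concat"`.
#'
#' @return A named numeric vector of feature differences (or the
#'   concatenated wild-type/variant vector).
#' @export
featurize_variant <- function(wt_seq, position, ref, alt, pwms = NULL,
                              k = 5, providers = NULL, p_threshold = 1e-4,
                              window = 20,
                              mode = c("difference", "concat")) {
  mode <- match.arg(mode)
  assert_dna(wt_seq, "wt_seq")
  observed <- substr(wt_seq, position + 1, position + 1)
  if (observed != ref) {
    abort(sprintf("wild-type base at position %d is %s, not the stated ref %s",
                  position, observed, ref))
  }
  var_seq <- wt_seq
  substr(var_seq, position + 1, position + 1) <- alt
  wt_f <- variant_sequence_features(wt_seq, pwms, k, providers, p_threshold,
                                    window)
  var_f <- variant_sequence_features(var_seq, pwms, k, providers, p_threshold,
                                     window)
  if (mode == "difference") {
    var_f - wt_f
  } else {
    c(setNames(wt_f, paste0("wt_", names(wt_f))),
      setNames(var_f, paste0("var_", names(var_f))))
  }
}

#' Featurize every variant of a variant table
#'
#' @param variants Tibble with `element_id`, `position`, `ref`, `alt` (e.g.
#'   from [simulate_saturation()]).
#' @param element_seqs Named character vector of wild-type sequences, one
#'   per element.
#' @inheritParams featurize_variant
#'
#' @return A tibble of feature differences, one row per variant, with the
#'   identifying columns of `variants` prepended.
#' @export
featurize_variant_table <- function(variants, element_seqs, pwms = NULL,
                                    k = 5, providers = NULL,
                                    p_threshold = 1e-4, window = 20,
                                    mode = "difference") {
  stopifnot(all(c("element_id", "position", "ref", "alt") %in% names(variants)))
  missing_el <- setdiff(unique(variants$element_id), names(element_seqs))
  if (length(missing_el)) {
    abort(paste0("no sequence for element(s): ",
                 paste(missing_el, collapse = ", ")))
  }
  # cache wild-type features per element
  wt_cache <- lapply(element_seqs, variant_sequence_features,
                     pwms = pwms, k = k, providers = providers,
                     p_threshold = p_threshold, window = window)
  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    el <- variants$element_id[i]
    wt_seq <- element_seqs[[el]]
    pos <- variants$position[i]
    observed <- substr(wt_seq, pos + 1, pos + 1)
    if (observed != variants$ref[i]) {
      abort(sprintf("element %s position %d: wild-type base %s != ref %s",
                    el, pos, observed, variants$ref[i]))
    }
    var_seq <- wt_seq
    substr(var_seq, pos + 1, pos + 1) <- variants$alt[i]
    vf <- variant_sequence_features(var_seq, pwms, k, providers,
                                    p_threshold, window)
    if (mode == "difference") vf - wt_cache[[el]] else
      c(setNames(wt_cache[[el]], paste0("wt_", names(vf))),
        setNames(vf, paste0("var_", names(vf))))
  })
  feat <- do.call(rbind, rows)
  dplyr::bind_cols(
    variants[intersect(c("element_id", "element_class", "position", "ref",
                         "alt", "effect", "effect_true", "class", "split"),
                       names(variants))],
    tibble::as_tibble(as.data.frame(feat))
  )
}

variant_roster <- function(element_class) {
  switch(element_class,
         promoter = c("rf", "et", "gb"),
         enhancer = c(rep("rf", 5), rep("et", 5)),
         abort(sprintf("unknown element class `%s`", element_class)))
}

#' Train the discrete variant-impact classifier ensemble
#'
#' A ten-member ensemble (five random forests, five extremely-randomized
#' forests; `n_estimators` trees each, square-root feature sampling, member
#' seeds `seed + index`) predicting the -1/0/+1 impact class from feature
#' differences. One model is intended per element class (all promoters
#' together, all enhancers together). Prediction is by highest mean class
#' probability, ties broken toward the lowest class.
#'
#' @param features Tibble/matrix of numeric feature differences.
#' @param classes Integer vector in `{-1, 0, 1}`.
#' @param n_estimators Trees per member.
#' @param seed Base seed.
#'
#' @return A `variant_classifier` object.
#' @export
train_discrete <- function(features, classes, n_estimators = 1000,
                           seed = 1L) {
  X <- feature_matrix_of(drop_id_cols(features))
  classes <- as.integer(classes)
  if (length(unique(classes)) < 2) {
    abort("discrete training needs at least 2 classes present")
  }
  yf <- factor(classes, levels = c(-1L, 0L, 1L))
  member_ids <- c(rep("rf", 5), rep("et", 5))
  members <- purrr::map(seq_along(member_ids), function(i) {
    df <- as.data.frame(X)
    df$.y <- yf
    ranger::ranger(dependent.variable.name = ".y", data = df,
                   num.trees = n_estimators, seed = seed + i,
                   num.threads = 1, mtry = max(1L, floor(sqrt(ncol(X)))),
                   min.node.size = 1,
                   splitrule = if (member_ids[i] == "et") "extratrees" else "gini",
                   num.random.splits = 1,
                   replace = member_ids[i] != "et",
                   sample.fraction = if (member_ids[i] == "et") 1 else 1,
                   probability = TRUE)
  })
  structure(list(members = members, member_ids = member_ids,
                 feature_names = colnames(X), levels = c(-1L, 0L, 1L)),
            class = "variant_classifier")
}

drop_id_cols <- function(df) {
  if (!is.data.frame(df)) return(tibble::as_tibble(as.data.frame(df)))
  df[setdiff(names(df), c("element_id", "element_class", "position", "ref",
                          "alt", "effect", "effect_true", "class", "split"))]
}

#' Predict discrete variant impacts
#'
#' @param object A `variant_classifier`.
#' @param newdata Feature tibble/matrix.
#' @param ... Unused.
#' @return A list with `prob` (n x 3 mean class-probability matrix, columns
#'   `-1`, `0`, `1`) and `class` (integer predictions).
#' @export
predict.variant_classifier <- function(object, newdata, ...) {
  newdata <- drop_id_cols(newdata)
  X <- as.data.frame(as.matrix(tibble::as_tibble(newdata)[object$feature_names]))
  probs <- lapply(object$members, function(m) {
    pr <- predict(m, data = X, num.threads = 1)$predictions
    full <- matrix(0, nrow(pr), 3, dimnames = list(NULL, c("-1", "0", "1")))
    full[, colnames(pr)] <- pr
    full
  })
  mean_prob <- Reduce(`+`, probs) / length(probs)
  cls <- object$levels[apply(mean_prob, 1, which.max)]  # which.max: first max wins -> lowest class
  list(prob = mean_prob, class = as.integer(cls))
}

#' Train continuous variant-effect regression ensembles
#'
#' Member rosters follow the element class: promoters use one random
#' forest, one extremely-randomized forest and one gradient-boosted model;
#' enhancers use five random forests and five extremely-randomized forests
#' (all `n_estimators` estimators, square-root feature sampling for the
#' forests, member seeds `seed + index`). The default scope fits one model
#' per element — element-specific effect maps favour it — while
#' `scope = "per_class"` fits one model per element class.
#'
#' @param variants Featurized variant tibble ([featurize_variant_table()])
#'   including `element_id`, `element_class`, `effect` and `split`; only
#'   `split == "train"` rows are fitted when a `split` column is present.
#' @param scope `"per_element"` or `"per_class"`.
#' @param n_estimators Estimators per member.
#' @param seed Base seed.
#' @param min_train Minimum training variants per fitted model.
#'
#' @return A `variant_regressor` object (list of fitted ensembles keyed by
#'   element id or class).
#' @export
train_continuous <- function(variants, scope = c("per_element", "per_class"),
                             n_estimators = 1000, seed = 1L, min_train = 50) {
  scope <- match.arg(scope)
  stopifnot(all(c("element_id", "element_class", "effect") %in% names(variants)))
  train <- if ("split" %in% names(variants)) {
    variants[variants$split == "train", ]
  } else {
    variants
  }
  key_col <- if (scope == "per_element") "element_id" else "element_class"
  fits <- list()
  for (key in unique(train[[key_col]])) {
    sub <- train[train[[key_col]] == key, ]
    if (nrow(sub) < min_train) {
      warn(sprintf("%s `%s` skipped: only %d training variants (< %d)",
                   key_col, key, nrow(sub), min_train))
      next
    }
    el_class <- sub$element_class[1]
    roster <- variant_roster(el_class)
    X <- feature_matrix_of(drop_id_cols(sub))
    y <- sub$effect
    members <- purrr::map(seq_along(roster), function(i) {
      sp <- model_spec("regression", members = c("rf", "et", "gb"),
                       n_estimators = n_estimators, mtry = "sqrt",
                       seed = seed + i)
      fit_member(roster[i], X, y, sp, seed = seed + i)
    })
    fits[[key]] <- list(members = members, member_ids = roster,
                        feature_names = colnames(X))
  }
  if (!length(fits)) abort("no model could be fitted (too few training variants)")
  structure(list(fits = fits, scope = scope), class = "variant_regressor")
}

#' Predict continuous variant effects
#'
#' @param object A `variant_regressor`.
#' @param newdata Featurized variant tibble including the scope key column.
#' @param ... Unused.
#' @return Numeric predictions (`NA` for variants whose scope key has no
#'   fitted model).
#' @export
predict.variant_regressor <- function(object, newdata, ...) {
  key_col <- if (object$scope == "per_element") "element_id" else "element_class"
  out <- rep(NA_real_, nrow(newdata))
  for (key in names(object$fits)) {
    idx <- which(newdata[[key_col]] == key)
    if (!length(idx)) next
    fit <- object$fits[[key]]
    X <- as.matrix(tibble::as_tibble(drop_id_cols(newdata[idx, ]))[fit$feature_names])
    preds <- vapply(fit$members,
                    function(m) predict_member(m, X, "regression"),
                    numeric(length(idx)))
    preds <- matrix(preds, nrow = length(idx))
    out[idx] <- rowMeans(preds)
  }
  out
}

#' Evaluate variant-effect predictions
#'
#' Reports the Pearson correlation of predicted discrete labels with the
#' continuous measured effects, Pearson and Spearman of continuous
#' predictions, and three one-vs-other AUROCs of the discretized task
#' (positive vs negative, positive vs rest, negative vs rest), scored with
#' the corresponding class probability when available (or the predicted
#' label otherwise). A metric whose required classes are absent, or whose
#' predictions are constant, is reported as `NA` with a flag.
#'
#' @param truth Tibble with `effect` (continuous) and `class` (-1/0/+1).
#' @param pred_class Optional integer predictions.
#' @param pred_prob Optional class-probability matrix (columns `-1`,`0`,`1`).
#' @param pred_cont Optional continuous predictions.
#'
#' @return A tibble `metric`, `value`, `flagged`.
#' @export
evaluate_variants <- function(truth, pred_class = NULL, pred_prob = NULL,
                              pred_cont = NULL) {
  stopifnot(all(c("effect", "class") %in% names(truth)))
  res <- list()
  add <- function(metric, value, flagged = FALSE) {
    res[[length(res) + 1L]] <<- tibble::tibble(metric = metric,
                                               value = value,
                                               flagged = flagged)
  }
  safe_cor <- function(x, y, method = "pearson") {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NULL)
    cor(x, y, method = method)
  }
  if (!is.null(pred_class)) {
    r <- safe_cor(as.numeric(pred_class), truth$effect)
    if (is.null(r)) add("label_pearson", 0, TRUE) else add("label_pearson", r)
  }
  if (!is.null(pred_cont)) {
    r <- safe_cor(pred_cont, truth$effect)
    if (is.null(r)) add("pearson", 0, TRUE) else add("pearson", r)
    rs <- safe_cor(pred_cont, truth$effect, "spearman")
    rs <- if (is.null(rs)) NULL else suppressWarnings(
      cor(pred_cont, truth$effect, method = "spearman"))
    if (is.null(rs)) add("spearman", 0, TRUE) else add("spearman", rs)
  }
  score_for <- function(target_class) {
    if (!is.null(pred_prob)) {
      pred_prob[, as.character(target_class)]
    } else if (!is.null(pred_class)) {
      if (target_class == 1) as.numeric(pred_class) else -as.numeric(pred_class)
    } else if (!is.null(pred_cont)) {
      if (target_class == 1) pred_cont else -pred_cont
    } else {
      NULL
    }
  }
  aurocs <- list(
    auroc_pos_vs_neg = list(keep = truth$class != 0, pos = 1),
    auroc_pos_vs_rest = list(keep = rep(TRUE, nrow(truth)), pos = 1),
    auroc_neg_vs_rest = list(keep = rep(TRUE, nrow(truth)), pos = -1)
  )
  for (nm in names(aurocs)) {
    sp <- aurocs[[nm]]
    sc <- score_for(sp$pos)
    if (is.null(sc)) next
    lab <- as.integer(truth$class[sp$keep] == sp$pos)
    if (length(unique(lab)) < 2) {
      add(nm, NA_real_, TRUE)
    } else {
      add(nm, auroc(sc[sp$keep], lab))
    }
  }
  dplyr::bind_rows(res)
}

#' Cross-element transfer of continuous variant-effect models
#'
#' For every ordered pair of elements within an element class, fits the
#' class's regression roster on all of the training element's variants and
#' evaluates the Pearson correlation on all of the test element's variants;
#' the diagonal holds the supervised within-element value from a
#' deterministic k-fold cross-validation over that element's variants.
#'
#' @param variants Featurized variant tibble covering >= 2 elements of the
#'   class.
#' @param element_class Class to evaluate (`"promoter"` or `"enhancer"`).
#' @param n_estimators Estimators per member.
#' @param seed Base seed.
#' @param diag_folds Number of folds for the diagonal.
#'
#' @return A tibble `train_element`, `test_element`, `pearson`.
#' @export
cross_element_evaluate <- function(variants, element_class = "enhancer",
                                   n_estimators = 1000, seed = 1L,
                                   diag_folds = 10) {
  sub <- variants[variants$element_class == element_class, ]
  els <- unique(sub$element_id)
  if (length(els) < 2) abort("need at least 2 elements of the class")
  res <- list()
  fit_on <- function(dat) {
    train_continuous(dat[setdiff(names(dat), "split")],
                     scope = "per_class", n_estimators = n_estimators,
                     seed = seed)
  }
  for (a in els) {
    da <- sub[sub$element_id == a, ]
    # diagonal: k-fold CV within the element
    vid <- sprintf("v%05d", seq_len(nrow(da)))
    plan <- make_splits(vid, n_sections = diag_folds)
    sec <- plan$section[match(vid, plan$region_id)]
    preds <- rep(NA_real_, nrow(da))
    for (s in sort(unique(sec))) {
      fit <- fit_on(da[sec != s, ])
      preds[sec == s] <- predict(fit, da[sec == s, ])
    }
    res[[length(res) + 1L]] <- tibble::tibble(
      train_element = a, test_element = a,
      pearson = suppressWarnings(cor(preds, da$effect)))
    fit_all <- fit_on(da)
    for (b in setdiff(els, a)) {
      db <- sub[sub$element_id == b, ]
      pb <- predict(fit_all, db)
      res[[length(res) + 1L]] <- tibble::tibble(
        train_element = a, test_element = b,
        pearson = suppressWarnings(cor(pb, db$effect)))
    }
  }
  dplyr::bind_rows(res)
}
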