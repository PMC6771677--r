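# Supervised and cross-dataset prediction of MPRA output: deterministic
# ten-section splits, the four-regressor / two-classifier ensembles, the
# shuffle-label null, and fold-wise evaluation with the nine tests.

#' Deterministic split of region ids into sections
#'
#' Regions are ordered lexicographically (locale-independent radix sort) and
#' dealt round-robin into `n_sections` sections, so the same id set always
#' produces the same plan regardless of input order. When a `paired` plan is
#' supplied, shared region ids inherit its section assignment and only the
#' remaining ids are dealt round-robin, keeping paired datasets consistent.
#'
#' @param region_ids Character vector of unique region ids.
#' @param n_sections Number of sections (folds).
#' @param paired Optional split plan of a partner dataset sharing regions.
#'
#' @return A tibble `region_id`, `section` (0-based).
#' @export
make_splits <- function(region_ids, n_sections = 10, paired = NULL) {
  if (anyDuplicated(region_ids)) abort("duplicate region ids")
  n_sections <- assert_count(n_sections, "n_sections")
  if (length(region_ids) < n_sections) {
    abort("need at least as many regions as sections")
  }
  ids <- sort_ids(region_ids)
  section <- rep(NA_integer_, length(ids))
  if (!is.null(paired)) {
    hit <- match(ids, paired$region_id)
    section[!is.na(hit)] <- paired$section[hit[!is.na(hit)]]
  }
  free <- which(is.na(section))
  section[free] <- (seq_along(free) - 1L) %% n_sections
  tibble::tibble(region_id = ids, section = section)
}

#' Ensemble model specification
#'
#' @param task `"regression"` or `"classification"`.
#' @param members Member algorithm ids; defaults to the full roster for the
#'   task (`enet`, `rf`, `et`, `gb` for regression; `rf`, `et` for
#'   classification).
#' @param n_estimators Trees/boosting rounds per tree-based member.
#' @param elastic_net_mixing Elastic-net mixing ratio between the L1 and L2
#'   penalties.
#' @param mtry `"default"` (implementation default) or `"sqrt"` (square root
#'   of the feature count, used by the variant-effect models).
#' @param seed Base seed; member `i` uses `seed + i`.
#'
#' @return A `model_spec` object.
#' @export
model_spec <- function(task = c("regression", "classification"),
                       members = NULL, n_estimators = 1000,
                       elastic_net_mixing = 0.5, mtry = "default",
                       seed = 1L) {
  task <- match.arg(task)
  members <- members %||%
    switch(task, regression = c("enet", "rf", "et", "gb"),
           classification = c("rf", "et"))
  allowed <- switch(task, regression = c("enet", "rf", "et", "gb"),
                    classification = c("rf", "et"))
  if (!all(members %in% allowed)) {
    abort(sprintf("unknown member(s) for %s: %s", task,
                  paste(setdiff(members, allowed), collapse = ", ")))
  }
  structure(list(task = task, members = members,
                 n_estimators = assert_count(n_estimators, "n_estimators"),
                 elastic_net_mixing = assert_proportion(elastic_net_mixing,
                                                        "elastic_net_mixing"),
                 mtry = match.arg(mtry, c("default", "sqrt")),
                 seed = assert_count(seed, "seed",
                                     min = -.Machine$integer.max)),
            class = "model_spec")
}

feature_matrix_of <- function(features) {
  feats <- setdiff(names(features), "region_id")
  X <- as.matrix(features[feats])
  if (!is.numeric(X)) abort("features must be numeric")
  if (anyNA(X)) abort("features contain missing values")
  X
}

mtry_value <- function(spec, p, task) {
  if (spec$mtry == "sqrt") {
    max(1L, floor(sqrt(p)))
  } else if (task == "classification") {
    max(1L, floor(sqrt(p)))       # ranger's own classification default
  } else {
    max(1L, floor(p / 3))         # ranger's own regression default
  }
}

fit_member <- function(id, X, y, spec, seed) {
  p <- ncol(X)
  df <- as.data.frame(X)
  df$.y <- y
  switch(
    id,
    enet = {
      fit <- glmnet::glmnet(X, y, alpha = spec$elastic_net_mixing,
                            standardize = TRUE)
      list(kind = "enet", fit = fit, lambda = min(fit$lambda))
    },
    rf = {
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = spec$n_estimators, seed = seed, num.threads = 1,
        mtry = mtry_value(spec, p, spec$task), min.node.size = 1,
        probability = spec$task == "classification",
        respect.unordered.factors = TRUE)
      list(kind = "rf", fit = fit)
    },
    et = {
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = spec$n_estimators, seed = seed, num.threads = 1,
        mtry = mtry_value(spec, p, spec$task), min.node.size = 1,
        splitrule = "extratrees", num.random.splits = 1,
        replace = FALSE, sample.fraction = 1,
        probability = spec$task == "classification")
      list(kind = "et", fit = fit)
    },
    gb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = list(max_depth = 3, eta = 0.1, subsample = 1,
                      colsample_bytree = 1, nthread = 1, seed = seed,
                      objective = "reg:squarederror"),
        data = dtrain, nrounds = spec$n_estimators, verbose = 0)
      list(kind = "gb", fit = fit)
    },
    abort(sprintf("unknown member id `%s`", id))
  )
}

predict_member <- function(member, X, task) {
  switch(
    member$kind,
    enet = as.numeric(predict(member$fit, newx = X, s = member$lambda)),
    gb = as.numeric(predict(member$fit, xgboost::xgb.DMatrix(X))),
    rf = ,
    et = {
      pr <- predict(member$fit, data = as.data.frame(X),
                    num.threads = 1)$predictions
      if (task == "classification") as.numeric(pr[, "1"]) else as.numeric(pr)
    }
  )
}

new_ensemble <- function(task, members, member_ids, feature_names, spec,
                         shuffled = FALSE) {
  structure(list(task = task, members = members, member_ids = member_ids,
                 feature_names = feature_names, spec = spec,
                 shuffled = shuffled),
            class = "mpra_ensemble")
}

#' Train the regression ensemble
#'
#' Fits the four regression members — an elastic-net linear model
#' (standardized features, mixing ratio from the spec), a random forest, an
#' extremely-randomized-trees forest and a gradient-boosted-trees model,
#' each with `n_estimators` estimators — and defines the ensemble prediction
#' as their arithmetic mean.
#'
#' @param features Tibble of numeric features (a `region_id` column is
#'   ignored for fitting).
#' @param y Quantitative response.
#' @param spec A [model_spec()] with `task = "regression"`.
#'
#' @return An `mpra_ensemble` object; see [predict.mpra_ensemble()].
#' @export
train_regression_ensemble <- function(features, y,
                                      spec = model_spec("regression")) {
  stopifnot(spec$task == "regression")
  X <- feature_matrix_of(features)
  if (nrow(X) < 50) abort("regression training needs n >= 50")
  if (length(unique(y)) < 2) abort("`y` is constant")
  members <- purrr::imap(setNames(spec$members, spec$members),
                         function(id, nm) {
                           fit_member(id, X, y, spec,
                                      seed = spec$seed + match(id, spec$members))
                         })
  new_ensemble("regression", members, spec$members, colnames(X), spec)
}

#' Train the classification ensemble
#'
#' Fits the two classification members — random-forest and
#' extremely-randomized-trees probability forests with `n_estimators` trees —
#' and defines the ensemble probability as the mean of the member
#' probabilities.
#'
#' @param features Tibble of numeric features.
#' @param labels Binary 0/1 labels; both classes need at least 10 examples.
#' @param spec A [model_spec()] with `task = "classification"`.
#'
#' @return An `mpra_ensemble` object.
#' @export
train_classification_ensemble <- function(features, labels,
                                          spec = model_spec("classification")) {
  stopifnot(spec$task == "classification")
  X <- feature_matrix_of(features)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) abort("both classes must be present in training labels")
  if (any(tab < 10)) abort("each class needs at least 10 training examples")
  yf <- factor(labels, levels = c(0, 1))
  members <- purrr::map(setNames(spec$members, spec$members), function(id) {
    fit_member(id, X, yf, spec, seed = spec$seed + match(id, spec$members))
  })
  new_ensemble("classification", members, spec$members, colnames(X), spec)
}

#' Predict from an ensemble
#'
#' @param object An `mpra_ensemble`.
#' @param newdata Tibble or matrix of features (must contain the training
#'   feature columns).
#' @param type `"mean"` for the ensemble prediction (the arithmetic mean of
#'   member outputs; predicted probability of the active class for
#'   classification) or `"members"` for the per-member matrix.
#' @param ... Unused.
#' @return Numeric vector, or matrix when `type = "members"`.
#' @export
predict.mpra_ensemble <- function(object, newdata, type = c("mean", "members"),
                                  ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols)) {
      abort(paste0("newdata lacks feature(s): ",
                   paste(head(missing_cols, 5), collapse = ", ")))
    }
    newdata <- as.matrix(newdata[object$feature_names])
  } else {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  preds <- vapply(object$members,
                  function(m) predict_member(m, newdata, object$task),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata),
                  dimnames = list(NULL, object$member_ids))
  if (type == "members") preds else rowMeans(preds)
}

#' @export
print.mpra_ensemble <- function(x, ...) {
  cat(sprintf("<mpra_ensemble> %s%s: members [%s], %d estimators, %d features\n",
              x$task, if (x$shuffled) " (shuffle null)" else "",
              paste(x$member_ids, collapse = ", "),
              x$spec$n_estimators, length(x$feature_names)))
  invisible(x)
}

#' Train a shuffle-label null ensemble
#'
#' Permutes the training response (only the training response — evaluation
#' targets are untouched) before fitting the ensemble of the requested task,
#' quantifying what the ensemble achieves by chance.
#'
#' @param features Tibble of numeric features.
#' @param y Quantitative response (regression) — supply exactly one of `y`
#'   and `labels`.
#' @param labels Binary labels (classification).
#' @param spec A [model_spec()].
#' @param seed Seed of the permutation.
#'
#' @return An `mpra_ensemble` with `shuffled = TRUE`.
#' @export
shuffle_null <- function(features, y = NULL, labels = NULL,
                         spec = NULL, seed = 1L) {
  if (is.null(y) == is.null(labels)) {
    abort("supply exactly one of `y` and `labels`")
  }
  n <- nrow(features)
  perm <- with_seed(seed, sample.int(n, n))
  if (!is.null(y)) {
    spec <- spec %||% model_spec("regression")
    fit <- train_regression_ensemble(features, y[perm], spec)
  } else {
    spec <- spec %||% model_spec("classification")
    fit <- train_classification_ensemble(features, labels[perm], spec)
  }
  fit$shuffled <- TRUE
  fit
}

eval_fold <- function(pred, truth, task) {
  if (task == "regression") {
    regression_tests(pred, truth)
  } else {
    classification_tests(pred, truth)
  }
}

new_eval <- function(fold_stats, metadata) {
  folds <- dplyr::bind_rows(fold_stats)
  summary <- folds |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(mean = mean(.data$statistic),
                     sd = if (dplyr::n() > 1) stats::sd(.data$statistic) else 0,
                     n_folds = dplyr::n(), .groups = "drop")
  structure(list(folds = folds, summary = summary, metadata = metadata),
            class = "mpra_eval")
}

#' @export
print.mpra_eval <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<mpra_eval> %s%s, %d fold(s)\n", md$task,
              if (!is.null(md$train_dataset))
                sprintf(" [%s -> %s]", md$train_dataset, md$test_dataset)
              else "",
              length(unique(x$folds$fold))))
  print(x$summary)
  invisible(x)
}

#' Cross-validate an ensemble within one dataset
#'
#' Ten-fold cross-validation over the deterministic section plan: each fold
#' trains on nine sections and evaluates on the remaining one with the
#' regression or classification test battery, and the per-fold statistics
#' are aggregated as mean and standard deviation. Classification folds whose
#' test labels are single-class are skipped with a diagnostic.
#'
#' @param features Tibble with `region_id` + numeric features.
#' @param response Tibble with `region_id` and `activity` (regression) or
#'   `label` (classification).
#' @param task `"regression"` or `"classification"`.
#' @param spec Optional [model_spec()].
#' @param split_plan Optional [make_splits()] plan; built from the region
#'   ids when omitted.
#' @param folds Sections to evaluate (0-based); default all. Evaluating a
#'   subset is useful when many replicate runs are needed.
#' @param shuffle Train the shuffle-label null instead of the real model.
#' @param shuffle_seed Permutation seed for the null.
#'
#' @return An `mpra_eval` object with `folds`, `summary` and `metadata`
#'   (tidy with [generics::tidy()], summarise with [generics::glance()]).
#' @export
cross_validate <- function(features, response,
                           task = c("regression", "classification"),
                           spec = NULL, split_plan = NULL, folds = NULL,
                           shuffle = FALSE, shuffle_seed = 1L) {
  task <- match.arg(task)
  spec <- spec %||% model_spec(task)
  stopifnot("region_id" %in% names(features))
  resp_col <- if (task == "regression") "activity" else "label"
  stopifnot(resp_col %in% names(response))
  split_plan <- split_plan %||% make_splits(features$region_id)
  folds <- folds %||% sort(unique(split_plan$section))

  dat <- dplyr::inner_join(features, response[c("region_id", resp_col)],
                           by = "region_id")
  sec <- split_plan$section[match(dat$region_id, split_plan$region_id)]
  if (anyNA(sec)) abort("split plan does not cover all regions")

  fold_stats <- list()
  for (s in folds) {
    test_idx <- which(sec == s)
    train_idx <- which(sec != s)
    y_tr <- dat[[resp_col]][train_idx]
    y_te <- dat[[resp_col]][test_idx]
    if (task == "classification" && length(unique(y_te)) < 2) {
      warn(sprintf("fold %d skipped: single-class test labels", s))
      next
    }
    Xtr <- dat[train_idx, setdiff(names(features), character()), drop = FALSE]
    Xte <- dat[test_idx, , drop = FALSE]
    fit <- if (shuffle) {
      if (task == "regression") {
        shuffle_null(Xtr, y = y_tr, spec = spec, seed = shuffle_seed + s)
      } else {
        shuffle_null(Xtr, labels = y_tr, spec = spec, seed = shuffle_seed + s)
      }
    } else if (task == "regression") {
      train_regression_ensemble(Xtr, y_tr, spec)
    } else {
      train_classification_ensemble(Xtr, y_tr, spec)
    }
    pred <- predict(fit, Xte)
    st <- eval_fold(pred, y_te, task)
    st$fold <- s
    st$region_id <- list(dat$region_id[test_idx])
    st$predictions <- list(pred)
    fold_stats[[length(fold_stats) + 1L]] <- st
  }
  if (!length(fold_stats)) abort("no evaluable folds")
  new_eval(fold_stats, list(task = task, shuffled = shuffle,
                            feature_subset = "supplied",
                            n_sections = length(unique(split_plan$section))))
}

#' Evaluate a model trained on one dataset against another
#'
#' Ten-fold cross-dataset evaluation: fold `s` trains on the training
#' dataset's nine sections other than `s` and evaluates on the test
#' dataset's section `s` (the paired split plan keeps shared region ids in
#' the same section). Before fitting, training rows whose region id matches
#' — or whose genomic interval overlaps by at least 1 bp, when intervals are
#' supplied — any test-fold region are removed, so no tested region leaks
#' into training.
#'
#' @param train_features,train_response Training dataset (as in
#'   [cross_validate()]).
#' @param test_features,test_response Test dataset; feature namespaces must
#'   share at least one column, and only shared columns are used.
#' @param task `"regression"` or `"classification"`.
#' @param spec Optional [model_spec()].
#' @param split_plan Optional shared split plan (built from the union of
#'   region ids when omitted).
#' @param folds Sections to evaluate; default all.
#' @param train_intervals,test_intervals Optional interval tibbles
#'   (`region_id`, `chrom`, `start`, `end`) enabling the overlap exclusion.
#'
#' @return An `mpra_eval` object.
#' @export
cross_dataset_evaluate <- function(train_features, train_response,
                                   test_features, test_response,
                                   task = c("regression", "classification"),
                                   spec = NULL, split_plan = NULL,
                                   folds = NULL,
                                   train_intervals = NULL,
                                   test_intervals = NULL) {
  task <- match.arg(task)
  spec <- spec %||% model_spec(task)
  shared_feats <- intersect(setdiff(names(train_features), "region_id"),
                            setdiff(names(test_features), "region_id"))
  if (!length(shared_feats)) abort("feature namespaces are disjoint")
  resp_col <- if (task == "regression") "activity" else "label"

  if (is.null(split_plan)) {
    split_plan <- make_splits(test_features$region_id)
    split_plan <- make_splits(union(train_features$region_id,
                                    test_features$region_id),
                              paired = split_plan)
  }
  tr <- dplyr::inner_join(train_features[c("region_id", shared_feats)],
                          train_response[c("region_id", resp_col)],
                          by = "region_id")
  te <- dplyr::inner_join(test_features[c("region_id", shared_feats)],
                          test_response[c("region_id", resp_col)],
                          by = "region_id")
  sec_tr <- split_plan$section[match(tr$region_id, split_plan$region_id)]
  sec_te <- split_plan$section[match(te$region_id, split_plan$region_id)]
  if (anyNA(sec_tr) || anyNA(sec_te)) {
    abort("split plan does not cover all regions")
  }
  folds <- folds %||% sort(unique(split_plan$section))

  fold_stats <- list()
  for (s in folds) {
    test_idx <- which(sec_te == s)
    if (!length(test_idx)) next
    test_ids <- te$region_id[test_idx]
    drop <- tr$region_id %in% test_ids | sec_tr == s
    if (!is.null(train_intervals) && !is.null(test_intervals)) {
      ti <- test_intervals[test_intervals$region_id %in% test_ids, ]
      ov <- interval_overlap_binary(train_intervals, ti)
      drop <- drop | (tr$region_id %in% train_intervals$region_id[ov == 1])
    }
    train_idx <- which(!drop)
    y_tr <- tr[[resp_col]][train_idx]
    y_te <- te[[resp_col]][test_idx]
    if (task == "classification" && length(unique(y_te)) < 2) {
      warn(sprintf("fold %d skipped: single-class test labels", s))
      next
    }
    fit <- if (task == "regression") {
      train_regression_ensemble(tr[train_idx, c("region_id", shared_feats)],
                                y_tr, spec)
    } else {
      train_classification_ensemble(tr[train_idx, c("region_id", shared_feats)],
                                    y_tr, spec)
    }
    pred <- predict(fit, te[test_idx, , drop = FALSE])
    st <- eval_fold(pred, y_te, task)
    st$fold <- s
    st$region_id <- list(test_ids)
    st$predictions <- list(pred)
    fold_stats[[length(fold_stats) + 1L]] <- st
  }
  if (!length(fold_stats)) abort("no evaluable folds")
  new_eval(fold_stats, list(task = task, shuffled = FALSE,
                            train_dataset = "train", test_dataset = "test",
                            n_sections = length(unique(split_plan$section))))
}
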