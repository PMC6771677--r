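# Split plans, ensemble contracts, cross-validation and transfer.
# Unit tests use small estimator counts; the full-size settings are
# exercised in the acceptance suite.

test_that("split plans are deterministic, balanced and pairing-consistent", {
  ids <- sprintf("r%02d", 1:20)
  plan <- make_splits(ids)
  expect_equal(as.vector(table(plan$section)), rep(2L, 10))
  # input order never matters
  expect_identical(plan, make_splits(rev(ids)))
  expect_identical(plan, make_splits(sample(ids)))
  # paired datasets over identical ids inherit sections exactly
  plan2 <- make_splits(ids, paired = plan)
  expect_identical(plan, plan2)
  # every region appears in exactly one section
  expect_equal(sort(plan$region_id), sort(ids))
  expect_error(make_splits(c("a", "a", "b")), "duplicate")
  expect_error(make_splits(c("a", "b")), "at least as many")
})

test_that("ensemble predictions equal the arithmetic member mean", {
  dat <- make_linear_dataset(n = 120, seed = 21)
  spec <- model_spec("regression", n_estimators = 60, seed = 1)
  fit <- train_regression_ensemble(dat$features, dat$y, spec)
  members <- predict(fit, dat$features, type = "members")
  expect_equal(ncol(members), 4)
  expect_lt(max(abs(predict(fit, dat$features) - rowMeans(members))), 1e-9)

  cls_spec <- model_spec("classification", n_estimators = 60, seed = 1)
  cfit <- train_classification_ensemble(dat$features, dat$labels, cls_spec)
  cm <- predict(cfit, dat$features, type = "members")
  expect_equal(ncol(cm), 2)
  p <- predict(cfit, dat$features)
  expect_lt(max(abs(p - rowMeans(cm))), 1e-9)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("refitting with the same seed reproduces predictions exactly", {
  dat <- make_linear_dataset(n = 100, seed = 22)
  spec <- model_spec("regression", n_estimators = 40, seed = 7)
  f1 <- train_regression_ensemble(dat$features, dat$y, spec)
  f2 <- train_regression_ensemble(dat$features, dat$y, spec)
  expect_identical(predict(f1, dat$features), predict(f2, dat$features))
})

test_that("training preconditions are enforced", {
  dat <- make_linear_dataset(n = 60, seed = 23)
  expect_error(train_regression_ensemble(dat$features[1:30, ], dat$y[1:30]),
               "n >= 50")
  expect_error(train_regression_ensemble(dat$features, rep(1, 60)),
               "constant")
  expect_error(train_classification_ensemble(dat$features, rep(1L, 60)),
               "both classes")
})

test_that("tidy and glance summarise ensembles and evaluations", {
  dat <- make_linear_dataset(n = 100, seed = 30)
  fit <- train_regression_ensemble(dat$features, dat$y,
                                   model_spec("regression", n_estimators = 30))
  td <- generics::tidy(fit)
  expect_equal(td$member, c("enet", "rf", "et", "gb"))
  gl <- generics::glance(fit)
  expect_equal(gl$task, "regression")
  expect_false(gl$shuffled)
})

test_that("the shuffle null permutes only the training targets", {
  dat <- make_linear_dataset(n = 300, p_noise = 4, seed = 24)
  spec <- model_spec("regression", n_estimators = 50, seed = 2)
  null_fit <- shuffle_null(dat$features[1:200, ], y = dat$y[1:200],
                           spec = spec, seed = 5)
  expect_true(null_fit$shuffled)
  # held-out correlation collapses near zero for the null model
  pred <- predict(null_fit, dat$features[201:300, ])
  real_fit <- train_regression_ensemble(dat$features[1:200, ], dat$y[1:200],
                                        spec)
  pred_real <- predict(real_fit, dat$features[201:300, ])
  rho_null <- abs(cor(pred, dat$y[201:300], method = "spearman"))
  rho_real <- cor(pred_real, dat$y[201:300], method = "spearman")
  expect_lt(rho_null, rho_real)
  # permutation reproducible
  null_fit2 <- shuffle_null(dat$features[1:200, ], y = dat$y[1:200],
                            spec = spec, seed = 5)
  expect_identical(predict(null_fit, dat$features[201:300, ]),
                   predict(null_fit2, dat$features[201:300, ]))
})

test_that("cross-validation partitions folds exactly and aggregates", {
  dat <- make_linear_dataset(n = 200, p_noise = 3, seed = 25)
  resp <- tibble::tibble(region_id = dat$features$region_id, activity = dat$y)
  spec <- model_spec("regression", members = "enet")
  # y equal to a feature: elastic net alone reaches Spearman 1 per fold
  resp_exact <- tibble::tibble(region_id = dat$features$region_id,
                               activity = dat$features$causal)
  ev <- cross_validate(dat$features, resp_exact, "regression", spec = spec)
  sp <- ev$folds$statistic[ev$folds$test == "spearman"]
  expect_true(all(sp > 0.999))
  # fold partition is exact
  ids <- unlist(ev$folds$region_id[!duplicated(ev$folds$fold)])
  expect_setequal(ids, dat$features$region_id)
  expect_equal(length(ids), nrow(dat$features))
  # aggregate equals mean/sd over folds
  expect_equal(ev$summary$mean[ev$summary$test == "spearman"], mean(sp))
  expect_equal(ev$summary$sd[ev$summary$test == "spearman"], sd(sp))
})

test_that("nonlinear signal favours the tree ensemble over the linear model", {
  set.seed(26)
  n <- 600
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  y <- xor(x1, x2) + rnorm(n, 0, 0.3)
  feats <- tibble::tibble(region_id = sprintf("r%03d", 1:n),
                          x1 = x1, x2 = x2, f = rnorm(n))
  resp <- tibble::tibble(region_id = feats$region_id, activity = y)
  ev_lin <- cross_validate(feats, resp, "regression",
                           spec = model_spec("regression", members = "enet"),
                           folds = 0:4)
  ev_full <- cross_validate(feats, resp, "regression",
                            spec = model_spec("regression",
                                              members = c("rf", "et"),
                                              n_estimators = 100),
                            folds = 0:4)
  expect_gt(ev_full$summary$mean[ev_full$summary$test == "spearman"],
            ev_lin$summary$mean[ev_lin$summary$test == "spearman"])
})

test_that("cross-dataset evaluation reduces to cross-validation on itself", {
  dat <- make_linear_dataset(n = 150, p_noise = 3, seed = 27)
  resp <- tibble::tibble(region_id = dat$features$region_id, activity = dat$y)
  spec <- model_spec("regression", members = "enet")
  plan <- make_splits(dat$features$region_id)
  ev_cv <- cross_validate(dat$features, resp, "regression", spec = spec,
                          split_plan = plan)
  ev_cd <- cross_dataset_evaluate(dat$features, resp, dat$features, resp,
                                  "regression", spec = spec,
                                  split_plan = plan)
  expect_equal(ev_cd$folds$statistic, ev_cv$folds$statistic, tolerance = 1e-10)
})

test_that("region leakage into training folds is removed", {
  dat <- make_linear_dataset(n = 120, p_noise = 2, seed = 28)
  feats <- dat$features
  resp <- tibble::tibble(region_id = feats$region_id, activity = dat$y)
  plan <- make_splits(feats$region_id)
  # same regions on both sides: every training fold must exclude the fold's
  # test ids; verified via the reduction identity plus interval overlap
  intervals <- tibble::tibble(region_id = feats$region_id, chrom = "chr1",
                              start = seq(0, by = 100,
                                          length.out = nrow(feats)),
                              end = seq(50, by = 100,
                                        length.out = nrow(feats)))
  ev <- cross_dataset_evaluate(feats, resp, feats, resp, "regression",
                               spec = model_spec("regression",
                                                 members = "enet"),
                               split_plan = plan,
                               train_intervals = intervals,
                               test_intervals = intervals)
  expect_equal(length(unique(ev$folds$fold)), 10)
  expect_error(
    cross_dataset_evaluate(feats, resp,
                           dplyr::rename(feats, z1 = "causal", z2 = "noise_1",
                                         z3 = "noise_2"),
                           resp, "regression"),
    "disjoint")
})

test_that("degenerate classification folds are skipped with a diagnostic", {
  dat <- make_linear_dataset(n = 200, p_noise = 2, seed = 29)
  plan <- make_splits(dat$features$region_id)
  # balanced labels everywhere except section 9, which is all-negative
  # (alternating blocks of 10 cut across the round-robin sections)
  sec <- plan$section[match(dat$features$region_id, plan$region_id)]
  labels <- as.integer(((seq_len(200) - 1) %/% 10) %% 2 == 0)
  labels[sec == 9] <- 0L
  resp <- tibble::tibble(region_id = dat$features$region_id, label = labels)
  expect_warning(
    ev <- cross_validate(dat$features, resp, "classification",
                         spec = model_spec("classification",
                                           n_estimators = 30),
                         split_plan = plan),
    "single-class")
  expect_equal(length(unique(ev$folds$fold)), 9)
  expect_false(9 %in% ev$folds$fold)
})
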