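# Variant featurization and effect prediction.

test_that("feature differencing has the zero-variant and antisymmetry identities", {
  set.seed(51)
  wt <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  pos <- 19L
  ref <- substr(wt, 20, 20)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  # synthetic control: alt == ref gives exactly the zero vector
  zero <- featurize_variant(wt, pos, ref, ref)
  expect_true(all(zero == 0))
  # antisymmetry: diff(wt -> var) = -diff(var -> wt)
  fwd <- featurize_variant(wt, pos, ref, alt)
  var_seq <- wt
  substr(var_seq, 20, 20) <- alt
  bwd <- featurize_variant(var_seq, pos, alt, ref)
  expect_equal(fwd, -bwd)
  # ref mismatch rejected with position and observed base
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[2]
  expect_error(featurize_variant(wt, pos, wrong, alt), "position 19")
})

test_that("destroying a planted motif changes the hit count by one", {
  pwm <- toy_pwm()
  cons <- pwm_consensus(pwm)
  set.seed(52)
  bg <- paste(sample(c("A", "T"), 60, replace = TRUE), collapse = "")
  wt <- paste0(substr(bg, 1, 30), cons, substr(bg, 41, 60))
  # mutate the fifth base of the motif (a T in the consensus) to C: one
  # mismatch pushes the site above the stringent p-value threshold
  pos <- 34L
  ref <- substr(wt, 35, 35)
  expect_equal(ref, substr(cons, 5, 5))
  d <- featurize_variant(wt, pos, ref, "C", pwms = list(pwm),
                         p_threshold = 1e-5)
  expect_equal(unname(d["n_motifs"]), -1)
})

test_that("concatenation mode carries both alleles", {
  wt <- strrep("ACGT", 10)
  cc <- featurize_variant(wt, 0L, "A", "G", mode = "concat")
  expect_true(any(startsWith(names(cc), "wt_")))
  expect_true(any(startsWith(names(cc), "var_")))
  expect_equal(sum(startsWith(names(cc), "wt_")),
               sum(startsWith(names(cc), "var_")))
})

test_that("variant tables are featurized consistently with the single-variant path", {
  sat <- simulate_saturation(satmut_sim_config(element_length = 30, seed = 53))
  fv <- featurize_variant_table(sat$variants, c(element_01 = sat$element_seq))
  expect_equal(nrow(fv), nrow(sat$variants))
  i <- 7
  single <- featurize_variant(sat$element_seq, sat$variants$position[i],
                              sat$variants$ref[i], sat$variants$alt[i])
  kcols <- names(single)
  expect_equal(as.numeric(fv[i, kcols]), unname(single))
})

test_that("discrete classifier predicts classes by mean probability", {
  cfg <- satmut_sim_config(element_length = 120, effect_sparsity = 0.5,
                           effect_sd = 2, noise_sd = 0.05,
                           class_threshold = 0.5, seed = 54)
  sat <- simulate_saturation(cfg)
  fv <- featurize_variant_table(sat$variants, c(element_01 = sat$element_seq))
  tr <- fv[fv$split == "train", ]
  te <- fv[fv$split == "test", ]
  fit <- train_discrete(tr, tr$class, n_estimators = 100, seed = 1)
  pred <- predict(fit, te)
  expect_true(all(pred$class %in% c(-1L, 0L, 1L)))
  expect_equal(rowSums(pred$prob), rep(1, nrow(te)), tolerance = 1e-9)
  expect_equal(pred$class,
               c(-1L, 0L, 1L)[apply(pred$prob, 1, which.max)])
  # the predicted labels track the continuous effect
  r <- cor(pred$class, te$effect)
  expect_gt(r, 0.3)
  expect_error(train_discrete(tr, rep(0L, nrow(tr))), "2 classes")
})

test_that("continuous per-element ensembles learn additive effects", {
  cfg <- satmut_sim_config(element_length = 150, effect_sparsity = 0.3,
                           effect_sd = 2, noise_sd = 0.1, seed = 55)
  sat <- simulate_saturation(cfg)
  fv <- featurize_variant_table(sat$variants, c(element_01 = sat$element_seq))
  fit <- train_continuous(fv, scope = "per_element", n_estimators = 150,
                          seed = 1)
  te <- fv[fv$split == "test", ]
  pred <- predict(fit, te)
  expect_gt(cor(pred, te$effect), 0.3)
})

test_that("evaluation metrics match their definitions on a hand fixture", {
  # 9 variants, predictions equal to truth classes, effects monotone
  truth <- tibble::tibble(effect = c(-3, -2, -1, -0.1, 0, 0.1, 1, 2, 3),
                          class = c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L))
  ev <- evaluate_variants(truth, pred_class = truth$class)
  lp <- ev$value[ev$metric == "label_pearson"]
  expect_equal(lp, cor(as.numeric(truth$class), truth$effect))
  expect_gt(lp, 0.9)
  aurocs <- ev$value[grepl("^auroc", ev$metric)]
  expect_true(all(aurocs == 1))

  # constant predictions are flagged, not crashed
  ev0 <- evaluate_variants(truth, pred_class = rep(0L, 9))
  expect_true(ev0$flagged[ev0$metric == "label_pearson"])
  expect_equal(ev0$value[ev0$metric == "label_pearson"], 0)

  # AUROC agrees with pair counting on 30 variants
  set.seed(56)
  tr30 <- tibble::tibble(effect = rnorm(30),
                         class = sample(c(-1L, 0L, 1L), 30, replace = TRUE))
  sc <- rnorm(30)
  prob <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("-1", "0", "1")))
  prob <- prob / rowSums(prob)
  ev30 <- evaluate_variants(tr30, pred_prob = prob, pred_cont = sc)
  keep <- tr30$class != 0
  expect_equal(ev30$value[ev30$metric == "auroc_pos_vs_neg"],
               pair_count_auroc(prob[keep, "1"],
                                as.integer(tr30$class[keep] == 1)),
               tolerance = 1e-12)
  expect_equal(ev30$value[ev30$metric == "auroc_neg_vs_rest"],
               pair_count_auroc(prob[, "-1"],
                                as.integer(tr30$class == -1)),
               tolerance = 1e-12)
})

test_that("cross-element transfer is weaker than within-element fitting", {
  seqs <- list()
  vars <- list()
  for (i in 1:2) {
    cfg <- satmut_sim_config(element_length = 100, effect_sparsity = 0.4,
                             effect_sd = 2, noise_sd = 0.1, seed = 60 + i)
    sat <- simulate_saturation(cfg, element_id = sprintf("el_%d", i))
    seqs[[sprintf("el_%d", i)]] <- sat$element_seq
    vars[[i]] <- sat$variants
  }
  fv <- featurize_variant_table(dplyr::bind_rows(vars),
                                unlist(seqs))
  mat <- cross_element_evaluate(fv, element_class = "enhancer",
                                n_estimators = 60, seed = 1, diag_folds = 5)
  expect_equal(nrow(mat), 4)
  expect_setequal(unique(mat$train_element), c("el_1", "el_2"))
  diag_mean <- mean(mat$pearson[mat$train_element == mat$test_element])
  off_mean <- mean(mat$pearson[mat$train_element != mat$test_element])
  expect_gt(diag_mean, off_mean)
})
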