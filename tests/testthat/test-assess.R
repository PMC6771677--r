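# The nine-test battery, rank aggregation, subsampling, and the
# shuffled-mean control.

test_that("regression tests recover hand-checked correlations", {
  n <- 12
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  y <- x
  res <- regression_tests(x, y)
  expect_equal(nrow(res), 7)
  # all six correlation tests are exactly 1 for x = y; the quintile test
  # compares x against a coarsened copy of itself, so it equals the
  # spearman of x with its own quintile index
  expect_equal(res$statistic[res$test != "spearman_quintile"], rep(1, 6))
  qi_oracle <- vapply(y, function(v) {
    1L + sum(v > quantile(y, c(.2, .4, .6, .8), names = FALSE))
  }, integer(1))
  expect_equal(res$statistic[res$test == "spearman_quintile"],
               suppressWarnings(cor(x, qi_oracle, method = "spearman")))
  expect_gt(res$statistic[res$test == "spearman_quintile"], 0.9)

  # perfect reversal
  res_rev <- regression_tests(1:12, 12:1)
  expect_equal(res_rev$statistic[res_rev$test == "kendall"], -1)

  # Kendall equals brute-force pair counting (with ties)
  set.seed(5)
  xr <- sample(1:6, n, replace = TRUE)
  yr <- rnorm(n)
  res_r <- regression_tests(xr, yr)
  expect_equal(res_r$statistic[res_r$test == "kendall"],
               pair_count_kendall(xr, yr), tolerance = 1e-12)

  # constant feature is flagged with statistic 0, p 1
  res_c <- regression_tests(rep(2, n), yr)
  expect_true(all(res_c$statistic == 0))
  expect_true(all(res_c$p == 1))
  expect_true(all(res_c$flagged))

  expect_error(regression_tests(1:5, 1:5), "n >= 8")
})

test_that("quintile binning assigns ties to the lower bin", {
  y <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  # breakpoints fall on the tied values; a value equal to a breakpoint must
  # stay in the lower bin
  brk <- quantile(y, c(.2, .4, .6, .8), names = FALSE)
  qi <- vapply(y, function(v) 1L + sum(v > brk), integer(1))
  expect_equal(qi, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  res <- regression_tests(seq_along(y), y)
  expect_false(any(is.na(res$statistic)))
  expect_equal(res$statistic[res$test == "spearman_quintile"],
               suppressWarnings(cor(seq_along(y), qi, method = "spearman")))
})

test_that("AUROC and AUPRC match brute-force oracles", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)

  set.seed(7)
  scores <- sample(seq(0, 1, by = 0.1), 50, replace = TRUE)  # many ties
  labels <- rbinom(50, 1, 0.4)
  expect_equal(auroc(scores, labels), pair_count_auroc(scores, labels),
               tolerance = 1e-12)
  # shift invariance
  expect_equal(auroc(scores + 17, labels), auroc(scores, labels))

  expect_error(auroc(scores, rep(1, 50)), "both classes")
  res <- classification_tests(scores, labels)
  expect_equal(res$test, c("auroc", "auprc"))
  ks <- ks.test(scores[labels == 1], scores[labels == 0])
  expect_equal(unique(res$p), ks$p.value)
})

test_that("within-dataset rank is the median of per-test ranks", {
  # six-feature fixture with a known per-test ordering
  set.seed(11)
  n <- 60
  y <- rnorm(n)
  feats <- tibble::tibble(
    region_id = sprintf("r%02d", 1:n),
    best = y + rnorm(n, 0, 0.05),
    good = y + rnorm(n, 0, 0.5),
    anti = -y + rnorm(n, 0, 0.05),   # ranked by |statistic|
    weak = y + rnorm(n, 0, 3),
    noise1 = rnorm(n),
    noise2 = rnorm(n)
  )
  labels <- as.integer(y > median(y))
  suite <- test_suite(feats, y = y, labels = labels)
  expect_equal(nrow(suite), 6 * 9)
  ranks <- within_dataset_rank(suite)
  # independent sort oracle per test, medianed
  oracle <- suite |>
    dplyr::group_by(test) |>
    dplyr::mutate(rk = rank(-abs(statistic), ties.method = "average")) |>
    dplyr::group_by(feature) |>
    dplyr::summarise(rank = median(rk), .groups = "drop")
  expect_equal(ranks$rank[match(oracle$feature, ranks$feature)], oracle$rank)
  expect_true(ranks$feature[1] %in% c("best", "anti"))
  expect_true(all(ranks$rank >= 1 & ranks$rank <= 6))

  # a feature ranked 1 everywhere gets rank 1; odd-length median is exact
  expect_equal(median(c(1, 1, 1, 1, 2, 2, 9, 9, 9)), 2)
})

test_that("rank aggregation is invariant to monotone transforms of one test", {
  set.seed(12)
  feats <- tibble::tibble(region_id = sprintf("r%02d", 1:40),
                          a = rnorm(40), b = rnorm(40), c = rnorm(40))
  y <- rnorm(40)
  suite <- test_suite(feats, y = y)
  mangled <- suite |>
    dplyr::mutate(statistic = ifelse(test == "pearson",
                                     sign(statistic) * abs(statistic)^3,
                                     statistic))
  expect_equal(within_dataset_rank(suite), within_dataset_rank(mangled))
})

test_that("comprehensive rank is the median across datasets", {
  r1 <- tibble::tibble(feature = c("f", "g"), rank = c(3, 1))
  r2 <- tibble::tibble(feature = c("f", "g"), rank = c(5, 2))
  r3 <- tibble::tibble(feature = c("f", "g"), rank = c(7, 1))
  cr <- comprehensive_rank(list(d1 = r1, d2 = r2, d3 = r3))
  expect_equal(cr$comprehensive_rank[cr$feature == "f"], 5)
  # single dataset: comprehensive == within
  cr1 <- comprehensive_rank(list(d1 = r1))
  expect_equal(cr1$comprehensive_rank, r1$rank[match(cr1$feature, r1$feature)])
  # feature present in a subset of datasets uses the datasets it has
  r2b <- r2[r2$feature == "f", ]
  cr2 <- comprehensive_rank(list(d1 = r1, d2 = r2b))
  expect_equal(cr2$comprehensive_rank[cr2$feature == "g"], 1)
})

test_that("subsample robustness has zero spread without resampling", {
  set.seed(13)
  x <- rnorm(100)
  y <- x
  full <- subsample_robustness(x, y = y, n_rep = 10, frac = 1, seed = 1)
  expect_true(all(full$sd == 0))
  expect_equal(full$mean[full$test == "spearman"], 1)

  sub <- subsample_robustness(x, y = x + rnorm(100, 0, 0.5),
                              n_rep = 50, frac = 0.8, seed = 1)
  rho_full <- cor(x, x, method = "spearman")
  expect_true(all(is.finite(sub$sd)))
  # subsample mean close to full-data value
  full_stat <- regression_tests(x, x + rnorm(100, 0, 0.5))
  expect_lt(abs(sub$mean[sub$test == "spearman"] -
                  full_stat$statistic[full_stat$test == "spearman"]), 0.2)
})

test_that("shuffled-mean control calibrates against its pool", {
  set.seed(14)
  n <- 200
  y <- rnorm(n)
  # pool of pure-noise binary tracks
  pool <- matrix(rbinom(n * 40, 1, 0.3), n, 40)
  # strongly predictive cell feature
  cell <- as.numeric(y > quantile(y, 0.6)) * 0.8 + runif(n) * 0.2
  ctl <- shuffled_mean_control(pool, n_tracks = 5, y = y,
                               cell_feature = cell, n_draws = 100, seed = 2)
  expect_lte(ctl$empirical_p, 0.05)

  # pool drawn from the same distribution as the feature -> p near 1 when
  # the "cell feature" is itself a random pool mean
  rand_feature <- rowMeans(pool[, 1:5])
  ctl2 <- shuffled_mean_control(pool, n_tracks = 5, y = y,
                                cell_feature = rand_feature,
                                n_draws = 100, seed = 2)
  expect_gte(ctl2$empirical_p, 0.25)

  # reproducible draws
  ctl3 <- shuffled_mean_control(pool, n_tracks = 5, y = y,
                                cell_feature = cell, n_draws = 100, seed = 2)
  expect_identical(ctl$draw_statistics, ctl3$draw_statistics)
  expect_error(shuffled_mean_control(pool[, 1:3], n_tracks = 5, y = y,
                                     cell_feature = cell), "fewer tracks")
})
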