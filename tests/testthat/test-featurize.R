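# Sequence, motif, interval and score-table featurization.

test_that("k-mer presence matches brute-force window enumeration", {
  km <- kmer_features("ACGTACGTA", k = 5)
  expect_equal(km$n_distinct, 4)
  expect_equal(kmer_features(strrep("A", 20), k = 5)$n_distinct, 1)

  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  km <- kmer_features(s, k = 5)
  oracle <- unique(substring(s, 1:(150 - 4), 5:150))
  expect_equal(sum(km$presence), length(oracle))
  expect_setequal(names(km$presence)[km$presence == 1], oracle)

  expect_error(kmer_features("ACGTN"), "position 5")
})

test_that("composition features count bases and runs exactly", {
  expect_equal(composition_features("GGCCAT")$n_gc, 4)
  comp <- composition_features("AAATAAAA")
  expect_equal(comp$poly_a, 4)
  expect_equal(comp$poly_t, 1)
  expect_error(composition_features(""), "non-empty")
})

test_that("motif scanning finds planted consensus sites and nothing else", {
  pwm <- toy_pwm()
  set.seed(1)
  bg <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                     prob = c(.4, .1, .1, .4)), collapse = "")
  planted <- paste0(substr(bg, 1, 20), pwm_consensus(pwm), substr(bg, 31, 60))
  sc <- scan_motifs(planted, list(pwm), p_threshold = 1e-5)
  fwd <- sc$hits[sc$hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 20L)

  # uniform PWM scores identically 0 -> p = 1 -> no hits
  unif <- make_pwm("unif", matrix(0.25, nrow = 5, ncol = 4))
  expect_equal(scan_motifs(planted, list(unif), p_threshold = 0.99)$n_motifs, 0)
})

test_that("motif density counts hit starts in the best 20-bp window", {
  # three intact planted consensi at 0-based starts 0, 12, 40: the first two
  # share a 20-bp window, the third is isolated
  pwm <- toy_pwm()
  cons <- pwm_consensus(pwm)
  s <- strrep("C", 60)
  for (st in c(0, 12, 40)) substr(s, st + 1, st + 10) <- cons
  sc <- scan_motifs(s, list(pwm), p_threshold = 1e-4)
  expect_setequal(sc$hits$start[sc$hits$strand == "+"], c(0L, 12L, 40L))
  dens_oracle <- max(vapply(sc$hits$start, function(w) {
    sum(sc$hits$start >= w & sc$hits$start < w + 20)
  }, integer(1)))
  expect_equal(sc$motif_density, dens_oracle)
  expect_equal(sc$motif_density, 2L)
})

test_that("scanning is strand-symmetric", {
  pwm <- toy_pwm()
  set.seed(2)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
    substr(s, 11, 20) <- pwm_consensus(pwm)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(scan_motifs(s, list(pwm))$n_motifs,
                 scan_motifs(rc, list(pwm))$n_motifs)
  }
})

test_that("interval overlap uses half-open semantics and aggregates means", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                            start = c(100L, 300L), end = c(250L, 400L))
  tracks <- tibble::tibble(
    track_id = c("t1", "t2", "t3", "t4"),
    chrom = "chr1",
    start = c(0L, 240L, 300L, 500L),
    end = c(100L, 260L, 401L, 600L)
  )
  meta <- tibble::tibble(track_id = c("t1", "t2", "t3", "t4"),
                         factor = "TFBS",
                         cell_type = c("k562", "k562", "hepg2", "hepg2"))
  out <- overlap_features(regions, tracks, meta)
  # [0,100) does not touch [100,250) under half-open coordinates
  expect_equal(out$t1, c(0L, 0L))
  expect_equal(out$t2, c(1L, 0L))
  expect_equal(out$t3, c(0L, 1L))
  expect_equal(out$tfbs_mean, c(1 / 4, 1 / 4))

  bad <- tracks
  bad$end[1] <- 0L
  expect_error(overlap_features(regions, bad, meta), "end <= start")
})

test_that("shuffled mean over a degenerate pool is exactly the pool value", {
  regions <- tibble::tibble(region_id = sprintf("r%d", 1:3), chrom = "chr1",
                            start = c(0L, 10L, 20L), end = c(5L, 15L, 25L))
  # every track covers everything -> all binaries 1 -> shuffled mean 1
  tracks <- tibble::tibble(track_id = sprintf("t%d", 1:5), chrom = "chr1",
                           start = 0L, end = 100L)
  meta <- tibble::tibble(track_id = sprintf("t%d", 1:5), factor = "TFBS",
                         cell_type = c("k562", rep("other", 4)))
  out1 <- overlap_features(regions, tracks, meta, cell_type = "k562", seed = 1)
  out2 <- overlap_features(regions, tracks, meta, cell_type = "k562", seed = 99)
  expect_equal(out1$tfbs_shuffled_mean, rep(1, 3))
  expect_equal(out2$tfbs_shuffled_mean, rep(1, 3))
})

test_that("score-table counts respect the strict percentile convention", {
  scores <- tibble::tibble(region_id = sprintf("r%02d", 1:10),
                           tf1 = 1:10)
  out <- score_table_features(scores, prefix = "deepbind")
  # only scores strictly above the 90th percentile count
  thr <- quantile(1:10, 0.9, names = FALSE)
  expect_equal(out$n_deepbind_top, as.integer((1:10) > thr))

  flat <- tibble::tibble(region_id = sprintf("r%02d", 1:10), tf1 = rep(5, 10))
  expect_true(all(score_table_features(flat)$n_score_top == 0))
})

test_that("expression strata are subsets of the top count", {
  set.seed(3)
  m <- 12
  scores <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("r%02d", 1:30)),
    tibble::as_tibble(as.data.frame(matrix(rnorm(30 * m), 30,
                                           dimnames = list(NULL, sprintf("tf%02d", 1:m)))))
  )
  expr <- tibble::tibble(factor = sprintf("tf%02d", 1:m), tpm = rexp(m))
  out <- score_table_features(scores, expression = expr, stratum_size = 4)
  # brute-force recomputation
  mat <- as.matrix(scores[-1])
  above <- sweep(mat, 2, apply(mat, 2, quantile, 0.9), ">")
  expect_equal(out$n_score_top, as.integer(rowSums(above)))
  expect_true(all(out$n_tf_high <= out$n_score_top))
  expect_true(all(out$n_tf_low <= out$n_score_top))
  ord <- sprintf("tf%02d", order(-expr$tpm))
  expect_equal(out$n_tf_high, as.integer(rowSums(above[, ord[1:4]])))
  expect_equal(out$n_tf_low, as.integer(rowSums(above[, ord[9:12]])))
  # middle stratum: ranks ceiling((m-k)/2)+1 .. +k
  mid <- ord[(ceiling((m - 4) / 2) + 1):(ceiling((m - 4) / 2) + 4)]
  expect_equal(out$n_tf_med, as.integer(rowSums(above[, mid])))

  expect_error(score_table_features(scores, expression = expr[1:5, ]),
               "missing expression")
})

test_that("locus features follow the distal definition and flag gaps", {
  regions <- tibble::tibble(region_id = c("a", "b"), chrom = "chr1",
                            start = c(100L, 1000L), end = c(150L, 1050L))
  exons <- tibble::tibble(chrom = "chr1", start = 120L, end = 130L)
  out <- locus_features(regions, exons = exons)
  expect_equal(out$promoter, c(0L, 0L))
  expect_equal(out$exon, c(1L, 0L))
  expect_equal(out$distal, c(0L, 1L))

  cons <- tibble::tibble(chrom = "chr1", pos = 100:149, score = 0.8)
  out2 <- locus_features(regions, exons = exons, conservation = cons)
  expect_equal(out2$conservation[1], 0.8)
  expect_true(is.na(out2$conservation[2]))  # uncovered -> missing, not zero
})

test_that("feature matrix assembly preserves order, categories and values", {
  ids <- sprintf("r%d", 1:4)
  b1 <- tibble::tibble(region_id = ids, f1 = 1:4, f2 = 5:8, f3 = 9:12)
  b2 <- tibble::tibble(region_id = rev(ids), g1 = 1.5, g2 = 2.5, g3 = 3.5,
                       g4 = 4.5)
  fm <- assemble_feature_matrix(list(seq = b1, locus = b2),
                                categories = c(seq = "kmer", locus = "locus"))
  expect_equal(setdiff(names(fm), "region_id"),
               c("f1", "f2", "f3", "g1", "g2", "g3", "g4"))
  cats <- attr(fm, "categories")
  expect_equal(nrow(cats), 7)
  sub <- select_features(fm, "locus")
  expect_equal(setdiff(names(sub), "region_id"), c("g1", "g2", "g3", "g4"))
  expect_equal(names(select_features(fm, "Full")), names(fm))

  dup <- tibble::tibble(region_id = ids, f1 = 0)
  expect_error(assemble_feature_matrix(list(a = b1, b = dup),
                                       c(a = "kmer", b = "kmer")),
               "duplicate feature")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(fm))
  expect_equal(attr(back, "categories")$category,
               attr(fm, "categories")$category)
})

test_that("sequence featurization is interval-free and joins all blocks", {
  pwm <- toy_pwm()
  ss <- simulate_sequences(6, 40, list(pwm), plant_prob = 0.5, seed = 13)
  ft <- featurize_sequences(ss$sequences, pwms = list(pwm))
  expect_equal(nrow(ft), 6)
  expect_true(all(c("n_kmers", "n_gc", "poly_a", "poly_t", "n_motifs",
                    "motif_density") %in% names(ft)))
  expect_true(all(ft$n_motifs >= 0))
  kcols <- grep("^kmer_", names(ft), value = TRUE)
  expect_length(kcols, 1024)
  expect_true(all(as.matrix(ft[kcols]) %in% 0:1))
})
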