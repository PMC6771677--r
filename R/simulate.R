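#' Simulation configuration for barcode-level MPRA counts
#'
#' Describes the generative model for a single synthetic MPRA experiment:
#' plasmid (DNA) copies per barcode are Gamma-distributed and, given the
#' plasmid count, RNA counts are Poisson with mean proportional to the
#' region's transcription rate alpha. True `log2(alpha)` is drawn from a
#' two-component normal mixture: an inactive component centred at 0 and an
#' active component shifted by `alpha_log2_mean`. Negative-control regions
#' always draw from the inactive component.
#'
#' @param n_regions Number of test regions.
#' @param n_controls Number of negative-control regions.
#' @param barcodes_per_region Barcodes tagging each region.
#' @param dna_gamma_shape,dna_gamma_scale Gamma parameters of the per-barcode
#'   plasmid count; `shape * scale` is the expected copy number.
#' @param alpha_log2_mean Shift (in log2 units) of the active component.
#' @param alpha_log2_sd Spread of `log2(alpha)` within each component.
#' @param active_fraction Fraction of test regions drawn from the active
#'   component.
#' @param rna_depth_factor Multiplicative RNA sequencing-depth factor.
#' @param barcode_effect_sd Standard deviation (log scale) of an optional
#'   multiplicative log-normal barcode effect on the RNA mean; 0 (default)
#'   disables it.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return A `sim_config` object (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_regions = 50, n_controls = 10, seed = 1)
#' sim <- simulate_counts(cfg)
#' head(sim$counts)
sim_config <- function(n_regions = 500,
                       n_controls = 100,
                       barcodes_per_region = 30,
                       dna_gamma_shape = 4,
                       dna_gamma_scale = 25,
                       alpha_log2_mean = 2,
                       alpha_log2_sd = 0.25,
                       active_fraction = 0.3,
                       rna_depth_factor = 1,
                       barcode_effect_sd = 0,
                       seed = 1L) {
  cfg <- list(
    n_regions = assert_count(n_regions, "n_regions"),
    n_controls = assert_count(n_controls, "n_controls", min = 0L),
    barcodes_per_region = assert_count(barcodes_per_region, "barcodes_per_region"),
    dna_gamma_shape = assert_positive(dna_gamma_shape, "dna_gamma_shape"),
    dna_gamma_scale = assert_positive(dna_gamma_scale, "dna_gamma_scale"),
    alpha_log2_mean = as.numeric(alpha_log2_mean),
    alpha_log2_sd = assert_nonneg(alpha_log2_sd, "alpha_log2_sd"),
    active_fraction = assert_proportion(active_fraction, "active_fraction"),
    rna_depth_factor = assert_positive(rna_depth_factor, "rna_depth_factor"),
    barcode_effect_sd = assert_nonneg(barcode_effect_sd, "barcode_effect_sd"),
    seed = assert_count(seed, "seed", min = -.Machine$integer.max)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a barcode-level MPRA count table
#'
#' Draws per-barcode DNA counts from `Gamma(shape, scale)` (rounded to
#' integers) and RNA counts from `Poisson(alpha * dna * rna_depth_factor)`,
#' with the per-region transcription rate alpha drawn from the two-component
#' log-normal mixture described in [sim_config()].
#'
#' @param config A [sim_config()] object.
#'
#' @return A list with two tibbles:
#' \describe{
#'   \item{counts}{barcode rows: `region_id`, `barcode_id`, `dna`, `rna`,
#'     `batch`, `is_control`.}
#'   \item{truth}{per region: `region_id`, `alpha_true`, `log2_alpha_true`,
#'     `active_true`, `is_control`.}
#' }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_regions
    nc <- config$n_controls
    n_active <- round(config$active_fraction * n)
    region_id <- sprintf("region_%04d", seq_len(n))
    control_id <- if (nc > 0) sprintf("control_%04d", seq_len(nc)) else character()

    active <- c(rep(TRUE, n_active), rep(FALSE, n - n_active))
    log2_alpha <- rnorm(n, mean = ifelse(active, config$alpha_log2_mean, 0),
                        sd = config$alpha_log2_sd)
    log2_alpha_ctl <- rnorm(nc, mean = 0, sd = config$alpha_log2_sd)

    truth <- tibble::tibble(
      region_id = c(region_id, control_id),
      log2_alpha_true = c(log2_alpha, log2_alpha_ctl),
      alpha_true = 2^c(log2_alpha, log2_alpha_ctl),
      active_true = c(active, rep(FALSE, nc)),
      is_control = c(rep(FALSE, n), rep(TRUE, nc))
    )

    bpr <- config$barcodes_per_region
    m <- nrow(truth) * bpr
    dna <- pmax(0L, as.integer(round(
      rgamma(m, shape = config$dna_gamma_shape, scale = config$dna_gamma_scale)
    )))
    bc_effect <- if (config$barcode_effect_sd > 0) {
      exp(rnorm(m, 0, config$barcode_effect_sd) - config$barcode_effect_sd^2 / 2)
    } else {
      rep(1, m)
    }
    alpha_rep <- rep(truth$alpha_true, each = bpr)
    rna <- rpois(m, lambda = alpha_rep * dna * config$rna_depth_factor * bc_effect)

    counts <- tibble::tibble(
      region_id = rep(truth$region_id, each = bpr),
      barcode_id = sprintf("bc_%02d", rep(seq_len(bpr), times = nrow(truth))),
      dna = dna,
      rna = as.integer(rna),
      batch = "b1",
      is_control = rep(truth$is_control, each = bpr)
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate DNA sequences with planted motif occurrences
#'
#' Background nucleotides are i.i.d. at the requested GC fraction; a subset of
#' sequences (chosen with probability `plant_prob`) receives one consensus
#' insertion of a randomly chosen motif at a random position, recorded in the
#' returned truth table (0-based start coordinates, forward strand).
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp; must be at least the longest motif.
#' @param motifs A list of PWMs as returned by [read_meme()] or [make_pwm()].
#' @param plant_prob Probability that a sequence receives a planted consensus.
#' @param gc GC fraction of the background.
#' @param seed Integer seed.
#'
#' @return List of tibbles `sequences` (`seq_id`, `sequence`, `planted`) and
#'   `inserts` (`seq_id`, `motif_id`, `start`, `strand`).
#' @export
simulate_sequences <- function(n, length, motifs, plant_prob = 0.5,
                               gc = 0.41, seed = 1L) {
  n <- assert_count(n, "n")
  length <- assert_count(length, "length")
  assert_proportion(plant_prob, "plant_prob")
  assert_proportion(gc, "gc")
  widths <- vapply(motifs, function(m) nrow(m$matrix), integer(1))
  if (length(motifs) > 0 && length < max(widths)) {
    abort("motif longer than the requested sequence length")
  }
  with_seed(seed, {
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(names(base_p), length, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))
    planted <- runif(n) < plant_prob
    inserts <- list()
    for (i in which(planted)) {
      mi <- sample.int(length(motifs), 1L)
      cons <- pwm_consensus(motifs[[mi]])
      w <- nchar(cons)
      start0 <- sample.int(length - w + 1L, 1L) - 1L
      substr(seqs[i], start0 + 1L, start0 + w) <- cons
      inserts[[length(inserts) + 1L]] <- tibble::tibble(
        seq_id = sprintf("seq_%04d", i),
        motif_id = motifs[[mi]]$motif_id,
        start = start0,
        strand = "+"
      )
    }
    list(
      sequences = tibble::tibble(
        seq_id = sprintf("seq_%04d", seq_len(n)),
        sequence = seqs,
        planted = planted
      ),
      inserts = if (length(inserts)) dplyr::bind_rows(inserts) else
        tibble::tibble(seq_id = character(), motif_id = character(),
                       start = integer(), strand = character())
    )
  })
}

#' Configuration for paired synthetic datasets over identical regions
#'
#' Emulates two MPRA experiments run on the same region set in different
#' cell types: activity in each dataset is a linear function of a shared
#' feature block plus a dataset-specific block plus noise, so part of the
#' signal transfers across datasets and part cannot.
#'
#' @param base A [sim_config()]; only `n_regions`, `active_fraction` and
#'   `seed` are used here.
#' @param shared_feature_count,specific_feature_count Numbers of features in
#'   the shared block and in each dataset-specific block.
#' @param shared_effect_sd,specific_effect_sd Standard deviations of the
#'   corresponding effect sizes.
#' @param noise_sd Residual activity noise.
#'
#' @return A `paired_sim_config` object.
#' @export
paired_sim_config <- function(base = sim_config(n_regions = 2000),
                              shared_feature_count = 5,
                              specific_feature_count = 5,
                              shared_effect_sd = 1,
                              specific_effect_sd = 1,
                              noise_sd = 1) {
  stopifnot(inherits(base, "sim_config"))
  structure(list(
    base = base,
    shared_feature_count = assert_count(shared_feature_count, "shared_feature_count", min = 0L),
    specific_feature_count = assert_count(specific_feature_count, "specific_feature_count", min = 0L),
    shared_effect_sd = assert_nonneg(shared_effect_sd, "shared_effect_sd"),
    specific_effect_sd = assert_nonneg(specific_effect_sd, "specific_effect_sd"),
    noise_sd = assert_nonneg(noise_sd, "noise_sd")
  ), class = "paired_sim_config")
}

#' Simulate two datasets sharing regions and part of their activity signal
#'
#' Both datasets observe the same feature matrix (shared block plus both
#' specific blocks — features are properties of the regions); dataset A's
#' activity loads on the shared block and its own specific block only, and
#' likewise for B. Binary labels are assigned by thresholding each dataset's
#' activity at its upper `active_fraction` quantile.
#'
#' @param config A [paired_sim_config()].
#'
#' @return A list with `features` (tibble, `region_id` + feature columns),
#'   per-dataset tibbles `a` and `b` (`region_id`, `activity`, `label`), and
#'   `truth` (effect vectors and feature block assignment).
#' @export
simulate_paired_datasets <- function(config) {
  stopifnot(inherits(config, "paired_sim_config"))
  if (config$specific_feature_count == 0 && config$specific_effect_sd > 0) {
    abort("specific_effect_sd > 0 requires specific_feature_count >= 1")
  }
  with_seed(config$base$seed, {
    n <- config$base$n_regions
    region_id <- sprintf("region_%04d", seq_len(n))
    ks <- config$shared_feature_count
    kd <- config$specific_feature_count
    X_sh <- matrix(rnorm(n * ks), n, ks)
    X_a <- matrix(rnorm(n * kd), n, kd)
    X_b <- matrix(rnorm(n * kd), n, kd)
    b_sh <- rnorm(ks, 0, config$shared_effect_sd)
    b_a <- rnorm(kd, 0, config$specific_effect_sd)
    b_b <- rnorm(kd, 0, config$specific_effect_sd)
    act_a <- drop(X_sh %*% b_sh) + drop(X_a %*% b_a) + rnorm(n, 0, config$noise_sd)
    act_b <- drop(X_sh %*% b_sh) + drop(X_b %*% b_b) + rnorm(n, 0, config$noise_sd)

    feat_names <- c(
      if (ks > 0) sprintf("shared_%02d", seq_len(ks)),
      if (kd > 0) sprintf("specA_%02d", seq_len(kd)),
      if (kd > 0) sprintf("specB_%02d", seq_len(kd))
    )
    features <- tibble::as_tibble(
      setNames(as.data.frame(cbind(X_sh, X_a, X_b)), feat_names)
    )
    features <- dplyr::bind_cols(tibble::tibble(region_id = region_id), features)

    thr_a <- quantile(act_a, 1 - config$base$active_fraction, names = FALSE)
    thr_b <- quantile(act_b, 1 - config$base$active_fraction, names = FALSE)
    list(
      features = features,
      a = tibble::tibble(region_id = region_id, activity = act_a,
                         label = as.integer(act_a > thr_a)),
      b = tibble::tibble(region_id = region_id, activity = act_b,
                         label = as.integer(act_b > thr_b)),
      truth = list(beta_shared = b_sh, beta_a = b_a, beta_b = b_b,
                   shared_features = feat_names[seq_len(ks)],
                   specific_a = grep("^specA", feat_names, value = TRUE),
                   specific_b = grep("^specB", feat_names, value = TRUE))
    )
  })
}

#' Configuration for synthetic saturation mutagenesis
#'
#' Emulates the design of a saturation-mutagenesis MPRA challenge: every
#' single-nucleotide substitution of an element is assayed, a stated fraction
#' of the results forms the training split, and the measured per-variant
#' effect is an additive per-position effect plus noise, with a point mass of
#' exactly-zero effects at inert positions.
#'
#' The continuous effect of variant (position, alt) is
#' `b[position] + d[position, alt]`. The position-effect map `b` mimics the
#' contiguous sensitive footprints (e.g. transcription-factor binding sites)
#' seen in saturation-mutagenesis assays: functional sites of `site_length`
#' consecutive positions are placed so that about `effect_sparsity` of
#' positions are covered, each site drawing one effect level from
#' `N(0, effect_sd)`; all other positions have exactly zero effect (the null
#' mass). `d` is a smaller per-alternative deviation (`N(0, alt_effect_sd)`
#' at covered positions). The discrete class is the sign of this noiseless
#' effect where its magnitude exceeds `class_threshold`, else 0; measurement
#' noise (`noise_sd`) is added only to the reported continuous effect.
#' `site_length = 1` recovers independent per-position effects.
#'
#' @param element_length Element length in bp.
#' @param train_fraction Fraction of variants assigned to the training split.
#' @param effect_sparsity Proportion of positions with a nonzero effect.
#' @param site_length Length (bp) of each contiguous functional site.
#' @param effect_sd Standard deviation of per-site effect levels.
#' @param alt_effect_sd Standard deviation of the per-alternative deviation at
#'   active positions; defaults to `0.25 * effect_sd`.
#' @param noise_sd Measurement noise on the continuous effect.
#' @param class_threshold Magnitude below which the discrete class is 0.
#' @param seed Integer seed.
#'
#' @return A `satmut_sim_config` object.
#' @export
satmut_sim_config <- function(element_length = 300,
                              train_fraction = 0.25,
                              effect_sparsity = 0.2,
                              site_length = 8,
                              effect_sd = 1,
                              alt_effect_sd = 0.25 * effect_sd,
                              noise_sd = 0.1,
                              class_threshold = 0.5,
                              seed = 1L) {
  structure(list(
    element_length = assert_count(element_length, "element_length"),
    train_fraction = assert_proportion(train_fraction, "train_fraction", open = TRUE),
    effect_sparsity = assert_proportion(effect_sparsity, "effect_sparsity"),
    site_length = assert_count(site_length, "site_length"),
    effect_sd = assert_nonneg(effect_sd, "effect_sd"),
    alt_effect_sd = assert_nonneg(alt_effect_sd, "alt_effect_sd"),
    noise_sd = assert_nonneg(noise_sd, "noise_sd"),
    class_threshold = assert_nonneg(class_threshold, "class_threshold"),
    seed = assert_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "satmut_sim_config")
}

#' Simulate a saturation-mutagenesis variant table for one element
#'
#' Enumerates all `3 * L` single-nucleotide substitutions of the element
#' sequence, draws effects under the model of [satmut_sim_config()], and
#' splits variants at random into train/test at the configured fraction.
#'
#' @param config A [satmut_sim_config()].
#' @param element_seq Optional element sequence (ACGT string of length
#'   `element_length`); a random sequence is generated when omitted.
#' @param element_id,element_class Identifier and class (`"promoter"` or
#'   `"enhancer"`) stamped on the variant rows.
#'
#' @return A list with `variants` — a tibble of `element_id`, `element_class`,
#'   `position` (0-based), `ref`, `alt`, `effect` (noisy continuous),
#'   `class` (-1/0/+1 from the noiseless effect), `split` — plus `element_seq`
#'   and `truth` (per-position effect vector).
#' @export
simulate_saturation <- function(config, element_seq = NULL,
                                element_id = "element_01",
                                element_class = "enhancer") {
  stopifnot(inherits(config, "satmut_sim_config"))
  L <- config$element_length
  with_seed(config$seed, {
    if (is.null(element_seq)) {
      element_seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = "")
    }
    assert_dna(element_seq, "element_seq")
    if (nchar(element_seq) != L) {
      abort("element_seq length does not match config$element_length")
    }
    ref <- strsplit(element_seq, "")[[1]]
    w <- min(config$site_length, L)
    n_sites <- round(config$effect_sparsity * L / w)
    b <- numeric(L)
    if (n_sites > 0) {
      starts <- sample.int(L - w + 1L, n_sites,
                           replace = n_sites > L - w + 1L)
      for (s in starts) b[s:(s + w - 1L)] <- rnorm(1, 0, config$effect_sd)
    }
    active_pos <- b != 0

    pos0 <- rep(seq_len(L) - 1L, each = 3L)
    refv <- rep(ref, each = 3L)
    altv <- unlist(lapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)),
                   use.names = FALSE)
    d <- ifelse(rep(active_pos, each = 3L),
                rnorm(3L * L, 0, config$alt_effect_sd), 0)
    effect_true <- b[pos0 + 1L] + d
    cls <- ifelse(abs(effect_true) > config$class_threshold,
                  sign(effect_true), 0)
    effect_obs <- effect_true + rnorm(3L * L, 0, config$noise_sd)

    n_var <- 3L * L
    n_train <- round(config$train_fraction * n_var)
    train_idx <- sample.int(n_var, n_train)
    split <- rep("test", n_var)
    split[train_idx] <- "train"

    variants <- tibble::tibble(
      element_id = element_id,
      element_class = element_class,
      position = pos0,
      ref = refv,
      alt = altv,
      effect = effect_obs,
      effect_true = effect_true,
      class = as.integer(cls),
      split = split
    )
    list(variants = variants, element_seq = element_seq,
         truth = tibble::tibble(position = seq_len(L) - 1L, effect_pos = b))
  })
}
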