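#' Estimate per-region transcription rates from barcode counts
#'
#' Two-stage fit of the Gamma-Poisson MPRA model. Stage 1 fits the DNA
#' (plasmid) counts by Gamma method of moments; because plasmid copies are
#' observed without additional noise in this model, the fitted latent plasmid
#' count of each barcode is its observed DNA count, and the Gamma fit
#' contributes the pooled dispersion default. Stage 2 maximizes, per region,
#' the negative-binomial likelihood of the RNA counts with mean
#' `alpha * dna * depth` and quadratic overdispersion `a`
#' (`Var = mu + a * mu^2`); `a = 0` is the Poisson limit, where the maximum
#' likelihood estimate is `sum(rna) / sum(dna * depth)` in closed form.
#' Standard errors come from the observed information at the maximum.
#'
#' Barcodes with `dna == 0` carry no information about alpha and are dropped
#' from stage 2 (their number is reported per region); a region whose
#' barcodes are all zero-DNA is returned with `alpha = NA` and a diagnostic
#' rather than dropped.
#'
#' @param counts A count table: `region_id`, `barcode_id`, `dna`, `rna`
#'   (see [read_count_table()]).
#' @param dispersion Optional non-negative quadratic overdispersion
#'   coefficient; when `NULL` it is moment-estimated once, pooled across
#'   regions.
#' @param rna_depth_factor Known RNA depth factor absorbed into the offset.
#'
#' @return A tibble with one row per region: `alpha`, `log2_alpha`, `se`
#'   (standard error of alpha), `n_barcodes`, `n_zero_dna`, `is_control`
#'   (if present in `counts`), and the `dispersion` used.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_regions = 20, n_controls = 5, seed = 1))
#' estimate_alpha(sim$counts)
estimate_alpha <- function(counts, dispersion = NULL, rna_depth_factor = 1) {
  counts <- validate_count_table(counts)
  if (!is.null(dispersion)) {
    if (!is.numeric(dispersion) || length(dispersion) != 1L || is.na(dispersion) ||
        dispersion < 0) {
      abort("`dispersion` must be a single non-negative number")
    }
  }
  depth <- assert_positive(rna_depth_factor, "rna_depth_factor")

  by_region <- split(counts, counts$region_id)
  # preliminary Poisson-limit alphas for the pooled moment dispersion
  prelim <- vapply(by_region, function(df) {
    d <- df$dna * depth
    if (sum(d) == 0) return(NA_real_)
    sum(df$rna) / sum(d)
  }, numeric(1))

  if (is.null(dispersion)) {
    dispersion <- moment_dispersion(by_region, prelim, depth)
  }

  fits <- purrr::imap(by_region, function(df, rid) {
    fit_region_alpha(df, dispersion, depth, alpha0 = prelim[[rid]])
  })
  out <- dplyr::bind_rows(fits)
  out$region_id <- names(by_region)
  if ("is_control" %in% names(counts)) {
    ctl <- vapply(by_region, function(df) any(df$is_control), logical(1))
    out$is_control <- unname(ctl)
  }
  out$dispersion <- dispersion
  dplyr::relocate(out, "region_id") |>
    dplyr::arrange(.data$region_id)
}

# Pooled method-of-moments estimate of the NB quadratic overdispersion a in
# Var = mu + a mu^2, using Pearson-type excess residuals across all barcodes.
moment_dispersion <- function(by_region, prelim, depth) {
  num <- 0
  den <- 0
  for (i in seq_along(by_region)) {
    df <- by_region[[i]]
    a0 <- prelim[[i]]
    if (!is.finite(a0)) next
    mu <- a0 * df$dna * depth
    keep <- mu > 0
    num <- num + sum((df$rna[keep] - mu[keep])^2 - mu[keep])
    den <- den + sum(mu[keep]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

nb_loglik <- function(alpha, rna, offset, dispersion) {
  mu <- alpha * offset
  if (dispersion <= 0) {
    sum(dpois(rna, lambda = mu, log = TRUE))
  } else {
    sum(dnbinom(rna, mu = mu, size = 1 / dispersion, log = TRUE))
  }
}

fit_region_alpha <- function(df, dispersion, depth, alpha0) {
  keep <- df$dna > 0
  n_zero <- sum(!keep)
  d <- df$dna[keep] * depth
  r <- df$rna[keep]
  if (length(d) == 0) {
    return(tibble::tibble(alpha = NA_real_, log2_alpha = NA_real_,
                          se = NA_real_, n_barcodes = nrow(df),
                          n_zero_dna = n_zero,
                          note = "all barcodes have zero DNA"))
  }
  if (dispersion <= 0 || sum(r) == 0) {
    # Poisson MLE is closed form; also the NB MLE when all RNA counts are 0.
    alpha <- sum(r) / sum(d)
  } else {
    opt <- optimize(function(la) nb_loglik(exp(la), r, d, dispersion),
                    interval = c(log(max(alpha0, 1e-8)) - 8,
                                 log(max(alpha0, 1e-8)) + 8),
                    maximum = TRUE, tol = 1e-10)
    alpha <- exp(opt$maximum)
  }
  se <- alpha_se(alpha, r, d, dispersion)
  tibble::tibble(alpha = alpha,
                 log2_alpha = ifelse(alpha > 0, log2(alpha), -Inf),
                 se = se, n_barcodes = nrow(df), n_zero_dna = n_zero,
                 note = NA_character_)
}

# standard error from the observed information (numerical second derivative
# of the log-likelihood in alpha).
alpha_se <- function(alpha, rna, offset, dispersion) {
  if (!is.finite(alpha) || alpha <= 0) return(NA_real_)
  h <- alpha * 1e-4
  ll <- function(a) nb_loglik(a, rna, offset, dispersion)
  d2 <- (ll(alpha + h) - 2 * ll(alpha) + ll(alpha - h)) / h^2
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  sqrt(-1 / d2)
}

#' Call active regions by robust standardization against controls
#'
#' Standardizes the estimated transcription rates into robust z-scores,
#' `z = (alpha - median_ref) / (1.4826 * MAD_ref)`, where the reference set is
#' the negative controls when supplied (or flagged in the table) and all
#' regions otherwise. One-sided p-values are the standard-normal survival
#' function of z (enhancer calling tests upward deviation only), q-values are
#' Benjamini-Hochberg over all regions, and a region is called active when
#' `q < fdr_threshold`.
#'
#' @param activity Tibble from [estimate_alpha()] (needs `region_id`,
#'   `alpha`; `is_control` used if present).
#' @param control_ids Optional character vector naming the control regions;
#'   overrides the `is_control` column.
#' @param fdr_threshold FDR level for the active call.
#'
#' @return The input tibble with `z`, `p`, `q` and `active` filled in.
#' @export
call_active <- function(activity, control_ids = NULL, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(activity), all(c("region_id", "alpha") %in% names(activity)))
  assert_proportion(fdr_threshold, "fdr_threshold")
  activity <- tibble::as_tibble(activity)

  ref <- if (!is.null(control_ids)) {
    activity$alpha[activity$region_id %in% control_ids]
  } else if ("is_control" %in% names(activity) && any(activity$is_control)) {
    activity$alpha[activity$is_control]
  } else {
    activity$alpha
  }
  ref <- ref[is.finite(ref)]
  is_ctl_ref <- !is.null(control_ids) ||
    ("is_control" %in% names(activity) && any(activity$is_control))
  if (is_ctl_ref && length(ref) < 5) {
    abort("need at least 5 control regions with finite alpha")
  }
  med <- median(ref)
  scaled_mad <- mad(ref, constant = 1.4826)
  if (scaled_mad == 0) {
    abort(sprintf(
      "reference set (%s) has zero MAD; z-scores are undefined",
      if (is_ctl_ref) "controls" else "all regions"))
  }
  activity$z <- (activity$alpha - med) / scaled_mad
  activity$p <- pnorm(activity$z, lower.tail = FALSE)
  activity$q <- p.adjust(activity$p, method = "BH")
  activity$active <- activity$q < fdr_threshold
  activity
}

#' Label regions active by a log2-activity cutoff
#'
#' The alternative categorization used for paired-region analyses: a region
#' is active iff `log2(alpha)` is strictly above the cutoff.
#'
#' @param activity Tibble with `log2_alpha` (or `alpha`).
#' @param log2_cutoff Activity cutoff on the log2 scale.
#'
#' @return The input tibble with an integer `label` column (1 = active).
#' @export
threshold_active <- function(activity, log2_cutoff = 1.5) {
  stopifnot(is.data.frame(activity))
  activity <- tibble::as_tibble(activity)
  l2 <- if ("log2_alpha" %in% names(activity)) {
    activity$log2_alpha
  } else if ("alpha" %in% names(activity)) {
    log2(activity$alpha)
  } else {
    abort("`activity` needs a `log2_alpha` or `alpha` column")
  }
  if (any(!is.finite(l2) & !is.infinite(l2))) {
    abort("log2 activity contains non-finite values")
  }
  activity$label <- as.integer(l2 > log2_cutoff)
  activity
}
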