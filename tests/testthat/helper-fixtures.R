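# Shared fixtures, built in code at test time.

# near-deterministic, non-self-complementary motif (consensus ACGGTAACGG);
# width 10 so a perfect match is significant at p < 1e-5 (0.25^10 ~ 9.5e-7)
toy_pwm <- function(id = "toy") {
  cons <- strsplit("ACGGTAACGG", "")[[1]]
  mat <- t(vapply(cons, function(b) {
    p <- rep(0.01, 4)
    p[match(b, c("A", "C", "G", "T"))] <- 0.97
    p
  }, numeric(4)))
  make_pwm(id, mat)
}

# simple dataset with one causal feature among noise features
make_linear_dataset <- function(n = 500, p_noise = 10, beta = 1,
                                noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_noise + 1)), n, p_noise + 1)
  colnames(X) <- c("causal", paste0("noise_", seq_len(p_noise)))
  y <- beta * X[, "causal"] + rnorm(n, 0, noise_sd)
  features <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("r%04d", seq_len(n))),
    tibble::as_tibble(as.data.frame(X))
  )
  list(features = features, y = y,
       labels = as.integer(y > quantile(y, 0.7)))
}

# brute-force AUROC: fraction of positive-negative pairs correctly ordered,
# half credit for ties
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force Kendall tau-b via pair counting with tie corrections
pair_count_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j])
    dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# hand BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
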