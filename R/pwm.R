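# Position weight matrices: construction, MEME format IO, log-odds scoring
# with exact p-values via dynamic programming over the background score
# distribution, and sequence scanning.

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param matrix Numeric matrix, positions x 4, columns A, C, G, T; each row
#'   must sum to 1 (tolerance 1e-6).
#' @param background Length-4 background nucleotide probabilities (A,C,G,T).
#'
#' @return A `pwm` object.
#' @export
make_pwm <- function(motif_id, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) abort("PWM matrix must have 4 columns (A, C, G, T)")
  dimnames(matrix) <- list(NULL, c("A", "C", "G", "T"))
  if (any(matrix < 0)) abort("PWM probabilities must be non-negative")
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    abort("each PWM row must sum to 1 (tolerance 1e-6)")
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  if (any(background == 0 & colSums(matrix) > 0)) {
    abort("zero background probability with nonzero matrix weight gives an infinite log-odds score")
  }
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 background = setNames(as.numeric(background),
                                       c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (width %d), consensus %s\n",
              x$motif_id, nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (per-position argmax, ties to the
#' alphabetically first base)
#' @param pwm A `pwm` object.
#' @return A character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$matrix)[apply(pwm$matrix, 1, which.max)], collapse = "")
}

#' Read motifs from a MEME-format file
#'
#' Supports the MEME minimal motif format: optional background frequency
#' line, `MOTIF` headers and `letter-probability matrix` blocks.
#'
#' @param path Path to a MEME motif file.
#' @return A named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at)) abort("no MOTIF blocks found in MEME file")
  pwms <- list()
  for (i in seq_along(motif_at)) {
    header <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]]
    motif_id <- header[2]
    j <- motif_at[i]
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) abort(sprintf("motif %s has no matrix block", motif_id))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    pwms[[motif_id]] <- make_pwm(motif_id, mat, bg)
  }
  pwms
}

#' Write motifs to a MEME-format file
#' @param pwms A list of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

# Integer-discretized log-odds scores for one PWM: list with the per-position
# integer score matrix (4 x width), granularity, and the exact background
# score distribution (pmf over integer total scores with its offset).
pwm_score_table <- function(pwm, granularity = 0.001) {
  mat <- t(pwm$matrix)          # 4 x w, rows A,C,G,T
  mat[mat == 0] <- 1e-6         # avoid -Inf; negligible mass
  lo <- log2(mat / pwm$background)
  s_int <- round(lo / granularity)
  w <- ncol(s_int)
  # DP: pmf over the sum of per-position integer scores under the background
  offset <- 0L
  pmf <- 1
  for (j in seq_len(w)) {
    sj <- s_int[, j]
    mn <- min(sj)
    span <- max(sj) - mn
    new <- numeric(length(pmf) + span)
    for (b in 1:4) {
      k <- sj[b] - mn
      idx <- seq_along(pmf) + k
      new[idx] <- new[idx] + pmf * pwm$background[b]
    }
    pmf <- new
    offset <- offset + mn
  }
  # tail[i] = P(S >= offset + i - 1)
  tail_p <- rev(cumsum(rev(pmf)))
  list(s_int = s_int, granularity = granularity, offset = offset,
       tail = tail_p)
}

# exact p-value P(score >= s) for integer score(s) s
pwm_score_pvalue <- function(tab, s) {
  i <- s - tab$offset + 1L
  i <- pmin(pmax(i, 1L), length(tab$tail) + 1L)
  ifelse(i > length(tab$tail), 0, tab$tail[i])
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan a sequence for significant motif hits
#'
#' Scores every position of both strands with each PWM's log-odds score
#' against the background and keeps positions whose exact score p-value —
#' computed by dynamic programming over the background distribution of
#' discretized scores — is below `p_threshold`. Summary features are the
#' total hit count (`n_motifs`) and the motif density, the maximum number of
#' hit start positions falling inside any window of `window` bp.
#'
#' @param seq An ACGT sequence string.
#' @param pwms List of `pwm` objects.
#' @param p_threshold Exact score p-value threshold for a hit.
#' @param window Window width (bp) for the density feature.
#' @param granularity Score discretization step (log2 units).
#'
#' @return A list with `hits` (tibble: `motif_id`, `start` 0-based on the
#'   forward strand, `strand`, `score`, `p`), `n_motifs` and
#'   `motif_density`.
#' @export
scan_motifs <- function(seq, pwms, p_threshold = 1e-4, window = 20,
                        granularity = 0.001) {
  assert_dna(seq)
  n <- nchar(seq)
  base_idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  hits <- list()
  for (pwm in pwms) {
    w <- nrow(pwm$matrix)
    if (w >= n + 1) abort(sprintf("PWM %s is longer than the sequence", pwm$motif_id))
    tab <- pwm_score_table(pwm, granularity)
    for (strand in c("+", "-")) {
      s_int <- if (strand == "+") tab$s_int else tab$s_int[4:1, w:1, drop = FALSE]
      n_pos <- n - w + 1L
      scores <- integer(n_pos)
      for (j in seq_len(w)) {
        col <- unname(s_int[, j])
        scores <- scores + col[base_idx[seq_len(n_pos) + j - 1L]]
      }
      pvals <- pwm_score_pvalue(tab, scores)
      keep <- which(pvals < p_threshold)
      if (length(keep)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          motif_id = pwm$motif_id,
          start = keep - 1L,
          strand = strand,
          score = scores[keep] * granularity,
          p = pvals[keep]
        )
      }
    }
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(motif_id = character(), start = integer(),
                   strand = character(), score = numeric(), p = numeric())
  n_motifs <- nrow(hits)
  motif_density <- if (n_motifs == 0) 0L else {
    starts <- sort(hits$start)
    max(vapply(starts, function(s) sum(starts >= s & starts < s + window),
               integer(1)))
  }
  list(hits = hits, n_motifs = n_motifs, motif_density = motif_density)
}
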