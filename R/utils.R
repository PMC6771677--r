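# Internal validation helpers shared across modules.

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  as.numeric(x)
}

assert_proportion <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    abort(sprintf("`%s` must be a proportion in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"))
  }
  as.numeric(x)
}

assert_dna <- function(seq, name = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single character string.", name))
  }
  if (nchar(seq) == 0L) {
    abort(sprintf("`%s` must be non-empty.", name))
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0) {
    abort(sprintf("`%s` contains a non-ACGT character at position %d.", name, bad))
  }
  seq
}

# Locale-independent deterministic ordering of region ids.
sort_ids <- function(ids) sort(ids, method = "radix")

# Run an expression under a locally-seeded RNG without touching the caller's
# global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Spearman rho (average-rank ties); own small helper so downstream modules
# do not depend on cor.test's machinery when only the statistic is needed.
spearman <- function(x, y) {
  suppressWarnings(cor(rank(x), rank(y)))
}
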