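# Readers and writers for the pipeline's plain-text interchange formats.
# All tabular artifacts are TSV with a header row; missing values are ".".

#' Read and validate a barcode-level count table
#'
#' Expected columns: `region_id`, `barcode_id`, `dna`, `rna`; optional
#' `batch` (defaults to a single batch) and `is_control` (defaults FALSE).
#' Counts must be non-negative integers and `(region_id, barcode_id, batch)`
#' must be unique.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".")
  validate_count_table(df)
}

validate_count_table <- function(df) {
  if (!is.data.frame(df)) abort("counts must be a data frame")
  need <- c("region_id", "barcode_id", "dna", "rna")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (!"batch" %in% names(df)) df$batch <- "b1"
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  for (col in c("dna", "rna")) {
    x <- df[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
      bad <- which(!is.numeric(x) | is.na(x) | x < 0 | x != floor(x))[1]
      abort(sprintf("column `%s` must hold non-negative integers (row %d)",
                    col, bad))
    }
    df[[col]] <- as.integer(x)
  }
  key <- paste(df$region_id, df$barcode_id, df$batch, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    abort(sprintf("duplicate (region_id, barcode_id, batch) rows: %s",
                  paste(head(rows, 5), collapse = ", ")))
  }
  df
}

#' Write a tibble as TSV (the package interchange dialect)
#'
#' Tab-separated, header row, UTF-8, `.` for missing values.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      na.strings = "."))
}

#' Read a BED3+ interval file (0-based half-open)
#'
#' Only the first three columns are interpreted (`chrom`, `start`, `end`);
#' a fourth column, when present, is kept as `name`. Intervals with
#' `end <= start` are rejected with their line number.
#'
#' @param path Path to a BED file.
#' @return A tibble of intervals.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-integer coordinates",
                  which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    abort(sprintf("BED line %d has end <= start", bad[1]))
  }
  tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = start,
    end = end,
    name = {
      nm <- ifelse(nf >= 4,
                   vapply(parts, function(p) if (length(p) >= 4) p[[4]] else
                     NA_character_, ""),
                   NA_character_)
      ifelse(nm == ".", NA_character_, nm)
    }
  )
}

#' Write intervals as BED3+
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- intervals[c("chrom", "start", "end",
                      intersect("name", names(intervals)))]
  utils::write.table(cols, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path Path to an uncompressed FASTA file.
#' @return A tibble with `seq_id` and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(seq_id = names(x),
                 sequence = unname(toupper(as.character(x))))
}

#' Write sequences to a FASTA file
#' @param sequences Tibble with `seq_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(setNames(sequences$sequence,
                                         sequences$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
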