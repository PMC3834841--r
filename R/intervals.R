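#' Genomic intervals as tibbles
#'
#' Throughout the package a set of genomic intervals (DNase I hypersensitive
#' sites, footprints, motif instances, ChIP-seq confirmed binding sites) is an
#' ordinary tibble with at least the columns `chrom`, `start` and `end`, using
#' 0-based half-open coordinates as in the BED standard. Optional columns
#' `name`, `score` and `strand` (`"+"`, `"-"` or `"."`) carry labels, per-site
#' values and orientation.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open span; `start < end`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (unstranded, default).
#' @param name Optional interval labels.
#' @param score Optional numeric per-interval score.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, one row per interval.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              score = NA_real_) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end", arg))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad)) {
    abort(sprintf(
      "`%s`: invalid span on row %d (start=%s, end=%s); need 0 <= start < end",
      arg, bad[1], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort(sprintf("`%s`: strand must be one of '+', '-', '.'", arg))
  }
  invisible(x)
}

#' Read a BED file into an interval tibble
#'
#' Parses BED (0-based, half-open, tab-separated) into the package's interval
#' tibble. `browser`, `track` and `#` comment lines, and blank lines, are
#' skipped. Strand is taken from column 6 when present; name from column 4 and
#' score from column 5.
#'
#' @param path Path to a BED file (or a connection readable by [readLines()]).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`. Malformed data lines (non-integer coordinates or `end <= start`)
#'   raise an error citing the offending line number.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^(browser|track)\\b", lines) | grepl("^#", lines) |
    !nzchar(trimws(lines))
  keep <- which(!skip)
  if (!length(keep)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 3) {
      abort(sprintf("BED line %d: fewer than 3 fields", lineno))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || f[2] != as.character(start) ||
        f[3] != as.character(end)) {
      abort(sprintf("BED line %d: non-integer coordinates '%s', '%s'",
                    lineno, f[2], f[3]))
    }
    if (end <= start || start < 0) {
      abort(sprintf("BED line %d: invalid span [%d, %d)", lineno, start, end))
    }
    tibble(
      chrom = f[1],
      start = start,
      end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
    )
  }
  out <- purrr::map2(fields, keep, parse_one)
  dplyr::bind_rows(out)
}

#' Write an interval tibble as BED6
#'
#' @param intervals Interval tibble (see [genomic_intervals()]); written in
#'   coordinate-sorted order regardless of input order.
#' @param path Output path.
#' @param digits Decimal places for the score column.
#' @return `intervals`, invisibly (pipe-friendly).
#' @export
write_bed <- function(intervals, path, digits = 2) {
  validate_intervals(intervals)
  x <- dplyr::arrange(intervals, .data$chrom, .data$start, .data$end)
  name <- if ("name" %in% names(x)) x$name else NA_character_
  name <- ifelse(is.na(name), sprintf("FP_%d", seq_len(nrow(x))), name)
  score <- if ("score" %in% names(x)) x$score else NA_real_
  score <- ifelse(is.na(score), "0", formatC(score, format = "f", digits = digits))
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   name, score, strand)
  writeLines(lines, path)
  invisible(intervals)
}

# midpoint convention shared with footprint centring: start + floor(length / 2)
interval_midpoint <- function(intervals) {
  intervals$start + (intervals$end - intervals$start) %/% 2L
}

as_granges_tbl <- function(intervals) {
  validate_intervals(intervals)
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}
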