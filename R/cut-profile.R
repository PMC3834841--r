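#' Per-base 5' cut-count profiles
#'
#' A cut profile holds, for one genomic interval, the number of DNase I cuts
#' (5' ends of aligned sequencing tags) at every base, separately for reads
#' aligned to the forward (`plus`) and reverse (`minus`) reference strand. It
#' is a tibble subclass with columns `pos` (0-based genomic coordinate),
#' `plus` and `minus`, plus attributes `chrom`, `start`, `end`.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the covered interval.
#' @param plus,minus Non-negative integer vectors of equal length: per-base
#'   cut counts on the forward and reverse strand.
#' @return A `wtn_cut_profile` tibble.
#' @examples
#' cut_profile("chr1", 100, plus = c(2, 0, 1), minus = c(0, 1, 0))
#' @export
cut_profile <- function(chrom, start, plus, minus) {
  plus <- as.integer(plus)
  minus <- as.integer(minus)
  if (length(plus) != length(minus)) {
    abort("`plus` and `minus` must have equal length")
  }
  if (length(plus) && (anyNA(plus) || anyNA(minus) || min(plus, minus) < 0)) {
    abort("cut counts must be non-negative integers")
  }
  start <- as.integer(start)
  out <- tibble(
    pos = start + seq_along(plus) - 1L,
    plus = plus,
    minus = minus
  )
  new_cut_profile(out, chrom = as.character(chrom), start = start,
                  end = start + length(plus))
}

new_cut_profile <- function(x, chrom, start, end) {
  structure(x,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    class = c("wtn_cut_profile", class(tibble())))
}

profile_chrom <- function(p) attr(p, "chrom")
profile_start <- function(p) attr(p, "start")
profile_end <- function(p) attr(p, "end")

#' @export
print.wtn_cut_profile <- function(x, ...) {
  cat(sprintf("# Cut profile %s:%d-%d (%d bp; %d + cuts, %d - cuts)\n",
              profile_chrom(x), profile_start(x), profile_end(x),
              nrow(x), sum(x$plus), sum(x$minus)))
  NextMethod()
}

#' Swap the strands of a cut profile
#'
#' Exchanges the `plus` and `minus` count vectors. Used by the reverse-mode
#' scoring identity (reverse Wellington on a profile equals forward Wellington
#' on the strand-swapped profile) and in symmetry tests.
#'
#' @param profile A [cut_profile()].
#' @return The profile with strands exchanged.
#' @export
swap_strands <- function(profile) {
  stopifnot(inherits(profile, "wtn_cut_profile"))
  cut_profile(profile_chrom(profile), profile_start(profile),
              plus = profile$minus, minus = profile$plus)
}

#' Extract strand-resolved 5' cut counts from aligned reads
#'
#' Reads an indexed BAM file and counts, at every base of `interval`, the
#' aligned tags whose 5'-most aligned reference base falls there: for a
#' forward-strand read this is its leftmost aligned base, for a reverse-strand
#' read its rightmost aligned base (no +/-1 shift; soft-clipped bases are
#' ignored). Reads whose 5' end falls outside the interval contribute nothing.
#' Duplicates are counted; supply `min_mapq` to filter on mapping quality.
#'
#' @param reads Path to a coordinate-sorted, indexed BAM file.
#' @param interval One-row interval tibble (see [genomic_intervals()]).
#' @param min_mapq Minimum mapping quality (default 0, i.e. keep all).
#' @return A [cut_profile()] over `interval`.
#' @export
extract_cuts <- function(reads, interval, min_mapq = 0) {
  validate_intervals(interval, "interval")
  if (nrow(interval) != 1) abort("`interval` must be a single interval (one row)")
  if (min_mapq < 0) abort("`min_mapq` must be >= 0")
  if (!file.exists(reads)) abort(sprintf("BAM file not found: %s", reads))
  has_index <- file.exists(paste0(reads, ".bai")) ||
    file.exists(sub("\\.bam$", ".bai", reads))
  if (!has_index) {
    abort(sprintf("BAM file %s has no index (.bai); index it first", reads))
  }
  bam <- Rsamtools::BamFile(reads)
  targets <- Rsamtools::scanBamHeader(bam)$targets
  chrom <- interval$chrom
  if (!chrom %in% names(targets)) {
    abort(sprintf("chromosome '%s' not present in %s", chrom, reads))
  }
  width <- interval$end - interval$start
  # 'which' returns reads overlapping the window; a reverse read whose 5' end
  # (rightmost base) is inside always overlaps, so nothing in-range is missed
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom,
      IRanges::IRanges(interval$start + 1L, interval$end)),
    what = c("pos", "strand", "cigar", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  pos <- res$pos
  keep <- !is.na(pos)
  if (min_mapq > 0) keep <- keep & !is.na(res$mapq) & res$mapq >= min_mapq
  pos <- pos[keep]
  strand <- as.character(res$strand)[keep]
  cigar <- res$cigar[keep]
  plus <- integer(width)
  minus <- integer(width)
  if (length(pos)) {
    ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    five_prime <- ifelse(strand == "+", pos - 1L, pos - 1L + ref_width - 1L)
    off <- five_prime - interval$start
    inside <- off >= 0L & off < width
    fwd <- tabulate(off[inside & strand == "+"] + 1L, nbins = width)
    rev <- tabulate(off[inside & strand == "-"] + 1L, nbins = width)
    plus <- as.integer(fwd)
    minus <- as.integer(rev)
  }
  cut_profile(chrom, interval$start, plus, minus)
}

#' @method autoplot wtn_cut_profile
#' @export
autoplot.wtn_cut_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("plus", "minus"),
                            names_to = "strand", values_to = "cuts")
  df$cuts <- ifelse(df$strand == "minus", -df$cuts, df$cuts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cuts,
                                   fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(plus = "#d73027", minus = "#1a9850")) +
    ggplot2::labs(
      x = sprintf("position on %s", profile_chrom(object)),
      y = "5' cuts (+ up, - down)", fill = "strand"
    ) +
    ggplot2::theme_minimal()
}
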