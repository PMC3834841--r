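#' Specification of a simulated DNase I hypersensitive site
#'
#' States the generative model for one synthetic DHS: independent per-base,
#' per-strand Poisson cut counts at `background_rate`, with planted footprints
#' in which both strands are depleted by the factor `1 - depletion`, an
#' elevated +strand rate (`shoulder_boost`) on the `sh_length` bases upstream
#' of each footprint, and an elevated -strand rate downstream — the strand
#' imbalance that double-hit library size selection produces around bound
#' sites, with cut density piling up immediately adjacent to the protected
#' region.
#'
#' Defaults state the reference simulation used throughout the test suite:
#' 600 bp DHS (a typical hypersensitive-site scale), background 0.5 cuts per
#' base per strand (deep ENCODE-like coverage), two 16 bp footprints with 90%
#' depletion, 3-fold shoulder boost over 35 bp shoulders, and a 90 bp minimum
#' gap so neighbouring shoulders never overlap.
#'
#' @param dhs_length DHS length in bp.
#' @param background_rate Mean cuts per base per strand (Poisson).
#' @param n_footprints Number of planted footprints.
#' @param footprint_lengths Footprint length(s) in bp; sampled per footprint
#'   when several are given.
#' @param depletion Fraction in `[0, 1]`; within-footprint rates are
#'   multiplied by `1 - depletion`.
#' @param shoulder_boost Multiplicative factor (>= 1) on the +strand rate in
#'   the upstream shoulder and the -strand rate in the downstream shoulder of
#'   each footprint.
#' @param sh_length Shoulder length in bp.
#' @param min_gap Minimum bp between planted footprints.
#' @param chrom Name of the synthetic contig.
#' @param origin 0-based genomic start of the DHS on the contig (kept >= the
#'   read length so reverse reads fit on the contig).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A `wtn_simulation_spec` list.
#' @export
simulation_spec <- function(dhs_length = 600, background_rate = 0.5,
                            n_footprints = 2, footprint_lengths = 16,
                            depletion = 0.9, shoulder_boost = 3,
                            sh_length = 35, min_gap = 90,
                            chrom = "chrS", origin = 100, seed = 1) {
  if (background_rate < 0) abort("`background_rate` must be >= 0")
  if (depletion < 0 || depletion > 1) abort("`depletion` must lie in [0, 1]")
  if (shoulder_boost < 1) abort("`shoulder_boost` must be >= 1")
  if (n_footprints > 0 &&
      dhs_length <= n_footprints * (max(footprint_lengths) + 2 * min_gap)) {
    abort("dhs_length too small for n_footprints at this min_gap")
  }
  structure(
    list(dhs_length = as.integer(dhs_length),
         background_rate = background_rate,
         n_footprints = as.integer(n_footprints),
         footprint_lengths = as.integer(footprint_lengths),
         depletion = depletion, shoulder_boost = shoulder_boost,
         sh_length = as.integer(sh_length), min_gap = as.integer(min_gap),
         chrom = as.character(chrom), origin = as.integer(origin),
         seed = as.integer(seed)),
    class = "wtn_simulation_spec"
  )
}

#' Simulate a DHS with planted, strand-imbalanced footprints
#'
#' Draws footprint positions without overlap (respecting `min_gap` and an
#' edge margin of `sh_length + footprint length` so every planted centre is
#' scoreable), then per-base per-strand Poisson counts under the rate model
#' of [simulation_spec()]. Identical specs (including seed) give identical
#' datasets.
#'
#' @param spec A [simulation_spec()].
#' @return A `wtn_synthetic_dataset`: list with `profile` (a [cut_profile()]),
#'   `truth` (interval tibble of planted footprints) and `spec`.
#' @export
simulate_dhs <- function(spec) {
  stopifnot(inherits(spec, "wtn_simulation_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$dhs_length
    lens <- if (spec$n_footprints == 0) {
      integer()
    } else if (length(spec$footprint_lengths) == 1) {
      rep(spec$footprint_lengths, spec$n_footprints)
    } else {
      sample(spec$footprint_lengths, spec$n_footprints, replace = TRUE)
    }
    starts <- integer()
    ends <- integer()
    tries <- 0L
    for (len in lens) {
      margin <- spec$sh_length + len
      repeat {
        tries <- tries + 1L
        if (tries > 1000L) {
          abort("could not place footprints after 1000 tries; loosen the spec")
        }
        s <- sample.int(L - 2L * margin - len + 1L, 1L) + margin - 1L
        e <- s + len
        clear <- all(s >= ends + spec$min_gap | e + spec$min_gap <= starts)
        if (clear) break
      }
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    rate_p <- rep(spec$background_rate, L)
    rate_m <- rep(spec$background_rate, L)
    for (j in seq_along(starts)) {
      fp <- (starts[j] + 1L):ends[j]
      rate_p[fp] <- rate_p[fp] * (1 - spec$depletion)
      rate_m[fp] <- rate_m[fp] * (1 - spec$depletion)
      up <- (starts[j] - spec$sh_length + 1L):starts[j]
      dn <- (ends[j] + 1L):(ends[j] + spec$sh_length)
      rate_p[up] <- rate_p[up] * spec$shoulder_boost
      rate_m[dn] <- rate_m[dn] * spec$shoulder_boost
    }
    profile <- cut_profile(spec$chrom, spec$origin,
                           plus = rpois(L, rate_p), minus = rpois(L, rate_m))
    ord <- order(starts)
    truth <- if (length(starts)) {
      genomic_intervals(spec$chrom, spec$origin + starts[ord],
                        spec$origin + ends[ord],
                        name = sprintf("planted_%d", seq_along(starts)))
    } else {
      genomic_intervals(character(), integer(), integer())
    }
    structure(list(profile = profile, truth = truth, spec = spec),
              class = "wtn_synthetic_dataset")
  })
}

#' @export
print.wtn_synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "# Synthetic DHS %s:%d-%d: %d planted footprints, %d cuts (seed %d)\n",
    x$spec$chrom, x$spec$origin, x$spec$origin + x$spec$dhs_length,
    nrow(x$truth), sum(x$profile$plus) + sum(x$profile$minus), x$spec$seed))
  invisible(x)
}

#' Emit simulated cut profiles as an indexed BAM file
#'
#' Writes one single-end alignment record per cut: a +strand cut at base `x`
#' becomes a forward read starting at `x`; a -strand cut at `x` becomes a
#' reverse read whose rightmost aligned base (its 5' end) is `x`. The file is
#' coordinate-sorted and indexed, with one synthetic contig per dataset, so
#' `extract_cuts()` over the profile interval recovers the profile exactly.
#'
#' @param datasets A `wtn_synthetic_dataset` or a list of them (contig names
#'   must be distinct).
#' @param path Output BAM path (`.bam`); the index is written alongside.
#' @param read_length Read length in bp (>= 1); dataset origins must be at
#'   least this large so reverse reads fit on the contig.
#' @return The BAM path, invisibly.
#' @export
emit_alignments <- function(datasets, path, read_length = 36) {
  if (inherits(datasets, "wtn_synthetic_dataset")) datasets <- list(datasets)
  read_length <- as.integer(read_length)
  if (read_length < 1) abort("`read_length` must be >= 1")
  chroms <- vapply(datasets, function(d) d$spec$chrom, character(1))
  if (anyDuplicated(chroms)) {
    abort("datasets must live on distinct contigs to share one BAM")
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate")
  body <- character()
  seq_str <- strrep("A", read_length)
  for (d in datasets) {
    prof <- d$profile
    start0 <- profile_start(prof)
    if (start0 < read_length) {
      abort(sprintf(
        "dataset origin %d < read_length %d: reverse reads would leave the contig",
        start0, read_length))
    }
    contig_len <- profile_end(prof) + read_length + 100L
    header <- c(header,
                sprintf("@SQ\tSN:%s\tLN:%d", profile_chrom(prof), contig_len))
    cuts0 <- prof$pos # 0-based cut coordinates
    fwd_pos <- rep(cuts0, prof$plus) # 0-based read start = cut
    rev_pos <- rep(cuts0, prof$minus) - read_length + 1L # leftmost base
    pos1 <- c(fwd_pos, rev_pos) + 1L
    flag <- c(rep(0L, length(fwd_pos)), rep(16L, length(rev_pos)))
    ord <- order(pos1)
    if (length(pos1)) {
      body <- c(body, sprintf(
        "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
        sprintf("%s_r%06d", profile_chrom(prof), seq_along(pos1)),
        flag[ord], profile_chrom(prof), pos1[ord], read_length, seq_str))
    }
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, body), sam)
  dest <- sub("\\.bam$", "", path)
  tmp_bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp_bam, dest)
  unlink(tmp_bam)
  Rsamtools::indexBam(sorted)
  invisible(sorted)
}
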