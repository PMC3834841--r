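#' Call non-overlapping footprints from a score track
#'
#' Greedy selection: every base whose score is at or below the cutoff is a
#' candidate footprint centred there, spanning the footprint length that
#' achieved its score. Candidates are visited from the smallest (most
#' significant) `log10p` upward, ties broken by leftmost coordinate, and a
#' candidate is accepted iff its span shares no base with a previously
#' accepted footprint.
#'
#' @param track A `wtn_score_track` from [score_interval()].
#' @param log10p_cutoff Calling threshold on the log10 p-value (<= 0), e.g.
#'   -30 reproduces the published figure-level threshold of 1e-30.
#' @return A tibble of footprints sorted by coordinate: `chrom`, `start`,
#'   `end`, `name`, `score` (-log10 p), `strand`, plus `centre`, `l_fp`,
#'   `l_sh` and `log10p`. Zero rows when nothing passes the cutoff.
#' @export
call_footprints <- function(track, log10p_cutoff) {
  stopifnot(inherits(track, "wtn_score_track"))
  if (log10p_cutoff > 0) abort("`log10p_cutoff` must be <= 0")
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    centre = integer(), l_fp = integer(), l_sh = integer(), log10p = numeric()
  )
  if (!nrow(track)) return(empty)
  cand <- which(track$log10p <= log10p_cutoff & track$best_lfp > 0L)
  if (!length(cand)) return(empty)
  ord <- cand[order(track$log10p[cand], track$pos[cand])]
  t0 <- attr(track, "start")
  occupied <- logical(attr(track, "end") - t0)
  keep <- integer()
  for (i in ord) {
    lfp <- track$best_lfp[i]
    fs <- track$pos[i] - t0 - lfp %/% 2L # 0-based offset of footprint start
    fe <- fs + lfp
    span <- (fs + 1L):fe
    if (fs < 0L || fe > length(occupied) || any(occupied[span])) next
    occupied[span] <- TRUE
    keep <- c(keep, i)
  }
  if (!length(keep)) return(empty)
  lfp <- track$best_lfp[keep]
  start <- track$pos[keep] - lfp %/% 2L
  out <- tibble(
    chrom = track_chrom(track),
    start = start,
    end = start + lfp,
    name = NA_character_,
    score = round(-track$log10p[keep], 2),
    strand = ".",
    centre = track$pos[keep],
    l_fp = lfp,
    l_sh = track$best_lsh[keep],
    log10p = track$log10p[keep]
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("FP_%d", seq_len(nrow(out)))
  out
}

#' Write score tracks as a fixedStep WIG file
#'
#' One `fixedStep` block per track, step 1, 1-based start per the WIG
#' standard (`start = interval start + 1`), one log10 p-value per line.
#' Values are printed at full double precision so a parsed WIG recovers the
#' scores exactly.
#'
#' @param tracks A `wtn_score_track` or a list of them.
#' @param path Output path.
#' @return `tracks`, invisibly.
#' @export
write_scores_wig <- function(tracks, path) {
  if (inherits(tracks, "wtn_score_track")) tracks <- list(tracks)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in tracks) {
    stopifnot(inherits(tr, "wtn_score_track"))
    if (!nrow(tr)) next
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       track_chrom(tr), attr(tr, "start") + 1L), con)
    writeLines(sprintf("%.17g", tr$log10p), con)
  }
  invisible(tracks)
}

#' Write called footprints as BED6
#'
#' Columns: chrom, start, end (0-based half-open), name, score = -log10 of the
#' footprint p-value rounded to 2 decimals, strand `"."`. Rows are emitted in
#' coordinate-sorted order whatever the input order.
#'
#' @param footprints A footprint tibble from [call_footprints()].
#' @param path Output path.
#' @return `footprints`, invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  if (!nrow(footprints)) {
    writeLines(character(), path)
    return(invisible(footprints))
  }
  x <- dplyr::arrange(footprints, .data$chrom, .data$start, .data$end)
  score <- if ("log10p" %in% names(x)) -x$log10p else x$score
  lines <- sprintf("%s\t%d\t%d\t%s\t%.2f\t.",
                   x$chrom, x$start, x$end,
                   ifelse(is.na(x$name), sprintf("FP_%d", seq_len(nrow(x))), x$name),
                   score)
  writeLines(lines, path)
  invisible(footprints)
}

#' Run the whole footprinting pipeline over a DHS list
#'
#' For every DNase I hypersensitive site: extract strand-resolved cut counts
#' from the BAM, score every base with the Wellington statistic, and call
#' footprints at each requested cutoff. Writes `scores.wig` (fixedStep) and
#' one `footprints.p<cutoff>.bed` (BED6) per cutoff into `out_dir`.
#'
#' @param reads Path to a coordinate-sorted, indexed BAM file.
#' @param dhs DHS intervals: a BED path or an interval tibble.
#' @param out_dir Output directory (created if missing).
#' @param grid A [length_grid()]; defaults to 11-26 bp footprints, 35 bp
#'   shoulders.
#' @param mode Scoring mode, see [footprint_pvalue()].
#' @param cutoffs Numeric vector of log10 p-value cutoffs (each <= 0).
#' @param min_mapq Minimum mapping quality for reads.
#' @param pad Extend each DHS by this many bp on each side using reads outside
#'   the interval, so bases near DHS edges get full windows; scores are
#'   reported for the original span only. Default 0 (edge bases score 0).
#' @param verbose Log the effective configuration and per-DHS progress.
#' @return Invisibly, a tibble of all called footprints with a `cutoff`
#'   column; the per-DHS score tracks are attached as attribute `tracks` and
#'   the written file paths as attribute `files`.
#' @export
run_footprinting <- function(reads, dhs, out_dir, grid = length_grid(),
                             mode = c("forward", "reverse", "one_d"),
                             cutoffs = c(-10, -20, -30), min_mapq = 0,
                             pad = 0, verbose = TRUE) {
  mode <- match.arg(mode)
  if (any(cutoffs > 0)) abort("all `cutoffs` must be <= 0 (log10 p-values)")
  if (is.character(dhs)) dhs <- read_bed(dhs)
  validate_intervals(dhs, "dhs")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) inform(sprintf(...))
  say("wellington: footprint lengths: %d..%d bp (step %d); shoulder: %s bp",
      grid$fp_min, grid$fp_max, grid$fp_step,
      paste(grid$sh_values, collapse = ", "))
  say("wellington: mode: %s; cutoffs: %s; min_mapq: %d; pad: %d bp",
      mode, paste(cutoffs, collapse = ", "), as.integer(min_mapq),
      as.integer(pad))
  pad <- as.integer(pad)
  tracks <- vector("list", nrow(dhs))
  for (i in seq_len(nrow(dhs))) {
    iv <- dhs[i, ]
    ext <- iv
    ext$start <- max(0L, iv$start - pad)
    ext$end <- iv$end + pad
    prof <- extract_cuts(reads, ext, min_mapq = min_mapq)
    tr <- score_interval(prof, grid = grid, mode = mode)
    if (pad > 0) {
      sel <- tr$pos >= iv$start & tr$pos < iv$end
      tr <- new_score_track(as_tibble(tr)[sel, ], chrom = iv$chrom,
                            start = iv$start, end = iv$end,
                            mode = mode, grid = grid)
    }
    tracks[[i]] <- tr
    say("wellington: DHS %d/%d %s:%d-%d: min log10p %.2f", i, nrow(dhs),
        iv$chrom, iv$start, iv$end,
        if (nrow(tr)) min(tr$log10p) else NA_real_)
  }
  wig <- file.path(out_dir, "scores.wig")
  write_scores_wig(tracks, wig)
  files <- wig
  all_fp <- list()
  for (co in cutoffs) {
    fp <- dplyr::bind_rows(lapply(tracks, call_footprints, log10p_cutoff = co))
    if (nrow(fp)) {
      fp <- dplyr::arrange(fp, .data$chrom, .data$start)
      fp$name <- sprintf("FP_%d", seq_len(nrow(fp)))
    }
    bed <- file.path(out_dir, sprintf("footprints.p%g.bed", co))
    write_footprints_bed(fp, bed)
    files <- c(files, bed)
    if (nrow(fp)) fp$cutoff <- co
    all_fp[[as.character(co)]] <- fp
    say("wellington: cutoff %g: %d footprints", co, nrow(fp))
  }
  out <- dplyr::bind_rows(all_fp)
  say("wellington: done: %d DHSs, %d footprint calls in total",
      nrow(dhs), nrow(out))
  attr(out, "tracks") <- tracks
  attr(out, "files") <- files
  invisible(out)
}
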