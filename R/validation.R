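#' Reciprocal-containment recapitulation rule
#'
#' A footprint recapitulates a ChIP-seq confirmed binding site when at least
#' 70% of the footprint is contained within the site, or vice versa. The
#' criterion tolerates protection that is not centred perfectly on the motif.
#' Intervals on different chromosomes never recapitulate each other.
#'
#' @param footprint,site One-row interval tibbles (or equal-length tibbles,
#'   compared row by row).
#' @param threshold Containment fraction; default 0.70.
#' @return Logical vector.
#' @examples
#' fp <- genomic_intervals("chr1", 100, 110)
#' site <- genomic_intervals("chr1", 95, 120)
#' recapitulated(fp, site) # TRUE: 100% of the footprint is inside the site
#' @export
recapitulated <- function(footprint, site, threshold = 0.70) {
  validate_intervals(footprint, "footprint")
  validate_intervals(site, "site")
  ov <- pmax(0L, pmin(footprint$end, site$end) - pmax(footprint$start, site$start))
  same <- footprint$chrom == site$chrom
  same & (ov >= threshold * (footprint$end - footprint$start) |
            ov >= threshold * (site$end - site$start))
}

#' Fraction of sites recapitulated by a footprint set
#'
#' For each site, checks whether any footprint satisfies [recapitulated()];
#' reports the recapitulated fraction together with the total number of base
#' pairs covered by the footprint set (the cost axis of
#' recapitulation-per-base-pair comparisons).
#'
#' @param footprints,sites Interval tibbles.
#' @param threshold Containment fraction; default 0.70.
#' @return A one-row tibble: `rate`, `n_sites`, `n_recapitulated`,
#'   `footprint_bp`.
#' @export
recapitulation_rate <- function(footprints, sites, threshold = 0.70) {
  validate_intervals(sites, "sites")
  if (!nrow(sites)) abort("`sites` is empty: recapitulation rate is undefined")
  validate_intervals(footprints, "footprints")
  fp_bp <- if (nrow(footprints)) {
    sum(IRanges::width(GenomicRanges::reduce(as_granges_tbl(footprints))))
  } else 0L
  hit <- logical(nrow(sites))
  if (nrow(footprints)) {
    ovl <- GenomicRanges::findOverlaps(as_granges_tbl(sites),
                                       as_granges_tbl(footprints))
    if (length(ovl)) {
      si <- S4Vectors::queryHits(ovl)
      fi <- S4Vectors::subjectHits(ovl)
      ok <- recapitulated(footprints[fi, ], sites[si, ], threshold = threshold)
      hit[unique(si[ok])] <- TRUE
    }
  }
  tibble(rate = mean(hit), n_sites = nrow(sites),
         n_recapitulated = sum(hit), footprint_bp = as.integer(fp_bp))
}

#' Footprint evidence at candidate sites
#'
#' Assigns each site the minimum log10 footprint p-value over the bases it
#' covers (the strongest footprint evidence within the site), for use as the
#' classifier score in ROC and PPV analyses. Sites with no scored base get
#' score 0 (no evidence).
#'
#' @param tracks A `wtn_score_track` or list of them.
#' @param sites Interval tibble of candidate (motif-instance) sites.
#' @return `sites` with a `score` column of minimum log10 p-values.
#' @export
site_scores <- function(tracks, sites) {
  if (inherits(tracks, "wtn_score_track")) tracks <- list(tracks)
  validate_intervals(sites, "sites")
  score <- rep(0, nrow(sites))
  for (tr in tracks) {
    chrom <- track_chrom(tr)
    for (i in seq_len(nrow(sites))) {
      if (sites$chrom[i] != chrom) next
      sel <- tr$pos >= sites$start[i] & tr$pos < sites$end[i]
      if (any(sel)) score[i] <- min(score[i], min(tr$log10p[sel]))
    }
  }
  sites$score <- score
  sites
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the site scores of a labelled site set (bound =
#' ChIP-seq confirmed motif instance) and reports the true/false positive
#' rates at each distinct score, with tied scores grouped into a single step,
#' and the area under the curve by trapezoidal integration.
#'
#' @param sites Tibble with logical column `bound` and numeric column `score`.
#' @param direction `"lower"` (default) when smaller scores mean stronger
#'   binding evidence (log10 p-values); `"higher"` for the opposite.
#' @return A `wtn_roc` object; `tidy()` gives the curve (`score`, `fpr`,
#'   `tpr`), `glance()` gives `auc`, `n_bound`, `n_unbound`.
#' @export
roc_auc <- function(sites, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (!all(c("bound", "score") %in% names(sites))) {
    abort("`sites` needs columns `bound` (logical) and `score` (numeric)")
  }
  if (anyNA(sites$score)) abort("all sites must carry a score")
  bound <- as.logical(sites$bound)
  npos <- sum(bound)
  nneg <- sum(!bound)
  if (npos == 0 || nneg == 0) {
    abort("need at least one bound and one unbound site")
  }
  evidence <- if (direction == "lower") -sites$score else sites$score
  ord <- order(evidence, decreasing = TRUE)
  ev <- evidence[ord]
  b <- bound[ord]
  last <- !duplicated(ev, fromLast = TRUE) # one step per distinct score
  tpr <- c(0, cumsum(b)[last] / npos)
  fpr <- c(0, cumsum(!b)[last] / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(curve = tibble(score = c(if (direction == "lower") Inf else -Inf,
                                  sites$score[ord][last]),
                        fpr = fpr, tpr = tpr),
         auc = auc, n_bound = npos, n_unbound = nneg),
    class = "wtn_roc"
  )
}

#' @export
print.wtn_roc <- function(x, ...) {
  cat(sprintf("# ROC: AUC = %.4f (%d bound, %d unbound sites)\n",
              x$auc, x$n_bound, x$n_unbound))
  invisible(x)
}

#' @rdname roc_auc
#' @param x,object A `wtn_roc`.
#' @param ... Unused.
#' @method tidy wtn_roc
#' @export
tidy.wtn_roc <- function(x, ...) x$curve

#' @rdname roc_auc
#' @method glance wtn_roc
#' @export
glance.wtn_roc <- function(x, ...) {
  tibble(auc = x$auc, n_bound = x$n_bound, n_unbound = x$n_unbound)
}

#' @rdname roc_auc
#' @method autoplot wtn_roc
#' @export
autoplot.wtn_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Positive predictive value of binding-site predictions
#'
#' The fraction of predicted bound motif instances confirmed by ChIP-seq.
#' Predictions are matched to the truth sets by exact interval identity
#' (chromosome, start, end), as predictions are made over known motif
#' instances.
#'
#' @param predicted_bound Interval tibble of motif instances predicted bound.
#' @param truth_bound,truth_unbound Interval tibbles of ChIP-seq confirmed and
#'   unconfirmed motif instances.
#' @return A one-row tibble: `ppv`, `n_predicted`, `n_confirmed`.
#' @export
positive_predictive_value <- function(predicted_bound, truth_bound,
                                      truth_unbound) {
  validate_intervals(predicted_bound, "predicted_bound")
  validate_intervals(truth_bound, "truth_bound")
  validate_intervals(truth_unbound, "truth_unbound")
  if (!nrow(predicted_bound)) {
    abort("no predictions: positive predictive value is undefined")
  }
  key <- function(x) paste(x$chrom, x$start, x$end, sep = ":")
  pk <- key(predicted_bound)
  known <- c(key(truth_bound), key(truth_unbound))
  if (!all(pk %in% known)) {
    abort("every prediction must be a known (bound or unbound) motif instance")
  }
  confirmed <- sum(pk %in% key(truth_bound))
  tibble(ppv = confirmed / length(pk), n_predicted = length(pk),
         n_confirmed = confirmed)
}

#' Nucleotide performance coefficient
#'
#' Base-pair-resolution agreement between a predicted and a true interval set:
#' `TP / (TP + FP + FN)` where TP counts bases in both sets, FP bases only
#' predicted and FN bases only true. Averaging across factors is left to the
#' caller.
#'
#' @param predicted,truth Interval tibbles.
#' @return A one-row tibble: `coefficient`, `tp`, `fp`, `fn`.
#' @export
nucleotide_performance <- function(predicted, truth) {
  validate_intervals(predicted, "predicted")
  validate_intervals(truth, "truth")
  if (!nrow(predicted) && !nrow(truth)) {
    abort("both interval sets are empty: coefficient is undefined")
  }
  gr_p <- GenomicRanges::reduce(as_granges_tbl(predicted))
  gr_t <- GenomicRanges::reduce(as_granges_tbl(truth))
  tp <- sum(IRanges::width(GenomicRanges::intersect(gr_p, gr_t)))
  fp <- sum(IRanges::width(GenomicRanges::setdiff(gr_p, gr_t)))
  fn <- sum(IRanges::width(GenomicRanges::setdiff(gr_t, gr_p)))
  tibble(coefficient = tp / (tp + fp + fn),
         tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

# expand interval-midpoint windows into (site, offset, chrom, pos) rows;
# -strand intervals are mirrored (offset sign flipped)
offset_windows <- function(intervals, flank, mirror_minus = TRUE) {
  validate_intervals(intervals)
  mids <- interval_midpoint(intervals)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  n <- nrow(intervals)
  offs <- seq(-flank, flank)
  out <- tibble(
    site = rep(seq_len(n), each = length(offs)),
    chrom = rep(intervals$chrom, each = length(offs)),
    pos = rep(mids, each = length(offs)) + rep(offs, n),
    offset = rep(offs, n)
  )
  if (mirror_minus) {
    minus <- rep(strand == "-", each = length(offs))
    out$offset[minus] <- -out$offset[minus]
  }
  out
}

#' Average a per-base signal track over footprint-centred windows
#'
#' Computes, for every offset in `-flank..flank` from interval midpoints, the
#' mean of a per-base signal (e.g. phyloP-style conservation) across
#' intervals. Minus-strand intervals are mirrored before averaging. Positions
#' absent from the track (gaps) are excluded from the per-offset mean rather
#' than treated as zero.
#'
#' @param track Per-base signal as a tibble with columns `chrom`, `pos`
#'   (0-based) and `score`, or bedGraph-style `chrom`, `start`, `end`,
#'   `score` spans (expanded internally).
#' @param intervals Interval tibble; midpoint convention
#'   `start + floor(length/2)`.
#' @param flank Half-window in bp.
#' @return Tibble with columns `offset`, `mean` and `n` (number of intervals
#'   contributing a value at that offset).
#' @export
mean_signal_profile <- function(track, intervals, flank) {
  validate_intervals(intervals, "intervals")
  if (!nrow(intervals)) abort("`intervals` is empty")
  if (all(c("start", "end") %in% names(track)) && !("pos" %in% names(track))) {
    track <- tidyr::uncount(track, weights = .data$end - .data$start,
                            .id = "off")
    track$pos <- track$start + track$off - 1L
  }
  if (!all(c("chrom", "pos", "score") %in% names(track))) {
    abort("`track` needs columns chrom, pos, score (or chrom, start, end, score)")
  }
  win <- offset_windows(intervals, flank)
  win <- dplyr::left_join(win, track[, c("chrom", "pos", "score")],
                          by = c("chrom", "pos"))
  out <- dplyr::summarise(
    dplyr::group_by(win, .data$offset),
    mean = mean(.data$score, na.rm = TRUE),
    n = sum(!is.na(.data$score)),
    .groups = "drop"
  )
  out$mean[out$n == 0] <- NA_real_
  dplyr::arrange(out, .data$offset)
}

#' Motif content around footprint centres
#'
#' For every offset in `-flank..flank` from footprint midpoints, the fraction
#' of footprints whose base at that offset is covered by at least one motif
#' interval.
#'
#' @param footprints Interval tibble of footprints.
#' @param motif_intervals Interval tibble of motif locations.
#' @param flank Half-window in bp.
#' @return Tibble with columns `offset` and `fraction`.
#' @export
motif_content <- function(footprints, motif_intervals, flank) {
  validate_intervals(footprints, "footprints")
  if (!nrow(footprints)) abort("`footprints` is empty")
  validate_intervals(motif_intervals, "motif_intervals")
  win <- offset_windows(footprints, flank, mirror_minus = FALSE)
  covered <- if (nrow(motif_intervals)) {
    pts <- GenomicRanges::GRanges(win$chrom,
                                  IRanges::IRanges(win$pos + 1L, win$pos + 1L))
    IRanges::overlapsAny(pts, as_granges_tbl(motif_intervals))
  } else rep(FALSE, nrow(win))
  win$covered <- covered
  out <- dplyr::summarise(dplyr::group_by(win, .data$offset),
                          fraction = mean(.data$covered), .groups = "drop")
  dplyr::arrange(out, .data$offset)
}
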