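#' Lower tail of the binomial distribution
#'
#' Returns `P(X <= k)` for `X ~ Binomial(n, p)`, the inclusive lower tail used
#' by the footprint test: fewer cuts in the footprint than expected from its
#' length fraction gives a small tail probability. Computed in log space
#' (via [stats::pbinom()]) so that the extreme tails arising at deep coverage
#' do not underflow before logs are taken.
#'
#' @param k Number of successes observed (vectorised); `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @param log10 If `TRUE`, return `log10 P(X <= k)` instead of the probability.
#' @return Probability (or its log10) with the same length as the inputs.
#' @examples
#' binom_lower_tail(0, 10, 0.5) # 2^-10
#' @export
binom_lower_tail <- function(k, n, p, log10 = FALSE) {
  if (any(k < 0 | n < 0 | k > n)) abort("need 0 <= k <= n")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  lp <- pbinom(k, n, p, lower.tail = TRUE, log.p = TRUE) / log(10)
  if (log10) lp else 10^lp
}

#' Footprint / shoulder length grid
#'
#' The candidate footprint lengths and shoulder length(s) searched at every
#' base. Defaults follow the published algorithm: footprint lengths bounded
#' between 11 and 26 bp (step 1) with the shoulder fixed at 35 bp on each
#' side. Both are user-settable as ranges or fixed values.
#'
#' @param fp_min,fp_max Smallest and largest candidate footprint length (bp).
#' @param fp_step Step between candidate footprint lengths (bp).
#' @param sh Shoulder length(s) in bp, one value per side (a vector searches
#'   several shoulder lengths).
#' @return A `wtn_length_grid` list with elements `fp_lengths` and `sh_values`.
#' @examples
#' length_grid()          # 11..26 bp footprints, 35 bp shoulders
#' length_grid(16, 16, sh = 20)
#' @export
length_grid <- function(fp_min = 11, fp_max = 26, fp_step = 1, sh = 35) {
  fp_min <- as.integer(fp_min); fp_max <- as.integer(fp_max)
  fp_step <- as.integer(fp_step); sh <- as.integer(sh)
  if (fp_min < 1 || fp_max < fp_min) abort("need 1 <= fp_min <= fp_max")
  if (fp_step < 1) abort("`fp_step` must be >= 1")
  if (!length(sh) || any(sh < 1)) abort("`sh` must contain lengths >= 1")
  structure(
    list(fp_min = fp_min, fp_max = fp_max, fp_step = fp_step,
         fp_lengths = seq(fp_min, fp_max, by = fp_step), sh_values = sh),
    class = "wtn_length_grid"
  )
}

#' @export
print.wtn_length_grid <- function(x, ...) {
  cat(sprintf("footprint lengths: %d..%d bp (step %d); shoulder: %s bp\n",
              x$fp_min, x$fp_max, x$fp_step,
              paste(x$sh_values, collapse = ", ")))
  invisible(x)
}

#' Shouldered cut counts at a candidate footprint
#'
#' Sums cut counts inside a candidate footprint and in its two shoulders, for
#' both strands. The footprint of length `l_fp` centred on `centre` occupies
#' `[centre - floor(l_fp/2), centre - floor(l_fp/2) + l_fp)`; each shoulder is
#' the `l_sh` bases immediately flanking it. In the spec of the forward test,
#' `sh_plus` is the upstream +strand count and `sh_minus` the downstream
#' -strand count; the opposite-strand shoulder sums are retained as
#' `sh_up_minus` / `sh_down_plus` so the reverse and strand-agnostic tests can
#' be formed from the same object.
#'
#' @param profile A [cut_profile()].
#' @param centre Genomic (0-based) coordinate of the candidate footprint
#'   centre; must lie inside the profile.
#' @param l_fp Footprint length (bp).
#' @param l_sh Shoulder length per side (bp).
#' @return A `wtn_shouldered_counts` list with fields `fp_plus`, `sh_plus`,
#'   `fp_minus`, `sh_minus`, `sh_up_minus`, `sh_down_plus`, `l_fp`, `l_sh`.
#' @export
counts_at <- function(profile, centre, l_fp, l_sh) {
  stopifnot(inherits(profile, "wtn_cut_profile"))
  l_fp <- as.integer(l_fp); l_sh <- as.integer(l_sh)
  if (l_fp < 1 || l_sh < 1) abort("need l_fp >= 1 and l_sh >= 1")
  off <- as.integer(centre) - profile_start(profile)
  s <- off - l_fp %/% 2L
  L <- nrow(profile)
  if (s - l_sh < 0L || s + l_fp + l_sh > L) {
    abort(sprintf(
      "window [centre - %d, centre + %d) out of profile bounds at centre %d",
      l_fp %/% 2L + l_sh, (l_fp - l_fp %/% 2L) + l_sh, centre))
  }
  win <- function(v, a, w) sum(v[(a + 1L):(a + w)])
  shouldered_counts(
    fp_plus = win(profile$plus, s, l_fp),
    sh_plus = win(profile$plus, s - l_sh, l_sh),
    fp_minus = win(profile$minus, s, l_fp),
    sh_minus = win(profile$minus, s + l_fp, l_sh),
    l_fp = l_fp, l_sh = l_sh,
    sh_up_minus = win(profile$minus, s - l_sh, l_sh),
    sh_down_plus = win(profile$plus, s + l_fp, l_sh)
  )
}

#' @rdname counts_at
#' @param fp_plus,sh_plus,fp_minus,sh_minus The four counts of the forward
#'   test: +strand cuts in the footprint, +strand cuts in the upstream
#'   shoulder, -strand cuts in the footprint, -strand cuts in the downstream
#'   shoulder.
#' @param sh_up_minus,sh_down_plus Opposite-strand shoulder counts (upstream
#'   -strand, downstream +strand); required for the reverse and 1D tests.
#' @export
shouldered_counts <- function(fp_plus, sh_plus, fp_minus, sh_minus,
                              l_fp, l_sh, sh_up_minus = NA_integer_,
                              sh_down_plus = NA_integer_) {
  counts <- c(fp_plus, sh_plus, fp_minus, sh_minus)
  if (anyNA(counts) || any(counts < 0)) abort("all counts must be >= 0")
  if (l_fp < 1 || l_sh < 1) abort("need l_fp >= 1 and l_sh >= 1")
  structure(
    list(fp_plus = as.integer(fp_plus), sh_plus = as.integer(sh_plus),
         fp_minus = as.integer(fp_minus), sh_minus = as.integer(sh_minus),
         sh_up_minus = as.integer(sh_up_minus),
         sh_down_plus = as.integer(sh_down_plus),
         l_fp = as.integer(l_fp), l_sh = as.integer(l_sh)),
    class = "wtn_shouldered_counts"
  )
}

#' The Wellington footprint p-value
#'
#' Tests the null hypothesis that cut counts are proportional to region length
#' against depletion inside the candidate footprint, strand by strand. With
#' `T(k, n) = P(X <= k)` for `X ~ Binomial(n, l_fp / (l_fp + l_sh))`:
#'
#' * `forward` — `T(FP+, FP+ + SH+) * T(FP-, FP- + SH-)`, pairing the upstream
#'   shoulder with the forward strand and the downstream shoulder with the
#'   reverse strand (the strand imbalance of double-hit DNase-seq libraries).
#'   The two strand tests are treated as independent because each sequenced
#'   fragment contributes at most one read of either orientation near a site.
#' * `reverse` — the mirrored control pairing (upstream shoulder with the
#'   -strand, downstream with the +strand); its hits lack conservation and
#'   motif support and are treated as artefacts.
#' * `one_d` — the strand-agnostic variant: one lower tail on the pooled
#'   counts, footprint (both strands) against both shoulders (both strands),
#'   with success probability `l_fp / (l_fp + 2 * l_sh)` so the null is still
#'   length-proportional on the pooled track. This form is exactly invariant
#'   under swapping the strands of the input.
#'
#' @param counts A [shouldered_counts()] (or [counts_at()]) object.
#' @param mode One of `"forward"`, `"reverse"`, `"one_d"`.
#' @param log10 If `TRUE`, return the log10 p-value.
#' @return The p-value in `(0, 1]` (or its log10).
#' @examples
#' cc <- shouldered_counts(fp_plus = 0, sh_plus = 50, fp_minus = 0,
#'                         sh_minus = 50, l_fp = 16, l_sh = 35)
#' footprint_pvalue(cc) # (35/51)^100
#' @export
footprint_pvalue <- function(counts, mode = c("forward", "reverse", "one_d"),
                             log10 = FALSE) {
  stopifnot(inherits(counts, "wtn_shouldered_counts"))
  mode <- match.arg(mode)
  p <- counts$l_fp / (counts$l_fp + counts$l_sh)
  lt <- function(fp, sh, pr) {
    binom_lower_tail(fp, fp + sh, pr, log10 = TRUE)
  }
  if (mode %in% c("reverse", "one_d") &&
      (is.na(counts$sh_up_minus) || is.na(counts$sh_down_plus))) {
    abort(sprintf(
      "mode '%s' needs sh_up_minus and sh_down_plus (see counts_at())", mode))
  }
  l10 <- switch(mode,
    forward = lt(counts$fp_plus, counts$sh_plus, p) +
      lt(counts$fp_minus, counts$sh_minus, p),
    reverse = lt(counts$fp_minus, counts$sh_up_minus, p) +
      lt(counts$fp_plus, counts$sh_down_plus, p),
    one_d = lt(counts$fp_plus + counts$fp_minus,
               counts$sh_plus + counts$sh_minus +
                 counts$sh_up_minus + counts$sh_down_plus,
               counts$l_fp / (counts$l_fp + 2 * counts$l_sh))
  )
  if (log10) l10 else 10^l10
}

#' Score every base of a cut profile
#'
#' Evaluates the footprint p-value at every base of the profile over the whole
#' length grid and keeps, per base, the smallest p-value (strongest evidence)
#' as a log10 score together with the footprint/shoulder lengths that achieved
#' it — the per-position maximum-evidence selection of `l_fp` and `l_sh`. The
#' score is assigned to the base at the centre of the footprint. Bases too
#' close to the profile edges for any `l_sh + l_fp` window to fit score 0.
#'
#' @param profile A [cut_profile()].
#' @param grid A [length_grid()].
#' @param mode Scoring mode, see [footprint_pvalue()].
#' @return A `wtn_score_track` tibble with columns `pos` (0-based genomic
#'   coordinate), `log10p` (<= 0), `best_lfp`, `best_lsh`, carrying `chrom`
#'   and `mode` attributes. If no window fits the profile a warning is issued
#'   and the track is identically 0.
#' @export
score_interval <- function(profile, grid = length_grid(),
                           mode = c("forward", "reverse", "one_d")) {
  stopifnot(inherits(profile, "wtn_cut_profile"))
  stopifnot(inherits(grid, "wtn_length_grid"))
  mode <- match.arg(mode)
  # reverse Wellington is, exactly, forward Wellington on the swapped strands
  work <- if (mode == "reverse") swap_strands(profile) else profile
  L <- nrow(work)
  cum_p <- c(0, cumsum(work$plus))
  cum_m <- c(0, cumsum(work$minus))
  win <- function(cum, a, w) cum[a + w + 1L] - cum[a + 1L] # 0-based start a
  best <- numeric(L)
  best_lfp <- integer(L)
  best_lsh <- integer(L)
  any_fit <- FALSE
  centres <- 0:(L - 1L)
  for (l_sh in grid$sh_values) {
    for (l_fp in grid$fp_lengths) {
      s <- centres - l_fp %/% 2L
      ok <- s - l_sh >= 0L & s + l_fp + l_sh <= L
      if (!any(ok)) next
      any_fit <- TRUE
      si <- s[ok]
      fp_p <- win(cum_p, si, l_fp)
      fp_m <- win(cum_m, si, l_fp)
      sh_up_p <- win(cum_p, si - l_sh, l_sh)
      sh_dn_m <- win(cum_m, si + l_fp, l_sh)
      if (mode == "one_d") {
        sh_up_m <- win(cum_m, si - l_sh, l_sh)
        sh_dn_p <- win(cum_p, si + l_fp, l_sh)
        k <- fp_p + fp_m
        n <- k + sh_up_p + sh_up_m + sh_dn_p + sh_dn_m
        l10 <- binom_lower_tail(k, n, l_fp / (l_fp + 2 * l_sh), log10 = TRUE)
      } else {
        pr <- l_fp / (l_fp + l_sh)
        l10 <- binom_lower_tail(fp_p, fp_p + sh_up_p, pr, log10 = TRUE) +
          binom_lower_tail(fp_m, fp_m + sh_dn_m, pr, log10 = TRUE)
      }
      oki <- which(ok)
      better <- l10 < best[oki]
      if (any(better)) {
        upd <- oki[better]
        best[upd] <- l10[better]
        best_lfp[upd] <- l_fp
        best_lsh[upd] <- l_sh
      }
    }
  }
  if (!any_fit) {
    warn(sprintf(
      "length grid does not fit profile of %d bp; track is identically 0", L))
  }
  out <- tibble(pos = profile_start(profile) + centres,
                log10p = best, best_lfp = best_lfp, best_lsh = best_lsh)
  new_score_track(out, chrom = profile_chrom(profile),
                  start = profile_start(profile), end = profile_end(profile),
                  mode = mode, grid = grid)
}

new_score_track <- function(x, chrom, start, end, mode, grid) {
  structure(x,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    mode = mode, grid = grid,
    class = c("wtn_score_track", class(tibble())))
}

track_chrom <- function(x) attr(x, "chrom")
track_mode <- function(x) attr(x, "mode")

#' @export
print.wtn_score_track <- function(x, ...) {
  cat(sprintf("# Footprint score track %s:%d-%d (mode %s, min log10p %.2f)\n",
              track_chrom(x), attr(x, "start"), attr(x, "end"),
              track_mode(x), if (nrow(x)) min(x$log10p) else NA_real_))
  NextMethod()
}

#' @rdname score_interval
#' @param x A `wtn_score_track`.
#' @param ... Unused.
#' @method tidy wtn_score_track
#' @export
tidy.wtn_score_track <- function(x, ...) {
  tibble(chrom = track_chrom(x), pos = x$pos, log10p = x$log10p,
         best_lfp = x$best_lfp, best_lsh = x$best_lsh)
}

#' @rdname score_interval
#' @method glance wtn_score_track
#' @export
glance.wtn_score_track <- function(x, ...) {
  scored <- x$log10p < 0
  tibble(
    chrom = track_chrom(x), start = attr(x, "start"), end = attr(x, "end"),
    mode = track_mode(x), n_bases = nrow(x), n_scored = sum(scored),
    min_log10p = if (nrow(x)) min(x$log10p) else NA_real_,
    pos_min = if (any(scored)) x$pos[which.min(x$log10p)] else NA_integer_
  )
}

#' @rdname score_interval
#' @param object A `wtn_score_track`.
#' @method autoplot wtn_score_track
#' @export
autoplot.wtn_score_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pos, y = .data$log10p)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(
      x = sprintf("position on %s", track_chrom(object)),
      y = expression(log[10] ~ "footprint p-value"),
      title = sprintf("Wellington scores (%s mode)", track_mode(object))
    ) +
    ggplot2::theme_minimal()
}
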