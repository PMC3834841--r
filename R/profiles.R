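# gather per-site strand-resolved cut windows (mid - flank .. mid + flank)
# cuts: BAM path, a single covering cut_profile, or a list of cut_profiles
# (one per site). Returns list(plus, minus): n_sites x (2*flank+1) matrices.
site_window_cuts <- function(cuts, sites, flank) {
  validate_intervals(sites, "sites")
  if (!nrow(sites)) abort("`sites` is empty")
  mids <- interval_midpoint(sites)
  width <- 2L * flank + 1L
  n <- nrow(sites)
  plus <- matrix(0L, n, width)
  minus <- matrix(0L, n, width)
  get_window <- function(profile, chrom, lo, hi) {
    if (profile_chrom(profile) != chrom ||
        lo < profile_start(profile) || hi >= profile_end(profile)) {
      abort(sprintf("window %s:%d-%d not covered by the supplied cut profile",
                    chrom, lo, hi))
    }
    sel <- (lo - profile_start(profile) + 1L):(hi - profile_start(profile) + 1L)
    list(plus = profile$plus[sel], minus = profile$minus[sel])
  }
  for (i in seq_len(n)) {
    lo <- mids[i] - flank
    hi <- mids[i] + flank
    w <- if (is.character(cuts)) {
      iv <- genomic_intervals(sites$chrom[i], lo, hi + 1L)
      p <- extract_cuts(cuts, iv)
      list(plus = p$plus, minus = p$minus)
    } else if (inherits(cuts, "wtn_cut_profile")) {
      get_window(cuts, sites$chrom[i], lo, hi)
    } else if (is.list(cuts) && length(cuts) == n) {
      get_window(cuts[[i]], sites$chrom[i], lo, hi)
    } else {
      abort("`cuts` must be a BAM path, a cut profile, or one profile per site")
    }
    plus[i, ] <- w$plus
    minus[i, ] <- w$minus
  }
  list(plus = plus, minus = minus)
}

#' Average strand-resolved cut profile around sites
#'
#' Mean +strand and -strand 5' cut counts at every offset from site midpoints
#' — the aggregate view in which the strand imbalance of double-hit DNase-seq
#' libraries appears as a +strand excess upstream and a -strand excess
#' downstream of bound sites. With `orient_by_motif`, windows of minus-strand
#' sites are mirrored and their strand vectors swapped before averaging, so
#' profiles are reported relative to motif orientation instead of the
#' reference strand.
#'
#' @param cuts A BAM path, a single [cut_profile()] covering all sites, or a
#'   list with one profile per site.
#' @param sites Interval tibble of sites (motif instances, footprints).
#' @param flank Half-window in bp.
#' @param orient_by_motif Mirror-and-swap minus-strand sites (default FALSE:
#'   reference-strand orientation).
#' @return A `wtn_strand_profile` tibble: `offset`, `plus`, `minus` (mean
#'   cuts per site).
#' @export
average_strand_profile <- function(cuts, sites, flank, orient_by_motif = FALSE) {
  w <- site_window_cuts(cuts, sites, flank)
  if (orient_by_motif) {
    strand <- if ("strand" %in% names(sites)) sites$strand else
      rep(".", nrow(sites))
    for (i in which(strand == "-")) {
      p <- rev(w$plus[i, ])
      m <- rev(w$minus[i, ])
      w$plus[i, ] <- m # mirrored -strand cuts read as +strand in motif frame
      w$minus[i, ] <- p
    }
  }
  out <- tibble(offset = seq(-flank, flank),
                plus = colMeans(w$plus), minus = colMeans(w$minus))
  structure(out, class = c("wtn_strand_profile", class(tibble())))
}

#' @rdname average_strand_profile
#' @param object A `wtn_strand_profile`.
#' @param ... Unused.
#' @method autoplot wtn_strand_profile
#' @export
autoplot.wtn_strand_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("plus", "minus"),
                            names_to = "strand", values_to = "cuts")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$cuts,
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(plus = "#d73027",
                                            minus = "#1a9850")) +
    ggplot2::labs(x = "offset from site centre (bp)",
                  y = "mean 5' cuts per site", colour = "strand") +
    ggplot2::theme_minimal()
}

#' Per-site strand-imbalance matrix
#'
#' One row per site of per-offset `plus - minus` cut excess (positive values:
#' +strand excess; negative: -strand excess), rows ordered by decreasing
#' `order_key` — heat-map semantics, with red/green rendering available via
#' `autoplot()`. The published heat maps order rows by a footprint occupancy
#' score; any per-site key may be supplied, defaulting to the total cut count
#' in the window.
#'
#' @inheritParams average_strand_profile
#' @param order_key Numeric vector, one value per site, used to sort rows in
#'   decreasing order; `NULL` (default) uses the total cut count per window.
#' @return A `wtn_site_matrix`: list with `offsets`, `excess` (sites x
#'   offsets matrix, rows sorted), `site_order` (original site indices in row
#'   order) and `order_key` (sorted).
#' @export
imbalance_matrix <- function(cuts, sites, flank, order_key = NULL) {
  w <- site_window_cuts(cuts, sites, flank)
  excess <- w$plus - w$minus
  key <- order_key %||% as.numeric(rowSums(w$plus) + rowSums(w$minus))
  if (length(key) != nrow(sites)) {
    abort("`order_key` must supply one value per site")
  }
  ord <- order(key, decreasing = TRUE)
  structure(
    list(offsets = seq(-flank, flank), excess = excess[ord, , drop = FALSE],
         site_order = ord, order_key = key[ord]),
    class = "wtn_site_matrix"
  )
}

#' @rdname imbalance_matrix
#' @param x,object A `wtn_site_matrix`.
#' @param ... Unused.
#' @method tidy wtn_site_matrix
#' @export
tidy.wtn_site_matrix <- function(x, ...) {
  n <- nrow(x$excess)
  tibble(
    row = rep(seq_len(n), each = length(x$offsets)),
    site = rep(x$site_order, each = length(x$offsets)),
    offset = rep(x$offsets, n),
    excess = as.vector(t(x$excess))
  )
}

#' @rdname imbalance_matrix
#' @method autoplot wtn_site_matrix
#' @export
autoplot.wtn_site_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$row,
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "black",
                                  high = "#d73027", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "offset from site centre (bp)", y = "site rank",
                  fill = "+ minus -\ncuts") +
    ggplot2::theme_minimal()
}

#' Write a site matrix as tab-separated text
#'
#' A header row of offsets followed by one row of excess values per site, in
#' the sorted row order.
#'
#' @param x A `wtn_site_matrix`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_site_matrix <- function(x, path) {
  stopifnot(inherits(x, "wtn_site_matrix"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(c("offset", x$offsets), collapse = "\t"), con)
  for (i in seq_len(nrow(x$excess))) {
    writeLines(paste(c(sprintf("site_%d", x$site_order[i]), x$excess[i, ]),
                     collapse = "\t"), con)
  }
  invisible(x)
}
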