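# Independent oracles and in-code fixtures shared across the suite.

# Brute-force binomial lower tail: direct pmf summation via log factorials,
# independent of stats::pbinom.
oracle_binom_cdf <- function(k, n, p) {
  if (n == 0) return(1)
  ks <- 0:k
  if (p == 0) return(1)
  if (p == 1) return(if (k >= n) 1 else 0)
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Brute-force greedy footprint selection: repeatedly pick the best remaining
# candidate (smallest log10p, then leftmost) whose span avoids all accepted
# spans. O(n^2) reference for call_footprints().
oracle_greedy <- function(track, cutoff) {
  pos <- track$pos
  lfp <- track$best_lfp
  starts <- pos - lfp %/% 2L
  ends <- starts + lfp
  cand <- which(track$log10p <= cutoff & lfp > 0L)
  accepted <- integer()
  repeat {
    free <- cand[vapply(cand, function(i) {
      !any(starts[i] < ends[accepted] & starts[accepted] < ends[i])
    }, logical(1))]
    if (!length(free)) break
    best <- free[order(track$log10p[free], pos[free])][1]
    accepted <- c(accepted, best)
    cand <- setdiff(cand, best)
  }
  accepted[order(pos[accepted])]
}

# Build a small indexed BAM from explicit read descriptions.
# reads: data.frame with chrom, pos0 (0-based leftmost aligned base), strand,
# and optionally cigar (default 36M) and mapq (default 60).
make_test_bam <- function(reads, path, chrom_lens = NULL) {
  if (is.null(reads$cigar)) reads$cigar <- "36M"
  if (is.null(reads$mapq)) reads$mapq <- 60L
  chroms <- unique(reads$chrom)
  if (is.null(chrom_lens)) {
    chrom_lens <- setNames(rep(100000L, length(chroms)), chroms)
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  rlen <- function(cig) { # query length: sum of query-consuming operations
    sum(as.integer(regmatches(cig, gregexpr("[0-9]+(?=[MISX=])", cig,
                                            perl = TRUE))[[1]]))
  }
  body <- vapply(seq_len(nrow(reads)), function(i) {
    n_read <- rlen(reads$cigar[i])
    sprintf("r%04d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            i, if (reads$strand[i] == "+") 0L else 16L,
            reads$chrom[i], reads$pos0[i] + 1L, reads$mapq[i],
            reads$cigar[i], strrep("A", n_read))
  }, character(1))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(header, body), sam)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
  unlink(tmp)
  Rsamtools::indexBam(sorted)
  sorted
}

# Random Poisson cut profile with mild structure, deterministic per seed.
random_profile <- function(seed, len = 150, rate = 0.6) {
  withr::with_seed(seed, {
    shape <- rate * exp(0.5 * sin(seq(0, 3 * pi, length.out = len)))
    cut_profile("chrR", 1000L, plus = rpois(len, shape),
                minus = rpois(len, rev(shape)))
  })
}

# Random score track whose qualifying candidates always fit inside the span.
random_track <- function(seed, len = 200) {
  withr::with_seed(seed, {
    log10p <- -round(rexp(len, 1 / 8), 1) # rounding creates score ties
    log10p[c(1:15, (len - 14):len)] <- 0
    wellington:::new_score_track(
      tibble::tibble(pos = 5000L + 0:(len - 1L), log10p = log10p,
                     best_lfp = sample(5:20, len, replace = TRUE),
                     best_lsh = 35L),
      chrom = "chrT", start = 5000L, end = 5000L + len,
      mode = "forward", grid = length_grid()
    )
  })
}

exec_script <- function(name) {
  file.path(find.package("wellington"), "exec", name)
}
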