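gi <- genomic_intervals

test_that("the reciprocal-containment rule flips exactly at 70%", {
  fp <- gi("chr1", 100, 110)
  expect_true(recapitulated(fp, gi("chr1", 95, 120)))   # fully contained
  expect_false(recapitulated(fp, gi("chr1", 500, 520))) # disjoint
  expect_false(recapitulated(fp, gi("chr2", 95, 120)))  # other chromosome
  # 20 bp footprint vs 20 bp site, overlap swept one base at a time
  fp20 <- gi("chr1", 100, 120)
  ov <- function(k) recapitulated(fp20, gi("chr1", 120 - k, 140 - k))
  expect_false(ov(13)) # 65%
  expect_true(ov(14))  # 70%
  # asymmetric containment: either direction suffices
  small <- gi("chr1", 100, 110)
  big <- gi("chr1", 98, 138)
  expect_true(recapitulated(small, big))
  expect_true(recapitulated(big, small)) # 10/40 = 25% of big, 100% of small
  expect_false(recapitulated(gi("chr1", 100, 140), gi("chr1", 130, 170)))
})

test_that("recapitulation_rate counts sites with a recapitulating footprint", {
  sites <- gi("chr1", c(100, 300, 500), c(120, 320, 520))
  expect_equal(recapitulation_rate(sites, sites)$rate, 1.0)
  none <- recapitulation_rate(sites[0, ], sites)
  expect_equal(none$rate, 0.0)
  expect_equal(none$footprint_bp, 0L)
  two <- recapitulation_rate(gi("chr1", c(100, 302), c(120, 318)), sites)
  expect_equal(two$rate, 2 / 3)
  expect_equal(two$n_recapitulated, 2L)
  expect_equal(two$footprint_bp, 36L)
  expect_error(recapitulation_rate(sites, sites[0, ]), "undefined")
})

test_that("roc_auc equals the normalised Mann-Whitney U statistic", {
  perfect <- tibble::tibble(bound = rep(c(TRUE, FALSE), each = 4),
                            score = c(-30, -25, -20, -15, -4, -3, -2, -1))
  expect_equal(roc_auc(perfect)$auc, 1.0)
  flat <- tibble::tibble(bound = rep(c(TRUE, FALSE), each = 4), score = -5)
  expect_equal(roc_auc(flat)$auc, 0.5)
  # rank-sum oracle on random scored site sets (with ties)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n1 <- sample(2:10, 1)
      n2 <- sample(2:10, 1)
      sc <- -sample(0:15, n1 + n2, replace = TRUE)
      sites <- tibble::tibble(bound = rep(c(TRUE, FALSE), c(n1, n2)),
                              score = sc)
    })
    u <- unname(suppressWarnings(
      stats::wilcox.test(-sc[sites$bound], -sc[!sites$bound])$statistic))
    # mid-rank U counts ties as 1/2, matching trapezoidal ROC integration
    expect_equal(roc_auc(sites)$auc, u / (n1 * n2), tolerance = 1e-12)
    curve <- tidy(roc_auc(sites))
    expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
  }
  expect_error(roc_auc(tibble::tibble(bound = TRUE, score = -1)),
               "bound and one unbound")
})

test_that("positive predictive value counts ChIP-confirmed predictions", {
  bound <- gi("chr1", c(0, 100, 200), c(20, 120, 220))
  unbound <- gi("chr1", c(400, 600), c(420, 620))
  expect_equal(positive_predictive_value(bound, bound, unbound)$ppv, 1.0)
  expect_equal(positive_predictive_value(unbound, bound, unbound)$ppv, 0.0)
  mix <- dplyr::bind_rows(bound, unbound[1, ])
  expect_equal(positive_predictive_value(mix, bound, unbound)$ppv, 0.75)
  expect_error(positive_predictive_value(bound[0, ], bound, unbound),
               "undefined")
  expect_error(positive_predictive_value(gi("chr9", 0, 5), bound, unbound),
               "known")
})

test_that("nucleotide performance is TP/(TP+FP+FN) at base resolution", {
  a <- gi("chr1", c(0, 100), c(50, 150))
  expect_equal(nucleotide_performance(a, a)$coefficient, 1.0)
  expect_equal(nucleotide_performance(a, gi("chr1", 500, 550))$coefficient, 0)
  half <- nucleotide_performance(gi("chr1", 0, 50), gi("chr1", 25, 75))
  expect_equal(half$coefficient, 25 / 75)
  expect_equal(c(half$tp, half$fp, half$fn), c(25L, 25L, 25L))
  # invariant under splitting intervals into adjacent pieces
  split <- gi("chr1", c(0, 10, 100, 130), c(10, 50, 130, 150))
  truth <- gi("chr1", 20, 140)
  expect_equal(nucleotide_performance(a, truth),
               nucleotide_performance(split, truth))
  expect_error(nucleotide_performance(a[0, ], a[0, ]), "undefined")
})

test_that("mean_signal_profile averages, mirrors and skips gaps", {
  # constant track
  track <- tibble::tibble(chrom = "chr1", pos = 0:99, score = 3.5)
  out <- mean_signal_profile(track, gi("chr1", 40, 50), flank = 5)
  expect_equal(out$mean, rep(3.5, 11))
  expect_equal(out$offset, -5:5)
  # single unstranded interval: the raw slice around the midpoint (45)
  ramp <- tibble::tibble(chrom = "chr1", pos = 0:99, score = as.numeric(0:99))
  out2 <- mean_signal_profile(ramp, gi("chr1", 40, 50), flank = 2)
  expect_equal(out2$mean, c(43, 44, 45, 46, 47))
  # a -strand interval is mirrored: hand-checked 5-value toy track
  out3 <- mean_signal_profile(ramp, gi("chr1", 40, 50, strand = "-"),
                              flank = 2)
  expect_equal(out3$mean, c(47, 46, 45, 44, 43))
  # gaps are excluded from the mean, not zero-filled
  gappy <- ramp[ramp$pos != 44, ]
  out4 <- mean_signal_profile(gappy, gi("chr1", c(40, 60), c(50, 70)),
                              flank = 2)
  expect_equal(out4$n[out4$offset == -1], 1L)
  expect_equal(out4$mean[out4$offset == -1], 64) # only the second interval
  # bedGraph-style spans are accepted too
  bg <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L, score = 2)
  out5 <- mean_signal_profile(bg, gi("chr1", 40, 50), flank = 3)
  expect_equal(out5$mean, rep(2, 7))
  expect_error(mean_signal_profile(track, gi("chr1", 1, 2)[0, ], 5), "empty")
})

test_that("motif_content reports per-offset coverage fractions", {
  fps <- gi("chr1", c(100, 200), c(120, 220)) # midpoints 110, 210
  full <- gi("chr1", c(90, 190), c(130, 230))
  out <- motif_content(fps, full, flank = 10)
  expect_equal(out$fraction, rep(1, 21))
  none <- motif_content(fps, full[0, ], flank = 10)
  expect_equal(none$fraction, rep(0, 21))
  half <- motif_content(fps, gi("chr1", 110, 111), flank = 2)
  expect_equal(half$fraction[half$offset == 0], 0.5)
  expect_error(motif_content(fps[0, ], full, 5), "empty")
})

test_that("site_scores takes the minimum log10p over each site", {
  prof <- random_profile(5, len = 200)
  tr <- score_interval(prof, length_grid(11, 15, 2, sh = 25))
  sites <- gi("chrR", c(1050, 1100, 5000), c(1070, 1130, 5010))
  scored <- site_scores(tr, sites)
  for (i in 1:2) {
    sel <- tr$pos >= sites$start[i] & tr$pos < sites$end[i]
    expect_equal(scored$score[i], min(tr$log10p[sel], 0))
  }
  expect_equal(scored$score[3], 0) # off-track site: no evidence
})
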