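test_that("binom_lower_tail matches brute-force pmf summation", {
  expect_equal(binom_lower_tail(0, 0, 0.3), 1.0)
  expect_equal(binom_lower_tail(0, 10, 0.5), 2^-10)
  expect_equal(binom_lower_tail(2, 10, 0.2), oracle_binom_cdf(2, 10, 0.2),
               tolerance = 1e-12)
  for (p in c(0.1, 16 / 51, 0.5, 0.9)) {
    for (n in c(1, 7, 25, 60)) {
      got <- binom_lower_tail(0:n, n, p)
      want <- vapply(0:n, oracle_binom_cdf, numeric(1), n = n, p = p)
      expect_lt(max(abs(got - want) / want), 1e-10)
    }
  }
  expect_error(binom_lower_tail(5, 3, 0.5), "k <= n")
  expect_error(binom_lower_tail(1, 3, 1.5), "\\[0, 1\\]")
})

test_that("footprint_pvalue follows the two-strand product formula", {
  # no reads anywhere: no evidence, p = 1 in every mode
  none <- shouldered_counts(0, 0, 0, 0, l_fp = 16, l_sh = 35,
                            sh_up_minus = 0, sh_down_plus = 0)
  for (m in c("forward", "reverse", "one_d")) {
    expect_equal(footprint_pvalue(none, mode = m), 1.0)
  }
  # empty footprint against full shoulders: closed form (1-p)^n per strand
  cc <- shouldered_counts(0, 50, 0, 50, l_fp = 16, l_sh = 35)
  expect_equal(footprint_pvalue(cc), (35 / 51)^100, tolerance = 1e-12)
  expect_equal(footprint_pvalue(cc, log10 = TRUE), 100 * log10(35 / 51),
               tolerance = 1e-12)
  # general case against the pmf-summation oracle
  cc2 <- shouldered_counts(2, 40, 1, 38, l_fp = 16, l_sh = 35)
  pr <- 16 / 51
  expect_equal(footprint_pvalue(cc2),
               oracle_binom_cdf(2, 42, pr) * oracle_binom_cdf(1, 39, pr),
               tolerance = 1e-12)
})

test_that("p-values respond monotonically to footprint depletion", {
  # raising FP+ with FP+ + SH+ fixed weakens the evidence
  p_of <- function(fp_plus) {
    footprint_pvalue(shouldered_counts(fp_plus, 40 - fp_plus, 1, 38,
                                       l_fp = 16, l_sh = 35))
  }
  ps <- vapply(0:40, p_of, numeric(1))
  expect_true(all(diff(ps) >= 0))
  # shrinking footprint counts toward 0 with shoulders fixed strengthens it
  p_shrink <- vapply(5:0, function(k) {
    footprint_pvalue(shouldered_counts(k, 40, k, 38, l_fp = 16, l_sh = 35))
  }, numeric(1))
  expect_true(all(diff(p_shrink) <= 0))
  expect_true(all(p_shrink > 0 & p_shrink <= 1))
})

test_that("counts_at sums the footprint and shoulder windows", {
  prof <- cut_profile("chr1", 0, plus = rep(1L, 100), minus = rep(0L, 100))
  cc <- counts_at(prof, centre = 50, l_fp = 10, l_sh = 35)
  expect_equal(cc$fp_plus, 10L)
  expect_equal(cc$sh_plus, 35L)
  expect_equal(cc$fp_minus, 0L)
  expect_equal(cc$sh_minus, 0L)
  zero <- cut_profile("chr1", 0, plus = integer(100), minus = integer(100))
  cz <- counts_at(zero, 50, 10, 35)
  expect_equal(cz$fp_plus + cz$sh_plus + cz$fp_minus + cz$sh_minus, 0L)
  single <- cut_profile("chr1", 0, plus = replace(integer(100), 51, 1L),
                        minus = integer(100))
  cs <- counts_at(single, 50, 10, 35)
  expect_equal(cs$fp_plus, 1L)
  expect_equal(cs$sh_plus + cs$fp_minus + cs$sh_minus, 0L)
  expect_error(counts_at(prof, 5, 10, 35), "out of profile bounds")
})

test_that("score_interval agrees with per-centre counts_at + footprint_pvalue", {
  prof <- random_profile(11, len = 120)
  grid <- length_grid(12, 18, 3, sh = c(20, 30))
  for (mode in c("forward", "reverse", "one_d")) {
    tr <- score_interval(prof, grid, mode = mode)
    # recompute a handful of centres by brute force over the grid
    base <- if (mode == "reverse") swap_strands(prof) else prof
    for (centre in c(1040L, 1060L, 1075L)) {
      combos <- expand.grid(l_fp = grid$fp_lengths, l_sh = grid$sh_values)
      ps <- vapply(seq_len(nrow(combos)), function(i) {
        cc <- tryCatch(
          counts_at(base, centre, combos$l_fp[i], combos$l_sh[i]),
          error = function(e) NULL)
        if (is.null(cc)) return(0)
        footprint_pvalue(cc, mode = if (mode == "one_d") "one_d" else "forward",
                         log10 = TRUE)
      }, numeric(1))
      expect_equal(tr$log10p[tr$pos == centre], min(ps, 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("forward/reverse duality and 1D strand-swap invariance hold", {
  for (seed in 1:25) {
    prof <- random_profile(seed)
    swapped <- swap_strands(prof)
    fwd_sw <- score_interval(swapped)
    rev <- score_interval(prof, mode = "reverse")
    expect_equal(rev$log10p, fwd_sw$log10p)
    expect_equal(rev$best_lfp, fwd_sw$best_lfp)
    one <- score_interval(prof, mode = "one_d")
    one_sw <- score_interval(swapped, mode = "one_d")
    expect_equal(one$log10p, one_sw$log10p)
    expect_true(all(one$log10p <= 0) && all(is.finite(one$log10p)))
  }
})

test_that("degenerate profiles produce zero tracks", {
  zero <- cut_profile("chr1", 0, plus = integer(200), minus = integer(200))
  tr <- score_interval(zero)
  expect_true(all(tr$log10p == 0))
  short <- cut_profile("chr1", 0, plus = rep(1L, 30), minus = rep(1L, 30))
  expect_warning(tr2 <- score_interval(short), "does not fit")
  expect_true(all(tr2$log10p == 0))
})

test_that("the strongest score lands inside a planted footprint", {
  d <- simulate_dhs(simulation_spec(n_footprints = 1, seed = 3))
  tr <- score_interval(d$profile)
  top <- tr$pos[which.min(tr$log10p)]
  expect_gte(top, d$truth$start)
  expect_lt(top, d$truth$end)
  # edge bases whose windows cannot fit score exactly 0
  expect_true(all(tr$log10p[1:10] == 0))
})
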