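test_that("pulse extraction finds rectangular bumps with hysteresis", {
  tr <- synthetic_trace(data.frame(syllable = "BA", onset = 1.0,
                                   width = 0.08))
  p <- extract_pulses(tr$mat, tr$time)
  expect_equal(nrow(p), 1L)
  expect_equal(p$syllable, "BA")
  expect_equal(p$n_peaks, 1L)
  expect_equal(p$shape, "normal")
  expect_equal(p$onset, 1.0, tolerance = 2e-3)
  expect_equal(p$offset - p$onset, 0.08, tolerance = 2e-3)
})

test_that("close same-syllable peaks merge into one multi-peak event", {
  tr <- synthetic_trace(data.frame(syllable = c("DA", "DA"),
                                   onset = c(1.0, 1.1), width = 0.04))
  p <- extract_pulses(tr$mat, tr$time)   # peaks 60 ms apart edge-to-edge
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_peaks, 2L)
  expect_equal(p$shape, "oscillatory")
  # beyond the merge window they stay separate events
  tr2 <- synthetic_trace(data.frame(syllable = c("DA", "DA"),
                                    onset = c(1.0, 1.3), width = 0.04))
  p2 <- extract_pulses(tr2$mat, tr2$time)
  expect_equal(nrow(p2), 2L)
  expect_true(all(p2$n_peaks == 1L))
})

test_that("a flat trace yields no pulses", {
  tr <- synthetic_trace(data.frame(syllable = character(), onset = numeric(),
                                   width = numeric()))
  expect_equal(nrow(extract_pulses(tr$mat, tr$time)), 0L)
})

test_that("sub-threshold activity is ignored", {
  tr <- synthetic_trace(data.frame(syllable = "GA", onset = 1, width = 0.1,
                                   peak = 0.6))
  expect_equal(nrow(extract_pulses(tr$mat, tr$time)), 0L)
})

test_that("correct-count follows the cyclic-successor rule", {
  expect_equal(count_correct(c("BA", "DA", "GA")), 3L)
  expect_equal(count_correct(c("BA", "DA", "DA", "GA")), 3L)
  expect_equal(count_correct(c("DA", "GA")), 1L)
  expect_equal(count_correct(character(0)), 0L)
  expect_equal(count_correct(rep(syllables(), 3)), 18L)
  # first pulse must be BA to count
  expect_equal(count_correct("BA"), 1L)
  expect_equal(count_correct("TA"), 0L)
})

test_that("correct-count is order-determined and monotone under deletion", {
  set.seed(20)
  for (k in 1:25) {
    syl <- sample(syllables(), sample(3:12, 1), replace = TRUE)
    n0 <- count_correct(syl)
    # invariant under onset-time shifts: counting uses only the order,
    # so the pulse data.frame representation must agree with the label one
    p <- pulse_df(syl, onset = sort(runif(length(syl), 0, 5)))
    expect_equal(count_correct(p), n0)
    # deleting one pulse removes at most its own contribution and can
    # create at most one new adjacency, so the count changes by at most +1
    # (removing an out-of-order intruder can reconnect the cycle)
    for (i in seq_along(syl)) {
      expect_lte(count_correct(syl[-i]), n0 + 1L)
    }
    # appending a pulse never affects the already-counted prefix
    expect_gte(count_correct(c(syl, sample(syllables(), 1))), n0)
  }
})

test_that("scripted error trials are classified exactly", {
  dur <- 5.5
  # perfect trial: 18 pulses, no errors
  perfect <- pulse_df(rep(syllables(), 3), onset = 0.7 + 0.28 * 0:17)
  expect_equal(classify_errors(perfect, dur), character(0))
  # repetition: DA twice in a row, cycle otherwise intact
  rep_syl <- c("BA", "DA", "DA", "GA", "PA", "TA", "KA",
               rep(syllables(), 2)[1:11])
  rep_tr <- pulse_df(rep_syl, onset = 0.7 + 0.28 * seq_along(rep_syl))
  expect_true("repetition" %in% classify_errors(rep_tr, dur))
  expect_false("skipping" %in% classify_errors(rep_tr, dur))
  # skipping: GA -> TA violates the cycle without repeating
  skip_tr <- pulse_df(c("BA", "DA", "GA", "TA", "KA", rep(syllables(), 2),
                        "BA"), onset = 0.7 + 0.27 * 0:17)
  expect_true("skipping" %in% classify_errors(skip_tr, dur))
  # restart: a long silent break with pulses after it
  restart_tr <- pulse_df(c("BA", "DA", "GA", "PA", "TA", "KA", "BA", "DA"),
                         onset = c(0.7 + 0.28 * 0:5, 3.4, 3.68))
  expect_true("restart" %in% classify_errors(restart_tr, dur))
  expect_true("halting" %in% classify_errors(restart_tr, dur))
  # halting: sequence stops well before the trial end
  halt_tr <- pulse_df(c("BA", "DA", "GA"), onset = c(0.7, 0.98, 1.26))
  expect_equal(classify_errors(halt_tr, dur), "halting")
  # a trial with no pulses at all halts trivially
  expect_equal(classify_errors(perfect[0, ], dur), "halting")
})

test_that("pulse shapes split into normal, oscillatory and broad", {
  expect_equal(classify_shape(list(n_peaks = 3, width = 0.04)), "oscillatory")
  expect_equal(classify_shape(list(n_peaks = 2, width = 0.3)), "oscillatory")
  expect_equal(classify_shape(list(n_peaks = 1, width = 0.25)), "broad")
  expect_equal(classify_shape(list(n_peaks = 1, width = 0.08)), "normal")
})

test_that("region codes partition 0..90 with the table boundaries", {
  r <- region_code(0:90)
  expect_true(all(r %in% 1:6))
  expect_equal(region_code(90), 1L)
  expect_equal(region_code(75), 1L)
  expect_equal(region_code(74), 2L)
  expect_equal(region_code(61), 2L)
  expect_equal(region_code(60), 3L)
  expect_equal(region_code(45), 3L)
  expect_equal(region_code(44), 4L)
  expect_equal(region_code(31), 4L)
  expect_equal(region_code(30), 5L)
  expect_equal(region_code(15), 5L)
  expect_equal(region_code(14), 6L)
  expect_equal(region_code(0), 6L)
  # every integer maps to exactly one region, monotonically
  expect_true(all(diff(r) <= 0))
  expect_error(region_code(91), "out of range")
  expect_error(region_code(-1), "out of range")
})

test_that("stability classes follow the region-edge thresholds", {
  expect_equal(stability_class(90), "stable")
  expect_equal(stability_class(75), "stable")
  expect_equal(stability_class(74), "mild")
  expect_equal(stability_class(56), "mild")
  expect_equal(stability_class(46), "mild")
  expect_equal(stability_class(45), "severe")
  expect_equal(stability_class(17), "severe")
})

test_that("one-sided pooled t test matches the closed form and stats::t.test", {
  a <- c(18, 18, 18, 18, 18); b <- c(1, 1, 1, 1, 1)
  same <- one_sided_t_test(a, a)
  expect_true(same$degenerate)
  r <- one_sided_t_test(c(18, 17, 18, 18, 19), b)
  # independent oracle: stats::t.test with pooled variance
  ref <- t.test(c(18, 17, 18, 18, 19), b, var.equal = TRUE,
                alternative = "greater")
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  expect_lt(r$p, 0.001)
  # hand-computed closed form for fixed integers: a = (3,4,5), b = (1,2,3)
  # mean diff 2, pooled var 1, t = 2 / sqrt(1 * 2/3) = sqrt(6)
  h <- one_sided_t_test(c(3, 4, 5), c(1, 2, 3))
  expect_equal(h$t, sqrt(6), tolerance = 1e-9)
  # near-equal means: t ~ 0, p ~ 0.5
  r2 <- one_sided_t_test(a, c(17, 18, 18, 18, 19))
  expect_equal(r2$t, 0, tolerance = 1e-9)
  expect_equal(r2$p, 0.5, tolerance = 1e-2)
  # zero variance, unequal means
  r3 <- one_sided_t_test(a, b)
  expect_equal(r3$t, Inf)
  expect_equal(r3$p, 0)
})

test_that("sweep aggregation sums, averages and labels cells", {
  res <- data.frame(dopamine = rep(c(0.2, 0.16), each = 5),
                    weight = 1.0,
                    trial = rep(1:5, 2),
                    n_correct = c(rep(18L, 5), c(5L, 6L, 5L, 6L, 5L)))
  tab <- aggregate_sweep(res)
  r1 <- tab[tab$dopamine == 0.2, ]
  expect_equal(r1$sum, 90)
  expect_equal(r1$mean, 18)
  expect_equal(r1$variance, 0)
  expect_equal(r1$region, 1L)
  expect_equal(r1$stability, "stable")
  r2 <- tab[tab$dopamine == 0.16, ]
  expect_equal(r2$sum, 27)
  expect_equal(r2$mean, 5.4)
  expect_equal(r2$variance, var(c(5, 6, 5, 6, 5)))
  expect_equal(r2$region, 5L)
  expect_equal(r2$stability, "severe")
  expect_error(aggregate_sweep(res[-1, ]), "expected 5")
})
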