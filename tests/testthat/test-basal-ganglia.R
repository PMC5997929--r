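test_that("parameter ranges are enforced", {
  expect_error(bg_params(lg = 0.3), "lg")
  expect_error(bg_params(le = -0.1), "le")
  expect_error(bg_params(wt = 1.2), "wt")
  expect_error(bg_params(wp = 0.95), "wp")
  p <- bg_params(lg = 0.1, wt = 0.5, wp = 0.3)
  expect_s3_class(p, "syllseq_bg_params")
})

test_that("ramp output function matches its closed form", {
  expect_equal(ramp(0.1, 0.2), 0)
  expect_equal(ramp(0.2, 0.2), 0)
  expect_equal(ramp(1, 0.2), 0.8)
  expect_equal(ramp(1, -0.25, m = 2), 2.5)
  x <- seq(-1, 2, by = 0.01)
  expect_true(all(diff(ramp(x, 0.3)) >= 0))
})

test_that("utilities are weighted condition dot products, clipped at zero", {
  vocab <- create_vocabulary(seed = 1)
  rules <- action_rules()
  states <- list(visual = pointer(vocab, "BA"),
                 phonemic = numeric(32),
                 somatosensory = numeric(32))
  u <- compute_utilities(states, rules, vocab)
  expect_equal(length(u), 14L)
  expect_equal(unname(u["start"]), 1.0, tolerance = 1e-9)
  expect_true(all(u >= 0))
  # zero states give zero utilities
  z <- compute_utilities(list(visual = numeric(32), phonemic = numeric(32),
                              somatosensory = numeric(32)), rules, vocab)
  expect_equal(unname(z), rep(0, 14))
  # linear in the state
  states$visual <- 0.5 * pointer(vocab, "BA")
  expect_equal(unname(compute_utilities(states, rules, vocab)["start"]),
               0.5, tolerance = 1e-9)
  expect_error(compute_utilities(list(visual = numeric(32)), rules, vocab),
               "missing buffer")
})

test_that("the rate oracle converges to the selection fixed point", {
  # zero utilities: all outputs at the same positive tonic level
  or0 <- steady_state_selection(rep(0, 14))
  expect_true(or0$converged)
  expect_true(all(or0$gpi > 0))
  expect_lt(diff(range(or0$gpi)), 1e-9)
  # equal utilities: symmetric equilibrium, no unique minimum
  ore <- steady_state_selection(rep(0.5, 5))
  expect_true(ore$converged)
  expect_lt(diff(range(ore$gpi)), 1e-9)
  # clear margin: winner is the unique minimum of the combined output
  orm <- steady_state_selection(c(0.8, 0.3, 0.3))
  tot <- orm$gpi + orm$snr
  expect_equal(which.min(tot), 1L)
  expect_true(all(tot[-1] > tot[1] + 0.1))
})

test_that("a dominant sparse utility drives the winner's output exactly to zero", {
  set.seed(101)
  for (k in 1:20) {
    u <- runif(13, 0, 0.15)
    w <- sample(14, 1)
    u <- append(u, runif(1, 1.0, 1.5), after = w - 1)
    or <- steady_state_selection(u)
    expect_true(or$converged)
    expect_equal(or$gpi[w] + or$snr[w], 0)
    expect_true(all((or$gpi + or$snr)[-w] > 0))
  }
})

test_that("required selection margin grows as dopamine is depleted", {
  # minimal utility margin (winner 0.7 + m vs competitor 0.7) at which the
  # winner's thalamic drive clears the gate, per dopamine level
  min_margin <- vapply(seq(0.20, 0.10, by = -0.02), function(lg) {
    for (m in seq(0, 0.6, by = 0.02)) {
      u <- c(0.7 + m, 0.7, rep(0, 10))
      or <- steady_state_selection(u, bg_params(lg = lg, le = lg))
      drive <- 1 - 1.5 * (or$gpi + or$snr)
      if (drive[1] > 0.22 && all(drive[-1] < 0.22)) return(m)
    }
    0.62  # no margin in the grid suffices at this dopamine level
  }, numeric(1))
  expect_true(all(diff(min_margin) >= 0))
  expect_gt(min_margin[length(min_margin)], min_margin[1])
  expect_lt(min_margin[1], 0.62)  # healthy dopamine: finite margin works
})

test_that("spiking circuit agrees with the rate oracle at late times", {
  set.seed(7)
  for (k in 1:3) {
    n <- sample(8:14, 1)
    u <- round(runif(n, 0, 0.6), 2)
    w <- sample(n, 1)
    u[w] <- max(u) + runif(1, 0.1, 0.5)
    or <- steady_state_selection(u)
    sp <- spiking_bg(u, seed = k)
    expect_lt(max(abs(sp$gpi - or$gpi)), 0.15)
    expect_equal(which.min(sp$gpi + sp$snr), w)
  }
})

test_that("thalamus disinhibits exactly one channel for clear margins", {
  for (s in 1:3) {
    u <- c(0.8, 0.7, rep(0, 10))  # margin 0.1 between active channels
    sp <- spiking_bg(u, seed = s + 10)
    act <- sum(sp$gate > 0.5 * max(sp$gate))
    expect_equal(act, 1L)
    expect_equal(which.max(sp$gate), 1L)
  }
  # all channels inhibited: no gate opens without utility
  sp0 <- spiking_bg(rep(0, 14), seed = 21)
  expect_lt(max(sp0$gate), 0.1)
})

test_that("selection latency is within the 15-40 ms band for clear margins", {
  lat <- vapply(1:3, function(s) {
    selection_latency(c(0.8, 0.3, 0.3, rep(0, 11)), seed = s)
  }, numeric(1))
  expect_true(all(lat >= 0.015 & lat <= 0.040))
})

test_that("zeroed STN afferents silence the STN", {
  u <- c(0.8, 0.3, 0.3, rep(0, 11))
  p0 <- bg_params(wt = 0)
  net <- nef_network(seed = 3)
  bg <- add_bg(net, length(u), p0)
  for (ch in seq_along(u)) {
    set_ext_input(net, bg$ens[ch, "str_d1"], u[ch] * (1 + p0$lg))
    set_ext_input(net, bg$ens[ch, "str_d2"], u[ch] * (1 - p0$le))
    set_ext_input(net, bg$ens[ch, "stn"], u[ch] * p0$wt)
    add_probe(net, bg$out[ch, "stn"], paste0("stn.", ch))
  }
  sim <- simulate(net, 0.3)
  # with wt = 0 the only STN drive is its tonic ramp offset minus GPe
  # inhibition; cortical input contributes nothing
  or <- steady_state_selection(u, p0)
  stn <- colMeans(sim$probes[250:300, , drop = FALSE])
  expect_lt(max(abs(stn - or$stn)), 0.15)
})
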