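test_that("the task network has six 1600-neuron buffers and 14 channels", {
  cfg <- trial_config()
  vocab <- create_vocabulary(seed = 1)
  model <- build_model(cfg, vocab)
  expect_equal(length(model$buffers), 6L)
  for (b in names(model$buffers)) {
    expect_equal(n_neurons(model$net, paste0(b, ".")), 1600L)
  }
  expect_equal(model$bg$n_channels, 14L)
  expect_equal(length(model$rules), 14L)
  # one BG ensemble per population per channel, 50 neurons each
  expect_equal(n_neurons(model$net, "bg."), 14L * 6L * 50L)
  expect_equal(n_neurons(model$net, "thal."), 14L * 50L)
})

test_that("a vocabulary missing task pointers is rejected", {
  cfg <- trial_config()
  small <- create_vocabulary(names = c("BA", "DA"), seed = 1)
  expect_error(build_model(cfg, small), "lacks pointers")
})

test_that("visual protocol: silence, then BA cue, then ZERO", {
  cfg <- trial_config()
  vocab <- create_vocabulary(seed = 1)
  expect_equal(visual_schedule(0.1, cfg, vocab), numeric(32))
  expect_equal(visual_schedule(0.6, cfg, vocab), pointer(vocab, "BA"))
  expect_equal(visual_schedule(3.0, cfg, vocab), pointer(vocab, "ZERO"))
  expect_equal(visual_schedule(0.7, cfg, vocab), pointer(vocab, "ZERO"))
})

test_that("motor execution feeds back delayed somatosensory pulses in order", {
  # scripted motor trace: drive the motor buffer externally with BA_EXEC
  # then DA_EXEC; the somatosensory buffer must echo each 200 ms later
  cfg <- trial_config(duration = 1.2)
  vocab <- create_vocabulary(seed = 3)
  model <- build_model(cfg, vocab)
  net <- model$net
  net$mexec$arm_from <- 0        # script starts early
  ba <- pointer(vocab, "BA_EXEC")
  da <- pointer(vocab, "DA_EXEC")
  for (k in 1:32) {
    local({
      kk <- k
      set_ext_input(net, model$buffers$motor$ens[kk], function(t) {
        if (t >= 0.15 && t < 0.25) 1.3 * ba[kk]
        else if (t >= 0.5 && t < 0.6) 1.3 * da[kk]
        else 0
      })
    })
  }
  sim <- simulate(net, cfg$duration)
  trg <- sim$triggers
  expect_equal(trg$syllable[1:2], c("BA", "DA"))
  som <- buffer_similarity(sim, "somatosensory", vocab)
  t_ba <- sim$time[which(som[, "BA_EXEC"] > 0.5)[1]]
  t_da <- sim$time[which(som[, "DA_EXEC"] > 0.5)[1]]
  # feedback onset = trigger + 200 ms articulation delay + neural rise time
  expect_gt(t_ba, trg$time[1] + 0.200)
  expect_lt(t_ba, trg$time[1] + 0.230)
  expect_gt(t_da, trg$time[2] + 0.200)
  expect_lt(t_da, trg$time[2] + 0.230)
  expect_lt(t_ba, t_da)
  # no spurious feedback for unseen syllables
  expect_lt(max(som[, "GA_EXEC"]), 0.45)
})

test_that("a short healthy trial sequences syllables in task order", {
  cfg <- trial_config(duration = 2.6, vocab_seed = 1, net_seed = 1)
  trace <- run_trial(cfg)
  res <- analyze_trial(trace)
  n <- res$n_pulses
  expect_gte(n, 5L)
  expect_equal(res$pulses$syllable[1:5], c("BA", "DA", "GA", "PA", "TA"))
  expect_equal(res$n_correct, n)
  # all healthy pulses are slim single peaks
  expect_true(all(res$pulses$shape == "normal"))
  expect_true(all(res$pulses$width <= 0.15))
  # syllable period and loop decomposition
  per <- onset_intervals(res)
  expect_true(mean(per) >= 0.260 && mean(per) <= 0.310)
  lp <- loop_times(trace, res)
  expect_true(mean(lp) >= 0.060 && mean(lp) <= 0.110)
})

test_that("trial simulation is reproducible under its seeds", {
  cfg <- trial_config(duration = 1.0, vocab_seed = 7, net_seed = 7)
  a <- run_trial(cfg)
  b <- run_trial(cfg)
  expect_identical(a$similarity$motor, b$similarity$motor)
  expect_identical(a$triggers, b$triggers)
})
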