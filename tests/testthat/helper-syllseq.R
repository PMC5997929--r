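# Shared fixtures. Heavy simulations (full 5.5 s trials) are cached in this
# environment so the acceptance tests reuse the same baseline runs.

.syllseq_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .syllseq_cache)) {
    assign(key, force(expr), .syllseq_cache)
  }
  get(key, .syllseq_cache)
}

# Five seeded 5.5 s trials at the given parameters; returns list of
# list(trace, result) pairs.
run_condition <- function(lg, wt = 1.0, wp = 0.9, seeds = 1:5) {
  key <- sprintf("cond_%g_%g_%g_%s", lg, wt, wp, paste(seeds, collapse = "_"))
  cached(key, lapply(seeds, function(s) {
    cfg <- trial_config(params = bg_params(lg = lg, le = lg,
                                           wt = wt, wp = wp),
                        vocab_seed = s, net_seed = s)
    trace <- run_trial(cfg)
    list(trace = trace, result = analyze_trial(trace))
  }))
}

baseline_trials <- function() run_condition(0.20)

correct_counts <- function(trials) {
  vapply(trials, function(x) x$result$n_correct, integer(1))
}

# Synthetic motor-similarity trace builder for analysis tests: `events` is a
# data.frame with columns syllable, onset, width (s), and optional peak.
synthetic_trace <- function(events, duration = 5.5, dt = 0.001) {
  time <- seq(0, duration - dt, by = dt)
  m <- matrix(0, nrow = length(time), ncol = 6,
              dimnames = list(NULL, paste0(syllables(), "_EXEC")))
  for (i in seq_len(nrow(events))) {
    peak <- if ("peak" %in% names(events)) events$peak[i] else 1
    j <- match(paste0(events$syllable[i], "_EXEC"), colnames(m))
    on <- time >= events$onset[i] & time < events$onset[i] + events$width[i]
    m[on, j] <- pmax(m[on, j], peak)
  }
  list(mat = m, time = time)
}

# pulse data.frame shaped like extract_pulses output
pulse_df <- function(syllable, onset, width = 0.08, n_peaks = 1) {
  data.frame(syllable = syllable, onset = onset, offset = onset + width,
             n_peaks = n_peaks, width = width, span = width,
             shape = "normal")
}

# constant-utility spiking BG + thalamus run (micro-benchmark)
spiking_bg <- function(u, seed, params = bg_params(), duration = 0.3) {
  net <- nef_network(seed = seed)
  bg <- add_bg(net, length(u), params)
  thal <- add_thalamus(net, bg)
  for (ch in seq_along(u)) {
    set_ext_input(net, bg$ens[ch, "str_d1"],
                  u[ch] * params$ws * (1 + params$lg))
    set_ext_input(net, bg$ens[ch, "str_d2"],
                  u[ch] * params$ws * (1 - params$le))
    set_ext_input(net, bg$ens[ch, "stn"], u[ch] * params$wt)
    add_probe(net, bg$out[ch, "gpi"], paste0("gpi.", ch))
    add_probe(net, bg$out[ch, "snr"], paste0("snr.", ch))
    add_probe(net, thal$sig[ch], paste0("gate.", ch))
  }
  sim <- simulate(net, duration, ext_tau = 0.002)
  late <- sim$time >= duration - 0.05
  list(gpi = unname(colMeans(sim$probes[late, paste0("gpi.", seq_along(u)),
                                        drop = FALSE])),
       snr = unname(colMeans(sim$probes[late, paste0("snr.", seq_along(u)),
                                        drop = FALSE])),
       gate = unname(colMeans(sim$probes[late, paste0("gate.",
                                                      seq_along(u)),
                                         drop = FALSE])),
       sim = sim)
}
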