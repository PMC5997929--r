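# Timing decomposition of the sequencing loop: onset intervals, the
# somatosensory-to-motor loop time, buffer-to-buffer transfer latency, and
# BG selection latency micro-benchmarks.

#' Onset-to-onset intervals between consecutive correct motor pulses
#'
#' @param result A `syllseq_trial_result` from [analyze_trial()].
#' @return Numeric vector of intervals in seconds between consecutive
#'   pulses that continue the cyclic order (the intervals entering the
#'   per-syllable speed of the task).
#' @export
onset_intervals <- function(result) {
  p <- result$pulses
  if (nrow(p) < 2) return(numeric(0))
  ok <- vapply(2:nrow(p), function(i) {
    p$syllable[i] == next_syllable(p$syllable[i - 1])
  }, logical(1))
  diff(p$onset)[ok]
}

#' Somatosensory-to-motor loop times
#'
#' The cortico-BG-thalamus-cortex loop time: for each motor pulse, the time
#' elapsed since the somatosensory feedback of the *previous* pulse became
#' available (trigger time of the previous pulse plus the articulation
#' delay). The articulation delay itself is excluded, so at the defaults a
#' ~277 ms syllable period decomposes into 200 ms delay + ~77 ms loop.
#'
#' @param trace A `syllseq_trace`.
#' @param result The matching [analyze_trial()] result.
#' @return Numeric vector of loop times in seconds, one per correct
#'   syllable transition.
#' @export
loop_times <- function(trace, result) {
  p <- result$pulses
  trig <- trace$triggers
  if (nrow(p) < 2 || nrow(trig) < 1) return(numeric(0))
  out <- numeric(0)
  for (i in 2:nrow(p)) {
    if (p$syllable[i] != next_syllable(p$syllable[i - 1])) next
    # feedback that caused pulse i: trigger of the previous syllable
    tprev <- trig$time[trig$syllable == p$syllable[i - 1] &
                         trig$time <= p$onset[i] - trace$config$delay]
    if (!length(tprev)) next
    out <- c(out, p$onset[i] - (max(tprev) + trace$config$delay))
  }
  out
}

#' Feedforward pointer-transfer latency between two buffers
#'
#' Builds a two-buffer micro-network, injects a pointer into the source at
#' 0.1 s, and measures the lag between the source holding the pointer and
#' the target holding it: the time between the source's and the target's
#' similarity each first reaching 80 % of the source's settled value.
#'
#' @param seed Network/vocabulary seed.
#' @param tau Feedforward synapse time constant (s).
#' @return Latency in seconds.
#' @export
transfer_latency <- function(seed = 1L, tau = 0.01) {
  vocab <- create_vocabulary(seed = seed)
  net <- nef_network(seed = seed)
  src <- add_buffer(net, "src")
  dst <- add_buffer(net, "dst")
  connect_buffers(net, src, dst, tau = tau)
  probe_buffer(net, src)
  probe_buffer(net, dst)
  p <- pointer(vocab, "BA")
  inject_pointer(net, src, fn = function(t) if (t >= 0.1) p else p * 0)
  sim <- simulate(net, 0.3)
  s_src <- buffer_similarity(sim, "src", vocab)[, "BA"]
  s_dst <- buffer_similarity(sim, "dst", vocab)[, "BA"]
  level <- 0.8 * mean(s_src[sim$time >= 0.25])
  t_src <- sim$time[which(sim$time >= 0.1 & s_src >= level)[1]]
  t_dst <- sim$time[which(sim$time >= 0.1 & s_dst >= level)[1]]
  t_dst - t_src
}

#' Basal ganglia selection latency micro-benchmark
#'
#' Builds a BG-thalamus circuit, lets it settle with zero utilities, then
#' steps a constant utility vector on and measures the time until the
#' winning channel's thalamic gate first exceeds half of its settled
#' (late-time) activation.
#'
#' @param utilities Constant utility vector applied from `t_on`.
#' @param params A [bg_params()].
#' @param seed Network seed.
#' @param t_on Onset time of the utilities (after tonic settling), s.
#' @param duration Total simulation time, s.
#' @return Latency in seconds (NA if the winner never activates).
#' @export
selection_latency <- function(utilities, params = bg_params(), seed = 1L,
                              t_on = 0.3, duration = 0.6) {
  net <- nef_network(seed = seed)
  bg <- add_bg(net, length(utilities), params)
  thal <- add_thalamus(net, bg)
  for (ch in seq_along(utilities)) {
    local({
      cc <- ch
      u <- utilities[cc]
      set_ext_input(net, bg$ens[cc, "str_d1"],
                    function(t) if (t >= t_on) u * params$ws * (1 + params$lg) else 0)
      set_ext_input(net, bg$ens[cc, "str_d2"],
                    function(t) if (t >= t_on) u * params$ws * (1 - params$le) else 0)
      set_ext_input(net, bg$ens[cc, "stn"],
                    function(t) if (t >= t_on) u * params$wt else 0)
    })
    add_probe(net, thal$sig[ch], paste0("gate.", ch))
  }
  sim <- simulate(net, duration, probe_tau = 0.005, ext_tau = 0.002)
  win <- which.max(utilities)
  g <- sim$probes[, paste0("gate.", win)]
  late <- mean(g[sim$time >= duration - 0.1])
  if (late <= 0.05) return(NA_real_)
  hit <- which(sim$time >= t_on & g >= 0.5 * late)[1]
  sim$time[hit] - t_on
}
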