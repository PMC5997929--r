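# Mutable network-under-construction. All randomness (tuning curves, initial
# voltages) is drawn from one seeded stream, so a (seed, builder-calls)
# pair defines the network bit-for-bit.

#' Create an empty spiking network
#'
#' Container for LIF ensembles, decoded signals, filtered connections, probes
#' and external inputs, advanced in fixed steps by [simulate()].
#'
#' @param dt Simulation time step in seconds (default 1 ms).
#' @param seed Integer seed governing all tuning-curve and initial-state
#'   randomness in this network.
#' @return A `syllseq_network` (an environment).
#' @export
nef_network <- function(dt = 0.001, seed = 1L) {
  net <- new.env(parent = emptyenv())
  net$dt <- dt
  net$seed <- as.integer(seed)
  net$rng <- local_rng(seed)
  net$ens <- list()          # ensemble_spec + label + v0
  net$sig_ens <- integer()   # decoded signals: owning ensemble
  net$sig_dec <- list()      #   decoder vectors
  net$sig_key <- character() #   cache key (ens|fn|eps)
  net$fsig_sig <- integer()  # filtered signals: source signal
  net$fsig_tau <- numeric()
  net$con_fsig <- integer()  # connections: filtered signal -> ensemble input
  net$con_dst <- integer()
  net$con_w <- numeric()
  net$probe_sig <- integer()
  net$probe_label <- character()
  net$ext <- list()          # per-ensemble external input time series
  net$mexec <- NULL
  class(net) <- "syllseq_network"
  net
}

#' @export
print.syllseq_network <- function(x, ...) {
  cat("<syllseq_network>", length(x$ens), "ensembles,",
      sum(vapply(x$ens, function(e) e$n_neurons, integer(1))), "neurons,",
      length(x$con_fsig), "connections,", length(x$probe_sig), "probes\n")
  invisible(x)
}

#' Total neurons in a network or in one labelled group
#'
#' @param net A `syllseq_network`.
#' @param label_prefix If given, count only ensembles whose label starts with
#'   this prefix (e.g. one buffer's name).
#' @return Integer neuron count.
#' @export
n_neurons <- function(net, label_prefix = NULL) {
  labs <- vapply(net$ens, function(e) e$label, character(1))
  keep <- if (is.null(label_prefix)) rep(TRUE, length(labs)) else {
    startsWith(labs, label_prefix)
  }
  sum(vapply(net$ens[keep], function(e) e$n_neurons, integer(1)))
}

#' Add a one-dimensional LIF ensemble to a network
#'
#' @param net A [nef_network()].
#' @param label Ensemble label (used in diagnostics and neuron counting).
#' @param n_neurons,radius,intercepts,max_rates,encoders Tuning parameters,
#'   see [ensemble_spec()].
#' @return Integer ensemble id.
#' @export
add_ensemble <- function(net, label, n_neurons = 50L, radius = 1,
                         intercepts = c(-1, 1), max_rates = c(200, 400),
                         encoders = NULL) {
  spec <- ensemble_spec(n_neurons = n_neurons, radius = radius,
                        intercepts = intercepts, max_rates = max_rates,
                        encoders = encoders, rng = net$rng)
  spec$label <- label
  spec$v0 <- net$rng$unif(spec$n_neurons)  # desynchronised start
  net$ens[[length(net$ens) + 1L]] <- spec
  length(net$ens)
}

#' Add (or reuse) a decoded output signal of an ensemble
#'
#' @param net A network.
#' @param ens Ensemble id.
#' @param fn `"identity"`, `"ramp"` (rectified linear above `eps`), or
#'   `"gate"` (a saturating ramp from 0 at `eps` to 1 at `hi`, the
#'   go-signal nonlinearity of thalamic channels).
#' @param eps Ramp threshold / gate foot.
#' @param hi Gate saturation point (gate only).
#' @return Integer signal id.
#' @export
add_decode <- function(net, ens, fn = c("identity", "ramp", "gate"),
                       eps = 0, hi = 1) {
  fn <- match.arg(fn)
  key <- paste(ens, fn, eps, hi, sep = "|")
  hit <- match(key, net$sig_key)
  if (!is.na(hit)) return(hit)
  target <- switch(fn,
    identity = identity,
    ramp = function(x) ramp(x, eps),
    gate = function(x) pmin(1, pmax(0, (x - eps) / (hi - eps))))
  sol <- solve_decoders(net$ens[[ens]], target)
  net$sig_ens <- c(net$sig_ens, ens)
  net$sig_dec[[length(net$sig_dec) + 1L]] <- sol$decoders
  net$sig_key <- c(net$sig_key, key)
  length(net$sig_ens)
}

# filtered-signal lookup/creation (one synapse state per (signal, tau))
fsig_id <- function(net, sig, tau) {
  hit <- which(net$fsig_sig == sig & net$fsig_tau == tau)
  if (length(hit)) return(hit[1L])
  net$fsig_sig <- c(net$fsig_sig, sig)
  net$fsig_tau <- c(net$fsig_tau, tau)
  length(net$fsig_sig)
}

#' Connect a decoded signal to an ensemble's input
#'
#' The signal is filtered by a first-order synapse with time constant `tau`
#' and added to the target ensemble's represented input with the given weight.
#'
#' @param net A network.
#' @param sig Source signal id (from [add_decode()]).
#' @param dst Target ensemble id.
#' @param weight Connection weight (sign sets excitatory/inhibitory).
#' @param tau Synaptic time constant in seconds.
#' @return The network, invisibly.
#' @export
add_connection <- function(net, sig, dst, weight, tau = 0.01) {
  stopifnot(tau > 0)
  f <- fsig_id(net, sig, tau)
  net$con_fsig <- c(net$con_fsig, f)
  net$con_dst <- c(net$con_dst, dst)
  net$con_w <- c(net$con_w, weight)
  invisible(net)
}

#' Probe a decoded signal
#'
#' Probed signals are filtered (10 ms synapse, as for a downstream reader)
#' and recorded at every step.
#'
#' @param net A network.
#' @param sig Signal id.
#' @param label Column label in the simulation output.
#' @return The network, invisibly.
#' @export
add_probe <- function(net, sig, label) {
  net$probe_sig <- c(net$probe_sig, sig)
  net$probe_label <- c(net$probe_label, label)
  invisible(net)
}

#' Drive an ensemble with an external input series
#'
#' @param net A network.
#' @param ens Ensemble id.
#' @param values Either a single number (constant input) or a function of
#'   time returning the input value.
#' @return The network, invisibly.
#' @export
set_ext_input <- function(net, ens, values) {
  net$ext[[as.character(ens)]] <- values
  invisible(net)
}

#' Run a network for a fixed duration
#'
#' Advances LIF membrane dynamics and synaptic filters in fixed steps of
#' `net$dt`. The run is exactly reproducible: the same network (same builder
#' calls and seed) yields bitwise-identical traces.
#'
#' @param net A `syllseq_network`.
#' @param duration Simulated time in seconds (must be a multiple of `dt`).
#' @param probe_tau Synaptic filter applied to probed/monitored signals (s).
#' @param ext_tau Synaptic filter applied to external inputs (s).
#' @return A `syllseq_sim` list: `time`, `probes` (matrix, one column per
#'   probe), `triggers` (data.frame of motor-execution events, if a motor
#'   execution module is attached), `dt`.
#' @export
simulate <- function(net, duration, probe_tau = 0.01, ext_tau = 0.01) {
  n_steps <- as.integer(round(duration / net$dt))
  if (abs(n_steps * net$dt - duration) > 1e-9) {
    stop("dt must divide duration")
  }
  E <- length(net$ens)
  probes <- matrix(numeric(0), nrow = 0, ncol = length(net$probe_sig))
  if (n_steps > 0L) {
    ext <- matrix(0, nrow = n_steps, ncol = E)
    tt <- (seq_len(n_steps) - 1L) * net$dt
    for (nm in names(net$ext)) {
      v <- net$ext[[nm]]
      ext[, as.integer(nm)] <- if (is.function(v)) {
        vapply(tt, v, numeric(1))
      } else v
    }
    ens_n <- vapply(net$ens, function(e) e$n_neurons, integer(1))
    args <- list(
      n_steps = n_steps, dt = net$dt,
      tau_rc = net$ens[[1]]$tau_rc, tau_ref = net$ens[[1]]$tau_ref,
      gain = unlist(lapply(net$ens, function(e) e$gain)),
      bias = unlist(lapply(net$ens, function(e) e$bias)),
      v0 = unlist(lapply(net$ens, function(e) e$v0)),
      ens_start = c(0L, cumsum(ens_n)),
      sig_ens = net$sig_ens - 1L,
      dec = unlist(net$sig_dec) %||% numeric(0),
      dec_start = c(0L, cumsum(vapply(net$sig_dec, length, integer(1)))),
      fsig_sig = net$fsig_sig - 1L,
      fsig_decay = exp(-net$dt / net$fsig_tau),
      con_fsig = net$con_fsig - 1L,
      con_dst = net$con_dst - 1L,
      con_w = net$con_w,
      ext = ext,
      ext_decay = exp(-net$dt / ext_tau),
      probe_sig = net$probe_sig - 1L,
      probe_decay = exp(-net$dt / probe_tau),
      labels = vapply(net$ens, function(e) e$label, character(1)),
      mexec = prepare_mexec(net)
    )
    out <- run_simulation(args)
    probes <- out$probes
    triggers <- out$triggers
  } else {
    triggers <- matrix(numeric(0), ncol = 2)
  }
  colnames(probes) <- net$probe_label
  trig <- data.frame(syllable = syllables()[triggers[, 1] + 1],
                     time = triggers[, 2])
  structure(list(time = (seq_len(n_steps) - 1L) * net$dt, probes = probes,
                 triggers = trig, dt = net$dt, seed = net$seed),
            class = "syllseq_sim")
}

#' @export
print.syllseq_sim <- function(x, ...) {
  cat("<syllseq_sim>", length(x$time), "steps @ dt =", x$dt, "s,",
      ncol(x$probes), "probes,", nrow(x$triggers), "motor triggers\n")
  invisible(x)
}

# Flatten the motor-execution module config for the C++ loop (NULL if absent).
prepare_mexec <- function(net) {
  m <- net$mexec
  if (is.null(m)) return(NULL)
  list(mon_sig = m$mon_sig - 1L,
       exec_vecs = m$exec_vecs,          # 6 x D dot-product weights
       somato_ens = m$somato_ens - 1L,   # D ensemble ids
       thr_on = m$thr_on, thr_off = m$thr_off,
       delay_steps = as.integer(round(m$delay / net$dt)),
       pulse_steps = as.integer(round(m$pulse / net$dt)),
       arm_step = as.integer(round((m$arm_from %||% 0) / net$dt)),
       amp = m$amp,
       mon_decay = exp(-net$dt / 0.01))
}

#' Export probed similarity traces to CSV
#'
#' @param sim A `syllseq_sim` from [simulate()].
#' @param path Output CSV path (columns: time plus one per probe).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  df <- data.frame(time = sim$time, sim$probes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
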