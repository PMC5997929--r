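# Assembly of the full task network: six cortical buffers, the BG-thalamus
# circuit over the 14 rules, the motor execution module with its 200 ms
# articulation delay, and the visual input protocol.

#' Configuration of one sequencing trial
#'
#' @param duration Total simulated time (s).
#' @param pre_input Silent lead-in before the visual cue (s).
#' @param cue_duration Duration of the visual BA cue (s).
#' @param delay Articulation delay between a motor pulse and its
#'   somatosensory feedback (s).
#' @param params A [bg_params()].
#' @param vocab_seed,net_seed Seeds for pointer generation and for neuron
#'   parameters / decoder solving ("covarying synaptic link weights").
#' @param dt Time step (s).
#' @param dimension Pointer dimensionality.
#' @param idle_weight,phonemic_gain,effect_gain Rule constants, see
#'   [action_rules()].
#' @param phonemic_feedback,phonemic_tau Recurrent gain and synapse of the
#'   phonemic memory buffer. The defaults give a leaky memory with an
#'   effective time constant of ~77 ms (`tau / (1 - gain)`), which sets the
#'   ~100 ms motor pulse width: a speak rule stays selected until its
#'   phonemic drive decays out of the selectable range.
#' @param trigger_on,trigger_off Motor execution trigger thresholds
#'   (hysteresis) on motor-buffer similarity.
#' @param feedback_amp Amplitude of the somatosensory feedback pulse.
#' @param feedback_pulse Duration of the somatosensory feedback pulse (s).
#'   The feedback is an event marker signalling the end of articulation; it
#'   must outlast the advance action's selection (~35 ms) but fade before
#'   the following speak action needs the channel, or the two actions block
#'   each other through the broad STN excitation.
#' @return A `syllseq_trial_config` list.
#' @export
trial_config <- function(duration = 5.5, pre_input = 0.5, cue_duration = 0.2,
                         delay = 0.2, params = bg_params(),
                         vocab_seed = 1L, net_seed = 1L, dt = 0.001,
                         dimension = 32L, idle_weight = 0.35,
                         phonemic_gain = 3.5, effect_gain = 1.8,
                         phonemic_feedback = 0.35, phonemic_tau = 0.05,
                         trigger_on = 0.7, trigger_off = 0.45,
                         feedback_amp = 1.0, feedback_pulse = 0.045) {
  stopifnot(duration > pre_input + cue_duration, delay > 0)
  structure(list(duration = duration, pre_input = pre_input,
                 cue_duration = cue_duration, delay = delay, params = params,
                 vocab_seed = as.integer(vocab_seed),
                 net_seed = as.integer(net_seed), dt = dt,
                 dimension = as.integer(dimension),
                 idle_weight = idle_weight, phonemic_gain = phonemic_gain,
                 effect_gain = effect_gain,
                 phonemic_feedback = phonemic_feedback,
                 phonemic_tau = phonemic_tau, trigger_on = trigger_on,
                 trigger_off = trigger_off, feedback_amp = feedback_amp,
                 feedback_pulse = feedback_pulse),
            class = "syllseq_trial_config")
}

#' Visual input protocol
#'
#' Nothing during the silent lead-in, the pointer BA while the cue is shown,
#' and the pointer ZERO (empty screen) for the rest of the trial.
#'
#' @param t Time in seconds.
#' @param config A [trial_config()].
#' @param vocab The trial vocabulary.
#' @return The visual input vector at time `t`.
#' @export
visual_schedule <- function(t, config, vocab) {
  if (t < config$pre_input) {
    numeric(vocab$dimension)
  } else if (t < config$pre_input + config$cue_duration) {
    pointer(vocab, "BA")
  } else {
    pointer(vocab, "ZERO")
  }
}

#' Build the full sequencing network
#'
#' @param config A [trial_config()].
#' @param vocab A vocabulary containing all 14 task pointers.
#' @param probe_bg Also probe the GPi/SNr/STN ramp outputs of every channel
#'   (diagnostic; off by default).
#' @return A `syllseq_model`: the network plus buffer/BG/thalamus handles and
#'   the rule list.
#' @export
build_model <- function(config, vocab, probe_bg = FALSE) {
  missing <- setdiff(default_pointer_names(), colnames(vocab$vectors))
  if (length(missing)) {
    stop("vocabulary lacks pointers: ", paste(missing, collapse = ", "))
  }
  stopifnot(vocab$dimension == config$dimension)
  p <- config$params
  rules <- action_rules(idle_weight = config$idle_weight,
                        phonemic_gain = config$phonemic_gain,
                        effect_gain = config$effect_gain)
  net <- nef_network(dt = config$dt, seed = config$net_seed)

  buffers <- list()
  for (b in c("visual", "phonemic", "somatosensory", "premotor",
              "auditory", "motor")) {
    buffers[[b]] <- add_buffer(net, b, dimension = config$dimension,
                               recurrent = (b == "phonemic"),
                               feedback_gain = config$phonemic_feedback,
                               feedback_tau = config$phonemic_tau)
    probe_buffer(net, buffers[[b]])
  }

  bg <- add_bg(net, n_channels = length(rules), params = p)
  thal <- add_thalamus(net, bg)
  for (ch in seq_along(thal$sig)) {
    add_probe(net, thal$sig[ch], paste0("thal.", rules[[ch]]$name))
  }
  if (probe_bg) {
    for (ch in seq_along(rules)) {
      for (pop in c("gpi", "snr", "stn", "str_d1", "gpe")) {
        add_probe(net, bg$out[ch, pop],
                  paste0(pop, ".", rules[[ch]]$name))
      }
    }
  }

  # conditions: utility terms feed striatum (with dopamine gains) and STN
  for (ch in seq_along(rules)) {
    for (trm in rules[[ch]]$condition) {
      buf <- buffers[[trm$buffer]]
      vec <- pointer(vocab, trm$pointer)
      for (k in seq_len(config$dimension)) {
        w <- trm$weight * vec[k]
        if (abs(w) < 1e-12) next
        add_connection(net, buf$sig[k], bg$ens[ch, "str_d1"],
                       w * p$ws * (1 + p$lg), p$tau_ampa)
        add_connection(net, buf$sig[k], bg$ens[ch, "str_d2"],
                       w * p$ws * (1 - p$le), p$tau_ampa)
        add_connection(net, buf$sig[k], bg$ens[ch, "stn"],
                       w * p$wt, p$tau_ampa)
      }
    }
  }

  # effects: disinhibited thalamic channel injects fixed pointers
  for (ch in seq_along(rules)) {
    for (eff in rules[[ch]]$effects) {
      buf <- buffers[[eff$buffer]]
      vec <- pointer(vocab, eff$pointer)
      for (k in seq_len(config$dimension)) {
        if (abs(vec[k]) < 1e-12) next
        add_connection(net, thal$sig[ch], buf$ens[k],
                       eff$gain * vec[k], 0.01)
      }
    }
  }

  # visual protocol (piecewise-constant per component)
  t_cue <- config$pre_input
  t_zero <- config$pre_input + config$cue_duration
  ba <- pointer(vocab, "BA")
  zero <- pointer(vocab, "ZERO")
  for (k in seq_len(config$dimension)) {
    local({
      kk <- k
      set_ext_input(net, buffers$visual$ens[kk], function(t) {
        if (t < t_cue) 0 else if (t < t_zero) ba[kk] else zero[kk]
      })
    })
  }

  # motor execution module: watch motor similarity to each S_EXEC pointer,
  # feed the pointer back into the somatosensory buffer after the delay
  exec_vecs <- t(vocab$vectors[, vapply(syllables(), exec_pointer,
                                        character(1))])
  net$mexec <- list(mon_sig = buffers$motor$sig, exec_vecs = exec_vecs,
                    somato_ens = buffers$somatosensory$ens,
                    thr_on = config$trigger_on, thr_off = config$trigger_off,
                    delay = config$delay, pulse = config$feedback_pulse,
                    amp = config$feedback_amp,
                    arm_from = config$pre_input)

  structure(list(net = net, buffers = buffers, bg = bg, thalamus = thal,
                 rules = rules, vocab = vocab, config = config),
            class = "syllseq_model")
}

#' @export
print.syllseq_model <- function(x, ...) {
  cat("<syllseq_model>", length(x$buffers), "buffers,",
      x$bg$n_channels, "action channels,", n_neurons(x$net), "neurons\n")
  invisible(x)
}

#' Run one sequencing trial
#'
#' Builds the vocabulary (from `vocab_seed`) and the network (from
#' `net_seed`), simulates the full duration, and returns similarity traces
#' for every buffer and every pointer.
#'
#' @param config A [trial_config()].
#' @param vocab Optional pre-built vocabulary (default: built from
#'   `config$vocab_seed`).
#' @return A `syllseq_trace`: list with `time`, `similarity` (named list of
#'   time x pointer matrices, one per buffer), `thalamus` (time x rule gate
#'   matrix), `triggers` (motor execution events), `config`, `vocab`.
#' @export
run_trial <- function(config = trial_config(), vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- create_vocabulary(dimension = config$dimension,
                               seed = config$vocab_seed)
  }
  model <- build_model(config, vocab)
  sim <- simulate(model$net, config$duration)
  as_trace(sim, model)
}

# Convert raw probe output into per-buffer similarity traces.
as_trace <- function(sim, model) {
  vocab <- model$vocab
  sims <- lapply(names(model$buffers), function(b) {
    buffer_similarity(sim, b, vocab)
  })
  names(sims) <- names(model$buffers)
  thal_cols <- paste0("thal.", vapply(model$rules, `[[`, character(1),
                                      "name"))
  structure(list(time = sim$time, similarity = sims,
                 thalamus = sim$probes[, thal_cols, drop = FALSE],
                 triggers = sim$triggers, config = model$config,
                 vocab = vocab, dt = sim$dt),
            class = "syllseq_trace")
}

#' @export
print.syllseq_trace <- function(x, ...) {
  cat("<syllseq_trace>", length(x$time), "steps,",
      nrow(x$triggers), "motor triggers, params:",
      sprintf("lg=le=%.2f wt=%.2f wp=%.2f\n", x$config$params$lg,
              x$config$params$wt, x$config$params$wp))
  invisible(x)
}
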