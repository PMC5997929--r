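# Cortical buffers: arrays of one-dimensional ensembles, one per vector
# component, jointly representing a semantic-pointer-valued state.

#' Add a cortical buffer to a network
#'
#' A buffer is `dimension` one-dimensional LIF ensembles of
#' `n_per_ensemble` neurons each (the default 32 x 50 = 1600 neurons). With
#' `recurrent = TRUE` each component feeds back onto itself through a synapse,
#' giving the buffer short-term memory: at `feedback_gain = 1` a loaded
#' pointer is held indefinitely (up to spiking drift); gains below 1 give a
#' leaky memory with effective time constant
#' `feedback_tau / (1 - feedback_gain)`.
#'
#' @param net A [nef_network()].
#' @param label Buffer name (component ensembles are labelled
#'   `"<label>.<k>"`).
#' @param dimension Number of vector components (default 32).
#' @param n_per_ensemble Neurons per component ensemble (default 50).
#' @param recurrent Add the memory feedback loop?
#' @param feedback_gain Recurrent gain (ignored unless recurrent).
#' @param feedback_tau Recurrent synapse time constant in seconds.
#' @param radius Representational radius per component.
#' @return A `syllseq_buffer`: list with ensemble ids `ens`, identity signal
#'   ids `sig`, and the construction arguments.
#' @export
add_buffer <- function(net, label, dimension = 32L, n_per_ensemble = 50L,
                       recurrent = FALSE, feedback_gain = 1.0,
                       feedback_tau = 0.01, radius = 1) {
  ens <- integer(dimension)
  sig <- integer(dimension)
  for (k in seq_len(dimension)) {
    ens[k] <- add_ensemble(net, paste0(label, ".", k),
                           n_neurons = n_per_ensemble, radius = radius)
    sig[k] <- add_decode(net, ens[k], "identity")
    if (recurrent && feedback_gain != 0) {
      add_connection(net, sig[k], ens[k], feedback_gain, tau = feedback_tau)
    }
  }
  structure(list(label = label, ens = ens, sig = sig,
                 dimension = as.integer(dimension),
                 n_per_ensemble = as.integer(n_per_ensemble),
                 recurrent = recurrent, feedback_gain = feedback_gain),
            class = "syllseq_buffer")
}

#' Feedforward pointer channel between two buffers
#'
#' Connects each component of `src` to the matching component of `dst`
#' (identity transform), so a pointer held in the source appears in the
#' target after roughly one synaptic time constant (about 15 ms at the
#' default 10 ms synapse, including neural rise time).
#'
#' @param net Network.
#' @param src,dst `syllseq_buffer` objects of equal dimension.
#' @param weight Scalar gain on the transfer.
#' @param tau Synapse time constant (s).
#' @return The network, invisibly.
#' @export
connect_buffers <- function(net, src, dst, weight = 1, tau = 0.01) {
  stopifnot(src$dimension == dst$dimension)
  for (k in seq_len(src$dimension)) {
    add_connection(net, src$sig[k], dst$ens[k], weight, tau)
  }
  invisible(net)
}

#' Inject a pointer into a buffer as external input
#'
#' @param net Network.
#' @param buffer A `syllseq_buffer`.
#' @param vec Pointer vector (length = buffer dimension) or a function of
#'   time returning such a vector... use `fn` for time-varying input.
#' @param fn Optional function of time returning the full input vector; when
#'   given, `vec` is ignored.
#' @return The network, invisibly.
#' @export
inject_pointer <- function(net, buffer, vec = NULL, fn = NULL) {
  for (k in seq_len(buffer$dimension)) {
    if (is.null(fn)) {
      set_ext_input(net, buffer$ens[k], vec[k])
    } else {
      local({
        kk <- k
        set_ext_input(net, buffer$ens[kk], function(t) fn(t)[kk])
      })
    }
  }
  invisible(net)
}

#' Probe every component of a buffer
#'
#' @param net Network.
#' @param buffer A `syllseq_buffer`.
#' @return The network, invisibly.
#' @export
probe_buffer <- function(net, buffer) {
  for (k in seq_len(buffer$dimension)) {
    add_probe(net, buffer$sig[k], paste0(buffer$label, ".", k))
  }
  invisible(net)
}

#' Similarity traces of a probed buffer
#'
#' @param sim A `syllseq_sim`.
#' @param buffer Buffer label.
#' @param vocab Vocabulary whose pointers to compare against.
#' @return Matrix (time x pointers) of dot products between the decoded
#'   buffer state and each pointer.
#' @export
buffer_similarity <- function(sim, buffer, vocab) {
  cols <- paste0(buffer, ".", seq_len(vocab$dimension))
  miss <- setdiff(cols, colnames(sim$probes))
  if (length(miss)) stop("buffer not fully probed: ", buffer)
  sim$probes[, cols, drop = FALSE] %*% vocab$vectors
}
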