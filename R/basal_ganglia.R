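# The modified Gurney action-selection circuit: striatum D1/D2, STN, GPe,
# and *separately implemented* GPi and SNr output nuclei, so that the STN
# afferent weight (wt) and the GPi-specific STN weight (wp) can be degraded
# independently, plus the disinhibition-gated thalamus.

#' Basal ganglia parameters
#'
#' The four swept parameters plus the fixed circuit constants of the
#' action-selection model. `lg` and `le` set the tonic dopamine level acting
#' on the D1 (selection) and D2 (control) striatal pathways; cortex drives
#' striatum with gains `ws * (1 + lg)` (D1) and `ws * (1 - le)` (D2). `wt`
#' scales the cortical (utility) afferents to the STN; `wp` scales the broad
#' STN excitation of the GPi specifically, while the SNr and GPe keep the
#' standard broadcast weight `w_stn = 0.9` (its maximum).
#'
#' @param lg D1 dopamine level, in `[0, 0.2]` (0.2 = typical).
#' @param le D2 dopamine level, in `[0, 0.2]`.
#' @param wt STN afferent weight, in `[0, 1]` (1 = standard).
#' @param wp STN-to-GPi weight, in `[0, 0.9]` (0.9 = maximum GPi activity).
#' @param ws,wm,wg,we Fixed weights: cortex->striatum, striatum D1->GPi/SNr,
#'   striatum D2->GPe, GPe->STN/GPi/SNr.
#' @param w_stn Fixed broad STN broadcast weight to GPe and SNr.
#' @param eps Named ramp thresholds per population.
#' @param m Ramp slope (shared).
#' @param tau_ampa,tau_gaba Excitatory / inhibitory synapse time constants (s).
#' @return A validated `syllseq_bg_params` list.
#' @export
bg_params <- function(lg = 0.2, le = 0.2, wt = 1.0, wp = 0.9,
                      ws = 1, wm = 1, wg = 1, we = 0.3, w_stn = 0.9,
                      eps = c(str = 0.2, stn = -0.25, gpe = -0.2,
                              gpi = -0.2, snr = -0.2),
                      m = 1, tau_ampa = 0.002, tau_gaba = 0.008) {
  if (lg < 0 || lg > 0.2) stop("lg must be in [0, 0.2]")
  if (le < 0 || le > 0.2) stop("le must be in [0, 0.2]")
  if (wt < 0 || wt > 1) stop("wt must be in [0, 1]")
  if (wp < 0 || wp > 0.9) stop("wp must be in [0, 0.9]")
  structure(list(lg = lg, le = le, wt = wt, wp = wp, ws = ws, wm = wm,
                 wg = wg, we = we, w_stn = w_stn, eps = eps, m = m,
                 tau_ampa = tau_ampa, tau_gaba = tau_gaba),
            class = "syllseq_bg_params")
}

#' @export
print.syllseq_bg_params <- function(x, ...) {
  cat(sprintf("<bg_params> lg=%.2f le=%.2f wt=%.2f wp=%.2f\n",
              x$lg, x$le, x$wt, x$wp))
  invisible(x)
}

#' Compute action utilities from cortical states
#'
#' Each action rule's utility is the weighted sum of dot products between the
#' named buffer states and the rule's condition pointers, clipped below at 0.
#'
#' @param states Named list mapping buffer label to a state vector.
#' @param rules A list of rules from [action_rules()].
#' @param vocab The vocabulary resolving pointer names.
#' @return Numeric utility vector, one entry per rule (named).
#' @export
compute_utilities <- function(states, rules, vocab) {
  u <- vapply(rules, function(r) {
    s <- 0
    for (term in r$condition) {
      if (is.null(states[[term$buffer]])) {
        stop("missing buffer state: ", term$buffer)
      }
      s <- s + term$weight *
        similarity(states[[term$buffer]], term$pointer, vocab)
    }
    s
  }, numeric(1))
  names(u) <- vapply(rules, `[[`, character(1), "name")
  pmax(u, 0)
}

#' Rate-based steady-state selection oracle
#'
#' Solves the ramp-equation fixed point of the action-selection circuit for a
#' constant utility vector, with the same wiring as the spiking network but
#' no neurons: the independent reference for what the spiking circuit should
#' settle to. The winning channel's GPi and SNr outputs are driven to the
#' circuit minimum - exactly zero when its utility dominates strongly enough
#' that striatal and pallidal inhibition exceed the broad STN excitation -
#' while losing channels stay at a positive (tonic) level, keeping their
#' thalamic targets suppressed.
#'
#' @param utilities Non-negative utility vector (one per channel).
#' @param params A [bg_params()].
#' @param eta Damping factor of the fixed-point iteration. The broad STN
#'   broadcast gives the symmetric mode a loop gain that grows with the
#'   channel count (about 0.27 per channel), so the default is safe for up
#'   to ~25 channels.
#' @param tol Convergence tolerance on the state change.
#' @param max_iter Iteration budget; exceeding it reports non-convergence
#'   (an oscillating equilibrium).
#' @return List with per-channel `gpi`, `snr`, `gpe`, `stn`, `str_d1`,
#'   `str_d2` outputs, `thalamus` (the disinhibition drive
#'   `1 - 1.5 * (gpi + snr)`, clipped at 0), `selected` (indices of
#'   disinhibited channels, i.e. thalamic drive above the 0.2 firing
#'   threshold), `converged`, `iterations`.
#' @export
steady_state_selection <- function(utilities, params = bg_params(),
                                   eta = 0.15, tol = 1e-9,
                                   max_iter = 20000L) {
  p <- params
  u <- pmax(utilities, 0)
  n <- length(u)
  str1 <- ramp(p$ws * (1 + p$lg) * u, p$eps[["str"]], p$m)
  str2 <- ramp(p$ws * (1 - p$le) * u, p$eps[["str"]], p$m)
  stn <- rep(0, n); gpe <- rep(0, n); gpi <- rep(0, n); snr <- rep(0, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    stn_new <- ramp(p$wt * u - p$we * gpe, p$eps[["stn"]], p$m)
    s <- sum(stn_new)
    gpe_new <- ramp(p$w_stn * s - p$wg * str2, p$eps[["gpe"]], p$m)
    gpi_new <- ramp(p$wp * s - p$wm * str1 - p$we * gpe_new,
                    p$eps[["gpi"]], p$m)
    snr_new <- ramp(p$w_stn * s - p$wm * str1 - p$we * gpe_new,
                    p$eps[["snr"]], p$m)
    delta <- max(abs(stn_new - stn), abs(gpe_new - gpe),
                 abs(gpi_new - gpi), abs(snr_new - snr))
    stn <- (1 - eta) * stn + eta * stn_new
    gpe <- (1 - eta) * gpe + eta * gpe_new
    gpi <- (1 - eta) * gpi + eta * gpi_new
    snr <- (1 - eta) * snr + eta * snr_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # one exact (undamped) pass: values below their ramp threshold at the
  # fixed point become exactly zero
  stn <- ramp(p$wt * u - p$we * gpe, p$eps[["stn"]], p$m)
  s <- sum(stn)
  gpe <- ramp(p$w_stn * s - p$wg * str2, p$eps[["gpe"]], p$m)
  gpi <- ramp(p$wp * s - p$wm * str1 - p$we * gpe, p$eps[["gpi"]], p$m)
  snr <- ramp(p$w_stn * s - p$wm * str1 - p$we * gpe, p$eps[["snr"]], p$m)
  thal <- pmax(1 - 1.5 * (gpi + snr), 0)
  list(gpi = gpi, snr = snr, gpe = gpe, stn = stn,
       str_d1 = str1, str_d2 = str2, thalamus = thal,
       selected = which(thal > 0.2),
       converged = converged, iterations = it)
}

#' Add the basal ganglia circuit to a network
#'
#' One action channel per utility input. Populations per channel: striatum D1
#' and D2, STN, GPe, and the split output nuclei GPi and SNr. Utility inputs
#' are wired by the caller onto the returned ensembles (`str_d1`, `str_d2`
#' with dopamine gains, `stn` with gain `wt`).
#'
#' @param net A network.
#' @param n_channels Number of action channels (>= 2).
#' @param params A [bg_params()].
#' @param n_per_ensemble Neurons per population ensemble.
#' @param radius Representational radius of the BG populations. Above 1 so
#'   that co-active channels (broad STN excitation summing over channels)
#'   stay inside the represented range and the GPe control loop keeps
#'   clamping the STN, as in the underlying rate equations.
#' @return A `syllseq_bg` list: matrices of ensemble ids and ramp-output
#'   signal ids per population, plus `params`.
#' @export
add_bg <- function(net, n_channels, params = bg_params(),
                   n_per_ensemble = 50L, radius = 1.5) {
  stopifnot(n_channels >= 2)
  p <- params
  pops <- c("str_d1", "str_d2", "stn", "gpe", "gpi", "snr")
  thr <- c(str_d1 = p$eps[["str"]], str_d2 = p$eps[["str"]],
           stn = p$eps[["stn"]], gpe = p$eps[["gpe"]],
           gpi = p$eps[["gpi"]], snr = p$eps[["snr"]])
  ens <- sapply(pops, function(pop) {
    vapply(seq_len(n_channels), function(ch) {
      add_ensemble(net, paste0("bg.", pop, ".", ch),
                   n_neurons = n_per_ensemble, radius = radius,
                   intercepts = c(thr[[pop]] / radius, 1), encoders = 1)
    }, integer(1))
  })
  out <- sapply(pops, function(pop) {
    vapply(seq_len(n_channels), function(ch) {
      add_decode(net, ens[ch, pop], "ramp", eps = thr[[pop]])
    }, integer(1))
  })
  for (ch in seq_len(n_channels)) {
    # selection pathway: D1 striatum inhibits both output nuclei
    add_connection(net, out[ch, "str_d1"], ens[ch, "gpi"], -p$wm, p$tau_gaba)
    add_connection(net, out[ch, "str_d1"], ens[ch, "snr"], -p$wm, p$tau_gaba)
    # control pathway: D2 striatum inhibits GPe
    add_connection(net, out[ch, "str_d2"], ens[ch, "gpe"], -p$wg, p$tau_gaba)
    # GPe control inhibition
    add_connection(net, out[ch, "gpe"], ens[ch, "stn"], -p$we, p$tau_gaba)
    add_connection(net, out[ch, "gpe"], ens[ch, "gpi"], -p$we, p$tau_gaba)
    add_connection(net, out[ch, "gpe"], ens[ch, "snr"], -p$we, p$tau_gaba)
    # broad STN excitation: every STN channel excites every output channel
    for (dst in seq_len(n_channels)) {
      add_connection(net, out[ch, "stn"], ens[dst, "gpe"], p$w_stn,
                     p$tau_ampa)
      add_connection(net, out[ch, "stn"], ens[dst, "snr"], p$w_stn,
                     p$tau_ampa)
      add_connection(net, out[ch, "stn"], ens[dst, "gpi"], p$wp, p$tau_ampa)
    }
  }
  structure(list(n_channels = as.integer(n_channels), ens = ens, out = out,
                 params = p),
            class = "syllseq_bg")
}

#' Add the thalamus and its disinhibition gating
#'
#' Per-channel thalamic ensembles with a constant positive bias, inhibited by
#' both output nuclei (each at half the combined model's output weight of -3,
#' so the total tonic suppression is unchanged by the GPi/SNr split) and
#' mutually inhibiting each other. A channel whose GPi and SNr outputs drop
#' toward zero is disinhibited; its decoded *gate* (a saturating go-signal
#' nonlinearity rising from 0 to 1 over the disinhibition range `gate_lo` to
#' `gate_hi`) drives the channel's rule effects. Channels under tonic
#' inhibition are silent and gate exactly 0.
#'
#' @param net A network.
#' @param bg A `syllseq_bg` from [add_bg()].
#' @param n_per_ensemble Neurons per thalamic channel ensemble.
#' @param output_weight Inhibitory weight from each output nucleus.
#' @param mutual_inhibit Weight of thalamic cross-channel inhibition.
#' @param gate_lo,gate_hi Foot and saturation of the gate nonlinearity, on
#'   the net disinhibition drive `1 + output_weight * (gpi + snr)`.
#' @return A `syllseq_thalamus`: ensemble ids `ens`, gate signal ids `sig`.
#' @export
add_thalamus <- function(net, bg, n_per_ensemble = 50L, output_weight = -1.5,
                         mutual_inhibit = 1, gate_lo = 0.02,
                         gate_hi = 0.22) {
  n <- bg$n_channels
  ens <- integer(n)
  sig <- integer(n)
  for (ch in seq_len(n)) {
    ens[ch] <- add_ensemble(net, paste0("thal.", ch),
                            n_neurons = n_per_ensemble,
                            intercepts = c(-0.2, 1), encoders = 1)
    sig[ch] <- add_decode(net, ens[ch], "gate", eps = gate_lo, hi = gate_hi)
    # tonic bias, ramped in over 50-200 ms so the output nuclei establish
    # their tonic inhibition first (otherwise every gate opens transiently
    # at startup, before any input)
    set_ext_input(net, ens[ch], function(t) min(1, max(0, (t - 0.05) / 0.15)))
    add_connection(net, bg$out[ch, "gpi"], ens[ch], output_weight,
                   bg$params$tau_gaba)
    add_connection(net, bg$out[ch, "snr"], ens[ch], output_weight,
                   bg$params$tau_gaba)
  }
  if (mutual_inhibit != 0) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a != b) add_connection(net, sig[a], ens[b], -mutual_inhibit, 0.01)
      }
    }
  }
  structure(list(ens = ens, sig = sig, n_channels = n),
            class = "syllseq_thalamus")
}
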