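# Analysis pipeline: motor-buffer similarity traces -> pulse events ->
# correct-sequence counts, error categories, pulse-shape classes, and the
# sweep-level aggregates and statistics.

#' Extract syllable pulses from motor similarity traces
#'
#' A pulse spans from an upward crossing of `onset` to the following downward
#' crossing of `offset` (hysteresis, so spiking ripple near threshold does
#' not split events). Same-syllable peaks separated by less than
#' `merge_window` are merged into a single event with `n_peaks` incremented -
#' the signature of oscillatory pulses.
#'
#' @param sim_mat Numeric matrix (time x syllables) of motor-buffer
#'   similarities to the six execution pointers; columns named by syllable or
#'   by execution pointer.
#' @param time Time vector matching the rows.
#' @param onset,offset Hysteresis thresholds.
#' @param merge_window Maximum same-syllable peak separation that still
#'   counts as one (multi-peak) pulse, in seconds.
#' @return Data frame with one row per pulse: `syllable`, `onset`, `offset`,
#'   `n_peaks`, `width` (longest single peak, s), `span` (onset to offset of
#'   the merged event, s), `shape`; ordered by onset.
#' @export
extract_pulses <- function(sim_mat, time, onset = 0.7, offset = 0.45,
                           merge_window = 0.12) {
  cols <- colnames(sim_mat)
  cols <- sub("_EXEC$", "", cols)
  stopifnot(all(syllables() %in% cols))
  out <- list()
  for (s in syllables()) {
    x <- sim_mat[, match(s, cols)]
    segs <- hysteresis_segments(x, time, onset, offset)
    if (!nrow(segs)) next
    gap <- segs$a[-1] - segs$b[-nrow(segs)]
    grp <- cumsum(c(1L, as.integer(gap >= merge_window)))
    for (g in unique(grp)) {
      sg <- segs[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        syllable = s, onset = sg$a[1], offset = sg$b[nrow(sg)],
        n_peaks = nrow(sg), width = max(sg$b - sg$a),
        span = sg$b[nrow(sg)] - sg$a[1])
    }
  }
  if (!length(out)) {
    return(data.frame(syllable = character(), onset = numeric(),
                      offset = numeric(), n_peaks = integer(),
                      width = numeric(), span = numeric(),
                      shape = character()))
  }
  pulses <- do.call(rbind, out)
  pulses <- pulses[order(pulses$onset), , drop = FALSE]
  rownames(pulses) <- NULL
  pulses$shape <- vapply(seq_len(nrow(pulses)), function(i) {
    classify_shape(pulses[i, ])
  }, character(1))
  pulses
}

# threshold crossings with hysteresis; returns data.frame(a = onset times,
# b = offset times)
hysteresis_segments <- function(x, time, onset, offset) {
  a <- numeric(0); b <- numeric(0)
  active <- FALSE
  start <- NA_real_
  for (i in seq_along(x)) {
    if (!active && x[i] >= onset) {
      active <- TRUE
      start <- time[i]
    } else if (active && x[i] < offset) {
      active <- FALSE
      a <- c(a, start); b <- c(b, time[i])
    }
  }
  if (active) {
    a <- c(a, start); b <- c(b, time[length(x)])
  }
  data.frame(a = a, b = b)
}

#' Count correctly sequenced syllables
#'
#' The first pulse counts only if it is BA (the cued start of the sequence);
#' each later pulse counts only if its syllable is the cyclic successor of the
#' immediately preceding pulse's syllable. Repetitions and out-of-order
#' pulses do not count.
#'
#' @param pulses Pulse data frame (ordered by onset) from
#'   [extract_pulses()], or a character vector of syllable labels.
#' @return Integer count.
#' @export
count_correct <- function(pulses) {
  syl <- if (is.character(pulses)) pulses else pulses$syllable
  if (!length(syl)) return(0L)
  n <- as.integer(syl[1] == "BA")
  if (length(syl) > 1) {
    for (i in 2:length(syl)) {
      if (syl[i] == next_syllable(syl[i - 1])) n <- n + 1L
    }
  }
  n
}

#' Classify sequencing errors of one trial
#'
#' Four categories: *repetition* (adjacent pulses of the same syllable),
#' *skipping* (adjacent pulses out of cyclic order, repetitions excluded),
#' *restart* (a gap longer than `restart_gap` with further pulses after it),
#' and *halting* (the last pulse ends more than `halt_window` before the end
#' of the trial; a trial with no pulses at all also halts).
#'
#' @param pulses Pulse data frame ordered by onset.
#' @param duration Trial duration (s).
#' @param restart_gap Inter-pulse gap identifying a break-and-restart (s).
#' @param halt_window Terminal silent window identifying a halt (s).
#' @return Character vector, a subset of
#'   `c("repetition", "skipping", "restart", "halting")`.
#' @export
classify_errors <- function(pulses, duration, restart_gap = 0.45,
                            halt_window = 0.7) {
  errs <- character(0)
  n <- nrow(pulses)
  if (n == 0) return("halting")
  if (n > 1) {
    prev <- pulses$syllable[-n]
    nxt <- pulses$syllable[-1]
    gaps <- pulses$onset[-1] - pulses$offset[-n]
    if (any(nxt == prev)) errs <- c(errs, "repetition")
    if (any(nxt != prev & nxt != vapply(prev, next_syllable, character(1)))) {
      errs <- c(errs, "skipping")
    }
    if (any(gaps > restart_gap)) errs <- c(errs, "restart")
  }
  if (pulses$offset[n] < duration - halt_window) errs <- c(errs, "halting")
  errs
}

#' Classify the shape of a single pulse
#'
#' @param pulse One row of a pulse data frame (needs `n_peaks` and `width`).
#' @param broad_width Single-peak width (s) above which a pulse is broad.
#' @return `"oscillatory"` (multiple peaks), `"broad"` (one long peak), or
#'   `"normal"`.
#' @export
classify_shape <- function(pulse, broad_width = 0.15) {
  if (pulse$n_peaks >= 2) "oscillatory"
  else if (pulse$width > broad_width) "broad"
  else "normal"
}

#' Map a five-trial sum of correct syllables to its region code
#'
#' Regions 1-6 partition 0..90 (the colour bands of the sweep tables):
#' 1 = 75-90 (dark red), 2 = 61-74, 3 = 45-60, 4 = 31-44, 5 = 15-30,
#' 6 = 0-14 (dark blue).
#'
#' @param total Sum of correct syllables over five trials (0-90).
#' @return Integer region code in 1..6.
#' @export
classify_region <- function(total) {
  if (any(total < 0 | total > 90)) stop("sum out of range [0, 90]")
  7L - cut(total, breaks = c(-1, 14, 30, 44, 60, 74, 90), labels = FALSE)
}

#' @rdname classify_region
#' @export
region_code <- classify_region

#' Stability class of a five-trial sum
#'
#' Stable: correct sequencing over more than 83 % of task time (sum >= 75,
#' the top region band); mildly distorted: more than 50 % (sum >= 46);
#' severely distorted otherwise.
#'
#' @param total Sum over five trials (0-90).
#' @return One of `"stable"`, `"mild"`, `"severe"`.
#' @export
stability_class <- function(total) {
  if (any(total < 0 | total > 90)) stop("sum out of range [0, 90]")
  ifelse(total >= 75, "stable", ifelse(total >= 46, "mild", "severe"))
}

#' One-sided two-sample t test (pooled variance)
#'
#' Tests whether `mean(a) > mean(b)` with the classical pooled-variance t
#' statistic, as used for comparing per-trial correct counts between
#' parameter settings.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return List with `t`, `p` (one-sided), `df`, and `degenerate` (TRUE when
#'   both samples have zero variance and equal means, leaving t undefined).
#' @export
one_sided_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  df <- na + nb - 2
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(t = NA_real_, p = NA_real_, df = df,
                            degenerate = TRUE))
    return(list(t = sign(d) * Inf, p = if (d > 0) 0 else 1, df = df,
                degenerate = FALSE))
  }
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = stats::pt(t, df, lower.tail = FALSE), df = df,
       degenerate = FALSE)
}

#' Analyse one trial trace
#'
#' Runs pulse extraction on the motor buffer over the scored task window
#' (everything after the silent lead-in) and derives the per-trial result.
#'
#' @param trace A `syllseq_trace` from [run_trial()].
#' @param onset,offset,merge_window Pulse-extraction settings.
#' @return A `syllseq_trial_result`: list with `pulses`, `n_correct`,
#'   `errors`, `shapes` (pulse-shape tally), `n_pulses`.
#' @export
analyze_trial <- function(trace, onset = 0.7, offset = 0.45,
                          merge_window = 0.12) {
  mot <- trace$similarity$motor
  execs <- vapply(syllables(), exec_pointer, character(1))
  keep <- trace$time >= trace$config$pre_input
  pulses <- extract_pulses(mot[keep, execs, drop = FALSE],
                           trace$time[keep], onset, offset, merge_window)
  structure(list(
    pulses = pulses,
    n_correct = count_correct(pulses),
    errors = classify_errors(pulses, trace$config$duration),
    shapes = table(factor(pulses$shape,
                          levels = c("normal", "oscillatory", "broad"))),
    n_pulses = nrow(pulses)),
    class = "syllseq_trial_result")
}

#' @export
print.syllseq_trial_result <- function(x, ...) {
  cat("<trial_result>", x$n_correct, "correct /", x$n_pulses, "pulses;",
      if (length(x$errors)) paste("errors:",
                                  paste(x$errors, collapse = ", ")) else
        "no errors", "\n")
  invisible(x)
}

#' Aggregate per-trial results over a parameter grid
#'
#' @param results Data frame with one row per trial: columns `dopamine`,
#'   `weight`, `trial`, `n_correct`, plus optional logical error columns
#'   `repetition`, `skipping`, `restart`, `halting` and shape tallies.
#' @param n_trials Required trials per cell (default 5).
#' @return A `syllseq_sweep_table` data frame, one row per (dopamine, weight)
#'   cell: `sum`, `mean`, `variance` (sample variance, n-1 denominator),
#'   `region`, `stability`, error-trial tallies.
#' @export
aggregate_sweep <- function(results, n_trials = 5L) {
  cells <- unique(results[, c("dopamine", "weight")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- results[results$dopamine == cells$dopamine[i] &
                      results$weight == cells$weight[i], , drop = FALSE]
    if (nrow(cell) != n_trials) {
      stop(sprintf("cell (dopamine=%g, weight=%g) has %d trials, expected %d",
                   cells$dopamine[i], cells$weight[i], nrow(cell), n_trials))
    }
    out <- data.frame(dopamine = cells$dopamine[i], weight = cells$weight[i],
                      sum = sum(cell$n_correct),
                      mean = mean(cell$n_correct),
                      variance = var(cell$n_correct))
    out$region <- region_code(min(out$sum, 90))
    out$stability <- stability_class(min(out$sum, 90))
    for (e in c("repetition", "skipping", "restart", "halting")) {
      if (e %in% names(cell)) out[[e]] <- sum(cell[[e]])
    }
    for (s in c("normal", "oscillatory", "broad")) {
      if (s %in% names(cell)) out[[s]] <- sum(cell[[s]])
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$weight, -tab$dopamine), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("syllseq_sweep_table", "data.frame")
  tab
}
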