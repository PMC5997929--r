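# Experiment harness: the two sweep sets (STN: wt x dopamine, GPi: wp x
# dopamine), deterministic per-cell seeding, resumable execution, and the
# table-style reports.

#' Default swept levels
#'
#' @return Numeric vector of levels.
#' @export
stn_levels <- function() c(1.0, 0.95, 0.9, 0.8, 0.6, 0.4, 0.2, 0)

#' @rdname stn_levels
#' @export
gpi_levels <- function() c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15, 0)

#' @rdname stn_levels
#' @export
dopamine_levels <- function() seq(0.20, 0, by = -0.02)

#' Specify a parameter sweep
#'
#' @param nucleus Which afferent weight is swept: `"stn"` (wt) or `"gpi"`
#'   (wp); the other stays at its maximum.
#' @param weights Swept weight levels (defaults per nucleus).
#' @param dopamine Dopamine levels (`le = lg`), default 0.20 down to 0 in
#'   steps of 0.02.
#' @param n_trials Trials per cell (default 5).
#' @param config Trial configuration template (its `params` lg/le/wt/wp and
#'   seeds are overridden per cell).
#' @param base_seed Offset entering every trial seed.
#' @param out_dir Directory for per-cell results and the manifest; `NULL`
#'   keeps everything in memory.
#' @return A `syllseq_sweep_spec` list.
#' @export
sweep_spec <- function(nucleus = c("stn", "gpi"), weights = NULL,
                       dopamine = dopamine_levels(), n_trials = 5L,
                       config = trial_config(), base_seed = 0L,
                       out_dir = NULL) {
  nucleus <- match.arg(nucleus)
  weights <- weights %||% if (nucleus == "stn") stn_levels() else gpi_levels()
  stopifnot(n_trials >= 1, all(dopamine >= 0 & dopamine <= 0.2))
  if (nucleus == "stn") stopifnot(all(weights >= 0 & weights <= 1))
  if (nucleus == "gpi") stopifnot(all(weights >= 0 & weights <= 0.9))
  structure(list(nucleus = nucleus, weights = weights, dopamine = dopamine,
                 n_trials = as.integer(n_trials), config = config,
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "syllseq_sweep_spec")
}

#' Deterministic trial seed for a sweep cell
#'
#' A fixed function of the cell coordinates and replicate index, so partial
#' and full sweeps agree cell-by-cell.
#'
#' @param dopamine,weight Cell coordinates.
#' @param replicate Replicate index (1-based).
#' @param base_seed Sweep-level offset.
#' @return Integer seed.
#' @export
trial_seed <- function(dopamine, weight, replicate, base_seed = 0L) {
  as.integer(base_seed * 100003L + round(dopamine * 100) * 7919L +
               round(weight * 100) * 53L + replicate)
}

# config for one cell of a sweep
cell_config <- function(spec, dopamine, weight, seed) {
  cfg <- spec$config
  p <- cfg$params
  p$lg <- dopamine
  p$le <- dopamine
  if (spec$nucleus == "stn") p$wt <- weight else p$wp <- weight
  cfg$params <- bg_params(lg = p$lg, le = p$le, wt = p$wt, wp = p$wp,
                          ws = p$ws, wm = p$wm, wg = p$wg, we = p$we,
                          w_stn = p$w_stn, eps = p$eps, m = p$m,
                          tau_ampa = p$tau_ampa, tau_gaba = p$tau_gaba)
  cfg$vocab_seed <- seed
  cfg$net_seed <- seed
  cfg
}

#' Run one cell of a sweep (n seeded trials at fixed parameters)
#'
#' @param spec A [sweep_spec()].
#' @param dopamine,weight Cell coordinates.
#' @param seeds Trial seeds; default the deterministic cell seeds.
#' @return Data frame with one row per trial (`dopamine`, `weight`, `trial`,
#'   `seed`, `n_correct`, `n_pulses`, error flags, shape tallies).
#' @export
run_cell <- function(spec, dopamine, weight, seeds = NULL) {
  seeds <- seeds %||% vapply(seq_len(spec$n_trials), function(r) {
    trial_seed(dopamine, weight, r, spec$base_seed)
  }, integer(1))
  rows <- lapply(seq_along(seeds), function(r) {
    cfg <- cell_config(spec, dopamine, weight, seeds[r])
    res <- analyze_trial(run_trial(cfg))
    out <- data.frame(dopamine = dopamine, weight = weight, trial = r,
                      seed = seeds[r], n_correct = res$n_correct,
                      n_pulses = res$n_pulses)
    for (e in c("repetition", "skipping", "restart", "halting")) {
      out[[e]] <- e %in% res$errors
    }
    for (s in c("normal", "oscillatory", "broad")) {
      out[[s]] <- as.integer(res$shapes[[s]])
    }
    out
  })
  do.call(rbind, rows)
}

#' Run a full parameter sweep
#'
#' Runs `n_trials` seeded trials per (dopamine, weight) cell, analyses each,
#' and aggregates. With `out_dir` set, each completed cell is written to its
#' own CSV and skipped on re-run, so an interrupted sweep resumes where it
#' stopped; a `manifest.json` records every seed and parameter.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print per-cell progress and timing?
#' @return List with `table` (a [aggregate_sweep()] result) and `trials`
#'   (per-trial rows).
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  grid <- expand.grid(dopamine = spec$dopamine, weight = spec$weights)
  use_dir <- !is.null(spec$out_dir)
  if (use_dir && !dir.exists(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE)
  }
  all_rows <- list()
  for (i in seq_len(nrow(grid))) {
    d <- grid$dopamine[i]; w <- grid$weight[i]
    f <- if (use_dir) {
      file.path(spec$out_dir, sprintf("cell_d%03d_w%03d.csv",
                                      round(d * 100), round(w * 100)))
    }
    if (use_dir && file.exists(f)) {
      rows <- utils::read.csv(f)
      if (nrow(rows) == spec$n_trials) {   # partial cells are re-run
        all_rows[[i]] <- rows
        next
      }
    }
    t0 <- Sys.time()
    rows <- run_cell(spec, d, w)
    if (use_dir) utils::write.csv(rows, f, row.names = FALSE)
    if (verbose) {
      message(sprintf("cell dopamine=%.2f %s=%.2f: sum=%d [%.1f s]",
                      d, if (spec$nucleus == "stn") "wt" else "wp", w,
                      sum(rows$n_correct),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    all_rows[[i]] <- rows
  }
  trials <- do.call(rbind, all_rows)
  tab <- aggregate_sweep(trials, n_trials = spec$n_trials)
  if (use_dir) {
    utils::write.csv(tab, file.path(spec$out_dir, "sweep_table.csv"),
                     row.names = FALSE)
    manifest <- list(nucleus = spec$nucleus, weights = spec$weights,
                     dopamine = spec$dopamine, n_trials = spec$n_trials,
                     base_seed = spec$base_seed,
                     seeds = trials[, c("dopamine", "weight", "trial",
                                        "seed")],
                     config = spec$config[setdiff(names(spec$config),
                                                  "params")],
                     params = unclass(spec$config$params))
    jsonlite::write_json(manifest, file.path(spec$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(table = tab, trials = trials)
}

#' Format a sweep table as the printed grids
#'
#' @param table A `syllseq_sweep_table`.
#' @param what `"sum"` for the five-trial totals, `"mean"` for
#'   `mean (+-variance)` strings, `"region"` or `"stability"`.
#' @param standard_layout Keep only the six standard STN rows
#'   (wt = 1.0, 0.8, 0.6, 0.4, 0.2, 0) in the printed grid even when the
#'   intermediate exploratory levels (0.95, 0.9) were simulated.
#' @return A matrix (weights x dopamine levels).
#' @export
sweep_grid <- function(table, what = c("sum", "mean", "region", "stability"),
                       standard_layout = FALSE) {
  what <- match.arg(what)
  ws <- sort(unique(table$weight), decreasing = TRUE)
  if (standard_layout) ws <- intersect(ws, c(1.0, 0.8, 0.6, 0.4, 0.2, 0))
  ds <- sort(unique(table$dopamine), decreasing = TRUE)
  g <- matrix(NA, nrow = length(ws), ncol = length(ds),
              dimnames = list(as.character(ws), as.character(ds)))
  if (what %in% c("stability")) g[] <- NA_character_
  for (i in seq_along(ws)) {
    for (j in seq_along(ds)) {
      row <- table[table$weight == ws[i] & table$dopamine == ds[j], ]
      if (!nrow(row)) next
      g[i, j] <- switch(what,
        sum = row$sum,
        mean = sprintf("%.1f (±%.1f)", row$mean, row$variance),
        region = row$region,
        stability = row$stability)
    }
  }
  g
}

#' Stability summary of a sweep table
#'
#' @param table A `syllseq_sweep_table`.
#' @return List with cell counts and fractions per stability class.
#' @export
stability_summary <- function(table) {
  n <- nrow(table)
  ns <- sum(table$stability == "stable")
  nm <- sum(table$stability %in% c("stable", "mild"))
  list(n_cells = n, stable = ns, stable_frac = ns / n,
       mild_or_better = nm, mild_frac = nm / n)
}

#' Plot Figure-style similarity panels for one trial
#'
#' One panel per buffer, one line per pointer, similarity against time.
#'
#' @param trace A `syllseq_trace`.
#' @param buffers Which buffers to draw.
#' @return Invisibly, `trace`.
#' @export
plot_trace <- function(trace, buffers = names(trace$similarity)) {
  old <- graphics::par(mfrow = c(length(buffers), 1),
                       mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (b in buffers) {
    sm <- trace$similarity[[b]]
    graphics::matplot(trace$time, sm, type = "l", lty = 1,
                      col = seq_len(ncol(sm)), ylab = "similarity",
                      main = b, cex.main = 0.9)
  }
  invisible(trace)
}
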