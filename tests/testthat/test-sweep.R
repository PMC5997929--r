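test_that("cell seeds are a deterministic function of coordinates", {
  s1 <- trial_seed(0.16, 0.8, 1)
  expect_identical(s1, trial_seed(0.16, 0.8, 1))
  expect_false(s1 == trial_seed(0.16, 0.8, 2))
  expect_false(s1 == trial_seed(0.14, 0.8, 1))
  expect_false(s1 == trial_seed(0.16, 0.6, 1))
  expect_false(s1 == trial_seed(0.16, 0.8, 1, base_seed = 9))
  # full grid x replicates: all distinct, all valid 32-bit integers
  grid <- expand.grid(d = dopamine_levels(), w = stn_levels(), r = 1:5)
  seeds <- mapply(trial_seed, grid$d, grid$w, grid$r)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(is.finite(seeds)))
})

test_that("sweep specs validate levels and default to the standard grids", {
  stn <- sweep_spec("stn")
  expect_equal(stn$weights, c(1.0, 0.95, 0.9, 0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(stn$dopamine, seq(0.20, 0, by = -0.02))
  expect_equal(nrow(expand.grid(stn$dopamine, stn$weights)), 88L)
  gpi <- sweep_spec("gpi")
  expect_equal(gpi$weights, c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15, 0))
  expect_equal(nrow(expand.grid(gpi$dopamine, gpi$weights)), 77L)
  expect_error(sweep_spec("gpi", weights = c(0.95)), "weights")
})

test_that("a reduced sweep runs, aggregates, persists and resumes", {
  out <- file.path(tempdir(), "syllseq_sweep_test")
  unlink(out, recursive = TRUE)
  spec <- sweep_spec("stn", weights = c(1.0, 0.2), dopamine = c(0.20, 0.02),
                     n_trials = 1L,
                     config = trial_config(duration = 1.2),
                     out_dir = out)
  r1 <- run_sweep(spec)
  expect_equal(nrow(r1$table), 4L)
  expect_equal(nrow(r1$trials), 4L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(length(list.files(out, pattern = "^cell_")), 4L)
  # resume: identical table, cell files untouched
  info1 <- file.info(list.files(out, pattern = "^cell_", full.names = TRUE))
  r2 <- run_sweep(spec)
  info2 <- file.info(list.files(out, pattern = "^cell_", full.names = TRUE))
  expect_equal(r1$table, r2$table)
  expect_identical(info1$mtime, info2$mtime)
  # a deleted cell is recomputed to the same values (deterministic seeds)
  f <- list.files(out, pattern = "^cell_", full.names = TRUE)[1]
  unlink(f)
  r3 <- run_sweep(spec)
  expect_equal(r1$table, r3$table)
  # manifest records every trial seed
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man$seeds), 4L)
  expect_equal(sort(man$seeds$seed), sort(r1$trials$seed))
  unlink(out, recursive = TRUE)
})

test_that("grid formatting and the stability summary match the table", {
  res <- expand.grid(dopamine = c(0.2, 0.1), weight = c(1.0, 0.95, 0.8),
                     trial = 1:5)
  res$n_correct <- ifelse(res$dopamine == 0.2, 18L, 3L)
  tab <- aggregate_sweep(res)
  g <- sweep_grid(tab, "sum")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(g["1", "0.2"], 90)
  expect_equal(g["1", "0.1"], 15)
  gm <- sweep_grid(tab, "mean")
  expect_match(gm["0.8", "0.2"], "18.0")
  # standard layout drops the intermediate 0.95 row
  gp <- sweep_grid(tab, "sum", standard_layout = TRUE)
  expect_equal(rownames(gp), c("1", "0.8"))
  s <- stability_summary(tab)
  expect_equal(s$n_cells, 6L)
  expect_equal(s$stable, 3L)
  expect_equal(s$stable_frac, 0.5)
})
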