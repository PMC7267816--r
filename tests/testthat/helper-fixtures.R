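# Shared fixture builders. Everything is generated in code at test time;
# heavier shared objects (a small simulated dataset and a model trained on
# it) are built once per test run and memoized.

make_locs <- function(x, y, frame = 0L, group = NULL) {
  n <- length(x)
  df <- data.frame(frame = rep_len(as.integer(frame), n), x = x, y = y,
                   photons = rep(1000, n), sx = rep(0.85, n), sy = rep(0.85, n),
                   bg = rep(20, n), lpx = rep(0.04, n), lpy = rep(0.04, n))
  if (!is.null(group)) df$group <- as.integer(rep_len(group, n))
  df
}

random_locs <- function(n, width = 32, height = 32, group = NULL) {
  make_locs(runif(n, 0, width), runif(n, 0, height),
            frame = sample.int(100, n, replace = TRUE) - 1L, group = group)
}

.fixture_env <- new.env(parent = emptyenv())

# Small simulated dataset + trained model, shared across test files.
small_trained <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  out_dir <- file.path(tempdir(), "smlm-small-fixture")
  sim <- simulate_dataset(n_per_class = 10L, cfg = sim_config(seed = 101L),
                          out_dir = out_dir)
  class_files <- split_by_truth(sim, file.path(out_dir, "classes"))
  res <- run_training(class_files, hidden = 50L, n_angles = 4L,
                      tcfg = train_config(max_epochs = 60L, seed = 11L),
                      seed = 11L)
  ds <- read_locs(sim$locs_path)
  .fixture_env$small <- list(sim = sim, class_files = class_files,
                             model = res$model, report = res$report, ds = ds)
  .fixture_env$small
}

expect_same_pixels <- function(a, b) {
  expect_identical(a$pixels, b$pixels)
}
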