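test_that("grid patterns have the stated lattice geometry", {
  single <- make_grid_pattern(1, 1, 20)
  expect_equal(nrow(single$sites), 1)
  expect_equal(unname(single$sites[1, ]), c(0, 0))

  g <- make_grid_pattern(4, 3, 20)  # the 20-nm grid
  expect_equal(nrow(g$sites), 12)
  expect_equal(diff(range(g$sites[, "x"])), 40)
  expect_equal(diff(range(g$sites[, "y"])), 60)
  expect_equal(colMeans(g$sites), c(x = 0, y = 0))

  q <- make_grid_pattern(2, 2, 10)
  expect_setequal(q$sites[, "x"], c(-5, 5))
  expect_setequal(q$sites[, "y"], c(-5, 5))

  expect_error(make_grid_pattern(0, 3, 20))
})

test_that("digit patterns come from fixed masks that differ pairwise", {
  d <- lapply(1:3, make_digit_pattern)
  expect_equal(vapply(d, function(p) nrow(p$sites), numeric(1)),
               c(8, 11, 10))
  site_key <- function(p) paste(p$sites[, 1], p$sites[, 2])
  for (i in 1:2) for (j in (i + 1):3) {
    a <- site_key(d[[i]]); b <- site_key(d[[j]])
    n_diff <- length(setdiff(a, b)) + length(setdiff(b, a))
    expect_gte(n_diff, 3)
  }
  expect_error(make_digit_pattern(7), "unsupported digit")

  # pitch scales coordinates linearly
  d20 <- make_digit_pattern(2, pitch_nm = 20)
  d40 <- make_digit_pattern(2, pitch_nm = 40)
  expect_equal(d40$sites, 2 * d20$sites)
})

test_that("labeling efficiency 0 and zero noise behave as degenerate limits", {
  cfg0 <- sim_config(labeling_efficiency = 0)
  set.seed(60)
  empty <- simulate_structure(make_grid_pattern(), c(5, 5), cfg0)
  expect_equal(nrow(empty), 0)

  one_site <- make_grid_pattern(1, 1, 20)
  cfg <- sim_config(precision_nm = 0, mean_events_per_site = 5,
                    labeling_efficiency = 1)
  set.seed(61)
  locs <- simulate_structure(one_site, c(7, 9), cfg)
  expect_gt(nrow(locs), 0)
  expect_true(all(locs$x == 7))
  expect_true(all(locs$y == 9))
  expect_true(all(locs$frame >= 0 & locs$frame < cfg$n_frames))
})

test_that("localization counts follow the thinned-Poisson expectation", {
  cfg <- sim_config(mean_events_per_site = 30, labeling_efficiency = 0.8)
  pat <- make_grid_pattern()  # 12 sites
  set.seed(62)
  n_rep <- 300
  counts <- vapply(seq_len(n_rep),
                   function(i) nrow(simulate_structure(pat, c(5, 5), cfg)),
                   numeric(1))
  mu <- 12 * 0.8 * 30
  # Var(sum) = n * (p * lambda + p * (1 - p) * lambda^2)
  sigma <- sqrt(12 * (0.8 * 30 + 0.8 * 0.2 * 30^2))
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(n_rep))
})

test_that("radial spread of a site's localizations reproduces the precision", {
  cfg <- sim_config(precision_nm = 5, mean_events_per_site = 2000,
                    labeling_efficiency = 1)
  set.seed(63)
  locs <- simulate_structure(make_grid_pattern(1, 1, 20), c(5, 5), cfg)
  dx_nm <- (locs$x - 5) * cfg$pixel_size_nm
  dy_nm <- (locs$y - 5) * cfg$pixel_size_nm
  rms <- sqrt(mean(dx_nm^2 + dy_nm^2) / 2)  # per-axis RMS
  expect_equal(rms, 5, tolerance = 0.1)
})

test_that("simulate_dataset writes a coherent file set", {
  out_dir <- file.path(tempdir(), "simds")
  sim <- simulate_dataset(n_per_class = 2L, cfg = sim_config(seed = 64L),
                          out_dir = out_dir)
  expect_equal(nrow(sim$truth), 8)
  expect_equal(nrow(sim$picks), 8)
  ds <- read_locs(sim$locs_path)
  expect_setequal(unique(stats::na.omit(ds$locs$group)), 0:7)
  picks <- read_picks(sim$pick_path)
  expect_equal(nrow(picks), 8)
  expect_equal(picks$center_x, sim$picks$center_x)
  truth <- utils::read.csv(sim$truth_path)
  expect_equal(sort(unique(truth$class)),
               c("digit1", "digit2", "digit3", "grid20"))

  # every structure's localizations fall inside its own pick
  parts <- groups_to_picksets(ds$locs)
  for (g in names(parts$picksets)) {
    p <- picks[picks$pick_id == as.integer(g), ]
    inside <- extract_pick(parts$picksets[[g]], p)
    expect_equal(nrow(inside), nrow(parts$picksets[[g]]))
  }
})

test_that("background is uniform and optional", {
  out_dir <- file.path(tempdir(), "simbg0")
  sim <- simulate_dataset(n_per_class = 2L,
                          cfg = sim_config(seed = 65L, background_rate = 0),
                          out_dir = out_dir)
  expect_equal(sim$n_background, 0)
  ds <- read_locs(sim$locs_path)
  expect_false(anyNA(ds$locs$group))
  expect_equal(nrow(ds$locs), sum(sim$n_structure_locs))
})

test_that("a too-small field is refused", {
  expect_error(simulate_dataset(n_per_class = 50L,
                                cfg = sim_config(width = 10, height = 10),
                                out_dir = tempdir()),
               "too small")
})

test_that("the same seed reproduces the output files byte for byte", {
  d1 <- file.path(tempdir(), "det-a")
  d2 <- file.path(tempdir(), "det-b")
  s1 <- simulate_dataset(n_per_class = 3L, cfg = sim_config(seed = 66L),
                         out_dir = d1)
  s2 <- simulate_dataset(n_per_class = 3L, cfg = sim_config(seed = 66L),
                         out_dir = d2)
  expect_identical(unname(tools::md5sum(s1$locs_path)),
                   unname(tools::md5sum(s2$locs_path)))
  expect_identical(readLines(s1$pick_path), readLines(s2$pick_path))
  expect_identical(readLines(s1$truth_path), readLines(s2$truth_path))
})

test_that("expected total localization count matches the generative model", {
  # one class to make the expectation exact: 12 sites * eff * events * n
  cfg <- sim_config(seed = 67L, background_rate = 0)
  sim <- simulate_dataset(patterns = list(make_grid_pattern()),
                          n_per_class = 60L, cfg = cfg,
                          out_dir = file.path(tempdir(), "simtot"))
  total <- sum(sim$n_structure_locs)
  mu <- 12 * 0.8 * 30 * 60
  sigma <- sqrt(60 * 12 * (0.8 * 30 + 0.8 * 0.2 * 900))
  expect_lt(abs(total - mu), 4 * sigma)
})
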