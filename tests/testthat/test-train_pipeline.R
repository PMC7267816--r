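test_that("the stratified split honours round(fraction * class size) per class", {
  labels <- rep(1:2, each = 50)
  sp <- split_train_test(labels, test_fraction = 0.3, seed = 1)
  expect_length(sp$test, 30)
  expect_length(sp$train, 70)
  expect_equal(sum(labels[sp$test] == 1), 15)
  expect_equal(sum(labels[sp$test] == 2), 15)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)

  tiny <- split_train_test(rep(1:2, each = 2), test_fraction = 0.5, seed = 2)
  expect_equal(sum(rep(1:2, each = 2)[tiny$test] == 1), 1)
  expect_equal(sum(rep(1:2, each = 2)[tiny$test] == 2), 1)

  expect_error(split_train_test(c(1, 1, 2), 0.3, 1), "at least 2")
})

test_that("the split is reproducible and unbalanced classes keep proportions", {
  labels <- c(rep(1, 37), rep(2, 63), rep(3, 10))
  a <- split_train_test(labels, 0.3, seed = 42)
  b <- split_train_test(labels, 0.3, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(labels[a$test] == 1), round(0.3 * 37))
  expect_equal(sum(labels[a$test] == 2), round(0.3 * 63))
  expect_equal(sum(labels[a$test] == 3), 3)
})

test_that("confusion counts true/predicted pairs exactly", {
  perfect <- confusion(rep(1:3, times = c(5, 2, 4)), rep(1:3, times = c(5, 2, 4)), 3)
  expect_equal(perfect, diag(c(5, 2, 4)))

  all0 <- confusion(c(1L, 2L, 3L), c(1L, 1L, 1L), 3)
  expect_equal(all0[, 1], c(1, 1, 1))
  expect_true(all(all0[, 2:3] == 0))

  set.seed(50)
  true <- sample(1:4, 1000, replace = TRUE)
  pred <- sample(1:4, 1000, replace = TRUE)
  cm <- confusion(true, pred, 4)
  brute <- matrix(0L, 4, 4)
  for (i in seq_along(true))
    brute[true[i], pred[i]] <- brute[true[i], pred[i]] + 1L
  expect_equal(cm, brute)
  expect_equal(sum(cm), 1000)

  expect_error(confusion(c(1L, 5L), c(1L, 1L), 4), "1..4")
})

test_that("assemble_training_set labels picksets by sorted class name", {
  dir <- tempdir()
  files <- character(0)
  for (cls in c("zeta", "alpha")) {
    locs <- random_locs(50, group = rep(0:4, each = 10))
    path <- file.path(dir, paste0("asm-", cls, ".hdf5"))
    write_locs(locs, loc_metadata(32, 32), path)
    files[cls] <- path
  }
  asm <- assemble_training_set(files)
  expect_length(asm$picksets, 10)
  expect_equal(asm$label_map, c("alpha", "zeta"))
  expect_equal(asm$labels, rep(1:2, each = 5))

  expect_error(assemble_training_set(files[1]), "2 classes")
  dup <- files; names(dup) <- c("x", "x")
  expect_error(assemble_training_set(dup), "duplicate")

  nogroup <- file.path(dir, "asm-nogroup.hdf5")
  write_locs(random_locs(10), loc_metadata(32, 32), nogroup)
  expect_error(assemble_training_set(c(a = nogroup, b = files[[1]])), "group")
})

test_that("run_training produces a consistent report on simulated data", {
  fx <- small_trained()
  rep <- fx$report
  C <- length(rep$label_map)
  expect_equal(dim(rep$confusion), c(C, C))
  expect_equal(sum(rep$confusion), rep$n_test_structures)
  # accuracy is the trace over the total of its own matrix
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  # augmenting only the training split: test total = structure count
  expect_equal(rep$n_test_structures,
               sum(vapply(fx$class_files, function(f) {
                 length(groups_to_picksets(read_locs(f)$locs)$picksets)
               }, numeric(1))) - rep$n_train_structures)
  expect_equal(rep$n_train_images,
               rep$n_train_structures * rep$config$n_angles)
  # per-class recall consistent with the matrix
  expect_equal(unname(rep$recall),
               unname(diag(rep$confusion) / rowSums(rep$confusion)))
})

test_that("run_training is deterministic and writes its artifacts", {
  sim <- simulate_dataset(n_per_class = 4L, cfg = sim_config(seed = 77L),
                          out_dir = file.path(tempdir(), "rt-det"))
  cf <- split_by_truth(sim, file.path(tempdir(), "rt-det", "classes"))
  out1 <- file.path(tempdir(), "rt-det", "o1")
  r1 <- run_training(cf, hidden = 20L, n_angles = 2L,
                     tcfg = train_config(max_epochs = 15L, seed = 5L),
                     seed = 5L, out_dir = out1)
  r2 <- run_training(cf, hidden = 20L, n_angles = 2L,
                     tcfg = train_config(max_epochs = 15L, seed = 5L),
                     seed = 5L)
  expect_identical(r1$report$confusion, r2$report$confusion)
  expect_identical(r1$model$W, r2$model$W)
  expect_identical(r1$report$learning_curve, r2$report$learning_curve)
  for (f in c("model.hdf5", "report.yaml", "confusion.csv",
              "learning_curve.csv"))
    expect_true(file.exists(file.path(out1, f)), label = f)
})
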