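# The "train model" workflow: labeled picksets from annotated files ->
# structure-level stratified 70/30 split -> rotation-augment the training
# split only -> render -> train MLP -> learning curve + confusion matrix.

#' Assemble labeled picksets from annotated localization files
#'
#' Each class contributes one file whose `group` column partitions its
#' localizations into structures; every group becomes one labeled pickset.
#' Classes are indexed in sorted-name order, which defines the label map.
#'
#' @param class_files Named character vector or list: class name -> path of a
#'   grouped localization HDF5 file.
#' @return List with `picksets` (list of data.frames), `labels` (1-based
#'   integer class per pickset), `label_map` (class names in index order) and
#'   `meta` (metadata of the first file).
#' @export
assemble_training_set <- function(class_files) {
  class_files <- unlist(class_files)
  if (length(class_files) < 2L)
    stop("training requires at least 2 classes, got ", length(class_files))
  if (anyDuplicated(names(class_files)))
    stop("duplicate class names: ",
         paste(unique(names(class_files)[duplicated(names(class_files))]),
               collapse = ", "))
  label_map <- sort(names(class_files))
  picksets <- list(); labels <- integer(0); meta <- NULL
  for (ci in seq_along(label_map)) {
    cls <- label_map[ci]
    ds <- read_locs(class_files[[cls]])
    if (is.null(meta)) meta <- ds$meta
    if (!"group" %in% names(ds$locs))
      stop("file for class '", cls, "' has no group column; annotate it first")
    parts <- groups_to_picksets(ds$locs)
    picksets <- c(picksets, parts$picksets)
    labels <- c(labels, rep(ci, length(parts$picksets)))
  }
  list(picksets = picksets, labels = labels, label_map = label_map, meta = meta)
}

#' Stratified train/test split at the structure level
#'
#' Per class, `round(class size * test_fraction)` structures (at least 1) go
#' to the test set; the split is drawn before any augmentation, so rotated
#' copies of one structure can never straddle the boundary. Order within each
#' side is a seeded shuffle; the same seed reproduces the same partition.
#'
#' @param labels Integer class label per item (structure).
#' @param test_fraction Fraction of each class withheld for testing
#'   (default 0.3).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   union = all items).
#' @export
split_train_test <- function(labels, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 structures to split; class(es) ",
         paste(names(counts)[counts < 2], collapse = ", "), " have fewer")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- integer(0)
  for (cls in names(counts)) {
    idx <- which(as.character(labels) == cls)
    n_test <- min(max(1L, round(length(idx) * test_fraction)), length(idx) - 1L)
    test <- c(test, sample(idx, n_test))
  }
  train <- setdiff(seq_along(labels), test)
  list(train = sample(train), test = sample(test))
}

#' Confusion matrix from true and predicted labels
#'
#' @param true,predicted 1-based integer class labels of equal length.
#' @param C Number of classes.
#' @param label_map Optional class names for dimnames.
#' @return `C x C` integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(true, predicted, C, label_map = NULL) {
  stopifnot(length(true) == length(predicted))
  if (any(true < 1 | true > C) || any(predicted < 1 | predicted > C))
    stop("labels must lie in 1..", C)
  m <- matrix(tabulate((true - 1L) * C + predicted, nbins = C * C),
              nrow = C, ncol = C, byrow = TRUE)
  if (!is.null(label_map)) dimnames(m) <- list(true = label_map,
                                               predicted = label_map)
  m
}

report_from_confusion <- function(cm) {
  total <- sum(cm)
  diag_ <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, diag_ / colSums(cm), NA_real_)
  recall <- ifelse(rowSums(cm) > 0, diag_ / rowSums(cm), NA_real_)
  list(accuracy = if (total > 0) sum(diag_) / total else NA_real_,
       precision = precision, recall = recall)
}

#' Run the full training workflow
#'
#' Assemble labeled picksets, split 70/30 stratified at structure level,
#' rotation-augment the training split only, render both splits with one
#' render configuration, train the MLP, and evaluate on the untouched test
#' structures. Fully seeded; the same configuration reproduces the same
#' model and report.
#'
#' @param class_files Named vector: class name -> grouped localization file.
#' @param render_cfg A [render_config()].
#' @param hidden Hidden layer sizes (1-3 entries).
#' @param tcfg A [train_config()].
#' @param n_angles Rotation-augmentation steps for the training split
#'   (default 1 = no augmentation; raise it when structure orientations
#'   vary, as they do on real surfaces).
#' @param test_fraction Held-out fraction of structures per class.
#' @param seed Seed for the split (training uses `tcfg$seed`).
#' @param out_dir Optional output directory; when given, writes
#'   `model.hdf5`, `report.yaml`, `confusion.csv`, `learning_curve.csv` and
#'   `learning_curve.png`.
#' @return List with `model` (an `mlp_model` carrying `label_map` and
#'   `render_config`) and `report` (accuracy, confusion matrix, per-class
#'   precision/recall, learning curve, configs, seed).
#' @export
run_training <- function(class_files, render_cfg = render_config(),
                         hidden = c(100L), tcfg = train_config(),
                         n_angles = 1L, test_fraction = 0.3, seed = 1L,
                         out_dir = NULL) {
  asm <- tryCatch(assemble_training_set(class_files),
                  error = function(e) stop("assemble: ", conditionMessage(e)))
  split <- tryCatch(split_train_test(asm$labels, test_fraction, seed),
                    error = function(e) stop("split: ", conditionMessage(e)))
  train_aug <- augment_set(asm$picksets[split$train], asm$labels[split$train],
                           cfg = render_cfg, n_angles = n_angles)
  test_plain <- augment_set(asm$picksets[split$test], asm$labels[split$test],
                            cfg = render_cfg, n_angles = 1L)
  Xtr <- flatten_images(train_aug$images)
  Xte <- flatten_images(test_plain$images)
  model <- tryCatch(mlp_train(Xtr, train_aug$labels, hidden = hidden, tcfg = tcfg),
                    error = function(e) stop("train: ", conditionMessage(e)))
  model$label_map <- asm$label_map
  model$render_config <- render_cfg
  pred <- mlp_predict(model, Xte)
  cm <- confusion(test_plain$labels, pred$class, C = length(asm$label_map),
                  label_map = asm$label_map)
  stats <- report_from_confusion(cm)
  report <- list(accuracy = stats$accuracy, confusion = cm,
                 precision = stats$precision, recall = stats$recall,
                 learning_curve = model$training_history,
                 n_train_structures = length(split$train),
                 n_test_structures = length(split$test),
                 n_train_images = nrow(Xtr),
                 label_map = asm$label_map,
                 config = list(render = unclass(render_cfg), hidden = hidden,
                               train = unclass(tcfg), n_angles = n_angles,
                               test_fraction = test_fraction, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(out_dir, "model.hdf5"))
    utils::write.csv(as.data.frame(cm), file.path(out_dir, "confusion.csv"))
    utils::write.csv(model$training_history,
                     file.path(out_dir, "learning_curve.csv"), row.names = FALSE)
    yaml_report <- report
    yaml_report$confusion <- apply(cm, 1, as.integer, simplify = FALSE)
    yaml_report$learning_curve <- NULL
    yaml::write_yaml(yaml_report, file.path(out_dir, "report.yaml"))
    plot_learning_curve(model$training_history,
                        file.path(out_dir, "learning_curve.png"))
  }
  list(model = model, report = report)
}

plot_learning_curve <- function(history, path) {
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(history$epoch, history$train_loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "cross-entropy loss (nats)",
                 main = "learning curve")
  if (any(is.finite(history$val_loss))) {
    graphics::lines(history$epoch, history$val_loss, lty = 2, lwd = 2)
    graphics::legend("topright", c("training", "validation"),
                     lty = c(1, 2), lwd = 2)
  }
  invisible(path)
}
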