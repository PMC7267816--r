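# Plug-and-play inference: classify every pick of a new dataset with a saved
# model and export one localization file per predicted class. The pick is
# atomic — a structure is classified as a whole, never per localization.

#' Classify every pick of a dataset
#'
#' Picks come either from a pick file (`picks`) or from the table's `group`
#' column. Each pick is rendered with the model's frozen render settings and
#' classified. Picks with fewer than `min_locs` localizations are reported as
#' `unclassified:too_few_locs`; predictions whose winning probability falls
#' below `min_probability` as `unclassified:low_confidence`.
#'
#' @param locs Localization data.frame.
#' @param model An `mlp_model` with `label_map` and `render_config` set.
#' @param picks Optional `pick_set`; when `NULL` the `group` column is used.
#' @param min_probability Confidence threshold in `[0, 1]` (default 0.5).
#' @param min_locs Minimum localizations per pick (default 10).
#' @return A data.frame with one row per pick: `pick_id`, `class` (class
#'   name or an `unclassified:*` tag), `probability`, `n_locs`. The
#'   localization row indices of each pick are attached as attribute
#'   `members` (a list, aligned with rows) for lossless export.
#' @export
classify_dataset <- function(locs, model, picks = NULL, min_probability = 0.5,
                             min_locs = 10L) {
  if (is.null(model$render_config))
    stop("model carries no render settings; retrain or load a complete bundle")
  if (is.null(model$label_map))
    stop("model carries no label map; retrain or load a complete bundle")
  if (model$layer_sizes[1] != model$render_config$image_size^2)
    stop("render settings disagree with the model input size (",
         model$render_config$image_size, "^2 != ", model$layer_sizes[1], ")")
  if (is.null(picks)) {
    if (!"group" %in% names(locs))
      stop("no pick file given and the table has no group column")
    grouped <- which(!is.na(locs$group))
    ids <- sort(unique(locs$group[grouped]))
    members <- lapply(ids, function(g) grouped[locs$group[grouped] == g])
    pick_ids <- as.integer(ids)
    pick_rows <- NULL
  } else {
    members <- lapply(seq_len(nrow(picks)), function(i) {
      p <- picks[i, ]
      r2 <- (p$diameter / 2)^2
      which((locs$x - p$center_x)^2 + (locs$y - p$center_y)^2 <= r2)
    })
    pick_ids <- picks$pick_id
    pick_rows <- picks
  }
  n_picks <- length(members)
  cls <- character(n_picks)
  prob <- rep(NA_real_, n_picks)
  n_locs <- lengths(members)
  classify_idx <- which(n_locs >= min_locs)
  cls[n_locs < min_locs] <- "unclassified:too_few_locs"
  if (length(classify_idx) > 0) {
    images <- lapply(classify_idx, function(i) {
      pick <- if (is.null(pick_rows)) NULL else pick_rows[i, , drop = FALSE]
      render_pick(locs[members[[i]], , drop = FALSE], pick, model$render_config)
    })
    pred <- mlp_predict(model, flatten_images(images))
    prob[classify_idx] <- pred$probability
    label <- model$label_map[pred$class]
    label[pred$probability < min_probability] <- "unclassified:low_confidence"
    cls[classify_idx] <- label
  }
  out <- data.frame(pick_id = pick_ids, class = cls, probability = prob,
                    n_locs = as.integer(n_locs), stringsAsFactors = FALSE)
  attr(out, "members") <- members
  attr(out, "settings") <- list(min_probability = min_probability,
                                min_locs = as.integer(min_locs),
                                layer_sizes = model$layer_sizes)
  out
}

#' Export classified localizations, one file per class
#'
#' Writes one standard localization HDF5+YAML per predicted class holding the
#' union of that class's picks, with the `group` column rewritten to
#' consecutive per-file pick indices (0-based). All `unclassified:*` picks
#' land in `unclassified.hdf5`. Provenance records the thresholds used. A
#' `predictions.csv` table accompanies the files.
#'
#' @param locs Localization data.frame the predictions refer to.
#' @param meta The table's [loc_metadata()].
#' @param predictions Output of [classify_dataset()] (with its `members`
#'   attribute intact).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector: class name -> file path (including an
#'   `"unclassified"` entry when any pick was unclassified).
#' @export
export_by_class <- function(locs, meta, predictions, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  members <- attr(predictions, "members")
  if (is.null(members))
    stop("predictions lack the pick-membership attribute; ",
         "pass the object returned by classify_dataset")
  target <- ifelse(startsWith(predictions$class, "unclassified:"),
                   "unclassified", predictions$class)
  paths <- character(0)
  for (cls in unique(target)) {
    rows <- which(target == cls)
    pieces <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      sub <- locs[members[[rows[k]]], , drop = FALSE]
      sub$group <- rep(k - 1L, nrow(sub))
      pieces[[k]] <- sub
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) {
      out <- locs[0, , drop = FALSE]
      out$group <- integer(0)
    }
    rownames(out) <- NULL
    path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", cls), ".hdf5"))
    settings <- attr(predictions, "settings") %||% list()
    write_locs(out, meta, path,
               provenance = c(list(Operation = "export_by_class", Class = cls,
                                   Picks = length(rows)), settings))
    paths[cls] <- path
  }
  if (!"unclassified" %in% names(paths)) {
    out <- locs[0, , drop = FALSE]
    out$group <- integer(0)
    path <- file.path(out_dir, "unclassified.hdf5")
    write_locs(out, meta, path,
               provenance = list(Operation = "export_by_class",
                                 Class = "unclassified", Picks = 0L))
    paths["unclassified"] <- path
  }
  utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  paths
}
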