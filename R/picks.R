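# Circular pick regions: each pick groups the localizations of one candidate
# structure. Pick files carry a list of centers and one global diameter, the
# convention of the upstream SMLM toolchain.

#' Read a pick file
#'
#' @param path YAML file with keys `Centers` (list of `[x, y]` in camera px),
#'   `Diameter` (camera px) and `Shape: Circle`.
#' @return A `pick_set` data.frame with columns `pick_id` (0-based, assigned
#'   in file order), `center_x`, `center_y` and `diameter`.
#' @export
read_picks <- function(path) {
  if (!file.exists(path)) stop("pick file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$Diameter)) stop("pick file '", path, "' lacks a Diameter")
  d <- as.numeric(doc$Diameter)
  if (!is.finite(d) || d <= 0) stop("pick Diameter must be > 0, got ", doc$Diameter)
  centers <- doc$Centers %||% list()
  n <- length(centers)
  cx <- vapply(centers, function(c) as.numeric(c[[1]]), numeric(1))
  cy <- vapply(centers, function(c) as.numeric(c[[2]]), numeric(1))
  pick_set(cx, cy, d)
}

#' Build a pick set from center coordinates
#'
#' @param center_x,center_y Pick centers in camera px.
#' @param diameter Single pick diameter in camera px, shared by all picks.
#' @return A `pick_set` data.frame; ids run 0, 1, ... in input order.
#' @export
pick_set <- function(center_x, center_y, diameter) {
  stopifnot(length(center_x) == length(center_y),
            is.numeric(diameter), length(diameter) == 1, diameter > 0)
  structure(data.frame(pick_id = seq_along(center_x) - 1L,
                       center_x = as.numeric(center_x),
                       center_y = as.numeric(center_y),
                       diameter = rep(as.numeric(diameter), length(center_x))),
            class = c("pick_set", "data.frame"))
}

#' Write a pick set to a YAML pick file
#'
#' @param picks A `pick_set` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_picks <- function(picks, path) {
  doc <- list(Centers = lapply(seq_len(nrow(picks)),
                               function(i) c(picks$center_x[i], picks$center_y[i])),
              Diameter = picks$diameter[1] %||% NA_real_,
              Shape = "Circle")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Extract the localizations inside one circular pick
#'
#' Membership uses the closed disc: a localization at distance exactly
#' `diameter / 2` from the center is included. Record order is preserved.
#'
#' @param locs Localization data.frame.
#' @param pick One row of a `pick_set` (or any list with `center_x`,
#'   `center_y`, `diameter`).
#' @return The subset data.frame (possibly empty).
#' @export
extract_pick <- function(locs, pick) {
  r2 <- (pick$diameter / 2)^2
  dx <- locs$x - pick$center_x
  dy <- locs$y - pick$center_y
  locs[dx * dx + dy * dy <= r2, , drop = FALSE]
}

#' Partition a grouped localization table by group id
#'
#' @param locs Localization data.frame with a `group` column.
#' @return A list with `picksets` (named list of data.frames, names are the
#'   group ids in increasing order) and `n_ungrouped` (records whose group is
#'   `NA`, excluded from the partition).
#' @export
groups_to_picksets <- function(locs) {
  if (!"group" %in% names(locs))
    stop("localization table has no 'group' column; annotate or supply picks")
  grouped <- !is.na(locs$group)
  sub <- locs[grouped, , drop = FALSE]
  ids <- sort(unique(sub$group))
  picksets <- lapply(ids, function(g) sub[sub$group == g, , drop = FALSE])
  names(picksets) <- as.character(ids)
  list(picksets = picksets, n_ungrouped = sum(!grouped))
}
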