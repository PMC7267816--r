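#' @useDynLib smlmclassify, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Columns every localization table must carry; `group` is optional.
LOC_REQUIRED_COLS <- c("frame", "x", "y", "photons", "sx", "sy", "bg", "lpx", "lpy")
LOC_DATASET_NAME <- "locs"

#' Construct acquisition metadata for a localization file
#'
#' @param width,height Field size in camera pixels.
#' @param pixel_size_nm Physical size of one camera pixel in nanometres
#'   (optional; required by the simulator).
#' @param provenance List of free-form history entries (named lists), one per
#'   processing step that touched the file.
#' @return A `loc_metadata` list.
#' @export
loc_metadata <- function(width, height, pixel_size_nm = NULL, provenance = list()) {
  stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0)
  if (!is.null(pixel_size_nm)) stopifnot(is.numeric(pixel_size_nm), pixel_size_nm > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 pixel_size_nm = if (is.null(pixel_size_nm)) NULL else as.numeric(pixel_size_nm),
                 provenance = provenance),
            class = "loc_metadata")
}

empty_metadata <- function() {
  structure(list(width = NA_real_, height = NA_real_, pixel_size_nm = NULL,
                 provenance = list()),
            class = "loc_metadata")
}

sidecar_path <- function(path) paste0(sub("\\.[hH][dD][fF]5$", "", path), ".yaml")

# Multi-document YAML stream helpers. Document 1 is acquisition metadata,
# every later document is one provenance entry.
read_yaml_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- grep("^---\\s*$", lines)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(lines))
  docs <- list()
  for (i in seq_along(starts)) {
    if (ends[i] < starts[i]) next
    chunk <- lines[seq.int(starts[i], ends[i])]
    if (length(chunk) == 0 || all(grepl("^\\s*$", chunk))) next
    docs[[length(docs) + 1L]] <- yaml::yaml.load(paste(chunk, collapse = "\n"))
  }
  docs
}

write_yaml_stream <- function(docs, path) {
  txt <- vapply(docs, function(d) yaml::as.yaml(d), character(1))
  writeLines(paste(txt, collapse = "---\n"), path, sep = "")
  invisible(path)
}

meta_to_doc <- function(meta) {
  doc <- list(Width = meta$width, Height = meta$height)
  if (!is.null(meta$pixel_size_nm)) doc$`Pixel size (nm)` <- meta$pixel_size_nm
  doc
}

doc_to_meta <- function(doc, provenance) {
  w <- doc$Width %||% NA_real_
  h <- doc$Height %||% NA_real_
  structure(list(width = as.numeric(w), height = as.numeric(h),
                 pixel_size_nm = if (is.null(doc$`Pixel size (nm)`)) NULL
                                 else as.numeric(doc$`Pixel size (nm)`),
                 provenance = provenance),
            class = "loc_metadata")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a localization table and its metadata sidecar
#'
#' Reads the standard SMLM dialect: an HDF5 file with a compound record table
#' under dataset `locs` (one record per fitted emitter) plus a same-stem
#' `.yaml` sidecar whose first document holds the acquisition metadata and
#' whose later documents are provenance entries.
#'
#' @param path Path to the `.hdf5` localization file.
#' @return A list with elements `locs` (data.frame, one row per localization,
#'   columns at least `frame, x, y, photons, sx, sy, bg, lpx, lpy`, plus
#'   `group` when present in the file) and `meta` (a [loc_metadata()] list).
#'   A missing `group` column is simply absent, never invented. A missing or
#'   malformed sidecar downgrades to empty metadata with a warning.
#' @export
read_locs <- function(path) {
  if (!file.exists(path)) stop("localization file not found: ", path)
  cols <- h5_read_table_(path, LOC_DATASET_NAME)
  locs <- as.data.frame(cols, optional = TRUE)
  missing <- setdiff(LOC_REQUIRED_COLS, names(locs))
  if (length(missing) > 0)
    stop("localization file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  sc <- sidecar_path(path)
  meta <- empty_metadata()
  if (!file.exists(sc)) {
    warning("metadata sidecar not found for '", path, "'; returning empty metadata")
  } else {
    docs <- tryCatch(read_yaml_stream(sc), error = function(e) NULL)
    if (is.null(docs) || length(docs) == 0) {
      warning("malformed metadata sidecar '", sc, "'; returning empty metadata")
    } else {
      meta <- doc_to_meta(docs[[1]], provenance = docs[-1])
    }
  }
  list(locs = locs, meta = meta)
}

#' Write a localization table with its metadata sidecar
#'
#' Validates the table, writes the HDF5 record table plus the YAML sidecar,
#' and appends exactly one provenance entry describing this write.
#'
#' @param locs Localization data.frame (see [read_locs()] for columns).
#' @param meta A [loc_metadata()] list.
#' @param path Output `.hdf5` path; the sidecar lands next to it.
#' @param provenance Optional named list merged into the appended provenance
#'   entry (e.g. the generating operation and its parameters).
#' @return `path`, invisibly.
#' @export
write_locs <- function(locs, meta, path, provenance = list()) {
  problems <- validate_locs(locs, meta)
  if (length(problems) > 0)
    stop("invalid localization table: ", paste(problems, collapse = "; "))
  out <- locs
  out$frame <- as.integer(out$frame)
  if ("group" %in% names(out)) out$group <- as.integer(out$group)
  for (nm in names(out))
    if (!is.integer(out[[nm]])) out[[nm]] <- as.numeric(out[[nm]])
  h5_write_table_(path, as.list(out), names(out), LOC_DATASET_NAME)
  entry <- c(list(Generated_by = "smlmclassify: write_locs",
                  Records = nrow(locs)), provenance)
  docs <- c(list(meta_to_doc(meta)), meta$provenance, list(entry))
  write_yaml_stream(docs, sidecar_path(path))
  invisible(path)
}

#' Validate a localization table against its metadata
#'
#' Checks the table invariants: required columns present, numeric fields
#' finite, `frame`/`group` integral and non-negative, `photons` non-negative,
#' and coordinates inside the field `[0, width] x [0, height]` when the
#' metadata carries a field size. Validation reports, it never raises.
#'
#' @param locs Localization data.frame.
#' @param meta A [loc_metadata()] list (field size may be `NA` to skip the
#'   bounds check).
#' @return Character vector of violation descriptions; empty when the table
#'   is valid. Each violation names the field, the first offending record and
#'   the rule.
#' @export
validate_locs <- function(locs, meta = empty_metadata()) {
  out <- character(0)
  if (!is.data.frame(locs)) return("locs is not a data.frame")
  missing <- setdiff(LOC_REQUIRED_COLS, names(locs))
  if (length(missing) > 0)
    out <- c(out, paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  bad1 <- function(ok, field, rule) {
    if (all(ok)) return(character(0))
    i <- which(!ok)[1]
    paste0("field '", field, "', record ", i, " (of ", sum(!ok), "): ", rule)
  }
  num_cols <- intersect(c("x", "y", "photons", "sx", "sy", "bg", "lpx", "lpy"),
                        names(locs))
  for (nm in num_cols)
    out <- c(out, bad1(is.finite(locs[[nm]]), nm, "must be finite"))
  if ("photons" %in% names(locs))
    out <- c(out, bad1(!is.finite(locs$photons) | locs$photons >= 0,
                       "photons", "must be >= 0"))
  if ("frame" %in% names(locs)) {
    f <- locs$frame
    out <- c(out, bad1(is.finite(f) & f >= 0 & f == floor(f),
                       "frame", "must be a non-negative integer"))
  }
  if ("group" %in% names(locs)) {
    g <- locs$group
    ok <- is.na(g) | (is.finite(g) & g >= 0 & g == floor(g))
    out <- c(out, bad1(ok, "group", "must be a non-negative integer or NA"))
  }
  if (is.finite(meta$width) && "x" %in% names(locs))
    out <- c(out, bad1(!is.finite(locs$x) | (locs$x >= 0 & locs$x <= meta$width),
                       "x", paste0("must lie in [0, ", meta$width, "]")))
  if (is.finite(meta$height) && "y" %in% names(locs))
    out <- c(out, bad1(!is.finite(locs$y) | (locs$y >= 0 & locs$y <= meta$height),
                       "y", paste0("must lie in [0, ", meta$height, "]")))
  out
}
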