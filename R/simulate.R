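# Ground-truth DNA-PAINT simulator. Binding-site patterns (digits on a
# 3 x 5 cell grid, rectangular lattices) are stamped across a synthetic
# field; each functional site emits a Poisson number of localizations spread
# by Gaussian localization noise; uniform background is added on top.
# Blinking kinetics are deliberately collapsed to "events per site ~
# Poisson": classification consumes only positional histograms, so per-frame
# on/off binding adds nothing downstream. Frames are assigned uniformly for
# format fidelity.

# Binary masks on a 3-wide x 5-tall cell grid; a lit cell is one docking
# site. These layouts are this package's own designs — any digit-like set
# with >= 3 pairwise differing sites separates equally well.
DIGIT_MASKS <- list(
  digit1 = matrix(c(0, 1, 0,
                    1, 1, 0,
                    0, 1, 0,
                    0, 1, 0,
                    1, 1, 1), nrow = 5, byrow = TRUE),
  digit2 = matrix(c(1, 1, 1,
                    0, 0, 1,
                    1, 1, 1,
                    1, 0, 0,
                    1, 1, 1), nrow = 5, byrow = TRUE),
  digit3 = matrix(c(1, 1, 1,
                    0, 0, 1,
                    0, 1, 1,
                    0, 0, 1,
                    1, 1, 1), nrow = 5, byrow = TRUE)
)

#' Rectangular grid binding-site pattern
#'
#' The classic origami test pattern: sites on a `rows x cols` lattice with
#' fixed spacing, centered at the origin. The default is the 20-nm grid
#' (4 rows x 3 columns, 20 nm pitch).
#'
#' @param rows,cols Lattice size (>= 1 each).
#' @param spacing_nm Lattice constant in nm (> 0).
#' @param name Pattern/class name.
#' @return A `pattern_spec`: `name` plus `sites`, an `n x 2` matrix of site
#'   coordinates in nm relative to the pattern center.
#' @export
make_grid_pattern <- function(rows = 4L, cols = 3L, spacing_nm = 20,
                              name = "grid20") {
  stopifnot(rows >= 1, cols >= 1, spacing_nm > 0)
  xs <- (seq_len(cols) - (cols + 1) / 2) * spacing_nm
  ys <- (seq_len(rows) - (rows + 1) / 2) * spacing_nm
  sites <- as.matrix(expand.grid(x = xs, y = ys))
  pattern_spec(name, sites)
}

#' Digit binding-site pattern
#'
#' Sites are the lit cells of a fixed 3 x 5 binary mask per digit, at a
#' 20-nm cell pitch by default, centered at the origin.
#'
#' @param digit 1, 2 or 3.
#' @param pitch_nm Cell pitch in nm.
#' @return A `pattern_spec`.
#' @export
make_digit_pattern <- function(digit, pitch_nm = 20) {
  key <- paste0("digit", digit)
  if (!key %in% names(DIGIT_MASKS))
    stop("unsupported digit '", digit, "'; available: 1, 2, 3")
  mask <- DIGIT_MASKS[[key]]
  lit <- which(mask == 1, arr.ind = TRUE)  # row = y cell, col = x cell
  sites <- cbind(x = (lit[, "col"] - 2) * pitch_nm,
                 y = (lit[, "row"] - 3) * pitch_nm)
  pattern_spec(key, sites)
}

pattern_spec <- function(name, sites) {
  sites <- as.matrix(sites)
  stopifnot(nrow(sites) >= 1, all(is.finite(sites)), ncol(sites) == 2)
  colnames(sites) <- c("x", "y")
  rownames(sites) <- NULL
  structure(list(name = name, sites = sites), class = "pattern_spec")
}

#' The four default demonstration patterns
#'
#' Digits 1, 2, 3 and the 20-nm grid — the standard mixed-origami test field.
#'
#' @return Named list of `pattern_spec` objects.
#' @export
default_patterns <- function() {
  pats <- c(lapply(1:3, make_digit_pattern), list(make_grid_pattern()))
  names(pats) <- vapply(pats, `[[`, character(1), "name")
  pats
}

#' Simulator configuration
#'
#' Defaults describe a typical DNA-PAINT experiment on surface-immobilized
#' origami: 130-nm camera pixels, 5 nm localization precision, 30 binding
#' events per functional site on average, 80% labeling efficiency, 0.5
#' background localizations per square micrometre, 10,000 frames, picks of
#' 1.5 camera px diameter.
#'
#' @param pixel_size_nm Camera pixel size in nm.
#' @param precision_nm Localization precision sigma in nm.
#' @param mean_events_per_site Poisson mean of localizations per kept site.
#' @param labeling_efficiency Per-site Bernoulli retention probability.
#' @param background_rate Background localizations per square micrometre.
#' @param n_frames Movie length in frames.
#' @param width,height Field size in camera px; `NULL` sizes the field to the
#'   requested structure count automatically.
#' @param pick_diameter Pick diameter in camera px.
#' @param random_orientation Rotate each structure's site pattern by a
#'   uniform random in-plane angle. Real surface-immobilized origami adsorb
#'   at arbitrary orientations (the reason rotation augmentation exists);
#'   the default `FALSE` keeps all structures co-oriented, which makes the
#'   four demo classes linearly separable in rendered-image space — the
#'   benchmark condition. Enable it to emulate the harder realistic case.
#' @param seed RNG seed driving the whole simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(pixel_size_nm = 130, precision_nm = 5,
                       mean_events_per_site = 30, labeling_efficiency = 0.8,
                       background_rate = 0.5, n_frames = 10000L,
                       width = NULL, height = NULL, pick_diameter = 1.5,
                       random_orientation = FALSE, seed = 1L) {
  stopifnot(pixel_size_nm > 0, precision_nm >= 0, mean_events_per_site >= 0,
            labeling_efficiency >= 0, labeling_efficiency <= 1,
            background_rate >= 0, n_frames >= 1, pick_diameter > 0)
  structure(list(pixel_size_nm = pixel_size_nm, precision_nm = precision_nm,
                 mean_events_per_site = mean_events_per_site,
                 labeling_efficiency = labeling_efficiency,
                 background_rate = background_rate,
                 n_frames = as.integer(n_frames),
                 width = width, height = height,
                 pick_diameter = pick_diameter,
                 random_orientation = isTRUE(random_orientation),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed ancillary-field distributions (documented constants): photon counts
# lognormal around ~2000, PSF width ~0.85 px with mild spread, background
# ~Gamma with mean 40 photons, reported precision = true sigma in px with
# 20% spread. These only need to look plausible; nothing downstream fits
# them.
sim_ancillary <- function(n, cfg) {
  lp <- cfg$precision_nm / cfg$pixel_size_nm
  data.frame(photons = stats::rlnorm(n, log(2000), 0.3),
             sx = stats::rnorm(n, 0.85, 0.05),
             sy = stats::rnorm(n, 0.85, 0.05),
             bg = stats::rgamma(n, shape = 4, scale = 10),
             lpx = pmax(lp, 1e-4) * stats::runif(n, 0.8, 1.2),
             lpy = pmax(lp, 1e-4) * stats::runif(n, 0.8, 1.2))
}

#' Simulate the localizations of one structure
#'
#' Each binding site survives with probability `labeling_efficiency`; a
#' surviving site emits `Poisson(mean_events_per_site)` localizations at the
#' site position plus isotropic Gaussian noise of `precision_nm`, converted
#' to camera px and offset to `center_px`. Frames are uniform over the
#' movie. Uses the current RNG state (seed at the dataset level).
#'
#' @param pattern A `pattern_spec`.
#' @param center_px Structure center `(x, y)` in camera px.
#' @param cfg A [sim_config()].
#' @return Localization data.frame (without `group`; the caller assigns it).
#' @export
simulate_structure <- function(pattern, center_px, cfg = sim_config()) {
  sites <- pattern$sites
  if (cfg$random_orientation %||% FALSE) {
    th <- stats::runif(1, 0, 2 * pi)
    sites <- cbind(x = cos(th) * sites[, "x"] - sin(th) * sites[, "y"],
                   y = sin(th) * sites[, "x"] + cos(th) * sites[, "y"])
  }
  kept <- which(stats::runif(nrow(sites)) < cfg$labeling_efficiency)
  counts <- if (length(kept) > 0)
    stats::rpois(length(kept), cfg$mean_events_per_site) else integer(0)
  n <- sum(counts)
  if (n == 0) {
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
    return(cbind(out, sim_ancillary(0, cfg)))
  }
  site_x <- rep(sites[kept, "x"], counts)
  site_y <- rep(sites[kept, "y"], counts)
  x_nm <- site_x + stats::rnorm(n, 0, cfg$precision_nm)
  y_nm <- site_y + stats::rnorm(n, 0, cfg$precision_nm)
  out <- data.frame(frame = sample.int(cfg$n_frames, n, replace = TRUE) - 1L,
                    x = center_px[1] + x_nm / cfg$pixel_size_nm,
                    y = center_px[2] + y_nm / cfg$pixel_size_nm)
  cbind(out, sim_ancillary(n, cfg))
}

#' Simulate a mixed-class dataset and write it to disk
#'
#' Places `n_per_class` structures per pattern on a jittered grid (spacing 3
#' pick diameters, jitter up to 0.5 diameters, so picks can never overlap),
#' assigns classes to positions in a seeded shuffle, adds uniform background
#' localizations at `background_rate`, and writes the standard localization
#' HDF5+YAML (with 0-based `group` ids; background records carry `NA`), a
#' pick YAML (one circle per structure) and a ground-truth CSV
#' (`group,class`).
#'
#' @param patterns List of `pattern_spec` objects (default: the four demo
#'   patterns).
#' @param n_per_class Structures per pattern.
#' @param cfg A [sim_config()]; `cfg$seed` drives everything.
#' @param out_dir Output directory.
#' @param basename Stem for the localization file (default `"simulated"`).
#' @return List with `locs_path`, `pick_path`, `truth_path`, the `truth`
#'   data.frame, `meta`, and bookkeeping: `n_structure_locs` (per-structure
#'   counts, by group id) and `n_background`.
#' @export
simulate_dataset <- function(patterns = default_patterns(), n_per_class = 50L,
                             cfg = sim_config(), out_dir = tempdir(),
                             basename = "simulated") {
  if (is.null(names(patterns)))
    names(patterns) <- vapply(patterns, `[[`, character(1), "name")
  n_total <- length(patterns) * n_per_class
  spacing <- 3 * cfg$pick_diameter
  n_cols <- ceiling(sqrt(n_total))
  n_rows <- ceiling(n_total / n_cols)
  width <- cfg$width %||% ceiling(spacing * (n_cols + 1))
  height <- cfg$height %||% ceiling(spacing * (n_rows + 1))
  if (width < spacing * (n_cols + 1) - 1e-9 ||
      height < spacing * (n_rows + 1) - 1e-9)
    stop("field ", width, " x ", height, " px is too small for ", n_total,
         " structures at spacing ", spacing, " px")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  # jittered grid of structure centers, row-major
  idx <- seq_len(n_total) - 1L
  gx <- (idx %% n_cols) + 1L
  gy <- (idx %/% n_cols) + 1L
  jitter_max <- 0.5 * cfg$pick_diameter
  cx <- gx * spacing + stats::runif(n_total, -jitter_max, jitter_max)
  cy <- gy * spacing + stats::runif(n_total, -jitter_max, jitter_max)

  class_of <- sample(rep(names(patterns), each = n_per_class))
  pieces <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sub <- simulate_structure(patterns[[class_of[i]]], c(cx[i], cy[i]), cfg)
    sub$group <- if (nrow(sub) > 0) rep(i - 1L, nrow(sub)) else integer(0)
    pieces[[i]] <- sub
  }
  n_structure_locs <- vapply(pieces, nrow, integer(1))

  area_um2 <- (width * cfg$pixel_size_nm / 1000) *
              (height * cfg$pixel_size_nm / 1000)
  n_bg <- stats::rpois(1, cfg$background_rate * area_um2)
  if (n_bg > 0) {
    bg <- data.frame(frame = sample.int(cfg$n_frames, n_bg, replace = TRUE) - 1L,
                     x = stats::runif(n_bg, 0, width),
                     y = stats::runif(n_bg, 0, height))
    bg <- cbind(bg, sim_ancillary(n_bg, cfg))
    bg$group <- rep(NA_integer_, n_bg)
    pieces[[n_total + 1L]] <- bg
  }
  locs <- do.call(rbind, pieces)
  rownames(locs) <- NULL

  meta <- loc_metadata(width, height, pixel_size_nm = cfg$pixel_size_nm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locs_path <- file.path(out_dir, paste0(basename, ".hdf5"))
  write_locs(locs, meta, locs_path,
             provenance = list(Operation = "simulate_dataset",
                               Patterns = paste(names(patterns), collapse = ","),
                               Structures_per_class = n_per_class,
                               Seed = cfg$seed))
  picks <- pick_set(cx, cy, cfg$pick_diameter)
  pick_path <- file.path(out_dir, "picks.yaml")
  write_picks(picks, pick_path)
  truth <- data.frame(group = idx, class = class_of, stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)

  list(locs_path = locs_path, pick_path = pick_path, truth_path = truth_path,
       truth = truth, picks = picks, meta = meta,
       n_structure_locs = n_structure_locs, n_background = n_bg)
}

#' Write one grouped localization file per class from a simulated dataset
#'
#' Convenience for assembling a training set: splits a simulated mixed file
#' by ground-truth class and renumbers groups per file, giving exactly the
#' per-class annotated files [assemble_training_set()] expects.
#'
#' @param sim Return value of [simulate_dataset()].
#' @param out_dir Output directory.
#' @return Named character vector: class name -> file path.
#' @export
split_by_truth <- function(sim, out_dir) {
  ds <- read_locs(sim$locs_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cls in sort(unique(sim$truth$class))) {
    groups <- sim$truth$group[sim$truth$class == cls]
    sub <- ds$locs[!is.na(ds$locs$group) & ds$locs$group %in% groups, ,
                   drop = FALSE]
    sub$group <- match(sub$group, sort(unique(sub$group))) - 1L
    rownames(sub) <- NULL
    path <- file.path(out_dir, paste0(cls, ".hdf5"))
    write_locs(sub, ds$meta, path,
               provenance = list(Operation = "split_by_truth", Class = cls))
    paths[cls] <- path
  }
  paths
}
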