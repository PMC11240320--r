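#' Parameters for a synthetic multiplex immunofluorescence scene
#'
#' A synthetic tissue core contains disk-shaped cells of five classes: the
#' four CD3+ T-cell subsets (helper/cytotoxic, CD57- early / CD57+ late
#' differentiation stage) and "other" nucleated cells. Each cell has a
#' filled nuclear disk (nuclear counterstain channel) and, depending on its
#' class, membrane rings in the CD3/CD8/CD57 channels. Default subset
#' frequencies follow typical tumor-rich lymphoma tissue, where T-helper
#' cells of early differentiation stage dominate the T-cell compartment and
#' CD57+ subsets are rare (roughly 4.9%, 2.5%, 0.5% and 0.7% of nucleated
#' cells for TH_57neg, TC_57neg, TH_57pos and TC_57pos).
#'
#' @param image_height,image_width image size in pixels.
#' @param n_cells number of cells to place.
#' @param subset_probs probability vector over classes
#'   `c(TH_57neg, TC_57neg, TH_57pos, TC_57pos, other)`; must sum to 1.
#' @param cell_radius_range numeric length-2, min/max cell radius (pixels).
#' @param background_level baseline background intensity (fraction of the
#'   full 16-bit scale, in `[0, 1]`).
#' @param background_gradient_amplitude amplitude of a smooth low-frequency
#'   background gradient (same units).
#' @param background_noise_sd standard deviation of per-pixel Gaussian
#'   background noise.
#' @param marker_intensity mean stain intensity of nuclei and marker rings.
#' @param intensity_jitter_sd per-cell Gaussian jitter of stain intensity.
#' @param min_separation extra pixels added to the minimum center distance
#'   of `2 * max(cell_radius_range)` so that rasterized cells are strictly
#'   disjoint.
#' @param pixel_size physical pixel size in micrometers.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_height = 512L,
                         image_width = 512L,
                         n_cells = 300L,
                         subset_probs = c(TH_57neg = 0.049,
                                          TC_57neg = 0.025,
                                          TH_57pos = 0.005,
                                          TC_57pos = 0.007,
                                          other    = 0.914),
                         cell_radius_range = c(5, 8),
                         background_level = 0.05,
                         background_gradient_amplitude = 0.03,
                         background_noise_sd = 0.01,
                         marker_intensity = 0.6,
                         intensity_jitter_sd = 0.05,
                         min_separation = 2,
                         pixel_size = 0.5,
                         seed = 1L) {
  stopifnot_scalar_number(image_height, "image_height", 16)
  stopifnot_scalar_number(image_width, "image_width", 16)
  stopifnot_scalar_number(n_cells, "n_cells", 0)
  if (length(subset_probs) != 5L || any(subset_probs < 0)) {
    stop("'subset_probs' must be 5 non-negative probabilities", call. = FALSE)
  }
  if (abs(sum(subset_probs) - 1) > 1e-9) {
    stop("'subset_probs' must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (length(cell_radius_range) != 2L || any(cell_radius_range <= 0) ||
      cell_radius_range[1] > cell_radius_range[2]) {
    stop("'cell_radius_range' must be positive with min <= max", call. = FALSE)
  }
  stopifnot_scalar_number(background_level, "background_level", 0, 1)
  stopifnot_scalar_number(background_gradient_amplitude,
                          "background_gradient_amplitude", 0, 1)
  stopifnot_scalar_number(background_noise_sd, "background_noise_sd", 0)
  stopifnot_scalar_number(marker_intensity, "marker_intensity", 0)
  stopifnot_scalar_number(intensity_jitter_sd, "intensity_jitter_sd", 0)
  stopifnot_scalar_number(seed, "seed")
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            n_cells = as.integer(n_cells),
            subset_probs = setNames(as.numeric(subset_probs), CELL_CLASSES),
            cell_radius_range = as.numeric(cell_radius_range),
            background_level = background_level,
            background_gradient_amplitude = background_gradient_amplitude,
            background_noise_sd = background_noise_sd,
            marker_intensity = marker_intensity,
            intensity_jitter_sd = intensity_jitter_sd,
            min_separation = min_separation,
            pixel_size = pixel_size,
            seed = as.integer(seed))
  structure(p, class = "scene_params")
}

# Rejection-sampling placement of cell centers with a hard minimum pairwise
# distance, using a uniform occupancy grid (cell width = min distance) so
# that only the 3x3 neighborhood has to be checked per candidate.
place_centers <- function(n, height, width, margin, min_dist,
                          max_attempts = NULL) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  max_attempts <- max_attempts %||% max(20000L, 400L * n)
  gx <- function(v) pmax(1L, pmin(ncell_x, ceiling(v / min_dist)))
  gy <- function(v) pmax(1L, pmin(ncell_y, ceiling(v / min_dist)))
  ncell_y <- max(1L, ceiling(height / min_dist))
  ncell_x <- max(1L, ceiling(width / min_dist))
  grid <- vector("list", ncell_y * ncell_x)
  centers <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  attempts <- 0L
  lo_r <- 1 + margin; hi_r <- height - margin
  lo_c <- 1 + margin; hi_c <- width - margin
  if (lo_r >= hi_r || lo_c >= hi_c) {
    stop("image too small for the requested cell radius", call. = FALSE)
  }
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, lo_r, hi_r)
    c <- runif(1, lo_c, hi_c)
    gi <- gy(r); gj <- gx(c)
    ok <- TRUE
    for (di in -1:1) {
      ii <- gi + di
      if (ii < 1L || ii > ncell_y) next
      for (dj in -1:1) {
        jj <- gj + dj
        if (jj < 1L || jj > ncell_x) next
        pts <- grid[[(jj - 1L) * ncell_y + ii]]
        if (is.null(pts)) next
        d2 <- (centers[pts, 1] - r)^2 + (centers[pts, 2] - c)^2
        if (any(d2 < min_dist^2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(r, c)
      idx <- (gj - 1L) * ncell_y + gi
      grid[[idx]] <- c(grid[[idx]], placed)
    }
  }
  if (placed < n) {
    stop(sprintf(
      "could not place %d non-overlapping cells (achieved %d after %d attempts); reduce n_cells or enlarge the image",
      n, placed, attempts), call. = FALSE)
  }
  centers
}

# Pixel index sets for a filled disk and an annulus around (r0, c0).
disk_pixels <- function(r0, c0, radius, height, width, inner = 0) {
  rr <- max(1L, floor(r0 - radius)):min(height, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(width, ceiling(c0 + radius))
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - r0)^2 + (g$col - c0)^2
  keep <- d2 <= radius^2 & d2 >= inner^2
  cbind(row = g$row[keep], col = g$col[keep])
}

#' Generate a synthetic multiplex immunofluorescence scene
#'
#' Places `n_cells` non-overlapping disk-like cells, draws a filled nuclear
#' disk (60% of the cell radius) per cell in the nuclear channel and
#' membrane rings in the CD3/CD8/CD57 channels according to each cell's
#' class, and adds a smooth background gradient plus Gaussian noise. The
#' returned scene carries pixel-exact ground truth: an instance label mask
#' over whole cells and a truth table of centroids and class labels.
#'
#' Class to marker map: `TH_57neg` = CD3; `TC_57neg` = CD3+CD8;
#' `TH_57pos` = CD3+CD57; `TC_57pos` = CD3+CD8+CD57; `other` = none.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `image_scene`: a list with `channels` (named
#'   list of numeric matrices `nuclear`, `CD3`, `CD8`, `CD57`),
#'   `pixel_size`, `truth_mask` (whole-cell integer label matrix,
#'   0 = background), `truth_nuclei_mask` (nucleus-disk labels, for
#'   evaluating nuclei segmentation) and `truth_table` (data.frame
#'   `cell_id`, `row`, `col`, `class`, `radius`). Coordinates are 1-based
#'   (row, col).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  h <- params$image_height; w <- params$image_width
  n <- params$n_cells
  rmax <- params$cell_radius_range[2]
  centers <- place_centers(n, h, w, margin = rmax + 1,
                           min_dist = 2 * rmax + params$min_separation)
  radii <- runif(n, params$cell_radius_range[1], params$cell_radius_range[2])
  classes <- if (n > 0) {
    sample(CELL_CLASSES, n, replace = TRUE, prob = params$subset_probs)
  } else character(0)

  # smooth low-frequency gradient: tilted plane plus one sinusoidal mode
  rowv <- seq_len(h) / h
  colv <- seq_len(w) / w
  gradient <- params$background_gradient_amplitude *
    (outer(rowv, colv, function(r, c) {
      0.5 * (r + c) / 2 + 0.5 * sin(pi * r) * cos(pi * c)
    }))
  make_bg <- function() {
    bg <- params$background_level + gradient
    if (params$background_noise_sd > 0) {
      bg <- bg + matrix(rnorm(h * w, 0, params$background_noise_sd), h, w)
    }
    pmax(bg, 0)
  }
  channels <- list(nuclear = make_bg(), CD3 = make_bg(),
                   CD8 = make_bg(), CD57 = make_bg())

  truth_mask <- matrix(0L, h, w)
  truth_nuclei_mask <- matrix(0L, h, w)
  if (n > 0) {
    jitter <- rnorm(n, 0, params$intensity_jitter_sd)
    for (i in seq_len(n)) {
      r0 <- centers[i, 1]; c0 <- centers[i, 2]
      rad <- radii[i]
      amp <- max(params$marker_intensity + jitter[i], 0.05)
      cell_px <- disk_pixels(r0, c0, rad, h, w)
      truth_mask[cell_px] <- i
      nuc_px <- disk_pixels(r0, c0, 0.6 * rad, h, w)
      truth_nuclei_mask[nuc_px] <- i
      channels$nuclear[nuc_px] <- channels$nuclear[nuc_px] + amp
      markers <- CLASS_MARKER_MAP[[classes[i]]]
      if (length(markers)) {
        ring_px <- disk_pixels(r0, c0, rad, h, w, inner = 0.7 * rad)
        for (m in markers) {
          channels[[m]][ring_px] <- channels[[m]][ring_px] + amp
        }
      }
    }
  }
  truth_table <- data.frame(
    cell_id = seq_len(n),
    row = if (n > 0) centers[, 1] else numeric(0),
    col = if (n > 0) centers[, 2] else numeric(0),
    class = factor(classes, levels = CELL_CLASSES),
    radius = radii
  )
  structure(list(channels = channels,
                 pixel_size = params$pixel_size,
                 truth_mask = truth_mask,
                 truth_nuclei_mask = truth_nuclei_mask,
                 truth_table = truth_table,
                 params = params),
            class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  cat(sprintf("image_scene: %d x %d px, %d cells\n",
              nrow(x$channels$nuclear), ncol(x$channels$nuclear),
              nrow(x$truth_table)))
  if (nrow(x$truth_table)) print(table(x$truth_table$class))
  invisible(x)
}

#' Write a scene's channels, truth mask and truth table to disk
#'
#' Channels are written as single-channel 16-bit TIFFs (intensities clipped
#' to `[0, 1]`), the truth mask as a 16-bit label TIFF and the truth table
#' as CSV.
#'
#' @param scene an `image_scene`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "image_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (ch in names(scene$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    img <- pmin(pmax(scene$channels[[ch]], 0), 1)
    tiff::writeTIFF(img, p, bits.per.sample = 16L)
    paths[ch] <- p
  }
  mp <- file.path(dir, sprintf("%s_truth_mask.tif", prefix))
  write_mask(label_mask(scene$truth_mask, "truth", scene$pixel_size), mp)
  paths["truth_mask"] <- mp
  np <- file.path(dir, sprintf("%s_truth_nuclei_mask.tif", prefix))
  write_mask(label_mask(scene$truth_nuclei_mask, "truth_nuclei",
                        scene$pixel_size), np)
  paths["truth_nuclei_mask"] <- np
  tp <- file.path(dir, sprintf("%s_truth_table.csv", prefix))
  write.csv(scene$truth_table, tp, row.names = FALSE)
  paths["truth_table"] <- tp
  invisible(paths)
}
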