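#' Marker presence per nucleus by centroid overlap
#'
#' For each nucleus instance, its centroid (unweighted mean of nucleus pixel
#' coordinates, rounded half-up to the nearest pixel) is looked up in each
#' marker mask; the marker is present iff the marker mask has a positive
#' label at that pixel. Border pixels belong to their object, so a centroid
#' landing exactly on an object's edge counts as inside. No intensity is
#' re-measured: presence is purely mask membership.
#'
#' @param nuclei a [label_mask()] of nucleus instances.
#' @param marker_masks named list of [label_mask()]s; names must include
#'   `CD3`, `CD8`, `CD57`. All masks must share the nucleus mask's shape.
#' @return data.frame with one row per nucleus: `cell_id`, `row`, `col`
#'   (1-based centroid pixel), logical `cd3`, `cd8`, `cd57`.
#' @export
marker_presence <- function(nuclei, marker_masks) {
  stopifnot(inherits(nuclei, "label_mask"))
  if (!all(MARKER_CHANNELS %in% names(marker_masks))) {
    stop("marker_masks must contain CD3, CD8 and CD57", call. = FALSE)
  }
  dm <- dim(nuclei$labels)
  for (m in MARKER_CHANNELS) {
    stopifnot(inherits(marker_masks[[m]], "label_mask"))
    if (!identical(dim(marker_masks[[m]]$labels), dm)) {
      stop(sprintf("mask shape mismatch: %s is %s, nuclei are %s", m,
                   paste(dim(marker_masks[[m]]$labels), collapse = "x"),
                   paste(dm, collapse = "x")), call. = FALSE)
    }
  }
  ids <- mask_ids(nuclei)
  if (!length(ids)) {
    return(data.frame(cell_id = integer(0), row = integer(0),
                      col = integer(0), cd3 = logical(0), cd8 = logical(0),
                      cd57 = logical(0)))
  }
  pos <- which(nuclei$labels > 0L)
  lab <- nuclei$labels[pos]
  rr <- (pos - 1L) %% dm[1] + 1L
  cc <- (pos - 1L) %/% dm[1] + 1L
  # round half-up, clamped to the image
  cent_r <- pmin(pmax(floor(tapply(rr, lab, mean) + 0.5), 1L), dm[1])
  cent_c <- pmin(pmax(floor(tapply(cc, lab, mean) + 0.5), 1L), dm[2])
  ord <- match(as.character(ids), names(cent_r))
  cent_r <- as.integer(cent_r[ord]); cent_c <- as.integer(cent_c[ord])
  at <- cbind(cent_r, cent_c)
  data.frame(cell_id = ids, row = cent_r, col = cent_c,
             cd3 = marker_masks$CD3$labels[at] > 0L,
             cd8 = marker_masks$CD8$labels[at] > 0L,
             cd57 = marker_masks$CD57$labels[at] > 0L)
}

#' Classify nucleated cells into T-cell subsets from marker flags
#'
#' The classification rule is a pure function of the three flags. CD3 gates
#' T-cell identity: CD3- cells are `other` regardless of CD8/CD57 (helper
#' T cells are defined by absence of CD8 on CD3+ cells; double-negative
#' T cells are rare enough to neglect). Among CD3+ cells, CD8 splits
#' cytotoxic (`TC`) from helper (`TH`) and CD57 splits late (`57pos`) from
#' early (`57neg`) differentiation stage.
#'
#' @param flags data.frame as returned by [marker_presence()].
#' @param core_id,patient_id,region annotations attached to every cell.
#' @return a `cell_table`: data.frame with columns `cell_id`, `row`, `col`,
#'   `cd3`, `cd8`, `cd57`, `class` (factor over the five classes),
#'   `core_id`, `patient_id`, `region`.
#' @export
classify_cells <- function(flags, core_id = "core1", patient_id = "patient1",
                           region = "tumor-rich") {
  req <- c("cell_id", "cd3", "cd8", "cd57")
  if (!all(req %in% names(flags))) {
    stop("flags must contain cell_id, cd3, cd8 and cd57", call. = FALSE)
  }
  if (anyDuplicated(flags$cell_id)) {
    stop("cell_ids must be unique within a core", call. = FALSE)
  }
  cls <- classify_rule(flags$cd3, flags$cd8, flags$cd57)
  out <- data.frame(cell_id = flags$cell_id,
                    row = flags$row %||% NA_integer_,
                    col = flags$col %||% NA_integer_,
                    cd3 = as.logical(flags$cd3),
                    cd8 = as.logical(flags$cd8),
                    cd57 = as.logical(flags$cd57),
                    class = cls,
                    core_id = core_id, patient_id = patient_id,
                    region = region)
  class(out) <- c("cell_table", "data.frame")
  out
}

# Total function on the flag space.
classify_rule <- function(cd3, cd8, cd57) {
  cls <- ifelse(!cd3, "other",
         ifelse(cd8 & !cd57, "TC_57neg",
         ifelse(!cd8 & !cd57, "TH_57neg",
         ifelse(cd8 & cd57, "TC_57pos", "TH_57pos"))))
  factor(cls, levels = CELL_CLASSES)
}

#' Segment and classify a scene end to end
#'
#' Convenience wrapper: nuclei and marker segmentation, centroid-overlap
#' marker presence and classification. Ground-truth masks can be supplied
#' instead of running the stand-in segmenter (e.g. imported masks).
#'
#' @param scene an `image_scene`.
#' @param core_id,patient_id,region annotations for the output table.
#' @param use_truth_masks if `TRUE`, phenotype directly on the scene's
#'   ground-truth instance masks instead of segmenting.
#' @param ... passed to [segment_nuclei()] and [segment_marker()].
#' @return a `cell_table` (see [classify_cells()]).
#' @export
phenotype_scene <- function(scene, core_id = "core1", patient_id = "patient1",
                            region = "tumor-rich", use_truth_masks = FALSE,
                            ...) {
  stopifnot(inherits(scene, "image_scene"))
  if (use_truth_masks) {
    masks <- truth_masks(scene)
    nuclei <- masks$nuclei
    marker_masks <- masks[MARKER_CHANNELS]
  } else {
    nuclei <- segment_nuclei(scene$channels$nuclear,
                             pixel_size = scene$pixel_size, ...)
    marker_masks <- lapply(MARKER_CHANNELS, function(m) {
      segment_marker(scene$channels[[m]], channel_name = m,
                     pixel_size = scene$pixel_size, ...)
    })
    names(marker_masks) <- MARKER_CHANNELS
  }
  flags <- marker_presence(nuclei, marker_masks)
  classify_cells(flags, core_id = core_id, patient_id = patient_id,
                 region = region)
}

#' Ground-truth instance masks for a synthetic scene
#'
#' Derives per-channel ground-truth label masks from a scene's truth masks
#' and truth table: the nucleus mask holds every cell's nucleus disk, each
#' marker mask keeps the whole-cell objects of the cells whose class
#' carries that marker.
#'
#' @param scene an `image_scene` with ground truth.
#' @return named list of [label_mask()]s: `nuclei`, `CD3`, `CD8`, `CD57`.
#' @export
truth_masks <- function(scene) {
  stopifnot(inherits(scene, "image_scene"))
  tm <- scene$truth_mask
  out <- list(nuclei = label_mask(scene$truth_nuclei_mask, "nuclear",
                                  scene$pixel_size))
  for (m in MARKER_CHANNELS) {
    carries <- vapply(as.character(scene$truth_table$class),
                      function(cl) m %in% CLASS_MARKER_MAP[[cl]], logical(1))
    ids <- scene$truth_table$cell_id[carries]
    mm <- tm
    mm[!(mm %in% ids)] <- 0L
    out[[m]] <- label_mask(mm, m, scene$pixel_size)
  }
  out
}
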