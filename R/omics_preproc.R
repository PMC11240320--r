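#' Construct an AOI-level expression container
#'
#' Wraps an analytes x AOIs matrix with analyte and AOI annotations in a
#' [SummarizedExperiment::SummarizedExperiment]. A `transform_state` flag in
#' the object metadata (`raw` -> `area_scaled` -> `normalized`) enforces the
#' preprocessing order: area scaling requires raw counts, normalization
#' requires area-scaled values, and each step refuses to run twice.
#'
#' @param values non-negative numeric matrix, analytes in rows, AOIs in
#'   columns.
#' @param analyte_info data.frame with columns `analyte` and
#'   `is_negative_control`, one row per matrix row.
#' @param aoi_info data.frame with columns `aoi_id`, `patient`, `region`,
#'   `cell_type`, `area`, `nuclei_count`, one row per matrix column.
#' @param transform_state one of `raw`, `area_scaled`, `normalized`.
#' @return a `SummarizedExperiment` with assay `exprs`.
#' @export
expression_matrix <- function(values, analyte_info, aoi_info,
                              transform_state = "raw") {
  stopifnot(is.matrix(values))
  if (transform_state == "raw" && any(values < 0)) {
    stop("raw expression values must be non-negative", call. = FALSE)
  }
  req <- c("aoi_id", "patient", "region", "cell_type", "area", "nuclei_count")
  if (!all(req %in% names(aoi_info))) {
    stop("aoi_info must contain ", paste(req, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("analyte", "is_negative_control") %in% names(analyte_info)),
            nrow(analyte_info) == nrow(values),
            nrow(aoi_info) == ncol(values))
  if (anyDuplicated(analyte_info$analyte)) {
    stop("duplicate analyte labels", call. = FALSE)
  }
  rownames(values) <- analyte_info$analyte
  colnames(values) <- aoi_info$aoi_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(analyte_info, row.names = analyte_info$analyte),
    colData = S4Vectors::DataFrame(aoi_info, row.names = aoi_info$aoi_id))
  S4Vectors::metadata(se)$transform_state <- transform_state
  se
}

transform_state <- function(se) {
  S4Vectors::metadata(se)$transform_state %||% "raw"
}

`transform_state<-` <- function(se, value) {
  S4Vectors::metadata(se)$transform_state <- value
  se
}

exprs_values <- function(se) SummarizedExperiment::assay(se, "exprs")

#' AOI quality control on nuclei counts
#'
#' AOIs sampling too few cells are unreliable and are dropped: the limit of
#' detection is 20 cells per AOI for protein panels and 100 cells for
#' transcript panels (inclusive bounds: an AOI at exactly the limit is
#' kept).
#'
#' @param se expression container from [expression_matrix()].
#' @param modality `"protein"` or `"rna"`.
#' @param min_cells_protein,min_cells_rna the two thresholds.
#' @return list with `data` (filtered container) and `report` (data.frame
#'   of dropped AOIs with their nuclei counts).
#' @export
aoi_qc <- function(se, modality = c("protein", "rna"),
                   min_cells_protein = 20L, min_cells_rna = 100L) {
  modality <- match.arg(modality)
  threshold <- switch(modality, protein = min_cells_protein,
                      rna = min_cells_rna)
  nuclei <- SummarizedExperiment::colData(se)$nuclei_count
  if (is.null(nuclei)) stop("nuclei counts missing", call. = FALSE)
  keep <- nuclei >= threshold
  n_drop <- sum(!keep)
  report <- data.frame(
    aoi_id = colnames(se)[!keep],
    nuclei_count = nuclei[!keep],
    threshold = rep(threshold, n_drop),
    modality = rep(modality, n_drop))
  list(data = se[, keep], report = report)
}

#' Scale expression by AOI collection area
#'
#' Divides each AOI's column by its collection area (square micrometers),
#' removing the proportionality of raw counts to sampled area. Only valid
#' on raw counts; the state machine raises if applied twice.
#'
#' @param se raw-state expression container.
#' @return area-scaled container.
#' @export
area_scale <- function(se) {
  if (transform_state(se) != "raw") {
    stop("area_scale requires raw counts (state is '",
         transform_state(se), "')", call. = FALSE)
  }
  area <- SummarizedExperiment::colData(se)$area
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("AOI areas must be positive", call. = FALSE)
  }
  SummarizedExperiment::assay(se, "exprs") <-
    sweep(exprs_values(se), 2, area, "/")
  transform_state(se) <- "area_scaled"
  se
}

#' Cyclic loess normalization within strata
#'
#' Removes intensity-dependent trends between AOIs: values are log2
#' transformed (pseudo-count 1) and, for every pair of AOIs within a
#' stratum, a loess curve of M (log difference) on A (log average) is
#' fitted and half of the fitted trend subtracted from each member;
#' repeated for `iterations` passes (delegated to
#' [limma::normalizeCyclicLoess()], pairwise method). Normalization runs
#' independently within each stratum — by default T-cell-subset AOIs and
#' tumor-cell (CD20) AOIs are normalized separately, so differing cell
#' sizes cannot leak across compartments. Each stratum's grand mean is
#' restored after normalization so the procedure only redistributes signal
#' between AOIs.
#'
#' @param se area-scaled expression container.
#' @param span loess span, default 0.7.
#' @param iterations number of cyclic passes, default 3.
#' @param group_by name of the `colData` column defining strata, or a
#'   factor of length `ncol(se)`. The default `"compartment"` splits
#'   CD20 AOIs from all T-cell AOIs.
#' @return normalized container (assay on the log2 scale).
#' @export
cyclic_loess_normalize <- function(se, span = 0.7, iterations = 3L,
                                   group_by = "compartment") {
  if (transform_state(se) != "area_scaled") {
    stop("cyclic_loess_normalize requires area-scaled values (state is '",
         transform_state(se), "')", call. = FALSE)
  }
  if (ncol(se) < 2L) stop("need at least 2 AOIs to normalize", call. = FALSE)
  cd <- SummarizedExperiment::colData(se)
  strata <- if (is.character(group_by) && length(group_by) == 1L) {
    if (group_by == "compartment") {
      factor(ifelse(cd$cell_type == "CD20", "CD20", "T"))
    } else {
      factor(cd[[group_by]])
    }
  } else factor(group_by)
  stopifnot(length(strata) == ncol(se))
  lg <- log2(exprs_values(se) + 1)
  out <- lg
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) next
    block <- lg[, idx, drop = FALSE]
    gm <- mean(block)
    norm <- limma::normalizeCyclicLoess(block, span = span,
                                        iterations = iterations,
                                        method = "pairs")
    out[, idx] <- norm - mean(norm) + gm
  }
  SummarizedExperiment::assay(se, "exprs") <- out
  transform_state(se) <- "normalized"
  se
}

#' Signal-to-noise ratio against negative-control probes
#'
#' `SNR(analyte, AOI) = value / geometric mean of the negative-control
#' probes in that AOI`. Because numerator and denominator share any
#' column-wise factor, the SNR is invariant to area scaling. Requires a
#' linear-scale matrix (raw or area-scaled) with at least one
#' negative-control probe.
#'
#' @param se raw or area-scaled expression container.
#' @return numeric matrix of SNR values for the non-control analytes.
#' @export
compute_snr <- function(se) {
  if (!transform_state(se) %in% c("raw", "area_scaled")) {
    stop("SNR must be computed on a linear-scale matrix (raw or area_scaled)",
         call. = FALSE)
  }
  ctrl <- SummarizedExperiment::rowData(se)$is_negative_control
  if (sum(ctrl) < 1L) {
    stop("at least one negative-control probe is required", call. = FALSE)
  }
  v <- exprs_values(se)
  geo <- exp(colMeans(log(v[ctrl, , drop = FALSE])))
  if (any(!is.finite(geo)) || any(geo == 0)) {
    stop("negative-control geometric mean is zero or undefined in some AOI",
         call. = FALSE)
  }
  sweep(v[!ctrl, , drop = FALSE], 2, geo, "/")
}

#' Filter transcripts by signal-to-noise ratio across patients
#'
#' An analyte is removed iff, in every one of the named cell types, more
#' than `max_fraction` of patients have SNR below `snr_min` (both
#' inequalities strict). "Across patients" is evaluated on patient-level
#' SNR: by default the mean SNR over a patient's AOIs of that cell type
#' (`aggregate = "patient_mean"`); `aggregate = "aoi"` instead counts
#' individual AOIs.
#'
#' @param snr SNR matrix from [compute_snr()].
#' @param aoi_info data.frame with `patient` and `cell_type` per SNR
#'   column (e.g. `colData` of the container).
#' @param cell_types cell types that must all fail for removal; default all
#'   cell types present.
#' @param snr_min SNR threshold, default 1.05.
#' @param max_fraction patient-fraction threshold, default 0.25.
#' @param aggregate `"patient_mean"` or `"aoi"`.
#' @return an object of class `filter_report`: list with `kept`, `removed`
#'   (analyte label vectors), `fraction_below` (analytes x cell types
#'   matrix of patient fractions with SNR < `snr_min`) and the thresholds.
#' @export
filter_transcripts <- function(snr, aoi_info, cell_types = NULL,
                               snr_min = 1.05, max_fraction = 0.25,
                               aggregate = c("patient_mean", "aoi")) {
  aggregate <- match.arg(aggregate)
  aoi_info <- as.data.frame(aoi_info)
  stopifnot(all(c("patient", "cell_type") %in% names(aoi_info)),
            nrow(aoi_info) == ncol(snr))
  if (is.null(cell_types)) cell_types <- unique(aoi_info$cell_type)
  missing_ct <- setdiff(cell_types, aoi_info$cell_type)
  if (length(missing_ct)) {
    stop("cell type(s) absent from the data: ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  frac <- matrix(NA_real_, nrow = nrow(snr), ncol = length(cell_types),
                 dimnames = list(rownames(snr), cell_types))
  for (ct in cell_types) {
    cols <- which(aoi_info$cell_type == ct)
    if (aggregate == "patient_mean") {
      pat <- factor(aoi_info$patient[cols])
      # patient-level mean SNR, then the fraction of patients below snr_min
      pm <- t(apply(snr[, cols, drop = FALSE], 1, function(x) {
        tapply(x, pat, mean)
      }))
      frac[, ct] <- rowMeans(pm < snr_min)
    } else {
      frac[, ct] <- rowMeans(snr[, cols, drop = FALSE] < snr_min)
    }
  }
  removed <- rownames(snr)[apply(frac > max_fraction, 1, all)]
  kept <- setdiff(rownames(snr), removed)
  structure(list(kept = kept, removed = removed, fraction_below = frac,
                 snr_min = snr_min, max_fraction = max_fraction,
                 cell_types = cell_types, aggregate = aggregate),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d kept, %d removed (SNR < %.2f in > %.0f%% of patients in all of: %s)\n",
    length(x$kept), length(x$removed), x$snr_min, 100 * x$max_fraction,
    paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Write an expression container as TSV plus annotation sidecars
#'
#' @param se expression container.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_expression <- function(se, dir, prefix = "expression") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  df <- data.frame(analyte = rownames(se), exprs_values(se),
                   check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  ap <- file.path(dir, paste0(prefix, "_aoi_annotations.csv"))
  write.csv(as.data.frame(SummarizedExperiment::colData(se)), ap,
            row.names = FALSE)
  rp <- file.path(dir, paste0(prefix, "_analytes.csv"))
  write.csv(as.data.frame(SummarizedExperiment::rowData(se)), rp,
            row.names = FALSE)
  invisible(c(matrix = mp, aoi = ap, analytes = rp))
}
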