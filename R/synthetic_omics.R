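#' Parameters for a synthetic AOI-level expression matrix
#'
#' Emulates spatial-profiler count matrices: analytes x AOIs (areas of
#' illumination), one AOI per patient x region x cell type, with log-normal
#' counts, per-(patient, analyte) random intercepts, AOI-area scaling
#' artifacts (raw counts are proportional to collection area, so area
#' scaling is recoverable), negative-control probes at a low baseline,
#' analytes planted at the control level (to exercise signal-to-noise
#' filtering) and planted region or patient-group log2 fold-changes.
#'
#' @param n_patients number of patients.
#' @param n_analytes number of non-control analytes (labeled `A001`, ...).
#' @param n_negative_controls number of negative-control probes
#'   (`NegProbe01`, ...).
#' @param cell_types AOI cell-type labels.
#' @param regions region labels; each patient gets one AOI per region x
#'   cell type.
#' @param baseline_log2,control_log2 mean log2 signal of ordinary analytes
#'   and of negative controls (per-analyte baselines jittered with sd
#'   `baseline_sd`).
#' @param baseline_sd sd of per-analyte baseline jitter (log2).
#' @param patient_sd sd of per-(patient, analyte) random intercepts (log2).
#' @param residual_sd sd of per-measurement residual noise (log2).
#' @param planted_effects data.frame (`analyte`, `cell_type`, `region`,
#'   `lfc`) adding `lfc` log2 units to that analyte in AOIs of that cell
#'   type and region; `cell_type`/`region` may be `"*"` for all.
#' @param low_snr_analytes analyte labels drawn at the negative-control
#'   baseline in every cell type (filter-recovery ground truth).
#' @param patient_groups optional named character vector (patient ->
#'   group label) for group-planted effects.
#' @param group_effects data.frame (`analyte`, `cell_type`, `group`,
#'   `lfc`) adding `lfc` to AOIs of patients in that group.
#' @param aoi_area_range,nuclei_count_range uniform sampling ranges for AOI
#'   collection area (square micrometers) and nuclei count.
#' @param seed integer seed.
#' @return an object of class `omics_sim_params`.
#' @export
omics_sim_params <- function(n_patients = 12L,
                             n_analytes = 60L,
                             n_negative_controls = 5L,
                             cell_types = c("T_H", "T_C", "CD20"),
                             regions = c("tumor-rich", "tumor-sparse"),
                             baseline_log2 = 6,
                             control_log2 = 2,
                             baseline_sd = 0.5,
                             patient_sd = 0.3,
                             residual_sd = 0.2,
                             planted_effects = NULL,
                             low_snr_analytes = character(0),
                             patient_groups = NULL,
                             group_effects = NULL,
                             aoi_area_range = c(5000, 20000),
                             nuclei_count_range = c(80L, 400L),
                             seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", 1)
  stopifnot_scalar_number(n_analytes, "n_analytes", 1)
  stopifnot_scalar_number(n_negative_controls, "n_negative_controls", 1)
  stopifnot_scalar_number(patient_sd, "patient_sd", 0)
  stopifnot_scalar_number(residual_sd, "residual_sd", 0)
  analytes <- sprintf("A%03d", seq_len(n_analytes))
  if (!all(low_snr_analytes %in% analytes)) {
    stop("low_snr_analytes must be a subset of the analyte labels", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    stopifnot(all(c("analyte", "cell_type", "region", "lfc") %in%
                    names(planted_effects)))
    if (!all(planted_effects$analyte %in% analytes)) {
      stop("planted analytes must be a subset of the analyte labels",
           call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_analytes = as.integer(n_analytes),
                 n_negative_controls = as.integer(n_negative_controls),
                 cell_types = cell_types, regions = regions,
                 baseline_log2 = baseline_log2, control_log2 = control_log2,
                 baseline_sd = baseline_sd, patient_sd = patient_sd,
                 residual_sd = residual_sd,
                 planted_effects = planted_effects,
                 low_snr_analytes = low_snr_analytes,
                 patient_groups = patient_groups,
                 group_effects = group_effects,
                 aoi_area_range = as.numeric(aoi_area_range),
                 nuclei_count_range = as.numeric(nuclei_count_range),
                 seed = as.integer(seed)),
            class = "omics_sim_params")
}

#' Generate a synthetic AOI-level expression matrix
#'
#' Signal model on the log2 scale: per-analyte baseline + per-(patient,
#' analyte) random intercept (sd `patient_sd`) + planted effects + residual
#' noise (sd `residual_sd`); linear-scale counts are `2^signal` multiplied
#' by the AOI's collection area. Negative-control probes and analytes
#' listed in `low_snr_analytes` use the control baseline. The result is a
#' raw-state [SummarizedExperiment::SummarizedExperiment] suitable for
#' [aoi_qc()], [area_scale()], [cyclic_loess_normalize()], [compute_snr()]
#' and [filter_transcripts()].
#'
#' @param params an [omics_sim_params()] object.
#' @return `SummarizedExperiment` with assay `exprs` (analytes x AOIs),
#'   `rowData` columns `analyte`, `is_negative_control`, `is_low_snr`, and
#'   `colData` columns `aoi_id`, `patient`, `region`, `cell_type`, `group`,
#'   `area`, `nuclei_count`.
#' @export
generate_expression <- function(params = omics_sim_params()) {
  stopifnot(inherits(params, "omics_sim_params"))
  set.seed(params$seed)
  analytes <- sprintf("A%03d", seq_len(params$n_analytes))
  controls <- sprintf("NegProbe%02d", seq_len(params$n_negative_controls))
  all_labels <- c(analytes, controls)
  if (anyDuplicated(all_labels)) stop("duplicate analyte labels", call. = FALSE)
  patients <- sprintf("P%02d", seq_len(params$n_patients))
  aoi <- expand.grid(patient = patients, region = params$regions,
                     cell_type = params$cell_types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  aoi <- aoi[order(aoi$patient, aoi$region, aoi$cell_type), , drop = FALSE]
  n_aoi <- nrow(aoi)
  aoi$aoi_id <- sprintf("AOI%03d", seq_len(n_aoi))
  aoi$area <- runif(n_aoi, params$aoi_area_range[1], params$aoi_area_range[2])
  aoi$nuclei_count <- as.integer(round(runif(
    n_aoi, params$nuclei_count_range[1], params$nuclei_count_range[2])))
  aoi$group <- if (!is.null(params$patient_groups)) {
    unname(params$patient_groups[aoi$patient])
  } else NA_character_

  n_feat <- length(all_labels)
  is_control <- all_labels %in% controls
  is_low <- all_labels %in% params$low_snr_analytes
  # ordinary analytes get per-analyte baseline jitter; negative controls
  # and planted low-SNR analytes sit exactly at the control baseline, so
  # SNR-filter recovery is exact when the noise terms are switched off
  baseline <- ifelse(is_control | is_low, params$control_log2,
                     params$baseline_log2 +
                       rnorm(n_feat, 0, params$baseline_sd))

  # per-(patient, analyte) random intercepts
  pat_eff <- matrix(rnorm(n_feat * params$n_patients, 0, params$patient_sd),
                    nrow = n_feat)
  colnames(pat_eff) <- patients

  log2sig <- matrix(baseline, nrow = n_feat, ncol = n_aoi)
  log2sig <- log2sig + pat_eff[, aoi$patient, drop = FALSE]
  add_effect <- function(analyte, cell_type, lfc, col_sel) {
    i <- match(analyte, all_labels)
    if (is.na(i)) stop("unknown analyte in effect table", call. = FALSE)
    sel <- col_sel & (cell_type == "*" | aoi$cell_type == cell_type)
    log2sig[i, sel] <<- log2sig[i, sel] + lfc
  }
  pe <- params$planted_effects
  if (!is.null(pe)) {
    for (k in seq_len(nrow(pe))) {
      add_effect(pe$analyte[k], pe$cell_type[k], pe$lfc[k],
                 pe$region[k] == "*" | aoi$region == pe$region[k])
    }
  }
  ge <- params$group_effects
  if (!is.null(ge)) {
    for (k in seq_len(nrow(ge))) {
      add_effect(ge$analyte[k], ge$cell_type[k], ge$lfc[k],
                 !is.na(aoi$group) & aoi$group == ge$group[k])
    }
  }
  if (params$residual_sd > 0) {
    log2sig <- log2sig + matrix(rnorm(n_feat * n_aoi, 0, params$residual_sd),
                                nrow = n_feat)
  }
  counts <- 2^log2sig * rep(aoi$area, each = n_feat)
  dimnames(counts) <- list(all_labels, aoi$aoi_id)
  expression_matrix(
    counts,
    analyte_info = data.frame(analyte = all_labels,
                              is_negative_control = is_control,
                              is_low_snr = is_low),
    aoi_info = aoi[, c("aoi_id", "patient", "region", "cell_type", "group",
                       "area", "nuclei_count")])
}
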