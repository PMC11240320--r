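# Stage seeds are derived from the global seed so each stochastic stage is
# independently reproducible; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% .Machine$integer.max)
}

#' Default pipeline configuration
#'
#' A small synthetic cohort exercising every stage: per patient one tissue
#' core imaged in four channels, with half the cohort given a T-cell-rich
#' composition (all four T-subset frequencies multiplied by
#' `tcell_rich_multiplier`); AOI-level expression with planted
#' patient-group markers (tied to the T-cell-rich group) and low-SNR
#' analytes; survival times driven by the image-derived CD3 frequency; and
#' a two-block (T-helper / T-cytotoxic expression) integration model
#' predicting the T-cell-rich group.
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory for stage tables and the manifest.
#' @return nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("timequant_run")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(images = TRUE, phenotyping = TRUE, metrics = TRUE,
                  evaluation = TRUE, omics = TRUE, stats = TRUE,
                  survival = TRUE, integration = TRUE),
    cohort = list(n_patients = 12L, cores_per_patient = 1L,
                  image_size = 384L, n_cells = 200L,
                  tcell_rich_fraction = 0.5, tcell_rich_multiplier = 2.5,
                  use_truth_masks = FALSE),
    omics = list(n_analytes = 40L, n_negative_controls = 5L,
                 n_low_snr = 4L, n_group_markers = 6L, group_lfc = 1.5,
                 n_region_markers = 4L, region_lfc = 1,
                 patient_sd = 0.3, residual_sd = 0.2),
    survival = list(baseline_hazard = 0.15, hazard_ratio = 3,
                    censor_rate = 0.2),
    integration = list(ncomp = 2L, keepX = 10L, cv_folds = 4L,
                       cv_repeats = 3L, n_permutations = 0L)
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Plain-text config with one section per stage; unspecified entries fall
#' back to [default_run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_run_config(seed = user$seed %||% 1L,
                               out_dir = user$out_dir %||%
                                 tempfile("timequant_run"))
  for (section in c("stages", "cohort", "omics", "survival", "integration")) {
    for (key in names(user[[section]])) {
      config[[section]][[key]] <- user[[section]][[key]]
    }
  }
  config
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort workflow
#'
#' Executes the enabled stages in dependency order — simulate images,
#' segment and phenotype, per-core and per-patient cell metrics, detection
#' evaluation against ground truth, expression simulation and
#' preprocessing (QC, area scaling, SNR filter, cyclic loess), mixed-model
#' differential expression, survival dichotomization, and multiblock
#' integration — writing each stage's tables under `config$out_dir` and a
#' manifest of output files with MD5 checksums. Outputs are pure functions
#' of (configuration, seed): rerunning with an identical configuration
#' reproduces identical checksums.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return list with `manifest` (data.frame stage/file/md5), `profiles`,
#'   `patient_profiles`, `detection`, `filter_report`, `diffexp`,
#'   `cutpoint`, `integration` — the in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0))
  add_output <- function(stage, path) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = basename(path)))
    path
  }
  result <- list()
  co <- config$cohort
  patients <- sprintf("P%02d", seq_len(co$n_patients))
  # first `tcell_rich_fraction` of patients get a T-cell-rich composition
  n_rich <- round(co$tcell_rich_fraction * co$n_patients)
  rich <- setNames(seq_len(co$n_patients) <= n_rich, patients)

  scenes <- NULL
  if (isTRUE(config$stages$images)) {
    base_probs <- scene_params()$subset_probs
    scenes <- list()
    k <- 0L
    for (p in patients) {
      probs <- base_probs
      if (rich[[p]]) {
        probs[TCELL_SUBSETS] <- probs[TCELL_SUBSETS] * co$tcell_rich_multiplier
        probs["other"] <- 1 - sum(probs[TCELL_SUBSETS])
      }
      for (core in seq_len(co$cores_per_patient)) {
        k <- k + 1L
        id <- sprintf("%s_core%d", p, core)
        scenes[[id]] <- generate_scene(scene_params(
          image_height = co$image_size, image_width = co$image_size,
          n_cells = co$n_cells, subset_probs = probs,
          seed = derive_seed(config$seed, k)))
      }
    }
    truth <- do.call(rbind, lapply(names(scenes), function(id) {
      cbind(core = id, scenes[[id]]$truth_table)
    }))
    add_output("images", write_stage_csv(truth, out_dir, "truth_tables.csv"))
  }

  cells <- NULL
  if (isTRUE(config$stages$phenotyping)) {
    if (is.null(scenes)) stop("phenotyping requires the images stage", call. = FALSE)
    cells <- do.call(rbind, lapply(names(scenes), function(id) {
      p <- sub("_core.*", "", id)
      phenotype_scene(scenes[[id]], core_id = id, patient_id = p,
                      region = "tumor-rich",
                      use_truth_masks = isTRUE(co$use_truth_masks))
    }))
    add_output("phenotyping", write_stage_csv(cells, out_dir, "cells.csv"))
  }

  if (isTRUE(config$stages$metrics)) {
    if (is.null(cells)) stop("metrics requires the phenotyping stage", call. = FALSE)
    profiles <- do.call(rbind, lapply(split(cells, cells$core_id),
                                      subset_profile))
    patient_profiles <- aggregate_by_patient(profiles)
    add_output("metrics", write_stage_csv(profiles, out_dir, "profiles.csv"))
    add_output("metrics", write_stage_csv(patient_profiles, out_dir,
                                          "patient_profiles.csv"))
    result$profiles <- profiles
    result$patient_profiles <- patient_profiles
  }

  if (isTRUE(config$stages$evaluation)) {
    if (is.null(scenes)) stop("evaluation requires the images stage", call. = FALSE)
    detection <- do.call(rbind, lapply(names(scenes), function(id) {
      sc <- scenes[[id]]
      pred <- segment_nuclei(sc$channels$nuclear)
      cbind(core = id,
            evaluate_detection(pred, label_mask(sc$truth_nuclei_mask,
                                                "truth_nuclei")))
    }))
    add_output("evaluation", write_stage_csv(detection, out_dir,
                                             "detection_scores.csv"))
    result$detection <- detection
  }

  se_norm <- NULL
  if (isTRUE(config$stages$omics)) {
    om <- config$omics
    analytes <- sprintf("A%03d", seq_len(om$n_analytes))
    low_snr <- analytes[seq_len(om$n_low_snr)]
    # group markers planted on the highest-index analytes, away from the
    # low-SNR set
    markers <- analytes[om$n_analytes - seq_len(om$n_group_markers) + 1L]
    groups <- setNames(ifelse(rich, "high", "low"), patients)
    ge <- expand.grid(analyte = markers, cell_type = c("T_H", "T_C"),
                      stringsAsFactors = FALSE)
    ge$group <- "high"; ge$lfc <- om$group_lfc
    # region contrast planted on analytes between the low-SNR and
    # group-marker sets, recovered by the mixed-model stage
    region_markers <- analytes[om$n_low_snr + seq_len(om$n_region_markers)]
    pe <- data.frame(analyte = region_markers, cell_type = "T_H",
                     region = "tumor-rich", lfc = om$region_lfc)
    se <- generate_expression(omics_sim_params(
      n_patients = co$n_patients, n_analytes = om$n_analytes,
      n_negative_controls = om$n_negative_controls,
      patient_sd = om$patient_sd, residual_sd = om$residual_sd,
      planted_effects = pe,
      low_snr_analytes = low_snr, patient_groups = groups,
      group_effects = ge, seed = derive_seed(config$seed, 101L)))
    qc <- aoi_qc(se, "protein")
    scaled <- area_scale(qc$data)
    snr <- compute_snr(scaled)
    frep <- filter_transcripts(snr,
                               SummarizedExperiment::colData(scaled))
    keep_rows <- rownames(scaled) %in%
      c(frep$kept,
        rownames(scaled)[SummarizedExperiment::rowData(scaled)$is_negative_control])
    se_norm <- cyclic_loess_normalize(scaled[keep_rows, ])
    add_output("omics", write_stage_csv(
      data.frame(analyte = rownames(snr), frep$fraction_below,
                 removed = rownames(snr) %in% frep$removed,
                 check.names = FALSE),
      out_dir, "filter_report.csv"))
    for (f in write_expression(se_norm, out_dir, "expression_normalized")) {
      add_output("omics", f)
    }
    result$filter_report <- frep
  }

  if (isTRUE(config$stages$stats)) {
    if (is.null(se_norm)) stop("stats requires the omics stage", call. = FALSE)
    cd <- SummarizedExperiment::colData(se_norm)
    de <- lmm_diffexp(se_norm, fixed = "region",
                      subset = cd$cell_type == "T_H")
    add_output("stats", write_stage_csv(de, out_dir, "diffexp_region_TH.csv"))
    result$diffexp <- de
  }

  if (isTRUE(config$stages$survival)) {
    if (is.null(result$patient_profiles)) {
      stop("survival requires the metrics stage", call. = FALSE)
    }
    pp <- result$patient_profiles
    covariate <- 100 * pp$cd3_frequency[match(patients, pp$patient_id)]
    sv <- config$survival
    surv_tab <- generate_survival(survival_sim_params(
      n_patients = co$n_patients, baseline_hazard = sv$baseline_hazard,
      hazard_ratio = sv$hazard_ratio,
      true_cutpoint = median(covariate), censor_rate = sv$censor_rate,
      seed = derive_seed(config$seed, 202L)), covariate = covariate)
    cut <- maxstat_cutpoint(surv_tab$covariate, surv_tab$time_years,
                            surv_tab$event)
    km <- kaplan_meier(surv_tab$time_years, surv_tab$event)
    add_output("survival", write_stage_csv(surv_tab, out_dir, "survival.csv"))
    add_output("survival", write_stage_csv(km, out_dir, "kaplan_meier.csv"))
    add_output("survival", write_stage_csv(
      data.frame(cutpoint = cut$cutpoint, statistic = cut$statistic,
                 selection_biased_p = cut$selection_biased_p),
      out_dir, "cutpoint.csv"))
    result$cutpoint <- cut
  }

  if (isTRUE(config$stages$integration)) {
    if (is.null(se_norm)) stop("integration requires the omics stage", call. = FALSE)
    ig <- config$integration
    cd <- SummarizedExperiment::colData(se_norm)
    ctrl <- SummarizedExperiment::rowData(se_norm)$is_negative_control
    vals <- exprs_values(se_norm)[!ctrl, , drop = FALSE]
    block_of <- function(ct) {
      cols <- cd$cell_type == ct & cd$region == "tumor-rich"
      m <- t(vals[, cols, drop = FALSE])
      rownames(m) <- cd$patient[cols]
      m[patients, , drop = FALSE]
    }
    bd <- block_dataset(list(T_H = block_of("T_H"), T_C = block_of("T_C")),
                        ifelse(rich, "high", "low"))
    keepx <- min(ig$keepX, ncol(bd$blocks$T_H))
    cfg <- integration_config(
      ncomp = ig$ncomp, keepX = list(T_H = keepx, T_C = keepx),
      cv_folds = ig$cv_folds, cv_repeats = ig$cv_repeats,
      n_permutations = max(ig$n_permutations, 19L),
      seed = derive_seed(config$seed, 303L))
    model <- fit_block_splsda(bd, cfg)
    cv <- cv_block_splsda(bd, cfg)
    perm_p <- NA_real_
    if (ig$n_permutations >= 19L) {
      perm_p <- permutation_test(bd, cfg)$p_value
    }
    feats <- selected_features(model)
    add_output("integration", write_stage_csv(feats, out_dir,
                                              "selected_features.csv"))
    add_output("integration", write_stage_csv(
      data.frame(cv_ber = cv$ber, permutation_p = perm_p),
      out_dir, "integration_performance.csv"))
    result$integration <- list(model = model, cv = cv,
                               permutation_p = perm_p)
  }

  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  result$manifest <- manifest
  result$out_dir <- out_dir
  result
}
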