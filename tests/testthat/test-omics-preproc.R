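toy_se <- function(values, patients, cell_types, areas = NULL,
                   nuclei = NULL, regions = NULL, controls = NULL) {
  n_aoi <- ncol(values)
  analytes <- rownames(values) %||% sprintf("G%02d", seq_len(nrow(values)))
  rownames(values) <- analytes
  expression_matrix(
    values,
    analyte_info = data.frame(
      analyte = analytes,
      is_negative_control = analytes %in% (controls %||% character(0))),
    aoi_info = data.frame(
      aoi_id = sprintf("aoi%02d", seq_len(n_aoi)),
      patient = patients, region = regions %||% rep("tumor-rich", n_aoi),
      cell_type = cell_types, area = areas %||% rep(1, n_aoi),
      nuclei_count = nuclei %||% rep(200L, n_aoi)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("AOI QC applies inclusive modality thresholds", {
  v <- matrix(1, 3, 4)
  se <- toy_se(v, patients = paste0("p", 1:4), cell_types = "T_H",
               nuclei = c(19L, 20L, 100L, 99L))
  prot <- aoi_qc(se, "protein")
  expect_identical(prot$report$aoi_id, "aoi01")   # 19 nuclei dropped
  expect_identical(ncol(prot$data), 3L)           # 20 kept (inclusive)
  rna <- aoi_qc(se, "rna")
  expect_setequal(rna$report$aoi_id, c("aoi01", "aoi02", "aoi04"))
  expect_identical(ncol(rna$data), 1L)            # only the 100-cell AOI
  all_pass <- aoi_qc(toy_se(v, paste0("p", 1:4), "T_H",
                            nuclei = rep(500L, 4)), "rna")
  expect_identical(ncol(all_pass$data), 4L)
  expect_identical(nrow(all_pass$report), 0L)
})

test_that("area scaling divides columns and enforces the state machine", {
  v <- matrix(c(100, 40, 60, 80), 2, 2)
  se <- toy_se(v, patients = c("p1", "p2"), cell_types = "T_H",
               areas = c(2, 4))
  scaled <- area_scale(se)
  got <- SummarizedExperiment::assay(scaled)
  expect_equal(unname(got[, 1]), c(50, 20))
  expect_equal(unname(got[, 2]), c(15, 20))
  expect_error(area_scale(scaled), "raw")
  # homogeneity: doubling every area halves every column
  se2 <- toy_se(v, c("p1", "p2"), "T_H", areas = c(4, 8))
  expect_equal(SummarizedExperiment::assay(area_scale(se2)), got / 2)
  expect_error(area_scale(toy_se(v, c("p1", "p2"), "T_H", areas = c(0, 1))),
               "positive")
})

test_that("identical columns are a fixed point of cyclic loess", {
  set.seed(3)
  col <- 2^rnorm(60, 6)
  v <- matrix(rep(col, 4), ncol = 4)
  se <- area_scale(toy_se(v, paste0("p", 1:4), "T_H"))
  norm <- cyclic_loess_normalize(se)
  expect_equal(SummarizedExperiment::assay(norm),
               log2(SummarizedExperiment::assay(se) + 1),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a constant log2 offset between AOIs is removed", {
  set.seed(4)
  base <- 2^rnorm(200, 7, 1.5)
  v <- cbind(base, base * 2)  # exact log2 offset of 1
  rownames(v) <- sprintf("G%03d", 1:200)
  se <- area_scale(toy_se(v, c("p1", "p2"), "T_H"))
  norm <- SummarizedExperiment::assay(cyclic_loess_normalize(se))
  m_after <- norm[, 2] - norm[, 1]
  expect_lt(median(abs(m_after)), 0.05)
  # the stratum grand mean is preserved by the centering convention
  expect_equal(mean(norm), mean(log2(v / 1 + 1)), tolerance = 1e-6)
})

test_that("normalization strata are independent (no cross-talk)", {
  set.seed(5)
  v <- matrix(2^rnorm(50 * 6, 6), 50, 6)
  patients <- rep(c("p1", "p2", "p3"), 2)
  cell_types <- rep(c("T_H", "CD20"), each = 3)
  se_a <- area_scale(toy_se(v, patients, cell_types))
  # perturb only the CD20 stratum; the T stratum's output must not move
  v2 <- v
  v2[, cell_types == "CD20"] <- v2[, cell_types == "CD20"] *
    matrix(2^runif(50 * 3, -1, 1), 50, 3)
  se_b <- area_scale(toy_se(v2, patients, cell_types))
  n_a <- SummarizedExperiment::assay(cyclic_loess_normalize(se_a))
  n_b <- SummarizedExperiment::assay(cyclic_loess_normalize(se_b))
  t_cols <- cell_types == "T_H"
  expect_equal(n_a[, t_cols], n_b[, t_cols], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(n_a[, !t_cols], n_b[, !t_cols])))
  expect_error(cyclic_loess_normalize(se_a[, 1]), "at least 2")
})

test_that("SNR is the ratio to the control geometric mean and is area-invariant", {
  v <- rbind(G1 = c(8, 16), G2 = c(2, 4), NC1 = c(1, 2), NC2 = c(4, 8))
  se <- toy_se(v, c("p1", "p2"), "T_H", areas = c(3, 5),
               controls = c("NC1", "NC2"))
  snr_raw <- compute_snr(se)
  # AOI1 control geomean = sqrt(1 * 4) = 2; AOI2 geomean = sqrt(2 * 8) = 4
  expect_equal(unname(snr_raw["G1", ]), c(4, 4))
  expect_equal(unname(snr_raw["G2", ]), c(1, 1))
  snr_scaled <- compute_snr(area_scale(se))
  expect_equal(snr_raw, snr_scaled, tolerance = 1e-12)
  no_ctrl <- toy_se(v, c("p1", "p2"), "T_H")
  expect_error(compute_snr(no_ctrl), "negative-control")
  zero <- toy_se(rbind(G1 = c(1, 1), NC1 = c(0, 1)), c("p1", "p2"), "T_H",
                 controls = "NC1")
  expect_error(compute_snr(zero), "zero")
})

test_that("the SNR filter implements the strict all-cell-types rule", {
  # 4 patients x 3 cell types; patient-level SNR crafted per analyte
  patients <- rep(paste0("p", 1:4), times = 3)
  cell_types <- rep(c("T_H", "T_C", "CD20"), each = 4)
  snr <- rbind(
    # 50% of patients below 1.05 in all three cell types -> removed
    fail_all = rep(c(0.9, 1.0, 2, 3), 3),
    # above 1.05 everywhere -> kept
    pass_all = rep(2, 12),
    # fails in two cell types, passes in the third -> kept
    fail_two = c(0.9, 1.0, 2, 3, 0.9, 1.0, 2, 3, 2, 2, 2, 2),
    # exactly 25% below is not > 25% -> kept (strict inequality)
    boundary = rep(c(0.9, 2, 2, 2), 3),
    # SNR exactly 1.05 is not < 1.05 -> kept
    at_threshold = rep(1.05, 12))
  info <- data.frame(patient = patients, cell_type = cell_types)
  rep_ <- filter_transcripts(snr, info,
                             cell_types = c("T_H", "T_C", "CD20"))
  expect_identical(rep_$removed, "fail_all")
  expect_setequal(rep_$kept, c("pass_all", "fail_two", "boundary",
                               "at_threshold"))
  expect_identical(sort(c(rep_$kept, rep_$removed)), sort(rownames(snr)))
  expect_error(filter_transcripts(snr, info, cell_types = "CD8"), "absent")
})

test_that("planted control-level analytes are removed exactly when noise is off", {
  planted <- c("A003", "A007", "A011")
  se <- generate_expression(omics_sim_params(
    n_patients = 8, n_analytes = 20, patient_sd = 0, residual_sd = 0,
    low_snr_analytes = planted, seed = 6))
  scaled <- area_scale(se)
  snr <- compute_snr(scaled)
  rep_ <- filter_transcripts(snr, SummarizedExperiment::colData(scaled),
                             cell_types = c("T_H", "T_C", "CD20"))
  expect_setequal(rep_$removed, planted)
})
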