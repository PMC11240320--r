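#' Parameters for a synthetic survival table
#'
#' Overall-survival times are exponential with hazard
#' `baseline_hazard * hazard_ratio^[covariate > true_cutpoint]`; the
#' covariate is uniform on `covariate_range`. Censoring is independent
#' exponential, with its rate chosen so that roughly `censor_rate` of
#' baseline-group subjects are censored (`censor_rate = 0` disables
#' censoring entirely).
#'
#' @param n_patients number of subjects.
#' @param baseline_hazard events per year in the low-covariate group.
#' @param hazard_ratio multiplicative hazard above the cutpoint.
#' @param true_cutpoint covariate threshold of the planted step.
#' @param covariate_range uniform sampling range of the covariate.
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(n_patients = 100L,
                                baseline_hazard = 0.2,
                                hazard_ratio = 1,
                                true_cutpoint = 0.5,
                                covariate_range = c(0, 1),
                                censor_rate = 0.2,
                                seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", 2)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio,
                 true_cutpoint = true_cutpoint,
                 covariate_range = as.numeric(covariate_range),
                 censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "survival_sim_params")
}

#' Generate a synthetic survival table
#'
#' @param params a [survival_sim_params()] object.
#' @param covariate optional externally measured covariate (e.g. an
#'   image-derived cell frequency) overriding the uniform draw; its length
#'   overrides `n_patients`.
#' @return data.frame with columns `patient`, `time_years`, `event`
#'   (1 = death observed, 0 = censored), `covariate`, `high_group`
#'   (ground-truth group indicator `covariate > true_cutpoint`).
#' @export
generate_survival <- function(params = survival_sim_params(),
                              covariate = NULL) {
  stopifnot(inherits(params, "survival_sim_params"))
  set.seed(params$seed)
  n <- if (is.null(covariate)) params$n_patients else length(covariate)
  if (is.null(covariate)) {
    covariate <- runif(n, params$covariate_range[1], params$covariate_range[2])
  }
  high <- covariate > params$true_cutpoint
  hazard <- params$baseline_hazard * params$hazard_ratio^high
  event_time <- rexp(n, rate = hazard)
  if (params$censor_rate > 0) {
    cens_rate <- params$baseline_hazard *
      params$censor_rate / (1 - params$censor_rate)
    cens_time <- rexp(n, rate = cens_rate)
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)
  } else {
    time <- event_time
    event <- rep(1L, n)
  }
  data.frame(patient = sprintf("P%03d", seq_len(n)),
             time_years = time, event = event,
             covariate = covariate, high_group = high)
}
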