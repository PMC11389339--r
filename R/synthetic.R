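#' Configuration for the synthetic panel generator
#'
#' Bundles and validates the parameters of the synthetic Delphi exercise.
#' Defaults mirror the dimensions of the Ethiopian benefit-package study:
#' 28 experts scoring 253 disease conditions on a 1-4 ordinal scale, with
#' condition-specific latent means spanning roughly 1.1-3.8 (the realized
#' range of panel averages), a minority of conditions flagged as maternal/
#' child health, and a few hundred interventions with right-skewed
#' (log-normal) cost-effectiveness ratios.
#'
#' @param n_experts number of panel experts (default 28).
#' @param n_conditions number of disease conditions (default 253).
#' @param latent_mean_range interval within \[1, 4\] from which per-condition
#'   latent means are drawn uniformly (default `c(1.1, 3.8)`).
#' @param expert_noise_sd standard deviation of expert-level Gaussian noise
#'   on the latent scale before rounding (default 0.7, giving the broad
#'   cross-expert disagreement real panels show).
#' @param missing_rate probability a cell is missing (default 0).
#' @param mch_fraction probability a condition carries the MCH flag
#'   (default 0.15).
#' @param n_interventions number of interventions (default 300).
#' @param cer_log_mean,cer_log_sd log-normal parameters of the CER draw
#'   (defaults `log(100)` and 1.5, US$ per DALY averted scale).
#' @param conditions_per_intervention integer, or integer vector sampled
#'   uniformly, giving how many conditions each intervention links to
#'   (default 1).
#' @param seed integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_experts = 28,
                         n_conditions = 253,
                         latent_mean_range = c(1.1, 3.8),
                         expert_noise_sd = 0.7,
                         missing_rate = 0,
                         mch_fraction = 0.15,
                         n_interventions = 300,
                         cer_log_mean = log(100),
                         cer_log_sd = 1.5,
                         conditions_per_intervention = 1L,
                         seed = 1L) {
  cfg <- list(n_experts = as.integer(n_experts),
              n_conditions = as.integer(n_conditions),
              latent_mean_range = as.numeric(latent_mean_range),
              expert_noise_sd = as.numeric(expert_noise_sd),
              missing_rate = as.numeric(missing_rate),
              mch_fraction = as.numeric(mch_fraction),
              n_interventions = as.integer(n_interventions),
              cer_log_mean = as.numeric(cer_log_mean),
              cer_log_sd = as.numeric(cer_log_sd),
              conditions_per_intervention = as.integer(conditions_per_intervention),
              seed = as.integer(seed))
  with(cfg, {
    if (n_experts < 1 || n_conditions < 1 || n_interventions < 1)
      abort_config("counts must be >= 1")
    if (length(latent_mean_range) != 2 || latent_mean_range[1] > latent_mean_range[2] ||
        latent_mean_range[1] < 1 || latent_mean_range[2] > 4)
      abort_config("latent_mean_range must be an interval within [1, 4]")
    if (expert_noise_sd < 0) abort_config("expert_noise_sd must be non-negative")
    if (missing_rate < 0 || missing_rate >= 1) abort_config("missing_rate must be in [0, 1)")
    if (mch_fraction < 0 || mch_fraction >= 1) abort_config("mch_fraction must be in [0, 1)")
    if (cer_log_sd < 0) abort_config("cer_log_sd must be non-negative")
    if (any(conditions_per_intervention < 1) ||
        any(conditions_per_intervention > n_conditions))
      abort_config("conditions_per_intervention must be in 1..n_conditions")
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic Delphi panel
#'
#' Simulates the panel under an ordinal latent-variable response model:
#' each condition has a latent mean drawn uniformly on
#' `latent_mean_range`; each expert's score is the latent mean plus
#' Gaussian noise (`expert_noise_sd`), rounded to the nearest integer and
#' clipped to \[1, 4\]. Cells are masked missing with `missing_rate`, MCH
#' flags drawn with `mch_fraction`, and GBD level-2 labels assigned
#' round-robin over 20 synthetic categories. Fully reproducible from the
#' seed.
#'
#' @param config a [synth_config()].
#' @param latent_means optional numeric vector overriding the latent means
#'   (length `n_conditions`); used e.g. by [recovery_experiment()] to hold
#'   the truth fixed across replicates.
#' @return A list with `scores` (a [score_matrix()]), `meta` (condition
#'   metadata tibble) and `latent_means` (named numeric vector).
#' @export
gen_panel <- function(config, latent_means = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_e <- config$n_experts
  n_c <- config$n_conditions
  condition_ids <- sprintf("C%03d", seq_len(n_c))
  expert_ids <- sprintf("E%02d", seq_len(n_e))

  if (is.null(latent_means)) {
    latent_means <- stats::runif(n_c, config$latent_mean_range[1],
                                 config$latent_mean_range[2])
  } else {
    stats::runif(n_c)  # keep the RNG stream aligned with the default path
    if (length(latent_means) != n_c) abort_config("latent_means length mismatch")
  }
  names(latent_means) <- condition_ids

  noise <- matrix(stats::rnorm(n_e * n_c, sd = config$expert_noise_sd), nrow = n_e)
  scores <- pmin(pmax(round(sweep(noise, 2, latent_means, "+")), 1), 4)
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_e * n_c) < config$missing_rate, nrow = n_e)
    # never blank out a condition entirely: keep one rater per condition
    keep <- cbind(apply(mask, 2, function(col) which.min(col)), seq_len(n_c))
    mask[keep] <- FALSE
    scores[mask] <- NA_integer_
  }

  mch <- stats::runif(n_c) < config$mch_fraction
  meta <- tibble::tibble(
    condition_id = condition_ids,
    name = sprintf("Synthetic condition %03d", seq_len(n_c)),
    gbd_level2 = sprintf("Synthetic GBD-L2 group %02d",
                         (seq_len(n_c) - 1L) %% 20L + 1L),
    mch_flag = mch
  )
  list(scores = score_matrix(scores, expert_ids, condition_ids),
       meta = meta,
       latent_means = latent_means)
}

#' Generate a synthetic intervention / CER table
#'
#' Each intervention links to `conditions_per_intervention` conditions
#' sampled without replacement and draws a strictly positive CER from a
#' log-normal distribution (right-skewed, as published cost-per-DALY
#' figures are). Reproducible from the seed (offset from the panel's so the
#' two draws are independent).
#'
#' @param config a [synth_config()].
#' @param condition_ids character vector of available condition ids.
#' @return An intervention tibble (`intervention_id`, `name`,
#'   `condition_ids` list-column, `cer`).
#' @export
gen_interventions <- function(config, condition_ids) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$conditions_per_intervention > length(condition_ids))) {
    abort_config("conditions_per_intervention exceeds the number of conditions")
  }
  set.seed(config$seed + 1L)
  n_i <- config$n_interventions
  k_pool <- config$conditions_per_intervention
  ks <- if (length(k_pool) == 1) rep(k_pool, n_i) else
    sample(k_pool, n_i, replace = TRUE)
  links <- lapply(ks, function(k) sort(sample(condition_ids, k)))
  tibble::tibble(
    intervention_id = sprintf("I%03d", seq_len(n_i)),
    name = sprintf("Synthetic intervention %03d", seq_len(n_i)),
    condition_ids = links,
    cer = stats::rlnorm(n_i, meanlog = config$cer_log_mean,
                        sdlog = config$cer_log_sd)
  )
}

#' Recovery experiment: panel means vs latent truth
#'
#' Monte-Carlo check of the aggregation stage: holding one draw of latent
#' condition means fixed, regenerates the panel `n_reps` times (replicate
#' seeds derived from the config seed) and measures per-condition and
#' pooled bias and RMSE of the panel mean scores against the latent means.
#' Bias here includes the systematic component introduced by rounding and
#' clipping of the ordinal response.
#'
#' @param config a [synth_config()].
#' @param n_reps number of Monte-Carlo replicates (>= 1).
#' @return A list with `per_condition` (tibble: `condition_id`,
#'   `latent_mean`, `bias`, `rmse`) and `pooled` (list with `bias`,
#'   `rmse`).
#' @export
recovery_experiment <- function(config, n_reps) {
  stopifnot(inherits(config, "synth_config"))
  if (n_reps < 1) abort_config("n_reps must be >= 1")
  truth <- gen_panel(config)$latent_means
  err <- matrix(NA_real_, nrow = n_reps, ncol = config$n_conditions)
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    panel <- gen_panel(cfg_r, latent_means = truth)
    err[r, ] <- mean_scores(panel$scores)$mean_score - truth
  }
  per_condition <- tibble::tibble(
    condition_id = names(truth),
    latent_mean = unname(truth),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2))
  )
  list(per_condition = per_condition,
       pooled = list(bias = mean(err), rmse = sqrt(mean(err^2))))
}
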