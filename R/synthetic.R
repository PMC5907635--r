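# Synthetic stand-ins for the study's trial-level and supplementary
# inputs: a patient-level generator with the statistical structure the
# estimation stages assume (multinomial monthly symptom transitions,
# linear EQ-5D utilities with covariates and Gaussian noise), and NMA-like
# per-drug effect summaries. The generating truth is retained alongside
# the outputs for recovery testing.

tridiag_transition <- function(p_down, p_up, L = 5) {
  M <- matrix(0, L, L)
  for (i in 1:L) {
    down <- if (i > 1) p_down else 0
    up <- if (i < L) p_up else 0
    M[i, i] <- 1 - down - up
    if (i > 1) M[i, i - 1] <- down
    if (i < L) M[i, i + 1] <- up
  }
  M
}

# Default generating dynamics for the reference drug: improvement strongest
# in month 1 and diminishing, with the month-3 matrix mildly improving so
# the sustained-effect assumption (month-3 matrix reused thereafter) holds
# a severity distribution close to baseline in the long run.
default_truth_matrices <- function(L = 5) {
  list(
    micturition = list(
      month1 = tridiag_transition(0.30, 0.15, L),
      month2 = tridiag_transition(0.22, 0.15, L),
      month3 = tridiag_transition(0.18, 0.12, L)),
    incontinence = list(
      month1 = tridiag_transition(0.28, 0.15, L),
      month2 = tridiag_transition(0.20, 0.15, L),
      month3 = tridiag_transition(0.18, 0.12, L))
  )
}

#' Generating truth for the synthetic-data module
#'
#' Bundles the quantities the synthetic generator draws from: monthly
#' transition matrices for the reference drug, the utility model
#' (coefficients, covariate effects, noise SD), per-drug NMA effects
#' (taken from the parameter set's drug specifications) and the baseline
#' severity distribution.
#'
#' @param params An `oab_paramset` supplying utilities, baseline
#'   distribution and per-drug NMA effects; defaults to the packaged
#'   configuration.
#' @param transition Generating matrices per dimension (lists of three);
#'   defaults to the packaged tridiagonal improvement dynamics.
#' @param covariate_effects Named list `sex`, `age`, `country` (country a
#'   named vector of level effects) entering the EQ-5D linear predictor.
#' @param noise_sd Gaussian noise SD on the EQ-5D index.
#' @param nma_ci_half_width Named list `mean_diff` (episodes/day) and
#'   `log_or` half-widths reported around the emitted NMA summaries.
#' @param seed Integer seed recorded with the truth.
#' @return A list of class `oab_synthetic_truth`.
#' @export
synthetic_truth <- function(params = NULL,
                            transition = NULL,
                            covariate_effects = list(
                              sex = -0.013, age = -0.0006,
                              country = c(uk = 0, de = 0.010, us = -0.010)),
                            noise_sd = 0.1,
                            nma_ci_half_width = list(mean_diff = 0.30,
                                                     log_or = 0.25),
                            seed = 1L) {
  if (is.null(params)) {
    params <- load_parameter_set(
      system.file("extdata", "default_config.yaml", package = "oabcea"))
  }
  L <- n_levels(params)
  transition <- transition %||% default_truth_matrices(L)
  for (dim in names(transition)) {
    for (M in transition[[dim]]) {
      if (!is_row_stochastic(M)) {
        abort_oab(sprintf("truth transition matrix (%s) is not row-stochastic",
                          dim))
      }
    }
  }
  structure(list(
    transition = transition,
    utility = list(base = params$utility$base_utility,
                   mict_coefs = params$utility$mict_coefs,
                   incont_coefs = params$utility$incont_coefs,
                   covariates = covariate_effects,
                   noise_sd = noise_sd),
    nma = lapply(params$drugs, function(d) list(
      mean_diff = d$nma_mean_diff,
      ae_prob_3m = d$ae_prob_3m,
      is_reference = d$is_reference)),
    baseline = params$settings$baseline_distribution,
    nma_ci_half_width = nma_ci_half_width,
    eq5d_range = c(-0.594, 1),
    seed = as.integer(seed)
  ), class = "oab_synthetic_truth")
}

sample_levels <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

#' Generate synthetic patient-level trial data
#'
#' One record per patient and month (months 0-3). Baseline severity levels
#' are drawn from the truth's baseline distribution; months 1-3 evolve by
#' the truth's monthly transition matrices (independently per dimension).
#' The EQ-5D index is the linear predictor
#' `base + mict_coef(level) + incont_coef(level) + covariate effects` plus
#' Gaussian noise, truncated to the UK tariff range `[-0.594, 1]`.
#' Identical `(truth, n_patients, seed)` give identical output.
#'
#' @param truth An [synthetic_truth()] object.
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `patient_id`, `sex` (1 = female),
#'   `age`, `country`, `month`, `mict_level`, `incont_level`,
#'   `eq5d_index`.
#' @export
generate_trial_data <- function(truth, n_patients, seed = truth$seed) {
  if (!is_scalar_number(n_patients) || n_patients < 1) {
    abort_oab("n_patients must be >= 1")
  }
  n <- as.integer(n_patients)
  L <- nrow(truth$baseline)
  withr::with_seed(as.integer(seed), {
    pm <- rowSums(truth$baseline)
    pi_ <- colSums(truth$baseline)
    # joint baseline draw (cell-wise), then split into the two levels
    cells <- sample.int(L * L, n, replace = TRUE,
                        prob = as.vector(t(truth$baseline)))
    mict <- matrix(0L, n, 4)
    incont <- matrix(0L, n, 4)
    mict[, 1] <- (cells - 1L) %/% L + 1L
    incont[, 1] <- (cells - 1L) %% L + 1L
    for (m in 1:3) {
      Mm <- truth$transition$micturition[[m]]
      Mi <- truth$transition$incontinence[[m]]
      for (i in 1:L) {
        idx <- which(mict[, m] == i)
        if (length(idx)) mict[idx, m + 1] <- sample_levels(length(idx),
                                                           Mm[i, ])
        idx <- which(incont[, m] == i)
        if (length(idx)) incont[idx, m + 1] <- sample_levels(length(idx),
                                                             Mi[i, ])
      }
    }
    sex <- as.integer(runif(n) < 0.75)          # OAB trials are ~75% female
    age <- pmin(pmax(round(rnorm(n, 55, 12)), 18), 90)
    ctry_levels <- names(truth$utility$covariates$country)
    country <- sample(ctry_levels, n, replace = TRUE)
    ut <- truth$utility
    recs <- do.call(rbind, lapply(0:3, function(m) {
      ml <- mict[, m + 1]; il <- incont[, m + 1]
      lp <- ut$base +
        ifelse(ml < L, ut$mict_coefs[pmin(ml, L - 1)], 0) +
        ifelse(il < L, ut$incont_coefs[pmin(il, L - 1)], 0) +
        ut$covariates$sex * sex +
        ut$covariates$age * (age - 55) +
        ut$covariates$country[country]
      eq <- lp + rnorm(n, 0, ut$noise_sd)
      eq <- pmin(pmax(eq, truth$eq5d_range[1]), truth$eq5d_range[2])
      data.frame(patient_id = seq_len(n), sex = sex, age = age,
                 country = country, month = m, mict_level = ml,
                 incont_level = il, eq5d_index = eq,
                 stringsAsFactors = FALSE)
    }))
    recs[order(recs$patient_id, recs$month), ]
  })
}

#' Emit NMA-like per-drug effect summaries
#'
#' Point estimates equal the truth's effects exactly (the NMA itself is
#' out of scope; only its outputs are emulated): mean differences in daily
#' micturitions/incontinence episodes versus the reference drug, and
#' adverse-event odds ratios implied by the truth's 3-month probabilities.
#' Interval half-widths are taken from the truth's configuration. The
#' reference drug has mean difference 0 and odds ratio 1.
#'
#' @param truth An [synthetic_truth()] object.
#' @param seed Integer seed (kept for interface symmetry; the summaries
#'   are deterministic given the truth).
#' @return Data frame, one row per drug, with point estimates and 95%
#'   interval bounds.
#' @export
generate_nma_inputs <- function(truth, seed = truth$seed) {
  ref <- names(truth$nma)[vapply(truth$nma, function(x)
    isTRUE(x$is_reference), logical(1))]
  p_ref <- truth$nma[[ref]]$ae_prob_3m
  hw_md <- truth$nma_ci_half_width$mean_diff
  hw_lo <- truth$nma_ci_half_width$log_or
  odds <- function(p) p / (1 - p)
  rows <- lapply(names(truth$nma), function(nm) {
    x <- truth$nma[[nm]]
    md_m <- x$mean_diff$micturitions_per_day %||% 0
    md_i <- x$mean_diff$incontinence_per_day %||% 0
    or_dm <- odds(x$ae_prob_3m$dry_mouth) / odds(p_ref$dry_mouth)
    or_c <- odds(x$ae_prob_3m$constipation) / odds(p_ref$constipation)
    if (nm == ref) { md_m <- 0; md_i <- 0; or_dm <- 1; or_c <- 1 }
    data.frame(
      drug = nm,
      mean_diff_micturitions = md_m,
      mean_diff_micturitions_lo = md_m - hw_md,
      mean_diff_micturitions_hi = md_m + hw_md,
      mean_diff_incontinence = md_i,
      mean_diff_incontinence_lo = md_i - hw_md,
      mean_diff_incontinence_hi = md_i + hw_md,
      or_dry_mouth = or_dm,
      or_dry_mouth_lo = exp(log(or_dm) - hw_lo),
      or_dry_mouth_hi = exp(log(or_dm) + hw_lo),
      or_constipation = or_c,
      or_constipation_lo = exp(log(or_c) - hw_lo),
      or_constipation_hi = exp(log(or_c) + hw_lo),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Packaged base-case parameter set with synthetic stand-ins
#'
#' Loads the packaged configuration (printed base-case values for adverse
#' events, pathway, utilities, resource use and costs), builds the
#' generating truth, attaches the reference drug's transition model from
#' the truth, and calibrates every comparator's matrices to its NMA mean
#' differences. Deterministic for a given seed.
#'
#' @param seed Integer seed recorded in the settings and truth.
#' @return List with elements `params` (a complete, valid `oab_paramset`)
#'   and `truth` (the [synthetic_truth()]).
#' @export
make_default_paramset <- function(seed = 1L) {
  params <- load_parameter_set(
    system.file("extdata", "default_config.yaml", package = "oabcea"))
  params$settings$seed <- as.integer(seed)
  truth <- synthetic_truth(params, seed = seed)
  ref <- reference_drug(params)
  ref_model <- transition_model(ref, truth$transition$micturition,
                                truth$transition$incontinence)
  params <- build_transition_models(params, ref_model)
  list(params = params, truth = truth)
}

#' Write synthetic outputs to disk
#'
#' Patient records as CSV (one row per patient-month) and the generating
#' truth as a structured-text sidecar.
#'
#' @param records Data frame from [generate_trial_data()].
#' @param truth The generating [synthetic_truth()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_synthetic_outputs <- function(records, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "trial_records.csv")
  write.csv(records, f1, row.names = FALSE)
  f2 <- file.path(dir, "truth.yaml")
  tr <- list(
    seed = truth$seed,
    noise_sd = truth$utility$noise_sd,
    base_utility = truth$utility$base,
    mict_coefs = truth$utility$mict_coefs,
    incont_coefs = truth$utility$incont_coefs,
    transition = lapply(truth$transition, function(dim_mats)
      lapply(dim_mats, function(M)
        lapply(seq_len(nrow(M)), function(i) M[i, ])))
  )
  yaml::write_yaml(tr, f2, precision = 15)
  c(f1, f2)
}
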