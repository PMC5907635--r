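# Shared fixture builders. Everything is generated in code at test time.

# memoized packaged base-case parameter set (calibration is not free)
cached_default_paramset <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache) || cache$params$settings$seed != seed) {
      cache <<- make_default_paramset(seed)
    }
    cache
  }
})

tridiag2 <- function(p_down, p_up) {
  matrix(c(1 - p_up, p_up,
           p_down, 1 - p_down), nrow = 2, byrow = TRUE)
}

identity_tm <- function(drug, L) {
  mats <- lapply(1:3, function(m) diag(L))
  transition_model(drug, mats, mats)
}

# Reduced model: two severity levels per dimension, short horizon.
# Defaults keep the base-case pathway probabilities.
make_reduced_paramset <- function(horizon = 12,
                                  p_disc_no_ae = 0.068,
                                  p_discontinue_ae = 0.90,
                                  p_switch = 0.261,
                                  p_restart = 0.056,
                                  p_btxa = 0.001,
                                  p_reinject = 0.70,
                                  ae_dm = 0.143, ae_cp = 0.072,
                                  identity_transitions = FALSE) {
  drugs <- list(
    solifenacin_5mg = drug_spec(
      "solifenacin_5mg", 28.00,
      ae_prob_3m = list(dry_mouth = ae_dm, constipation = ae_cp),
      discontinuation_monthly_no_ae = p_disc_no_ae,
      is_reference = TRUE),
    tolterodine_er_4mg = drug_spec(
      "tolterodine_er_4mg", 28.01,
      ae_prob_3m = list(dry_mouth = 0.149, constipation = 0.043),
      discontinuation_monthly_no_ae = p_disc_no_ae,
      nma_mean_diff = list(micturitions_per_day = 0.2,
                           incontinence_per_day = 0.05)),
    oxybutynin_ir_10mg = drug_spec(
      "oxybutynin_ir_10mg", 2.40,
      ae_prob_3m = list(dry_mouth = 0.371, constipation = 0.037),
      discontinuation_monthly_no_ae = p_disc_no_ae,
      nma_mean_diff = list(micturitions_per_day = 0.2,
                           incontinence_per_day = 0.1))
  )
  params <- param_set(
    drugs = drugs,
    pathway = pathway_spec(
      p_discontinue_ae = p_discontinue_ae,
      p_discontinue_no_ae = p_disc_no_ae,
      p_switch_after_discontinuation = p_switch,
      p_restart_monthly = p_restart,
      p_btxa_monthly = p_btxa,
      p_btxa_reinjection_6m = p_reinject),
    utility = utility_spec(base_utility = 0.8, mict_coefs = 0.06,
                           incont_coefs = 0.05),
    cost = cost_spec(pads_per_month = c(6.97, 121.30)),
    settings = model_settings(
      horizon = horizon,
      baseline_distribution = baseline_from_decay(c(0.7, 0.7), L = 2),
      severity_midpoints = list(micturition = c(6, 16),
                                incontinence = c(0, 6)))
  )
  if (identity_transitions) {
    params$transition_models <- lapply(names(drugs), identity_tm, L = 2)
    names(params$transition_models) <- names(drugs)
  } else {
    ref_model <- transition_model(
      "solifenacin_5mg",
      micturition = list(tridiag2(0.30, 0.15), tridiag2(0.22, 0.15),
                         tridiag2(0.18, 0.12)),
      incontinence = list(tridiag2(0.28, 0.15), tridiag2(0.20, 0.15),
                          tridiag2(0.18, 0.12)))
    params <- build_transition_models(params, ref_model)
  }
  params
}

# Frozen dynamics: no events, identity transitions; the distribution is a
# fixed point of the cycle map.
make_frozen_paramset <- function(horizon = 12, L = 2) {
  params <- make_reduced_paramset(horizon = horizon,
                                  p_disc_no_ae = 0,
                                  p_switch = 0, p_restart = 0,
                                  p_btxa = 0,
                                  ae_dm = 0, ae_cp = 0,
                                  identity_transitions = TRUE)
  for (nm in names(params$drugs)) {
    params$drugs[[nm]]$ae_prob_3m <- list(dry_mouth = 0, constipation = 0)
    params$drugs[[nm]]$discontinuation_monthly_no_ae <- 0
  }
  params
}

# a one-state distribution: all mass at the given pathway state / symptom
# cell of an arm's state space
make_point_dist <- function(params, drug, key, mict, incont) {
  d <- build_initial_distribution(params, drug)
  ctx <- attr(d, "ctx")
  L <- ctx$L
  d$mass[] <- 0
  d$mass[ctx$idx[[key]], (mict - 1) * L + incont] <- 1
  d
}

zero_tally <- function() {
  c(ae_dry_mouth = 0, ae_constipation = 0, discontinuations = 0,
    switches = 0, restarts = 0, btxa_injections = 0, initiations = 0,
    entry = 0)
}
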