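#' Drug specification
#'
#' One oral antimuscarinic agent: monthly acquisition cost, 3-month adverse
#' event probabilities (dry mouth, constipation), monthly discontinuation
#' probability without adverse events, and network-meta-analysis (NMA)
#' effects versus the reference drug (mean differences in daily micturitions
#' and incontinence episodes; optionally adverse-event odds ratios used when
#' 3-month probabilities are to be derived from the reference).
#'
#' @param name Drug identifier, e.g. `"solifenacin_5mg"`.
#' @param monthly_cost Monthly acquisition cost, GBP.
#' @param ae_prob_3m Named list `dry_mouth`, `constipation`: probabilities
#'   of each adverse event over the first 3 months on the drug.
#' @param discontinuation_monthly_no_ae Monthly probability of
#'   discontinuation without an adverse event.
#' @param nma_mean_diff Named list `micturitions_per_day`,
#'   `incontinence_per_day`: NMA mean difference in daily episode counts
#'   versus the reference drug (positive = more episodes, i.e. worse).
#' @param ae_odds_ratio Optional named list `dry_mouth`, `constipation` of
#'   NMA odds ratios versus the reference drug.
#' @param is_reference Is this the reference (intervention) drug?
#' @param dsa Named list of deterministic-sensitivity ranges, keyed by
#'   dotted sub-path (e.g. `"ae_prob_3m.dry_mouth"`), each `c(low, high)`.
#' @return A list of class `oab_drug_spec`.
#' @export
drug_spec <- function(name, monthly_cost,
                      ae_prob_3m = list(dry_mouth = 0, constipation = 0),
                      discontinuation_monthly_no_ae = 0.068,
                      nma_mean_diff = list(micturitions_per_day = 0,
                                           incontinence_per_day = 0),
                      ae_odds_ratio = NULL,
                      is_reference = FALSE,
                      dsa = list()) {
  structure(list(
    name = name,
    monthly_cost = monthly_cost,
    ae_prob_3m = ae_prob_3m,
    discontinuation_monthly_no_ae = discontinuation_monthly_no_ae,
    nma_mean_diff = nma_mean_diff,
    ae_odds_ratio = ae_odds_ratio,
    is_reference = isTRUE(is_reference),
    dsa = dsa
  ), class = "oab_drug_spec")
}

#' Treatment-pathway specification
#'
#' Probabilities governing movement between treatment phases: AE-driven and
#' other discontinuation, immediate switch to the next oral line, restart
#' from off-treatment, and botulinum toxin type A (BTX-A) injection and
#' 6-monthly reinjection. Restarts split between the previous drug and the
#' two configured next-line agents.
#'
#' @param p_discontinue_ae Per-cycle discontinuation probability while an
#'   adverse event is active (base case 0.90).
#' @param p_discontinue_no_ae Fallback monthly discontinuation probability
#'   without adverse events, used when a drug does not set its own.
#' @param p_switch_after_discontinuation Probability that a discontinuation
#'   is followed by an immediate switch to the next oral line (0.261).
#' @param p_restart_monthly Monthly probability of restarting treatment
#'   from off-treatment (0.056).
#' @param restart_split Length-3 fractions (previous drug, next-line A,
#'   next-line B); must sum to 1.
#' @param p_btxa_monthly Monthly probability of BTX-A injection for
#'   patients off treatment with >= 2 failed oral lines (0.001).
#' @param p_btxa_reinjection_6m Probability of reinjection at each 6-month
#'   point while BTX-A is successful (0.70).
#' @param next_line_a,next_line_b Drug names of the two next-line agents.
#' @param next_line_transition_source Drug whose symptom transition model
#'   next-line therapies borrow (tolterodine, per the model's assumption).
#' @param scenario_discontinuation Optional named list drug -> monthly
#'   discontinuation probability applied regardless of adverse events
#'   (observational-rates scenario); `NULL` in the base case.
#' @param dsa Named list of DSA ranges keyed by field name.
#' @return A list of class `oab_pathway_spec`.
#' @export
pathway_spec <- function(p_discontinue_ae = 0.90,
                         p_discontinue_no_ae = 0.068,
                         p_switch_after_discontinuation = 0.261,
                         p_restart_monthly = 0.056,
                         restart_split = c(previous = 1 / 3,
                                           next_line_a = 1 / 3,
                                           next_line_b = 1 / 3),
                         p_btxa_monthly = 0.001,
                         p_btxa_reinjection_6m = 0.70,
                         next_line_a = "tolterodine_er_4mg",
                         next_line_b = "oxybutynin_ir_10mg",
                         next_line_transition_source = "tolterodine_er_4mg",
                         scenario_discontinuation = NULL,
                         dsa = list()) {
  structure(list(
    p_discontinue_ae = p_discontinue_ae,
    p_discontinue_no_ae = p_discontinue_no_ae,
    p_switch_after_discontinuation = p_switch_after_discontinuation,
    p_restart_monthly = p_restart_monthly,
    restart_split = restart_split,
    p_btxa_monthly = p_btxa_monthly,
    p_btxa_reinjection_6m = p_btxa_reinjection_6m,
    next_line_a = next_line_a,
    next_line_b = next_line_b,
    next_line_transition_source = next_line_transition_source,
    scenario_discontinuation = scenario_discontinuation,
    dsa = dsa
  ), class = "oab_pathway_spec")
}

#' Health-state utility specification
#'
#' EQ-5D-derived utilities by symptom severity. Coefficients are increments
#' relative to the worst level (level 5) in each dimension; the utility of a
#' state is `base_utility + mict_coefs[level] + incont_coefs[level]` with a
#' decrement while an adverse event is active on treatment.
#'
#' @param base_utility Utility of the reference state (micturition level 5,
#'   incontinence level 5). Not printed in the source tables; the packaged
#'   default 0.76 is a documented synthetic stand-in.
#' @param mict_coefs,incont_coefs Numeric vectors of length `L - 1`
#'   (levels 1..L-1), increments versus level L.
#' @param ae_decrement Utility change while an adverse event is active
#'   (-0.0357).
#' @param dsa Named list of DSA ranges.
#' @return A list of class `oab_utility_spec`.
#' @export
utility_spec <- function(base_utility = 0.76,
                         mict_coefs = c(0.0632, 0.0422, 0.0204, 0.0104),
                         incont_coefs = c(0.0586, 0.0437, 0.0314, 0.0157),
                         ae_decrement = -0.0357,
                         dsa = list()) {
  structure(list(
    base_utility = base_utility,
    mict_coefs = as.numeric(mict_coefs),
    incont_coefs = as.numeric(incont_coefs),
    ae_decrement = ae_decrement,
    dsa = dsa
  ), class = "oab_utility_spec")
}

#' Resource-use and unit-cost specification
#'
#' @param pads_per_month Pads used per month at incontinence levels 1..L.
#' @param pad_unit_cost Cost per incontinence pad, GBP.
#' @param gp_first_visit GP consultation at model entry, GBP.
#' @param gp_followup GP consultation at later treatment initiations, GBP.
#' @param specialist_visit Specialist (urologist) visit, GBP.
#' @param specialist_visits_at_initiation Specialist visits per treatment
#'   initiation (1 per the resource-use table; 1.5 supported).
#' @param btxa_injection_cost BTX-A injection/reinjection cost including
#'   procedure, GBP.
#' @param dsa Named list of DSA ranges.
#' @return A list of class `oab_cost_spec`.
#' @export
cost_spec <- function(pads_per_month = c(6.97, 23.48, 44.47, 58.13, 121.30),
                      pad_unit_cost = 0.17,
                      gp_first_visit = 65.00,
                      gp_followup = 27.00,
                      specialist_visit = 94.00,
                      specialist_visits_at_initiation = 1,
                      btxa_injection_cost = 1151.98,
                      dsa = list()) {
  structure(list(
    pads_per_month = as.numeric(pads_per_month),
    pad_unit_cost = pad_unit_cost,
    gp_first_visit = gp_first_visit,
    gp_followup = gp_followup,
    specialist_visit = specialist_visit,
    specialist_visits_at_initiation = specialist_visits_at_initiation,
    btxa_injection_cost = btxa_injection_cost,
    dsa = dsa
  ), class = "oab_cost_spec")
}

#' Model settings
#'
#' @param cycle_length Cycle length in months (1).
#' @param horizon Time horizon in months (60; must be a multiple of
#'   `cycle_length`).
#' @param annual_discount_rate Annual discount rate for costs and outcomes
#'   (0.035).
#' @param baseline_distribution `L x L` matrix of baseline occupancy over
#'   (micturition level, incontinence level); entries >= 0, sum 1.
#' @param severity_midpoints Named list `micturition`, `incontinence`:
#'   daily episode counts attached to levels 1..L, used by the
#'   calibration bridge between severity levels and NMA effects.
#' @param wtp_grid Willingness-to-pay grid, GBP per QALY.
#' @param seed Integer seed recorded with the parameter set.
#' @param half_cycle_correction Apply a half-cycle correction when
#'   accumulating (off in the base case).
#' @param btxa_symptom_distribution Optional `L x L` matrix of symptom
#'   occupancy held while on BTX-A; defaults to the baseline distribution.
#' @return A list of class `oab_settings`.
#' @export
model_settings <- function(cycle_length = 1,
                           horizon = 60,
                           annual_discount_rate = 0.035,
                           baseline_distribution = baseline_from_decay(),
                           severity_midpoints = list(
                             micturition = c(6, 9, 11, 13, 16),
                             incontinence = c(0, 0.5, 1.5, 3, 6)),
                           wtp_grid = seq(0, 50000, by = 2000),
                           seed = 1L,
                           half_cycle_correction = FALSE,
                           btxa_symptom_distribution = NULL) {
  structure(list(
    cycle_length = cycle_length,
    horizon = horizon,
    annual_discount_rate = annual_discount_rate,
    baseline_distribution = baseline_distribution,
    severity_midpoints = severity_midpoints,
    wtp_grid = as.numeric(wtp_grid),
    seed = as.integer(seed),
    half_cycle_correction = isTRUE(half_cycle_correction),
    btxa_symptom_distribution = btxa_symptom_distribution
  ), class = "oab_settings")
}

#' Baseline severity distribution from truncated-geometric marginals
#'
#' Stand-in for the (unavailable) pooled trial baseline strata: independent
#' truncated-geometric marginals over levels 1..L in each symptom
#' dimension, giving monotonically decreasing occupancy with severity.
#'
#' @param decay Length-2 decay ratios (micturition, incontinence) in (0,1).
#' @param L Number of severity levels.
#' @return `L x L` matrix (rows = micturition level, cols = incontinence
#'   level) summing to 1.
#' @export
baseline_from_decay <- function(decay = c(0.7, 0.7), L = 5) {
  if (any(decay <= 0) || any(decay >= 1)) {
    abort_oab("baseline decay ratios must lie in (0, 1)")
  }
  m <- decay[1]^(0:(L - 1)); m <- m / sum(m)
  i <- decay[2]^(0:(L - 1)); i <- i / sum(i)
  outer(m, i)
}

#' Assemble a full model parameterization
#'
#' @param drugs Named list of [drug_spec()] objects (names = drug ids).
#' @param pathway A [pathway_spec()].
#' @param utility A [utility_spec()].
#' @param cost A [cost_spec()].
#' @param settings A [model_settings()].
#' @param transition_models Optional named list drug -> transition model
#'   (see [transition_model()]); attached later by the estimation /
#'   calibration pipeline if `NULL`.
#' @param schema_version Configuration schema version string.
#' @return A list of class `oab_paramset`.
#' @export
param_set <- function(drugs, pathway = pathway_spec(),
                      utility = utility_spec(), cost = cost_spec(),
                      settings = model_settings(),
                      transition_models = NULL,
                      schema_version = "1.0") {
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    names(drugs) <- vapply(drugs, function(d) d$name, character(1))
  }
  structure(list(
    schema_version = schema_version,
    drugs = drugs,
    pathway = pathway,
    utility = utility,
    cost = cost,
    settings = settings,
    transition_models = transition_models
  ), class = "oab_paramset")
}

#' Reference (intervention) drug of a parameter set
#'
#' @param params An `oab_paramset`.
#' @return Drug name flagged `is_reference`.
#' @export
reference_drug <- function(params) {
  refs <- names(params$drugs)[vapply(params$drugs, function(d)
    isTRUE(d$is_reference), logical(1))]
  if (length(refs) != 1L) {
    abort_oab("parameter set must contain exactly one reference drug")
  }
  refs
}

n_levels <- function(params) nrow(params$settings$baseline_distribution)

violation <- function(type, field, rule) {
  data.frame(type = type, field = field, rule = rule,
             stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every type invariant of the parameterization and returns the
#' violations as data, not exceptions: an empty data frame means the set is
#' valid. Each violation names the offending type, field and rule.
#'
#' @param params An `oab_paramset`.
#' @return Data frame with columns `type`, `field`, `rule` (zero rows if
#'   valid).
#' @export
validate_parameter_set <- function(params) {
  v <- list()
  add <- function(type, field, rule) {
    v[[length(v) + 1L]] <<- violation(type, field, rule)
  }
  tol <- 1e-6

  ## drugs
  if (length(params$drugs) == 0L) {
    add("DrugSpec", "drugs", "at least one drug required")
  }
  n_ref <- sum(vapply(params$drugs, function(d) isTRUE(d$is_reference),
                      logical(1)))
  if (n_ref != 1L) {
    add("ParamSet", "drugs.is_reference",
        sprintf("exactly one reference drug required (found %d)", n_ref))
  }
  for (nm in names(params$drugs)) {
    d <- params$drugs[[nm]]
    if (!is_scalar_number(d$monthly_cost) || d$monthly_cost < 0) {
      add("DrugSpec", paste0("drugs.", nm, ".monthly_cost"),
          "cost must be >= 0")
    }
    for (ae in c("dry_mouth", "constipation")) {
      p <- d$ae_prob_3m[[ae]]
      if (!is.null(p) && (!is_scalar_number(p) || p < 0 || p > 1)) {
        add("DrugSpec", paste0("drugs.", nm, ".ae_prob_3m.", ae),
            "probability out of [0,1]")
      }
      o <- d$ae_odds_ratio[[ae]]
      if (!is.null(o) && (!is_scalar_number(o) || o <= 0)) {
        add("DrugSpec", paste0("drugs.", nm, ".ae_odds_ratio.", ae),
            "odds ratio must be > 0")
      }
    }
    p <- d$discontinuation_monthly_no_ae
    if (!is_scalar_number(p) || p < 0 || p > 1) {
      add("DrugSpec",
          paste0("drugs.", nm, ".discontinuation_monthly_no_ae"),
          "probability out of [0,1]")
    }
    for (dim in c("micturitions_per_day", "incontinence_per_day")) {
      md <- d$nma_mean_diff[[dim]]
      if (!is.null(md) && !is_scalar_number(md)) {
        add("DrugSpec", paste0("drugs.", nm, ".nma_mean_diff.", dim),
            "mean difference must be finite")
      }
    }
  }

  ## pathway
  pw <- params$pathway
  for (f in c("p_discontinue_ae", "p_discontinue_no_ae",
              "p_switch_after_discontinuation", "p_restart_monthly",
              "p_btxa_monthly", "p_btxa_reinjection_6m")) {
    p <- pw[[f]]
    if (!is_scalar_number(p) || p < 0 || p > 1) {
      add("PathwaySpec", paste0("pathway.", f),
          "probability out of [0,1]")
    }
  }
  if (length(pw$restart_split) != 3L ||
      any(pw$restart_split < 0) ||
      abs(sum(pw$restart_split) - 1) > tol) {
    add("PathwaySpec", "pathway.restart_split",
        "fractions must sum to 1")
  }
  for (f in c("next_line_a", "next_line_b",
              "next_line_transition_source")) {
    if (!pw[[f]] %in% names(params$drugs)) {
      add("PathwaySpec", paste0("pathway.", f),
          sprintf("drug name '%s' does not resolve", pw[[f]]))
    }
  }
  if (!is.null(pw$scenario_discontinuation)) {
    for (nm in names(pw$scenario_discontinuation)) {
      p <- pw$scenario_discontinuation[[nm]]
      if (!is_scalar_number(p) || p < 0 || p > 1) {
        add("PathwaySpec",
            paste0("pathway.scenario_discontinuation.", nm),
            "probability out of [0,1]")
      }
    }
  }

  ## utility
  L <- n_levels(params)
  ut <- params$utility
  if (!all(is.finite(c(ut$base_utility, ut$mict_coefs, ut$incont_coefs,
                       ut$ae_decrement)))) {
    add("UtilitySpec", "utility", "coefficients must be finite")
  }
  if (length(ut$mict_coefs) != L - 1L) {
    add("UtilitySpec", "utility.mict_coefs",
        sprintf("expected %d coefficients (levels 1..%d)", L - 1L, L - 1L))
  }
  if (length(ut$incont_coefs) != L - 1L) {
    add("UtilitySpec", "utility.incont_coefs",
        sprintf("expected %d coefficients (levels 1..%d)", L - 1L, L - 1L))
  }
  if (is.finite(ut$base_utility) &&
      ut$base_utility + max(c(ut$mict_coefs, 0)) +
      max(c(ut$incont_coefs, 0)) > 1 + tol) {
    add("UtilitySpec", "utility.base_utility",
        "resulting state utilities must be <= 1")
  }

  ## cost
  cs <- params$cost
  for (f in c("pad_unit_cost", "gp_first_visit", "gp_followup",
              "specialist_visit", "specialist_visits_at_initiation",
              "btxa_injection_cost")) {
    if (!is_scalar_number(cs[[f]]) || cs[[f]] < 0) {
      add("CostSpec", paste0("cost.", f), "cost must be >= 0")
    }
  }
  if (length(cs$pads_per_month) != L) {
    add("CostSpec", "cost.pads_per_month",
        sprintf("expected %d pad counts (one per incontinence level)", L))
  } else {
    if (any(cs$pads_per_month < 0)) {
      add("CostSpec", "cost.pads_per_month", "pad counts must be >= 0")
    }
    if (is.unsorted(cs$pads_per_month)) {
      add("CostSpec", "cost.pads_per_month",
          "pad counts must be nondecreasing in incontinence level")
    }
  }

  ## settings
  st <- params$settings
  B <- st$baseline_distribution
  if (!is.matrix(B) || nrow(B) != ncol(B)) {
    add("Settings", "settings.baseline_distribution",
        "must be a square matrix")
  } else {
    if (any(B < 0)) {
      add("Settings", "settings.baseline_distribution",
          "entries must be >= 0")
    }
    if (abs(sum(B) - 1) > tol) {
      add("Settings", "settings.baseline_distribution",
          sprintf("entries must sum to 1 (sum = %.6g)", sum(B)))
    }
  }
  if (!is_scalar_number(st$annual_discount_rate) ||
      st$annual_discount_rate < 0) {
    add("Settings", "settings.annual_discount_rate",
        "discount rate must be >= 0")
  }
  if (!is_scalar_number(st$horizon) || st$horizon < 0 ||
      st$horizon %% st$cycle_length != 0) {
    add("Settings", "settings.horizon",
        "horizon must be a nonnegative multiple of cycle_length")
  }
  for (dim in c("micturition", "incontinence")) {
    mp <- st$severity_midpoints[[dim]]
    if (length(mp) != L || any(!is.finite(mp)) || is.unsorted(mp)) {
      add("Settings", paste0("settings.severity_midpoints.", dim),
          sprintf("expected %d finite nondecreasing daily counts", L))
    }
  }
  if (!is.null(st$btxa_symptom_distribution)) {
    Bx <- st$btxa_symptom_distribution
    if (!is.matrix(Bx) || nrow(Bx) != L || ncol(Bx) != L ||
        any(Bx < 0) || abs(sum(Bx) - 1) > tol) {
      add("Settings", "settings.btxa_symptom_distribution",
          "must be an L x L nonnegative matrix summing to 1")
    }
  }

  ## transition models (optional until estimation attaches them)
  if (!is.null(params$transition_models)) {
    for (nm in names(params$transition_models)) {
      if (!nm %in% names(params$drugs)) {
        add("TransitionModel", paste0("transition_models.", nm),
            "drug name does not resolve")
        next
      }
      tm <- params$transition_models[[nm]]
      for (dim in c("micturition", "incontinence")) {
        for (m in 1:3) {
          M <- tm[[dim]][[m]]
          if (!is_row_stochastic(M) || nrow(M) != L) {
            add("TransitionModel",
                sprintf("transition_models.%s.%s.month%d", nm, dim, m),
                "matrix must be L x L row-stochastic")
          }
        }
      }
    }
  }

  if (length(v) == 0L) {
    return(data.frame(type = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
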