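# Structured-text (YAML) configuration mirroring the model's parameter
# tables. Unknown keys are hard errors: silent typos in health-economic
# inputs are a known failure mode.

config_schema <- list(
  top = c("schema_version", "drugs", "pathway", "utility", "cost",
          "settings"),
  drug = c("monthly_cost", "ae_prob_3m", "discontinuation_monthly_no_ae",
           "nma_mean_diff", "ae_odds_ratio", "is_reference", "dsa"),
  ae = c("dry_mouth", "constipation"),
  nma = c("micturitions_per_day", "incontinence_per_day"),
  pathway = c("p_discontinue_ae", "p_discontinue_no_ae",
              "p_switch_after_discontinuation", "p_restart_monthly",
              "restart_split", "p_btxa_monthly", "p_btxa_reinjection_6m",
              "next_line_a", "next_line_b", "next_line_transition_source",
              "scenario_discontinuation", "dsa"),
  utility = c("base_utility", "mict_coefs", "incont_coefs", "ae_decrement",
              "dsa"),
  cost = c("pads_per_month", "pad_unit_cost", "gp_first_visit",
           "gp_followup", "specialist_visit",
           "specialist_visits_at_initiation", "btxa_injection_cost",
           "dsa"),
  settings = c("cycle_length", "horizon", "annual_discount_rate",
               "baseline_distribution", "severity_midpoints", "wtp_grid",
               "seed", "half_cycle_correction",
               "btxa_symptom_distribution"),
  baseline = c("decay", "matrix"),
  midpoints = c("micturition", "incontinence")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0L) {
    abort_oab(sprintf("unknown key%s in %s: %s",
                      if (length(bad) > 1) "s" else "", where,
                      paste(bad, collapse = ", ")),
              class = "oab_schema_error")
  }
  invisible(x)
}

parse_baseline <- function(x, where) {
  if (is.null(x)) return(baseline_from_decay())
  if (!is.list(x)) abort_oab(sprintf("%s must be a mapping", where),
                             class = "oab_schema_error")
  check_keys(x, config_schema$baseline, where)
  if (!is.null(x$matrix)) {
    do.call(rbind, lapply(x$matrix, as.numeric))
  } else if (!is.null(x$decay)) {
    baseline_from_decay(as.numeric(x$decay))
  } else {
    abort_oab(sprintf("%s needs either 'decay' or 'matrix'", where),
              class = "oab_schema_error")
  }
}

parse_matrix_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  do.call(rbind, lapply(x, as.numeric))
}

#' Load a parameter set from a structured-text configuration file
#'
#' Reads the documented YAML schema (see
#' `system.file("extdata", "default_config.yaml", package = "oabcea")`),
#' fills defaults for omitted fields, rejects unknown keys, and validates
#' every type invariant. Transition matrices are not part of the
#' configuration; they are attached by the estimation / calibration
#' pipeline (see [make_default_paramset()], [build_transition_models()]).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `oab_paramset`.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) {
    abort_oab(sprintf("configuration file not found: %s", path),
              class = "oab_io_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_oab(sprintf("cannot parse configuration %s: %s", path,
                      conditionMessage(e)), class = "oab_schema_error")
  })
  params <- params_from_list(raw)
  viol <- validate_parameter_set(params)
  if (nrow(viol) > 0L) {
    abort_oab(paste0("parameter validation failed:\n",
                     paste(sprintf("  - [%s] %s: %s", viol$type,
                                   viol$field, viol$rule),
                           collapse = "\n")),
              class = "oab_validation_error")
  }
  params
}

params_from_list <- function(raw) {
  check_keys(raw, config_schema$top, "configuration")
  if (is.null(raw$drugs) || length(raw$drugs) == 0L) {
    abort_oab("configuration must define at least one drug under 'drugs'",
              class = "oab_schema_error")
  }

  drugs <- lapply(names(raw$drugs), function(nm) {
    d <- raw$drugs[[nm]]
    check_keys(d, config_schema$drug, sprintf("drugs.%s", nm))
    if (!is.null(d$ae_prob_3m)) {
      check_keys(d$ae_prob_3m, config_schema$ae,
                 sprintf("drugs.%s.ae_prob_3m", nm))
    }
    if (!is.null(d$nma_mean_diff)) {
      check_keys(d$nma_mean_diff, config_schema$nma,
                 sprintf("drugs.%s.nma_mean_diff", nm))
    }
    if (!is.null(d$ae_odds_ratio)) {
      check_keys(d$ae_odds_ratio, config_schema$ae,
                 sprintf("drugs.%s.ae_odds_ratio", nm))
    }
    args <- d[intersect(names(d), config_schema$drug)]
    args$name <- nm
    do.call(drug_spec, args)
  })
  names(drugs) <- names(raw$drugs)

  pw_args <- raw$pathway %||% list()
  check_keys(pw_args, config_schema$pathway, "pathway")
  if (!is.null(pw_args$restart_split)) {
    pw_args$restart_split <- unlist(pw_args$restart_split)
  }
  pathway <- do.call(pathway_spec, pw_args)

  ut_args <- raw$utility %||% list()
  check_keys(ut_args, config_schema$utility, "utility")
  utility <- do.call(utility_spec, ut_args)

  cs_args <- raw$cost %||% list()
  check_keys(cs_args, config_schema$cost, "cost")
  cost <- do.call(cost_spec, cs_args)

  st_raw <- raw$settings %||% list()
  check_keys(st_raw, config_schema$settings, "settings")
  st_args <- st_raw
  st_args$baseline_distribution <-
    parse_baseline(st_raw$baseline_distribution,
                   "settings.baseline_distribution")
  if (!is.null(st_raw$severity_midpoints)) {
    check_keys(st_raw$severity_midpoints, config_schema$midpoints,
               "settings.severity_midpoints")
    st_args$severity_midpoints <-
      lapply(st_raw$severity_midpoints, as.numeric)
  }
  st_args$btxa_symptom_distribution <-
    parse_matrix_or_null(st_raw$btxa_symptom_distribution)
  settings <- do.call(model_settings, st_args)

  param_set(drugs = drugs, pathway = pathway, utility = utility,
            cost = cost, settings = settings,
            schema_version = raw$schema_version %||% "1.0")
}

params_to_list <- function(params) {
  drugs <- lapply(params$drugs, function(d) {
    out <- list(
      monthly_cost = d$monthly_cost,
      ae_prob_3m = d$ae_prob_3m,
      discontinuation_monthly_no_ae = d$discontinuation_monthly_no_ae,
      nma_mean_diff = d$nma_mean_diff,
      is_reference = d$is_reference
    )
    if (!is.null(d$ae_odds_ratio)) out$ae_odds_ratio <- d$ae_odds_ratio
    if (length(d$dsa) > 0L) out$dsa <- d$dsa
    out
  })
  pw <- unclass(params$pathway)
  pw$restart_split <- as.list(pw$restart_split)
  pw <- pw[!vapply(pw, is.null, logical(1))]
  if (length(pw$dsa) == 0L) pw$dsa <- NULL
  ut <- unclass(params$utility)
  if (length(ut$dsa) == 0L) ut$dsa <- NULL
  cs <- unclass(params$cost)
  if (length(cs$dsa) == 0L) cs$dsa <- NULL
  st <- unclass(params$settings)
  st$baseline_distribution <-
    list(matrix = lapply(seq_len(nrow(st$baseline_distribution)),
                         function(i) st$baseline_distribution[i, ]))
  if (!is.null(st$btxa_symptom_distribution)) {
    st$btxa_symptom_distribution <-
      lapply(seq_len(nrow(st$btxa_symptom_distribution)),
             function(i) st$btxa_symptom_distribution[i, ])
  } else {
    st$btxa_symptom_distribution <- NULL
  }
  list(schema_version = params$schema_version, drugs = drugs,
       pathway = pw, utility = ut, cost = cs, settings = st)
}

#' Write a parameter set to a configuration file
#'
#' Inverse of [load_parameter_set()]: a written set reloads to an
#' equivalent parameterization (transition models, which are not part of
#' the configuration schema, excepted).
#'
#' @param params An `oab_paramset`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path, precision = 15)
  invisible(path)
}

#' Read a drug table from CSV
#'
#' Import helper mirroring the per-drug rows of the model's input tables.
#' Fixed header: `name, monthly_cost, is_reference, dry_mouth_3m,
#' constipation_3m, discontinuation_monthly_no_ae, mean_diff_micturitions,
#' mean_diff_incontinence`.
#'
#' @param path CSV path (UTF-8, comma separated, header row).
#' @return Named list of [drug_spec()] objects.
#' @export
read_drug_table <- function(path) {
  expected <- c("name", "monthly_cost", "is_reference", "dry_mouth_3m",
                "constipation_3m", "discontinuation_monthly_no_ae",
                "mean_diff_micturitions", "mean_diff_incontinence")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), expected)) {
    abort_oab(paste0("drug table must have header: ",
                     paste(expected, collapse = ", ")),
              class = "oab_schema_error")
  }
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    drug_spec(
      name = df$name[i],
      monthly_cost = df$monthly_cost[i],
      ae_prob_3m = list(dry_mouth = df$dry_mouth_3m[i],
                        constipation = df$constipation_3m[i]),
      discontinuation_monthly_no_ae =
        df$discontinuation_monthly_no_ae[i],
      nma_mean_diff = list(
        micturitions_per_day = df$mean_diff_micturitions[i],
        incontinence_per_day = df$mean_diff_incontinence[i]),
      is_reference = as.logical(df$is_reference[i])
    )
  })
  names(drugs) <- df$name
  drugs
}

#' Write a drug table to CSV
#'
#' @param drugs Named list of [drug_spec()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(drugs, path) {
  df <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(
      name = d$name, monthly_cost = d$monthly_cost,
      is_reference = d$is_reference,
      dry_mouth_3m = d$ae_prob_3m$dry_mouth,
      constipation_3m = d$ae_prob_3m$constipation,
      discontinuation_monthly_no_ae = d$discontinuation_monthly_no_ae,
      mean_diff_micturitions = d$nma_mean_diff$micturitions_per_day,
      mean_diff_incontinence = d$nma_mean_diff$incontinence_per_day,
      stringsAsFactors = FALSE
    )
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
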