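#' Month-indexed symptom transition model for one drug
#'
#' Holds, for each symptom dimension, the monthly `L x L` row-stochastic
#' transition matrices for months 1-3 on treatment. After month 3 the
#' month-3 matrix is reused (sustained treatment effect).
#'
#' @param drug Drug name.
#' @param micturition,incontinence Lists of three `L x L` matrices
#'   (months 1, 2, 3).
#' @return A list of class `oab_transition_model`.
#' @export
transition_model <- function(drug, micturition, incontinence) {
  tm <- structure(list(drug = drug,
                       micturition = micturition,
                       incontinence = incontinence,
                       post_month3_rule = "reuse month-3 matrix"),
                  class = "oab_transition_model")
  validate_transition_model(tm)
  tm
}

#' Validate a transition model
#'
#' @param tm An `oab_transition_model`.
#' @param tol Row-sum tolerance.
#' @return `tm`, invisibly; errors if any matrix is not row-stochastic.
#' @export
validate_transition_model <- function(tm, tol = 1e-9) {
  for (dim in c("micturition", "incontinence")) {
    mats <- tm[[dim]]
    if (length(mats) != 3L) {
      abort_oab(sprintf("transition model (%s) needs matrices for months 1-3",
                        dim))
    }
    for (m in 1:3) {
      if (!is_row_stochastic(mats[[m]], tol)) {
        abort_oab(sprintf(
          "transition matrix (%s, month %d) is not row-stochastic", dim, m))
      }
    }
  }
  invisible(tm)
}

#' Convert a 3-month probability to its monthly equivalent
#'
#' Constant-hazard conversion `1 - (1 - p3m)^(1/3)`: the monthly
#' probability that, applied as three independent monthly risks,
#' reproduces the 3-month cumulative probability. Used because adverse
#' event probabilities are reported at 3 months but the model cycle is one
#' month.
#'
#' @param p3m Probability over 3 months, in `[0, 1]` (vectorized).
#' @return Monthly probability.
#' @export
#' @examples
#' three_month_to_monthly_prob(0.143)  # 0.0501
three_month_to_monthly_prob <- function(p3m) {
  check_prob(p3m, "p3m")
  1 - (1 - p3m)^(1 / 3)
}

#' Adjust a probability by an odds ratio
#'
#' Applies an NMA odds ratio to a reference probability on the odds scale:
#' `OR * o / (1 + OR * o)` with `o = p / (1 - p)`. Used to derive
#' comparator adverse-event probabilities from the reference drug's.
#'
#' @param p_ref Reference probability in `[0, 1)`.
#' @param or_value Odds ratio, `> 0`.
#' @return Adjusted probability.
#' @export
#' @examples
#' adjust_probability_by_odds_ratio(0.143, 1.5)  # 0.2002
adjust_probability_by_odds_ratio <- function(p_ref, or_value) {
  if (!is.numeric(p_ref) || anyNA(p_ref) || any(p_ref < 0) ||
      any(p_ref >= 1)) {
    abort_oab("p_ref must lie in [0, 1) (odds are infinite at 1)")
  }
  if (!is.numeric(or_value) || anyNA(or_value) || any(or_value <= 0)) {
    abort_oab("or_value must be > 0")
  }
  o <- or_value * p_ref / (1 - p_ref)
  o / (1 + o)
}

#' Daily episode count attached to a severity level
#'
#' The level-to-count bridge used by the calibration: each severity level
#' maps to a representative daily count (configurable midpoints).
#'
#' @param level Integer severity level in `1..L`.
#' @param dimension `"micturition"` or `"incontinence"`.
#' @param midpoints `severity_midpoints` list from [model_settings()].
#' @return Episodes per day.
#' @export
severity_to_daily_count <- function(level, dimension, midpoints) {
  dimension <- match.arg(dimension, c("micturition", "incontinence"))
  mp <- midpoints[[dimension]]
  if (any(level != as.integer(level)) || any(level < 1) ||
      any(level > length(mp))) {
    abort_oab(sprintf("severity level must be an integer in 1..%d",
                      length(mp)))
  }
  mp[level]
}

## ---- transition regression -------------------------------------------

level_column <- function(dimension) {
  switch(dimension, micturition = "mict_level",
         incontinence = "incont_level")
}

# origin/destination pairs for month m (destination at month m, origin at
# month m-1), from long patient records
transition_pairs <- function(records, dimension, m) {
  col <- level_column(dimension)
  a <- records[records$month == m - 1L, c("patient_id", col)]
  b <- records[records$month == m, c("patient_id", col)]
  names(a)[2] <- "origin"; names(b)[2] <- "dest"
  merge(a, b, by = "patient_id")
}

#' Fit monthly symptom transition matrices from patient-level data
#'
#' Estimates, for months 1-3, the `L x L` matrices of
#' `P(level_m = j | level_{m-1} = i)`. The default `"saturated"`
#' specification has one parameter block per origin level, whose maximum
#' likelihood estimates are the observed destination frequencies (computed
#' in closed form). `"smoothed"` fits a multinomial logit linear in origin
#' level via [nnet::multinom()]. Origin levels with no observations get an
#' identity row and are flagged in the `"flagged"` attribute.
#'
#' @param records Data frame with columns `patient_id`, `month` (0-3) and
#'   `mict_level` / `incont_level`.
#' @param dimension `"micturition"` or `"incontinence"`.
#' @param method `"saturated"` (default) or `"smoothed"`.
#' @param n_levels Number of severity levels.
#' @return Named list `month1`..`month3` of row-stochastic matrices, with
#'   attribute `flagged` listing (month, origin) pairs that had no data.
#' @export
fit_transition_regression <- function(records, dimension,
                                      method = c("saturated", "smoothed"),
                                      n_levels = 5L) {
  dimension <- match.arg(dimension, c("micturition", "incontinence"))
  method <- match.arg(method)
  if (is.null(records) || nrow(records) == 0L) {
    abort_oab("no patient records supplied")
  }
  L <- n_levels
  flagged <- list()
  mats <- lapply(1:3, function(m) {
    pairs <- transition_pairs(records, dimension, m)
    if (nrow(pairs) == 0L) {
      abort_oab(sprintf("no origin/destination pairs for month %d", m))
    }
    M <- diag(L)
    if (method == "saturated") {
      tab <- table(factor(pairs$origin, levels = 1:L),
                   factor(pairs$dest, levels = 1:L))
      for (i in 1:L) {
        tot <- sum(tab[i, ])
        if (tot == 0) {
          flagged[[length(flagged) + 1L]] <<- c(month = m, origin = i)
        } else {
          M[i, ] <- as.numeric(tab[i, ]) / tot
        }
      }
    } else {
      fit <- nnet::multinom(factor(dest, levels = 1:L) ~ origin,
                            data = pairs, trace = FALSE, maxit = 500)
      if (!is.null(fit$convergence) && fit$convergence != 0) {
        abort_oab(sprintf(
          "multinomial logit did not converge for month %d (value %.4g)",
          m, fit$value), class = "oab_estimation_error")
      }
      pr <- predict(fit, newdata = data.frame(origin = 1:L),
                    type = "probs")
      pr <- matrix(pr, nrow = L,
                   ncol = length(fit$lev))  # single-row predict safety
      observed <- sort(unique(pairs$origin))
      for (i in 1:L) {
        if (i %in% observed || method == "smoothed") {
          M[i, as.integer(fit$lev)] <- pr[i, ]
        }
      }
      missing_orig <- setdiff(1:L, observed)
      for (i in missing_orig) {
        flagged[[length(flagged) + 1L]] <<- c(month = m, origin = i)
      }
    }
    M
  })
  names(mats) <- paste0("month", 1:3)
  attr(mats, "flagged") <- flagged
  mats
}

#' Fit the EQ-5D utility regression
#'
#' Ordinary least squares of the EQ-5D index on indicator terms for
#' micturition levels 1..L-1 and incontinence levels 1..L-1 (level L is
#' the reference), adjusting for sex, age and country when those columns
#' are present. Mirrors the published utility model; the intercept is the
#' utility of the worst state at reference covariate values.
#'
#' @param records Data frame with `eq5d_index`, `mict_level`,
#'   `incont_level` and optionally `sex`, `age`, `country`.
#' @param n_levels Number of severity levels.
#' @return List with elements `utility` (a [utility_spec()] built from the
#'   estimates), `coefficients`, `se` (named vectors) and `fit` summary
#'   statistics.
#' @export
fit_utility_regression <- function(records, n_levels = 5L) {
  if (is.null(records) || nrow(records) == 0L) {
    abort_oab("no patient records supplied")
  }
  L <- n_levels
  df <- records
  df$mict_f <- factor(df$mict_level, levels = c(L, 1:(L - 1)))
  df$incont_f <- factor(df$incont_level, levels = c(L, 1:(L - 1)))
  for (term in c("mict_f", "incont_f")) {
    if (length(unique(df[[term]])) < 2L) {
      abort_oab(paste0("utility regression design matrix is rank ",
                       "deficient; collinear terms: ", term,
                       " (single observed level)"),
                class = "oab_estimation_error")
    }
  }
  covs <- intersect(c("sex", "age", "country"), names(df))
  covs <- covs[vapply(covs, function(cv)
    length(unique(df[[cv]])) > 1L, logical(1))]  # drop constants
  rhs <- c("mict_f", "incont_f", covs)
  form <- as.formula(paste("eq5d_index ~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort_oab(paste0("utility regression design matrix is rank deficient; ",
                     "collinear terms: ",
                     paste(names(cf)[is.na(cf)], collapse = ", ")),
              class = "oab_estimation_error")
  }
  # noiseless (perfectly interpolating) data triggers a benign
  # "essentially perfect fit" warning from summary.lm
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  pick <- function(prefix) {
    vapply(1:(L - 1), function(l) unname(cf[paste0(prefix, l)]),
           numeric(1))
  }
  est <- utility_spec(
    base_utility = unname(cf["(Intercept)"]),
    mict_coefs = pick("mict_f"),
    incont_coefs = pick("incont_f"),
    ae_decrement = -0.0357  # not identifiable from symptom-only records
  )
  sm <- suppressWarnings(summary(fit))
  list(utility = est, coefficients = cf, se = se,
       fit = list(sigma = sm$sigma, r_squared = sm$r.squared,
                  n = nrow(df)))
}

## ---- calibration ------------------------------------------------------

#' Latent-scale shift of a row-stochastic matrix
#'
#' One-parameter monotone family used by the calibration: each row's
#' cumulative destination probabilities are shifted by `delta` on the
#' logit scale (a proportional-odds shift over the ordered destination
#' levels) and differenced back. Positive `delta` moves mass toward lower
#' (better) levels; `delta = 0` is the identity.
#'
#' @param M Row-stochastic matrix.
#' @param delta Latent additive shift.
#' @return Shifted row-stochastic matrix.
#' @export
shift_transition_matrix <- function(M, delta) {
  L <- ncol(M)
  out <- M
  for (i in seq_len(nrow(M))) {
    cum <- cumsum(M[i, ])[-L]
    shifted <- ifelse(cum <= 0, 0,
                      ifelse(cum >= 1, 1, plogis(qlogis(cum) + delta)))
    out[i, ] <- diff(c(0, shifted, 1))
  }
  out
}

shift_dimension <- function(mats, delta) lapply(mats, shift_transition_matrix,
                                                delta = delta)

baseline_marginal <- function(baseline, dimension) {
  if (is.matrix(baseline)) {
    if (dimension == "micturition") rowSums(baseline) else
      colSums(baseline)
  } else {
    as.numeric(baseline)
  }
}

#' Model-predicted change in daily episode count at month 3
#'
#' Expected daily count after applying the month 1-3 matrices to the
#' baseline severity distribution, minus the baseline expected count,
#' using the configured severity midpoints. This is the quantity matched
#' against NMA effects during calibration.
#'
#' @param mats List of three `L x L` matrices (months 1-3), or an
#'   `oab_transition_model` (the dimension's matrices are extracted).
#' @param baseline Baseline distribution: `L`-vector marginal or `L x L`
#'   joint matrix.
#' @param dimension `"micturition"` or `"incontinence"`.
#' @param midpoints `severity_midpoints` list.
#' @return Change in episodes/day (negative = improvement).
#' @export
predicted_mean_change <- function(mats, baseline, dimension, midpoints) {
  dimension <- match.arg(dimension, c("micturition", "incontinence"))
  if (inherits(mats, "oab_transition_model")) mats <- mats[[dimension]]
  b <- baseline_marginal(baseline, dimension)
  b <- b / sum(b)
  mid <- midpoints[[dimension]]
  v <- b
  for (m in 1:3) v <- as.numeric(v %*% mats[[m]])
  sum(v * mid) - sum(b * mid)
}

#' Calibrate a comparator's transition matrices to an NMA effect
#'
#' Finds the scalar latent shift `delta` (applied uniformly to the months
#' 1-3 matrices via [shift_transition_matrix()]) that minimizes the squared
#' difference between the calibrated model's predicted month-3 change in
#' daily episode count and the target `reference change + target_diff`,
#' where `target_diff` is the NMA mean difference versus the reference
#' drug. The search is a deterministic bounded scalar minimization
#' ([stats::optimize()]).
#'
#' @param ref_mats Reference drug's matrices for one dimension (list of 3)
#'   or an `oab_transition_model`.
#' @param target_diff NMA mean difference in episodes/day versus the
#'   reference (positive = comparator worse).
#' @param baseline Baseline distribution (vector or joint matrix).
#' @param dimension `"micturition"` or `"incontinence"`.
#' @param midpoints `severity_midpoints` list.
#' @param interval Search interval for `delta`.
#' @return List with `result` (drug-agnostic calibration summary: `delta`,
#'   `achieved_change`, `target_change`, `objective_value`) and `mats`
#'   (the calibrated matrices).
#' @export
calibrate_comparator_transitions <- function(ref_mats, target_diff,
                                             baseline, dimension,
                                             midpoints,
                                             interval = c(-8, 8)) {
  dimension <- match.arg(dimension, c("micturition", "incontinence"))
  if (inherits(ref_mats, "oab_transition_model")) {
    ref_mats <- ref_mats[[dimension]]
  }
  if (!is.finite(target_diff)) abort_oab("target_diff must be finite")
  ref_change <- predicted_mean_change(ref_mats, baseline, dimension,
                                      midpoints)
  target <- ref_change + target_diff
  obj <- function(delta) {
    (predicted_mean_change(shift_dimension(ref_mats, delta), baseline,
                           dimension, midpoints) - target)^2
  }
  opt <- optimize(obj, interval = interval, tol = 1e-12)
  delta <- opt$minimum
  # the family is exactly the identity at 0; snap near-zero solutions so
  # a zero target reproduces the reference matrices bit-for-bit
  if (abs(target_diff) < 1e-14 && obj(0) <= opt$objective + 1e-18) {
    delta <- 0
  }
  mats <- shift_dimension(ref_mats, delta)
  achieved <- predicted_mean_change(mats, baseline, dimension, midpoints)
  objective <- (achieved - target)^2
  if (sqrt(objective) > 1e-4 * max(1, abs(target))) {
    warn_oab(sprintf(
      "calibration target %.4f not reached (achieved %.4f) within delta bounds",
      target, achieved), class = "oab_calibration_warning")
  }
  list(result = list(delta = delta, achieved_change = achieved,
                     target_change = target,
                     objective_value = objective),
       mats = mats)
}

#' Build calibrated transition models for every comparator
#'
#' Takes the reference drug's fitted transition model and, for each other
#' drug, calibrates a latent shift per symptom dimension to that drug's
#' NMA mean differences. The reference model itself is attached unchanged;
#' next-line therapy phases use the model of
#' `pathway$next_line_transition_source` at run time.
#'
#' @param params An `oab_paramset`.
#' @param ref_model The reference drug's `oab_transition_model`. Defaults
#'   to the one already attached to `params`.
#' @param drugs Drugs to (re)calibrate; default all non-reference drugs.
#' @return `params` with `transition_models` filled and a
#'   `calibration` attribute (per-drug, per-dimension summaries).
#' @export
build_transition_models <- function(params, ref_model = NULL,
                                    drugs = NULL) {
  ref <- reference_drug(params)
  ref_model <- ref_model %||% params$transition_models[[ref]]
  if (is.null(ref_model)) {
    abort_oab("no transition model available for the reference drug",
              class = "oab_config_error")
  }
  validate_transition_model(ref_model)
  drugs <- drugs %||% setdiff(names(params$drugs), ref)
  if (is.null(params$transition_models)) {
    params$transition_models <- list()
  }
  params$transition_models[[ref]] <- ref_model
  B <- params$settings$baseline_distribution
  mid <- params$settings$severity_midpoints
  calib <- attr(params$transition_models, "calibration") %||% list()
  for (nm in drugs) {
    d <- params$drugs[[nm]]
    per_dim <- list()
    mats <- list()
    for (dim in c("micturition", "incontinence")) {
      td <- switch(dim,
                   micturition = d$nma_mean_diff$micturitions_per_day,
                   incontinence = d$nma_mean_diff$incontinence_per_day)
      cal <- calibrate_comparator_transitions(ref_model[[dim]],
                                              td %||% 0, B, dim, mid)
      per_dim[[dim]] <- cal$result
      mats[[dim]] <- cal$mats
    }
    params$transition_models[[nm]] <-
      transition_model(nm, mats$micturition, mats$incontinence)
    calib[[nm]] <- per_dim
  }
  attr(params$transition_models, "calibration") <- calib
  params
}

## ---- matrix CSV interchange ------------------------------------------

#' Write a transition matrix to CSV
#'
#' 5x5 (or `L x L`) matrix with a header row/column of levels.
#'
#' @param M Matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(M, path) {
  df <- as.data.frame(M)
  names(df) <- paste0("to_level_", seq_len(ncol(M)))
  df <- cbind(from_level = seq_len(nrow(M)), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' @param path CSV path written by [write_transition_matrix()].
#' @return Matrix.
#' @export
read_transition_matrix <- function(path) {
  df <- read.csv(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- NULL
  if (!is_row_stochastic(M, tol = 1e-6)) {
    abort_oab(sprintf("matrix read from %s is not row-stochastic", path))
  }
  M
}
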