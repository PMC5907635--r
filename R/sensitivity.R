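# Deterministic (tornado) and probabilistic sensitivity analyses, and the
# observational-discontinuation-rates scenario. Parameters are addressed
# by dotted paths into the parameter set, e.g.
# "drugs.tolterodine_er_4mg.ae_prob_3m.dry_mouth",
# "pathway.p_restart_monthly", "utility.mict_coefs.2",
# "cost.pads_per_month.5".

path_parts <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Read a parameter by dotted path
#'
#' @param params An `oab_paramset`.
#' @param path Dotted path string; numeric components index vectors.
#' @return The value.
#' @export
get_param_by_path <- function(params, path) {
  x <- params
  for (p in path_parts(path)) {
    i <- suppressWarnings(as.integer(p))
    x <- if (!is.na(i) && !is.list(x)) x[[i]] else x[[p]]
    if (is.null(x)) {
      abort_oab(sprintf("unknown parameter path: %s", path))
    }
  }
  x
}

#' Set a parameter by dotted path
#'
#' @param params An `oab_paramset`.
#' @param path Dotted path string.
#' @param value Replacement value.
#' @return Modified `oab_paramset` (derived quantities not yet rebuilt;
#'   see [rebuild_derived()]).
#' @export
set_param_by_path <- function(params, path, value) {
  get_param_by_path(params, path)  # errors on unknown path
  parts <- path_parts(path)
  assign_rec <- function(x, parts, value) {
    p <- parts[1]
    i <- suppressWarnings(as.integer(p))
    key <- if (!is.na(i) && !is.list(x)) i else p
    if (length(parts) == 1L) {
      x[[key]] <- value
    } else {
      x[[key]] <- assign_rec(x[[key]], parts[-1], value)
    }
    x
  }
  assign_rec(params, parts, value)
}

#' Rebuild derived quantities after changing parameters
#'
#' Recalibrates the transition models that the next run will use (the
#' comparator's and the next-line transition source's) against the
#' current NMA mean differences, baseline distribution and severity
#' midpoints. The reference drug's model is left untouched.
#'
#' @param params An `oab_paramset`.
#' @param comparator Comparator drug of the upcoming run; `NULL`
#'   recalibrates every non-reference drug.
#' @return Updated `oab_paramset`.
#' @export
rebuild_derived <- function(params, comparator = NULL) {
  ref <- reference_drug(params)
  drugs <- if (is.null(comparator)) {
    setdiff(names(params$drugs), ref)
  } else {
    setdiff(unique(c(comparator,
                     params$pathway$next_line_transition_source)), ref)
  }
  build_transition_models(params, drugs = drugs)
}

#' Default deterministic-sensitivity ranges
#'
#' Collects the `[low, high]` ranges stored in the parameter set's `dsa`
#' blocks into a single map of dotted paths.
#'
#' @param params An `oab_paramset`.
#' @return Named list path -> `c(low, high)`.
#' @export
default_dsa_ranges <- function(params) {
  out <- list()
  for (nm in names(params$drugs)) {
    for (k in names(params$drugs[[nm]]$dsa)) {
      out[[paste0("drugs.", nm, ".", k)]] <-
        as.numeric(params$drugs[[nm]]$dsa[[k]])
    }
  }
  for (k in names(params$pathway$dsa)) {
    out[[paste0("pathway.", k)]] <- as.numeric(params$pathway$dsa[[k]])
  }
  for (k in names(params$utility$dsa)) {
    out[[paste0("utility.", k)]] <- as.numeric(params$utility$dsa[[k]])
  }
  for (k in names(params$cost$dsa)) {
    out[[paste0("cost.", k)]] <- as.numeric(params$cost$dsa[[k]])
  }
  out
}

run_at <- function(params, comparator, wtp) {
  res <- run_cea(params, comparator, wtp = wtp)
  c(delta_cost = res$cea$incremental_cost,
    delta_qalys = res$cea$incremental_qalys)
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' Each parameter is set to its lower and upper bound in turn (all others
#' at base case), derived transition models are recalibrated, both arms
#' are rerun, and the incremental cost and QALYs are recorded. Results
#' are sorted by outcome range for tornado display.
#'
#' @param params Base-case `oab_paramset`.
#' @param ranges Named list path -> `c(low, high)`; each range must
#'   bracket the base value. See [default_dsa_ranges()].
#' @param comparator Comparator drug.
#' @param wtp Willingness-to-pay threshold.
#' @return Data frame of class `oab_oneway`: one row per parameter with
#'   bounds, incremental outcomes at each bound and outcome ranges.
#' @export
run_one_way <- function(params, ranges, comparator, wtp = 30000) {
  empty <- data.frame(parameter = character(), low = numeric(),
                      high = numeric(), base = numeric(),
                      dc_low = numeric(), dq_low = numeric(),
                      dc_high = numeric(), dq_high = numeric(),
                      range_dc = numeric(), range_dq = numeric(),
                      stringsAsFactors = FALSE)
  if (length(ranges) == 0L) {
    return(structure(empty, class = c("oab_oneway", "data.frame")))
  }
  for (p in names(ranges)) {
    base <- get_param_by_path(params, p)
    r <- ranges[[p]]
    if (!(r[1] <= base + 1e-12 && base <= r[2] + 1e-12)) {
      abort_oab(sprintf(
        "range [%g, %g] for %s does not bracket base value %g",
        r[1], r[2], p, base), class = "oab_validation_error")
    }
  }
  rows <- lapply(names(ranges), function(p) {
    base <- get_param_by_path(params, p)
    r <- ranges[[p]]
    at <- function(val) {
      pp <- rebuild_derived(set_param_by_path(params, p, val),
                            comparator)
      run_at(pp, comparator, wtp)
    }
    lo <- at(r[1])
    hi <- at(r[2])
    data.frame(parameter = p, low = r[1], high = r[2], base = base,
               dc_low = lo["delta_cost"], dq_low = lo["delta_qalys"],
               dc_high = hi["delta_cost"], dq_high = hi["delta_qalys"],
               range_dc = abs(hi["delta_cost"] - lo["delta_cost"]),
               range_dq = abs(hi["delta_qalys"] - lo["delta_qalys"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$range_dc), ]
  structure(out, class = c("oab_oneway", "data.frame"))
}

## ---- probabilistic sensitivity analysis ------------------------------

psa_class_for_path <- function(path) {
  if (grepl("ae_prob_3m|discontinuation|pathway\\.p_", path)) "beta"
  else if (grepl("nma_mean_diff|utility\\.", path)) "normal"
  else if (grepl("pads_per_month|specialist_visits_at_initiation", path))
    "gamma"
  else if (grepl("odds_ratio", path)) "lognormal"
  else "normal"
}

#' Default PSA distribution specification
#'
#' One entry per DSA range: distribution family by parameter class
#' (beta for probabilities, normal for utility coefficients and NMA mean
#' differences, gamma for resource counts, lognormal for odds ratios),
#' with moments matched to the base value and the range treated as a 95%
#' interval (`SE = width / 3.92`).
#'
#' @param params An `oab_paramset`.
#' @param ranges Named list path -> `c(low, high)`; defaults to
#'   [default_dsa_ranges()].
#' @return Data frame path / class / base / low / high.
#' @export
default_psa_spec <- function(params, ranges = default_dsa_ranges(params)) {
  if (length(ranges) == 0L) {
    return(data.frame(path = character(), class = character(),
                      base = numeric(), low = numeric(),
                      high = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    path = names(ranges),
    class = vapply(names(ranges), psa_class_for_path, character(1)),
    base = vapply(names(ranges), function(p)
      get_param_by_path(params, p), numeric(1)),
    low = vapply(ranges, `[`, numeric(1), 1),
    high = vapply(ranges, `[`, numeric(1), 2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# one random draw per spec row; returns value and whether a moment-match
# fallback to uniform occurred
psa_draw <- function(class, base, low, high) {
  se <- (high - low) / 3.92
  if (se <= 0) return(list(value = base, fallback = FALSE))
  switch(class,
    beta = {
      m <- base
      v <- se^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        list(value = runif(1, low, high), fallback = TRUE)
      } else {
        a <- m * (m * (1 - m) / v - 1)
        b <- (1 - m) * (m * (1 - m) / v - 1)
        list(value = rbeta(1, a, b), fallback = FALSE)
      }
    },
    normal = list(value = rnorm(1, base, se), fallback = FALSE),
    gamma = {
      if (base <= 0) {
        list(value = runif(1, max(low, 0), high), fallback = TRUE)
      } else {
        v <- se^2
        list(value = rgamma(1, shape = base^2 / v, rate = base / v),
             fallback = FALSE)
      }
    },
    lognormal = {
      if (base <= 0 || low <= 0) {
        list(value = runif(1, low, high), fallback = TRUE)
      } else {
        sdlog <- (log(high) - log(low)) / 3.92
        list(value = rlnorm(1, log(base), sdlog), fallback = FALSE)
      }
    },
    abort_oab(sprintf("unknown PSA distribution class: %s", class)))
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter simultaneously from its assigned
#' distribution, recalibrates derived transition models, reruns both arms
#' and records the incremental cost and QALYs per iteration. A fixed seed
#' gives a bit-identical sample set.
#'
#' @param params Base-case `oab_paramset`.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer seed.
#' @param comparator Comparator drug.
#' @param psa_spec Distribution specification; defaults to
#'   [default_psa_spec()].
#' @param wtp Willingness-to-pay threshold.
#' @return Data frame of class `oab_psa`: `draw_id`, `delta_cost`,
#'   `delta_qalys`; drawn parameter values in the `"draws"` attribute and
#'   uniform-fallback counts in `"fallbacks"`.
#' @export
run_psa <- function(params, n_iter, seed, comparator,
                    psa_spec = default_psa_spec(params), wtp = 30000) {
  if (!is_scalar_number(n_iter) || n_iter < 1) {
    abort_oab("n_iter must be >= 1")
  }
  n_iter <- as.integer(n_iter)
  npar <- nrow(psa_spec)
  draws <- matrix(NA_real_, n_iter, npar,
                  dimnames = list(NULL, psa_spec$path))
  fallbacks <- setNames(integer(npar), psa_spec$path)
  dc <- numeric(n_iter); dq <- numeric(n_iter)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      p_it <- params
      if (npar > 0) {
        for (j in seq_len(npar)) {
          d <- psa_draw(psa_spec$class[j], psa_spec$base[j],
                        psa_spec$low[j], psa_spec$high[j])
          draws[it, j] <- d$value
          if (d$fallback) fallbacks[j] <- fallbacks[j] + 1L
          p_it <- set_param_by_path(p_it, psa_spec$path[j], d$value)
        }
      }
      p_it <- rebuild_derived(p_it, comparator)
      out <- run_at(p_it, comparator, wtp)
      dc[it] <- out["delta_cost"]
      dq[it] <- out["delta_qalys"]
    }
  })
  res <- data.frame(draw_id = seq_len(n_iter), delta_cost = dc,
                    delta_qalys = dq)
  attr(res, "draws") <- draws
  attr(res, "fallbacks") <- fallbacks
  class(res) <- c("oab_psa", "data.frame")
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA samples with
#' nonnegative net monetary benefit `w * dQ - dC`.
#'
#' @param samples PSA samples (data frame with `delta_cost`,
#'   `delta_qalys`).
#' @param wtp_grid Numeric vector of thresholds.
#' @return Data frame `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (is.null(samples) || nrow(samples) == 0L) {
    abort_oab("no PSA samples supplied")
  }
  prob <- vapply(wtp_grid, function(w)
    mean(w * samples$delta_qalys - samples$delta_cost >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Scenario analysis with observational discontinuation rates
#'
#' Replaces both the AE-driven and the no-AE discontinuation
#' probabilities with a single per-drug monthly rate (discontinuation
#' assumed identical with and without adverse events) and reruns the
#' comparison for each requested comparator.
#'
#' @param params Base-case `oab_paramset`.
#' @param per_drug_rates Named list/vector drug -> monthly
#'   discontinuation probability. Every drug used in a run (first-line
#'   drugs and the two next-line agents) must have a rate.
#' @param comparators Comparator drugs; default all non-reference drugs.
#' @param wtp Willingness-to-pay threshold.
#' @return Named list of `oab_cea_result`, one per comparator.
#' @export
run_scenario_discontinuation <- function(params, per_drug_rates,
                                         comparators = NULL,
                                         wtp = 30000) {
  rates <- as.list(per_drug_rates)
  for (nm in names(rates)) check_prob(rates[[nm]], paste0("rate for ", nm))
  unknown <- setdiff(names(rates), names(params$drugs))
  if (length(unknown) > 0) {
    abort_oab(paste0("rates given for unknown drugs: ",
                     paste(unknown, collapse = ", ")))
  }
  params$pathway$scenario_discontinuation <- rates
  ref <- reference_drug(params)
  # by default compare against every drug the rates table covers
  comparators <- comparators %||%
    setdiff(intersect(names(params$drugs), names(rates)), ref)
  out <- lapply(comparators, function(cmp)
    run_cea(params, cmp, wtp = wtp)$cea)
  names(out) <- comparators
  out
}

## ---- optional plots ---------------------------------------------------

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_oab("ggplot2 is required for plotting",
              class = "oab_config_error")
  }
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  require_ggplot()
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = wtp,
                                        y = probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective")
}

#' Plot the cost-effectiveness plane
#'
#' @param samples PSA samples from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples) {
  require_ggplot()
  ggplot2::ggplot(samples, ggplot2::aes(x = delta_qalys,
                                        y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)")
}

#' Tornado plot of one-way sensitivity results
#'
#' @param oneway Output of [run_one_way()].
#' @param outcome `"cost"` or `"qalys"`.
#' @return A ggplot object.
#' @export
plot_tornado <- function(oneway, outcome = c("cost", "qalys")) {
  require_ggplot()
  outcome <- match.arg(outcome)
  lo <- if (outcome == "cost") oneway$dc_low else oneway$dq_low
  hi <- if (outcome == "cost") oneway$dc_high else oneway$dq_high
  df <- data.frame(parameter = oneway$parameter, lo = lo, hi = hi)
  df$parameter <- factor(df$parameter,
                         levels = rev(oneway$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = parameter),
                          linewidth = 4, color = "steelblue") +
    ggplot2::labs(x = if (outcome == "cost")
      "Incremental cost (GBP)" else "Incremental QALYs", y = NULL)
}
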