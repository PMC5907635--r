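COST_CATEGORIES <- c("drug_acquisition", "other_oab_drugs", "gp_visits",
                     "specialist_visits", "btxa", "pads")

#' Discount factor for a model cycle
#'
#' `(1 + rate)^(-(cycle - 1)/12)`: cycle 1 is undiscounted and subsequent
#' monthly cycles are discounted at the annual rate (3.5%/year in the base
#' case).
#'
#' @param cycle 1-based cycle index (vectorized).
#' @param annual_rate Annual discount rate.
#' @return Discount multiplier(s).
#' @export
#' @examples
#' discount_factor(13, 0.035)  # 0.96618
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 1)) abort_oab("cycle index must be >= 1")
  (1 + annual_rate)^(-(cycle - 1) / 12)
}

incont_occupancy <- function(dist) {
  L <- dist$L
  m <- colSums(dist$mass)                     # occupancy per symptom cell
  il <- (seq_len(L * L) - 1L) %% L + 1L       # incontinence level per cell
  as.numeric(tapply(m, il, sum))
}

line_mass <- function(dist) {
  st <- dist$states
  rs <- rowSums(dist$mass)
  vapply(1:3, function(l)
    sum(rs[st$phase == "on" & st$line == l]), numeric(1))
}

#' Undiscounted cost of one cycle, by category
#'
#' Drug acquisition for the first-line drug, other OAB drug costs for the
#' next-line agents, GP and specialist visits driven by initiation
#' tallies (first-visit GP cost at model entry, follow-up thereafter),
#' BTX-A injections, and incontinence pads driven by incontinence-level
#' occupancy in all phases. Costing uses end-of-cycle occupancy, so
#' switchers pay the new drug from the switch cycle.
#'
#' @param dist End-of-cycle `oab_distribution`.
#' @param tally Per-capita event tally from [step_cycle()].
#' @param params The `oab_paramset`.
#' @param drug First-line drug of the arm (defaults to the engine context
#'   attached to `dist`).
#' @return Named cost vector over categories, GBP per capita.
#' @export
cycle_cost <- function(dist, tally, params, drug = NULL) {
  ctx <- attr(dist, "ctx")
  drug <- drug %||% ctx$drug
  pw <- params$pathway
  cs <- params$cost
  lm_ <- line_mass(dist)
  drug_costs <- c(params$drugs[[drug]]$monthly_cost,
                  params$drugs[[pw$next_line_a]]$monthly_cost,
                  params$drugs[[pw$next_line_b]]$monthly_cost)
  initiations <- unname(tally["initiations"])
  entry <- unname(tally["entry"])
  gp <- entry * cs$gp_first_visit + initiations * cs$gp_followup
  spec <- (entry + initiations) * cs$specialist_visit *
    cs$specialist_visits_at_initiation
  occ <- incont_occupancy(dist)
  pads <- sum(occ * cs$pads_per_month) * cs$pad_unit_cost
  c(drug_acquisition = lm_[1] * drug_costs[1],
    other_oab_drugs = lm_[2] * drug_costs[2] + lm_[3] * drug_costs[3],
    gp_visits = gp,
    specialist_visits = spec,
    btxa = unname(tally["btxa_injections"]) * cs$btxa_injection_cost,
    pads = pads)
}

#' Undiscounted QALYs accrued in one cycle
#'
#' Sum over states of occupancy times the state utility
#' `base + mict_coef(level) + incont_coef(level)`, with the adverse-event
#' decrement while an AE is active on treatment, times one month
#' (`1/12` year).
#'
#' @param dist End-of-cycle `oab_distribution`.
#' @param params The `oab_paramset`.
#' @return QALYs per capita for the cycle.
#' @export
cycle_qaly <- function(dist, params) {
  L <- dist$L
  ut <- params$utility
  mc <- c(ut$mict_coefs, 0)
  ic <- c(ut$incont_coefs, 0)
  cells <- seq_len(L * L)
  ml <- (cells - 1L) %/% L + 1L
  il <- (cells - 1L) %% L + 1L
  u_sym <- ut$base_utility + mc[ml] + ic[il]
  st <- dist$states
  on_ae <- st$phase == "on" & st$ae == 1L
  on_ae[is.na(on_ae)] <- FALSE
  total <- sum(dist$mass %*% u_sym) +
    sum(dist$mass[on_ae, , drop = FALSE]) * ut$ae_decrement
  total * (params$settings$cycle_length / 12)
}

#' Accumulate a trace into discounted per-arm results
#'
#' Per-cycle category costs and QALYs are discounted with
#' [discount_factor()] and summed over the horizon. With the optional
#' half-cycle correction, each cycle's contribution is averaged with the
#' previous cycle's occupancy value (off in the base case).
#'
#' @param trace An `oab_trace` from [run_cohort()].
#' @param params The `oab_paramset`.
#' @return An `oab_arm_result`: `cost_by_category`, `total_cost`,
#'   `total_qalys`, `arm`.
#' @export
accumulate <- function(trace, params) {
  r <- params$settings$annual_discount_rate
  hcc <- isTRUE(params$settings$half_cycle_correction)
  cost <- setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  qalys <- 0
  if (hcc && length(trace$cycles) > 0) {
    d0 <- build_initial_distribution(params, trace$arm)
    prev_cost <- cycle_cost(d0, empty_tally(), params, drug = trace$arm)
    prev_qaly <- cycle_qaly(d0, params)
  }
  for (t in seq_along(trace$cycles)) {
    cyc <- trace$cycles[[t]]
    df <- discount_factor(t, r)
    cc <- cycle_cost(cyc$dist, cyc$tally, params, drug = trace$arm)
    cq <- cycle_qaly(cyc$dist, params)
    if (hcc) {
      # occupancy-driven quantities averaged over the cycle; event-driven
      # tallies are already within-cycle expectations and enter once
      cc_use <- (cc + prev_cost) / 2
      ev <- c("gp_visits", "specialist_visits", "btxa")
      cc_use[ev] <- cc[ev]
      cq_use <- (cq + prev_qaly) / 2
      prev_cost <- cc; prev_qaly <- cq
      cc <- cc_use; cq <- cq_use
    }
    cost <- cost + df * cc
    qalys <- qalys + df * cq
  }
  structure(list(arm = trace$arm, cost_by_category = cost,
                 total_cost = sum(cost), total_qalys = qalys),
            class = "oab_arm_result")
}

#' Pairwise cost-effectiveness comparison
#'
#' Incremental cost and QALYs (intervention minus comparator), the ICER
#' `delta cost / delta QALYs` where defined, and a dominance
#' classification: `dominant` (cheaper and more effective), `dominated`
#' (costlier and less effective), `equivalent` (both increments zero), or
#' cost-effective / not cost-effective at the willingness-to-pay
#' threshold by the net-monetary-benefit rule.
#'
#' @param intervention,comparator `oab_arm_result` objects, or lists with
#'   `total_cost` and `total_qalys` (e.g. published per-arm totals).
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @return An `oab_cea_result` with `incremental_cost`,
#'   `incremental_qalys`, `icer` (`NA` when undefined),
#'   `classification`, `nmb`, `wtp`, and the two arm labels.
#' @export
#' @examples
#' compare(list(total_cost = 1733, total_qalys = 3.732),
#'         list(total_cost = 1756, total_qalys = 3.725))
compare <- function(intervention, comparator, wtp = 30000) {
  tol <- 1e-12
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  icer <- if (abs(dq) > tol) dc / dq else NA_real_
  nmb <- wtp * dq - dc
  classification <-
    if (abs(dc) <= tol && abs(dq) <= tol) "equivalent"
    else if (dc < -tol && dq > tol) "dominant"
    else if (dc > tol && dq < -tol) "dominated"
    else if (nmb >= 0) "cost_effective_at_wtp"
    else "not_cost_effective_at_wtp"
  structure(list(
    intervention = intervention$arm %||% "intervention",
    comparator = comparator$arm %||% "comparator",
    incremental_cost = dc, incremental_qalys = dq,
    icer = icer, classification = classification,
    nmb = nmb, wtp = wtp
  ), class = "oab_cea_result")
}

#' Net monetary benefit of a comparison
#'
#' `wtp * delta QALYs - delta cost`; nonnegative means cost-effective at
#' the threshold.
#'
#' @param cea An `oab_cea_result`.
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @return Net monetary benefit, GBP.
#' @export
net_monetary_benefit <- function(cea, wtp) {
  wtp * cea$incremental_qalys - cea$incremental_cost
}

#' Run a full pairwise cost-effectiveness analysis
#'
#' Runs the cohort for the reference drug and a comparator under the same
#' parameter set, accumulates discounted costs and QALYs, and compares.
#'
#' @param params A validated `oab_paramset` with transition models.
#' @param comparator Comparator drug name.
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @return List with `intervention` and `comparator` (`oab_arm_result`)
#'   and `cea` (`oab_cea_result`).
#' @export
run_cea <- function(params, comparator, wtp = 30000) {
  ref <- reference_drug(params)
  if (!comparator %in% names(params$drugs)) {
    abort_oab(sprintf("unknown comparator drug: %s", comparator))
  }
  arm_i <- accumulate(run_cohort(params, ref), params)
  arm_c <- accumulate(run_cohort(params, comparator), params)
  list(intervention = arm_i, comparator = arm_c,
       cea = compare(arm_i, arm_c, wtp = wtp))
}

#' Tabulate arm results in the published layout
#'
#' Rows are the six cost categories, total costs, total QALYs,
#' incremental costs and QALYs and the ICER/dominance field; columns are
#' the intervention and each comparator.
#'
#' @param results Named list of [run_cea()] outputs (names = comparator
#'   drugs).
#' @return Data frame.
#' @export
cea_table <- function(results) {
  stopifnot(length(results) > 0)
  first <- results[[1]]
  arms <- c(list(first$intervention),
            lapply(results, function(r) r$comparator))
  labels <- c(first$intervention$arm,
              vapply(results, function(r) r$comparator$arm, character(1)))
  rows <- c(COST_CATEGORIES, "total_costs", "total_qalys",
            "incremental_costs", "incremental_qalys", "icer")
  tab <- data.frame(quantity = rows, stringsAsFactors = FALSE)
  for (j in seq_along(arms)) {
    a <- arms[[j]]
    col <- c(round(unname(a$cost_by_category)), round(a$total_cost),
             round(a$total_qalys, 3), NA, NA, NA)
    tab[[labels[j]]] <- col
  }
  for (j in seq_along(results)) {
    cea <- results[[j]]$cea
    nm <- labels[j + 1]
    tab[tab$quantity == "incremental_costs", nm] <-
      round(cea$incremental_cost)
    tab[tab$quantity == "incremental_qalys", nm] <-
      round(cea$incremental_qalys, 4)
    tab[tab$quantity == "icer", nm] <-
      if (cea$classification == "dominant") NA else round(cea$icer)
  }
  tab
}

#' @export
print.oab_cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness: %s vs %s\n", x$intervention,
              x$comparator))
  cat(sprintf("  incremental cost : %10.2f GBP\n", x$incremental_cost))
  cat(sprintf("  incremental QALYs: %10.4f\n", x$incremental_qalys))
  if (is.na(x$icer)) {
    cat("  ICER             : undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER             : %10.0f GBP/QALY\n", x$icer))
  }
  cat(sprintf("  classification   : %s (WTP %.0f)\n", x$classification,
              x$wtp))
  invisible(x)
}

#' @export
print.oab_arm_result <- function(x, ...) {
  cat(sprintf("Arm: %s\n", x$arm))
  for (nm in names(x$cost_by_category)) {
    cat(sprintf("  %-18s %10.2f GBP\n", nm, x$cost_by_category[[nm]]))
  }
  cat(sprintf("  %-18s %10.2f GBP\n", "total", x$total_cost))
  cat(sprintf("  %-18s %10.4f\n", "QALYs", x$total_qalys))
  invisible(x)
}
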