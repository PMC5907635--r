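# Cohort state-transition engine. The state space factorizes into a
# "pathway state" (treatment phase, months on current drug, failed oral
# lines, adverse-event flag, plus bookkeeping: previous line while off
# treatment, months since BTX-A injection) crossed with the joint symptom
# state (micturition level x incontinence level). The cohort distribution
# is a matrix: rows = pathway states, columns = symptom cells.
#
# Within-cycle event order: adverse-event onset -> discontinuation ->
# switch / off-treatment -> BTX-A / restart -> symptom transition. New
# entrants to a treatment line (switch, restart) hold their symptom
# distribution for the entry cycle and start month-1 dynamics the next
# cycle.

PHASES <- c("on", "off", "btxa_success", "btxa_failed")

state_key_on <- function(line, m, f, ae) sprintf("on|%d|%d|%d|%d",
                                                 line, m, f, ae)
state_key_off <- function(prev, f) sprintf("off|%d|%d", prev, f)
state_key_bs <- function(k) sprintf("bs|%d", k)
STATE_KEY_BF <- "bf"

build_state_table <- function() {
  on <- expand.grid(line = 1:3, m = 1:4, f = 0:2, ae = 0:1,
                    KEEP.OUT.ATTRS = FALSE)
  on <- data.frame(phase = "on", on, prev = NA_integer_, k = NA_integer_,
                   stringsAsFactors = FALSE)
  off <- expand.grid(prev = 1:3, f = 0:2, KEEP.OUT.ATTRS = FALSE)
  off <- data.frame(phase = "off", line = NA_integer_, m = NA_integer_,
                    f = off$f, ae = NA_integer_, prev = off$prev,
                    k = NA_integer_, stringsAsFactors = FALSE)
  bs <- data.frame(phase = "btxa_success", line = NA_integer_,
                   m = NA_integer_, f = 2L, ae = NA_integer_,
                   prev = NA_integer_, k = 1:6, stringsAsFactors = FALSE)
  bf <- data.frame(phase = "btxa_failed", line = NA_integer_,
                   m = NA_integer_, f = 2L, ae = NA_integer_,
                   prev = NA_integer_, k = NA_integer_,
                   stringsAsFactors = FALSE)
  st <- rbind(on, off, bs, bf)
  st$key <- NA_character_
  i_on <- st$phase == "on"
  st$key[i_on] <- state_key_on(st$line[i_on], st$m[i_on], st$f[i_on],
                               st$ae[i_on])
  i_off <- st$phase == "off"
  st$key[i_off] <- state_key_off(st$prev[i_off], st$f[i_off])
  i_bs <- st$phase == "btxa_success"
  st$key[i_bs] <- state_key_bs(st$k[i_bs])
  st$key[st$phase == "btxa_failed"] <- STATE_KEY_BF
  rownames(st) <- NULL
  st
}

# monthly AE probabilities for a drug: direct 3-month probabilities when
# given, otherwise derived from the reference drug via NMA odds ratios
ae_monthly_probs <- function(params, drug) {
  d <- params$drugs[[drug]]
  p3 <- d$ae_prob_3m
  if (is.null(p3$dry_mouth) || is.null(p3$constipation)) {
    ref <- reference_drug(params)
    pref <- params$drugs[[ref]]$ae_prob_3m
    ors <- d$ae_odds_ratio
    if (is.null(ors)) {
      abort_oab(sprintf(
        "drug %s has neither 3-month AE probabilities nor odds ratios",
        drug), class = "oab_config_error")
    }
    p3 <- list(
      dry_mouth = p3$dry_mouth %||%
        adjust_probability_by_odds_ratio(pref$dry_mouth, ors$dry_mouth),
      constipation = p3$constipation %||%
        adjust_probability_by_odds_ratio(pref$constipation,
                                         ors$constipation))
  }
  list(dry_mouth = three_month_to_monthly_prob(p3$dry_mouth),
       constipation = three_month_to_monthly_prob(p3$constipation))
}

build_engine_context <- function(params, drug) {
  if (!drug %in% names(params$drugs)) {
    abort_oab(sprintf("unknown drug: %s", drug))
  }
  L <- n_levels(params)
  pw <- params$pathway
  line_drugs <- c(drug, pw$next_line_a, pw$next_line_b)
  tm_names <- c(drug, rep(pw$next_line_transition_source, 2))
  for (nm in unique(tm_names)) {
    if (is.null(params$transition_models[[nm]])) {
      abort_oab(sprintf("no transition model available for drug %s", nm),
                class = "oab_config_error")
    }
  }
  P <- lapply(tm_names, function(nm) {
    tm <- params$transition_models[[nm]]
    lapply(1:3, function(m)
      kronecker(tm$micturition[[m]], tm$incontinence[[m]]))
  })
  scen <- pw$scenario_discontinuation
  p_dm <- numeric(3); p_c <- numeric(3)
  p_disc_no <- numeric(3); p_disc_ae <- numeric(3)
  for (l in 1:3) {
    aep <- ae_monthly_probs(params, line_drugs[l])
    p_dm[l] <- aep$dry_mouth
    p_c[l] <- aep$constipation
    if (!is.null(scen)) {
      r <- scen[[line_drugs[l]]]
      if (is.null(r)) {
        abort_oab(sprintf(
          "scenario discontinuation rate missing for drug %s",
          line_drugs[l]))
      }
      p_disc_no[l] <- r
      p_disc_ae[l] <- r
    } else {
      p_disc_no[l] <- params$drugs[[line_drugs[l]]]$
        discontinuation_monthly_no_ae %||% pw$p_discontinue_no_ae
      p_disc_ae[l] <- pw$p_discontinue_ae
    }
  }
  states <- build_state_table()
  idx <- setNames(seq_len(nrow(states)), states$key)
  B <- params$settings$baseline_distribution
  baseline_vec <- as.vector(t(B))
  Bx <- params$settings$btxa_symptom_distribution
  btxa_vec <- if (is.null(Bx)) baseline_vec else as.vector(t(Bx))
  list(
    drug = drug, L = L, L2 = L * L,
    states = states, idx = idx, nstates = nrow(states),
    # plain vectors for the hot loop (data-frame row access is slow)
    st_phase = states$phase, st_line = states$line, st_m = states$m,
    st_f = states$f, st_ae = states$ae, st_prev = states$prev,
    st_k = states$k,
    line_drugs = line_drugs,
    P = P,
    p_dm = p_dm, p_c = p_c,
    p_onset = 1 - (1 - p_dm) * (1 - p_c),
    p_disc_no = p_disc_no, p_disc_ae = p_disc_ae,
    p_switch = pw$p_switch_after_discontinuation,
    p_restart = pw$p_restart_monthly,
    restart_split = as.numeric(pw$restart_split),
    p_btxa = pw$p_btxa_monthly,
    p_reinject = pw$p_btxa_reinjection_6m,
    baseline_vec = baseline_vec,
    btxa_vec = btxa_vec,
    horizon = params$settings$horizon %/% params$settings$cycle_length
  )
}

empty_tally <- function() {
  c(ae_dry_mouth = 0, ae_constipation = 0, discontinuations = 0,
    switches = 0, restarts = 0, btxa_injections = 0, initiations = 0,
    entry = 0)
}

#' Initial cohort distribution for one treatment arm
#'
#' All mass starts on the first-line drug (month 1 on treatment, no failed
#' lines, no active adverse event) with symptom occupancy equal to the
#' baseline severity distribution.
#'
#' @param params A validated `oab_paramset` with transition models.
#' @param drug First-line drug for this arm.
#' @return An `oab_distribution`: pathway-state x symptom-cell mass matrix
#'   with the engine context attached.
#' @export
build_initial_distribution <- function(params, drug) {
  ctx <- build_engine_context(params, drug)
  mass <- matrix(0, ctx$nstates, ctx$L2)
  mass[ctx$idx[[state_key_on(1L, 1L, 0L, 0L)]], ] <- ctx$baseline_vec
  structure(list(mass = mass, states = ctx$states, L = ctx$L),
            class = "oab_distribution", ctx = ctx)
}

#' Advance the cohort by one cycle
#'
#' Applies, to every occupied state and in order: adverse-event onset
#' (monthly-converted probability of the current drug, first 3 months on
#' the drug only, not while an AE is already active), discontinuation
#' (pathway AE probability if an AE is active or onset this cycle, else
#' the drug's monthly probability), immediate switch to the next oral
#' line versus off-treatment with symptom reset to baseline, BTX-A
#' injection (off-treatment, >= 2 failed lines) or treatment restart,
#' BTX-A 6-month reinjection draws, and the month-indexed symptom
#' transition of the current drug (month-3 matrix after month 3;
#' next-line phases use the configured tolterodine model). Expected
#' per-capita event counts are tallied for the economics layer.
#'
#' @param dist An `oab_distribution` (from [build_initial_distribution()]
#'   or a previous step).
#' @param cycle 1-based cycle index; must not exceed the horizon.
#' @param params The `oab_paramset` the distribution was built from.
#' @return List with elements `dist` (the end-of-cycle distribution) and
#'   `tally` (named per-capita event counts).
#' @export
step_cycle <- function(dist, cycle, params) {
  ctx <- attr(dist, "ctx")
  if (cycle < 1 || cycle > ctx$horizon) {
    abort_oab(sprintf("cycle %d outside horizon 1..%d", cycle,
                      ctx$horizon))
  }
  M <- dist$mass
  new <- matrix(0, ctx$nstates, ctx$L2)
  tally <- empty_tally()
  rs <- rowSums(M)
  idx <- ctx$idx
  add <- function(key, vec) {
    i <- idx[[key]]
    new[i, ] <<- new[i, ] + vec
  }
  split <- ctx$restart_split
  for (s in which(rs > 0)) {
    phase <- ctx$st_phase[s]
    v <- M[s, ]
    tot <- rs[s]
    if (phase == "on") {
      l <- ctx$st_line[s]; m <- ctx$st_m[s]
      f <- ctx$st_f[s]; ae <- ctx$st_ae[s]
      eligible <- (m <= 3L && ae == 0L)
      p_on <- if (eligible) ctx$p_onset[l] else 0
      pd_ae <- ctx$p_disc_ae[l]
      pd_no <- if (ae == 1L) pd_ae else ctx$p_disc_no[l]
      stay_on <- p_on * (1 - pd_ae)         # onset this cycle, stays
      stay_no <- (1 - p_on) * (1 - pd_no)   # no onset, stays
      disc <- p_on * pd_ae + (1 - p_on) * pd_no
      if (stay_on + stay_no > 0) {
        vP <- as.numeric(v %*% ctx$P[[l]][[min(m, 3L)]])
        m2 <- min(m + 1L, 4L)
        if (stay_on > 0) {
          add(state_key_on(l, m2, f, 1L), vP * stay_on)
        }
        if (stay_no > 0) {
          add(state_key_on(l, m2, f, ae), vP * stay_no)
        }
      }
      if (disc > 0) {
        f2 <- min(f + 1L, 2L)
        if (l < 3L) {
          sw <- disc * ctx$p_switch
          offw <- disc * (1 - ctx$p_switch)
        } else {
          sw <- 0
          offw <- disc
        }
        if (sw > 0) {
          add(state_key_on(l + 1L, 1L, f2, 0L), v * sw)
          tally["switches"] <- tally["switches"] + tot * sw
          tally["initiations"] <- tally["initiations"] + tot * sw
        }
        if (offw > 0) {
          add(state_key_off(l, f2), ctx$baseline_vec * (tot * offw))
        }
        tally["discontinuations"] <- tally["discontinuations"] +
          tot * disc
      }
      if (eligible) {
        tally["ae_dry_mouth"] <- tally["ae_dry_mouth"] + tot * ctx$p_dm[l]
        tally["ae_constipation"] <- tally["ae_constipation"] +
          tot * ctx$p_c[l]
      }
    } else if (phase == "off") {
      f <- ctx$st_f[s]; prev <- ctx$st_prev[s]
      if (f >= 2L) {
        pb <- ctx$p_btxa
        if (pb > 0) {
          add(state_key_bs(1L), ctx$btxa_vec * (tot * pb))
          tally["btxa_injections"] <- tally["btxa_injections"] + tot * pb
          tally["initiations"] <- tally["initiations"] + tot * pb
        }
        add(state_key_off(prev, f), v * (1 - pb))
      } else {
        pr <- ctx$p_restart
        if (pr > 0) {
          add(state_key_on(prev, 1L, f, 0L), v * (pr * split[1]))
          add(state_key_on(2L, 1L, f, 0L), v * (pr * split[2]))
          add(state_key_on(3L, 1L, f, 0L), v * (pr * split[3]))
          tally["restarts"] <- tally["restarts"] + tot * pr
          tally["initiations"] <- tally["initiations"] + tot * pr
        }
        add(state_key_off(prev, f), v * (1 - pr))
      }
    } else if (phase == "btxa_success") {
      k <- ctx$st_k[s]
      if (k < 6L) {
        add(state_key_bs(k + 1L), v)
      } else {
        re <- ctx$p_reinject
        if (re > 0) {
          add(state_key_bs(1L), v * re)
          tally["btxa_injections"] <- tally["btxa_injections"] + tot * re
        }
        add(STATE_KEY_BF, v * (1 - re))
      }
    } else {  # btxa_failed: absorbing, no further treatment
      add(STATE_KEY_BF, v)
    }
  }
  total_in <- sum(rs)
  if (abs(sum(new) - total_in) > 1e-9 * max(1, total_in)) {
    abort_oab(sprintf("mass not conserved in cycle %d (%.3e -> %.3e)",
                      cycle, total_in, sum(new)),
              class = "oab_internal_error")
  }
  out <- structure(list(mass = new, states = ctx$states, L = ctx$L),
                   class = "oab_distribution", ctx = ctx)
  list(dist = out, tally = tally)
}

#' Run the cohort simulation for one treatment arm
#'
#' Deterministic cohort propagation from the baseline distribution over
#' the full horizon (no randomness in cohort mode). Model-entry
#' consultations are tallied in cycle 1.
#'
#' @param params A validated `oab_paramset` with transition models
#'   attached.
#' @param drug First-line drug of the arm.
#' @return An `oab_trace`: per-cycle end-of-cycle distributions and event
#'   tallies, plus the arm label and engine context.
#' @export
run_cohort <- function(params, drug) {
  dist <- build_initial_distribution(params, drug)
  ctx <- attr(dist, "ctx")
  n_cyc <- ctx$horizon
  cycles <- vector("list", n_cyc)
  for (t in seq_len(n_cyc)) {
    stepped <- step_cycle(dist, t, params)
    dist <- stepped$dist
    tally <- stepped$tally
    if (t == 1L) tally["entry"] <- 1
    cycles[[t]] <- list(dist = dist, tally = tally)
  }
  structure(list(arm = drug, cycles = cycles, states = ctx$states,
                 ctx = ctx, n_cycles = n_cyc),
            class = "oab_trace")
}

#' Per-cycle treatment-phase occupancy of a trace
#'
#' @param trace An `oab_trace`.
#' @return Data frame: cycle, occupancy of first line, next lines A/B,
#'   off-treatment, BTX-A success and BTX-A failed.
#' @export
phase_occupancy <- function(trace) {
  st <- trace$states
  grp <- ifelse(st$phase == "on", paste0("line", st$line), st$phase)
  out <- lapply(seq_along(trace$cycles), function(t) {
    m <- rowSums(trace$cycles[[t]]$dist$mass)
    occ <- tapply(m, grp, sum)
    data.frame(cycle = t,
               line1 = unname(occ["line1"] %||% 0),
               line2 = unname(occ["line2"] %||% 0),
               line3 = unname(occ["line3"] %||% 0),
               off = unname(occ["off"] %||% 0),
               btxa_success = unname(occ["btxa_success"] %||% 0),
               btxa_failed = unname(occ["btxa_failed"] %||% 0))
  })
  out <- do.call(rbind, out)
  out[is.na(out)] <- 0
  out
}

#' Export a trace as tidy CSV
#'
#' One row per (cycle, pathway state, symptom cell) with positive mass,
#' plus a per-cycle tally file.
#'
#' @param trace An `oab_trace`.
#' @param dir Output directory.
#' @return Character vector of written paths.
#' @export
export_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- trace$ctx$L
  st <- trace$states
  rows <- list()
  for (t in seq_along(trace$cycles)) {
    M <- trace$cycles[[t]]$dist$mass
    nz <- which(M > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    rows[[t]] <- data.frame(
      cycle = t,
      phase = st$phase[nz[, 1]],
      line = st$line[nz[, 1]],
      months_on_current = st$m[nz[, 1]],
      n_failed_lines = st$f[nz[, 1]],
      ae_active = st$ae[nz[, 1]],
      mict_level = (nz[, 2] - 1L) %/% L + 1L,
      incont_level = (nz[, 2] - 1L) %% L + 1L,
      mass = M[nz],
      stringsAsFactors = FALSE
    )
  }
  f1 <- file.path(dir, sprintf("trace_%s.csv", trace$arm))
  write.csv(do.call(rbind, rows), f1, row.names = FALSE)
  tl <- do.call(rbind, lapply(seq_along(trace$cycles), function(t)
    as.data.frame(t(trace$cycles[[t]]$tally))))
  tl <- cbind(cycle = seq_along(trace$cycles), tl)
  f2 <- file.path(dir, sprintf("tallies_%s.csv", trace$arm))
  write.csv(tl, f2, row.names = FALSE)
  c(f1, f2)
}
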