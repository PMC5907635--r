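# Independent Monte-Carlo microsimulation oracle: simulates individual
# walkers under the same treatment-pathway rules as the cohort engine,
# but with its own bookkeeping (no code shared with step_cycle). Used to
# check cohort phase occupancies against binomial sampling error.

microsim_phase_occupancy <- function(params, drug, n_walkers, n_cycles,
                                     seed) {
  pw <- params$pathway
  line_drugs <- c(drug, pw$next_line_a, pw$next_line_b)
  tm_src <- pw$next_line_transition_source
  L <- nrow(params$settings$baseline_distribution)
  B <- params$settings$baseline_distribution
  p_base_m <- rowSums(B)
  p_base_i <- colSums(B)

  p_dm <- numeric(3); p_c <- numeric(3); p_no <- numeric(3)
  for (l in 1:3) {
    d <- params$drugs[[line_drugs[l]]]
    p_dm[l] <- 1 - (1 - d$ae_prob_3m$dry_mouth)^(1 / 3)
    p_c[l] <- 1 - (1 - d$ae_prob_3m$constipation)^(1 / 3)
    p_no[l] <- d$discontinuation_monthly_no_ae
  }
  p_onset <- 1 - (1 - p_dm) * (1 - p_c)
  mats <- function(l, dim) {
    nm <- if (l == 1) drug else tm_src
    params$transition_models[[nm]][[dim]]
  }

  withr::with_seed(as.integer(seed), {
    n <- n_walkers
    phase <- rep(1L, n)      # 1 on, 2 off, 3 btxa success, 4 btxa failed
    line <- rep(1L, n)
    m <- rep(1L, n)
    f <- rep(0L, n)
    ae <- rep(FALSE, n)
    prev <- rep(NA_integer_, n)
    k <- rep(NA_integer_, n)
    mict <- sample.int(L, n, replace = TRUE, prob = p_base_m)
    incont <- sample.int(L, n, replace = TRUE, prob = p_base_i)

    draw_dest <- function(levels_now, M) {
      out <- levels_now
      for (i in seq_len(nrow(M))) {
        idx <- which(levels_now == i)
        if (length(idx)) {
          out[idx] <- sample.int(ncol(M), length(idx), replace = TRUE,
                                 prob = M[i, ])
        }
      }
      out
    }

    occ <- matrix(0, n_cycles, 6,
                  dimnames = list(NULL, c("line1", "line2", "line3",
                                          "off", "btxa_success",
                                          "btxa_failed")))
    for (t in seq_len(n_cycles)) {
      on_idx <- which(phase == 1L)
      off_idx <- which(phase == 2L)
      bs_idx <- which(phase == 3L)

      ## on-treatment walkers
      if (length(on_idx)) {
        l_on <- line[on_idx]
        eligible <- m[on_idx] <= 3L & !ae[on_idx]
        onset <- eligible & runif(length(on_idx)) < p_onset[l_on]
        ae_now <- ae[on_idx] | onset
        pd <- ifelse(ae_now, pw$p_discontinue_ae, p_no[l_on])
        disc <- runif(length(on_idx)) < pd
        can_switch <- disc & l_on < 3L
        sw <- can_switch & runif(length(on_idx)) <
          pw$p_switch_after_discontinuation
        go_off <- disc & !sw
        stay <- !disc
        # stayers: symptom transition with month-indexed matrices
        si <- on_idx[stay]
        if (length(si)) {
          for (l in 1:3) {
            for (mm in 1:3) {
              sel <- si[line[si] == l & pmin(m[si], 3L) == mm]
              if (length(sel)) {
                mict[sel] <- draw_dest(mict[sel], mats(l, "micturition")[[mm]])
                incont[sel] <- draw_dest(incont[sel],
                                         mats(l, "incontinence")[[mm]])
              }
            }
          }
          ae[si] <- ae_now[stay]
          m[si] <- pmin(m[si] + 1L, 4L)
        }
        swi <- on_idx[sw]
        if (length(swi)) {
          f[swi] <- pmin(f[swi] + 1L, 2L)
          line[swi] <- line[swi] + 1L
          m[swi] <- 1L
          ae[swi] <- FALSE
        }
        offi <- on_idx[go_off]
        if (length(offi)) {
          f[offi] <- pmin(f[offi] + 1L, 2L)
          prev[offi] <- line[offi]
          phase[offi] <- 2L
          mict[offi] <- sample.int(L, length(offi), replace = TRUE,
                                   prob = p_base_m)
          incont[offi] <- sample.int(L, length(offi), replace = TRUE,
                                     prob = p_base_i)
          ae[offi] <- FALSE
        }
      }

      ## off-treatment walkers (state at cycle start)
      if (length(off_idx)) {
        eligible_btxa <- f[off_idx] >= 2L
        inj <- eligible_btxa & runif(length(off_idx)) < pw$p_btxa_monthly
        inji <- off_idx[inj]
        if (length(inji)) {
          phase[inji] <- 3L
          k[inji] <- 1L
        }
        rest_pool <- off_idx[!eligible_btxa]
        if (length(rest_pool)) {
          restart <- runif(length(rest_pool)) < pw$p_restart_monthly
          ri <- rest_pool[restart]
          if (length(ri)) {
            u <- runif(length(ri))
            sp <- cumsum(pw$restart_split)
            dest <- ifelse(u < sp[1], prev[ri],
                           ifelse(u < sp[2], 2L, 3L))
            phase[ri] <- 1L
            line[ri] <- dest
            m[ri] <- 1L
            ae[ri] <- FALSE
          }
        }
      }

      ## BTX-A success walkers
      if (length(bs_idx)) {
        at6 <- k[bs_idx] >= 6L
        young <- bs_idx[!at6]
        k[young] <- k[young] + 1L
        due <- bs_idx[at6]
        if (length(due)) {
          re <- runif(length(due)) < pw$p_btxa_reinjection_6m
          k[due[re]] <- 1L
          phase[due[!re]] <- 4L
        }
      }

      occ[t, "line1"] <- mean(phase == 1L & line == 1L)
      occ[t, "line2"] <- mean(phase == 1L & line == 2L)
      occ[t, "line3"] <- mean(phase == 1L & line == 3L)
      occ[t, "off"] <- mean(phase == 2L)
      occ[t, "btxa_success"] <- mean(phase == 3L)
      occ[t, "btxa_failed"] <- mean(phase == 4L)
    }
    as.data.frame(occ)
  })
}
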