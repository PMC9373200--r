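#' Simulate one factorial-MAMS trial
#'
#' Runs a single trial end to end: deterministic accrual, sequential
#' stratified block randomisation, outcome generation, scheduled design
#' adaptations, interim looks with lack-of-benefit and efficacy stopping,
#' deterministic completion accounting (a comparison completes when its
#' accounted contribution reaches target, mirroring [plan_flow()]), and
#' final concurrent-control stage-stratified analyses.
#'
#' Progress towards each comparison's target uses the same deterministic
#' accounting as the flow planner (patients entering a randomisation count
#' `(w_i + w_0) / sum(w)` towards each of its comparisons), so with
#' stopping disabled the realised stage sizes equal the planned flow table
#' for any seed.
#'
#' @param design an `fm_design` (scheduled adaptations are replayed from
#'   the initial scheme at their cumulative-patient times).
#' @param model an `fm_outcome_model`.
#' @param plan an `fm_monitoring_plan`; `NULL` means a single final
#'   analysis at one-sided alpha 0.025.
#' @param seed integer seed; arrivals, randomisation and outcomes use
#'   separate derived substreams.
#' @param eligibility_probs,consent_probs,factors passed to the patient
#'   profile generator (see [simulate_arrivals()]).
#' @param block_multiples block-size multiples for the randomiser.
#' @param stopping if `FALSE`, interim looks are recorded but no stopping
#'   decisions are applied (used for planner-equivalence checks).
#' @param look_batch patient-count resolution for event-count and calendar
#'   look triggers.
#' @param max_patients safety cap on total recruitment.
#' @return An `fm_trial_result`.
#' @export
run_trial <- function(design, model, plan = NULL, seed = 1,
                      eligibility_probs = NULL, consent_probs = NULL,
                      factors = NULL, block_multiples = c(1, 2),
                      stopping = TRUE, look_batch = 100,
                      max_patients = 1e6) {
  stopifnot(inherits(design, "fm_design"), inherits(model, "fm_outcome_model"))
  if (is.null(plan)) plan <- monitoring_plan(K = 1L, alpha = 0.025)
  streams <- new_rng_streams(seed, c("arrivals", "randomisation", "outcomes"))

  work <- design_from_initial(design)
  pending <- design$adaptations
  if (length(pending)) {
    pt <- vapply(pending, `[[`, numeric(1), "time")
    pending <- pending[order(pt)]
  }
  comps <- planner_comparisons(work, design)
  comps$stopped <- NA_character_
  comps$rejected <- NA
  rnd <- new_randomiser(work, block_multiples)
  rate <- design$accrual_rate

  # interim looks by cumulative patients: explicit patient triggers plus the
  # design's planned interim analyses
  look_n <- sort(unique(c(
    unlist(lapply(plan$triggers, function(tr) {
      if (tr$type == "patients") tr$value
      else if (tr$type == "calendar") floor(tr$value * rate)
      else NA_real_
    })),
    design$interim_at)))
  look_n <- look_n[!is.na(look_n)]
  event_triggers <- Filter(function(tr) tr$type == "events", plan$triggers)
  event_tau <- vapply(event_triggers, `[[`, numeric(1), "value")
  looks_done <- 0L
  look_results <- list()

  # patient-level collectors
  n_cap <- 2048L
  arrival <- numeric(n_cap); stage_at <- integer(n_cap)
  arm_cols <- list(); mech_cols <- list()
  prof_cols <- list()
  ev <- integer(n_cap); int_ev <- integer(n_cap)
  tt <- numeric(n_cap); stt <- integer(n_cap); cal <- numeric(n_cap)
  ensure_cap <- function(n) {
    while (n > n_cap) {
      n_cap <<- n_cap * 2L
      length(arrival) <<- n_cap; length(stage_at) <<- n_cap
      length(ev) <<- n_cap; length(int_ev) <<- n_cap
      length(tt) <<- n_cap; length(stt) <<- n_cap; length(cal) <<- n_cap
      for (nm in names(arm_cols)) {
        length(arm_cols[[nm]]) <<- n_cap; length(mech_cols[[nm]]) <<- n_cap
      }
      for (nm in names(prof_cols)) length(prof_cols[[nm]]) <<- n_cap
    }
  }
  adopted <- character(0)
  cum <- 0
  rows <- list()
  guard <- 0

  elig_names <- names(eligibility_probs)
  consent_names <- names(consent_probs)
  factor_names <- names(factors)

  assemble_data <- function(n) {
    if (n == 0) return(NULL)
    out <- data.frame(id = seq_len(n), arrival = arrival[seq_len(n)],
                      stage = stage_at[seq_len(n)])
    for (nm in names(arm_cols)) {
      out[[paste0("arm_", nm)]] <- arm_cols[[nm]][seq_len(n)]
      mc <- mech_cols[[nm]][seq_len(n)]
      mc[is.na(mc)] <- "not-in-trial"
      out[[paste0("mech_", nm)]] <- mc
    }
    for (nm in names(prof_cols)) out[[nm]] <- prof_cols[[nm]][seq_len(n)]
    if (model$outcome_type == "binary") {
      out$event <- ev[seq_len(n)]
      if (!is.null(model$intermediate)) out$int_event <- int_ev[seq_len(n)]
    } else {
      out$time <- tt[seq_len(n)]; out$status <- stt[seq_len(n)]
      out$calendar <- cal[seq_len(n)]
      if (!is.null(model$intermediate)) out$int_event <- int_ev[seq_len(n)]
    }
    out
  }

  comp_analyses <- function(data, open_idx, look_time) {
    do.call(rbind, lapply(open_idx, function(i) {
      avail <- if (model$outcome_type == "binary") {
        data[data$arrival + model$outcome_delay <= look_time, , drop = FALSE]
      } else {
        d2 <- data
        # censor follow-up at the look
        expos <- pmax(pmin(look_time - d2$arrival, model$follow_up), 0)
        seen <- d2$time <= expos
        d2$status <- ifelse(seen, d2$status, 0L)
        d2$time <- pmin(d2$time, expos)
        d2[expos > 0, , drop = FALSE]
      }
      aset <- select_concurrent(avail, work, comps$comparison[i])
      r_def <- stage_stratified_test(aset, model$outcome_type)
      z_int <- NA_real_
      if (!is.null(model$intermediate) && "int_event" %in% names(avail)) {
        aset_int <- aset
        aset_int$data$event <- aset_int$data$int_event
        r_int <- stage_stratified_test(aset_int, "binary")
        z_int <- r_int$z
      }
      data.frame(comparison = comps$comparison[i],
                 z_intermediate = z_int, z_definitive = r_def$z,
                 stringsAsFactors = FALSE)
    }))
  }

  apply_stop <- function(i, kind, time) {
    ad <- adaptation(kind, comps$research[i], time)
    ok <- tryCatch({
      work <<- apply_adaptation(work, ad)
      adapt_randomiser(rnd, ad, design$deliver_control_after_stop)
      TRUE
    }, error = function(e) FALSE)
    comps$stopped[i] <<- kind
    invisible(ok)
  }

  repeat {
    guard <- guard + 1
    if (guard > 100000) stop("run_trial failed to terminate")
    rates <- comp_rates(work, comps)
    active <- !comps$complete & is.na(comps$stopped)
    if (!any(active) || all(rates[active] <= 0)) {
      if (!length(pending)) break
    }
    cand <- numeric(0)
    ptimes <- vapply(pending, `[[`, numeric(1), "time")
    due_now <- length(ptimes) && any(ptimes <= cum + 1e-9)
    if (length(ptimes) && any(ptimes > cum + 1e-9)) {
      cand <- c(cand, min(ptimes[ptimes > cum + 1e-9]))
    }
    fut_looks <- look_n[look_n > cum + 1e-9]
    if (length(fut_looks)) cand <- c(cand, fut_looks[1])
    if (length(event_tau) && looks_done < length(plan$triggers)) {
      cand <- c(cand, cum + look_batch)
    }
    for (i in which(active)) {
      if (rates[i] <= 0) next
      m <- comp_granularity(work, comps$randomisation[i])
      n0 <- ceiling((comps$target[i] - comps$got[i]) / rates[i] - 1e-9)
      cand <- c(cand, cum + m * ceiling(n0 / m - 1e-9))
    }
    if (!length(cand) && !due_now) break
    t_next <- if (due_now) cum else min(cand, max_patients)
    n_adv <- round(t_next - cum)

    if (n_adv > 0) {
      idx <- (cum + 1):(cum + n_adv)
      ensure_cap(cum + n_adv)
      arrival[idx] <- idx / rate
      stage_at[idx] <- rnd$stage_index

      # patient profiles
      prof <- with_stream(streams, "arrivals", {
        p <- list()
        for (nm in elig_names) {
          p[[paste0("elig_", nm)]] <- stats::runif(n_adv) < eligibility_probs[[nm]]
        }
        for (nm in consent_names) {
          p[[paste0("consent_", nm)]] <- stats::runif(n_adv) < consent_probs[[nm]]
        }
        for (nm in factor_names) {
          p[[nm]] <- sample(as.character(factors[[nm]]), n_adv, replace = TRUE)
        }
        p
      })
      for (nm in names(prof)) {
        if (is.null(prof_cols[[nm]])) {
          prof_cols[[nm]] <- rep(if (is.logical(prof[[nm]])) NA else NA_character_, n_cap)
        }
        prof_cols[[nm]][idx] <- prof[[nm]]
      }

      # randomise the batch
      open_rids <- rnd$order
      for (nm in open_rids) {
        if (is.null(arm_cols[[nm]])) {
          arm_cols[[nm]] <- rep(NA_character_, n_cap)
          mech_cols[[nm]] <- rep(NA_character_, n_cap)
        }
      }
      entered <- stats::setNames(numeric(length(open_rids)), open_rids)
      with_stream(streams, "randomisation", {
        for (j in seq_len(n_adv)) {
          pid <- cum + j
          elig <- NULL
          if (length(elig_names)) {
            elig <- lapply(stats::setNames(open_rids, open_rids), function(rid) {
              r <- rnd$scheme[[rid]]
              ok <- vapply(r$arms, function(a) {
                col <- paste0("elig_", a)
                if (is.null(prof[[col]])) TRUE else prof[[col]][j]
              }, logical(1))
              if (all(ok)) TRUE else r$arms[ok]
            })
          }
          consent <- NULL
          if (length(consent_names)) {
            consent <- lapply(stats::setNames(open_rids, open_rids), function(rid) {
              col <- paste0("consent_", rid)
              if (is.null(prof[[col]])) TRUE else prof[[col]][j]
            })
          }
          facs <- if (length(factor_names)) {
            lapply(stats::setNames(factor_names, factor_names),
                   function(nm) prof[[nm]][j])
          } else NULL
          res <- engine_randomise(rnd, as.character(pid), arrival[pid],
                                  facs, elig, consent)
          for (nm in names(res$arm)) {
            arm_cols[[nm]][pid] <- res$arm[[nm]]
            mech_cols[[nm]][pid] <- res$mech[[nm]]
          }
          rr <- res$mech == "randomised"
          if (any(rr)) entered[names(res$mech)[rr]] <- entered[names(res$mech)[rr]] + 1
        }
      })

      # outcomes for the batch (arms are fixed at allocation, so batching
      # does not look ahead)
      assign_df <- as.data.frame(lapply(arm_cols, function(v) v[idx]),
                                 stringsAsFactors = FALSE, check.names = FALSE)
      if (length(adopted)) {
        for (w in adopted) assign_df[[paste0("soc_", w)]] <- w
      }
      with_stream(streams, "outcomes", {
        if (model$outcome_type == "binary") {
          ev[idx] <- simulate_binary(assign_df, model, time = arrival[idx])
          if (!is.null(model$intermediate)) {
            int_ev[idx] <- simulate_intermediate(assign_df, model,
                                                 time = arrival[idx])
          }
        } else {
          o <- simulate_tte(assign_df, model, arrival = arrival[idx])
          tt[idx] <- o$time; stt[idx] <- o$status; cal[idx] <- o$calendar
          if (!is.null(model$intermediate)) {
            int_ev[idx] <- simulate_intermediate(assign_df, model,
                                                 time = arrival[idx])
          }
        }
      })

      # deterministic contribution accounting: patients entering each
      # randomisation, with the expected split across active arms
      for (i in seq_len(nrow(comps))) {
        if (comps$complete[i] || !is.na(comps$stopped[i])) next
        if (rates[i] <= 0) next
        rid <- comps$randomisation[i]
        frac <- design$eligibility_fraction[[rid]] %||% 1
        n_in <- if (length(elig_names) || length(consent_names)) {
          entered[[rid]] %||% 0
        } else {
          n_adv * frac
        }
        r <- work$randomisations[[rid]]
        w <- r$arms$weight
        comps$got[i] <- comps$got[i] +
          n_in * sum(w[r$arms$id %in% c(comps$research[i], comps$control[i])]) / sum(w)
      }

      rows[[length(rows) + 1]] <- c(list(
        design = scheme_label(current_stage(work)$scheme),
        n_randomised = n_adv),
        stats::setNames(as.list(ifelse(comps$complete | !is.na(comps$stopped),
                                       0, n_adv * rates)),
                        comps$comparison))
      cum <- cum + n_adv
    }

    # completions
    newly <- which(!comps$complete & is.na(comps$stopped) &
                     comps$got >= comps$target - 1e-6)
    if (length(newly)) {
      comps$complete[newly] <- TRUE
      comps$milestone[newly] <- cum
      for (rid in names(work$randomisations)) {
        r <- work$randomisations[[rid]]
        if (!identical(r$status, "open")) next
        res <- research_arms(r)
        if (!length(res)) next
        cids <- comparison_id(res, control_arm(r))
        ci <- match(cids, comps$comparison)
        done <- comps$complete[ci] | !is.na(comps$stopped[ci])
        if (all(done)) {
          ad <- adaptation("drop_completed", rid, cum)
          work <- apply_adaptation(work, ad)
          adapt_randomiser(rnd, ad, design$deliver_control_after_stop)
        } else if (any(comps$complete[ci] & res %in% research_arms(r))) {
          for (arm in res[comps$complete[ci]]) {
            ad <- adaptation("drop_completed", arm, cum)
            work <- apply_adaptation(work, ad)
            adapt_randomiser(rnd, ad, design$deliver_control_after_stop)
          }
        }
      }
    }

    # scheduled adaptations
    if (length(pending)) {
      ptimes <- vapply(pending, `[[`, numeric(1), "time")
      due <- ptimes <= cum + 1e-9
      for (ad in pending[due]) {
        ad$time <- cum
        work <- apply_adaptation(work, ad)
        adapt_randomiser(rnd, ad, design$deliver_control_after_stop)
        comps <- refresh_comparisons(comps, work, design)
      }
      pending <- pending[!due]
    }

    # interim looks
    fire_patient_look <- any(abs(look_n - cum) < 1e-9)
    if (fire_patient_look) look_n <- look_n[abs(look_n - cum) >= 1e-9]
    fire_event_look <- FALSE
    look_time <- cum / rate
    if (length(event_tau) && looks_done < plan$K - 1) {
      ev_times <- if (model$outcome_type == "binary") {
        arrival[seq_len(cum)][ev[seq_len(cum)] == 1L] + model$outcome_delay
      } else {
        cal[seq_len(cum)][stt[seq_len(cum)] == 1L]
      }
      nt <- sum(ev_times <= cum / rate)
      k_next <- looks_done + 1L
      if (k_next <= length(event_tau) && nt >= event_tau[k_next]) {
        fire_event_look <- TRUE
        look_time <- sort(ev_times)[event_tau[k_next]]
      }
    }
    if ((fire_patient_look || fire_event_look) && looks_done < plan$K - 1) {
      looks_done <- looks_done + 1L
      data_now <- assemble_data(cum)
      open_idx <- which(!comps$complete & is.na(comps$stopped))
      if (length(open_idx) && stopping) {
        an <- comp_analyses(data_now, open_idx, look_time)
        lr <- evaluate_look(plan, looks_done, an,
                            n_comparisons = nrow(comps))
        look_results[[length(look_results) + 1]] <- lr
        for (i in seq_len(nrow(lr$decisions))) {
          dec <- lr$decisions$decision[i]
          ci <- match(lr$decisions$comparison[i], comps$comparison)
          if (dec == "stop_efficacy") {
            apply_stop(ci, "stop_efficacy", cum)
            comps$rejected[ci] <- TRUE
            if (isTRUE(plan$adopt_winner)) {
              adopted <- union(adopted, comps$research[ci])
            }
          } else if (dec == "stop_lack_of_benefit") {
            apply_stop(ci, "stop_lack_of_benefit", cum)
            comps$rejected[ci] <- FALSE
          }
        }
      }
    }
    if (cum >= max_patients) break
  }

  # final analyses on complete data
  dataset <- assemble_data(cum)
  alpha_final <- plan$alpha
  if (plan$multiplicity == "bonferroni" && nrow(comps) > 1) {
    alpha_final <- alpha_final / nrow(comps)
  }
  final_bound <- efficacy_boundary(plan$efficacy$kind %||% "haybittle_peto",
                                   k = plan$K, K = plan$K,
                                   alpha = alpha_final, sided = 1,
                                   p_star = plan$efficacy$p_star %||% 0.001,
                                   spending = plan$efficacy$spending %||% "obf")
  results <- list()
  for (i in seq_len(nrow(comps))) {
    aset <- select_concurrent(dataset, work, comps$comparison[i])
    r <- stage_stratified_test(aset, model$outcome_type)
    results[[comps$comparison[i]]] <- r
    if (is.na(comps$rejected[i])) {
      comps$rejected[i] <- r$informative && !is.na(r$z) && r$z > final_bound
    }
  }

  rows_df <- if (length(rows)) {
    all_cols <- c("design", "n_randomised", comps$comparison)
    out <- do.call(rbind, lapply(rows, function(r) {
      missing <- setdiff(all_cols, names(r))
      r[missing] <- 0
      as.data.frame(r[all_cols], check.names = FALSE)
    }))
    cbind(stage = seq_len(nrow(out)), out)
  } else NULL

  structure(list(seed = seed, comparisons = comps, results = results,
                 rows = rows_df, dataset = dataset,
                 allocation_log = allocation_log(rnd),
                 look_results = look_results, trajectory = work,
                 total_n = cum, duration = cum / rate,
                 total_events = if (model$outcome_type == "binary")
                   sum(dataset$event) else sum(dataset$status),
                 final_boundary = final_bound),
            class = "fm_trial_result")
}

#' @export
print.fm_trial_result <- function(x, ...) {
  cat(sprintf("Simulated factorial-MAMS trial: %d patients, %d events, %.1f time units\n",
              x$total_n, x$total_events, x$duration))
  cc <- x$comparisons
  for (i in seq_len(nrow(cc))) {
    r <- x$results[[cc$comparison[i]]]
    cat(sprintf("  %s: %s%s, %s\n", cc$comparison[i],
                if (cc$complete[i]) "complete" else "incomplete",
                if (!is.na(cc$stopped[i])) paste0(" (", cc$stopped[i], ")") else "",
                if (isTRUE(cc$rejected[i])) "null rejected" else "null not rejected"))
  }
  invisible(x)
}

#' Monte-Carlo operating characteristics
#'
#' Runs independent trial replicates (seeds `base_seed + 1:reps`) and
#' aggregates per-comparison rejection probabilities (type-I error under
#' null effects, power otherwise), stopping probabilities, expected
#' contribution sizes, familywise error over a specified null set, expected
#' total sample size and duration, all with binomial Monte-Carlo standard
#' errors.
#'
#' @param design,model,plan,... as in [run_trial()].
#' @param reps number of replicates.
#' @param base_seed base seed for the replicate seed ladder.
#' @param null_comparisons comparison ids regarded as truly null for the
#'   familywise error (default: all).
#' @return An `fm_oc`: list with `per_comparison` (data.frame), `trial`
#'   (list), `reps`.
#' @export
run_monte_carlo <- function(design, model, plan = NULL, reps = 100,
                            base_seed = 1, null_comparisons = NULL, ...) {
  stopifnot(reps >= 1)
  acc <- NULL
  tot_n <- numeric(reps); dur <- numeric(reps); fw <- logical(reps)
  for (r in seq_len(reps)) {
    tr <- run_trial(design, model, plan, seed = base_seed + r, ...)
    cc <- tr$comparisons
    if (is.null(acc)) {
      acc <- data.frame(comparison = cc$comparison,
                        reject = 0, stop_lob = 0, stop_eff = 0, n_contrib = 0,
                        stringsAsFactors = FALSE)
    }
    m <- match(cc$comparison, acc$comparison)
    acc$reject[m] <- acc$reject[m] + as.numeric(isTRUE_v(cc$rejected))
    acc$stop_lob[m] <- acc$stop_lob[m] +
      as.numeric(cc$stopped %in% "stop_lack_of_benefit")
    acc$stop_eff[m] <- acc$stop_eff[m] +
      as.numeric(cc$stopped %in% "stop_efficacy")
    acc$n_contrib[m] <- acc$n_contrib[m] + cc$got
    tot_n[r] <- tr$total_n
    dur[r] <- tr$duration
    nulls <- null_comparisons %||% cc$comparison
    fw[r] <- any(isTRUE_v(cc$rejected[cc$comparison %in% nulls]))
  }
  per <- data.frame(
    comparison = acc$comparison,
    p_reject = acc$reject / reps,
    se_reject = sqrt(acc$reject / reps * (1 - acc$reject / reps) / reps),
    p_stop_lack_of_benefit = acc$stop_lob / reps,
    p_stop_efficacy = acc$stop_eff / reps,
    mean_contribution = acc$n_contrib / reps,
    stringsAsFactors = FALSE)
  p_fw <- mean(fw)
  structure(list(
    per_comparison = per,
    trial = list(fwer = p_fw, se_fwer = sqrt(p_fw * (1 - p_fw) / reps),
                 mean_total_n = mean(tot_n), mean_duration = mean(dur)),
    reps = reps, base_seed = base_seed), class = "fm_oc")
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.fm_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d replicates)\n", x$reps))
  print(x$per_comparison, row.names = FALSE, digits = 4)
  cat(sprintf("FWER = %.4f (SE %.4f), E[N] = %.1f, E[duration] = %.2f\n",
              x$trial$fwer, x$trial$se_fwer, x$trial$mean_total_n,
              x$trial$mean_duration))
  invisible(x)
}
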