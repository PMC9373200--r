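#' Deterministic patient-flow plan for a factorial-MAMS design
#'
#' Computes, stage by stage, the number of patients randomised and the number
#' contributing to each pairwise comparison, under deterministic accounting:
#' of `n` patients entering a randomisation with active arm weights `w`, the
#' comparison of research arm `i` against control `0` accrues
#' `n * (w_i + w_0) / sum(w)` patients (with equal weights over `k` arms,
#' `2/k`), scaled by that randomisation's eligibility fraction. A new flow
#' row opens at every scheduled adaptation, at every planned interim
#' analysis, and at every comparison completion; when all comparisons of a
#' randomisation are complete the randomisation is dropped, and when one
#' comparison of a three-or-more-way randomisation completes, that research
#' arm is dropped. Recruitment ends when every comparison has reached its
#' target (or can no longer reach it, which is flagged with a warning).
#'
#' Completion points implying fractional patient counts are rounded up to
#' the next multiple that restores exact allocation, so a comparison is
#' never under-recruited.
#'
#' @param design an `fm_design` (scheduled adaptations, with times expressed
#'   as cumulative patients randomised, are replayed from the initial
#'   scheme).
#' @param interim_at cumulative patient counts of planned interim analyses;
#'   these split flow rows without changing the scheme.
#' @return An `fm_flow`: list with `rows` (data.frame: stage, design,
#'   n_randomised, one column per comparison), `totals`, `milestones`
#'   (cumulative patients randomised when each comparison completes),
#'   `comparisons`, `incomplete`, and the realised stage `trajectory`.
#' @examples
#' d <- make_factorial_design(
#'   randomisations = list(
#'     list(id = "A", arms = list(list(id = "A0", role = "control"),
#'                                list(id = "A1", role = "research"))),
#'     list(id = "B", arms = list(list(id = "B0", role = "control"),
#'                                list(id = "B1", role = "research")))),
#'   targets = 3000, interim_at = 1500)
#' plan_flow(d)
#' @export
plan_flow <- function(design, interim_at = design$interim_at) {
  stopifnot(inherits(design, "fm_design"))
  work <- design_from_initial(design)
  pending <- design$adaptations
  if (length(pending)) {
    times <- vapply(pending, `[[`, numeric(1), "time")
    if (is.unsorted(times)) pending <- pending[order(times)]
  }
  interims <- sort(unique(as.numeric(interim_at)))

  comps <- planner_comparisons(work, design)
  cum <- 0
  rows <- list()
  guard <- 0

  repeat {
    guard <- guard + 1
    if (guard > 10000) stop("plan_flow failed to converge (runaway event loop)")
    rates <- comp_rates(work, comps)
    todo <- !comps$complete
    if (!any(todo)) break

    cand <- numeric(0)
    ptimes <- vapply(pending, `[[`, numeric(1), "time")
    if (length(ptimes) && any(ptimes > cum + 1e-9)) {
      cand <- c(cand, min(ptimes[ptimes > cum + 1e-9]))
    }
    # adaptations scheduled at or before cum are due now (time 0 included)
    due_now <- length(ptimes) && any(ptimes <= cum + 1e-9)
    fut_int <- interims[interims > cum + 1e-9]
    if (length(fut_int)) cand <- c(cand, fut_int[1])
    for (i in which(todo)) {
      if (rates[i] <= 0) next
      remaining <- comps$target[i] - comps$got[i]
      m <- comp_granularity(work, comps$randomisation[i])
      n0 <- ceiling(remaining / rates[i] - 1e-9)
      n <- m * ceiling(n0 / m - 1e-9)
      cand <- c(cand, cum + n)
    }
    if (!length(cand) && !due_now) {
      break  # nothing can progress; incomplete comparisons flagged below
    }
    t_next <- if (due_now) cum else min(cand)
    n_stage <- t_next - cum
    if (n_stage > 1e-9) {
      contrib <- ifelse(comps$complete, 0, n_stage * rates)
      rows[[length(rows) + 1]] <- c(list(
        design = scheme_label(current_stage(work)$scheme),
        n_randomised = n_stage),
        stats::setNames(as.list(contrib), comps$comparison))
      comps$got <- comps$got + contrib
      cum <- t_next
    }

    # completions first: they may discontinue a randomisation that an
    # adaptation at the same time would otherwise touch
    newly <- which(!comps$complete & comps$got >= comps$target - 1e-6)
    if (length(newly)) {
      comps$complete[newly] <- TRUE
      comps$milestone[newly] <- cum
      work <- drop_completed_arms(work, comps, cum)
    }
    if (length(pending)) {
      ptimes <- vapply(pending, `[[`, numeric(1), "time")
      due <- ptimes <= cum + 1e-9
      for (ad in pending[due]) {
        ad$time <- cum
        work <- apply_adaptation(work, ad)
        comps <- refresh_comparisons(comps, work, design)
      }
      pending <- pending[!due]
    }
  }

  rows_df <- if (length(rows)) {
    # comparisons added mid-trial are absent from earlier rows; fill with 0
    all_cols <- c("design", "n_randomised", comps$comparison)
    out <- do.call(rbind, lapply(rows, function(r) {
      missing <- setdiff(all_cols, names(r))
      r[missing] <- 0
      as.data.frame(r[all_cols], check.names = FALSE)
    }))
    out <- cbind(stage = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  } else {
    data.frame(stage = integer(0), design = character(0),
               n_randomised = numeric(0))
  }

  incomplete <- comps$comparison[!comps$complete]
  if (length(incomplete)) {
    warning("target unreachable for comparison(s): ",
            paste(incomplete, collapse = ", "),
            " (contributing arms no longer randomised)")
  }
  totals <- c(n_randomised = sum(rows_df$n_randomised),
              colSums(rows_df[, comps$comparison, drop = FALSE]))
  structure(list(rows = rows_df, totals = totals,
                 milestones = stats::setNames(comps$milestone, comps$comparison),
                 comparisons = comps, incomplete = incomplete,
                 trajectory = work, accrual_rate = design$accrual_rate),
            class = "fm_flow")
}

# Rebuild the design as it was at stage 1 (before any adaptation).
design_from_initial <- function(design) {
  initial <- design$stages[[1]]$scheme
  make_factorial_design(
    randomisations = lapply(unname(initial), function(r) {
      list(id = r$id, arms = lapply(seq_len(nrow(r$arms)), function(i) {
        list(id = r$arms$id[i], role = r$arms$role[i], weight = r$arms$weight[i])
      }))
    }),
    targets = design$targets,
    stratification_factors = design$stratification_factors,
    accrual_rate = design$accrual_rate,
    eligibility_fraction = design$eligibility_fraction,
    interim_at = design$interim_at,
    deliver_control_after_stop = design$deliver_control_after_stop)
}

planner_comparisons <- function(work, design) {
  cc <- design_comparisons(work)
  cc$target <- vapply(cc$comparison, function(id) comparison_target(design, id),
                      numeric(1))
  cc$got <- 0
  cc$complete <- FALSE
  cc$milestone <- NA_real_
  cc
}

# Merge comparisons that appeared after an adaptation, keeping accrual state.
refresh_comparisons <- function(comps, work, design) {
  cc <- planner_comparisons(work, design)
  new <- cc[!cc$comparison %in% comps$comparison, , drop = FALSE]
  if (!nrow(new)) return(comps)
  for (col in setdiff(names(comps), names(new))) {
    new[[col]] <- if (is.character(comps[[col]])) NA_character_ else NA
  }
  rbind(comps, new[names(comps)])
}

comp_rates <- function(work, comps) {
  vapply(seq_len(nrow(comps)), function(i) {
    r <- work$randomisations[[comps$randomisation[i]]]
    if (is.null(r) || !identical(r$status, "open")) return(0)
    if (!all(c(comps$research[i], comps$control[i]) %in% r$arms$id)) return(0)
    w <- r$arms$weight
    elig <- work$eligibility_fraction[[r$id]] %||% 1
    elig * sum(w[r$arms$id %in% c(comps$research[i], comps$control[i])]) / sum(w)
  }, numeric(1))
}

comp_granularity <- function(work, rand_id) {
  r <- work$randomisations[[rand_id]]
  if (is.null(r) || !identical(r$status, "open")) return(1)
  allocation_granularity(r$arms$weight)
}

# Apply drop_completed semantics after completions at time `cum`.
drop_completed_arms <- function(work, comps, cum) {
  for (rid in names(work$randomisations)) {
    r <- work$randomisations[[rid]]
    if (!identical(r$status, "open")) next
    res <- research_arms(r)
    if (!length(res)) next
    cids <- comparison_id(res, control_arm(r))
    done <- comps$complete[match(cids, comps$comparison)]
    if (all(done)) {
      work <- apply_adaptation(work, adaptation("drop_completed", rid, cum))
    } else if (any(done)) {
      for (arm in res[done]) {
        work <- apply_adaptation(work, adaptation("drop_completed", arm, cum))
      }
    }
  }
  work
}

#' Cumulative recruitment at which each comparison can be reported
#'
#' @param flow an `fm_flow` from [plan_flow()].
#' @return named numeric: for each completed comparison, the cumulative
#'   number of patients randomised when its contribution total reaches
#'   target. Incomplete comparisons are omitted with a warning.
#' @export
reporting_milestones <- function(flow) {
  stopifnot(inherits(flow, "fm_flow"))
  m <- flow$milestones
  if (any(is.na(m))) {
    warning("comparison(s) never complete: ",
            paste(names(m)[is.na(m)], collapse = ", "))
  }
  m[!is.na(m)]
}

#' Export the flow plan as calendar timeline segments
#'
#' Converts the flow table into Gantt-style segments (one per comparison)
#' under constant accrual: segment boundaries are cumulative patient counts
#' divided by the accrual rate.
#'
#' @param flow an `fm_flow`.
#' @param accrual_rate patients per unit time; must be positive.
#' @param path optional CSV output path.
#' @return data.frame with columns `comparison`, `start`, `end`, `complete`.
#' @export
timeline_export <- function(flow, accrual_rate = flow$accrual_rate, path = NULL) {
  stopifnot(inherits(flow, "fm_flow"))
  if (is.null(accrual_rate) || accrual_rate <= 0) stop("accrual_rate must be > 0")
  rows <- flow$rows
  comps <- flow$comparisons
  if (!nrow(rows) || !nrow(comps)) {
    out <- data.frame(comparison = character(0), start = numeric(0),
                      end = numeric(0), complete = logical(0))
  } else {
    cum_end <- cumsum(rows$n_randomised)
    cum_start <- c(0, cum_end[-length(cum_end)])
    out <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
      contrib <- rows[[comps$comparison[i]]]
      active <- which(contrib > 1e-9)
      if (!length(active)) return(NULL)
      end_n <- if (comps$complete[i]) comps$milestone[i] else cum_end[max(active)]
      data.frame(comparison = comps$comparison[i],
                 start = cum_start[min(active)] / accrual_rate,
                 end = end_n / accrual_rate,
                 complete = comps$complete[i], stringsAsFactors = FALSE)
    }))
    if (is.null(out)) {
      out <- data.frame(comparison = character(0), start = numeric(0),
                        end = numeric(0), complete = logical(0))
    }
    rownames(out) <- NULL
  }
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Write a flow table as CSV
#'
#' @param flow an `fm_flow`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  rows <- flow$rows
  total <- rows[1, ]
  total$stage <- NA
  total$design <- "Total"
  for (nm in setdiff(names(rows), c("stage", "design"))) {
    total[[nm]] <- sum(rows[[nm]])
  }
  utils::write.csv(rbind(rows, total), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fm_flow <- function(x, ...) {
  cat("Factorial-MAMS patient-flow plan\n")
  rows <- x$rows
  rows$n_randomised <- round(rows$n_randomised, 1)
  print(rows, row.names = FALSE)
  cat("Totals:", paste(sprintf("%s=%g", names(x$totals), round(x$totals, 1)),
                       collapse = "  "), "\n")
  if (length(x$incomplete)) {
    cat("Incomplete:", paste(x$incomplete, collapse = ", "), "\n")
  }
  invisible(x)
}
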