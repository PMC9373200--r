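#' Define an interim monitoring plan
#'
#' @param triggers list of look triggers, each
#'   `list(type = "events", value = tau)` (cumulative outcome events pooled
#'   over ALL arms — never per-comparison control-arm counts, which would
#'   leak effect information), `list(type = "calendar", value = t)`, or
#'   `list(type = "patients", value = n)` (cumulative patients randomised,
#'   the fixed-in-advance option).
#' @param K number of analyses (looks) including the final one; defaults to
#'   `length(triggers) + 1`.
#' @param efficacy efficacy boundary spec: list with `kind` one of
#'   `"haybittle_peto"` (fixed extreme interim threshold, near-nominal
#'   final), `"obrien_fleming"`, `"alpha_spending"`; optional `p_star`
#'   (Haybittle-Peto two-sided interim p, default 0.001) and `spending`
#'   (`"obf"` or `"pocock"`).
#' @param futility one-sided z thresholds for lack-of-benefit stopping on
#'   the intermediate outcome, one per interim look (benefit-positive
#'   orientation); `NULL` disables futility stopping.
#' @param alpha pairwise one-sided significance level in `(0, 0.5)`.
#' @param multiplicity `"none"` or `"bonferroni"` (divide alpha by the
#'   number of comparisons).
#' @param adopt_winner after an efficacy stop, fold the winning
#'   intervention into standard of care for subsequently recruited patients
#'   (lowers the baseline event rate for the remaining comparisons).
#' @return An `fm_monitoring_plan`.
#' @export
monitoring_plan <- function(triggers = list(), K = length(triggers) + 1L,
                            efficacy = list(kind = "haybittle_peto"),
                            futility = NULL, alpha = 0.025,
                            multiplicity = c("none", "bonferroni"),
                            adopt_winner = TRUE) {
  multiplicity <- match.arg(multiplicity)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  if (K < 1) stop("K must be >= 1")
  vals <- vapply(triggers, `[[`, numeric(1), "value")
  types <- vapply(triggers, `[[`, character(1), "type")
  for (ty in unique(types)) {
    if (is.unsorted(vals[types == ty], strictly = TRUE)) {
      stop("trigger values must be strictly increasing within type")
    }
  }
  if (!is.null(futility) && length(futility) < K - 1) {
    futility <- c(futility, rep(futility[length(futility)], K - 1 - length(futility)))
  }
  structure(list(triggers = triggers, K = as.integer(K), efficacy = efficacy,
                 futility = futility, alpha = alpha,
                 multiplicity = multiplicity, adopt_winner = adopt_winner),
            class = "fm_monitoring_plan")
}

#' Time of the next interim look
#'
#' Event-count triggers fire when the pooled event count over all arms
#' reaches the threshold; calendar triggers fire at fixed times. Control-arm
#' event counts are never used for timing (see [control_event_audit()]).
#'
#' @param plan an `fm_monitoring_plan`.
#' @param event_times calendar times of observed outcome events, pooled over
#'   all arms.
#' @param after return only looks strictly after this time.
#' @param recruitment_end if an event trigger cannot be reached, the look
#'   falls back to this time (final analysis at data maturity) with a
#'   warning.
#' @return numeric vector of look times (one per trigger still to come).
#' @export
next_look <- function(plan, event_times = numeric(0), after = -Inf,
                      recruitment_end = NULL) {
  ev <- sort(event_times)
  out <- vapply(plan$triggers, function(tr) {
    if (tr$type == "calendar") return(tr$value)
    if (tr$type == "patients") return(NA_real_)  # resolved by the runner
    if (tr$type != "events") stop("unknown trigger type: ", tr$type)
    if (tr$value <= length(ev)) return(ev[tr$value])
    if (!is.null(recruitment_end)) {
      warning("event trigger ", tr$value,
              " not reached; analysis deferred to data maturity")
      return(recruitment_end)
    }
    NA_real_
  }, numeric(1))
  out <- out[!is.na(out) & out > after]
  sort(out)
}

#' Per-comparison control-arm event count (monitoring-committee audit only)
#'
#' Sums observed events over the combination arms whose level in the
#' comparison's randomisation is the control. In a factorial design each
#' comparison has a different control group, so revealing these counts
#' comparatively would indicate treatment effects; this function exists for
#' closed Data Monitoring Committee reports only and is never consulted by
#' the look scheduler.
#'
#' @param arm_event_counts named numeric: events per combination arm, names
#'   like `"A0+B1"`.
#' @param comparison comparison id (`"<research>_vs_<control>"`).
#' @param design an `fm_design` (to resolve the comparison's randomisation).
#' @return single numeric count.
#' @export
control_event_audit <- function(arm_event_counts, comparison, design) {
  comps <- design_comparisons(design)
  row <- comps[comps$comparison == comparison, , drop = FALSE]
  if (!nrow(row)) stop("unknown comparison: ", comparison)
  ctl <- row$control
  parts <- strsplit(names(arm_event_counts), "+", fixed = TRUE)
  in_control <- vapply(parts, function(p) ctl %in% p, logical(1))
  sum(arm_event_counts[in_control])
}

#' Efficacy stopping boundary at a given look
#'
#' @param kind `"haybittle_peto"`, `"obrien_fleming"` or `"alpha_spending"`.
#' @param k look index (1-based); `NULL` returns all K boundaries.
#' @param K total number of looks.
#' @param alpha total significance level (interpreted per `sided`).
#' @param sided 1 or 2.
#' @param p_star Haybittle-Peto interim two-sided p-value threshold.
#' @param info information fractions (default equal spacing).
#' @param spending spending function for `"alpha_spending"` (see
#'   [spending_boundary()]).
#' @return critical z value(s).
#' @export
efficacy_boundary <- function(kind = c("haybittle_peto", "obrien_fleming",
                                       "alpha_spending"),
                              k = NULL, K = 1, alpha = 0.05, sided = 2,
                              p_star = 0.001,
                              info = seq_len(K) / K, spending = "obf") {
  kind <- match.arg(kind)
  if (!is.null(k) && (k < 1 || k > K)) stop("look index k must be in 1..K")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha out of range (0, 0.5)")
  bounds <- switch(kind,
    haybittle_peto = {
      final <- stats::qnorm(1 - alpha / sided)
      if (K == 1) final else c(rep(stats::qnorm(1 - p_star / 2), K - 1), final)
    },
    obrien_fleming = obf_boundary(K, alpha, sided),
    alpha_spending = spending_boundary(alpha, info, spending, sided)
  )
  if (is.null(k)) bounds else bounds[k]
}

#' Evaluate stopping decisions at an interim look
#'
#' For every comparison open at the look: stop for lack of benefit if the
#' intermediate-outcome z statistic (benefit-positive) falls below the
#' futility bound for this look; stop for efficacy if the definitive-outcome
#' z exceeds the efficacy boundary; otherwise continue. Analyses must come
#' from the concurrent-control analysis engine.
#'
#' @param plan an `fm_monitoring_plan`.
#' @param k look index.
#' @param analyses data.frame with columns `comparison`, `z_intermediate`,
#'   `z_definitive` (benefit-positive), one row per open comparison.
#' @param n_comparisons number of comparisons for Bonferroni adjustment
#'   (default: rows of `analyses`).
#' @return An `fm_look_result`: `look`, `boundary`, `futility_bound` and a
#'   `decisions` data.frame (`comparison`, `decision`).
#' @export
evaluate_look <- function(plan, k, analyses,
                          n_comparisons = nrow(analyses)) {
  stopifnot(inherits(plan, "fm_monitoring_plan"))
  if (anyNA(analyses$z_definitive)) {
    stop("missing definitive analysis for an open comparison")
  }
  alpha <- plan$alpha
  if (plan$multiplicity == "bonferroni" && n_comparisons > 1) {
    alpha <- alpha / n_comparisons
  }
  eff <- plan$efficacy
  bound <- efficacy_boundary(eff$kind, k = k, K = plan$K, alpha = alpha,
                             sided = 1, p_star = eff$p_star %||% 0.001,
                             spending = eff$spending %||% "obf")
  fut <- if (!is.null(plan$futility) && k < plan$K) plan$futility[k] else -Inf
  decision <- character(nrow(analyses))
  for (i in seq_len(nrow(analyses))) {
    decision[i] <- if (analyses$z_definitive[i] > bound) {
      if (k == plan$K) "reject" else "stop_efficacy"
    } else if (k < plan$K && !is.na(analyses$z_intermediate[i]) &&
               analyses$z_intermediate[i] < fut) {
      "stop_lack_of_benefit"
    } else {
      "continue"
    }
  }
  structure(list(look = k, boundary = bound, futility_bound = fut,
                 decisions = data.frame(comparison = analyses$comparison,
                                        decision = decision,
                                        z_intermediate = analyses$z_intermediate,
                                        z_definitive = analyses$z_definitive,
                                        stringsAsFactors = FALSE)),
            class = "fm_look_result")
}

#' @export
print.fm_look_result <- function(x, ...) {
  cat(sprintf("Look %d: efficacy boundary z > %.4f, futility z < %s\n",
              x$look, x$boundary,
              if (is.finite(x$futility_bound)) sprintf("%.4f", x$futility_bound)
              else "-Inf"))
  print(x$decisions, row.names = FALSE)
  invisible(x)
}
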