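#' Diluted marginal control-group event rate
#'
#' In a factorial design, effective interventions in other randomisations
#' lower the marginal event rate seen by a given comparison. With
#' co-interventions allocated independently, the marginal control-group
#' event probability is the mixture over the co-intervention allocation
#' cells. On the risk-ratio scale this is exact and linear in `p0`:
#' `p0 * prod_j (1 - f_j + f_j * rr_j)`; on the odds-ratio scale each cell
#' probability passes through the logistic form before mixing.
#'
#' @param p0 control event probability with no effective co-interventions.
#' @param co_interventions data.frame (or list coercible to one) with
#'   columns `ratio` (risk or odds ratio of each co-intervention) and
#'   `fraction` (proportion of patients receiving it, in `[0, 1]`).
#' @param scale `"rr"` (default) or `"or"`.
#' @return diluted event probability.
#' @examples
#' marginal_event_rate(0.2, data.frame(ratio = 0.5, fraction = 0.5))  # 0.15
#' @export
marginal_event_rate <- function(p0, co_interventions = NULL, scale = c("rr", "or")) {
  scale <- match.arg(scale)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (is.null(co_interventions) || !length(co_interventions) ||
      (is.data.frame(co_interventions) && !nrow(co_interventions))) {
    return(p0)
  }
  co <- as.data.frame(co_interventions)
  if (any(co$fraction < 0 | co$fraction > 1)) stop("fractions must be in [0, 1]")
  if (any(co$ratio <= 0)) stop("effect ratios must be > 0")
  J <- nrow(co)
  # expand the 2^J independent-allocation cells
  cells <- expand.grid(rep(list(c(FALSE, TRUE)), J))
  p <- 0
  for (i in seq_len(nrow(cells))) {
    on <- unlist(cells[i, ])
    w <- prod(ifelse(on, co$fraction, 1 - co$fraction))
    if (w == 0) next
    pc <- if (scale == "rr") {
      p0 * prod(co$ratio[on])
    } else {
      stats::plogis(stats::qlogis(p0) + sum(log(co$ratio[on])))
    }
    p <- p + w * pc
  }
  if (p <= 0 || p >= 1) stop("diluted event probability outside (0, 1)")
  p
}

#' Planning scenario for one pairwise comparison
#'
#' @param p0 undiluted control event probability.
#' @param target_effect risk ratio (or odds ratio, per `scale`) the
#'   comparison is powered to detect; must differ from 1.
#' @param co_interventions as in [marginal_event_rate()].
#' @param alpha significance level.
#' @param sided 1 or 2.
#' @param power target power.
#' @param n_comparisons number of comparisons for Bonferroni adjustment.
#' @param multiplicity `"none"` or `"bonferroni"`.
#' @param scale `"rr"` or `"or"`.
#' @return An `fm_scenario`.
#' @export
planning_scenario <- function(p0, target_effect, co_interventions = NULL,
                              alpha = 0.05, sided = 2, power = 0.9,
                              n_comparisons = 1,
                              multiplicity = c("none", "bonferroni"),
                              scale = c("rr", "or")) {
  multiplicity <- match.arg(multiplicity)
  scale <- match.arg(scale)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  structure(list(p0 = p0, target_effect = target_effect,
                 co_interventions = co_interventions, alpha = alpha,
                 sided = sided, power = power, n_comparisons = n_comparisons,
                 multiplicity = multiplicity, scale = scale),
            class = "fm_scenario")
}

scenario_alpha <- function(scenario) {
  a <- scenario$alpha
  if (scenario$multiplicity == "bonferroni" && scenario$n_comparisons > 1) {
    a <- a / scenario$n_comparisons
  }
  a / scenario$sided
}

scenario_rates <- function(scenario) {
  p0d <- marginal_event_rate(scenario$p0, scenario$co_interventions,
                             scenario$scale)
  p1d <- if (scenario$scale == "rr") {
    p0d * scenario$target_effect
  } else {
    stats::plogis(stats::qlogis(p0d) + log(scenario$target_effect))
  }
  if (p1d <= 0 || p1d >= 1) stop("treated event probability outside (0, 1)")
  c(control = p0d, research = p1d)
}

#' Patients per arm for a binary-outcome comparison
#'
#' Standard normal-approximation two-proportion formula, applied to the
#' event rates after co-intervention dilution:
#' `n = (z_{1-a} + z_{pow})^2 (p0 q0 + p1 q1) / (p0 - p1)^2` per arm.
#'
#' @param scenario an `fm_scenario`; its `target_effect` must differ from 1.
#' @return patients per arm (rounded up).
#' @export
sample_size_binary <- function(scenario) {
  stopifnot(inherits(scenario, "fm_scenario"))
  if (scenario$target_effect == 1) {
    stop("null target effect: sample size is unbounded")
  }
  p <- scenario_rates(scenario)
  za <- stats::qnorm(1 - scenario_alpha(scenario))
  zb <- stats::qnorm(scenario$power)
  n <- (za + zb)^2 * (p[1] * (1 - p[1]) + p[2] * (1 - p[2])) / (p[1] - p[2])^2
  ceiling(unname(n))
}

#' Events required for a time-to-event comparison
#'
#' Schoenfeld events formula `4 (z_{1-a} + z_{pow})^2 / log(HR)^2` (equal
#' allocation), with the trial duration backed out from the diluted pooled
#' event rate under constant accrual.
#'
#' @param scenario an `fm_scenario` whose `target_effect` is a hazard ratio.
#' @param accrual_rate patients per unit time (optional, for the duration).
#' @param event_rate pooled event probability per patient by analysis time,
#'   after dilution (optional; defaults to the scenario's diluted mixture
#'   rate).
#' @return list: `events`, `n_total` (patients to observe them), `duration`
#'   (if `accrual_rate` given).
#' @export
sample_size_events <- function(scenario, accrual_rate = NULL,
                               event_rate = NULL) {
  stopifnot(inherits(scenario, "fm_scenario"))
  hr <- scenario$target_effect
  if (hr == 1) stop("null target effect: sample size is unbounded")
  za <- stats::qnorm(1 - scenario_alpha(scenario))
  zb <- stats::qnorm(scenario$power)
  events <- ceiling(4 * (za + zb)^2 / log(hr)^2)
  p <- scenario_rates(scenario)
  pooled <- event_rate %||% mean(p)
  n_total <- ceiling(events / pooled)
  out <- list(events = events, n_total = n_total)
  if (!is.null(accrual_rate)) out$duration <- n_total / accrual_rate
  out
}

#' Analytic power across a grid of co-intervention effects
#'
#' For fixed per-arm `n`, computes the normal-approximation power of the
#' two-proportion comparison at each grid point, where the grid varies the
#' effectiveness of a co-intervention in another randomisation (received by
#' `fraction` of patients). More effective co-interventions dilute the event
#' rate and shrink the absolute risk difference, so the curve is monotone
#' non-increasing in co-intervention efficacy for a binary outcome.
#'
#' @param scenario an `fm_scenario`.
#' @param co_effect_grid vector of co-intervention effect ratios (1 = none).
#' @param n per-arm sample size.
#' @param fraction fraction of patients receiving the co-intervention
#'   (default 0.5, equal two-way allocation).
#' @return data.frame: `co_effect`, `p_control`, `p_research`, `power`.
#' @export
power_loss_curve <- function(scenario, co_effect_grid, n, fraction = 0.5) {
  stopifnot(inherits(scenario, "fm_scenario"))
  if (!length(co_effect_grid)) stop("empty co-intervention effect grid")
  za <- stats::qnorm(1 - scenario_alpha(scenario))
  out <- lapply(co_effect_grid, function(r) {
    sc <- scenario
    sc$co_interventions <- rbind(
      if (!is.null(scenario$co_interventions)) as.data.frame(scenario$co_interventions),
      data.frame(ratio = r, fraction = fraction))
    p <- scenario_rates(sc)
    se <- sqrt((p[1] * (1 - p[1]) + p[2] * (1 - p[2])) / n)
    pow <- stats::pnorm(abs(p[1] - p[2]) / se - za)
    data.frame(co_effect = r, p_control = unname(p[1]),
               p_research = unname(p[2]), power = pow)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
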