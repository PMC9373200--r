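#' Specify the outcome-generating model
#'
#' Factorial effects model for a binary or time-to-event definitive outcome
#' plus an optional intermediate outcome. Effects are per research
#' intervention, versus the control of its randomisation: odds ratios on the
#' logit scale (binary, `effect_scale = "or"`), risk ratios (binary,
#' `effect_scale = "rr"`, which makes event-rate dilution arithmetic exact)
#' or hazard ratios (time-to-event). Under the factorial no-interaction
#' default all pairwise interaction multipliers are 1; multipliers other
#' than 1 enter the linear predictor as `log` terms for patients receiving
#' both members of a pair. The intermediate outcome shares the definitive
#' outcome's linear predictor scaled by a concordance parameter `rho`
#' (`rho = 1`: identical treatment effects; `rho = 0`: independent of
#' treatment).
#'
#' @param outcome_type `"binary"` or `"tte"`.
#' @param baseline control-group event probability `p0` (binary) or hazard
#'   per unit time (tte).
#' @param effects named numeric, one ratio per research intervention id.
#' @param interactions optional named numeric of pairwise multipliers, names
#'   like `"A1:B1"` (order irrelevant), default 1.
#' @param intermediate optional list: `baseline` (probability or hazard) and
#'   `rho` in `[0, 1]` (concordance with the definitive effects).
#' @param follow_up follow-up duration for time-to-event outcomes.
#' @param secular_trend multiplier applied to the baseline odds (binary,
#'   `"or"` scale), risk (binary, `"rr"` scale) or hazard (tte) per unit of
#'   calendar time; 1 (default) means no drift.
#' @param effect_scale `"or"` (default) or `"rr"` for binary outcomes.
#' @param outcome_delay time from randomisation until a binary outcome is
#'   observed (default 0).
#' @return An `fm_outcome_model`.
#' @export
outcome_model <- function(outcome_type = c("binary", "tte"),
                          baseline, effects = numeric(0),
                          interactions = numeric(0),
                          intermediate = NULL, follow_up = 1,
                          secular_trend = 1, effect_scale = c("or", "rr"),
                          outcome_delay = 0) {
  outcome_type <- match.arg(outcome_type)
  effect_scale <- match.arg(effect_scale)
  if (outcome_type == "binary" && (baseline <= 0 || baseline >= 1)) {
    stop("baseline event probability must be in (0, 1)")
  }
  if (outcome_type == "tte" && baseline <= 0) stop("baseline hazard must be > 0")
  if (any(effects <= 0)) stop("effect ratios must be > 0")
  if (!is.null(intermediate)) {
    rho <- intermediate$rho %||% 1
    if (rho < 0 || rho > 1) stop("intermediate concordance rho must be in [0, 1]")
    intermediate$rho <- rho
  }
  structure(list(outcome_type = outcome_type, baseline = baseline,
                 effects = effects, interactions = interactions,
                 intermediate = intermediate, follow_up = follow_up,
                 secular_trend = secular_trend, effect_scale = effect_scale,
                 outcome_delay = outcome_delay),
            class = "fm_outcome_model")
}

#' Simulate patient arrivals with eligibility and stratification factors
#'
#' Arrival times are deterministic at spacing `1/rate` (the constant-accrual
#' planning assumption) or a Poisson process of the same rate. Eligibility
#' flags are drawn independently per intervention, consent flags per
#' randomisation.
#'
#' @param rate patients per unit time (> 0).
#' @param horizon calendar length of the accrual window (> 0).
#' @param eligibility_probs named numeric: probability a patient is eligible
#'   for each named intervention (omitted interventions: always eligible).
#' @param consent_probs named numeric per randomisation (default 1).
#' @param factors named list: each entry a vector of levels (sampled
#'   uniformly) or a named probability vector.
#' @param process `"deterministic"` (default) or `"poisson"`.
#' @return data.frame: `id`, `arrival`, one logical `elig_<id>` column per
#'   named intervention, one logical `consent_<id>` per named randomisation,
#'   one column per factor.
#' @export
simulate_arrivals <- function(rate, horizon, eligibility_probs = NULL,
                              consent_probs = NULL, factors = NULL,
                              process = c("deterministic", "poisson")) {
  process <- match.arg(process)
  if (rate <= 0) stop("accrual rate must be > 0")
  if (horizon <= 0) stop("accrual horizon must be > 0")
  arrival <- if (process == "deterministic") {
    seq_len(floor(rate * horizon + 1e-9)) / rate
  } else {
    t <- cumsum(stats::rexp(ceiling(rate * horizon * 2 + 10), rate))
    while (length(t) && t[length(t)] < horizon) {
      t <- c(t, t[length(t)] + cumsum(stats::rexp(ceiling(rate * horizon), rate)))
    }
    t[t <= horizon]
  }
  n <- length(arrival)
  out <- data.frame(id = seq_len(n), arrival = arrival)
  for (nm in names(eligibility_probs)) {
    out[[paste0("elig_", nm)]] <- stats::runif(n) < eligibility_probs[[nm]]
  }
  for (nm in names(consent_probs)) {
    out[[paste0("consent_", nm)]] <- stats::runif(n) < consent_probs[[nm]]
  }
  for (nm in names(factors)) {
    f <- factors[[nm]]
    probs <- if (!is.null(names(f)) && is.numeric(f)) f / sum(f)
             else rep(1 / length(f), length(f))
    levels <- if (!is.null(names(f)) && is.numeric(f)) names(f) else as.character(f)
    out[[nm]] <- sample(levels, n, replace = TRUE, prob = probs)
  }
  out
}

# Linear predictor contribution of the received research interventions:
# sum of log effect ratios plus log interaction multipliers, times `scale`.
effect_lp <- function(assignments, model, scale = 1) {
  known <- names(model$effects)
  amat <- as.matrix(as.data.frame(assignments, stringsAsFactors = FALSE))
  lp <- numeric(nrow(amat))
  received <- matrix(FALSE, nrow(amat), length(known),
                     dimnames = list(NULL, known))
  for (j in seq_len(ncol(amat))) {
    hit <- match(amat[, j], known)
    ok <- !is.na(hit)
    if (any(ok)) {
      lp[ok] <- lp[ok] + log(model$effects[hit[ok]])
      received[cbind(which(ok), hit[ok])] <- TRUE
    }
  }
  for (nm in names(model$interactions)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    bad <- setdiff(pair, known)
    if (length(bad)) stop("interaction references unknown intervention: ", bad[1])
    both <- received[, pair[1]] & received[, pair[2]]
    lp[both] <- lp[both] + log(model$interactions[[nm]])
  }
  lp * scale
}

check_known_arms <- function(assignments, model, controls = NULL) {
  ids <- unique(unlist(lapply(assignments, as.character)))
  ids <- ids[!is.na(ids) & ids != "" & !startsWith(ids, "all-") & ids != "none"]
  if (is.null(controls)) return(invisible(TRUE))  # ids without an effect act as controls
  unknown <- setdiff(ids, c(names(model$effects), controls))
  if (length(unknown)) {
    stop("assignment references unknown intervention(s): ",
         paste(unknown, collapse = ", "))
  }
}

#' Simulate the definitive binary outcome
#'
#' Event probability is `invlogit(logit(p0 * trend) + sum log-OR + sum log
#' interaction multipliers)` on the odds-ratio scale, or `p0 * trend *
#' prod(RR)` on the risk-ratio scale, over the research interventions each
#' patient received.
#'
#' @param assignments data.frame (or named list of equal-length vectors):
#'   one column per randomisation holding the received intervention id.
#' @param model an `fm_outcome_model` with `outcome_type = "binary"`.
#' @param time calendar time of randomisation (vector or scalar), used by
#'   the secular trend.
#' @param controls optional character vector of control arm ids (for
#'   validation of assignment labels).
#' @return integer vector of event indicators.
#' @export
simulate_binary <- function(assignments, model, time = 0, controls = NULL) {
  stopifnot(model$outcome_type == "binary")
  check_known_arms(assignments, model, controls)
  p <- event_probability(assignments, model, time)
  stats::rbinom(length(p), 1L, p)
}

#' @rdname simulate_binary
#' @export
event_probability <- function(assignments, model, time = 0) {
  lp <- effect_lp(assignments, model)
  trend <- model$secular_trend ^ time
  if (model$effect_scale == "or") {
    stats::plogis(stats::qlogis(model$baseline) + log(trend) + lp)
  } else {
    pmin(model$baseline * trend * exp(lp), 1 - 1e-12)
  }
}

#' Simulate the definitive time-to-event outcome
#'
#' Exponential event times with hazard `lambda0 * trend^t * prod(HR) *
#' interaction multipliers`, administratively censored at `follow_up`.
#'
#' @inheritParams simulate_binary
#' @param arrival calendar arrival times (for the secular trend and for the
#'   calendar timestamp of observed events).
#' @return data.frame: `time` (observed), `status` (1 event, 0 censored),
#'   `calendar` (arrival + observed time, used by event-driven monitoring).
#' @export
simulate_tte <- function(assignments, model, arrival = 0, controls = NULL) {
  stopifnot(model$outcome_type == "tte")
  if (model$follow_up < 0) stop("follow_up must be >= 0")
  check_known_arms(assignments, model, controls)
  lp <- effect_lp(assignments, model)
  n <- length(lp)
  arrival <- rep_len(arrival, n)
  hazard <- model$baseline * model$secular_trend ^ arrival * exp(lp)
  t_event <- if (n) stats::rexp(n, hazard) else numeric(0)
  time <- pmin(t_event, model$follow_up)
  status <- as.integer(t_event <= model$follow_up)
  data.frame(time = time, status = status, calendar = arrival + time)
}

#' Simulate the intermediate outcome
#'
#' The intermediate outcome is information-rich and earlier than the
#' definitive outcome; it is generated from the same treatment linear
#' predictor scaled by the concordance parameter `rho`, around its own
#' baseline.
#'
#' @inheritParams simulate_binary
#' @return integer event indicators (binary models) or a data.frame as in
#'   [simulate_tte()] (time-to-event models, with `follow_up` shared).
#' @export
simulate_intermediate <- function(assignments, model, time = 0, controls = NULL) {
  if (is.null(model$intermediate)) stop("no intermediate outcome configured")
  im <- model$intermediate
  lp <- effect_lp(assignments, model, scale = im$rho)
  if (model$outcome_type == "binary") {
    trend <- model$secular_trend ^ time
    p <- if (model$effect_scale == "or") {
      stats::plogis(stats::qlogis(im$baseline) + log(trend) + lp)
    } else {
      pmin(im$baseline * trend * exp(lp), 1 - 1e-12)
    }
    stats::rbinom(length(p), 1L, p)
  } else {
    n <- length(lp)
    arrival <- rep_len(time, n)
    hazard <- im$baseline * model$secular_trend ^ arrival * exp(lp)
    t_event <- stats::rexp(n, hazard)
    data.frame(time = pmin(t_event, model$follow_up),
               status = as.integer(t_event <= model$follow_up),
               calendar = arrival + pmin(t_event, model$follow_up))
  }
}
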