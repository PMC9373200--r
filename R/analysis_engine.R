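#' Build the concurrent-control analysis set for one comparison
#'
#' The analysis set for research arm vs control contains exactly the
#' patients randomised (through the randomisation mechanism, not by
#' preference or scheme) to one of the two arms, during a stage in which
#' both arms were open to randomisation, and who were eligible for both
#' arms. Patients allocated to either arm otherwise — scheme-fixed delivery
#' after a discontinuation, preference, or randomisation within a reduced
#' arm set not containing both arms — are excluded and logged with a
#' reason, as are patients randomised to the control after the research arm
#' had stopped (non-concurrent stage).
#'
#' @param data patient-level dataset: one row per patient with columns
#'   `id`, `stage`, per randomisation `arm_<R>` and `mech_<R>`, optional
#'   `elig_<intervention>` logicals, and outcome columns.
#' @param design an `fm_design` whose stage trajectory matches the data.
#' @param comparison comparison id (`"<research>_vs_<control>"`).
#' @return An `fm_analysis_set`: `comparison`, `randomisation`, `data`
#'   (included rows, with a two-level factor `arm`, control first),
#'   `exclusions` (data.frame `id`, `reason`), `stages` (concurrent stage
#'   indices).
#' @export
select_concurrent <- function(data, design, comparison) {
  comps <- design_comparisons(design)
  row <- comps[comps$comparison == comparison, , drop = FALSE]
  if (!nrow(row)) stop("unknown comparison: ", comparison)
  rid <- row$randomisation; res <- row$research; ctl <- row$control
  arm_col <- paste0("arm_", rid); mech_col <- paste0("mech_", rid)
  if (!all(c(arm_col, mech_col) %in% names(data))) {
    stop("dataset lacks allocation columns for randomisation ", rid)
  }
  open_stages <- stages_with_both_open(design, rid, res, ctl)

  in_arms <- data[[arm_col]] %in% c(res, ctl)
  randomised <- data[[mech_col]] == "randomised"
  concurrent <- data$stage %in% open_stages
  eligible <- rep(TRUE, nrow(data))
  for (a in c(res, ctl)) {
    col <- paste0("elig_", a)
    if (col %in% names(data)) eligible <- eligible & data[[col]]
  }
  include <- in_arms & randomised & concurrent & eligible

  reason <- rep(NA_character_, nrow(data))
  reason[in_arms & !randomised] <- "non-randomised allocation"
  reason[in_arms & randomised & !concurrent] <- "non-concurrent stage"
  reason[in_arms & randomised & concurrent & !eligible] <- "ineligible for one arm"
  excl <- data.frame(id = data$id[!is.na(reason)],
                     reason = reason[!is.na(reason)], stringsAsFactors = FALSE)

  sub <- data[include, , drop = FALSE]
  sub$arm <- factor(sub[[arm_col]], levels = c(ctl, res))
  structure(list(comparison = comparison, randomisation = rid,
                 research = res, control = ctl, data = sub,
                 exclusions = excl, stages = open_stages),
            class = "fm_analysis_set")
}

#' @export
print.fm_analysis_set <- function(x, ...) {
  cat(sprintf("Analysis set %s: %d included (%s), %d excluded\n",
              x$comparison, nrow(x$data),
              paste(sprintf("%s=%d", levels(x$data$arm),
                            tabulate(x$data$arm, 2)), collapse = ", "),
              nrow(x$exclusions)))
  invisible(x)
}

#' Stage-stratified estimate and test for one comparison
#'
#' Binary outcomes: Mantel-Haenszel common odds ratio across stage strata
#' with the Cochran-Mantel-Haenszel test and a Robins-Breslow-Greenland
#' standard error. Time-to-event outcomes: Cox proportional-hazards
#' estimate and stage-stratified log-rank test (`strata(stage)`).
#' Uninformative strata (an empty arm, or no event margin) are dropped and
#' logged. The z statistic is signed so that benefit (fewer events, lower
#' hazard) is positive.
#'
#' @param aset an `fm_analysis_set` from [select_concurrent()].
#' @param outcome_type `"binary"` (expects column `event`) or `"tte"`
#'   (expects `time`, `status`).
#' @return An `fm_comparison_result` with `estimate` (log OR / log HR),
#'   `se`, `ci`, `z` (benefit-positive), `stage_table`, `dropped_strata`,
#'   `n` and `events` per arm, `informative`.
#' @export
stage_stratified_test <- function(aset, outcome_type = c("binary", "tte")) {
  outcome_type <- match.arg(outcome_type)
  d <- aset$data
  empty <- function(note) {
    structure(list(comparison = aset$comparison, estimate = NA_real_,
                   se = NA_real_, ci = c(NA_real_, NA_real_), z = NA_real_,
                   stage_table = NULL, dropped_strata = integer(0),
                   n = c(0, 0), events = c(0, 0), informative = FALSE,
                   note = note, outcome_type = outcome_type),
              class = "fm_comparison_result")
  }
  if (!nrow(d)) return(empty("empty analysis set"))

  if (outcome_type == "binary") {
    stage_tab <- table(arm = d$arm, event = factor(d$event, levels = c(0, 1)),
                       stage = d$stage)
    K <- dim(stage_tab)[3]
    keep <- vapply(seq_len(K), function(k) {
      t2 <- stage_tab[, , k]
      all(rowSums(t2) > 0) && sum(t2[, "1"]) > 0 && sum(t2[, "0"]) > 0
    }, logical(1))
    dropped <- as.integer(dimnames(stage_tab)$stage[!keep])
    if (!any(keep)) return(empty("no informative stratum"))
    tab <- stage_tab[, , keep, drop = FALSE]
    mh <- mantel_haenszel(tab)
    if (!is.finite(mh$estimate)) return(empty("all events on one side"))
    est <- mh$estimate; se <- mh$se
    res <- list(comparison = aset$comparison, estimate = est, se = se,
                ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
                z = -est / se,  # benefit (OR < 1) positive
                stage_table = stage_tab, dropped_strata = dropped,
                n = as.numeric(table(d$arm)),
                events = as.numeric(tapply(d$event, d$arm, sum, default = 0)),
                informative = TRUE, note = NULL, outcome_type = outcome_type,
                cmh_statistic = mh$cmh_statistic)
  } else {
    if (length(unique(d$arm[d$status == 1])) == 0 || !any(d$status == 1)) {
      return(empty("no events"))
    }
    multi_stage <- length(unique(d$stage)) > 1
    fml <- if (multi_stage) {
      survival::Surv(time, status) ~ arm + survival::strata(stage)
    } else {
      survival::Surv(time, status) ~ arm
    }
    fit <- tryCatch(survival::coxph(fml, data = d),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[1])) return(empty("degenerate fit"))
    est <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    lr <- tryCatch(survival::survdiff(fml, data = d),
                   error = function(e) NULL)
    res <- list(comparison = aset$comparison, estimate = est, se = se,
                ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
                z = -est / se,
                stage_table = table(arm = d$arm, status = d$status,
                                    stage = d$stage),
                dropped_strata = integer(0),
                n = as.numeric(table(d$arm)),
                events = as.numeric(tapply(d$status, d$arm, sum, default = 0)),
                informative = TRUE, note = NULL, outcome_type = outcome_type,
                logrank_statistic = if (!is.null(lr)) lr$chisq else NA_real_)
  }
  structure(res, class = "fm_comparison_result")
}

#' Mantel-Haenszel common odds ratio over strata
#'
#' Closed-form Mantel-Haenszel estimator of the common odds ratio of a
#' 2x2xK table (rows: control then research arm; columns: no-event, event),
#' with the Robins-Breslow-Greenland variance of its log and the
#' Cochran-Mantel-Haenszel test statistic. Zero cells are handled natively
#' (no continuity correction is applied to the MH sums).
#'
#' @param tab a 2x2xK array: `tab[arm, event, stratum]` with arm levels
#'   (control, research) and event levels (0, 1).
#' @return list: `estimate` (log common OR, research vs control), `se`
#'   (RBG), `cmh_statistic` (1 df, uncorrected).
#' @export
mantel_haenszel <- function(tab) {
  stopifnot(length(dim(tab)) == 3, all(dim(tab)[1:2] == 2))
  K <- dim(tab)[3]
  a <- as.numeric(tab[2, 2, ]); b <- as.numeric(tab[2, 1, ])   # research: events, non-events
  c_ <- as.numeric(tab[1, 2, ]); d <- as.numeric(tab[1, 1, ])  # control: events, non-events
  n <- a + b + c_ + d
  R <- a * d / n; S <- b * c_ / n
  if (sum(R) == 0 || sum(S) == 0) {
    return(list(estimate = log(sum(R) / sum(S)), se = NA_real_,
                cmh_statistic = NA_real_))
  }
  est <- log(sum(R) / sum(S))
  P <- (a + d) / n; Q <- (b + c_) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  n1 <- a + b; n0 <- c_ + d; m1 <- a + c_; m0 <- b + d
  Ek <- n1 * m1 / n
  Vk <- n1 * n0 * m1 * m0 / (n^2 * (n - 1))
  cmh <- if (sum(Vk) > 0) (sum(a) - sum(Ek))^2 / sum(Vk) else NA_real_
  list(estimate = est, se = sqrt(v), cmh_statistic = cmh)
}

#' @export
print.fm_comparison_result <- function(x, ...) {
  if (!x$informative) {
    cat(sprintf("%s: no information (%s)\n", x$comparison, x$note))
    return(invisible(x))
  }
  lab <- if (x$outcome_type == "binary") "log-OR" else "log-HR"
  cat(sprintf("%s: %s = %.4f (SE %.4f, 95%% CI %.4f to %.4f), z(benefit) = %.3f\n",
              x$comparison, lab, x$estimate, x$se, x$ci[1], x$ci[2], x$z))
  if (length(x$dropped_strata)) {
    cat("  dropped uninformative stage strata:",
        paste(x$dropped_strata, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combined all-intervention regression model
#'
#' Fits one regression on all concurrent data (the union of the
#' per-comparison concurrent-control analysis sets): one indicator per
#' research intervention, plus a categorical trial-stage term to preserve
#' concurrency. Binary outcomes use logistic regression; time-to-event
#' outcomes a Cox model with stage strata. Degenerate coefficients
#' (separation) are flagged rather than dropped.
#'
#' @param data patient-level dataset as in [select_concurrent()].
#' @param design an `fm_design`.
#' @param outcome_type `"binary"` or `"tte"`.
#' @return data.frame: `intervention`, `estimate` (log OR / log HR), `se`,
#'   `lcl`, `ucl`, `z` (benefit-positive), `flagged`.
#' @export
combined_model <- function(data, design, outcome_type = c("binary", "tte")) {
  outcome_type <- match.arg(outcome_type)
  comps <- design_comparisons(design)
  sets <- lapply(comps$comparison, function(cid) {
    select_concurrent(data, design, cid)
  })
  ids <- unique(unlist(lapply(sets, function(s) s$data$id)))
  if (!length(ids)) stop("no comparison with information")
  sub <- data[data$id %in% ids, , drop = FALSE]
  for (i in seq_len(nrow(comps))) {
    arm_col <- paste0("arm_", comps$randomisation[i])
    mech_col <- paste0("mech_", comps$randomisation[i])
    sub[[paste0("trt_", comps$research[i])]] <-
      as.integer(sub[[arm_col]] == comps$research[i] &
                 sub[[mech_col]] == "randomised")
  }
  trt_cols <- paste0("trt_", comps$research)
  multi_stage <- length(unique(sub$stage)) > 1
  if (outcome_type == "binary") {
    fml <- stats::reformulate(c(trt_cols, if (multi_stage) "factor(stage)"),
                              response = "event")
    fit <- stats::glm(fml, family = stats::binomial(), data = sub)
    cf <- summary(fit)$coefficients
  } else {
    fml <- stats::reformulate(c(trt_cols, if (multi_stage) "survival::strata(stage)"),
                              response = "survival::Surv(time, status)")
    fit <- survival::coxph(fml, data = sub)
    cf <- summary(fit)$coefficients[, c("coef", "se(coef)"), drop = FALSE]
    colnames(cf) <- c("Estimate", "Std. Error")
  }
  rows <- lapply(seq_len(nrow(comps)), function(i) {
    nm <- trt_cols[i]
    if (!nm %in% rownames(cf)) {
      return(data.frame(intervention = comps$research[i], estimate = NA_real_,
                        se = NA_real_, lcl = NA_real_, ucl = NA_real_,
                        z = NA_real_, flagged = TRUE))
    }
    est <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    data.frame(intervention = comps$research[i], estimate = est, se = se,
               lcl = est - stats::qnorm(0.975) * se,
               ucl = est + stats::qnorm(0.975) * se,
               z = -est / se,
               flagged = !is.finite(est) || !is.finite(se) ||
                 abs(est) > 10 || se > 10)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup and interaction analysis across another randomisation
#'
#' Estimates the comparison's effect within subgroups defined by the
#' randomised arms of another randomisation (concurrent patients only) and
#' tests homogeneity of the effect across subgroups with a likelihood-ratio
#' test for the interaction term (stage-adjusted).
#'
#' @param data patient-level dataset.
#' @param design an `fm_design`.
#' @param comparison comparison id being examined.
#' @param by_randomisation id of the other randomisation defining subgroups.
#' @param outcome_type `"binary"` or `"tte"`.
#' @return list: `subgroups` (data.frame of per-subgroup estimates, empty
#'   subgroups reported with NA), `interaction_p`, `interaction_df`.
#' @export
interaction_analysis <- function(data, design, comparison, by_randomisation,
                                 outcome_type = c("binary", "tte")) {
  outcome_type <- match.arg(outcome_type)
  aset <- select_concurrent(data, design, comparison)
  if (by_randomisation == aset$randomisation) {
    stop("subgroups must come from a different randomisation")
  }
  if (!by_randomisation %in% names(design$randomisations)) {
    stop("no such randomisation to interact with: ", by_randomisation)
  }
  d <- aset$data
  by_arm <- paste0("arm_", by_randomisation)
  by_mech <- paste0("mech_", by_randomisation)
  d <- d[d[[by_mech]] == "randomised", , drop = FALSE]
  levels_by <- sort(unique(d[[by_arm]]))
  if (length(levels_by) < 2) {
    stop("fewer than two concurrent subgroup levels in randomisation ",
         by_randomisation)
  }
  subs <- lapply(levels_by, function(lv) {
    di <- d[d[[by_arm]] == lv, , drop = FALSE]
    sub_aset <- aset; sub_aset$data <- di
    r <- stage_stratified_test(sub_aset, outcome_type)
    data.frame(subgroup = lv, n = nrow(di),
               estimate = r$estimate, se = r$se, z = r$z,
               informative = r$informative, stringsAsFactors = FALSE)
  })
  subs <- do.call(rbind, subs)

  d$subgroup <- factor(d[[by_arm]])
  multi_stage <- length(unique(d$stage)) > 1
  stage_term <- if (multi_stage) "factor(stage)" else NULL
  if (outcome_type == "binary") {
    f0 <- stats::reformulate(c("arm", "subgroup", stage_term), "event")
    f1 <- stats::reformulate(c("arm * subgroup", stage_term), "event")
    m0 <- stats::glm(f0, stats::binomial(), data = d)
    m1 <- stats::glm(f1, stats::binomial(), data = d)
    an <- stats::anova(m0, m1, test = "LRT")
    p <- an$`Pr(>Chi)`[2]; df <- an$Df[2]
  } else {
    st <- if (multi_stage) "survival::strata(stage)" else NULL
    f0 <- stats::reformulate(c("arm", "subgroup", st), "survival::Surv(time, status)")
    f1 <- stats::reformulate(c("arm * subgroup", st), "survival::Surv(time, status)")
    m0 <- survival::coxph(f0, data = d)
    m1 <- survival::coxph(f1, data = d)
    an <- stats::anova(m0, m1)
    p <- an$`Pr(>|Chi|)`[2] %||% an$`P(>|Chi|)`[2]
    df <- abs(an$Df[2] %||% (length(stats::coef(m1)) - length(stats::coef(m0))))
  }
  list(subgroups = subs, interaction_p = p, interaction_df = df)
}
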