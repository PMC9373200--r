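#' Construct a factorial multi-arm multi-stage trial design
#'
#' Builds the initial design of a factorial-MAMS platform trial: an ordered
#' set of concurrent randomisations, each with exactly one control arm and one
#' or more research arms. Stage 1 is the full cross of all randomisations;
#' every later change of randomisation scheme (an adaptation, or a comparison
#' completing) opens a new stage.
#'
#' @param randomisations list of randomisation specs; each is a list with
#'   `id` (label, e.g. `"A"`) and `arms`, a list of arms each with `id`,
#'   `role` (`"control"` or `"research"`) and optional `weight` (positive
#'   integer allocation weight, default 1).
#' @param targets per-comparison sample-size target: a single number applied
#'   to every pairwise comparison, or a named vector keyed by comparison id
#'   (`"<research>_vs_<control>"`). Names may also include comparisons that
#'   only arise after a planned adaptation.
#' @param stratification_factors named list of baseline stratification
#'   factors, each a vector of levels (used by the randomisation engine).
#' @param accrual_rate patients recruited per unit time (calendar planning).
#' @param eligibility_fraction named numeric, fraction of patients entering
#'   each randomisation (default 1 for all); used by the flow planner.
#' @param interim_at cumulative patient counts at which interim analyses are
#'   planned (these split the flow table into stages even without a scheme
#'   change).
#' @param deliver_control_after_stop if `TRUE` (default), patients recruited
#'   after a two-way randomisation is discontinued are recorded as receiving
#'   its control (`"all-<control>"`); otherwise no intervention. Labelling
#'   only; never a randomised allocation.
#' @return An object of class `fm_design`.
#' @examples
#' d <- make_factorial_design(
#'   randomisations = list(
#'     list(id = "A", arms = list(list(id = "A0", role = "control"),
#'                                list(id = "A1", role = "research"))),
#'     list(id = "B", arms = list(list(id = "B0", role = "control"),
#'                                list(id = "B1", role = "research")))),
#'   targets = 3000)
#' enumerate_arms(current_stage(d))
#' @export
make_factorial_design <- function(randomisations, targets,
                                  stratification_factors = list(),
                                  accrual_rate = 100,
                                  eligibility_fraction = NULL,
                                  interim_at = numeric(0),
                                  deliver_control_after_stop = TRUE) {
  if (length(randomisations) < 1) stop("at least one randomisation is required")
  rands <- list()
  seen_arms <- character(0)
  for (i in seq_along(randomisations)) {
    spec <- randomisations[[i]]
    if (is.null(spec$id)) stop("randomisation ", i, " has no id")
    arms <- normalise_arms(spec$arms, spec$id)
    if (sum(arms$role == "control") != 1) {
      stop("randomisation ", spec$id, " must have exactly one control arm")
    }
    if (nrow(arms) < 2) stop("randomisation ", spec$id, " needs at least 2 arms")
    dup <- intersect(arms$id, seen_arms)
    if (length(dup)) stop("duplicate intervention id(s): ", paste(dup, collapse = ", "))
    seen_arms <- c(seen_arms, arms$id)
    rands[[spec$id]] <- list(id = spec$id, position = i, arms = arms,
                             status = "open", fixed_value = NA_character_)
  }
  design <- structure(list(
    randomisations = rands,
    targets = targets,
    stratification_factors = stratification_factors,
    accrual_rate = accrual_rate,
    eligibility_fraction = eligibility_fraction %||%
      stats::setNames(rep(1, length(rands)), names(rands)),
    interim_at = interim_at,
    adaptations = list(),
    deliver_control_after_stop = deliver_control_after_stop,
    stages = list()
  ), class = "fm_design")
  design$stages <- list(new_stage(1L, 0, scheme_snapshot(rands), "initial"))
  design
}

normalise_arms <- function(arms, rand_id) {
  if (is.null(arms) || !length(arms)) stop("randomisation ", rand_id, " has no arms")
  out <- do.call(rbind, lapply(arms, function(a) {
    data.frame(id = a$id, role = a$role %||% "research",
               weight = a$weight %||% 1, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(out$id)) stop("duplicate arm id within randomisation ", rand_id)
  if (any(out$weight <= 0)) stop("allocation weights must be positive")
  if (!all(out$role %in% c("control", "research"))) {
    stop("arm role must be 'control' or 'research'")
  }
  out
}

new_stage <- function(index, start, scheme, trigger) {
  structure(list(index = index, start = start, scheme = scheme,
                 trigger = trigger), class = "fm_stage")
}

scheme_snapshot <- function(rands) {
  lapply(rands, function(r) {
    list(id = r$id, position = r$position, status = r$status,
         arms = r$arms, fixed_value = r$fixed_value)
  })
}

#' @rdname make_factorial_design
#' @param design an `fm_design`.
#' @export
current_stage <- function(design) design$stages[[length(design$stages)]]

control_arm <- function(rand) rand$arms$id[rand$arms$role == "control"]
research_arms <- function(rand) rand$arms$id[rand$arms$role == "research"]

#' List the pairwise comparisons of a design
#'
#' One comparison per research arm that is (or ever was) part of the design's
#' stage trajectory: that arm versus the control of its randomisation.
#'
#' @param design an `fm_design`.
#' @return data.frame with columns `comparison`, `randomisation`, `research`,
#'   `control`.
#' @export
design_comparisons <- function(design) {
  seen <- list()
  for (st in design$stages) {
    for (r in st$scheme) {
      ctl <- r$arms$id[r$arms$role == "control"]
      for (res in r$arms$id[r$arms$role == "research"]) {
        cid <- comparison_id(res, ctl)
        if (is.null(seen[[cid]])) {
          seen[[cid]] <- data.frame(comparison = cid, randomisation = r$id,
                                    research = res, control = ctl,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, seen)
  rownames(out) <- NULL
  out
}

comparison_target <- function(design, comp_id) {
  t <- design$targets
  if (length(t) == 1 && is.null(names(t))) return(as.numeric(t))
  if (!comp_id %in% names(t)) {
    stop("no sample-size target configured for comparison ", comp_id)
  }
  as.numeric(t[[comp_id]])
}

#' Enumerate the active arm combinations of a stage
#'
#' Returns the cross product of the active arms of all open randomisations in
#' a stage's scheme, in deterministic order: arms sorted within each
#' randomisation, randomisations by position, with the first randomisation
#' varying fastest (so a 2x2 scheme gives `A0+B0, A1+B0, A0+B1, A1+B1`).
#'
#' @param stage an `fm_stage` (e.g. from [current_stage()]).
#' @return character vector of combination labels, arms joined by `"+"`.
#' @export
enumerate_arms <- function(stage) {
  scheme <- if (inherits(stage, "fm_stage")) stage$scheme else stage
  open <- Filter(function(r) identical(r$status, "open"), scheme)
  if (!length(open)) stop("no open randomisation in stage scheme")
  open <- open[order(vapply(open, `[[`, numeric(1), "position"))]
  grids <- lapply(open, function(r) sort(r$arms$id))
  combos <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  apply(combos, 1, paste, collapse = "+")
}

#' Define a design adaptation
#'
#' @param kind one of `"stop_lack_of_benefit"`, `"stop_efficacy"`,
#'   `"add_randomisation"`, `"add_intervention"`, `"drop_completed"`.
#' @param target intervention id (stop/drop kinds), randomisation id
#'   (`add_intervention`, or `drop_completed` of a whole randomisation).
#' @param time adaptation time, expressed as cumulative patients randomised
#'   (the flow planner's clock) or calendar time in the simulator.
#' @param arm for `add_intervention`: list with `id` and optional `weight`.
#' @param spec for `add_randomisation`: a randomisation spec as in
#'   [make_factorial_design()] (two-way: one research vs one control arm).
#' @return An `fm_adaptation`.
#' @export
adaptation <- function(kind, target, time, arm = NULL, spec = NULL) {
  kinds <- c("stop_lack_of_benefit", "stop_efficacy", "add_randomisation",
             "add_intervention", "drop_completed")
  kind <- match.arg(kind, kinds)
  structure(list(kind = kind, target = target, time = time, arm = arm,
                 spec = spec), class = "fm_adaptation")
}

#' Apply an adaptation to a design, opening a new stage
#'
#' Implements the four factorial-MAMS adaptation operators. Stopping a
#' research arm of a two-way randomisation discontinues the whole
#' randomisation (subsequent patients all receive its control, or nothing);
#' stopping an arm of a three-or-more-way randomisation removes that arm
#' only. `add_randomisation` appends a new two-way randomisation at the end
#' of the sequence; `add_intervention` inserts a research arm into an
#' existing randomisation. `drop_completed` uses the same removal semantics
#' as stopping and marks the routine end of a comparison that reached its
#' target, so that every scheme change opens a stage.
#'
#' @param design an `fm_design`.
#' @param adapt an `fm_adaptation` from [adaptation()].
#' @return The updated `fm_design` with one more stage.
#' @export
apply_adaptation <- function(design, adapt) {
  stopifnot(inherits(design, "fm_design"), inherits(adapt, "fm_adaptation"))
  rands <- design$randomisations
  kind <- adapt$kind

  if (kind %in% c("stop_lack_of_benefit", "stop_efficacy", "drop_completed")) {
    if (adapt$target %in% names(rands)) {
      if (kind != "drop_completed") {
        stop("stop_* adaptations target an intervention, not a randomisation")
      }
      rands[[adapt$target]] <- discontinue_randomisation(rands[[adapt$target]],
                                                         design)
    } else {
      rid <- find_randomisation_of_arm(rands, adapt$target)
      r <- rands[[rid]]
      if (identical(r$status, "discontinued")) {
        stop("randomisation ", rid, " is already discontinued")
      }
      if (adapt$target == control_arm(r)) {
        stop("cannot stop the control arm ", adapt$target)
      }
      if (!adapt$target %in% r$arms$id) {
        stop("arm ", adapt$target, " is not active in randomisation ", rid)
      }
      if (nrow(r$arms) <= 2) {
        rands[[rid]] <- discontinue_randomisation(r, design)
      } else {
        r$arms <- r$arms[r$arms$id != adapt$target, , drop = FALSE]
        rands[[rid]] <- r
      }
    }
  } else if (kind == "add_randomisation") {
    spec <- adapt$spec
    if (is.null(spec)) stop("add_randomisation requires a randomisation spec")
    arms <- normalise_arms(spec$arms, spec$id)
    if (sum(arms$role == "control") != 1) {
      stop("added randomisation must have exactly one control arm")
    }
    if (spec$id %in% names(rands)) {
      stop("randomisation id ", spec$id, " already exists")
    }
    existing <- unlist(lapply(rands, function(r) r$arms$id))
    if (any(arms$id %in% existing)) stop("duplicate intervention id in added randomisation")
    rands[[spec$id]] <- list(id = spec$id,
                             position = max(vapply(rands, `[[`, numeric(1), "position")) + 1,
                             arms = arms, status = "open",
                             fixed_value = NA_character_)
    design$eligibility_fraction[spec$id] <- 1
  } else if (kind == "add_intervention") {
    rid <- adapt$target
    if (!rid %in% names(rands)) stop("unknown randomisation ", rid)
    r <- rands[[rid]]
    if (identical(r$status, "discontinued")) {
      stop("cannot add an intervention to discontinued randomisation ", rid)
    }
    if (is.null(adapt$arm) || is.null(adapt$arm$id)) {
      stop("add_intervention requires an arm with an id")
    }
    existing <- unlist(lapply(rands, function(x) x$arms$id))
    if (adapt$arm$id %in% existing) {
      stop("duplicate intervention id ", adapt$arm$id)
    }
    r$arms <- rbind(r$arms,
                    data.frame(id = adapt$arm$id, role = "research",
                               weight = adapt$arm$weight %||% 1,
                               stringsAsFactors = FALSE))
    rands[[rid]] <- r
  }

  design$randomisations <- rands
  stage <- new_stage(length(design$stages) + 1L, adapt$time,
                     scheme_snapshot(rands),
                     paste(kind, adapt$target, sep = ":"))
  design$stages <- c(design$stages, list(stage))
  design$adaptations <- c(design$adaptations, list(adapt))
  design
}

discontinue_randomisation <- function(r, design) {
  r$status <- "discontinued"
  r$fixed_value <- if (isTRUE(design$deliver_control_after_stop)) {
    paste0("all-", control_arm(r))
  } else {
    "none"
  }
  r
}

find_randomisation_of_arm <- function(rands, arm_id) {
  for (r in rands) if (arm_id %in% r$arms$id) return(r$id)
  stop("no randomisation contains arm ", arm_id)
}

# Stages of the trajectory during which both arms of a comparison were open
# to randomisation: the concurrent stages for the analysis engine.
stages_with_both_open <- function(design, randomisation, research, control) {
  idx <- vapply(design$stages, function(st) {
    r <- st$scheme[[randomisation]]
    !is.null(r) && identical(r$status, "open") &&
      all(c(research, control) %in% r$arms$id)
  }, logical(1))
  vapply(design$stages[idx], `[[`, integer(1), "index")
}

#' @export
print.fm_design <- function(x, ...) {
  cat("Factorial-MAMS design:", length(x$randomisations), "randomisation(s),",
      length(x$stages), "stage(s)\n")
  for (r in x$randomisations) {
    cat(sprintf("  %s [%s]: %s\n", r$id, r$status,
                paste(sprintf("%s(%s,w=%g)", r$arms$id,
                              substr(r$arms$role, 1, 1), r$arms$weight),
                      collapse = " ")))
  }
  st <- current_stage(x)
  cat("Current stage", st$index, "arms:",
      paste(tryCatch(enumerate_arms(st), error = function(e) "none"),
            collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.fm_stage <- function(x, ...) {
  cat(sprintf("Stage %d (start %g, trigger %s): %s\n", x$index, x$start,
              x$trigger, scheme_label(x$scheme)))
  invisible(x)
}

# "(A1 vs A2 vs A0) x (B1 vs B0)" with research arms first, control last.
scheme_label <- function(scheme) {
  open <- Filter(function(r) identical(r$status, "open"), scheme)
  if (!length(open)) return("(none)")
  open <- open[order(vapply(open, `[[`, numeric(1), "position"))]
  parts <- vapply(open, function(r) {
    res <- sort(r$arms$id[r$arms$role == "research"])
    ctl <- r$arms$id[r$arms$role == "control"]
    paste0("(", paste(c(res, ctl), collapse = " vs "), ")")
  }, character(1))
  paste(parts, collapse = " × ")
}
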