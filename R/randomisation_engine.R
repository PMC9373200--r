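#' Create a sequential stratified block-randomisation engine
#'
#' Implements stratified permuted-block randomisation performed sequentially
#' across the randomisations of a factorial-MAMS design. Each randomisation
#' is stratified by the configured baseline factors and by the patient's
#' allocations in all earlier randomisations, with a `"not-randomised"` level
#' for patients who did not enter (or no longer can enter) an earlier
#' randomisation. Blocks contain each active arm in proportion to its
#' allocation weight; block sizes are a randomly chosen multiple (from
#' `block_multiples`) of the weighted arm total. Patients eligible for only
#' a reduced subset of a multi-way randomisation draw from separate block
#' families over that subset.
#'
#' The returned engine is a mutable state object (an environment); drawing
#' assignments advances it in place, so identical seeds and patient streams
#' reproduce identical allocation logs.
#'
#' @param design an `fm_design`; the engine starts from its current stage.
#' @param block_multiples integer multiples of the weighted arm count used
#'   as block sizes, sampled uniformly per block (default `c(1, 2)`).
#' @return An `fm_randomiser` environment.
#' @export
new_randomiser <- function(design, block_multiples = c(1, 2)) {
  st <- new.env(parent = emptyenv())
  st$scheme <- lapply(design$randomisations, function(r) {
    list(id = r$id, position = r$position, status = r$status,
         arms = r$arms$id, roles = r$arms$role,
         weights = as.integer(round(r$arms$weight)),
         control = r$arms$id[r$arms$role == "control"],
         fixed_value = r$fixed_value, gen = 1L)
  })
  st$order <- names(st$scheme)[order(vapply(st$scheme, `[[`, numeric(1), "position"))]
  st$factors <- names(design$stratification_factors)
  st$block_multiples <- as.integer(block_multiples)
  st$blocks <- new.env(parent = emptyenv(), hash = TRUE)
  st$n_blocks <- 0L
  st$stage_index <- current_stage(design)$index
  st$seq <- 0L
  st$cap <- 1024L
  st$len <- 0L
  for (col in c("patient_id", "randomisation", "stratum", "assignment",
                "mechanism")) assign(paste0("L_", col), character(1024L), envir = st)
  st$L_block <- integer(1024L)
  st$L_stage <- integer(1024L)
  st$L_seq <- integer(1024L)
  st$L_time <- numeric(1024L)
  class(st) <- "fm_randomiser"
  st
}

rand_grow <- function(st) {
  newcap <- st$cap * 2L
  for (col in c("L_patient_id", "L_randomisation", "L_stratum",
                "L_assignment", "L_mechanism", "L_block", "L_stage",
                "L_seq", "L_time")) {
    v <- get(col, envir = st)
    length(v) <- newcap
    assign(col, v, envir = st)
  }
  st$cap <- newcap
}

rand_log <- function(st, pid, rid, stratum, assignment, mechanism, block, time) {
  i <- st$len + 1L
  if (i > st$cap) rand_grow(st)
  st$len <- i
  st$seq <- st$seq + 1L
  st$L_patient_id[i] <- pid
  st$L_randomisation[i] <- rid
  st$L_stratum[i] <- stratum
  st$L_assignment[i] <- assignment
  st$L_mechanism[i] <- mechanism
  st$L_block[i] <- block
  st$L_stage[i] <- st$stage_index
  st$L_seq[i] <- st$seq
  st$L_time[i] <- time
}

# Draw one assignment from the open block for (randomisation, eligible
# subset, stratum), opening a new block when the current one is exhausted.
rand_draw <- function(st, r, subset_sig, arms, weights, stratum) {
  key <- paste(r$id, r$gen, subset_sig, stratum, sep = "|")
  b <- st$blocks[[key]]
  if (is.null(b) || b$pos > length(b$seq)) {
    mult <- if (length(st$block_multiples) > 1L) {
      st$block_multiples[sample.int(length(st$block_multiples), 1L)]
    } else st$block_multiples
    st$n_blocks <- st$n_blocks + 1L
    content <- rep(arms, times = weights * mult)
    b <- list(seq = content[sample.int(length(content))], pos = 1L,
              id = st$n_blocks)
  }
  arm <- b$seq[b$pos]
  b$pos <- b$pos + 1L
  st$blocks[[key]] <- b
  list(arm = arm, block = b$id)
}

#' Randomise one patient through all randomisations in sequence
#'
#' Processes the design's randomisations in position order. The patient's
#' stratum for each randomisation is built from the baseline factor levels
#' plus the outcome of every earlier randomisation (the assigned arm, or
#' `"not-randomised"`). Patients ineligible for, or not consenting to, a
#' randomisation receive a non-randomised record (delivered the control arm
#' where applicable); after a two-way randomisation has been discontinued,
#' patients receive a `"scheme-fixed"` record.
#'
#' @param state an `fm_randomiser`.
#' @param patient list with `id`, optional `time`, optional `factors` (named
#'   character, one per stratification factor), optional `eligible` (named
#'   list: per randomisation `TRUE` or a character vector of eligible arm
#'   ids), optional `consent` (named logical per randomisation).
#' @return data.frame of allocation records (one per randomisation).
#' @export
randomise_patient <- function(state, patient) {
  res <- engine_randomise(state, as.character(patient$id),
                          patient$time %||% NA_real_,
                          patient$factors, patient$eligible, patient$consent)
  if (!any(res$mech == "randomised")) {
    stop("patient ", patient$id, " is eligible for no randomisation")
  }
  allocation_log(state, tail = length(res$arm))
}

# Core drawing routine; returns list(arm, mech), both named by
# randomisation id, and appends to the log.
engine_randomise <- function(st, pid, time, factors, eligible, consent) {
  fac_levels <- if (length(st$factors)) {
    vapply(st$factors, function(f) as.character(factors[[f]] %||% "."),
           character(1))
  } else character(0)
  earlier <- character(0)
  out <- character(length(st$order))
  mech <- character(length(st$order))
  names(out) <- names(mech) <- st$order
  for (rid in st$order) {
    r <- st$scheme[[rid]]
    stratum <- paste(c(fac_levels, earlier), collapse = "/")
    if (stratum == "") stratum <- "."
    if (!identical(r$status, "open")) {
      rand_log(st, pid, rid, stratum, r$fixed_value, "scheme-fixed", NA_integer_, time)
      out[rid] <- r$fixed_value
      mech[rid] <- "scheme-fixed"
      earlier <- c(earlier, "not-randomised")
      next
    }
    if (!is.null(consent) && isFALSE(consent[[rid]] %||% TRUE)) {
      rand_log(st, pid, rid, stratum, r$control, "not-consented", NA_integer_, time)
      out[rid] <- r$control
      mech[rid] <- "not-consented"
      earlier <- c(earlier, "not-randomised")
      next
    }
    el <- if (is.null(eligible)) TRUE else eligible[[rid]] %||% TRUE
    if (isTRUE(el)) {
      arms <- r$arms; weights <- r$weights; subset_sig <- "*"
    } else {
      keep <- r$arms %in% el
      arms <- r$arms[keep]; weights <- r$weights[keep]
      subset_sig <- paste(sort(arms), collapse = ",")
    }
    if (length(arms) < 2L) {
      delivered <- if (r$control %in% arms) r$control
                   else if (length(arms)) arms else "none"
      rand_log(st, pid, rid, stratum, delivered, "not-eligible", NA_integer_, time)
      out[rid] <- delivered
      mech[rid] <- "not-eligible"
      earlier <- c(earlier, "not-randomised")
      next
    }
    d <- rand_draw(st, r, subset_sig, arms, weights, stratum)
    rand_log(st, pid, rid, stratum, d$arm, "randomised", d$block, time)
    out[rid] <- d$arm
    mech[rid] <- "randomised"
    earlier <- c(earlier, d$arm)
  }
  list(arm = out, mech = mech)
}

#' Adapt the randomisation engine after a design adaptation
#'
#' Mirrors the design-level adaptation in the engine state, following the
#' block/stratum rules for sequential stratified randomisation: adding an
#' intervention to, or dropping one from, a multi-way randomisation closes
#' that randomisation's open blocks and opens new blocks over the new arm
#' set (later randomisations keep their blocks; strata for a new arm appear
#' as its patients arrive); dropping the research arm of a two-way
#' randomisation discontinues it, and later randomisations use the
#' `"not-randomised"` level for subsequent patients; a new randomisation is
#' appended last in the sequence, leaving earlier state untouched.
#'
#' @param state an `fm_randomiser`.
#' @param adapt an `fm_adaptation` (already applied to the design).
#' @param deliver_control_after_stop as in [make_factorial_design()].
#' @return the state, invisibly (modified in place).
#' @export
adapt_randomiser <- function(state, adapt, deliver_control_after_stop = TRUE) {
  st <- state
  kind <- adapt$kind
  st$stage_index <- st$stage_index + 1L
  if (kind %in% c("stop_lack_of_benefit", "stop_efficacy", "drop_completed")) {
    if (adapt$target %in% names(st$scheme)) {
      rid <- adapt$target
      if (kind != "drop_completed") stop("stop_* adaptations target an intervention")
    } else {
      rid <- engine_rand_of_arm(st, adapt$target)
    }
    r <- st$scheme[[rid]]
    if (!identical(r$status, "open")) {
      stop("randomisation ", rid, " is already discontinued")
    }
    if (adapt$target == r$control) stop("cannot stop the control arm")
    if (adapt$target %in% names(st$scheme) || length(r$arms) <= 2L) {
      r$status <- "discontinued"
      r$fixed_value <- if (deliver_control_after_stop) paste0("all-", r$control) else "none"
    } else {
      keep <- r$arms != adapt$target
      r$arms <- r$arms[keep]; r$roles <- r$roles[keep]; r$weights <- r$weights[keep]
      r$gen <- r$gen + 1L  # close existing blocks; reopen over remaining arms
    }
    st$scheme[[rid]] <- r
  } else if (kind == "add_intervention") {
    rid <- adapt$target
    r <- st$scheme[[rid]]
    if (is.null(r)) stop("unknown randomisation ", rid)
    if (!identical(r$status, "open")) {
      stop("cannot add an intervention to discontinued randomisation ", rid)
    }
    r$arms <- c(r$arms, adapt$arm$id)
    r$roles <- c(r$roles, "research")
    r$weights <- c(r$weights, as.integer(round(adapt$arm$weight %||% 1)))
    r$gen <- r$gen + 1L  # Table 3: close blocks, new blocks for future patients
    st$scheme[[rid]] <- r
  } else if (kind == "add_randomisation") {
    spec <- adapt$spec
    arms <- normalise_arms(spec$arms, spec$id)
    st$scheme[[spec$id]] <- list(
      id = spec$id,
      position = max(vapply(st$scheme, `[[`, numeric(1), "position")) + 1,
      arms = arms$id, roles = arms$role,
      weights = as.integer(round(arms$weight)),
      control = arms$id[arms$role == "control"],
      fixed_value = NA_character_, gen = 1L)
    st$order <- c(st$order, spec$id)
  }
  invisible(st)
}

engine_rand_of_arm <- function(st, arm_id) {
  for (r in st$scheme) if (arm_id %in% r$arms) return(r$id)
  for (r in st$scheme) if (!is.na(r$fixed_value) && arm_id %in% r$arms) return(r$id)
  stop("no open randomisation contains arm ", arm_id)
}

#' Extract the allocation log
#'
#' @param state an `fm_randomiser`.
#' @param tail if given, return only the last `tail` records.
#' @return data.frame: `patient_id`, `time`, `stage`, `randomisation`,
#'   `stratum`, `block`, `assignment`, `mechanism`, `sequence`.
#' @export
allocation_log <- function(state, tail = NULL) {
  idx <- seq_len(state$len)
  if (!is.null(tail)) idx <- idx[idx > state$len - tail]
  data.frame(patient_id = state$L_patient_id[idx],
             time = state$L_time[idx],
             stage = state$L_stage[idx],
             randomisation = state$L_randomisation[idx],
             stratum = state$L_stratum[idx],
             block = state$L_block[idx],
             assignment = state$L_assignment[idx],
             mechanism = state$L_mechanism[idx],
             sequence = state$L_seq[idx],
             stringsAsFactors = FALSE)
}

#' Report within-stratum allocation imbalance
#'
#' Counts randomised allocations per randomisation, stratum and arm, and the
#' maximum pairwise count difference within each stratum. With permuted
#' blocks, imbalance arises only from incomplete blocks, so the difference
#' is bounded by the per-arm quota of a single open block.
#'
#' @param state an `fm_randomiser`.
#' @return list with `counts` (long data.frame: randomisation, stratum, arm,
#'   n) and `imbalance` (randomisation, stratum, max_diff).
#' @export
imbalance_report <- function(state) {
  log <- allocation_log(state)
  log <- log[log$mechanism == "randomised", , drop = FALSE]
  if (!nrow(log)) {
    return(list(counts = data.frame(), imbalance = data.frame()))
  }
  counts <- list()
  imb <- list()
  for (rid in unique(log$randomisation)) {
    sub <- log[log$randomisation == rid, , drop = FALSE]
    arms <- sort(unique(sub$assignment))
    for (strat in unique(sub$stratum)) {
      n <- vapply(arms, function(a) {
        sum(sub$assignment == a & sub$stratum == strat)
      }, numeric(1))
      counts[[length(counts) + 1]] <- data.frame(
        randomisation = rid, stratum = strat, arm = arms, n = n,
        stringsAsFactors = FALSE)
      imb[[length(imb) + 1]] <- data.frame(
        randomisation = rid, stratum = strat, max_diff = max(n) - min(n),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts)
  imb <- do.call(rbind, imb)
  rownames(counts) <- rownames(imb) <- NULL
  list(counts = counts, imbalance = imb)
}

#' @export
print.fm_randomiser <- function(x, ...) {
  cat("Stratified sequential randomiser:", length(x$order),
      "randomisation(s),", x$len, "allocation record(s),",
      x$n_blocks, "block(s) opened\n")
  invisible(x)
}
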