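# Reusable design fixtures and small data generators, built in code.

design_2x2 <- function(target = 3000, interim = 1500, ...) {
  make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research"))),
      list(id = "B", arms = list(list(id = "B0", role = "control"),
                                 list(id = "B1", role = "research")))),
    targets = target, interim_at = interim, ...)
}

# The illustrative adapted design: A2 joins randomisation A at the interim.
design_adapted <- function(target = 3000, interim = 1500) {
  apply_adaptation(design_2x2(target, interim),
                   adaptation("add_intervention", "A", interim,
                              arm = list(id = "A2")))
}

design_3way <- function(target = 300) {
  make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research"),
                                 list(id = "A2", role = "research"))),
      list(id = "B", arms = list(list(id = "B0", role = "control"),
                                 list(id = "B1", role = "research")))),
    targets = target)
}

# Balanced 2x2 factorial dataset in the analysis engine's layout, with
# outcomes from the package simulator (single stage, complete blocks).
make_2x2_dataset <- function(n, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n %% 4 == 0)
  arm_A <- sample(rep(c("A0", "A1"), n / 2))
  arm_B <- sample(rep(c("B0", "B1"), n / 2))
  d <- data.frame(id = seq_len(n), arrival = seq_len(n) / n, stage = 1L,
                  arm_A = arm_A, mech_A = "randomised",
                  arm_B = arm_B, mech_B = "randomised",
                  stringsAsFactors = FALSE)
  d$event <- simulate_binary(d[, c("arm_A", "arm_B")], model, time = 0)
  d
}

# Brute-force per-patient flow oracle: randomise synthetic patients one at a
# time (deterministic round-robin within each randomisation, which realises
# exact equal allocation), count realised contributions, advance stages at
# scheduled adaptations and completions. Independent of plan_flow.
brute_force_flow <- function(design) {
  scheme <- lapply(design$stages[[1]]$scheme, function(r) {
    list(id = r$id, arms = sort(r$arms$id),
         control = r$arms$id[r$arms$role == "control"],
         open = TRUE, next_i = 1L)
  })
  target_of <- function(cid) fmams:::comparison_target(design, cid)
  comps <- list()
  sync_comps <- function() {
    for (r in scheme) {
      for (arm in setdiff(r$arms, r$control)) {
        cid <- paste0(arm, "_vs_", r$control)
        if (is.null(comps[[cid]])) {
          comps[[cid]] <<- list(rand = r$id, research = arm,
                                control = r$control, got = 0,
                                target = target_of(cid), done = FALSE)
        }
      }
    }
  }
  sync_comps()
  pending <- design$adaptations
  stage_sizes <- integer(0)
  this_stage <- 0L
  cum <- 0L
  repeat {
    open_comps <- Filter(function(cc) {
      r <- scheme[[cc$rand]]
      !cc$done && r$open && all(c(cc$research, cc$control) %in% r$arms)
    }, comps)
    if (!length(open_comps) && !length(pending)) break
    # one patient
    cum <- cum + 1L
    this_stage <- this_stage + 1L
    for (rid in names(scheme)) {
      r <- scheme[[rid]]
      if (!r$open) next
      arm <- r$arms[r$next_i]
      scheme[[rid]]$next_i <- (r$next_i %% length(r$arms)) + 1L
      for (cid in names(comps)) {
        cc <- comps[[cid]]
        if (cc$done || cc$rand != rid) next
        if (!cc$research %in% r$arms) next  # stopped: no further accrual
        if (arm %in% c(cc$research, cc$control)) {
          comps[[cid]]$got <- cc$got + 1
        }
      }
    }
    changed <- FALSE
    # completions
    for (cid in names(comps)) {
      cc <- comps[[cid]]
      if (!cc$done && cc$got >= cc$target) {
        comps[[cid]]$done <- TRUE
        r <- scheme[[cc$rand]]
        others <- setdiff(setdiff(r$arms, r$control), cc$research)
        other_cids <- if (length(others)) paste0(others, "_vs_", r$control) else character(0)
        all_done <- all(vapply(other_cids, function(oc) comps[[oc]]$done, logical(1)))
        if (all_done) {
          scheme[[cc$rand]]$open <- FALSE
        } else {
          scheme[[cc$rand]]$arms <- setdiff(r$arms, cc$research)
          scheme[[cc$rand]]$next_i <- 1L
        }
        changed <- TRUE
      }
    }
    # scheduled adaptations
    if (length(pending)) {
      due <- vapply(pending, function(a) a$time <= cum, logical(1))
      for (ad in pending[due]) {
        if (ad$kind == "add_intervention") {
          r <- scheme[[ad$target]]
          scheme[[ad$target]]$arms <- sort(c(r$arms, ad$arm$id))
          scheme[[ad$target]]$next_i <- 1L
        } else if (ad$kind %in% c("stop_lack_of_benefit", "stop_efficacy")) {
          rid <- NULL
          for (r in scheme) if (ad$target %in% r$arms) rid <- r$id
          r <- scheme[[rid]]
          if (length(r$arms) <= 2) {
            scheme[[rid]]$open <- FALSE
          } else {
            scheme[[rid]]$arms <- setdiff(r$arms, ad$target)
            scheme[[rid]]$next_i <- 1L
          }
        } else if (ad$kind == "add_randomisation") {
          arms <- vapply(ad$spec$arms, `[[`, character(1), "id")
          roles <- vapply(ad$spec$arms, `[[`, character(1), "role")
          scheme[[ad$spec$id]] <- list(id = ad$spec$id, arms = sort(arms),
                                       control = arms[roles == "control"],
                                       open = TRUE, next_i = 1L)
        }
        sync_comps()
        changed <- TRUE
      }
      pending <- pending[!due]
    }
    if (changed) {
      stage_sizes <- c(stage_sizes, this_stage)
      this_stage <- 0L
    }
  }
  if (this_stage > 0) stage_sizes <- c(stage_sizes, this_stage)
  list(total = cum, stage_sizes = stage_sizes,
       contributions = vapply(comps, `[[`, numeric(1), "got"))
}
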