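#' Read a trial design from a configuration file
#'
#' The configuration is YAML (or JSON, which YAML parses) with keys:
#' \describe{
#'   \item{randomisations}{list of \code{{id, arms: [{id, role, weight}]}}}
#'   \item{targets}{single number, or map comparison-id -> patients}
#'   \item{stratification_factors}{map factor name -> list of levels}
#'   \item{accrual_rate}{patients per unit time}
#'   \item{eligibility_fraction}{map randomisation id -> fraction entering}
#'   \item{interim_at}{list of cumulative patient counts}
#'   \item{adaptations}{list of \code{{kind, target, time, arm, spec}}}
#'   \item{deliver_control_after_stop}{logical flag}
#' }
#' Scheduled adaptations are applied immediately, so the returned design
#' carries its full stage trajectory; their times are cumulative patients
#' randomised.
#'
#' @param path file path, or a yaml string.
#' @return An `fm_design`.
#' @export
read_design_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  design_from_config(cfg)
}

design_from_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$randomisations)) problems <- c(problems, "missing 'randomisations'")
  if (is.null(cfg$targets)) problems <- c(problems, "missing 'targets'")
  if (length(problems)) {
    stop("invalid design config: ", paste(problems, collapse = "; "))
  }
  targets <- cfg$targets
  if (is.list(targets)) targets <- unlist(targets)
  design <- make_factorial_design(
    randomisations = cfg$randomisations,
    targets = targets,
    stratification_factors = cfg$stratification_factors %||% list(),
    accrual_rate = cfg$accrual_rate %||% 100,
    eligibility_fraction = if (!is.null(cfg$eligibility_fraction))
      unlist(cfg$eligibility_fraction),
    interim_at = as.numeric(unlist(cfg$interim_at %||% numeric(0))),
    deliver_control_after_stop = cfg$deliver_control_after_stop %||% TRUE
  )
  for (ad in cfg$adaptations %||% list()) {
    design <- apply_adaptation(design, adaptation(
      kind = ad$kind, target = ad$target, time = ad$time,
      arm = ad$arm, spec = ad$spec))
  }
  design
}

#' Write a trial design back to a configuration file
#'
#' Serialises the design's initial scheme plus its scheduled adaptations so
#' that [read_design_config()] reproduces an identical stage trajectory.
#'
#' @param design an `fm_design`.
#' @param path output file; `NULL` returns the yaml string.
#' @return `path`, invisibly (or the yaml string when `path` is `NULL`).
#' @export
write_design_config <- function(design, path = NULL) {
  initial <- design$stages[[1]]$scheme
  cfg <- list(
    randomisations = lapply(unname(initial), function(r) {
      list(id = r$id, arms = lapply(seq_len(nrow(r$arms)), function(i) {
        list(id = r$arms$id[i], role = r$arms$role[i],
             weight = r$arms$weight[i])
      }))
    }),
    targets = if (is.null(names(design$targets))) as.numeric(design$targets)
              else as.list(design$targets),
    stratification_factors = design$stratification_factors,
    accrual_rate = design$accrual_rate,
    eligibility_fraction = as.list(design$eligibility_fraction),
    interim_at = as.numeric(design$interim_at),
    deliver_control_after_stop = design$deliver_control_after_stop,
    adaptations = lapply(design$adaptations, function(a) {
      out <- list(kind = a$kind, target = a$target, time = a$time)
      if (!is.null(a$arm)) out$arm <- a$arm
      if (!is.null(a$spec)) out$spec <- a$spec
      out
    })
  )
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
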