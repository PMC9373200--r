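`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named RNG substream seed
#'
#' Deterministically maps a base seed and a stream name to a 32-bit seed, so
#' that draws for arrivals, randomisation and outcomes come from separate,
#' reproducible streams and adding draws to one stream never perturbs another.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  s <- (as.numeric(seed) * 48271 + h) %% (2^31 - 1)
  as.integer(s) + 1L
}

# Swap-in/swap-out .Random.seed so independent streams can interleave.
# `streams` is an environment holding one saved seed per stream name.
new_rng_streams <- function(seed, names) {
  env <- new.env(parent = emptyenv())
  for (nm in names) {
    set.seed(derive_seed(seed, nm))
    assign(nm, get(".Random.seed", globalenv()), envir = env)
  }
  env
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Smallest positive integer m such that m * w_j / sum(w) is an integer for
# every arm weight w_j: the granularity that restores exact allocation.
allocation_granularity <- function(weights) {
  w <- as.integer(round(weights))
  if (any(abs(weights - w) > 1e-8) || any(w <= 0)) {
    stop("allocation weights must be positive integers (or scale to them)")
  }
  s <- sum(w)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  lcm2 <- function(a, b) a / gcd2(a, b) * b
  Reduce(lcm2, s / vapply(w, function(x) gcd2(s, x), numeric(1)))
}

comparison_id <- function(research, control) paste0(research, "_vs_", control)

split_comparison_id <- function(id) {
  parts <- strsplit(id, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed comparison id: ", id)
  list(research = parts[1], control = parts[2])
}
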