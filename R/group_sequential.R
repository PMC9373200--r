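# Group-sequential crossing probabilities by numerical integration.
#
# The sequence of standardised test statistics Z_1..Z_K at information
# fractions t_1 < ... < t_K is multivariate normal with cov(Z_i, Z_j) =
# sqrt(t_i / t_j).  Working on the score scale S_k = Z_k * sqrt(t_k), the
# increments S_k - S_{k-1} are independent N(drift * d_k, d_k) with
# d_k = t_k - t_{k-1}, which permits the classical recursion: propagate the
# sub-density of S_k over the continuation region on a grid, and read the
# probability mass crossing each boundary off the lost tail at each look.

#' Boundary crossing probabilities for a group-sequential test
#'
#' @param upper critical z values, one per look.
#' @param info information fractions, increasing, last equal to 1 (default
#'   equally spaced).
#' @param sided 2 for symmetric two-sided boundaries, 1 for an upper
#'   boundary only.
#' @param drift expected value of the final-look z statistic (0 under the
#'   null).
#' @param grid_points integration grid size per look.
#' @return list with `increment` (per-look crossing probability) and
#'   `total`.
#' @export
gs_crossing_prob <- function(upper, info = seq_along(upper) / length(upper),
                             sided = 2, drift = 0, grid_points = 512) {
  K <- length(upper)
  stopifnot(length(info) == K, all(diff(c(0, info)) > 0))
  d <- diff(c(0, info))
  increment <- numeric(K)
  grid <- NULL
  dens <- NULL
  for (k in seq_len(K)) {
    hi <- upper[k] * sqrt(info[k])
    lo <- if (sided == 2) -hi else min(-10, drift * info[k] - 10)
    mean_k <- drift * d[k]
    if (k == 1) {
      new_grid <- seq(lo, hi, length.out = grid_points)
      new_dens <- stats::dnorm(new_grid, mean = drift * info[1], sd = sqrt(d[1]))
    } else {
      new_grid <- seq(lo, hi, length.out = grid_points)
      h_old <- grid[2] - grid[1]
      w <- rep(h_old, length(grid)); w[c(1, length(grid))] <- h_old / 2
      # convolve the surviving density with the next increment
      new_dens <- vapply(new_grid, function(s) {
        sum(w * dens * stats::dnorm(s - grid, mean = mean_k, sd = sqrt(d[k])))
      }, numeric(1))
    }
    h <- new_grid[2] - new_grid[1]
    wts <- rep(h, grid_points); wts[c(1, grid_points)] <- h / 2
    surviving <- sum(wts * new_dens)
    prev_mass <- if (k == 1) 1 else {
      h_old <- grid[2] - grid[1]
      w <- rep(h_old, length(grid)); w[c(1, length(grid))] <- h_old / 2
      sum(w * dens)
    }
    increment[k] <- prev_mass - surviving
    grid <- new_grid
    dens <- new_dens
  }
  list(increment = increment, total = sum(increment))
}

#' O'Brien-Fleming group-sequential boundaries
#'
#' Critical values `c * sqrt(K / k)` with the constant `c` solved
#' numerically so that the cumulative boundary-crossing probability under
#' the null equals `alpha`, assuming equal information spacing.
#'
#' @param K number of looks.
#' @param alpha total significance level (two-sided when `sided = 2`).
#' @param sided 1 or 2.
#' @return numeric vector of K critical z values.
#' @export
obf_boundary <- function(K, alpha = 0.05, sided = 2) {
  stopifnot(K >= 1, alpha > 0, alpha < 0.5)
  if (K == 1) {
    return(stats::qnorm(1 - alpha / sided))
  }
  f <- function(c) {
    gs_crossing_prob(c * sqrt(K / seq_len(K)), sided = sided)$total - alpha
  }
  c_star <- stats::uniroot(f, c(0.5, 6), tol = 1e-7)$root
  c_star * sqrt(K / seq_len(K))
}

#' Alpha-spending boundaries (Lan-DeMets)
#'
#' Boundaries solved look by look so that the cumulative crossing
#' probability at look `k` equals the spent alpha `f(t_k)`.
#'
#' @param alpha total alpha to spend.
#' @param info information fractions.
#' @param spending `"obf"` (O'Brien-Fleming-like,
#'   `2 - 2 * pnorm(qnorm(1 - alpha/2) / sqrt(t))`) or `"pocock"`
#'   (`alpha * log(1 + (exp(1) - 1) * t)`), or a function of `(t, alpha)`.
#' @param sided 1 or 2.
#' @return numeric vector of critical z values, one per look.
#' @export
spending_boundary <- function(alpha = 0.05,
                              info = c(0.5, 1),
                              spending = c("obf", "pocock"),
                              sided = 2) {
  f <- if (is.function(spending)) spending else switch(
    match.arg(spending),
    obf = function(t, a) 2 - 2 * stats::pnorm(stats::qnorm(1 - a / 2) / sqrt(t)),
    pocock = function(t, a) a * log(1 + (exp(1) - 1) * t)
  )
  K <- length(info)
  spent <- pmin(f(info, alpha), alpha)
  spent[K] <- alpha
  bounds <- numeric(K)
  for (k in seq_len(K)) {
    g <- function(u) {
      gs_crossing_prob(c(bounds[seq_len(k - 1)], u), info = info[seq_len(k)],
                       sided = sided)$total - spent[k]
    }
    bounds[k] <- stats::uniroot(g, c(0.1, 9), tol = 1e-7)$root
  }
  bounds
}
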