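#' Update the threshold count
#'
#' The threshold count records how many hours a cell's intracellular
#' concentration has been above the differentiation threshold: it is
#' incremented when `conc > c_th` (strict) and decremented otherwise, with a
#' floor at zero (a negative count of supra-threshold hours is meaningless
#' and would make the even-exponent Hill probability non-monotone).
#'
#' @param tc current threshold count (>= 0).
#' @param conc intracellular concentration at the end of the hour.
#' @param c_th threshold concentration (default 0.74).
#' @return updated count; vectorized.
#' @examples
#' update_threshold_count(0, 0.8)   # 1
#' update_threshold_count(5, 0.74)  # 4 (strict inequality)
#' @export
update_threshold_count <- function(tc, conc, c_th = 0.74) {
  stopifnot(all(tc >= 0))
  ifelse(conc > c_th, tc + 1, pmax(tc - 1, 0))
}

#' Threshold-driven differentiation probability
#'
#' Hill function of the threshold count: `tc^n / (tc^n + K_th^n)` with
#' `K_th = 2` and `n = 4` at defaults. Zero at `tc = 0`, one half at
#' `tc = K_th`, saturating towards 1.
#'
#' @param tc threshold count (>= 0).
#' @param params a [gj_params()] object (fields `k_th`, `hill_n`).
#' @return probability in \[0, 1\]; vectorized.
#' @examples
#' p_diff(2)  # 0.5
#' @export
p_diff <- function(tc, params = gj_params()) {
  stopifnot(all(tc >= 0))
  tc^params$hill_n / (tc^params$hill_n + params$k_th^params$hill_n)
}

#' Oscillatory stochastic differentiation probability
#'
#' Baseline stochastic differentiation rate with an oscillation tied to the
#' retinoic-acid feeding cycle: `p0 + |amp * sin(t_sim / period_scale)|`,
#' i.e. `0.002 + |0.001 sin(t/8)|` at defaults, bounded in \[0.002, 0.003\].
#' (As printed, the |sin(t/8)| term has period 8 * pi ~ 25.1 h rather than
#' exactly 24 h; the function is implemented as defined.)
#'
#' @param t_sim simulation time in hours (>= 0).
#' @param params a [gj_params()] object.
#' @return probability per hour; vectorized.
#' @examples
#' p_stochastic(0)  # 0.002
#' @export
p_stochastic <- function(t_sim, params = gj_params()) {
  if (any(t_sim < 0)) stop("t_sim must be non-negative", call. = FALSE)
  params$p0 + abs(params$amp * sin(t_sim / params$period_scale))
}

#' Hourly cell-fate step
#'
#' Applied once per 1-h differentiation step, after the transport substeps.
#' Every cell's threshold count is updated from its end-of-hour
#' concentration; every pluripotent cell then draws two independent
#' Bernoulli trials, one at the threshold-count Hill probability and one at
#' the oscillatory stochastic probability evaluated at the colony's current
#' time. If either succeeds the cell differentiates irreversibly, adopting
#' the differentiated cell-cycle length, nascent permeability and
#' production constants immediately; its division clock is carried over
#' unchanged. Random draws are consumed in ascending cell-id order.
#'
#' @param colony a `gj_colony`.
#' @param params a [gj_params()] object.
#' @return the colony with updated threshold counts and phenotypes.
#' @export
fate_step <- function(colony, params = gj_params()) {
  stopifnot(inherits(colony, "gj_colony"))
  cells <- colony$cells  # already in ascending id order
  cells$tc <- update_threshold_count(cells$tc, cells$conc, params$c_th)
  plur <- which(cells$phenotype == "P")
  if (length(plur)) {
    p_thr <- p_diff(cells$tc[plur], params)
    p_sto <- p_stochastic(colony$time, params)
    u <- matrix(runif(2 * length(plur)), ncol = 2, byrow = TRUE)
    hit <- u[, 1] < p_thr | u[, 2] < p_sto
    cells$phenotype[plur[hit]] <- "D"
  }
  colony$cells <- cells
  colony
}
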