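#' Cell-cycle transform of the division clock
#'
#' Shifts the minimum of the cell-cycle modulation forward by a quarter of
#' the cell-cycle length: `DT_norm = |t_div - CCL/4|`, so that the
#' permeability maximum falls in early G1 rather than at the division event
#' itself.
#'
#' @param t_div hours since last division (0 <= t_div <= CCL).
#' @param ccl cell-cycle length in hours.
#' @return transformed division time (h); vectorized.
#' @examples
#' dt_norm(0, 18)    # 4.5
#' dt_norm(4.5, 18)  # 0
#' @export
dt_norm <- function(t_div, ccl) {
  if (any(t_div < 0)) stop("t_div must be non-negative", call. = FALSE)
  if (any(ccl <= 0)) stop("ccl must be positive", call. = FALSE)
  abs(t_div - ccl / 4)
}

#' Cell-cycle effect on gap-junction permeability
#'
#' Dimensionless modulation of a cell's nascent permeability across its
#' division cycle:
#' \deqn{CCE = \frac{1}{1 + (DT_{norm}/CCL)^2} -
#'       \frac{0.69\, t_{div}^6}{t_{div}^6 + CCL^6}}
#' The function peaks at ~1 (100% of nascent permeability) at
#' `t_div = CCL/4` (G1 phase) and falls to ~0.295 (~30%) at `t_div = CCL`
#' (mitosis). Under `sign = "printed"` the second term is added instead of
#' subtracted, which loses the mitotic minimum; the subtracted form is the
#' default (see the methods vignette).
#'
#' @inheritParams dt_norm
#' @param sign `"corrected"` (subtract the sixth-order term, default) or
#'   `"printed"` (add it).
#' @return modulation factor in (0, 1]; vectorized.
#' @examples
#' cycle_effect(4.5, 18)  # ~1.00
#' cycle_effect(18, 18)   # ~0.295
#' @export
cycle_effect <- function(t_div, ccl, sign = c("corrected", "printed")) {
  sign <- match.arg(sign)
  if (any(ccl <= 0)) stop("ccl must be positive", call. = FALSE)
  if (any(t_div < 0) || any(t_div > ccl)) {
    stop("t_div must lie in [0, ccl]", call. = FALSE)
  }
  base <- 1 / (1 + (dt_norm(t_div, ccl) / ccl)^2)
  osc <- 0.69 * t_div^6 / (t_div^6 + ccl^6)
  if (sign == "corrected") base - osc else base + osc
}

#' Effective permeability between two contacting cells
#'
#' The per-substep effective permeability of a cell pair is the maximum
#' permeability scaled by the product of the two cells' cycle-modulated
#' nascent permeabilities:
#' `PM_eff = PM_max * (CCE_1 * PM_n1) * (CCE_2 * PM_n2)`. Symmetric in the
#' two cells.
#'
#' @param cell1,cell2 one-row cell data frames (fields `phenotype`, `t_div`).
#' @param params a [gj_params()] object.
#' @return effective permeability (fraction of the concentration gradient
#'   transported per 3-s substep).
#' @export
pair_permeability <- function(cell1, cell2, params = gj_params()) {
  check_phenotype(c(cell1$phenotype, cell2$phenotype))
  side <- function(cell) {
    ccl <- ptype_param(params, "ccl", cell$phenotype)
    cce <- cycle_effect(cell$t_div, ccl, params$eq2_sign)
    cce * ptype_param(params, "pm_n", cell$phenotype)
  }
  params$pm_max * side(cell1) * side(cell2)
}

# per-cell modulated nascent permeability (CCE * PM_n) for a cell table
modulated_pmn <- function(cells, params) {
  ccl <- ptype_param(params, "ccl", cells$phenotype)
  # clamp the clock into the current cycle: between the hourly clock
  # increment and the division check, t_div may exceed CCL transiently
  td <- pmin(cells$t_div, ccl)
  cycle_effect(td, ccl, params$eq2_sign) *
    ptype_param(params, "pm_n", cells$phenotype)
}

# effective permeability for every edge of a colony, in edge order
edge_permeability <- function(colony, params) {
  if (!nrow(colony$edges)) return(numeric(0))
  side <- modulated_pmn(colony$cells, params)
  ia <- match(colony$edges[, 1], colony$cells$id)
  ib <- match(colony$edges[, 2], colony$cells$id)
  params$pm_max * side[ia] * side[ib]
}

#' Production of the diffusible molecule
#'
#' Inhibitory Hill function with exponent 1: `vp / (1 + conc / K50)`, using
#' the phenotype-specific production constant `vp` and half-inhibition
#' constant `K50`. Returns the concentration increment per 3-s substep.
#'
#' @param conc intracellular concentration (arbitrary units, >= 0).
#' @param phenotype `"P"` or `"D"` (vectorized with `conc`).
#' @param params a [gj_params()] object.
#' @return production per substep; vectorized.
#' @examples
#' production(0, "P")  # the pluripotent vp, 4.89e-6
#' @export
production <- function(conc, phenotype, params = gj_params()) {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  check_phenotype(phenotype)
  vp <- ptype_param(params, "vp", phenotype)
  k50 <- ptype_param(params, "k50", phenotype)
  vp / (1 + conc / k50)
}

#' Degradation of the diffusible molecule
#'
#' First-order decay `-kd * conc`, with the degradation constant shared by
#' both phenotypes. Returns the (negative) concentration increment per 3-s
#' substep.
#'
#' @inheritParams production
#' @return degradation per substep (<= 0); vectorized.
#' @export
degradation <- function(conc, params = gj_params()) {
  -params$kd * conc
}

# guard for the explicit scheme: the summed effective permeability over any
# cell's neighbors must stay below 1, otherwise the 3-s update can diverge
check_stability <- function(colony, pm, params) {
  if (!length(pm)) return(invisible(TRUE))
  idx <- match(as.vector(colony$edges), colony$cells$id)
  load <- tabulate(idx, nbins = nrow(colony$cells))
  tot <- numeric(nrow(colony$cells))
  ia <- match(colony$edges[, 1], colony$cells$id)
  ib <- match(colony$edges[, 2], colony$cells$id)
  for (k in seq_along(pm)) {
    tot[ia[k]] <- tot[ia[k]] + pm[k]
    tot[ib[k]] <- tot[ib[k]] + pm[k]
  }
  if (max(tot) >= 1) {
    stop(sprintf(
      "explicit transport update unstable: summed permeability over a cell's neighbors is %.3f >= 1; reduce pm_max",
      max(tot)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Advance intracellular concentrations by transport substeps
#'
#' Runs `n` synchronous explicit 3-s substeps of the intercellular
#' reaction-diffusion update on the colony's current contact network. For
#' every cell the concentration change per substep is the sum of the
#' gap-junction fluxes `pm_eff * (conc_j - conc_i)` over its neighbors,
#' phenotype-specific production and first-order degradation, all evaluated
#' from the pre-substep state. Effective permeabilities are computed once
#' from the current division clocks (they change only on the 1-h
#' differentiation step cadence). Concentrations that are driven negative
#' numerically are clipped at zero with a warning.
#'
#' @param colony a `gj_colony` with a current network.
#' @param params a [gj_params()] object.
#' @param n number of substeps (default 1).
#' @return the colony with updated concentrations.
#' @export
substep_update <- function(colony, params = gj_params(), n = 1L) {
  stopifnot(inherits(colony, "gj_colony"))
  pm <- edge_permeability(colony, params)
  check_stability(colony, pm, params)
  ia <- match(colony$edges[, 1], colony$cells$id) - 1L
  ib <- match(colony$edges[, 2], colony$cells$id) - 1L
  res <- diffuse_cpp(colony$cells$conc, as.integer(ia), as.integer(ib), pm,
                     ptype_param(params, "vp", colony$cells$phenotype),
                     ptype_param(params, "k50", colony$cells$phenotype),
                     params$kd, as.integer(n), params$clip_negative)
  if (res$n_clipped > 0) {
    warning(sprintf("%d negative concentration(s) clipped at 0", res$n_clipped),
            call. = FALSE)
  }
  colony$cells$conc <- res$conc
  colony
}

#' Analytic single-cell steady state
#'
#' Concentration at which production balances degradation for an isolated
#' cell, i.e. the positive root of `vp / (1 + C/K50) = kd * C` (a quadratic
#' in `C`).
#'
#' @param phenotype `"P"` or `"D"`.
#' @param params a [gj_params()] object.
#' @return steady-state concentration.
#' @export
steady_state_conc <- function(phenotype = "P", params = gj_params()) {
  check_phenotype(phenotype)
  vp <- ptype_param(params, "vp", phenotype)
  k50 <- ptype_param(params, "k50", phenotype)
  kd <- params$kd
  if (kd == 0) return(Inf)
  # kd/k50 C^2 + kd C - vp = 0
  a <- kd / k50; b <- kd; cc <- -vp
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}
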