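#' Model parameters for the colony simulation
#'
#' Builds the full parameter set of the agent-based model: per-phenotype
#' constants (cell-cycle length, nascent gap-junction permeability,
#' production constant and half-inhibition constant of the diffusible
#' molecule), shared constants (degradation rate, differentiation threshold
#' and Hill constants, stochastic-term constants), geometry (cell radius and
#' contact gap) and numerical settings (substep count, overlap tolerance).
#'
#' Concentrations are in arbitrary units; `vp` and `kd` are per-3-s-substep
#' increments; times are in hours. Phenotype vectors are named
#' `c(pluripotent = , differentiated = )`.
#'
#' Two printed-versus-working constant choices are exposed:
#'
#' * `eq2_sign`: the oscillatory term of the cell-cycle effect is
#'   subtracted under `"corrected"` (the default), which reproduces the
#'   intended 100% permeability maximum in G1 and ~30% minimum at mitosis;
#'   `"printed"` adds it.
#' * `table_constants`: under `"corrected"` (the default) the production
#'   half-inhibition constants are `K50 = 3.0 / 4.0`, which places the
#'   half-inhibition point above the operating concentration range and gives
#'   the ~24-h threshold-crossing dynamics of the model; `"printed"` uses
#'   `0.03 / 0.04`, under which net production is ~25-fold slower and the
#'   concentration threshold is not reached within a 72-h simulation. See the
#'   methods vignette for the full rationale.
#'
#' @param pm_max maximum permeability: per-substep transported fraction of
#'   the concentration gradient if all gap junctions of a pair were open.
#'   The default 0.1 keeps the explicit 3-s update stable (per-cell summed
#'   permeability < 1) even for the densest attainable disk packing with
#'   both neighbors differentiated at peak cell-cycle effect.
#' @param eq2_sign sign convention of the cell-cycle-effect oscillatory term.
#' @param table_constants scale convention for the production
#'   half-inhibition constants (see Details).
#' @param ccl,pm_n,vp,k50 per-phenotype constants; `k50 = NULL` selects the
#'   value implied by `table_constants`.
#' @param kd degradation constant (shared by both phenotypes).
#' @param c_th,k_th,hill_n threshold concentration, Hill constant and Hill
#'   exponent of the threshold-count differentiation probability.
#' @param p0,amp,period_scale constants of the oscillatory stochastic
#'   differentiation probability `p0 + |amp * sin(t/period_scale)|`.
#' @param radius cell radius (µm); cells are rigid disks of constant size.
#' @param contact_gap membrane gap (µm) below which two cells are connected;
#'   the center-distance threshold is `2 * radius + contact_gap`.
#' @param conc_init,tdiv_init uniform initialisation ranges for intracellular
#'   concentration and division clock (h).
#' @param substeps_per_hour number of 3-s transport substeps per 1-h
#'   differentiation step.
#' @param overlap_tol maximum tolerated pairwise overlap (µm) after
#'   mechanical relaxation.
#' @param max_relax_iter iteration budget of the overlap-relaxation solver.
#' @param sq_vp_scale,bga_pm_scale default scale factors of the SQ
#'   (adenylyl-cyclase inhibition: reduced production in differentiated
#'   cells) and beta-GA (gap-junction inhibition: globally reduced
#'   permeability) in-silico perturbations.
#' @param clip_negative clip numerically negative concentrations at zero
#'   (with a warning) instead of propagating them.
#'
#' @return an object of class `gj_params` (a named list).
#' @examples
#' p <- gj_params()
#' p$ccl
#' @export
gj_params <- function(pm_max = 0.1,
                      eq2_sign = c("corrected", "printed"),
                      table_constants = c("corrected", "printed"),
                      ccl = c(pluripotent = 18, differentiated = 51),
                      pm_n = c(pluripotent = 0.45, differentiated = 0.85),
                      vp = c(pluripotent = 4.89e-6, differentiated = 6.0e-6),
                      k50 = NULL,
                      kd = 1.3e-7,
                      c_th = 0.74,
                      k_th = 2,
                      hill_n = 4,
                      p0 = 0.002,
                      amp = 0.001,
                      period_scale = 8,
                      radius = 6.5,
                      contact_gap = 2,
                      conc_init = c(0.6, 0.65),
                      tdiv_init = c(0, 18),
                      substeps_per_hour = 1200,
                      overlap_tol = 0.05,
                      max_relax_iter = 500,
                      sq_vp_scale = 0.5,
                      bga_pm_scale = 0.5,
                      clip_negative = TRUE) {
  eq2_sign <- match.arg(eq2_sign)
  table_constants <- match.arg(table_constants)
  if (is.null(k50)) {
    k50 <- if (table_constants == "corrected") {
      c(pluripotent = 3.0, differentiated = 4.0)
    } else {
      c(pluripotent = 0.03, differentiated = 0.04)
    }
  }
  ptypes <- c("pluripotent", "differentiated")
  as_ptype <- function(x, what) {
    if (length(x) == 1L) x <- c(pluripotent = unname(x), differentiated = unname(x))
    if (is.null(names(x)) && length(x) == 2L) names(x) <- ptypes
    if (!all(ptypes %in% names(x))) {
      stop(sprintf("'%s' must be named for both phenotypes", what), call. = FALSE)
    }
    x[ptypes]
  }
  ccl <- as_ptype(ccl, "ccl"); pm_n <- as_ptype(pm_n, "pm_n")
  vp <- as_ptype(vp, "vp"); k50 <- as_ptype(k50, "k50")

  stopifnot(
    pm_max >= 0, all(ccl > 0), all(pm_n >= 0), all(vp >= 0), all(k50 > 0),
    kd >= 0, c_th > 0, k_th > 0, hill_n > 0, p0 >= 0, amp >= 0,
    period_scale > 0, radius > 0, contact_gap >= 0,
    length(conc_init) == 2L, conc_init[1] <= conc_init[2],
    length(tdiv_init) == 2L, tdiv_init[1] <= tdiv_init[2],
    substeps_per_hour >= 1, overlap_tol > 0, max_relax_iter >= 1
  )
  if (ccl["differentiated"] < ccl["pluripotent"]) {
    stop("differentiated cell-cycle length must be >= pluripotent", call. = FALSE)
  }

  structure(list(
    pm_max = pm_max, eq2_sign = eq2_sign, table_constants = table_constants,
    ccl = ccl, pm_n = pm_n, vp = vp, k50 = k50, kd = kd,
    c_th = c_th, k_th = k_th, hill_n = hill_n,
    p0 = p0, amp = amp, period_scale = period_scale,
    radius = radius, contact_gap = contact_gap,
    conc_init = conc_init, tdiv_init = tdiv_init,
    substeps_per_hour = as.integer(substeps_per_hour),
    overlap_tol = overlap_tol, max_relax_iter = as.integer(max_relax_iter),
    sq_vp_scale = sq_vp_scale, bga_pm_scale = bga_pm_scale,
    clip_negative = isTRUE(clip_negative)
  ), class = "gj_params")
}

#' @export
print.gj_params <- function(x, ...) {
  cat("<gj_params>\n")
  cat(sprintf("  pm_max: %g  (eq2 sign: %s, table constants: %s)\n",
              x$pm_max, x$eq2_sign, x$table_constants))
  cat(sprintf("  CCL: P %g h / D %g h   PM_n: %g / %g\n",
              x$ccl[1], x$ccl[2], x$pm_n[1], x$pm_n[2]))
  cat(sprintf("  vp: %g / %g   K50: %g / %g   kd: %g (per 3-s substep)\n",
              x$vp[1], x$vp[2], x$k50[1], x$k50[2], x$kd))
  cat(sprintf("  fate: C_th %g, K_th %g, n %g; stochastic %g + |%g sin(t/%g)|\n",
              x$c_th, x$k_th, x$hill_n, x$p0, x$amp, x$period_scale))
  invisible(x)
}

# phenotype codes used in cell tables; pluripotent = "P", differentiated = "D"
.ptype_long <- c(P = "pluripotent", D = "differentiated")

# look up a per-phenotype parameter for a vector of "P"/"D" codes
ptype_param <- function(params, field, phenotype) {
  unname(params[[field]][.ptype_long[phenotype]])
}

check_phenotype <- function(phenotype) {
  if (!all(phenotype %in% names(.ptype_long))) {
    stop("phenotype must be 'P' (pluripotent) or 'D' (differentiated)",
         call. = FALSE)
  }
  invisible(phenotype)
}

#' In-silico intercellular perturbations
#'
#' Returns a modified parameter set implementing one of the two perturbation
#' modes studied with the model: `"SQ"` (adenylyl-cyclase inhibition,
#' emulated by scaling down the production constant of differentiated cells)
#' or `"BGA"` (gap-junction inhibition by beta-glycyrrhetinic acid, emulated
#' by scaling down the maximum permeability globally). `"control"` returns
#' the parameters unchanged.
#'
#' @param params a [gj_params()] object.
#' @param mode one of `"control"`, `"SQ"`, `"BGA"`.
#' @param scale scale factor in (0, 1]; defaults to `params$sq_vp_scale` or
#'   `params$bga_pm_scale` depending on the mode.
#' @return a `gj_params` object.
#' @examples
#' p <- perturb_params(gj_params(), "SQ", scale = 0.5)
#' p$vp
#' @export
perturb_params <- function(params, mode = c("control", "SQ", "BGA"),
                           scale = NULL) {
  stopifnot(inherits(params, "gj_params"))
  mode <- match.arg(mode)
  if (mode == "control") return(params)
  if (is.null(scale)) {
    scale <- if (mode == "SQ") params$sq_vp_scale else params$bga_pm_scale
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale < 0) {
    stop("'scale' must be a single non-negative number", call. = FALSE)
  }
  if (mode == "SQ") {
    params$vp["differentiated"] <- params$vp["differentiated"] * scale
  } else {
    params$pm_max <- params$pm_max * scale
  }
  params
}
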