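test_that("dt_norm shifts the clock by a quarter cycle", {
  expect_equal(dt_norm(4.5, 18), 0)
  expect_equal(dt_norm(0, 18), 4.5)
  expect_equal(dt_norm(18, 18), 13.5)
  expect_equal(dt_norm(12.75, 51), 0)
  expect_error(dt_norm(-1, 18), "non-negative")
  expect_error(dt_norm(1, 0), "positive")
})

test_that("cycle_effect reproduces the characteristic endpoints", {
  # peak ~1 at t_div = CCL/4 (G1)
  expect_equal(cycle_effect(4.5, 18), 1 / (1 + (0 / 18)^2) - 0.69 * 4.5^6 / (4.5^6 + 18^6))
  expect_gt(cycle_effect(4.5, 18), 0.995)
  expect_lte(cycle_effect(4.5, 18), 1)
  # mitotic minimum ~0.295 (~30% of nascent permeability) at t_div = CCL
  expect_equal(cycle_effect(18, 18), 1 / (1 + (13.5 / 18)^2) - 0.69 / 2)
  expect_equal(cycle_effect(18, 18), 0.295, tolerance = 5e-3)
  # fresh daughter: 1/(1+0.0625) = 16/17
  expect_equal(cycle_effect(0, 18), 16 / 17)
  # same shape for the differentiated cycle length
  expect_equal(cycle_effect(51, 51), cycle_effect(18, 18))
})

test_that("cycle_effect under the printed sign loses the mitotic minimum", {
  printed <- cycle_effect(18, 18, sign = "printed")
  expect_equal(printed, 1 / (1 + 0.75^2) + 0.345)
  expect_gt(printed, cycle_effect(4.5, 18, sign = "printed") - 0.05)
})

test_that("cycle_effect stays within (0, 1] over the whole cycle", {
  for (ccl in c(18, 51)) {
    td <- seq(0, ccl, length.out = 500)
    v <- cycle_effect(td, ccl)
    expect_true(all(v > 0 & v <= 1))
    expect_equal(max(v), 1, tolerance = 5e-3)
    expect_equal(min(v), 0.295, tolerance = 5e-3)
  }
})

test_that("cycle_effect validates its domain", {
  expect_error(cycle_effect(-0.1, 18), "t_div")
  expect_error(cycle_effect(19, 18), "t_div")
  expect_error(cycle_effect(1, -5), "positive")
})

test_that("pair_permeability multiplies the two modulated nascent permeabilities", {
  params <- gj_params(pm_max = 1)
  # both cells at their permeability peak: CCE ~ 1
  p <- make_cells(0, 0, phenotype = "P", t_div = 4.5)
  d <- make_cells(13, 0, phenotype = "D", t_div = 12.75)
  cce_p <- cycle_effect(4.5, 18)
  cce_d <- cycle_effect(12.75, 51)
  expect_equal(pair_permeability(p, p, params), (cce_p * 0.45)^2)
  expect_equal(pair_permeability(d, d, params), (cce_d * 0.85)^2)
  expect_equal(pair_permeability(p, d, params),
               (cce_p * 0.45) * (cce_d * 0.85))
  # symmetric in the two cells
  expect_equal(pair_permeability(p, d, params), pair_permeability(d, p, params))
  # scales linearly with pm_max
  expect_equal(pair_permeability(p, d, gj_params(pm_max = 0.1)),
               0.1 * pair_permeability(p, d, params))
})

test_that("production is the inhibitory Hill function with the published constants", {
  params <- gj_params()
  expect_equal(production(0, "P", params), 4.89e-6)
  expect_equal(production(0, "D", params), 6.0e-6)
  # half-maximal at conc = K50
  k50p <- params$k50[["pluripotent"]]
  expect_equal(production(k50p, "P", params), 4.89e-6 / 2)
  # monotone decreasing in conc
  cs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(production(cs, rep("P", length(cs)), params)) < 0))
  expect_error(production(-1, "P", params), "non-negative")
})

test_that("the printed constant table is selectable", {
  printed <- gj_params(table_constants = "printed")
  expect_equal(printed$k50[["pluripotent"]], 0.03)
  expect_equal(printed$k50[["differentiated"]], 0.04)
  expect_equal(production(0.03, "P", printed), 4.89e-6 / 2)
})

test_that("degradation is first-order decay", {
  params <- gj_params()
  expect_equal(degradation(0, params), 0)
  expect_equal(degradation(1, params), -1.3e-7)
  expect_equal(degradation(c(2, 4), params), 2 * degradation(c(1, 2), params))
})

test_that("an isolated cell with no reactions is unchanged", {
  params <- gj_params(vp = c(0, 0), kd = 0)
  col <- new_colony(make_cells(0, 0, conc = 0.62), params = params)
  out <- substep_update(col, params, n = 1000)
  expect_equal(out$cells$conc, 0.62)
})

test_that("transport without reactions conserves total concentration", {
  params <- gj_params(vp = c(0, 0), kd = 0)
  set.seed(8)
  for (rep in 1:5) {
    st <- hex_structure(sample(5:25, 1))
    cells <- make_cells(st$x, st$y, conc = runif(nrow(st), 0, 1),
                        t_div = runif(nrow(st), 0, 18))
    col <- new_colony(cells, params = params)
    out <- substep_update(col, params, n = 200)
    expect_equal(sum(out$cells$conc), sum(cells$conc), tolerance = 1e-9)
  }
})

test_that("pairwise fluxes are antisymmetric: a two-cell exchange is zero-sum", {
  params <- gj_params(vp = c(0, 0), kd = 0)
  cells <- make_cells(c(0, 13), c(0, 0), conc = c(1, 0), t_div = c(3, 9))
  col <- new_colony(cells, params = params)
  out <- substep_update(col, params, n = 1)
  gain <- out$cells$conc[2] - 0
  loss <- 1 - out$cells$conc[1]
  expect_equal(gain, loss, tolerance = 1e-12)
  expect_gt(gain, 0)
})

test_that("two coupled cells equilibrate monotonically to the mean", {
  params <- gj_params(vp = c(0, 0), kd = 0)
  col <- new_colony(make_cells(c(0, 13), c(0, 0), conc = c(1, 0)),
                    params = params)
  gaps <- numeric(25)
  for (k in 1:25) {
    col <- substep_update(col, params, n = 20)
    gaps[k] <- abs(diff(col$cells$conc))
  }
  expect_true(all(diff(gaps) < 0))                # strictly shrinking gap
  expect_equal(col$cells$conc, c(0.5, 0.5), tolerance = 1e-3)
})

test_that("substep_update matches an independent plain-R explicit-Euler oracle", {
  set.seed(21)
  params <- gj_params()
  st <- hex_structure(9)
  cells <- make_cells(st$x, st$y,
                      phenotype = sample(c("P", "D"), 9, replace = TRUE),
                      conc = runif(9, 0, 2), t_div = runif(9, 0, 18))
  col <- new_colony(cells, params = params)
  pm <- gjcolony:::edge_permeability(col, params)
  ia <- match(col$edges[, 1], col$cells$id)
  ib <- match(col$edges[, 2], col$cells$id)
  ref <- oracle_substep(col$cells$conc, cbind(ia, ib), pm,
                        vp_vec = ifelse(col$cells$phenotype == "P", 4.89e-6, 6e-6),
                        k50_vec = ifelse(col$cells$phenotype == "P", 3, 4),
                        kd = 1.3e-7, nsub = 25)
  out <- substep_update(col, params, n = 25)
  expect_equal(out$cells$conc, ref, tolerance = 1e-12)
})

test_that("the stability guard rejects permeability loads of 1 or more", {
  params <- gj_params(pm_max = 4)   # hex center with 6 neighbors overloads
  col <- new_colony(make_cells(hex_structure(7)$x, hex_structure(7)$y,
                               t_div = 4.5), params = params)
  expect_error(substep_update(col, params), "reduce pm_max")
})

test_that("an isolated cell converges to the analytic steady state", {
  params <- gj_params()
  ss <- steady_state_conc("P", params)
  # closed form satisfies the balance equation
  expect_equal(production(ss, "P", params), params$kd * ss, tolerance = 1e-12)
  expect_equal(steady_state_conc("P", gj_params(kd = 0)), Inf)
})
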