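# The FBA primal, its explicit dual, strong duality, and shadow-price
# validity ranges.

test_that("the one-metabolite toy solves to the hand-derived optimum", {
  fx <- make_fixture("figure1")
  sol <- solve_fba(fx$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(10, 10))
  expect_equal(unname(sol$shadow_prices), -1)
  expect_equal(sol$dual_objective, 10)
})

test_that("decreasing b (extra outflow) raises Z, so the shadow price is negative", {
  fx <- make_fixture("figure1")
  m <- fx$model
  m$b[1] <- -1
  expect_equal(solve_fba(m)$objective_value, 11)
  m$b[1] <- 2
  expect_equal(solve_fba(m)$objective_value, 8)
  expect_lt(solve_fba(fx$model)$shadow_prices[["M[c]"]], 0)
})

test_that("degenerate inputs are reported, never silently mangled", {
  fx <- make_fixture("figure1")
  bad <- fx$model
  bad$reactions$lower_bound[1] <- 20          # lb > ub
  expect_error(validate_model(bad), "lower_bound > upper_bound")
  zo <- fx$model
  zo$objective[] <- 0
  s <- solve_fba(zo)                          # all-zero objective: Z = 0
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 0)
  expect_true(max(abs(as.matrix(zo$S) %*% s$fluxes - zo$b)) < 1e-8)
  unb <- model_from_reactions(list(
    list(id = "R_in", stoich = c(M = 1), lb = 0, ub = Inf),
    list(id = "R_out", stoich = c(M = -1), lb = 0, ub = Inf)),
    objective = c(R_out = 1))
  expect_equal(solve_fba(unb)$status, "unbounded")
})

test_that("the simplex reproduces an independently solved reference LP", {
  # frozen reference: solved with an independent HiGHS implementation
  A <- matrix(c(1.76, 1.47, -0.58, 1.88, 1.9, -0.94, -0.92, -1.9, -0.12,
                -0.83, -1.87, -1.18, 1.16, -0.98, -1.72), 3, 5)
  obj <- c(2.84, -0.51, 0.97, 0.13, 1.25)
  rhs <- c(0.27, -0.28, 0.42)
  lb <- c(-2.66, 0, 0, 0, -1.51)
  ub <- c(2.51, 3.46, 9.69, 3.32, 9.99)
  sol <- simplex_lp(obj, A, rhs, lb, ub)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$z, 8.04321515509061, tolerance = 1e-9)
  expect_equal(sol$y, c(1.4505135325, -1.2684408917, 0.879710369),
               tolerance = 1e-8)
})

test_that("the explicit dual has m + n_ub + n_lb variables and matches the primal", {
  fx <- make_fixture("figure1")
  dual <- build_dual(fx$model)
  expect_equal(length(dual$objective), 1 + 2 + 2)
  ds <- solve_dual(dual)
  expect_equal(ds$status, "optimal")
  expect_equal(ds$dual_objective, 10)
  expect_equal(unname(ds$lambda), -1)
})

test_that("strong duality and complementary slackness hold on random networks", {
  for (seed in 1:25) {
    sb <- solved_branched(seed)
    sol <- sb$sol
    expect_equal(sol$status, "optimal", info = paste("seed", seed))
    expect_equal(sol$objective_value, sb$fx$truth$Z, tolerance = 1e-8,
                 info = paste("seed", seed))
    dual <- solve_dual(build_dual(sb$fx$model))
    gap <- abs(sol$objective_value - dual$dual_objective)
    expect_lt(gap, 1e-6 * max(1, abs(sol$objective_value)))
    # complementary slackness of the bound multipliers
    v <- sol$fluxes
    lbv <- sb$fx$model$reactions$lower_bound
    ubv <- sb$fx$model$reactions$upper_bound
    expect_lt(max(abs(sol$reduced_costs_lower * (v - lbv))), 1e-6)
    expect_lt(max(abs(sol$reduced_costs_upper * (ubv - v))), 1e-6)
  }
})

test_that("Z responds linearly with slope lambda inside the validity range", {
  for (seed in c(2, 7, 13)) {
    sb <- solved_branched(seed)
    model <- sb$fx$model; sol <- sb$sol
    spt <- shadow_price_table(model, sol)
    for (i in seq_len(nrow(spt))) {
      lo <- spt$range_low[i]; hi <- spt$range_high[i]
      for (f in c(-0.9, -0.4, 0.15, 0.5, 0.85)) {
        t <- if (f < 0) -f * lo else f * hi
        if (!is.finite(t) || abs(t) < 1e-12) next
        m2 <- model
        m2$b[i] <- t
        z <- solve_fba(m2)$objective_value
        expect_equal(z, sol$objective_value + spt$lambda[i] * t,
                     tolerance = 1e-6,
                     info = sprintf("seed %d met %d t %.3g", seed, i, t))
      }
    }
  }
})

test_that("shadow-price ranges match the hand analysis and the eps rule", {
  fx <- make_fixture("figure1")
  spt <- shadow_price_table(fx$model)
  expect_equal(spt$lambda, -1)
  expect_equal(spt$range_low, -990)
  expect_equal(spt$range_high, 10)
  expect_true(spt$valid)
  # a range narrower than eps_range is flagged invalid
  wide <- shadow_price_table(fx$model, eps_range = 999)
  expect_true(wide$valid)
  narrow <- shadow_price_table(fx$model, eps_range = 1001)
  expect_false(narrow$valid)
  expect_error(shadow_price_table(fx$model,
                                  solution = structure(list(status = "infeasible"),
                                                       class = "fba_solution")),
               "optimal")
})

test_that("metabolites with slack on both sides carry zero shadow price", {
  # a downstream bottleneck leaves the upstream metabolite non-binding
  m <- model_from_reactions(list(
    list(id = "EX_in", stoich = c(A = 1), lb = 0, ub = 10),
    list(id = "conv", stoich = c(A = -1, B = 1), lb = 0, ub = 3),
    list(id = "EX_out", stoich = c(B = -1), lb = 0, ub = 50)),
    objective = c(EX_out = 1))
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 3)
  expect_equal(unname(sol$shadow_prices["A"]), 0)
  expect_equal(unname(sol$shadow_prices["B"]), -1)
})
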