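# Expression integration: thresholds, penalties, the RMF bound, the
# inconsistency-score LP and its shadow prices.

test_that("gene thresholds are per-gene quantiles of the pooled samples", {
  vals <- rbind(g1 = 1:100, g2 = rep(7, 100))
  expr <- expression_dataset(vals)
  thr <- gene_thresholds(expr, 0.5)
  expect_equal(unname(thr["g1"]), oracle_quantile(1:100, 0.5))  # 50.5
  expect_equal(unname(thr["g1"]), 50.5)
  expect_equal(unname(thr["g2"]), 7)
  thr88 <- gene_thresholds(expr, 0.88)
  expect_equal(unname(thr88["g1"]), oracle_quantile(1:100, 0.88))
  expect_equal(formals(gene_thresholds)$theta, 0.88)
  single <- expression_dataset(matrix(5, 1, 1, dimnames = list("g", "s1")))
  expect_warning(thr1 <- gene_thresholds(single, 0.5), "one measurement")
  expect_equal(unname(thr1), 5)
})

test_that("gene penalties are the shortfall below the threshold", {
  thr <- c(gA = 10, gB = 10, gC = 10)
  p <- gene_penalties(c(gA = 12, gB = 7, gC = 10), thr)
  expect_equal(unname(p), c(0, 3, 0))
  expect_named(p, c("gA", "gB", "gC"))
  expect_error(gene_penalties(c(gZ = 1), thr), "no threshold")
})

test_that("penalty propagation matches the brute-force truth-table oracle", {
  rules <- c("", "g1", "g1 and g2", "g1 or g2",
             "(g1 and g2) or g3", "g1 and (g2 or g3)",
             "g1 or g2 and g3", "(g1 or g2) and (g2 or g3)")
  set.seed(42)
  for (rule in rules) {
    for (rep in 1:5) {
      pen <- stats::setNames(round(runif(3, 0, 8), 2),
                             c("g1", "g2", "g3"))
      expect_equal(gpr_penalty(rule, pen), oracle_gpr_penalty(rule, pen),
                   info = rule)
    }
  }
  # genes without data carry no penalty
  expect_equal(gpr_penalty("g1 and g9", c(g1 = 4)), 4)
  expect_equal(gpr_penalty("g1 or g9", c(g1 = 4)), 0)
})

test_that("reaction penalties map rules over the model", {
  fx <- make_fixture("two_pathway_team")
  cp <- reaction_penalties(fx$model, c(gLow = 5, gHigh = 0))
  expect_equal(unname(cp[c("R_low", "R_high", "R_src")]), c(5, 0, 0))
  m2 <- fx$model
  m2$reactions$gpr[2] <- "gLow and ("
  expect_error(metabolic_model(m2$metabolites, m2$reactions, m2$S),
               "malformed gpr")
})

test_that("the RMF bound is the stated fraction of the FBA maximum", {
  fx <- make_fixture("two_pathway_team")
  expect_equal(rmf_bound(fx$model, "R_rmf", 0.3), 0.3 * fx$truth$rmf_max)
  expect_equal(rmf_bound(fx$model, "R_rmf", 1), fx$truth$rmf_max)
  expect_equal(formals(rmf_bound)$fraction, 0.3)
  blocked <- fx$model
  blocked$reactions$upper_bound[blocked$reactions$id == "R_src"] <- 0
  expect_error(rmf_bound(blocked, "R_rmf", 0.3), "RMF unreachable")
})

test_that("the integration LP reproduces the hand-derived toys", {
  # penalized producer: relaxing steady state downward cuts the
  # penalized flux, so dIS/db = +2 and the metabolite should decrease
  toy <- model_from_reactions(list(
    list(id = "R_p", stoich = c(M = 1), lb = 0, ub = 10),
    list(id = "R_rmf", stoich = c(M = -1), lb = 0, ub = 10)))
  ts <- solve_team(toy, c(R_p = 2, R_rmf = 0), "R_rmf", 1)
  expect_equal(ts$inconsistency_score, 2)
  expect_equal(unname(ts$shadow_prices["M"]), 2)
  expect_equal(unname(ts$directions["M"]), "decrease")
  # mirrored polarity: RMF produces M, the penalized reaction drains it
  toy2 <- model_from_reactions(list(
    list(id = "R_rmf", stoich = c(M = 1), lb = 0, ub = 10),
    list(id = "R_c", stoich = c(M = -1), lb = 0, ub = 10)))
  ts2 <- solve_team(toy2, c(R_rmf = 0, R_c = 2), "R_rmf", 1)
  expect_equal(ts2$inconsistency_score, 2)
  expect_lt(unname(ts2$shadow_prices["M"]), 0)
  expect_equal(unname(ts2$directions["M"]), "increase")
  # all-zero penalties: a consistent flux distribution always exists
  ts0 <- solve_team(toy, c(R_p = 0, R_rmf = 0), "R_rmf", 1)
  expect_equal(ts0$inconsistency_score, 0)
})

test_that("TEAM shadow prices match brute-force IS re-solves", {
  toy <- model_from_reactions(list(
    list(id = "R_p", stoich = c(M = 1), lb = 0, ub = 10),
    list(id = "R_rmf", stoich = c(M = -1), lb = 0, ub = 10)))
  base <- solve_team(toy, c(R_p = 2, R_rmf = 0), "R_rmf", 1)
  for (delta in c(0.1, -0.1, 0.3)) {
    pert <- toy
    pert$b[1] <- delta
    is2 <- solve_team(pert, c(R_p = 2, R_rmf = 0), "R_rmf", 1)$inconsistency_score
    expect_equal((is2 - base$inconsistency_score) / delta,
                 unname(base$shadow_prices["M"]), tolerance = 1e-8,
                 info = paste("delta", delta))
  }
})

test_that("flux avoids the penalized branch when a free alternative exists", {
  fx <- make_fixture("two_pathway_team")
  rmf_min <- rmf_bound(fx$model, "R_rmf", 0.3)
  ts <- solve_team(fx$model, c(R_low = 1), "R_rmf", rmf_min)
  expect_equal(ts$inconsistency_score, 0)
  expect_equal(unname(ts$fluxes["R_low"]), 0)
  expect_equal(unname(ts$fluxes["R_high"]), rmf_min)
  expect_error(solve_team(fx$model, c(R_low = 1), "R_rmf", 99),
               "RMF")
})

test_that("reversible flux is penalized by magnitude", {
  m <- model_from_reactions(list(
    list(id = "R_rmf", stoich = c(M = 1), lb = 0, ub = 10),
    list(id = "R_rev", stoich = c(M = 1), lb = -10, ub = 0)))
  ts <- solve_team(m, c(R_rmf = 0, R_rev = 3), "R_rmf", 2)
  expect_equal(unname(ts$fluxes["R_rev"]), -2)
  expect_equal(ts$inconsistency_score, 3 * 2)
  expect_equal(ts$inconsistency_score,
               sum(ts$penalties * abs(ts$fluxes)), tolerance = 1e-9)
})

test_that("raising theta never lowers penalties or the inconsistency score", {
  fx <- make_fixture("two_pathway_team")
  expr <- simulate_expression(fx$model, "R_high", seed = 8)
  es <- stats::setNames(expr$values[, 1], expr$genes)
  rmf_min <- rmf_bound(fx$model, "R_rmf", 0.3)
  thetas <- c(0.3, 0.5, 0.7, 0.88, 0.95)
  pen <- sapply(thetas, function(th)
    gene_penalties(es, gene_thresholds(expr, th)))
  expect_true(all(diff(t(pen)) >= -1e-12))
  is_vals <- vapply(thetas, function(th) {
    cp <- reaction_penalties(fx$model,
                             gene_penalties(es, gene_thresholds(expr, th)))
    solve_team(fx$model, cp, "R_rmf", rmf_min)$inconsistency_score
  }, numeric(1))
  expect_true(all(diff(is_vals) >= -1e-9))
})

test_that("theta_scan reruns the pipeline and is flat for bimodal expression", {
  fx <- make_fixture("two_pathway_team")
  # bimodal data: values sit at two plateaus, so mid-range quantile
  # thresholds (hence penalties) do not move with theta
  vals <- rbind(gLow = c(1, rep(c(1, 10), 5), 10),
                gHigh = c(10, rep(c(1, 10), 5), 1))
  expr <- expression_dataset(vals)
  score_is <- function(ts, theta) ts$inconsistency_score
  tab <- theta_scan(fx$model, expr, 1, c(0.6, 0.7, 0.8), score_is, "R_rmf")
  expect_equal(length(unique(round(tab$score, 9))), 1L)
  one <- theta_scan(fx$model, expr, 1, 0.88, score_is, "R_rmf")
  thr <- gene_thresholds(expr, 0.88)
  cp <- reaction_penalties(fx$model,
                           gene_penalties(stats::setNames(vals[, 1],
                                                          rownames(vals)), thr))
  direct <- solve_team(fx$model, cp, "R_rmf",
                       rmf_bound(fx$model, "R_rmf", 0.3))
  expect_equal(one$score, direct$inconsistency_score)
})
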