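# Temporal variation, the quadrant permutation test, MCC, and the
# correlation report.

test_that("temporal variation is sd/mean over the window", {
  expect_equal(temporal_variation(c(0, 5, 10, 15), rep(5, 4)), 0)
  expect_equal(temporal_variation(c(0, 10), c(2, 4)), sqrt(2) / 3)
  # scale invariance
  expect_equal(temporal_variation(c(0, 10), c(20, 40)),
               temporal_variation(c(0, 10), c(2, 4)))
  # points outside the window are ignored
  expect_equal(temporal_variation(c(0, 10, 45), c(2, 4, 1000)),
               sqrt(2) / 3)
  expect_equal(temporal_variation(c(0, 10, 45), c(2, 4, 1000),
                                  window_minutes = 60),
               sd(c(2, 4, 1000)) / mean(c(2, 4, 1000)))
  # optional exclusion of the baseline point
  expect_equal(temporal_variation(c(0, 10, 20), c(100, 2, 4),
                                  include_t0 = FALSE), sqrt(2) / 3)
  expect_error(temporal_variation(c(0, 40), c(1, 2)), "at least 2")
  expect_error(temporal_variation(c(0, 5, 2), c(1, 2, 3)), "increasing")
  expect_warning(cv <- temporal_variation(c(0, 10), c(-3, 3)), "mean is zero")
  expect_true(is.na(cv))
})

test_that("a dataset with an empty forbidden quadrant gets p-value 0", {
  # perfectly rank-anticorrelated lambda and CV: the most negative
  # shadow prices carry the smallest variation, so no metabolite is in
  # the forbidden quadrant and no permutation can beat a count of 0
  n <- 40
  lambda <- seq(-2, 0, length.out = n)
  cv <- seq(0.9, 0.05, length.out = n)[rank(-lambda)]
  res <- permutation_test(lambda, cv, n_perm = 2000, seed = 1)
  expect_equal(res$p_original, 0L)
  expect_equal(res$p_value, 0)
})

test_that("mean- and median-centered tests agree on symmetric data", {
  lambda <- c(-(1:10), 1:10) / 10
  cv <- c(seq(0.1, 0.5, length.out = 10), seq(0.6, 1, length.out = 10))
  r1 <- permutation_test(lambda, cv, n_perm = 3000, center = "mean",
                         seed = 7)
  r2 <- permutation_test(lambda, cv, n_perm = 3000, center = "median",
                         seed = 7)
  expect_equal(r1$p_original, r2$p_original)
  expect_equal(r1$p_value, r2$p_value, tolerance = 0.02)
})

test_that("median-centered p-values survive monotone rescaling of CV", {
  set.seed(3)
  lambda <- runif(30, -2, 0)
  cv <- runif(30, 0.05, 0.9)
  r1 <- permutation_test(lambda, cv, n_perm = 2000, center = "median",
                         seed = 11)
  r2 <- permutation_test(lambda, cv^3 + 1, n_perm = 2000,
                         center = "median", seed = 11)
  expect_equal(r1$p_original, r2$p_original)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the strict inequality is never larger than the inclusive one", {
  set.seed(9)
  lambda <- runif(25, -2, 0); cv <- runif(25, 0, 1)
  ps <- permutation_test(lambda, cv, n_perm = 2000, seed = 5,
                         strict = TRUE)$p_value
  pl <- permutation_test(lambda, cv, n_perm = 2000, seed = 5,
                         strict = FALSE)$p_value
  expect_lte(ps, pl)
})

test_that("fully tied inputs yield an undefined p-value, flagged", {
  res <- permutation_test(rep(1, 5), rep(2, 5), n_perm = 100)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
  expect_error(permutation_test(1:2, 1:2), "at least 3")
})

test_that("MCC matches the closed-form oracle and its identities", {
  perfect <- mcc(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE), n_perm = 0)
  expect_equal(perfect$mcc, 1)
  opposite <- mcc(c(TRUE, FALSE), c(FALSE, TRUE), n_perm = 0)
  expect_equal(opposite$mcc, -1)
  # arbitrary confusion matrix vs direct formula
  pred <- c(rep(TRUE, 40), rep(FALSE, 8), rep(TRUE, 3), rep(FALSE, 12))
  obs <- c(rep(TRUE, 40), rep(FALSE, 8), rep(FALSE, 3), rep(TRUE, 12))
  got <- mcc(pred, obs, n_perm = 0)
  expect_equal(got$mcc, oracle_mcc(tp = 40, tn = 8, fp = 3, fn = 12))
  # MCC equals the Pearson correlation of the binary labels
  set.seed(21)
  for (k in 1:10) {
    a <- runif(30) > 0.5; b <- runif(30) > 0.4
    if (length(unique(b)) < 2 || length(unique(a)) < 2) next
    expect_equal(mcc(a, b, n_perm = 0)$mcc, cor(a, b), tolerance = 1e-12)
  }
  expect_error(mcc(c(TRUE, FALSE), c(TRUE, TRUE)), "single class")
  degen <- mcc(c(TRUE, TRUE), c(TRUE, FALSE), n_perm = 0)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$mcc))
  # permutation p-value: strong agreement is significant
  set.seed(4)
  obs2 <- rep(c(TRUE, FALSE), each = 20)
  strong <- mcc(obs2, obs2, n_perm = 2000, seed = 2)
  expect_lt(strong$p_value, 0.01)
})

test_that("associate reports rank and linear correlation with midranks", {
  a <- associate(1:10, 1:10)
  expect_equal(a$spearman_rho, 1)
  expect_equal(a$pearson_r, 1)
  b <- associate(1:10, -(1:10)^3)
  expect_equal(b$spearman_rho, -1)
  expect_lt(abs(b$pearson_r), 1)
  ties <- associate(c(1, 1, 2), c(3, 3, 4))
  expect_equal(ties$spearman_rho, 1)
  const <- associate(rep(1, 5), 1:5)
  expect_true(const$degenerate)
  expect_true(is.na(const$spearman_rho))
})

test_that("variation_table joins CVs to shadow prices and drops undefined rows", {
  lam <- c(m1 = -1, m2 = 0, m3 = -0.5)
  tc <- rbind(
    data.frame(metabolite_id = "m1", time_min = c(0, 10, 20),
               value = c(10, 11, 9)),
    data.frame(metabolite_id = "m2", time_min = c(0, 10, 20),
               value = c(5, 50, 20)),
    data.frame(metabolite_id = "m3", time_min = c(0, 10),
               value = c(-3, 3)),             # zero mean: dropped
    data.frame(metabolite_id = "m9", time_min = c(0, 10),
               value = c(1, 2)))              # no shadow price: dropped
  vt <- variation_table(tc, lam)
  expect_setequal(vt$metabolite_id, c("m1", "m2"))
  expect_equal(vt$cv[vt$metabolite_id == "m1"],
               sd(c(10, 11, 9)) / 10)
  expect_equal(vt$lambda[vt$metabolite_id == "m2"], 0)
})
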