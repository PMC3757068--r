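# Model container, GPR rules, medium application, knockouts, and the
# three file dialects.

test_that("model construction enforces the structural invariants", {
  mets <- data.frame(id = c("A", "B"))
  rxns <- data.frame(id = c("r1", "r2"), lower_bound = 0, upper_bound = 10)
  S <- matrix(c(1, 0, -1, 1), 2, 2)
  m <- metabolic_model(mets, rxns, S)
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$b, c(0, 0))
  expect_true(m$reactions$is_exchange[1])   # touches only A
  expect_false(m$reactions$is_exchange[2])

  expect_error(metabolic_model(data.frame(id = c("A", "A")), rxns, S),
               "duplicate metabolite")
  bad <- rxns; bad$lower_bound <- c(5, 0); bad$upper_bound <- c(1, 10)
  expect_error(metabolic_model(mets, bad, S), "lower_bound > upper_bound")
  S0 <- S; S0[, 2] <- 0
  expect_error(metabolic_model(mets, rxns, S0), "empty stoichiometry")
})

test_that("gpr parsing handles precedence, case, and malformed rules", {
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_setequal(gpr_genes(tree), c("g1", "g2", "g3"))
  # AND binds tighter than OR
  t2 <- parse_gpr("g1 or g2 and g3")
  expect_equal(t2$op, "or")
  expect_true(eval_gpr(t2, c(g1 = TRUE, g2 = FALSE, g3 = FALSE)))
  expect_false(eval_gpr(t2, c(g1 = FALSE, g2 = TRUE, g3 = FALSE)))
  # case-insensitive keywords
  expect_true(eval_gpr(parse_gpr("g1 AND g2"), c(g1 = TRUE, g2 = TRUE)))
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NA))
  expect_error(parse_gpr("g1 and"), "malformed gpr")
  expect_error(parse_gpr("(g1 or g2"), "malformed gpr")
  expect_error(parse_gpr("g1 g2"), "malformed gpr")
})

test_that("knockouts follow the Boolean rules and zero bounds in place", {
  m <- model_from_reactions(list(
    list(id = "r_and", stoich = c(M = 1), lb = 0, ub = 10,
         gpr = "g1 and g2"),
    list(id = "r_or", stoich = c(M = 1), lb = -5, ub = 10,
         gpr = "g1 or g2"),
    list(id = "r_free", stoich = c(M = -1), lb = 0, ub = 10)))
  ko <- knockout_genes(m, "g1")
  expect_equal(unname(ko$reactions$lower_bound), c(0, -5, 0))
  expect_equal(unname(ko$reactions$upper_bound), c(0, 10, 10))
  ko2 <- knockout_genes(m, c("g1", "g2"))
  expect_equal(unname(ko2$reactions$upper_bound), c(0, 0, 10))
  expect_error(knockout_genes(m, "nope"), "unknown gene")
  # idempotent
  expect_identical(knockout_genes(ko, "g1")$reactions, ko$reactions)
  # monotone: superset of knockouts disables superset of reactions
  dis <- function(mm) which(mm$reactions$lower_bound == 0 &
                              mm$reactions$upper_bound == 0)
  expect_true(all(dis(ko) %in% dis(ko2)))
})

test_that("double knockout of both nitrogen-assimilation isozymes is lethal", {
  nf <- make_fixture("nitrogen_assimilation")
  expect_equal(solve_fba(nf$model)$objective_value, nf$truth$Z)
  single <- solve_fba(knockout_genes(nf$model, "gGDH"))
  expect_equal(single$objective_value, nf$truth$Z_single_ko)
  dko <- knockout_genes(nf$model, c("gGDH", "gGOGAT"))
  expect_equal(solve_fba(dko)$objective_value, 0)
  # with required growth the model becomes infeasible, flagged as lethal
  dko$reactions$lower_bound[dko$reactions$id == "R_growth"] <- 0.1
  s <- solve_fba(dko)
  expect_equal(s$status, "infeasible")
  expect_match(s$infeasible_reason, "lethal")
})

test_that("apply_medium closes unlisted uptakes and leaves the interior alone", {
  m <- model_from_reactions(list(
    list(id = "EX_a", stoich = c(A = 1), lb = -10, ub = 1000),
    list(id = "EX_b", stoich = c(B = 1), lb = -10, ub = 1000),
    list(id = "conv", stoich = c(A = -1, B = 1), lb = -50, ub = 50)))
  closed <- apply_medium(m, NULL)
  expect_equal(unname(closed$reactions$lower_bound),
               c(0, 0, -50))                 # intracellular untouched
  med <- data.frame(reaction_id = "EX_a", lower_bound = -10,
                    upper_bound = 1000)
  opened <- apply_medium(m, med)
  expect_equal(unname(opened$reactions$lower_bound), c(-10, 0, -50))
  expect_equal(unname(opened$reactions$upper_bound), c(1000, 1000, 50))
  expect_error(apply_medium(m, data.frame(reaction_id = "conv",
                                          lower_bound = 0, upper_bound = 1)),
               "non-exchange")
  expect_error(apply_medium(m, data.frame(reaction_id = "EX_zzz",
                                          lower_bound = 0, upper_bound = 1)),
               "unknown reaction")
})

test_that("tsv dialect parses equations into the right dimensions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tgpr",
               "R1\t-> M[c]\t0\t10\t",
               "R2\tM[c] ->\t0\t1000\t"), path)
  m <- read_model(path)
  expect_equal(dim(m$S), c(1L, 2L))
  expect_equal(as.numeric(m$S), c(1, -1))
  expect_equal(m$metabolites$compartment, "c")
  # stoichiometric coefficients and compartments
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tgpr",
               "R1\t2 A[c] + B[c] -> C[e]\t0\t5\tg1"), path2)
  m2 <- read_model(path2)
  expect_equal(as.numeric(m2$S[, 1]), c(-2, -1, 1))
  expect_equal(m2$metabolites$compartment, c("c", "c", "e"))
})

test_that("json dialect extracts the gene set from the rules", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "M", "name": "M", "compartment": "c"}],
    "reactions": [
      {"id": "R1", "metabolites": {"M": 1}, "lower_bound": 0,
       "upper_bound": 10, "gene_reaction_rule": "(g1 and g2) or g3"},
      {"id": "R2", "metabolites": {"M": -1}, "lower_bound": 0,
       "upper_bound": 10}
    ],
    "objective": {"R2": 1}
  }', path)
  m <- read_model(path)
  expect_setequal(m$genes, c("g1", "g2", "g3"))
  expect_equal(unname(m$objective["R2"]), 1)
})

test_that("all three dialects round-trip S, bounds, objective and rules", {
  fx <- make_fixture("branched", seed = 4)
  model <- fx$model
  for (fmt in c("json", "tsv", "sbml")) {
    ext <- if (fmt == "sbml") ".xml" else paste0(".", fmt)
    path <- withr::local_tempfile(fileext = ext)
    write_model(model, path, fmt)
    back <- read_model(path, fmt)
    expect_equal(as.matrix(back$S), as.matrix(model$S),
                 info = fmt, tolerance = 1e-12)
    expect_equal(back$reactions$lower_bound, model$reactions$lower_bound,
                 info = fmt)
    expect_equal(back$reactions$upper_bound, model$reactions$upper_bound,
                 info = fmt)
    expect_equal(unname(back$objective), unname(model$objective), info = fmt)
    # gpr preserved modulo whitespace/parenthesization
    norm <- function(g) vapply(g, function(s)
      gpr_to_string(parse_gpr(s)), character(1), USE.NAMES = FALSE)
    expect_equal(norm(back$reactions$gpr), norm(model$reactions$gpr),
                 info = fmt)
    # second trip is byte-stable
    path2 <- withr::local_tempfile(fileext = ext)
    write_model(back, path2, fmt)
    expect_identical(readLines(path2), readLines(path), info = fmt)
  }
})

test_that("medium files read back the three required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tlower_bound\tupper_bound",
               "EX_glc\t-10\t1000"), path)
  med <- read_medium(path)
  expect_equal(med$reaction_id, "EX_glc")
  expect_equal(med$lower_bound, -10)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("reaction_id\tlb", path2)
  expect_error(read_medium(path2), "lacks column")
})
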