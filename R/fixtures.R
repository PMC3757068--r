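# Deterministic toy networks and seeded synthetic-data generators.
#
# Every fixture carries a ground-truth record derived analytically at
# generation time (the hand LP solutions are worked out in the comments
# below), never from the solver under test, so the solver can be checked
# against an independent oracle.

#' Construct a toy network fixture
#'
#' Available kinds:
#' \describe{
#'   \item{figure1}{One metabolite M, an uptake reaction (0 <= v1 <= 10)
#'     producing it and an objective drain (0 <= v2 <= 1000) consuming
#'     it. Hand LP: Z = 10 at v = (10, 10). Perturbing b_M by t gives
#'     Z = 10 - t for t in [-990, 10] (the drain cap 1000 limits
#'     relaxation, the uptake cap 10 limits tightening), so
#'     lambda_M = -1 with validity range [-990, 10] and
#'     lambda+ = lambda- = -1: nondegenerate.}
#'   \item{degenerate}{One metabolite M, producer v1 (<= 5) and two
#'     drains: vA (<= 5, objective weight 1) and vB (<= 1000, weight
#'     0.5), maximizing vA + 0.5 vB. Hand LP: Z = 5 (all flux through
#'     vA). Accumulation (b = t > 0) removes weight-1 flux:
#'     Z = 5 - t, lambda+ = -1. Depletion (t < 0) routes the extra
#'     drain through the weight-0.5 reaction: Z = 5 + 0.5|t|,
#'     lambda- = -0.5. The two one-sided sensitivities differ: the
#'     shadow price is degenerate by construction, and a solver may
#'     report either value.}
#'   \item{branched}{Seeded random linear pathway (uptake, conversion
#'     stages, objective sink) where some stages have two parallel
#'     isozyme reactions; all bounds are drawn to be pairwise distinct
#'     so the optimum is nondegenerate. Ground-truth Z and shadow
#'     prices follow from bottleneck analysis: with up_i the tightest
#'     stage capacity upstream of metabolite i and down_i downstream,
#'     Z = min(up, down) and lambda_i = -1 if up_i < down_i else 0.}
#'   \item{two_pathway_team}{A -> M by two routes: R_low (to be
#'     penalized) and R_high (well-expressed alternative), plus an
#'     uptake and an RMF drain of M. With a penalty only on R_low the
#'     integration LP routes all flux through R_high: IS = 0.}
#'   \item{nitrogen_assimilation}{Ammonium uptake (<= 8) and two
#'     isozyme assimilation routes (GDH-like and GOGAT-like, each
#'     <= 10) into glutamate, drained by a growth-like objective.
#'     Either single knockout leaves Z = 8 and all shadow prices
#'     unchanged (the paths are redundant at the optimum); knocking
#'     out both genes makes growth impossible.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param seed integer seed (used by \code{branched}).
#' @param params optional list of overrides; \code{branched} honours
#'   \code{n_mets} (number of internal metabolites, default 5).
#' @return list with \code{model} (a \code{\link{metabolic_model}}) and
#'   \code{truth} (the analytically derived ground-truth record).
#' @export
make_fixture <- function(kind = c("figure1", "degenerate", "branched",
                                  "two_pathway_team",
                                  "nitrogen_assimilation"),
                         seed = NULL, params = list()) {
  kind <- match.arg(kind)
  switch(kind,
    figure1 = {
      model <- model_from_reactions(list(
        list(id = "R_in", stoich = c("M[c]" = 1), lb = 0, ub = 10),
        list(id = "R_out", stoich = c("M[c]" = -1), lb = 0, ub = 1000)),
        objective = c(R_out = 1), compartment_of = met_compartment)
      list(model = model,
           truth = list(Z = 10, fluxes = c(R_in = 10, R_out = 10),
                        lambda = c("M[c]" = -1),
                        range_low = -990, range_high = 10,
                        lambda_plus = -1, lambda_minus = -1,
                        degenerate = FALSE))
    },
    degenerate = {
      model <- model_from_reactions(list(
        list(id = "R_in", stoich = c("M[c]" = 1), lb = 0, ub = 5),
        list(id = "R_a", stoich = c("M[c]" = -1), lb = 0, ub = 5),
        list(id = "R_b", stoich = c("M[c]" = -1), lb = 0, ub = 1000)),
        objective = c(R_a = 1, R_b = 0.5), compartment_of = met_compartment)
      list(model = model,
           truth = list(Z = 5,
                        lambda_plus = -1, lambda_minus = -0.5,
                        lambda_solver_set = c(-1, -0.5),
                        range_high = 5, range_low = -1000,
                        degenerate = TRUE))
    },
    branched = make_branched_fixture(seed, params),
    two_pathway_team = {
      model <- model_from_reactions(list(
        list(id = "R_src", stoich = c("A[c]" = 1), lb = 0, ub = 10),
        list(id = "R_low", stoich = c("A[c]" = -1, "M[c]" = 1),
             lb = 0, ub = 10, gpr = "gLow"),
        list(id = "R_high", stoich = c("A[c]" = -1, "M[c]" = 1),
             lb = 0, ub = 10, gpr = "gHigh"),
        list(id = "R_rmf", stoich = c("M[c]" = -1), lb = 0, ub = 10)),
        compartment_of = met_compartment)
      list(model = model,
           truth = list(rmf_max = 10, IS_penalized_low = 0,
                        active_reactions = c("R_src", "R_high", "R_rmf")))
    },
    nitrogen_assimilation = {
      model <- model_from_reactions(list(
        list(id = "EX_nh4", stoich = c("NH4[c]" = 1), lb = 0, ub = 8),
        list(id = "R_gdh", stoich = c("NH4[c]" = -1, "GLU[c]" = 1),
             lb = 0, ub = 10, gpr = "gGDH"),
        list(id = "R_gogat", stoich = c("NH4[c]" = -1, "GLU[c]" = 1),
             lb = 0, ub = 10, gpr = "gGOGAT"),
        list(id = "R_growth", stoich = c("GLU[c]" = -1), lb = 0, ub = 20)),
        objective = c(R_growth = 1), compartment_of = met_compartment)
      list(model = model,
           truth = list(Z = 8, Z_single_ko = 8, Z_double_ko = 0,
                        genes = c("gGDH", "gGOGAT")))
    })
}

# Seeded random pathway: uptake -> M1 -> ... -> Mk -> sink, some stages
# carrying two parallel reactions. Stage capacities are resampled until
# pairwise distinct by > 0.05, which keeps the optimum nondegenerate:
# exactly one stage is the bottleneck, and every running-minimum
# comparison up_i vs down_i is strict.
make_branched_fixture <- function(seed = NULL, params = list()) {
  if (!is.null(seed)) set.seed(seed)
  n_mets <- if (!is.null(params$n_mets)) params$n_mets else 5L
  stopifnot(n_mets >= 1)
  n_stages <- n_mets + 1L
  repeat {
    parallel <- c(FALSE, stats::runif(n_stages - 2) < 0.4, FALSE)
    arm1 <- round(stats::runif(n_stages, 0.5, 10), 2)
    arm2 <- ifelse(parallel, round(stats::runif(n_stages, 0.5, 10), 2), 0)
    cap <- arm1 + arm2
    if (min(dist(cap)) > 0.05) break
  }
  mets <- paste0("M", seq_len(n_mets), "[c]")
  rxns <- list()
  for (s in seq_len(n_stages)) {
    stoich <- c()
    if (s > 1) stoich[mets[s - 1]] <- -1
    if (s <= n_mets) stoich[mets[s]] <- 1
    base_id <- if (s == 1) "EX_in" else if (s == n_stages) "EX_out"
               else paste0("R", s - 1)
    rxns[[length(rxns) + 1]] <- list(
      id = base_id, stoich = stoich, lb = 0, ub = arm1[s],
      gpr = if (s > 1 && s < n_stages) paste0("g_", base_id, "a") else "")
    if (parallel[s]) {
      rxns[[length(rxns) + 1]] <- list(
        id = paste0(base_id, "_iso"), stoich = stoich, lb = 0, ub = arm2[s],
        gpr = paste0("g_", base_id, "b"))
    }
  }
  model <- model_from_reactions(rxns, objective = c(EX_out = 1),
                                compartment_of = met_compartment)
  up <- cummin(cap)[seq_len(n_mets)]                   # stages 1..i
  down <- rev(cummin(rev(cap)))[1 + seq_len(n_mets)]   # stages i+1..end
  lambda <- ifelse(up < down, -1, 0)
  list(model = model,
       truth = list(Z = min(cap), lambda = stats::setNames(lambda, mets),
                    stage_capacity = cap, degenerate = FALSE))
}

#' Simulate a gene-expression matrix for a fixture model
#'
#' Emulates a time-course transcriptome in which the genes of a chosen
#' set of active reactions peak in the query sample: active genes take
#' their maximal value there (so their own empirical quantile threshold
#' sits at or below it and their penalty is zero for any
#' \eqn{\theta < 1} when \code{noise_sd = 0}), while inactive genes are
#' at their minimum in the query sample and higher elsewhere, giving
#' them a positive penalty at high \eqn{\theta}.
#'
#' @param model a \code{metabolic_model} with gene-associated reactions.
#' @param active_reactions reaction ids whose genes are highly expressed
#'   in the query sample; must all carry a rule.
#' @param n_samples number of samples (default 12; the first is the
#'   query sample).
#' @param noise_sd Gaussian noise added to every measurement
#'   (default 0.25).
#' @param seed integer seed.
#' @param high,low expression levels of active/inactive genes in the
#'   query sample (defaults 10 and 1).
#' @return an \code{\link{expression_dataset}}; the query sample is the
#'   first column, \code{"s1"}.
#' @export
simulate_expression <- function(model, active_reactions, n_samples = 12,
                                noise_sd = 0.25, seed = 1,
                                high = 10, low = 1) {
  stopifnot(n_samples >= 2)
  idx <- match(active_reactions, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(active_reactions[is.na(idx)], collapse = ", "))
  no_gpr <- !nzchar(model$reactions$gpr[idx])
  if (any(no_gpr))
    stop("active reaction(s) without gene rule: ",
         paste(active_reactions[no_gpr], collapse = ", "))
  active_genes <- unique(unlist(lapply(model$gpr_trees[idx], gpr_genes)))
  genes <- model$genes
  if (!length(genes)) stop("model has no gene-associated reactions")
  set.seed(seed)
  vals <- matrix(0, length(genes), n_samples,
                 dimnames = list(genes, paste0("s", seq_len(n_samples))))
  for (g in genes) {
    if (g %in% active_genes) {
      vals[g, ] <- c(high, stats::runif(n_samples - 1, low, 0.8 * high))
    } else {
      vals[g, ] <- c(low, stats::runif(n_samples - 1, 0.4 * high, high))
    }
  }
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow(vals), ncol(vals))
  expression_dataset(vals)
}

#' Simulate metabolite time courses with a given shadow-price structure
#'
#' Generates per-metabolite post-perturbation trajectories whose
#' coefficient of variation depends (in \code{"signal"} mode) on the
#' sign of the metabolite's shadow price: growth-limiting metabolites
#' (negative shadow price) receive tightly controlled, low-CV
#' trajectories, while non-limiting metabolites (zero shadow price) get
#' a broad CV spread. In \code{"null"} mode every metabolite draws from
#' the broad spread regardless of its shadow price, which is the
#' calibration reference for the permutation test.
#'
#' @param shadow_prices named numeric vector of shadow prices.
#' @param cv_rule list with \code{cv_limiting} (CV range for negative
#'   shadow prices, default \code{c(0.02, 0.15)}) and \code{cv_free}
#'   (range otherwise, default \code{c(0.05, 0.9)}).
#' @param n_points measurements per trajectory (default 7, >= 3),
#'   equally spaced on 0..30 minutes.
#' @param seed integer seed.
#' @param mode \code{"signal"} or \code{"null"}.
#' @return long data.frame (\code{metabolite_id}, \code{time_min},
#'   \code{value}) with the per-metabolite target CV as attribute
#'   \code{"target_cv"}.
#' @export
simulate_timecourses <- function(shadow_prices,
                                 cv_rule = list(cv_limiting = c(0.02, 0.15),
                                                cv_free = c(0.05, 0.9)),
                                 n_points = 7, seed = 1,
                                 mode = c("signal", "null")) {
  mode <- match.arg(mode)
  stopifnot(n_points >= 3)
  if (is.null(names(shadow_prices)))
    stop("shadow_prices must be named by metabolite")
  lim <- if (!is.null(cv_rule$cv_limiting)) cv_rule$cv_limiting else c(0.02, 0.15)
  fre <- if (!is.null(cv_rule$cv_free)) cv_rule$cv_free else c(0.05, 0.9)
  set.seed(seed)
  times <- seq(0, 30, length.out = n_points)
  baseline <- 100
  rows <- lapply(names(shadow_prices), function(id) {
    target <- if (mode == "signal" && shadow_prices[[id]] < 0)
      stats::runif(1, lim[1], lim[2])
    else stats::runif(1, fre[1], fre[2])
    vals <- baseline * (1 + stats::rnorm(n_points, 0, target))
    vals <- pmax(vals, 0.01 * baseline)
    data.frame(metabolite_id = id, time_min = times, value = vals,
               target_cv = target, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  target_cv <- stats::setNames(
    vapply(rows, function(r) r$target_cv[1], numeric(1)),
    names(shadow_prices))
  out$target_cv <- NULL
  attr(out, "target_cv") <- target_cv
  out
}
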