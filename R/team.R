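# Expression-data integration (GIMME/TEAM): gene-specific penalty
# thresholds, reaction penalty propagation, the inconsistency-score LP,
# and shadow-price-based prediction of metabolite accumulation/depletion.
#
# Instead of maximizing growth, the integration LP minimizes the
# inconsistency score IS = sum_j c_j |v_j| between predicted fluxes and
# expression data, subject to steady state, the flux bounds, and a
# required metabolic functionality (RMF) -- a user-chosen minimal flux
# (e.g. acetate secretion at 30% of its FBA maximum) that rules out the
# trivial all-zero solution. The shadow price of metabolite i is then
# dIS*/db_i: positive means that letting the metabolite deplete lowers
# the inconsistency, i.e. its abundance is predicted to be decreasing;
# negative means it is predicted to be increasing.

#' Construct an expression dataset
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @return object of class \code{expression_dataset} with fields
#'   \code{genes}, \code{samples}, \code{values}.
#' @export
expression_dataset <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression dataset:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Gene-specific penalty thresholds
#'
#' For each gene, the threshold \eqn{x_g} is the \eqn{\theta}-quantile of
#' that gene's own expression measurements pooled across all samples
#' (its empirical CDF). Quantiles use linear interpolation between order
#' statistics so thresholds vary continuously with \eqn{\theta}.
#'
#' @param expr an \code{\link{expression_dataset}}.
#' @param theta percentile in (0,1); default 0.88.
#' @return named numeric vector of thresholds, one per gene.
#' @export
gene_thresholds <- function(expr, theta = 0.88) {
  stopifnot(inherits(expr, "expression_dataset"), theta > 0, theta < 1)
  if (ncol(expr$values) < 2)
    warning("only one measurement per gene; thresholds equal that value")
  apply(expr$values, 1, stats::quantile, probs = theta, type = 7,
        names = FALSE)
}

#' Gene penalties for one expression sample
#'
#' A gene expressed at or above its threshold gets no penalty; below the
#' threshold, the penalty is the shortfall:
#' \eqn{p_g = \max(0, x_g - EXP_g)}.
#'
#' @param expr_sample named numeric vector of expression values
#'   \eqn{EXP_g} for one sample.
#' @param thresholds named thresholds from \code{\link{gene_thresholds}};
#'   must cover all supplied genes.
#' @return named nonnegative numeric vector of penalties.
#' @export
gene_penalties <- function(expr_sample, thresholds) {
  miss <- setdiff(names(expr_sample), names(thresholds))
  if (length(miss))
    stop("no threshold for gene(s): ", paste(miss, collapse = ", "))
  shortfall <- thresholds[names(expr_sample)] - expr_sample
  pmax(shortfall, 0)
}

#' Map gene penalties to reaction penalties
#'
#' Propagates gene penalties through each reaction's Boolean
#' gene-protein-reaction rule: OR (isozymes) takes the minimum penalty,
#' AND (complexes) the maximum; reactions without a rule, and genes
#' without expression data, get penalty 0.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_penalties named penalties from
#'   \code{\link{gene_penalties}}.
#' @return numeric penalty vector \eqn{c \ge 0}, named by reaction id.
#' @export
reaction_penalties <- function(model, gene_penalties) {
  validate_model(model)
  pen <- vapply(model$gpr_trees, gpr_penalty, numeric(1),
                penalties = gene_penalties)
  stats::setNames(pen, model$reactions$id)
}

#' Minimal required-functionality flux
#'
#' Uses plain FBA to find the maximum achievable flux through the RMF
#' reaction (under steady state and the model bounds) and returns the
#' requested fraction of it.
#'
#' @param model a \code{metabolic_model}.
#' @param rmf_reaction_id reaction whose flux is the required metabolic
#'   functionality (e.g. an acetate exchange).
#' @param fraction fraction of the maximum in (0,1]; default 0.3.
#' @return \eqn{v_{RMF,min}} as a single number.
#' @export
rmf_bound <- function(model, rmf_reaction_id, fraction = 0.3) {
  stopifnot(fraction > 0, fraction <= 1)
  j <- match(rmf_reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown RMF reaction: ", rmf_reaction_id)
  probe <- model
  probe$objective[] <- 0
  probe$objective[j] <- 1
  sol <- solve_fba(probe)
  if (sol$status != "optimal")
    stop("RMF maximization did not solve (status: ", sol$status, ")")
  if (sol$objective_value <= 1e-9)
    stop("RMF unreachable: maximum flux through ", rmf_reaction_id,
         " is zero, the functionality constraint would be vacuous")
  fraction * sol$objective_value
}

#' Solve the expression-integration LP
#'
#' Minimizes the inconsistency score \eqn{IS = \sum_j c_j |v_j|} subject
#' to \eqn{S v = b}, the flux bounds, and \eqn{v_{RMF} \ge v_{RMF,min}}.
#' Absolute values are handled by splitting every reaction into forward
#' and reverse half-reactions, both nonnegative and both carrying the
#' reaction's penalty, so reversible flux is penalized by magnitude in
#' either direction.
#'
#' @param model a \code{metabolic_model}.
#' @param penalties nonnegative reaction penalty vector (length n or
#'   named by reaction id), from \code{\link{reaction_penalties}}.
#' @param rmf_reaction_id the required-functionality reaction.
#' @param rmf_min minimal RMF flux from \code{\link{rmf_bound}}.
#' @param tol solver tolerance.
#' @return object of class \code{team_solution}: \code{fluxes} (net, per
#'   reaction), \code{inconsistency_score}, \code{shadow_prices}
#'   (\eqn{\partial IS^*/\partial b_i}, named by metabolite),
#'   \code{directions} (predicted abundance change per metabolite),
#'   \code{rmf_reaction_id}, \code{rmf_min}, \code{status}.
#' @export
solve_team <- function(model, penalties, rmf_reaction_id, rmf_min,
                       tol = 1e-9) {
  validate_model(model)
  n <- nrow(model$reactions)
  if (!is.null(names(penalties))) {
    pen <- rep(0, n)
    idx <- match(names(penalties), model$reactions$id)
    if (anyNA(idx)) stop("penalty for unknown reaction(s): ",
                         paste(names(penalties)[is.na(idx)], collapse = ", "))
    pen[idx] <- penalties
  } else {
    stopifnot(length(penalties) == n)
    pen <- as.numeric(penalties)
  }
  if (any(pen < 0)) stop("reaction penalties must be nonnegative")
  j_rmf <- match(rmf_reaction_id, model$reactions$id)
  if (is.na(j_rmf)) stop("unknown RMF reaction: ", rmf_reaction_id)

  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  lb[j_rmf] <- max(lb[j_rmf], rmf_min)
  if (lb[j_rmf] > ub[j_rmf])
    stop("RMF bound ", rmf_min, " exceeds the upper bound of ",
         rmf_reaction_id)

  # split v = v_fwd - v_rev, both >= 0, both penalized
  Sd <- as.matrix(model$S)
  A <- cbind(Sd, -Sd)
  obj <- c(pen, pen)
  lb_split <- c(pmax(lb, 0), pmax(-ub, 0))
  ub_split <- c(pmax(ub, 0), pmax(-lb, 0))
  sol <- simplex_lp(obj, A, model$b, lb_split, ub_split,
                    maximize = FALSE, tol = tol)
  if (sol$status != "optimal") {
    if (sol$status == "infeasible")
      stop("integration LP infeasible: the RMF requirement v_",
           rmf_reaction_id, " >= ", rmf_min,
           " cannot be met under the model bounds")
    stop("integration LP not optimal (status: ", sol$status, ")")
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  is_score <- sol$z
  lambda <- stats::setNames(sol$y, model$metabolites$id)
  out <- structure(list(
    status = "optimal",
    fluxes = stats::setNames(v, model$reactions$id),
    inconsistency_score = is_score,
    shadow_prices = lambda,
    rmf_reaction_id = rmf_reaction_id,
    rmf_min = rmf_min,
    penalties = stats::setNames(pen, model$reactions$id),
    lp_solution = sol), class = "team_solution")
  out$directions <- predict_direction(out)
  out
}

#' @export
print.team_solution <- function(x, ...) {
  cat("expression-integration solution: IS =",
      format(x$inconsistency_score, digits = 8),
      "; RMF", x$rmf_reaction_id, ">=", format(x$rmf_min, digits = 8), "\n")
  tab <- table(factor(x$directions, levels = c("increase", "decrease", "none")))
  cat("predicted abundance changes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict the direction of metabolite abundance change
#'
#' A positive shadow price (relaxing steady state by draining the
#' metabolite lowers the inconsistency score) predicts a decreasing
#' abundance; a negative one predicts an increase; near-zero predicts
#' neither.
#'
#' @param team_solution an optimal \code{\link{solve_team}} result.
#' @param tol zero threshold on the shadow price (default \code{1e-6}).
#' @return named character vector, values in
#'   \code{c("increase", "decrease", "none")}.
#' @export
predict_direction <- function(team_solution, tol = 1e-6) {
  stopifnot(inherits(team_solution, "team_solution"))
  lam <- team_solution$shadow_prices
  dir <- ifelse(lam > tol, "decrease", ifelse(lam < -tol, "increase", "none"))
  stats::setNames(dir, names(lam))
}

#' Scan the penalty-threshold percentile
#'
#' Re-runs the full thresholds-to-penalties-to-LP pipeline for each
#' value of \eqn{\theta} in a grid and scores every solution with a
#' caller-supplied function, as in a threshold sensitivity analysis.
#'
#' @param model a \code{metabolic_model}.
#' @param expr an \code{\link{expression_dataset}}.
#' @param sample sample (column) name or index used for the penalties.
#' @param theta_grid numeric vector of percentiles in (0,1).
#' @param score_fn function \code{(team_solution, theta) -> numeric}.
#' @param rmf_reaction_id,rmf_fraction forwarded to
#'   \code{\link{rmf_bound}}.
#' @return data.frame with columns \code{theta} and \code{score}.
#' @export
theta_scan <- function(model, expr, sample, theta_grid, score_fn,
                       rmf_reaction_id, rmf_fraction = 0.3) {
  stopifnot(all(theta_grid > 0), all(theta_grid < 1))
  expr_sample <- expr$values[, sample]
  names(expr_sample) <- expr$genes
  rmf_min <- rmf_bound(model, rmf_reaction_id, rmf_fraction)
  score <- vapply(theta_grid, function(theta) {
    thr <- gene_thresholds(expr, theta)
    gp <- gene_penalties(expr_sample, thr)
    cp <- reaction_penalties(model, gp)
    ts <- solve_team(model, cp, rmf_reaction_id, rmf_min)
    as.numeric(score_fn(ts, theta))
  }, numeric(1))
  data.frame(theta = theta_grid, score = score)
}
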