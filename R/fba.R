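# Flux balance analysis and its dual: shadow prices, reduced costs, and
# validity ranges.
#
# The primal LP is the canonical FBA problem
#     maximize  c'v   s.t.  S v = b,  v_LB <= v <= v_UB
# and the duals of the steady-state rows are the shadow prices
# lambda_i = dZ*/db_i: the marginal change of the optimum per unit of
# flux imbalance (net accumulation b_i > 0 or depletion b_i < 0) at
# metabolite i. Under growth maximization a negative shadow price marks
# a growth-limiting metabolite: letting the network drain it (b_i < 0)
# raises the optimal growth rate.

model_to_lp <- function(model) {
  list(obj = as.numeric(model$objective),
       A = as.matrix(model$S),
       rhs = model$b,
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound)
}

#' Solve the FBA primal problem and extract its dual values
#'
#' @param model a \code{metabolic_model}.
#' @param tol solver pivot tolerance.
#' @return object of class \code{fba_solution}: a list with
#' \describe{
#'   \item{status}{\code{"optimal"}, \code{"infeasible"} or
#'     \code{"unbounded"}.}
#'   \item{fluxes}{named optimal flux vector \eqn{v^*} (optimal only).}
#'   \item{objective_value}{optimal \eqn{Z}.}
#'   \item{shadow_prices}{named vector \eqn{\lambda}, one per metabolite,
#'     with the convention \eqn{\lambda_i = \partial Z^*/\partial b_i}.}
#'   \item{reduced_costs_lower, reduced_costs_upper}{nonnegative
#'     multipliers of the lower/upper flux bound constraints.}
#'   \item{dual_objective}{value of the dual program at those
#'     multipliers; equals \eqn{Z} by strong duality.}
#'   \item{infeasible_reason}{for infeasible models, a short diagnosis --
#'     in particular whether gene knockouts have zeroed reaction bounds,
#'     the typical signature of a lethal deletion.}
#' }
#' @export
solve_fba <- function(model, tol = 1e-9) {
  validate_model(model)
  lp <- model_to_lp(model)
  sol <- simplex_lp(lp$obj, lp$A, lp$rhs, lp$lb, lp$ub,
                    maximize = TRUE, tol = tol)
  out <- list(status = sol$status)
  if (sol$status == "infeasible") {
    disabled <- model$reactions$lower_bound == 0 &
      model$reactions$upper_bound == 0 &
      nzchar(model$reactions$gpr)
    out$infeasible_reason <- if (any(model$reactions$lower_bound >
                                     model$reactions$upper_bound))
      "inconsistent flux bounds"
    else if (any(disabled))
      paste0("constraints inconsistent; ", sum(disabled),
             " gene-associated reaction(s) are knocked out ",
             "(possible lethal deletion)")
    else "constraints inconsistent with bounds"
    return(structure(out, class = "fba_solution"))
  }
  if (sol$status != "optimal") return(structure(out, class = "fba_solution"))

  fluxes <- stats::setNames(sol$x, model$reactions$id)
  lambda <- stats::setNames(sol$y, model$metabolites$id)
  mu_ub <- stats::setNames(pmax(sol$dj, 0), model$reactions$id)
  mu_lb <- stats::setNames(pmax(-sol$dj, 0), model$reactions$id)
  finite_ub <- is.finite(lp$ub); finite_lb <- is.finite(lp$lb)
  dual_obj <- sum(lp$rhs * sol$y) +
    sum(lp$ub[finite_ub] * mu_ub[finite_ub]) -
    sum(lp$lb[finite_lb] * mu_lb[finite_lb])

  structure(list(
    status = "optimal",
    fluxes = fluxes,
    objective_value = sol$z,
    shadow_prices = lambda,
    reduced_costs_lower = mu_lb,
    reduced_costs_upper = mu_ub,
    dual_objective = dual_obj,
    lp_solution = sol), class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution: status =", x$status)
  if (x$status == "optimal")
    cat(", Z =", format(x$objective_value, digits = 8))
  if (!is.null(x$infeasible_reason)) cat(" (", x$infeasible_reason, ")")
  cat("\n")
  invisible(x)
}

#' Construct the explicit dual program of an FBA model
#'
#' Builds the dual LP over the shadow prices \eqn{\lambda} (free, one per
#' metabolite) and the bound multipliers \eqn{\mu^{LB}, \mu^{UB} \ge 0}
#' (one per finite flux bound):
#' \deqn{\min\; b'\lambda + v^{UB'}\mu^{UB} - v^{LB'}\mu^{LB}
#'  \quad s.t.\quad S'\lambda + \mu^{UB} - \mu^{LB} = c .}
#' Solving it independently of the primal must reproduce the primal
#' optimum (strong duality); this is used as a live self-check in the
#' test suite.
#'
#' @param model a \code{metabolic_model}.
#' @return object of class \code{dual_lp}: the fully-specified LP
#'   (objective, equality matrix, variable bounds, variable names) plus
#'   index maps back to metabolites and reactions.
#' @export
build_dual <- function(model) {
  validate_model(model)
  m <- nrow(model$metabolites); n <- nrow(model$reactions)
  St <- t(as.matrix(model$S))
  ub <- model$reactions$upper_bound; lb <- model$reactions$lower_bound
  j_ub <- which(is.finite(ub)); j_lb <- which(is.finite(lb))
  # variables: lambda (m, free), mu_ub (finite ub), mu_lb (finite lb)
  A <- cbind(St,
             diag(1, n)[, j_ub, drop = FALSE],
             -diag(1, n)[, j_lb, drop = FALSE])
  obj <- c(model$b, ub[j_ub], -lb[j_lb])
  nvar <- m + length(j_ub) + length(j_lb)
  var_names <- c(paste0("lambda.", model$metabolites$id),
                 paste0("mu_ub.", model$reactions$id[j_ub]),
                 paste0("mu_lb.", model$reactions$id[j_lb]))
  structure(list(
    objective = obj, A = A, rhs = as.numeric(model$objective),
    lb = c(rep(-Inf, m), rep(0, nvar - m)),
    ub = rep(Inf, nvar),
    maximize = FALSE,
    var_names = var_names,
    n_metabolites = m, j_ub = j_ub, j_lb = j_lb), class = "dual_lp")
}

#' Solve an explicit dual program
#'
#' @param dual a \code{dual_lp} from \code{\link{build_dual}}.
#' @param tol solver tolerance.
#' @return list with \code{status}, \code{dual_objective}, and the
#'   optimal \code{lambda} (named by metabolite).
#' @export
solve_dual <- function(dual, tol = 1e-9) {
  stopifnot(inherits(dual, "dual_lp"))
  sol <- simplex_lp(dual$objective, dual$A, dual$rhs, dual$lb, dual$ub,
                    maximize = dual$maximize, tol = tol)
  if (sol$status != "optimal")
    return(list(status = sol$status, dual_objective = NA_real_))
  lambda <- sol$x[seq_len(dual$n_metabolites)]
  names(lambda) <- sub("^lambda\\.", "", dual$var_names[seq_len(dual$n_metabolites)])
  list(status = "optimal", dual_objective = sol$z, lambda = lambda,
       x = stats::setNames(sol$x, dual$var_names))
}

#' Shadow prices with their validity ranges
#'
#' One record per metabolite: the shadow price \eqn{\lambda_i}, the
#' interval \eqn{[G^-_i, G^+_i]} of right-hand-side perturbations over
#' which the optimal basis (hence the shadow price) remains valid, and a
#' validity flag. Shadow prices whose range is narrower than
#' \code{eps_range} are marked invalid and should be discarded from
#' downstream comparisons.
#'
#' @param model a \code{metabolic_model}.
#' @param solution an optimal \code{\link{solve_fba}} result for
#'   \code{model} (solved afresh when omitted).
#' @param eps_range minimal range width for a shadow price to count as
#'   valid (default \code{1e-6}).
#' @return data.frame with columns \code{metabolite_id},
#'   \code{compartment}, \code{lambda}, \code{range_low},
#'   \code{range_high}, \code{valid}.
#' @export
shadow_price_table <- function(model, solution = NULL, eps_range = 1e-6) {
  if (is.null(solution)) solution <- solve_fba(model)
  stopifnot(inherits(solution, "fba_solution"))
  if (solution$status != "optimal")
    stop("shadow prices require an optimal solution (status: ",
         solution$status, ")")
  m <- nrow(model$metabolites)
  rng <- t(vapply(seq_len(m),
                  function(i) simplex_rhs_range(solution$lp_solution, i),
                  numeric(2)))
  data.frame(
    metabolite_id = model$metabolites$id,
    compartment = model$metabolites$compartment,
    lambda = as.numeric(solution$shadow_prices),
    range_low = rng[, 1],
    range_high = rng[, 2],
    valid = (rng[, 2] - rng[, 1]) >= eps_range,
    stringsAsFactors = FALSE)
}
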