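# Brute-force validation of shadow prices against alternate optima, and
# the growth-limitation classification.
#
# At a degenerate optimum the dual solution is not unique: the marginal
# value of relaxing a steady-state constraint can differ depending on
# whether the metabolite accumulates (b_i > 0) or depletes (b_i < 0).
# The incremental shadow price lambda+ and the decremental shadow price
# lambda- re-measure the sensitivity by brute force -- re-solving the
# primal with the right-hand side perturbed a fraction p into its
# validity range -- and any disagreement with the solver's dual value
# beyond tolerance flags the metabolite as degenerate.

set_rhs <- function(model, metabolite_id, value) {
  i <- match(metabolite_id, model$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", metabolite_id)
  model$b[i] <- value
  model
}

# First breakpoint of the optimal-value function Z(b_i) on one side of 0.
#
# Z(b_i) is concave piecewise-linear; the one-sided slope at 0 is the
# shadow price on that side and stays constant up to the first
# breakpoint. The basis range gives a certified linear segment; at a
# degenerate vertex it can collapse to zero even though Z is still
# linear, so we probe beyond it with fresh re-solves (doubling then
# bisection). Returns list(range = signed breakpoint, slope).
value_breakpoint <- function(model, metabolite_id, direction,
                             base = NULL, t_max = 1e6, probe = 1e-3,
                             lin_tol = 1e-6) {
  stopifnot(direction %in% c(1, -1))
  if (is.null(base)) base <- solve_fba(model)
  if (base$status != "optimal")
    stop("base model must be optimal (status: ", base$status, ")")
  z0 <- base$objective_value
  i <- match(metabolite_id, model$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", metabolite_id)
  b0 <- model$b[i]

  z_at <- function(t) {
    s <- solve_fba(set_rhs(model, metabolite_id, b0 + direction * t))
    if (s$status != "optimal") NA_real_ else s$objective_value
  }
  zscale <- max(1, abs(z0))

  g <- simplex_rhs_range(base$lp_solution, i)
  g_side <- if (direction > 0) g[2] else -g[1]
  g_side <- min(g_side, t_max)

  if (g_side > probe) {
    slope <- direction * base$shadow_prices[[i]]   # certified on [0, g_side]
    t_good <- g_side
  } else {
    zt <- z_at(probe)
    if (is.na(zt)) return(list(range = 0, slope = base$shadow_prices[[i]]))
    slope <- (zt - z0) / probe
    t_good <- probe
  }
  is_linear <- function(t) {
    zt <- z_at(t)
    !is.na(zt) && abs(zt - (z0 + slope * t)) <= lin_tol * zscale
  }
  # quick exit for the common nondegenerate case: nothing linear past g
  step <- max(probe, 1e-3 * t_good)
  if (t_good < t_max && !is_linear(t_good + step)) {
    return(list(range = direction * t_good, slope = direction * slope))
  }
  t_bad <- NA_real_
  while (t_good < t_max) {
    t_try <- min(2 * t_good + step, t_max)
    if (is_linear(t_try)) t_good <- t_try else { t_bad <- t_try; break }
  }
  if (!is.na(t_bad)) {
    for (k in 1:30) {
      if ((t_bad - t_good) <= 1e-6 * max(1, t_good)) break
      mid <- (t_good + t_bad) / 2
      if (is_linear(mid)) t_good <- mid else t_bad <- mid
    }
  }
  list(range = direction * t_good, slope = direction * slope)
}

#' Incremental shadow price \eqn{\lambda^+}
#'
#' Re-solves the primal with the steady-state right-hand side of one
#' metabolite set to \eqn{p \cdot G^+_i} (a fraction of its upward
#' validity range) and returns the brute-force sensitivity
#' \eqn{(Z^+ - Z) / (p G^+_i)}, i.e. the change in the optimum divided
#' by the perturbation actually applied.
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_id metabolite to perturb.
#' @param p fraction of the validity range to use, in (0,1);
#'   default 0.2.
#' @param range_high optional precomputed upward range \eqn{G^+_i};
#'   found by brute-force probing when omitted.
#' @return \eqn{\lambda^+} as a single number.
#' @export
incremental_shadow_price <- function(model, metabolite_id, p = 0.2,
                                     range_high = NULL) {
  stopifnot(p > 0, p < 1)
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("model must solve to optimality (status: ", base$status, ")")
  if (is.null(range_high))
    range_high <- value_breakpoint(model, metabolite_id, 1, base = base)$range
  if (!(range_high > 0))
    stop("cannot perturb up: G+ is not positive for ", metabolite_id)
  delta <- p * min(range_high, 1e6)
  i <- match(metabolite_id, model$metabolites$id)
  pert <- solve_fba(set_rhs(model, metabolite_id, model$b[i] + delta))
  if (pert$status != "optimal")
    stop("perturbed LP not optimal (status: ", pert$status, ")")
  (pert$objective_value - base$objective_value) / delta
}

#' Decremental shadow price \eqn{\lambda^-}
#'
#' Mirror image of \code{\link{incremental_shadow_price}}: the right-hand
#' side is set to \eqn{p \cdot G^-_i} (a fraction of the downward
#' validity range, \eqn{G^-_i < 0}) and the sensitivity
#' \eqn{(Z^- - Z)/(p G^-_i)} is returned.
#'
#' @inheritParams incremental_shadow_price
#' @param range_low optional precomputed downward range \eqn{G^-_i}
#'   (negative).
#' @return \eqn{\lambda^-} as a single number.
#' @export
decremental_shadow_price <- function(model, metabolite_id, p = 0.2,
                                     range_low = NULL) {
  stopifnot(p > 0, p < 1)
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("model must solve to optimality (status: ", base$status, ")")
  if (is.null(range_low))
    range_low <- value_breakpoint(model, metabolite_id, -1, base = base)$range
  if (!(range_low < 0))
    stop("cannot perturb down: G- is not negative for ", metabolite_id)
  delta <- p * max(range_low, -1e6)
  i <- match(metabolite_id, model$metabolites$id)
  pert <- solve_fba(set_rhs(model, metabolite_id, model$b[i] + delta))
  if (pert$status != "optimal")
    stop("perturbed LP not optimal (status: ", pert$status, ")")
  (pert$objective_value - base$objective_value) / delta
}

#' Brute-force degeneracy check of shadow prices
#'
#' For every requested metabolite, recomputes the shadow price by
#' perturbing the steady-state right-hand side a fraction \code{p} into
#' its upward range (when \eqn{G^+ > 0}) and downward range (when
#' \eqn{G^- < 0}), each by a fresh LP solve, and compares the resulting
#' \eqn{\lambda^+} and \eqn{\lambda^-} with the solver's dual value.
#' When only one direction admits a perturbation, only that direction is
#' recalculated and the other is reported as \code{NA}. Any deviation
#' beyond \code{tolerance} flags the metabolite as degenerate.
#' The input model is never modified; all perturbations run on copies.
#'
#' @param model a \code{metabolic_model}, solvable at \code{b = 0}.
#' @param metabolite_ids metabolites to check (default: all).
#' @param p perturbation fraction in (0,1); default 0.2.
#' @param tolerance comparison tolerance; defaults to 10 times the
#'   solver feasibility tolerance.
#' @return data.frame with columns \code{metabolite_id},
#'   \code{lambda_solver}, \code{lambda_plus}, \code{lambda_minus},
#'   \code{range_high}, \code{range_low}, \code{p}, \code{degenerate}.
#' @export
check_degeneracy <- function(model, metabolite_ids = NULL, p = 0.2,
                             tolerance = 1e-6) {
  stopifnot(p > 0, p < 1)
  if (is.null(metabolite_ids)) metabolite_ids <- model$metabolites$id
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("degeneracy check requires an optimal base solve (status: ",
         base$status, ")")
  rows <- lapply(metabolite_ids, function(met) {
    lam <- base$shadow_prices[[met]]
    up <- value_breakpoint(model, met, 1, base = base)
    dn <- value_breakpoint(model, met, -1, base = base)
    lam_plus <- if (up$range > 0)
      incremental_shadow_price(model, met, p, range_high = up$range)
    else NA_real_
    lam_minus <- if (dn$range < 0)
      decremental_shadow_price(model, met, p, range_low = dn$range)
    else NA_real_
    degen <- (!is.na(lam_plus) && abs(lam_plus - lam) > tolerance) ||
      (!is.na(lam_minus) && abs(lam_minus - lam) > tolerance)
    data.frame(metabolite_id = met, lambda_solver = lam,
               lambda_plus = lam_plus, lambda_minus = lam_minus,
               range_high = up$range, range_low = dn$range,
               p = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify metabolites as growth-limiting from their shadow prices
#'
#' Under growth maximization, a metabolite with a negative shadow price
#' is growth-limiting: extra outflow from it (\eqn{b_i < 0}) increases
#' the maximal growth rate. Zero shadow prices mark non-limiting
#' metabolites. Positive shadow prices of intracellular metabolites are
#' reported under their own label rather than forced into either class.
#'
#' @param records a \code{\link{shadow_price_table}} data.frame (or any
#'   data.frame with \code{metabolite_id} and \code{lambda}).
#' @param eps classification threshold on \eqn{|\lambda|}
#'   (default \code{1e-6}).
#' @return named character vector, values in
#'   \code{c("limiting", "non_limiting", "positive")}.
#' @export
classify_growth_limiting <- function(records, eps = 1e-6) {
  lam <- records$lambda
  cls <- ifelse(lam < -eps, "limiting",
                ifelse(lam > eps, "positive", "non_limiting"))
  stats::setNames(cls, records$metabolite_id)
}

#' Differential shadow prices between two strains
#'
#' Aligns the shadow-price vectors of two models with identical
#' metabolite ordering (e.g. wild type and an in-silico knockout, where
#' knockouts zero reaction bounds rather than deleting columns) and
#' reports the per-metabolite change.
#'
#' @param model_ref reference (e.g. wild-type) model.
#' @param model_alt comparison (e.g. knockout) model with the same
#'   metabolites.
#' @return data.frame with \code{metabolite_id}, \code{lambda_ref},
#'   \code{lambda_alt}, \code{delta} (alt minus ref).
#' @export
delta_shadow_prices <- function(model_ref, model_alt) {
  if (!identical(model_ref$metabolites$id, model_alt$metabolites$id))
    stop("models must share an identical metabolite ordering")
  s1 <- solve_fba(model_ref); s2 <- solve_fba(model_alt)
  for (s in list(s1, s2)) if (s$status != "optimal")
    stop("both models must solve to optimality (status: ", s$status, ")")
  data.frame(
    metabolite_id = model_ref$metabolites$id,
    lambda_ref = as.numeric(s1$shadow_prices),
    lambda_alt = as.numeric(s2$shadow_prices),
    delta = as.numeric(s2$shadow_prices - s1$shadow_prices),
    stringsAsFactors = FALSE)
}
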