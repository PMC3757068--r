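# Medium application and in-silico gene knockouts.

#' Apply a growth medium to a model
#'
#' Replaces the bounds of the exchange reactions named in the medium and
#' closes uptake (lower bound 0) for every exchange reaction the medium
#' does not mention; secretion stays as in the model. Intracellular
#' reaction bounds are never touched. The sign convention is the COBRA
#' one: negative exchange flux is uptake, positive is secretion.
#'
#' @param model a \code{metabolic_model}.
#' @param medium data.frame with columns \code{reaction_id},
#'   \code{lower_bound}, \code{upper_bound} (as read by
#'   \code{\link{read_medium}}), or an empty data.frame / \code{NULL}
#'   for a closed medium.
#' @return a modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  validate_model(model)
  if (is.null(medium) || nrow(as.data.frame(medium)) == 0) {
    medium <- data.frame(reaction_id = character(0),
                         lower_bound = numeric(0), upper_bound = numeric(0))
  }
  medium <- as.data.frame(medium, stringsAsFactors = FALSE)
  idx <- match(medium$reaction_id, model$reactions$id)
  if (anyNA(idx))
    stop("medium references unknown reaction(s): ",
         paste(medium$reaction_id[is.na(idx)], collapse = ", "))
  not_ex <- !model$reactions$is_exchange[idx]
  if (any(not_ex))
    stop("medium references non-exchange reaction(s): ",
         paste(medium$reaction_id[not_ex], collapse = ", "))
  out <- model
  ex <- which(out$reactions$is_exchange)
  closed <- setdiff(ex, idx)
  out$reactions$lower_bound[closed] <- pmax(
    out$reactions$lower_bound[closed], 0)
  out$reactions$lower_bound[idx] <- medium$lower_bound
  out$reactions$upper_bound[idx] <- medium$upper_bound
  validate_model(out)
  out
}

#' Simulate gene knockouts
#'
#' Evaluates each reaction's gene-protein-reaction rule with the knocked
#' out genes set to inactive and every other gene active; reactions whose
#' rule evaluates false have both flux bounds set to zero. Reactions
#' without a rule are untouched. Reactions are disabled in place (bounds
#' zeroed) rather than removed, so metabolite and reaction indices stay
#' aligned across strains and shadow-price tables can be compared
#' metabolite by metabolite.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_ids character vector of genes to knock out; must all be
#'   known to the model.
#' @return a modified copy of the model.
#' @export
knockout_genes <- function(model, gene_ids) {
  validate_model(model)
  gene_ids <- unique(as.character(gene_ids))
  unknown <- setdiff(gene_ids, model$genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  active <- stats::setNames(rep(TRUE, length(model$genes)), model$genes)
  active[gene_ids] <- FALSE
  out <- model
  for (j in seq_along(out$gpr_trees)) {
    tree <- out$gpr_trees[[j]]
    if (is.null(tree)) next
    if (!eval_gpr(tree, active)) {
      out$reactions$lower_bound[j] <- 0
      out$reactions$upper_bound[j] <- 0
    }
  }
  out
}
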