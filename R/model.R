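# The constraint-based metabolic model container.
#
# A model is the classical FBA quintuple: a sparse m x n stoichiometric
# matrix S over m metabolites and n reactions, flux bounds, a right-hand
# side b (rates of accumulation/depletion, zero at steady state), an
# objective weight vector c, and Boolean gene-protein-reaction rules.

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns \code{id} (unique, non-empty),
#'   \code{name} and \code{compartment} (missing columns are filled:
#'   \code{name = id}, \code{compartment = "c"}).
#' @param reactions data.frame with columns \code{id} (unique),
#'   \code{lower_bound}, \code{upper_bound}, and optionally \code{gpr}
#'   (gene-protein-reaction rule strings, \code{""} for none).
#' @param S stoichiometric matrix, m x n, rows ordered as
#'   \code{metabolites}, columns as \code{reactions}. Dense or
#'   \pkg{Matrix} sparse.
#' @param objective numeric objective weights: either length n (reaction
#'   order) or a named vector of nonzero weights by reaction id.
#'   Default all-zero.
#' @param b right-hand side vector, length m; defaults to zero
#'   (steady state).
#' @return object of class \code{metabolic_model} with derived fields
#'   \code{genes} (all gene ids appearing in rules) and
#'   \code{reactions$is_exchange} (reaction touches exactly one
#'   metabolite, i.e. a source/sink across the system boundary).
#' @export
metabolic_model <- function(metabolites, reactions, S,
                            objective = NULL, b = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""

  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)

  m <- nrow(metabolites); n <- nrow(reactions)
  if (is.null(b)) b <- rep(0, m)
  obj <- rep(0, n); names(obj) <- reactions$id
  if (!is.null(objective)) {
    if (!is.null(names(objective)) && any(nzchar(names(objective)))) {
      unknown <- setdiff(names(objective), reactions$id)
      if (length(unknown))
        stop("objective names not in model: ", paste(unknown, collapse = ", "))
      obj[names(objective)] <- objective
    } else {
      stopifnot(length(objective) == n)
      obj[] <- objective
    }
  }

  gpr_trees <- lapply(reactions$gpr, parse_gpr)
  genes <- unique(unlist(lapply(gpr_trees, gpr_genes)))
  if (is.null(genes)) genes <- character(0)
  touched <- Matrix::colSums(S != 0)
  reactions$is_exchange <- as.vector(touched == 1L)

  model <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    S = S,
    b = as.numeric(b),
    objective = obj,
    genes = genes,
    gpr_trees = gpr_trees), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty metabolite and
#' reaction ids, matching matrix dimensions, ordered bounds, non-empty
#' stoichiometry for every reaction, and \code{b} of length m.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites; rxns <- model$reactions
  if (any(!nzchar(mets$id)) || anyNA(mets$id))
    stop("metabolite ids must be non-empty")
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (nrow(model$S) != nrow(mets) || ncol(model$S) != nrow(rxns))
    stop("S dimensions (", nrow(model$S), "x", ncol(model$S),
         ") do not match metabolite/reaction counts (",
         nrow(mets), "x", nrow(rxns), ")")
  if (any(rxns$lower_bound > rxns$upper_bound))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  empty <- Matrix::colSums(model$S != 0) == 0
  if (any(empty))
    stop("reaction(s) with empty stoichiometry: ",
         paste(rxns$id[empty], collapse = ", "))
  if (length(model$b) != nrow(mets))
    stop("b must have one entry per metabolite")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model:", nrow(x$metabolites), "metabolites x",
      nrow(x$reactions), "reactions;",
      sum(x$reactions$is_exchange), "exchanges;",
      length(x$genes), "genes\n")
  nz <- x$objective[x$objective != 0]
  if (length(nz))
    cat("objective:", paste(sprintf("%g*%s", nz, names(nz)), collapse = " + "),
        "\n")
  invisible(x)
}

#' Build a model from reaction descriptions
#'
#' Convenience constructor used by the file readers and the fixture
#' generators: metabolites are collected from the reaction
#' stoichiometries.
#'
#' @param rxns list of reactions, each a list with \code{id},
#'   \code{stoich} (named numeric, metabolite id to signed
#'   coefficient), \code{lb}, \code{ub}, and optional \code{gpr}.
#' @param metabolites optional metabolite data.frame (as in
#'   \code{\link{metabolic_model}}); derived from the stoichiometries
#'   when omitted.
#' @param objective optional named objective weights by reaction id.
#' @param compartment_of optional function mapping a metabolite id to
#'   its compartment label.
#' @return a \code{\link{metabolic_model}}.
#' @export
model_from_reactions <- function(rxns, metabolites = NULL, objective = NULL,
                                 compartment_of = NULL) {
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  if (is.null(metabolites)) {
    comp <- if (is.null(compartment_of)) rep("c", length(met_ids))
            else vapply(met_ids, compartment_of, character(1))
    metabolites <- data.frame(id = met_ids, name = met_ids,
                              compartment = comp, stringsAsFactors = FALSE)
  }
  m <- nrow(metabolites); n <- length(rxns)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$stoich
    idx <- match(names(st), metabolites$id)
    if (anyNA(idx))
      stop("reaction ", rxns[[j]]$id, " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    ii <- c(ii, idx); jj <- c(jj, rep(j, length(st))); vv <- c(vv, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(m, n))
  reactions <- data.frame(
    id = vapply(rxns, `[[`, character(1), "id"),
    lower_bound = vapply(rxns, function(r) as.numeric(r$lb), numeric(1)),
    upper_bound = vapply(rxns, function(r) as.numeric(r$ub), numeric(1)),
    gpr = vapply(rxns, function(r) if (is.null(r$gpr)) "" else r$gpr,
                 character(1)),
    stringsAsFactors = FALSE)
  metabolic_model(metabolites, reactions, S, objective = objective)
}
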