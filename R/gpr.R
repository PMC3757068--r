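# Gene-protein-reaction (GPR) rules.
#
# Grammar: identifiers, AND / OR (case-insensitive), parentheses; AND binds
# tighter than OR, matching the SBML-FBC gene-association convention.
# A rule is parsed once into a nested list tree:
#   list(op = "and"|"or", args = list(...))  or  list(gene = "g1")
# and then evaluated either as a Boolean (knockouts) or over penalties
# (expression integration: OR takes the minimum across isozymes, AND the
# maximum across complex members).

gpr_tokenize <- function(text) {
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction rule
#'
#' @param text rule string such as \code{"(g1 and g2) or g3"}; \code{NA},
#'   \code{NULL} or the empty string yield \code{NULL} (no rule).
#' @return a parse tree (nested list) or \code{NULL}.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) ||
      !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(msg) stop(sprintf("malformed gpr '%s': %s", text, msg),
                             call. = FALSE)
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of rule")
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) fail("missing closing parenthesis")
      advance()
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or"))
      fail(sprintf("unexpected token '%s'", t))
    advance()
    list(gene = t)
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) { advance(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) { advance(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }

  tree <- parse_or()
  if (pos <= length(toks)) fail(sprintf("trailing token '%s'", toks[pos]))
  tree
}

#' Genes referenced by a rule
#' @param tree a parse tree from \code{\link{parse_gpr}} (or a rule string).
#' @return character vector of gene identifiers (unique, in order of
#'   first appearance); empty for a missing rule.
#' @export
gpr_genes <- function(tree) {
  if (is.character(tree)) tree <- parse_gpr(tree)
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a rule as a Boolean
#'
#' @param tree parse tree or rule string.
#' @param active named logical vector; genes absent from it are taken as
#'   active (\code{TRUE}).
#' @return logical; \code{TRUE} for a missing rule (reaction not
#'   gene-associated).
#' @export
eval_gpr <- function(tree, active) {
  if (is.character(tree)) tree <- parse_gpr(tree)
  if (is.null(tree)) return(TRUE)
  if (!is.null(tree$gene)) {
    g <- tree$gene
    if (!is.null(names(active)) && g %in% names(active)) return(unname(active[g]))
    return(TRUE)
  }
  vals <- vapply(tree$args, eval_gpr, logical(1), active = active)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Propagate gene penalties through a rule
#'
#' Isozymes (OR) take the minimum penalty -- any sufficiently expressed
#' isozyme carries the reaction; enzyme complexes (AND) take the maximum --
#' the complex is limited by its least-expressed member. Genes without a
#' penalty entry contribute 0 (no evidence, no penalty).
#'
#' @param tree parse tree or rule string.
#' @param penalties named numeric vector of nonnegative gene penalties.
#' @return nonnegative penalty; 0 for a missing rule.
#' @export
gpr_penalty <- function(tree, penalties) {
  if (is.character(tree) && length(tree) == 1L) tree <- parse_gpr(tree)
  if (is.null(tree)) return(0)
  if (!is.null(tree$gene)) {
    g <- tree$gene
    if (!is.null(names(penalties)) && g %in% names(penalties))
      return(unname(penalties[g]))
    return(0)
  }
  vals <- vapply(tree$args, gpr_penalty, numeric(1), penalties = penalties)
  if (tree$op == "and") max(vals) else min(vals)
}

# Canonical text form of a parse tree (used by the writers; round-trips
# modulo whitespace and redundant parentheses).
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (!is.null(a$op) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
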