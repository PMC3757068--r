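# Readers and writers for the three model dialects (JSON, TSV, SBML
# Level 3 + FBC v2) plus the small tabular inputs (medium, expression
# matrices, metabolite time courses).

#' Read a metabolic model
#'
#' @param path file path.
#' @param format \code{"json"}, \code{"tsv"}, \code{"sbml"}, or
#'   \code{"auto"} (default: guessed from the file extension,
#'   \code{.xml}/\code{.sbml} for SBML).
#' @return a validated \code{\link{metabolic_model}} with \code{b}
#'   initialized to zero and the objective taken from the file (all-zero
#'   if the file declares none).
#' @export
read_model <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension '.",
                          ext, "'; pass format explicitly"))
  }
  switch(format,
         json = read_model_json(path),
         tsv = read_model_tsv(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @param format \code{"json"}, \code{"tsv"} or \code{"sbml"}
#'   (\code{"auto"}: from extension).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension '.",
                          ext, "'"))
  }
  switch(format,
         json = write_model_json(model, path),
         tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

## ---- JSON dialect -------------------------------------------------------
# {metabolites:[{id,name,compartment}],
#  reactions:[{id, metabolites:{id:coef}, lower_bound, upper_bound,
#              gene_reaction_rule}],
#  objective:{reaction_id: weight}}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$reactions)) stop("JSON model '", path, "' has no reactions")
  mets <- NULL
  if (!is.null(doc$metabolites)) {
    mets <- data.frame(
      id = vapply(doc$metabolites, function(x) as.character(x$id), character(1)),
      name = vapply(doc$metabolites, function(x)
        if (is.null(x$name)) as.character(x$id) else as.character(x$name),
        character(1)),
      compartment = vapply(doc$metabolites, function(x)
        if (is.null(x$compartment)) "c" else as.character(x$compartment),
        character(1)),
      stringsAsFactors = FALSE)
  }
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("JSON model '", path, "': reaction without id")
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st))
      stop("JSON model '", path, "': reaction '", r$id,
           "' has empty stoichiometry")
    list(id = as.character(r$id), stoich = st,
         lb = if (is.null(r$lower_bound)) -Inf else r$lower_bound,
         ub = if (is.null(r$upper_bound)) Inf else r$upper_bound,
         gpr = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule)
  })
  objective <- if (!is.null(doc$objective)) unlist(doc$objective) else NULL
  model_from_reactions(rxns, metabolites = mets, objective = objective)
}

write_model_json <- function(model, path) {
  S <- model$S
  rx <- lapply(seq_len(nrow(model$reactions)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    list(id = model$reactions$id[j],
         metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                               model$metabolites$id[nz])),
         lower_bound = model$reactions$lower_bound[j],
         upper_bound = model$reactions$upper_bound[j],
         gene_reaction_rule = model$reactions$gpr[j])
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i], name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i]))
  nz <- model$objective[model$objective != 0]
  doc <- list(metabolites = mets, reactions = rx,
              objective = as.list(nz))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

## ---- TSV dialect --------------------------------------------------------
# Columns: id, equation, lb, ub, gpr, [objective]. Equation strings like
# "2 A[c] + B[c] -> C[e]"; metabolite compartments come from the bracket
# suffix (default "c"); "->" and "<->" are both accepted (reversibility
# is governed by the bounds, not the arrow).

parse_equation <- function(eq, line = NA) {
  where <- if (is.na(line)) "" else paste0(" (line ", line, ")")
  sides <- strsplit(eq, "<->|->", perl = TRUE)[[1]]
  if (length(sides) > 2)
    stop("equation with more than one arrow", where, ": ", eq)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
    st <- numeric(0)
    for (term in terms) {
      parts <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(parts) == 1) { coef <- 1; id <- parts }
      else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad stoichiometric coefficient '", parts[1],
                              "'", where, " in: ", eq)
        id <- parts[2]
      } else stop("cannot parse term '", term, "'", where, " in: ", eq)
      st[id] <- (if (is.na(st[id])) 0 else st[id]) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  st <- st[st != 0]
  if (!length(st)) stop("equation with empty net stoichiometry", where, ": ", eq)
  st
}

met_compartment <- function(id) {
  m <- regmatches(id, regexec("\\[([^]]+)\\]$", id))[[1]]
  if (length(m) == 2) m[2] else "c"
}

read_model_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("TSV parse failure in '", path, "': ",
                             conditionMessage(e)))
  need <- c("id", "equation", "lb", "ub")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("TSV model '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(tab$gpr)) tab$gpr <- ""
  tab$gpr[is.na(tab$gpr)] <- ""
  rxns <- lapply(seq_len(nrow(tab)), function(k) {
    list(id = tab$id[k],
         stoich = parse_equation(tab$equation[k], line = k + 1L),
         lb = tab$lb[k], ub = tab$ub[k], gpr = tab$gpr[k])
  })
  objective <- NULL
  if (!is.null(tab$objective)) {
    w <- tab$objective; w[is.na(w)] <- 0
    if (any(w != 0)) objective <- stats::setNames(w[w != 0], tab$id[w != 0])
  }
  model_from_reactions(rxns, objective = objective,
                       compartment_of = met_compartment)
}

format_equation <- function(model, j) {
  col <- model$S[, j]
  nz <- which(col != 0)
  fmt <- function(ids, coefs) paste(
    ifelse(coefs == 1, ids, paste(format(coefs, trim = TRUE), ids)),
    collapse = " + ")
  lhs <- nz[col[nz] < 0]; rhs <- nz[col[nz] > 0]
  paste(fmt(model$metabolites$id[lhs], -as.numeric(col[lhs])),
        "->",
        fmt(model$metabolites$id[rhs], as.numeric(col[rhs])))
}

write_model_tsv <- function(model, path) {
  tab <- data.frame(
    id = model$reactions$id,
    equation = vapply(seq_len(nrow(model$reactions)),
                      function(j) format_equation(model, j), character(1)),
    lb = model$reactions$lower_bound,
    ub = model$reactions$upper_bound,
    gpr = model$reactions$gpr,
    objective = as.numeric(model$objective),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---- SBML Level 3 + FBC v2 ---------------------------------------------

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]], fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("SBML file '", path, "' has no model element")

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE)[!boundary, , drop = FALSE]

  pars <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  assoc_to_gpr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_gpr, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", tag, "/s:speciesReference"), ns)
      ids <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      keep <- ids %in% mets$id        # drop boundary species
      stats::setNames(sign * coef[keep], ids[keep])
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    lbid <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)
    ubid <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -Inf
    ub <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else Inf
    ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_missing")) "" else {
      kids <- xml2::xml_children(ga)
      if (length(kids)) assoc_to_gpr(kids[[1]]) else ""
    }
    if (!length(st)) stop("SBML model '", path, "': reaction '", id,
                          "' has empty stoichiometry")
    list(id = id, stoich = stats::setNames(as.numeric(st), names(st)),
         lb = lb, ub = ub, gpr = gpr)
  })

  # gene product labels: rules reference fbc:id; translate to labels if given
  gps <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  if (length(gps)) {
    gid <- xml2::xml_attr(gps, "fbc:id", ns = ns)
    glab <- xml2::xml_attr(gps, "fbc:label", ns = ns)
    glab[is.na(glab)] <- gid[is.na(glab)]
    lut <- stats::setNames(glab, gid)
    rxns <- lapply(rxns, function(r) {
      if (nzchar(r$gpr)) {
        toks <- gpr_tokenize(r$gpr)
        toks <- ifelse(toks %in% names(lut), lut[toks], toks)
        tree <- parse_gpr(paste(toks, collapse = " "))
        r$gpr <- gpr_to_string(tree)
      }
      r
    })
  }

  objective <- NULL
  fobj <- xml2::xml_find_all(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(fobj)) {
    coef <- as.numeric(xml2::xml_attr(fobj, "fbc:coefficient", ns = ns))
    coef[is.na(coef)] <- 1
    objective <- stats::setNames(coef, xml2::xml_attr(fobj, "fbc:reaction", ns = ns))
  }
  model_from_reactions(rxns, metabolites = mets, objective = objective)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

gpr_to_fbc <- function(tree, indent) {
  pad <- strrep(" ", indent)
  if (!is.null(tree$gene))
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, xml_escape(tree$gene)))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(tree$args, gpr_to_fbc, character(1), indent = indent + 2)
  paste0(pad, "<", tag, '>\n',
         paste(inner, collapse = "\n"), "\n", pad, "</", tag, ">")
}

write_model_sbml <- function(model, path) {
  num <- function(x) vapply(x, function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(sprintf("par_bound_%d", seq_along(bounds)),
                         num(bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="%s" level="3" version="1" fbc:required="false">'), FBC_NS),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            xml_escape(model$metabolites$id),
            xml_escape(model$metabolites$name),
            xml_escape(model$metabolites$compartment)),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            unname(bid), names(bid)),
    '    </listOfParameters>')

  genes <- model$genes
  if (length(genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       xml_escape(genes), xml_escape(genes)),
               '    </fbc:listOfGeneProducts>')
  }

  lines <- c(lines, '    <listOfReactions>')
  for (j in seq_len(nrow(model$reactions))) {
    col <- model$S[, j]; nz <- which(col != 0)
    rid <- model$reactions$id[j]
    lbp <- bid[[num(model$reactions$lower_bound[j])]]
    ubp <- bid[[num(model$reactions$upper_bound[j])]]
    lines <- c(lines, sprintf(paste0(
      '      <reaction id="%s" reversible="%s" fast="false" ',
      'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(rid),
      if (model$reactions$lower_bound[j] < 0) "true" else "false", lbp, ubp))
    tree <- model$gpr_trees[[j]]
    if (!is.null(tree)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_to_fbc(tree, 10), '        </fbc:geneProductAssociation>')
    }
    react <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(react)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         xml_escape(model$metabolites$id[react]),
                         num(-as.numeric(col[react]))),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         xml_escape(model$metabolites$id[prod]),
                         num(as.numeric(col[prod]))),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')

  nzobj <- which(model$objective != 0)
  if (length(nzobj)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                     'fbc:coefficient="%s"/>'),
              xml_escape(names(model$objective)[nzobj]),
              num(as.numeric(model$objective[nzobj]))),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

## ---- small tabular inputs ----------------------------------------------

#' Read a medium definition
#'
#' TSV with columns \code{reaction_id}, \code{lower_bound},
#' \code{upper_bound}; one row per exchange reaction open in the medium.
#' @param path file path.
#' @return data.frame suitable for \code{\link{apply_medium}}.
#' @export
read_medium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lower_bound", "upper_bound")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("medium file '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab[need]
}

#' Read a gene-expression matrix
#'
#' TSV with gene ids in the first column and one column per sample.
#' @param path file path.
#' @return an \code{\link{expression_dataset}}.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes
  expression_dataset(values)
}

#' Read metabolite time courses
#'
#' Long-format TSV with columns \code{metabolite_id}, \code{time_min},
#' \code{value}.
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_timecourses <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "time_min", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("time-course file '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab[need]
}
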