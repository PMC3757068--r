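# End-to-end flux-imbalance report: FBA -> shadow prices -> degeneracy
# check -> growth-limitation classification, with optional expression
# and time-course joins, written as TSV/JSON bundles.

#' Default run configuration
#'
#' @param ... overrides of the default fields (unknown fields error).
#' @return a \code{run_config} list: \code{model}, \code{format},
#'   \code{medium}, \code{knockouts}, \code{tolerance},
#'   \code{eps_range}, \code{p}, \code{theta}, \code{expression},
#'   \code{expression_sample}, \code{rmf_reaction}, \code{rmf_fraction},
#'   \code{timecourses}, \code{window}, \code{nperm}, \code{center},
#'   \code{seed}, \code{outdir}.
#' @export
run_config <- function(...) {
  cfg <- list(model = NULL, format = "auto", medium = NULL,
              knockouts = character(0),
              tolerance = 1e-9, eps_range = 1e-6, p = 0.2,
              theta = 0.88, expression = NULL, expression_sample = 1L,
              rmf_reaction = NULL, rmf_fraction = 0.3,
              timecourses = NULL, window = 30,
              nperm = 1e5L, center = "mean", seed = 1L,
              outdir = ".")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full flux-imbalance report
#'
#' Loads the model (applying medium and knockouts if configured), solves
#' the growth FBA, tabulates shadow prices with validity ranges, runs
#' the brute-force degeneracy check, classifies growth-limiting
#' metabolites, and writes the report bundle into the output directory:
#' \code{shadow_prices.tsv}, \code{degeneracy.tsv},
#' \code{classification.tsv} and \code{run_metadata.json} (every
#' parameter echoed for reproducibility). When an expression matrix and
#' an RMF reaction are configured, the expression-integration analysis
#' is added (\code{team.tsv}); when time courses are configured, the
#' CV/shadow-price join and permutation test are added
#' (\code{dynamics.tsv}, \code{permutation.json}).
#'
#' Identical configurations (including seed) produce byte-identical
#' TSV output.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with the computed tables, invisibly; errors on
#'   infeasible or unbounded models.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$model)) stop("config$model is required")
  model <- if (inherits(config$model, "metabolic_model")) config$model
           else read_model(config$model, config$format)
  if (!is.null(config$medium)) {
    med <- if (is.character(config$medium)) read_medium(config$medium)
           else config$medium
    model <- apply_medium(model, med)
  }
  if (length(config$knockouts)) model <- knockout_genes(model, config$knockouts)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sol <- solve_fba(model, tol = config$tolerance)
  if (sol$status != "optimal")
    stop("model_core/lp_duality: FBA did not reach optimality (status: ",
         sol$status,
         if (!is.null(sol$infeasible_reason))
           paste0("; ", sol$infeasible_reason) else "", ")")

  spt <- shadow_price_table(model, sol, eps_range = config$eps_range)
  degen <- check_degeneracy(model, p = config$p)
  cls <- classify_growth_limiting(spt, eps = config$eps_range)
  cls_df <- data.frame(metabolite_id = names(cls), class = unname(cls),
                       stringsAsFactors = FALSE)

  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    df
  }
  write_tsv(fmt(spt), file.path(config$outdir, "shadow_prices.tsv"))
  write_tsv(fmt(degen), file.path(config$outdir, "degeneracy.tsv"))
  write_tsv(cls_df, file.path(config$outdir, "classification.tsv"))

  out <- list(model = model, fba = sol, shadow_prices = spt,
              degeneracy = degen, classification = cls_df)

  if (!is.null(config$expression) && !is.null(config$rmf_reaction)) {
    expr <- if (inherits(config$expression, "expression_dataset"))
      config$expression else read_expression(config$expression)
    thr <- gene_thresholds(expr, config$theta)
    es <- expr$values[, config$expression_sample]
    names(es) <- expr$genes
    gp <- gene_penalties(es, thr)
    cp <- reaction_penalties(model, gp)
    rmf_min <- rmf_bound(model, config$rmf_reaction, config$rmf_fraction)
    team <- solve_team(model, cp, config$rmf_reaction, rmf_min)
    team_df <- data.frame(metabolite_id = names(team$shadow_prices),
                          shadow_price = as.numeric(team$shadow_prices),
                          predicted_direction = unname(team$directions),
                          stringsAsFactors = FALSE)
    write_tsv(fmt(team_df), file.path(config$outdir, "team.tsv"))
    out$team <- team
    out$team_table <- team_df
  }

  if (!is.null(config$timecourses)) {
    tc <- if (is.data.frame(config$timecourses)) config$timecourses
          else read_timecourses(config$timecourses)
    vt <- variation_table(tc, sol$shadow_prices,
                          window_minutes = config$window)
    pt <- permutation_test(vt$lambda, vt$cv, n_perm = config$nperm,
                           center = config$center, seed = config$seed)
    vt$quadrant <- ifelse(vt$lambda < pt$m_S & vt$cv > pt$m_T,
                          "forbidden", "expected")
    write_tsv(fmt(vt), file.path(config$outdir, "dynamics.tsv"))
    jsonlite::write_json(
      list(m_S = pt$m_S, m_T = pt$m_T, p_original = pt$p_original,
           n_permutations = pt$n_permutations, p_value = pt$p_value,
           center = pt$center, seed = config$seed),
      file.path(config$outdir, "permutation.json"),
      auto_unbox = TRUE, digits = NA)
    out$dynamics <- vt
    out$permutation <- pt
  }

  meta <- config
  class(meta) <- NULL
  meta$model <- if (is.character(config$model)) config$model else "<in-memory>"
  meta$expression <- if (is.character(config$expression)) config$expression
                     else if (!is.null(config$expression)) "<in-memory>" else NULL
  meta$timecourses <- if (is.character(config$timecourses)) config$timecourses
                      else if (!is.null(config$timecourses)) "<in-memory>" else NULL
  meta$medium <- if (is.character(config$medium)) config$medium
                 else if (!is.null(config$medium)) "<in-memory>" else NULL
  meta$package_version <- as.character(utils::packageVersion("fluximba"))
  meta$objective_value <- sol$objective_value
  jsonlite::write_json(meta, file.path(config$outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
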