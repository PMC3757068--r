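#!/usr/bin/env Rscript
# Genome-scale knockout shadow-price reproduction.
#
# Recomputes wild-type vs knockout shadow-price tables on a genome-scale
# model (e.g. the E. coli reconstruction iJO1366 in SBML/FBC form, which
# must be downloaded separately -- it is not shipped with the package).
# Results are sensitive to the medium configuration and the model
# version, so the medium is an explicit input (TSV: reaction_id,
# lower_bound, upper_bound) rather than a hard-coded formulation, and
# every setting used is echoed into <outdir>/config.json alongside the
# outputs.
#
# usage:
#   Rscript scripts/reproduce_knockouts.R \
#     --model iJO1366.xml --medium minimal_nh4.tsv \
#     --knockouts b3212,b3213 --outdir results/knockout_run
#
# outputs: shadow_prices_wt.tsv, shadow_prices_ko.tsv,
#          delta_shadow_prices.tsv, config.json

suppressPackageStartupMessages(library(fluximba))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(outdir = "knockout_run", format = "auto", eps_range = 1e-6)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (i == length(args)) stop("flag --", key, " needs a value")
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
for (req in c("model", "medium")) {
  if (is.null(opt[[req]]))
    stop("--", req, " is required (the medium must be supplied explicitly; ",
         "published media do not map uniquely onto exchange bounds)")
}

model <- read_model(opt$model, opt$format)
medium <- read_medium(opt$medium)
model <- apply_medium(model, medium)
knockouts <- if (is.null(opt$knockouts)) {
  character(0)
} else {
  strsplit(opt$knockouts, ",")[[1]]
}

dir.create(opt$outdir, showWarnings = FALSE, recursive = TRUE)

wt_sol <- solve_fba(model)
if (wt_sol$status != "optimal")
  stop("wild-type FBA not optimal (status: ", wt_sol$status, ")")
wt <- shadow_price_table(model, wt_sol,
                         eps_range = as.numeric(opt$eps_range))
write.table(wt, file.path(opt$outdir, "shadow_prices_wt.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

result <- list(model = opt$model, medium = opt$medium,
               knockouts = knockouts, eps_range = opt$eps_range,
               wt_objective = wt_sol$objective_value)

if (length(knockouts)) {
  ko_model <- knockout_genes(model, knockouts)
  ko_sol <- solve_fba(ko_model)
  result$ko_status <- ko_sol$status
  if (ko_sol$status == "optimal") {
    ko <- shadow_price_table(ko_model, ko_sol,
                             eps_range = as.numeric(opt$eps_range))
    write.table(ko, file.path(opt$outdir, "shadow_prices_ko.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    delta <- delta_shadow_prices(model, ko_model)
    write.table(delta, file.path(opt$outdir, "delta_shadow_prices.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    result$ko_objective <- ko_sol$objective_value
    result$n_drop_gt_1 <- sum(delta$delta < -1)
    result$max_drop <- min(delta$delta)
    result$max_rise <- max(delta$delta)
  } else {
    message("knockout model not optimal (", ko_sol$status,
            "): ", ko_sol$infeasible_reason)
  }
}

jsonlite::write_json(result, file.path(opt$outdir, "config.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", opt$outdir)
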