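#!/usr/bin/env Rscript
# Render the evaluation tables: per comparison, the five metrics of the
# best Orig / Syn / Custom models, four decimal places, undefined values
# printed as NA — the layout of the study's results tables.

library(cogstage)

man <- jsonlite::read_json("results/pipeline/manifest.json")

mk_report <- function(m) {
  vals <- lapply(m, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  structure(c(vals, list(counts = NULL, aggregation = "pooled")),
            class = "metric_report")
}
complete <- Filter(function(r) is.null(r$skipped), man$comparisons)
results <- lapply(complete, function(r) lapply(r$metrics, mk_report))
names(results) <- vapply(complete, `[[`, "", "name")

tab <- render_report(results, "results/metrics.md")
render_report(results, "results/metrics.csv")

cat("Evaluation metrics (pooled out-of-fold confusion counts):\n\n")
print(tab[, 1:min(7, ncol(tab))], row.names = FALSE)
cat("\nFull tables: results/metrics.md, results/metrics.csv\n")
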