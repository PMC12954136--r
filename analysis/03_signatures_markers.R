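#!/usr/bin/env Rscript

## Stage 3: expression signatures and marker panels.
##
## Scores the planted gene programs across the untreated organoid
## expression profiles, correlates scores with screen viability (positive
## correlation = resistance-associated program), ordinates the samples,
## and derives per-group marker panels by one-vs-rest differential
## expression (25-sample screens cannot clear q < 0.05 for the smallest
## group, in which case panels fall back to pure effect ranking).

suppressPackageStartupMessages(library(pdoresponse))

data_dir <- "results/data"
out <- "results/03_signatures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr_df <- read.delim(file.path(data_dir, "organoid_expression.tsv"),
                      check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene
sets <- read_gmt(file.path(data_dir, "planted_programs.gmt"))
assignment <- read.delim("results/02_screen/assignment.tsv")
screen <- read.delim(file.path(data_dir, "viability.tsv"))

## per-organoid mean viability, expanded to the expression replicates
mean_viab <- rowMeans(average_replicates(screen))
organoid_of <- sub("_c[0-9]+$", "", colnames(expr))
viab <- setNames(mean_viab[organoid_of], colnames(expr))

scores <- score_genesets(expr, sets)
write.table(data.frame(geneset = rownames(scores), round(scores, 4),
                       check.names = FALSE),
            file.path(out, "program_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

corr <- correlate_scores_with_viability(scores, viab)
write.table(corr, file.path(out, "score_viability_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("score-viability correlations (positive r = resistance-linked):")
for (i in seq_len(nrow(corr))) {
  message(sprintf("  %-20s r = %+.3f, q = %.3g", corr$geneset[i],
                  corr$r[i], corr$q[i]))
}

ord <- ordinate_samples(expr)
message("PCA variance explained: ",
        paste(sprintf("%.1f%%", 100 * ord$var_explained), collapse = ", "))

labels <- setNames(assignment$group[match(organoid_of, assignment$sample)],
                   colnames(expr))
panels <- derive_marker_panels(expr, labels)
if (any(lengths(panels$panels) < 5L)) {
  message("undersized panel(s) at q < 0.05; falling back to effect ranking")
  panels <- derive_marker_panels(expr, labels, q_threshold = 1)
}
message("marker panel sizes: ",
        paste(names(panels$panels), lengths(panels$panels), sep = "=",
              collapse = ", "))
write_gmt(panels$panels, file.path(out, "marker_panels.gmt"))
for (g in names(panels$tables)) {
  write.table(panels$tables[[g]],
              file.path(out, paste0("markers_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

## over-representation of the planted programs in each panel
universe <- rownames(expr)
for (g in names(panels$panels)) {
  if (!length(panels$panels[[g]])) next
  ora <- ora_enrichment(panels$panels[[g]], sets, universe)
  top <- ora[which.min(ora$p), ]
  message(sprintf("panel %s is most enriched for %s (p = %.3g)", g,
                  top$geneset, top$p))
}
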