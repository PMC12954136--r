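#!/usr/bin/env Rscript

## Stage 4: transfer the response-group labels to the external cohort.
##
## Scores every cohort sample against the three marker panels (z-scores
## within the cohort) and assigns the argmax group, leaving samples whose
## best panel shows no significant signal as "undefined". The
## clustering-based mode is run alongside as a concordance check.

suppressPackageStartupMessages(library(pdoresponse))

out <- "results/04_transfer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr_df <- read.delim("results/data/cohort_expression.tsv",
                      check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene
panels <- read_gmt("results/03_signatures/marker_panels.gmt")

by_score <- assign_response_groups(expr, panels)
by_clust <- assign_by_clustering(expr, panels)

message("score-based labels: ",
        paste(names(table(by_score$label)), table(by_score$label),
              sep = "=", collapse = ", "))
message("cluster-based labels: ",
        paste(names(table(by_clust$label)), table(by_clust$label),
              sep = "=", collapse = ", "))
both_defined <- by_score$label != "undefined" &
  by_clust$label != "undefined"
message(sprintf("concordance on mutually defined samples: %.1f%% (n = %d)",
                100 * mean(by_score$label[both_defined] ==
                             by_clust$label[both_defined]),
                sum(both_defined)))

write.table(by_score, file.path(out, "cohort_assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(by_clust, file.path(out, "cohort_assignment_clustering.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
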