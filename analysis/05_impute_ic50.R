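#!/usr/bin/env Rscript

## Stage 5: impute log-IC50 in the external cohort and compare groups.
##
## Trains a ridge model per drug on the cell-line panel (quantile
## homogenization, top-variance gene filter, seeded 10-fold CV over a
## log-spaced penalty grid), predicts cohort log-IC50, scales per drug and
## tests the response-group ordering (Kruskal-Wallis + one-sided pairwise
## rank tests, BH within drug).

suppressPackageStartupMessages(library(pdoresponse))

out <- "results/05_ic50"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_mat <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]
  m
}
train_expr <- read_mat("results/data/cellline_expression.tsv")
response <- read_mat("results/data/cellline_ic50.tsv")
cohort <- read_mat("results/data/cohort_expression.tsv")
assignment <- read.delim("results/04_transfer/cohort_assignment.tsv")

hom <- homogenize_expression(train_expr, cohort)
pred <- sapply(rownames(response), function(d) {
  m <- fit_ridge_model(hom$train, response, d, seed = 20260921L,
                       ref_quantiles = hom$ref_quantiles)
  message(sprintf("%s: lambda = %g, training R2 = %.3f", d, m$lambda,
                  m$train_r2))
  predict_log_ic50(m, hom$target, homogenize = FALSE)
})
scaled <- scale_ic50(t(pred))
write.table(data.frame(drug = rownames(scaled), round(scaled, 4),
                       check.names = FALSE),
            file.path(out, "scaled_ic50.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cmp <- compare_groups_ic50(
  scaled, assignment,
  drug_moa = c(drug_mt = "anti_microtubule", drug_rep = "anti_replication"))
write.table(cmp$per_drug, file.path(out, "group_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp$pairwise, file.path(out, "pairwise_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("scaled IC50 group means (rows: drug):")
print(cmp$per_drug[, c("drug", "moa", "mean_double", "mean_single",
                       "mean_not", "kruskal_p")], row.names = FALSE)
message("the anti-microtubule drug should be low in double+single, the ",
        "anti-replication drug low in double only")
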