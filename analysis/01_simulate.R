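#!/usr/bin/env Rscript

## Stage 1: generate the full set of synthetic study inputs.
##
## Emulates the study geometry — 19 organoid samples screened against the
## five 5-fluorouracil-based combination regimens in triplicate, untreated
## expression profiles (three control replicates per organoid), a cell-line
## training panel with paired log-IC50 response, and an external tumor
## cohort — and writes everything, plus the planted truth, under
## results/data/. Later stages read only the data files; the truth sidecar
## is consumed exclusively by 99_report (honest-recovery separation).

suppressPackageStartupMessages(library(pdoresponse))

seed <- 20260921L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = seed)

message("screen: ", cfg$n_samples, " samples x ", nrow(cfg$regimens),
        " regimens x ", cfg$n_replicates, " replicates")
scr <- gen_viability_screen(cfg)
write.table(scr$screen, file.path(out, "viability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cfg$regimens, file.path(out, "regimens.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## untreated expression: 3 control replicates per organoid
org_labels <- setNames(rep(scr$truth$groups, each = 3L),
                       paste0(rep(names(scr$truth$groups), each = 3L),
                              "_c", 1:3))
org <- gen_expression_cohort(cfg, labels = org_labels)
expr_df <- data.frame(gene = rownames(org$expr), round(org$expr, 6),
                      check.names = FALSE)
write.table(expr_df, file.path(out, "organoid_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(org$truth$programs, file.path(out, "planted_programs.gmt"))

## cell-line training panel; group programs are latent co-expression axes
## and the two planted drugs respond to them with opposite signs
progs <- org$truth$programs
b <- 0.25
training <- gen_cellline_training(cfg, programs = progs, drug_specs = list(
  drug_mt = list(
    genes = unlist(progs, use.names = FALSE),
    beta = rep(c(-b, -b, b), times = lengths(progs))),
  drug_rep = list(
    genes = c(progs$double_sensitive, progs$not_sensitive),
    beta = rep(c(-b, b), each = length(progs$double_sensitive)))
))
write.table(data.frame(gene = rownames(training$expr),
                       round(training$expr, 6), check.names = FALSE),
            file.path(out, "cellline_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(drug = rownames(training$response),
                       round(training$response, 6), check.names = FALSE),
            file.path(out, "cellline_ic50.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## external tumor cohort: 300 samples, three programmed groups + null class
cohort_labels <- setNames(
  rep(c(names(cfg$group_sizes), "null"), each = 75L),
  sprintf("T%04d", 1:300))
cohort <- gen_target_cohort(cfg, training, labels = cohort_labels)
write.table(data.frame(gene = rownames(cohort$expr),
                       round(cohort$expr, 6), check.names = FALSE),
            file.path(out, "cohort_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## clinical outcomes tied to the not-sensitive program score (higher
## program expression -> worse prognosis), and a per-group mutation table
program_score <- colMeans(cohort$expr[progs$not_sensitive, ])
surv <- gen_survival_cohort(cfg, program_score)
write.table(surv, file.path(out, "clinical.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
mut <- gen_mutation_table(cfg, cohort_labels[cohort_labels != "null"])
write.table(data.frame(sample = rownames(mut$mut), mut$mut,
                       check.names = FALSE),
            file.path(out, "mutations.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## planted truth sidecar (report stage only)
truth <- list(
  seed = seed,
  groups = as.list(scr$truth$groups),
  moa = as.list(scr$truth$moa),
  programs = org$truth$programs,
  cohort_labels = as.list(cohort_labels),
  survival_marker = "not_sensitive_program_score",
  drugs = lapply(training$truth$drugs, function(d)
    list(genes = d$genes, beta = as.list(d$beta), noise_sd = d$noise_sd))
)
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = 10)

manifest <- list(seed = seed,
                 files = as.list(tools::md5sum(
                   file.path(out, sort(list.files(out))))))
names(manifest$files) <- sort(list.files(out))
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote ", length(manifest$files), " files under ", out)
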