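## End-to-end orchestration over synthetic inputs: simulate -> classify the
## screen -> derive markers -> transfer to an external cohort -> impute
## IC50 -> compare groups -> survival and mutation association. Every stage
## writes plain-text artifacts; a manifest records the config, seed and
## file hashes so a run can be reproduced and verified byte for byte.

#' Default pipeline configuration
#'
#' @param seed master seed; all stage streams derive from it.
#' @param out_dir output directory.
#' @param n_cohort external-cohort size (labelled 3 groups + null class).
#' @param cohort_null_fraction fraction of cohort samples with no program.
#' @param top_k marker-panel size per group.
#' @param n_top_genes genes kept in homogenization.
#' @param ... overrides for [sim_config()] fields.
#' @return a config list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = "pipeline_out",
                            n_cohort = 300L, cohort_null_fraction = 0.25,
                            top_k = 25L, n_top_genes = 1000L, ...) {
  list(seed = as.integer(seed), out_dir = out_dir,
       n_cohort = as.integer(n_cohort),
       cohort_null_fraction = cohort_null_fraction,
       top_k = as.integer(top_k), n_top_genes = n_top_genes,
       sim = list(...))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("seed", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    abort("pipeline config missing field(s): ",
          paste(missing, collapse = ", "))
  }
  defaults <- pipeline_config(seed = config$seed, out_dir = config$out_dir)
  for (f in setdiff(names(defaults), names(config))) {
    config[[f]] <- defaults[[f]]
  }
  config
}

pipeline_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes all stages in dependency order on generated data and writes the
#' artifacts (assignment, centroid, panel, transfer, prediction, comparison,
#' survival and mutation tables), a JSON summary and a manifest with file
#' hashes under `config$out_dir`. Two runs with the same seed and config
#' produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] list or path to a YAML file with the
#'   same fields.
#' @return (invisibly) a list with the in-memory stage results, the summary
#'   and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  ## --- stage: simulate the organoid screen -------------------------------
  pipeline_log("simulate", "viability screen: ", cfg$n_samples,
               " samples x ", nrow(cfg$regimens), " regimens x ",
               cfg$n_replicates, " replicates")
  scr <- gen_viability_screen(cfg)
  write_tsv(scr$screen, out("viability.tsv"))
  write_tsv(cfg$regimens, out("regimens.tsv"))

  ## --- stage: classify the screen ----------------------------------------
  cls <- classify_screen(scr$screen, cfg$regimens)
  pipeline_log("classify", "groups: ",
               paste(names(table(cls$assignment$group)),
                     table(cls$assignment$group),
                     sep = "=", collapse = ", "),
               "; separation ", signif(cls$separation, 3))
  write_tsv(cls$assignment, out("assignment.tsv"))
  write_matrix_tsv(cls$centroids, out("centroids.tsv"), id_col = "group")

  ## --- stage: organoid expression + markers ------------------------------
  ## Untreated expression profiles: three control replicates per organoid
  ## (21/27/9 samples over the 7/9/3 groups), mirroring the screen's
  ## untreated-control design.
  groups0 <- stats::setNames(cls$assignment$group, cls$assignment$sample)
  org_labels <- stats::setNames(
    rep(groups0, each = 3L),
    paste0(rep(names(groups0), each = 3L), "_c", 1:3)
  )
  org <- gen_expression_cohort(cfg, labels = org_labels)
  write_matrix_tsv(round(org$expr, 6), out("organoid_expression.tsv"))
  write_gmt(org$truth$programs, out("planted_programs.gmt"))
  panels <- derive_marker_panels(org$expr, org_labels, top_k = config$top_k)
  nonempty <- panels$panels[lengths(panels$panels) > 0L]
  pipeline_log("markers", "panel sizes: ",
               paste(names(panels$panels), lengths(panels$panels),
                     sep = "=", collapse = ", "))
  if (length(nonempty)) write_gmt(nonempty, out("marker_panels.gmt"))

  ## --- stage: cell-line training + external cohort -----------------------
  ## Two planted drugs tie response to the group programs: the
  ## anti-microtubule-like drug is cheaper to kill in the double- and
  ## single-sensitive programs, the anti-replication-like drug only in the
  ## double-sensitive program (higher program expression -> lower IC50).
  progs <- org$truth$programs
  b <- 0.25
  training <- gen_cellline_training(cfg, programs = progs, drug_specs = list(
    drug_mt = list(
      genes = c(progs$double_sensitive, progs$single_sensitive,
                progs$not_sensitive),
      beta = rep(c(-b, -b, b), times = lengths(progs))
    ),
    drug_rep = list(
      genes = c(progs$double_sensitive, progs$not_sensitive),
      beta = rep(c(-b, b), times = c(length(progs$double_sensitive),
                                     length(progs$not_sensitive)))
    )
  ))
  n_null <- round(config$n_cohort * config$cohort_null_fraction)
  per_group <- (config$n_cohort - n_null) %/% 3L
  groups <- names(cfg$group_sizes)
  lab <- c(rep(groups, each = per_group),
           rep("null", config$n_cohort - 3L * per_group))
  cohort_labels <- stats::setNames(lab, sprintf("T%04d",
                                                seq_len(config$n_cohort)))
  cohort <- gen_target_cohort(cfg, training, labels = cohort_labels,
                              programs = org$truth$programs)

  ## Tiny screens (3 samples in the smallest group) cannot clear q < 0.05
  ## in a rank test after BH over all genes; when a panel comes back with
  ## too few markers, fall back to pure effect ranking (q_threshold = 1) so
  ## the panels still come from the data only.
  usable <- all(lengths(panels$panels) >= max(5L, config$top_k %/% 5L))
  if (!usable) {
    pipeline_log("markers",
                 "undersized panel(s) at q < 0.05; using effect-ranked panels")
    panels <- derive_marker_panels(org$expr, org_labels,
                                   top_k = config$top_k, q_threshold = 1)
  }
  transfer_panels <- panels$panels
  assign_cohort <- assign_response_groups(cohort$expr, transfer_panels)
  pipeline_log("transfer", "labels: ",
               paste(names(table(assign_cohort$label)),
                     table(assign_cohort$label),
                     sep = "=", collapse = ", "))
  write_tsv(assign_cohort, out("cohort_assignment.tsv"))

  ## --- stage: IC50 imputation + group comparison -------------------------
  hom <- homogenize_expression(training$expr, cohort$expr,
                               n_top_genes = config$n_top_genes)
  predictions <- list()
  for (d in rownames(training$response)) {
    model <- fit_ridge_model(hom$train, training$response, d,
                             seed = stage_seed(config$seed, "misc"),
                             ref_quantiles = hom$ref_quantiles)
    predictions[[d]] <- predict_log_ic50(model, hom$target,
                                         homogenize = FALSE)
    pipeline_log("impute", d, ": lambda ", format(model$lambda),
                 ", training R2 ", round(model$train_r2, 3))
  }
  pred <- do.call(rbind, predictions)
  scaled <- scale_ic50(pred)
  write_matrix_tsv(round(scaled, 6), out("scaled_ic50.tsv"),
                   id_col = "drug")
  comparison <- compare_groups_ic50(
    scaled, assign_cohort,
    drug_moa = c(drug_mt = "anti_microtubule", drug_rep = "anti_replication")
  )
  write_tsv(comparison$per_drug, out("ic50_comparison.tsv"))

  ## --- stage: survival + mutations ---------------------------------------
  marker_gene <- transfer_panels[["not_sensitive"]][1L]
  surv <- gen_survival_cohort(cfg, cohort$expr[marker_gene, ])
  write_tsv(surv, out("clinical.tsv"))
  surv_res <- marker_survival_analysis(cohort$expr, marker_gene, surv)
  pipeline_log("survival", marker_gene, ": log-rank p ",
               signif(surv_res$p, 3))

  mut <- gen_mutation_table(cfg, cohort_labels[cohort_labels != "null"])
  mut_res <- mutation_enrichment(mut$mut,
                                 cohort_labels[cohort_labels != "null"])
  write_tsv(mut_res, out("mutation_enrichment.tsv"))
  pipeline_log("mutations", sum(mut_res$q < 0.05), " enriched gene-group ",
               "pairs at q < 0.05")

  ## --- summary + manifest -------------------------------------------------
  summary <- list(
    seed = config$seed,
    group_sizes = as.list(table(cls$assignment$group)),
    separation = cls$separation,
    centroids = as.data.frame(cls$centroids),
    panel_sizes = as.list(lengths(panels$panels)),
    transfer_labels = as.list(table(assign_cohort$label)),
    ic50_group_means = comparison$per_drug,
    survival = list(gene = marker_gene, p = surv_res$p,
                    hazard_ratio = surv_res$hazard_ratio),
    mutation_hits = sum(mut_res$q < 0.05)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    files = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(screen = scr, classification = cls, panels = panels,
                 cohort = cohort, assignment = assign_cohort,
                 scaled_ic50 = scaled, comparison = comparison,
                 survival = surv_res, mutations = mut_res,
                 summary = summary, manifest = manifest))
}
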