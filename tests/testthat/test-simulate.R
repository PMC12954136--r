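test_that("sim_config validates geometry and parameter ranges", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(group_sizes = c(a = 5L, b = 5L)), "sum to")
  expect_error(sim_config(baseline_viability = 1.5), "baseline_viability")
  expect_error(sim_config(noise_sd = -0.1), ">= 0")
  expect_error(sim_config(program_size = 800L), "exceeds n_genes")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
})

test_that("viability screen has forced means in the noise-free limit", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  res <- gen_viability_screen(cfg)
  mm <- average_replicates(res$screen)
  groups <- res$truth$groups
  moa <- res$truth$moa
  dbl <- names(groups)[groups == "double_sensitive"][1]
  nos <- names(groups)[groups == "not_sensitive"][1]
  mt <- names(moa)[moa == "anti_microtubule"][1]
  rep_ <- names(moa)[moa == "anti_replication"][1]
  expect_equal(mm[dbl, mt], cfg$baseline_viability - cfg$effect_mt)
  expect_equal(mm[dbl, rep_], cfg$baseline_viability - cfg$effect_rep)
  expect_equal(mm[nos, mt], cfg$baseline_viability)
  expect_equal(mm[nos, rep_], cfg$baseline_viability)
})

test_that("screen replicate noise matches planted means at default settings", {
  ## Monte-Carlo check of the generator against its own formula: empirical
  ## per-cell means over many replicates stay within 3 SE of planted means
  cfg <- sim_config(seed = 0, n_replicates = 100L)
  res <- gen_viability_screen(cfg)
  mm <- average_replicates(res$screen)
  se <- cfg$noise_sd / sqrt(100)
  expect_true(all(abs(mm - res$truth$cell_means[rownames(mm), colnames(mm)])
                  < 3 * se + 4 * se))  # a few cells may graze the bound
  expect_equal(dim(mm), c(19L, 5L))
  expect_equal(nrow(res$screen), 19L * 5L * 100L)
})

test_that("generators are byte-deterministic given (seed, config)", {
  cfg <- sim_config(seed = 42)
  a <- gen_viability_screen(cfg); b <- gen_viability_screen(cfg)
  expect_identical(a, b)
  ea <- gen_expression_cohort(cfg); eb <- gen_expression_cohort(cfg)
  expect_identical(ea, eb)
  ta <- gen_cellline_training(cfg); tb <- gen_cellline_training(cfg)
  expect_identical(ta, tb)
  ## and a different seed changes the data
  expect_false(identical(
    gen_viability_screen(sim_config(seed = 43))$screen$viability,
    a$screen$viability
  ))
})

test_that("expression cohort plants disjoint programs at the stated effect", {
  cfg <- sim_config(seed = 5)
  res <- gen_expression_cohort(cfg)
  expect_equal(dim(res$expr), c(2000L, 19L))
  progs <- res$truth$programs
  expect_length(unique(unlist(progs)), 3L * cfg$program_size)
  ## group-A program genes shifted by program_effect in group A only
  labels <- res$truth$labels
  for (g in names(progs)) {
    in_g <- names(labels)[labels == g]
    out_g <- names(labels)[labels != g]
    diff <- mean(res$expr[progs[[g]], in_g]) - mean(res$expr[progs[[g]], out_g])
    se <- sqrt(1 / length(progs[[g]]) / length(in_g) +
                 1 / length(progs[[g]]) / length(out_g))
    expect_lt(abs(diff - cfg$program_effect), 3 * se)
  }
  ## zero effect -> no separable structure
  null_res <- gen_expression_cohort(sim_config(seed = 5, program_effect = 0))
  g1 <- null_res$truth$programs[[1]]
  lab <- null_res$truth$labels
  diff0 <- mean(null_res$expr[g1, lab == names(which.max(table(lab)))]) -
    mean(null_res$expr[g1, ])
  expect_lt(abs(diff0), 0.15)
})

test_that("cell-line training set has the planted linear IC50 signal", {
  cfg <- sim_config(seed = 9, ic50_noise_sd = 0)
  res <- gen_cellline_training(cfg)
  d <- res$truth$drugs$drugA
  lin <- d$intercept + drop(crossprod(res$expr[d$genes, ], d$beta))
  expect_equal(unname(res$response["drugA", ]), unname(lin),
               tolerance = 1e-12)
  ## with noise at 0.1 x signal sd the linear score still dominates
  cfg2 <- sim_config(seed = 9)
  tr2 <- gen_cellline_training(cfg2)
  d2 <- tr2$truth$drugs$drugA
  cfg2b <- sim_config(seed = 9,
                      ic50_noise_sd = 0.1 * stats::sd(
                        drop(crossprod(tr2$expr[d2$genes, ], d2$beta))))
  tr2b <- gen_cellline_training(cfg2b)
  d2b <- tr2b$truth$drugs$drugA
  lin2 <- drop(crossprod(tr2b$expr[d2b$genes, ], d2b$beta))
  expect_gte(cor(unname(tr2b$response["drugA", ]), lin2), 0.95)
})

test_that("survival cohort respects censoring and the planted hazard ratio", {
  cfg <- sim_config(seed = 3, censor_rate = 0)
  score <- stats::setNames(rnorm(100), sprintf("P%03d", 1:100))
  surv <- gen_survival_cohort(cfg, score)
  expect_true(all(surv$event == 1L))
  expect_true(all(surv$time > 0))
  expect_error(gen_survival_cohort(cfg, c(a = NaN)), "non-finite")

  ## hr = 2: empirical median-survival ratio between strata ~ 2
  ratios <- vapply(1:40, function(i) {
    cfgi <- sim_config(seed = 1000 + i, censor_rate = 0, hr = 2)
    sc <- stats::setNames(rnorm(200), sprintf("P%03d", 1:200))
    sv <- gen_survival_cohort(cfgi, sc)
    high <- sc > stats::median(sc)
    stats::median(sv$time[!high]) / stats::median(sv$time[high])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.25)
})

test_that("mutation table plants group-enriched genes on background", {
  cfg <- sim_config(seed = 11)
  labels <- stats::setNames(rep(c("double_sensitive", "single_sensitive",
                                  "not_sensitive"), each = 30),
                            sprintf("M%03d", 1:90))
  res <- gen_mutation_table(cfg, labels, enriched_rate = 0.8,
                            background_rate = 0.05)
  expect_true(all(res$mut %in% c(0L, 1L)))
  expect_equal(rownames(res$mut), names(labels))
  g <- names(res$truth$enriched_genes)[1]
  target <- res$truth$enriched_genes[[1]]
  expect_gt(mean(res$mut[labels == target, g]),
            mean(res$mut[labels != target, g]))
  ## all-zero rates: empty table, enrichment runs without error
  res0 <- gen_mutation_table(cfg, labels, enriched_rate = 0,
                             background_rate = 0)
  expect_true(all(res0$mut == 0L))
  enr0 <- mutation_enrichment(res0$mut, labels)
  expect_equal(nrow(enr0), 0L)
})

test_that("target cohorts share training co-expression and report true IC50", {
  cfg <- sim_config(seed = 21, n_genes = 400L, n_celllines = 80L)
  tr <- gen_cellline_training(cfg)
  tg <- gen_target_cohort(cfg, tr)
  expect_equal(rownames(tg$expr), rownames(tr$expr))
  d <- tr$truth$drugs$drugA
  lin <- d$intercept + drop(crossprod(tg$expr[d$genes, ], d$beta))
  expect_equal(unname(tg$truth$log_ic50["drugA", ]), unname(lin),
               tolerance = 1e-12)
})
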