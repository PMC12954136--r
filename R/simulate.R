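## Synthetic-data generators.
##
## Every pipeline input (viability screen, expression cohorts, cell-line
## training sets, clinical tables, mutation tables) can be generated with a
## known planted truth, so recovery of the planted structure by the analysis
## operations is measurable. Generators are deterministic given (seed, config)
## and each consumes its own seed stream (see stage_seed()) so that, e.g.,
## regenerating the screen does not perturb the expression cohort.

#' The five combination chemotherapy regimens screened against the organoids
#'
#' All regimens are 5-fluorouracil-based; Comb2 and Comb3 additionally carry
#' a taxane (docetaxel or paclitaxel) and therefore act on microtubules,
#' while Comb1/4/5 act purely on DNA replication/transcription.
#'
#' @return data.frame with columns `regimen` and `drugs` (semicolon-separated).
#' @export
default_regimens <- function() {
  data.frame(
    regimen = paste0("Comb", 1:5),
    drugs = c(
      "5-fluorouracil;oxaliplatin",
      "5-fluorouracil;oxaliplatin;docetaxel",
      "5-fluorouracil;paclitaxel",
      "5-fluorouracil;irinotecan",
      "5-fluorouracil;oxaliplatin;epirubicin"
    ),
    stringsAsFactors = FALSE
  )
}

#' Median screening IC50 concentrations of the six component drugs
#'
#' Organoid-derived median IC50 values used as the screening concentrations;
#' stored as configuration constants (dose-response refitting is out of scope).
#'
#' @format data.frame with columns `drug`, `median_ic50`, `unit`.
#' @export
gc_median_ic50 <- data.frame(
  drug = c("5-fluorouracil", "docetaxel", "epirubicin",
           "irinotecan", "oxaliplatin", "paclitaxel"),
  median_ic50 = c(2.348, 16.94, 100.4, 6.729, 22.55, 10.49),
  unit = c("uM", "nM", "nM", "uM", "uM", "nM"),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generators. The
#' defaults reproduce the geometry of the organoid study: 19 samples screened
#' against 5 regimens in 3 replicates, with response-group sizes 7/9/3
#' (double-/single-/not-sensitive).
#'
#' @param seed integer master seed; all generator streams derive from it.
#' @param n_samples number of screened samples.
#' @param group_sizes named integer vector of planted response-group sizes
#'   (must sum to `n_samples`).
#' @param regimens data.frame of regimen compositions (see
#'   [default_regimens()]).
#' @param n_replicates replicates per (sample, regimen) cell.
#' @param baseline_viability mean control-normalized viability with no
#'   planted drug effect; must lie in (0, 1.2].
#' @param effect_mt viability decrement under anti-microtubule regimens for
#'   the double- and single-sensitive groups.
#' @param effect_rep additional decrement under anti-replication regimens
#'   for the double-sensitive group.
#' @param noise_sd replicate-level Gaussian noise sd (truncated at 0).
#' @param n_genes genes per expression matrix.
#' @param program_size genes per planted group program.
#' @param program_effect mean shift (z units) of a program gene in its group.
#' @param n_celllines training cell lines.
#' @param n_causal_genes causal genes per drug in the training generator.
#' @param beta_sd sd of the planted regression coefficients.
#' @param ic50_noise_sd residual sd of the planted log-IC50; `NULL` (default)
#'   sets it to half the sd of the linear signal at generation time.
#' @param n_factors latent co-expression factors in cell-line expression.
#' @param factor_var per-gene variance contributed by the latent factors
#'   (idiosyncratic variance is 1), emulating the low effective rank of real
#'   transcriptomes.
#' @param hr planted hazard ratio for survival cohorts (high vs low score).
#' @param censor_rate independent censoring fraction.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 19L,
                       group_sizes = c(double_sensitive = 7L,
                                       single_sensitive = 9L,
                                       not_sensitive = 3L),
                       regimens = default_regimens(),
                       n_replicates = 3L,
                       baseline_viability = 0.85,
                       effect_mt = 0.40,
                       effect_rep = 0.30,
                       noise_sd = 0.08,
                       n_genes = 2000L,
                       program_size = 25L,
                       program_effect = 1.0,
                       n_celllines = 200L,
                       n_causal_genes = 50L,
                       beta_sd = 1.0,
                       ic50_noise_sd = NULL,
                       n_factors = 15L,
                       factor_var = 6,
                       hr = 2.0,
                       censor_rate = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    group_sizes = group_sizes, regimens = regimens,
    n_replicates = as.integer(n_replicates),
    baseline_viability = baseline_viability,
    effect_mt = effect_mt, effect_rep = effect_rep, noise_sd = noise_sd,
    n_genes = as.integer(n_genes), program_size = as.integer(program_size),
    program_effect = program_effect,
    n_celllines = as.integer(n_celllines),
    n_causal_genes = as.integer(n_causal_genes),
    beta_sd = beta_sd, ic50_noise_sd = ic50_noise_sd,
    n_factors = as.integer(n_factors), factor_var = factor_var,
    hr = hr, censor_rate = censor_rate
  )
  if (sum(cfg$group_sizes) != cfg$n_samples) {
    abort("group_sizes must sum to n_samples (",
          sum(cfg$group_sizes), " != ", cfg$n_samples, ")")
  }
  if (is.null(names(cfg$group_sizes)) || any(names(cfg$group_sizes) == "")) {
    abort("group_sizes must be a named vector of response groups")
  }
  num_nonneg <- c("effect_mt", "effect_rep", "noise_sd", "program_effect",
                  "beta_sd", "censor_rate", "factor_var")
  for (f in num_nonneg) {
    if (cfg[[f]] < 0) abort(f, " must be >= 0")
  }
  if (cfg$baseline_viability <= 0 || cfg$baseline_viability > 1.2) {
    abort("baseline_viability must lie in (0, 1.2]")
  }
  if (!is.null(cfg$ic50_noise_sd) && cfg$ic50_noise_sd < 0) {
    abort("ic50_noise_sd must be >= 0")
  }
  if (3L * cfg$program_size > cfg$n_genes) {
    abort("program_size x 3 exceeds n_genes")
  }
  if (cfg$n_causal_genes > cfg$n_genes) {
    abort("n_causal_genes exceeds n_genes")
  }
  if (cfg$hr <= 0) abort("hr must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

planted_group_labels <- function(config) {
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  stats::setNames(groups, sprintf("S%02d", seq_len(config$n_samples)))
}

#' Generate a replicate-level viability screen with planted response groups
#'
#' Mean viability of a (sample, regimen) cell is `baseline_viability`, minus
#' `effect_mt` when the regimen is anti-microtubule and the sample's group is
#' double- or single-sensitive, minus `effect_rep` when the regimen is
#' anti-replication and the group is double-sensitive. Replicates add
#' Gaussian noise truncated at 0 (viabilities above 1 are left as-is:
#' control-normalized values can exceed 1).
#'
#' @param config a [sim_config()].
#' @return list with `screen` (long data.frame: sample, regimen, replicate,
#'   viability) and `truth` (planted group per sample, MOA class per regimen,
#'   planted cell means).
#' @export
gen_viability_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "screen"))
  groups <- planted_group_labels(config)
  moa <- annotate_moa(config$regimens)
  grid <- expand.grid(
    sample = names(groups), regimen = config$regimens$regimen,
    replicate = seq_len(config$n_replicates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- groups[grid$sample]
  m <- moa[grid$regimen]
  mu <- config$baseline_viability -
    config$effect_mt * (m == "anti_microtubule" &
                          g %in% c("double_sensitive", "single_sensitive")) -
    config$effect_rep * (m == "anti_replication" & g == "double_sensitive")
  grid$viability <- pmax(0, mu + stats::rnorm(nrow(grid), 0, config$noise_sd))
  truth <- list(
    groups = groups, moa = moa,
    cell_means = aggregate_means(mu, grid$sample, grid$regimen),
    params = config[c("baseline_viability", "effect_mt", "effect_rep",
                      "noise_sd")]
  )
  list(screen = grid, truth = truth)
}

## planted cell means as a sample x regimen matrix (deterministic part only)
aggregate_means <- function(mu, sample, regimen) {
  tab <- tapply(mu, list(sample, regimen), mean)
  tab[unique(sample), unique(regimen), drop = FALSE]
}

#' Generate a log-expression cohort with planted group programs
#'
#' Background genes are independent standard normals per gene; each response
#' group owns a disjoint program of `program_size` genes whose expression is
#' shifted by `program_effect` only in that group's samples. Samples labelled
#' `"null"` carry no program (the undefined class of the transfer step).
#'
#' @param config a [sim_config()].
#' @param labels named character vector, sample -> group or "null". Defaults
#'   to the planted screen groups.
#' @param programs optional named list group -> gene ids to reuse (e.g. so an
#'   external cohort expresses the same planted programs as the discovery
#'   cohort); default draws fresh disjoint programs from the gene universe.
#' @return list with `expr` (gene x sample matrix), `truth` (programs as a
#'   named list of gene ids, labels).
#' @export
gen_expression_cohort <- function(config, labels = NULL, programs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(labels)) labels <- planted_group_labels(config)
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    abort("labels must be uniquely named by sample")
  }
  groups <- names(config$group_sizes)
  bad <- setdiff(unique(labels), c(groups, "null"))
  if (length(bad)) abort("unknown labels: ", paste(bad, collapse = ", "))
  set.seed(stage_seed(config$seed, "expression"))
  genes <- gene_ids(config$n_genes)
  n <- length(labels)
  expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                 dimnames = list(genes, names(labels)))
  if (is.null(programs)) {
    prog_genes <- sample(genes, 3L * config$program_size)
    programs <- split(prog_genes, rep(groups, each = config$program_size))
  } else {
    missing <- setdiff(unlist(programs), genes)
    if (length(missing)) {
      abort("program gene(s) outside the gene universe: ",
            paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  for (g in groups) {
    in_g <- labels == g
    if (any(in_g)) {
      expr[programs[[g]], in_g] <- expr[programs[[g]], in_g] +
        config$program_effect
    }
  }
  list(expr = expr,
       truth = list(programs = programs[groups], labels = labels,
                    program_effect = config$program_effect))
}

#' Generate a cell-line expression + log-IC50 training set
#'
#' Cell-line expression follows a latent-factor co-expression model
#' (`n_factors` shared factors contributing `factor_var` of each gene's
#' variance on top of unit idiosyncratic noise), emulating the low effective
#' rank of real transcriptome panels. The planted log-IC50 of each drug is
#' linear in expression over a sparse causal gene set plus Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param drug_specs optional named list; each element may carry `genes`
#'   (causal gene ids) and `beta` (their coefficients) to plant a specific
#'   signal (used to tie drug response to group programs). Default: one drug
#'   `"drugA"` with `n_causal_genes` random causal genes, beta ~
#'   N(0, beta_sd).
#' @param programs optional named list group -> gene ids. When given, each
#'   program becomes an additional latent factor (unit loading on its genes),
#'   so cell lines vary continuously along the group programs just as tumor
#'   cohorts do - the premise that makes marker-based transfer of the
#'   response groups to cell-line panels meaningful.
#' @return list with `expr` (gene x line), `response` (drug x line matrix of
#'   log10 IC50), and `truth` (per-drug beta, intercept, noise sd; the factor
#'   loadings, so held-out cohorts can share the co-expression structure).
#' @export
gen_cellline_training <- function(config, drug_specs = NULL,
                                  programs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "training"))
  genes <- gene_ids(config$n_genes)
  p <- config$n_genes; n <- config$n_celllines
  loadings <- factor_loadings(config, genes, programs)
  lines <- sprintf("CL%04d", seq_len(n))
  r <- nrow(loadings)
  expr <- t(matrix(stats::rnorm(n * r), n, r) %*% loadings +
              matrix(stats::rnorm(n * p), n, p))
  dimnames(expr) <- list(genes, lines)
  if (is.null(drug_specs)) drug_specs <- list(drugA = list())
  truth_drugs <- list()
  response <- matrix(NA_real_, length(drug_specs), n,
                     dimnames = list(names(drug_specs), lines))
  for (d in names(drug_specs)) {
    spec <- drug_specs[[d]]
    causal <- spec$genes %||% sample(genes, config$n_causal_genes)
    beta <- spec$beta %||% stats::rnorm(length(causal), 0, config$beta_sd)
    if (length(beta) != length(causal)) {
      abort("drug spec for ", d, ": beta and genes lengths differ")
    }
    intercept <- spec$intercept %||% 0
    signal <- drop(crossprod(expr[causal, , drop = FALSE], beta))
    noise_sd <- config$ic50_noise_sd %||% (0.5 * stats::sd(signal))
    response[d, ] <- intercept + signal + stats::rnorm(n, 0, noise_sd)
    truth_drugs[[d]] <- list(
      genes = causal, beta = stats::setNames(beta, causal),
      intercept = intercept, noise_sd = noise_sd
    )
  }
  list(expr = expr, response = response,
       truth = list(drugs = truth_drugs, loadings = loadings,
                    programs = programs))
}

## Latent loadings: n_factors dense background factors; one extra factor
## per group program with unit loading restricted to the program's genes.
factor_loadings <- function(config, genes, programs = NULL) {
  r <- config$n_factors
  p <- length(genes)
  loadings <- matrix(stats::rnorm(r * p, 0, sqrt(config$factor_var / r)),
                     r, p, dimnames = list(paste0("F", seq_len(r)), genes))
  if (!is.null(programs)) {
    prog_rows <- matrix(0, length(programs), p,
                        dimnames = list(paste0("prog_", names(programs)),
                                        genes))
    for (g in names(programs)) {
      prog_rows[paste0("prog_", g), programs[[g]]] <- 1
    }
    loadings <- rbind(loadings, prog_rows)
  }
  loadings
}

## marginal sd of a program gene under the factor model (+1 for its
## program factor, +1 idiosyncratic)
program_gene_sd <- function(config, with_program_factor) {
  sqrt(config$factor_var + 1 + as.numeric(with_program_factor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a target expression cohort sharing training co-expression
#'
#' Draws new samples from the same latent-factor model as a training set
#' (its `truth$loadings`), optionally adding planted group programs, and
#' reports the noiseless planted log-IC50 of every training drug for the new
#' samples. This is the held-out cohort used to measure imputation recovery.
#'
#' @param config a [sim_config()].
#' @param training result of [gen_cellline_training()].
#' @param labels optional named sample -> group/"null" vector; when supplied,
#'   group program shifts are added on `programs`. `program_effect` is
#'   interpreted in z units, so the absolute shift is scaled by the
#'   marginal per-gene sd of the factor model, `sqrt(1 + factor_var)`.
#' @param programs optional named list group -> gene ids (required with
#'   `labels`).
#' @return list with `expr` (gene x sample) and `truth` (per-drug noiseless
#'   log-IC50 per sample, labels).
#' @export
gen_target_cohort <- function(config, training, labels = NULL,
                              programs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "transfer"))
  loadings <- training$truth$loadings
  genes <- colnames(loadings)
  p <- length(genes); r <- nrow(loadings)
  if (is.null(labels)) {
    labels <- stats::setNames(rep("null", 100L), sprintf("T%04d", 1:100))
  }
  n <- length(labels)
  scores <- matrix(stats::rnorm(n * r), n, r,
                   dimnames = list(names(labels), rownames(loadings)))
  trained_programs <- training$truth$programs
  if (!is.null(trained_programs)) {
    ## programs are latent factors shared with the training panel: group
    ## membership shifts the sample's program-factor score so the per-gene
    ## shift equals program_effect in z units of a program gene
    delta <- config$program_effect * program_gene_sd(config, TRUE)
    for (g in names(trained_programs)) {
      scores[labels == g, paste0("prog_", g)] <-
        scores[labels == g, paste0("prog_", g)] + delta
    }
  }
  expr <- t(scores %*% loadings + matrix(stats::rnorm(n * p), n, p))
  dimnames(expr) <- list(genes, names(labels))
  if (is.null(trained_programs) && !is.null(programs)) {
    ## training carried no program factors: shift the genes directly
    shift <- config$program_effect * program_gene_sd(config, FALSE)
    for (g in names(programs)) {
      in_g <- labels == g
      if (any(in_g)) {
        expr[programs[[g]], in_g] <- expr[programs[[g]], in_g] + shift
      }
    }
  }
  true_ic50 <- vapply(training$truth$drugs, function(d) {
    d$intercept + drop(crossprod(expr[d$genes, , drop = FALSE], d$beta))
  }, numeric(n))
  true_ic50 <- t(as.matrix(true_ic50))
  rownames(true_ic50) <- names(training$truth$drugs)
  list(expr = expr, truth = list(log_ic50 = true_ic50, labels = labels))
}

#' Generate a survival cohort tied to a marker score
#'
#' Event times are exponential with rate `base_rate * hr^(score > median)`,
#' i.e. samples above the median marker score have their hazard multiplied by
#' the planted hazard ratio. A fraction `censor_rate` of subjects is censored
#' independently at a uniform fraction of their event time.
#'
#' @param config a [sim_config()].
#' @param marker_score named numeric vector, sample -> score.
#' @param base_rate baseline hazard (per day); default gives a one-year
#'   median for the low-score stratum.
#' @return data.frame with columns sample, time (days), event (0/1).
#' @export
gen_survival_cohort <- function(config, marker_score,
                                base_rate = log(2) / 365) {
  stopifnot(inherits(config, "sim_config"))
  if (any(!is.finite(marker_score))) abort("marker_score has non-finite values")
  if (is.null(names(marker_score))) abort("marker_score must be named")
  set.seed(stage_seed(config$seed, "survival"))
  n <- length(marker_score)
  high <- marker_score > stats::median(marker_score)
  rate <- base_rate * config$hr^high
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < config$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  data.frame(
    sample = names(marker_score),
    time = pmax(time, .Machine$double.eps),
    event = as.integer(!censored),
    stringsAsFactors = FALSE
  )
}

#' Generate a binary somatic-mutation table with group-enriched genes
#'
#' Designated genes are mutated with probability `enriched_rate` in their
#' target group and `background_rate` elsewhere; all other genes mutate at
#' the background rate everywhere.
#'
#' @param config a [sim_config()].
#' @param labels named sample -> group vector.
#' @param enriched_genes named character vector gene -> target group;
#'   default plants two genes per response group (`mutA1`, `mutA2`, ...).
#' @param n_background_genes extra genes with no planted enrichment.
#' @param enriched_rate,background_rate mutation probabilities.
#' @return list with `mut` (sample x gene 0/1 matrix) and `truth`.
#' @export
gen_mutation_table <- function(config, labels,
                               enriched_genes = NULL,
                               n_background_genes = 30L,
                               enriched_rate = 0.4,
                               background_rate = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(labels))) abort("labels must be named by sample")
  set.seed(stage_seed(config$seed, "mutation"))
  groups <- intersect(names(config$group_sizes), unique(labels))
  if (is.null(enriched_genes)) {
    enriched_genes <- stats::setNames(
      rep(groups, each = 2L),
      paste0("mut", rep(seq_along(groups), each = 2L), c("a", "b"))
    )
  }
  bg <- sprintf("bg%03d", seq_len(n_background_genes))
  genes <- c(names(enriched_genes), bg)
  n <- length(labels)
  prob <- matrix(background_rate, n, length(genes),
                 dimnames = list(names(labels), genes))
  for (g in names(enriched_genes)) {
    prob[labels == enriched_genes[[g]], g] <- enriched_rate
  }
  mut <- matrix(stats::rbinom(length(prob), 1L, prob), n,
                dimnames = dimnames(prob))
  list(mut = mut,
       truth = list(enriched_genes = enriched_genes,
                    enriched_rate = enriched_rate,
                    background_rate = background_rate))
}
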