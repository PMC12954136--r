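## Somatic-mutation enrichment per response group and mutated-geneset
## prognosis.

validate_mutation_table <- function(mut) {
  if (!is.matrix(mut) || !all(mut %in% c(0, 1))) {
    abort("mutation table must be a sample x gene 0/1 matrix")
  }
  if (is.null(rownames(mut)) || anyDuplicated(rownames(mut))) {
    abort("mutation table needs unique sample rownames")
  }
  if (nrow(mut) == 0L || ncol(mut) == 0L) abort("empty mutation table")
  mut
}

#' Per-group somatic-mutation enrichment (one-vs-rest Fisher exact tests)
#'
#' For every response group and gene, tests the 2x2 table of mutated status
#' inside vs outside the group with a two-sided Fisher exact test; BH
#' adjustment is applied within each group. Genes mutated in fewer than
#' `min_mutated` samples overall are skipped. Odds ratios use the
#' Haldane-Anscombe 0.5 correction when any cell is zero, so enrichment
#' direction stays recoverable.
#'
#' @param mut sample x gene 0/1 matrix.
#' @param assignment data.frame sample, group or named sample -> group
#'   vector (groups with < 3 samples are dropped; >= 2 groups must remain).
#' @param min_mutated minimum total mutations for a gene to be tested.
#' @return data.frame group, gene, n_mut_in, n_in, n_mut_out, n_out,
#'   odds_ratio, p, q. Zero rows (without error) when no gene is testable.
#' @export
mutation_enrichment <- function(mut, assignment, min_mutated = 3L) {
  mut <- validate_mutation_table(mut)
  labels <- assignment_labels(assignment)
  labels <- labels[intersect(names(labels), rownames(mut))]
  sizes <- table(labels)
  groups <- names(sizes)[sizes >= 3L]
  if (length(groups) < 2L) abort("need >= 2 groups with >= 3 samples")
  mut <- mut[names(labels), , drop = FALSE]
  testable <- colnames(mut)[colSums(mut) >= min_mutated]
  out <- list()
  for (g in groups) {
    in_g <- labels == g
    rows <- lapply(testable, function(gene) {
      a <- sum(mut[in_g, gene])          # mutated in group
      b <- sum(in_g) - a
      c_ <- sum(mut[!in_g, gene])        # mutated outside
      d <- sum(!in_g) - c_
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L))$p.value
      or <- if (any(c(a, b, c_, d) == 0)) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      } else {
        (a * d) / (b * c_)
      }
      data.frame(group = g, gene = gene, n_mut_in = a, n_in = sum(in_g),
                 n_mut_out = c_, n_out = sum(!in_g), odds_ratio = or,
                 p = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) {
      tab$q <- stats::p.adjust(tab$p, method = "BH")
      out[[g]] <- tab
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(), gene = character(),
                      n_mut_in = integer(), n_in = integer(),
                      n_mut_out = integer(), n_out = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prognosis of carrying a mutation in a gene set
#'
#' Stratifies samples by whether at least one gene of `gene_list` is
#' mutated and runs a log-rank test against survival.
#'
#' @param mut sample x gene 0/1 matrix.
#' @param gene_list non-empty character vector of table genes.
#' @param surv data.frame sample, time, event.
#' @return [logrank_test()] result plus the `mutated` indicator.
#' @export
geneset_mutation_prognosis <- function(mut, gene_list, surv) {
  mut <- validate_mutation_table(mut)
  if (!length(gene_list)) abort("empty gene list: stratification degenerate")
  missing <- setdiff(gene_list, colnames(mut))
  if (length(missing)) {
    abort("gene(s) not in the table: ", paste(missing, collapse = ", "))
  }
  shared <- intersect(rownames(mut), surv$sample)
  ind <- rowSums(mut[shared, gene_list, drop = FALSE]) > 0
  if (length(unique(ind)) < 2L) {
    abort("all samples fall in one stratum; prognosis test undefined")
  }
  strata <- stats::setNames(ifelse(ind, "mutated", "wildtype"), shared)
  res <- logrank_test(surv[surv$sample %in% shared, , drop = FALSE], strata)
  res$mutated <- strata
  res
}
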