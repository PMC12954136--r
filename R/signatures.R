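## Gene-signature scoring, differential expression, marker derivation,
## over-representation analysis and ordination.

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name <tab> description <tab> gene1 <tab> gene2 ...`.
#' @return named list of character vectors (duplicate genes dropped; empty
#'   sets rejected).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) abort("malformed GMT line: ", f[1L])
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  if (any(lengths(sets) == 0L)) {
    abort("empty gene set(s): ",
          paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  desc <- rep_len(description, length(sets))
  lines <- mapply(function(name, d, genes) {
    paste(c(name, d, genes), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Score samples against gene sets (mean of per-gene z-scores)
#'
#' Each gene present in the matrix is z-scored across samples (constant
#' genes contribute 0); a sample's score for a set is the mean z over the
#' set's present genes. Scores are therefore invariant to per-gene affine
#' rescaling of the input and to gene order.
#'
#' @param expr gene x sample log-expression matrix.
#' @param sets named list of character vectors (or a single character vector
#'   for one set).
#' @return geneset x sample score matrix. Sets with no genes in the matrix
#'   raise an error; partially missing genes are reported via a message.
#' @export
score_genesets <- function(expr, sets) {
  assert_finite_matrix(expr, "expression matrix")
  if (!is.list(sets)) sets <- list(geneset = sets)
  z <- zscore_rows(expr)
  present <- lapply(sets, intersect, x = rownames(expr))
  none <- names(sets)[lengths(present) == 0L]
  if (length(none)) {
    abort("gene set(s) with no genes in the matrix: ",
          paste(none, collapse = ", "))
  }
  n_missing <- lengths(sets) - lengths(present)
  if (any(n_missing > 0L)) {
    message(sum(n_missing), " set gene(s) absent from the matrix")
  }
  out <- t(vapply(present, function(g) {
    colMeans(z[g, , drop = FALSE])
  }, numeric(ncol(expr))))
  rownames(out) <- names(sets)
  out
}

#' Correlate geneset scores with sample viability
#'
#' Pearson (default) or Spearman correlation of each geneset score with mean
#' viability across the shared samples, BH-adjusted across genesets.
#' Positive r means a higher score accompanies higher viability, i.e. worse
#' killing (a resistance-associated program).
#'
#' @param scores geneset x sample score matrix.
#' @param viability named sample -> mean viability vector.
#' @param method "pearson" or "spearman".
#' @return data.frame geneset, r, p, q (NA for zero-variance scores).
#' @export
correlate_scores_with_viability <- function(scores, viability,
                                            method = c("pearson",
                                                       "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(scores), names(viability))
  if (length(shared) < 3L) abort("fewer than 3 shared samples")
  v <- viability[shared]
  res <- lapply(rownames(scores), function(s) {
    x <- scores[s, shared]
    if (stats::sd(x) == 0 || stats::sd(v) == 0) {
      return(data.frame(geneset = s, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, v, method = method, exact = FALSE)
    data.frame(geneset = s, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

## Two-sided Wilcoxon rank-sum p; exact enumeration when both sides are
## small and there are no ties, normal approximation (with continuity
## correction) otherwise.
wilcox_p <- function(a, b, exact_max = 10L) {
  if (stats::sd(c(a, b)) == 0) return(1)
  use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Per-gene differential expression between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per gene (exact enumeration when both
#' groups have <= 10 samples and no ties), BH adjustment across genes;
#' effect size is the difference of group means on the log scale.
#'
#' @param expr gene x sample matrix.
#' @param group_a,group_b disjoint character vectors of sample ids
#'   (>= 2 each).
#' @return data.frame gene, effect (meanA - meanB), p, q.
#' @export
differential_expression <- function(expr, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    abort("groups overlap: ",
          paste(intersect(group_a, group_b), collapse = ", "))
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) {
    abort("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs >= 2 samples")
  }
  A <- expr[, group_a, drop = FALSE]
  B <- expr[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)),
              function(i) wilcox_p(A[i, ], B[i, ]), numeric(1))
  data.frame(
    gene = rownames(expr),
    effect = rowMeans(A) - rowMeans(B),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' Derive per-group marker panels from untreated-sample expression
#'
#' One-vs-rest differential expression per response group; a group's
#' markers are the genes with q below `q_threshold` and positive effect
#' (over-expressed in the group), ranked by effect, truncated at `top_k`.
#' A gene selected by several groups is kept only for the group where its
#' effect is largest, so panels are disjoint.
#'
#' @param expr gene x sample matrix of untreated samples.
#' @param assignment data.frame with columns sample, group (as produced by
#'   [name_response_groups()]), or a named sample -> group vector.
#' @param top_k maximum markers per group (default 25).
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @return list with `panels` (named list group -> ordered marker genes) and
#'   `tables` (per-group data.frames gene, effect, p, q).
#' @export
derive_marker_panels <- function(expr, assignment, top_k = 25L,
                                 q_threshold = 0.05) {
  labels <- assignment_labels(assignment)
  labels <- labels[intersect(names(labels), colnames(expr))]
  groups <- unique(labels)
  if (length(groups) < 2L) abort("need >= 2 groups with expression data")
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    abort("group(s) below minimum size 2: ",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  tables <- lapply(groups, function(g) {
    de <- differential_expression(expr,
                                  names(labels)[labels == g],
                                  names(labels)[labels != g])
    de[de$q < q_threshold & de$effect > 0, , drop = FALSE]
  })
  names(tables) <- groups
  ## resolve cross-group duplicates to the group with the larger effect
  all_hits <- do.call(rbind, lapply(groups, function(g) {
    t <- tables[[g]]
    if (nrow(t)) cbind(t, group = g) else NULL
  }))
  panels <- stats::setNames(
    rep(list(character(0)), length(groups)), groups)
  if (!is.null(all_hits) && nrow(all_hits)) {
    all_hits <- all_hits[order(-all_hits$effect), ]
    all_hits <- all_hits[!duplicated(all_hits$gene), ]
    for (g in groups) {
      hits <- all_hits[all_hits$group == g, ]
      panels[[g]] <- utils::head(hits$gene[order(-hits$effect)], top_k)
    }
  }
  list(panels = panels, tables = tables)
}

assignment_labels <- function(assignment) {
  if (is.data.frame(assignment)) {
    if (!all(c("sample", "group") %in% names(assignment))) {
      abort("assignment needs columns sample, group")
    }
    stats::setNames(assignment$group, assignment$sample)
  } else {
    if (is.null(names(assignment))) abort("assignment must be named")
    assignment
  }
}

#' Hypergeometric over-representation of gene sets in a hit list
#'
#' Upper-tail hypergeometric test of the overlap between `hits` and each
#' gene set within `universe`; BH adjustment across the sets tested.
#' Fold-enrichment is (overlap / n_hits) / (set size / universe size).
#'
#' @param hits character vector of hit genes (subset of the universe).
#' @param sets named list of gene sets (restricted to the universe).
#' @param universe character vector of all testable genes.
#' @return data.frame geneset, overlap, set_size, fold_enrichment, p, q.
#' @export
ora_enrichment <- function(hits, sets, universe) {
  if (!length(universe)) abort("empty universe")
  universe <- unique(universe)
  hits <- unique(intersect(hits, universe))
  if (!is.list(sets)) sets <- list(geneset = sets)
  res <- lapply(names(sets), function(s) {
    set <- unique(intersect(sets[[s]], universe))
    ov <- length(intersect(hits, set))
    p <- stats::phyper(ov - 1L, length(set),
                       length(universe) - length(set),
                       length(hits), lower.tail = FALSE)
    fe <- if (length(hits) && length(set)) {
      (ov / length(hits)) / (length(set) / length(universe))
    } else NA_real_
    data.frame(geneset = s, overlap = ov, set_size = length(set),
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Principal-component ordination of samples
#'
#' PCA of centered sample profiles. The sign of each component is fixed so
#' that its largest-magnitude gene loading is positive, making coordinates
#' reproducible across runs and platforms.
#'
#' @param expr gene x sample matrix.
#' @param n_components number of components to return (default 2).
#' @return list with `coordinates` (sample x component), `var_explained`
#'   (fraction per component) and `loadings` (gene x component).
#' @export
ordinate_samples <- function(expr, n_components = 2L) {
  if (ncol(expr) < 2L) abort("need >= 2 samples")
  n_components <- min(n_components, ncol(expr) - 1L, nrow(expr))
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  coords <- pc$x[, k, drop = FALSE]
  for (j in k) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, var_explained = ve[k], loadings = rot)
}
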