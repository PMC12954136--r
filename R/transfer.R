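## Transfer of response-group labels to external expression cohorts via
## marker panels, with an explicit undefined class for samples expressing
## none of the three marker programs.

#' Assign cohort samples to response groups by marker-panel scores
#'
#' Each sample is scored against every group panel with the mean-z score of
#' [score_genesets()] (z-scores computed within the target cohort; no
#' cross-cohort reference is used). The label is the argmax panel; a sample
#' is `undefined` when its best panel shows no real signal. Two undefined
#' rules are available:
#'
#' * default (`tau = NULL`): the best panel's mean z must be significantly
#'   greater than 0 by a one-sided t-test across the panel's genes at level
#'   `alpha`. This calibrates the call against the panel size, so
#'   background-only samples are left undefined at rate ~ 1 - alpha^3.
#' * fixed threshold (`tau` numeric): undefined when the best score is
#'   <= `tau`.
#'
#' In both modes a sample is also undefined when the margin between the top
#' two scores is below `delta` (default 0, i.e. inactive).
#'
#' @param expr gene x sample cohort matrix.
#' @param panels named list group -> marker genes.
#' @param tau numeric score threshold, or NULL (default) for the
#'   significance rule.
#' @param delta minimum winning margin (default 0).
#' @param alpha level of the one-sided t rule (default 0.05).
#' @return data.frame: sample, label (group or "undefined"), one
#'   `score_<group>` column per panel, margin, best_t.
#' @export
assign_response_groups <- function(expr, panels, tau = NULL, delta = 0,
                                   alpha = 0.05) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  present <- lapply(panels, intersect, x = rownames(expr))
  none <- names(panels)[lengths(present) == 0L]
  if (length(none)) {
    abort("panel(s) with zero overlap with the cohort: ",
          paste(none, collapse = ", "))
  }
  z <- zscore_rows(expr)
  scores <- t(vapply(present, function(g) colMeans(z[g, , drop = FALSE]),
                     numeric(ncol(expr))))
  tstat <- t(vapply(present, function(g) {
    zz <- z[g, , drop = FALSE]
    k <- nrow(zz)
    if (k < 2L) return(rep(Inf, ncol(zz)))
    se <- apply(zz, 2L, stats::sd) / sqrt(k)
    ifelse(se > 0, colMeans(zz) / se, 0)
  }, numeric(ncol(expr))))
  best <- apply(scores, 2L, which.max)
  best_score <- scores[cbind(best, seq_along(best))]
  second <- apply(scores, 2L, function(s) sort(s, decreasing = TRUE)[2L])
  margin <- best_score - second
  best_t <- tstat[cbind(best, seq_along(best))]

  if (is.null(tau)) {
    k_min <- min(lengths(present))
    crit <- stats::qt(1 - alpha, df = max(k_min - 1L, 1L))
    defined <- best_t > crit
  } else {
    defined <- best_score > tau
  }
  defined <- defined & margin >= delta
  label <- ifelse(defined, names(panels)[best], "undefined")

  out <- data.frame(sample = colnames(expr), label = label,
                    stringsAsFactors = FALSE)
  for (g in names(panels)) out[[paste0("score_", g)]] <- scores[g, ]
  out$margin <- margin
  out$best_t <- best_t
  out
}

#' Assign cohort samples to response groups by unsupervised clustering
#'
#' Agglomerative clustering of samples restricted to the panel genes
#' (z-scored), `k` clusters; each cluster is labelled by the panel with the
#' highest cluster-mean score. When two clusters claim the same panel
#' (a collision), their samples are left undefined.
#'
#' @param expr gene x sample cohort matrix.
#' @param panels named list group -> marker genes.
#' @param k number of clusters (default one per panel).
#' @param distance,linkage see [cluster_samples()].
#' @return data.frame sample, label, cluster.
#' @export
assign_by_clustering <- function(expr, panels, k = length(panels),
                                 distance = "euclidean",
                                 linkage = "ward.D2") {
  genes <- intersect(unlist(panels), rownames(expr))
  if (!length(genes)) abort("no panel genes present in the cohort")
  if (k > ncol(expr)) abort("k exceeds the number of samples")
  z <- zscore_rows(expr[genes, , drop = FALSE])
  cl <- hclust_rows(t(z), k, distance, linkage)
  scores <- t(vapply(panels, function(g) {
    colMeans(z[intersect(g, genes), , drop = FALSE])
  }, numeric(ncol(expr))))
  cl_label <- vapply(sort(unique(cl)), function(cc) {
    names(panels)[which.max(rowMeans(scores[, cl == cc, drop = FALSE]))]
  }, character(1))
  collided <- cl_label %in% cl_label[duplicated(cl_label)]
  cl_label[collided] <- "undefined"
  data.frame(sample = colnames(expr),
             label = unname(cl_label[cl]),
             cluster = unname(cl),
             stringsAsFactors = FALSE)
}
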