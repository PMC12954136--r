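## Drug-screen viability processing and response-group classification.
##
## The screen design: each organoid sample is exposed to five combination
## regimens for five days, viability (CellTiter-Glo style signal) is
## normalized to the sample's untreated control, replicates are averaged,
## and the sample x regimen matrix is bi-clustered: regimens into two
## mechanism-of-action (MOA) classes and samples into three response groups,
## which are then named semantically from the class centroids.

TAXANES <- c("docetaxel", "paclitaxel")
RESPONSE_GROUPS <- c("double_sensitive", "single_sensitive", "not_sensitive")

#' Normalize raw screen signal to per-sample untreated controls
#'
#' @param raw long data.frame: sample, regimen, replicate, signal.
#' @param control data.frame: sample, replicate, signal (untreated wells).
#' @return long data.frame sample, regimen, replicate, viability where
#'   viability = signal / mean(control signal of that sample). Values are
#'   not clamped at 1: control-normalized viabilities above 1 occur.
#' @export
normalize_to_control <- function(raw, control) {
  need <- c("sample", "regimen", "replicate", "signal")
  if (!all(need %in% names(raw))) {
    abort("raw must have columns ", paste(need, collapse = ", "))
  }
  if (!all(c("sample", "signal") %in% names(control))) {
    abort("control must have columns sample, signal")
  }
  ctrl_mean <- tapply(control$signal, control$sample, mean)
  bad <- names(ctrl_mean)[!is.finite(ctrl_mean) | ctrl_mean <= 0]
  if (length(bad)) {
    abort("non-positive control mean for sample(s): ",
          paste(bad, collapse = ", "))
  }
  missing <- setdiff(unique(raw$sample), names(ctrl_mean))
  if (length(missing)) {
    abort("no control wells for sample(s): ", paste(missing, collapse = ", "))
  }
  out <- raw[c("sample", "regimen", "replicate")]
  out$viability <- raw$signal / ctrl_mean[raw$sample]
  validate_screen(out)
}

## shared load-time checks for a viability screen
validate_screen <- function(screen) {
  need <- c("sample", "regimen", "replicate", "viability")
  if (!all(need %in% names(screen))) {
    abort("screen must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(screen$viability))) {
    abort("screen contains non-finite viabilities")
  }
  if (any(screen$viability < 0)) abort("screen contains negative viabilities")
  screen
}

#' Average replicate viabilities into a sample x regimen matrix
#'
#' @param screen long viability data.frame (see [normalize_to_control()]).
#' @return numeric matrix, samples as rows, regimens as columns, each cell
#'   the arithmetic mean of its replicates.
#' @export
average_replicates <- function(screen) {
  screen <- validate_screen(screen)
  mat <- tapply(screen$viability, list(screen$sample, screen$regimen), mean)
  if (any(is.na(mat))) {
    empty <- which(is.na(mat), arr.ind = TRUE)
    abort("empty (sample, regimen) cell(s): ",
          paste(rownames(mat)[empty[, 1]], colnames(mat)[empty[, 2]],
                sep = "/", collapse = ", "))
  }
  ## tapply sorts levels; restore input order
  mat[unique(screen$sample), unique(screen$regimen), drop = FALSE]
}

#' Annotate regimens with their mechanism-of-action class
#'
#' A regimen containing a taxane (docetaxel or paclitaxel, which stabilize
#' microtubules) is `anti_microtubule`; all others are `anti_replication`
#' (their drugs inhibit DNA replication/transcription). Unknown drug names
#' are treated as non-taxane with a warning.
#'
#' @param regimen_composition data.frame with columns `regimen` and `drugs`
#'   (semicolon-separated), or a named list regimen -> character vector.
#' @return named character vector regimen -> MOA class.
#' @export
annotate_moa <- function(regimen_composition) {
  comp <- regimen_drug_list(regimen_composition)
  known <- c(TAXANES, "5-fluorouracil", "5-fu", "oxaliplatin", "irinotecan",
             "epirubicin")
  all_drugs <- tolower(unlist(comp))
  unknown <- setdiff(unique(all_drugs), known)
  if (length(unknown)) {
    warning("unknown drug(s) treated as non-taxane: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(comp, function(drugs) {
    if (any(tolower(drugs) %in% TAXANES)) "anti_microtubule"
    else "anti_replication"
  }, character(1))
}

regimen_drug_list <- function(regimen_composition) {
  if (is.data.frame(regimen_composition)) {
    if (!all(c("regimen", "drugs") %in% names(regimen_composition))) {
      abort("regimen composition needs columns regimen, drugs")
    }
    comp <- strsplit(regimen_composition$drugs, ";", fixed = TRUE)
    names(comp) <- regimen_composition$regimen
  } else {
    comp <- regimen_composition
  }
  comp <- lapply(comp, function(d) trimws(d))
  if (any(lengths(comp) == 0L)) abort("every regimen must list >= 1 drug")
  comp
}

## Agglomerative (Ward, Euclidean by default) clustering of matrix rows.
## Ties are resolved by stats::hclust's agglomeration order, which is
## deterministic for a fixed input ordering.
hclust_rows <- function(mat, k, distance = "euclidean",
                        linkage = "ward.D2") {
  if (k > nrow(mat)) {
    abort("k = ", k, " exceeds the number of items (", nrow(mat), ")")
  }
  hc <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  stats::cutree(hc, k = k)
}

#' Cluster regimens into treatment classes from the mean-viability matrix
#'
#' Hierarchical (agglomerative) clustering of the regimen columns; the
#' cluster with the lower grand-mean viability (the stronger killing) is
#' reported first. When an MOA annotation is supplied, concordance between
#' the data-driven partition and the annotation is reported.
#'
#' @param mean_matrix sample x regimen mean-viability matrix.
#' @param k number of treatment classes (default 2).
#' @param distance,linkage dissimilarity and agglomeration method
#'   (defaults: Euclidean, Ward).
#' @param moa optional named regimen -> MOA class vector to compare against.
#' @return list with `cluster` (named integer, 1 = lower grand-mean
#'   viability), `grand_means` per cluster, and `moa_concordant` (logical or
#'   NA when no annotation given: TRUE iff the partition separates the MOA
#'   classes exactly).
#' @export
cluster_treatments <- function(mean_matrix, k = 2L,
                               distance = "euclidean", linkage = "ward.D2",
                               moa = NULL) {
  cl <- hclust_rows(t(mean_matrix), k, distance, linkage)
  gm <- tapply(colMeans(mean_matrix)[names(cl)], cl, mean)
  ord <- order(gm)  # lower viability class first
  relabel <- stats::setNames(seq_along(ord), ord)
  cl <- stats::setNames(as.integer(relabel[as.character(cl)]), names(cl))
  concordant <- NA
  if (!is.null(moa)) {
    concordant <- length(unique(paste(cl, moa[names(cl)]))) ==
      length(unique(cl)) &&
      length(unique(moa[names(cl)])) == length(unique(cl))
    message("treatment partition ",
            if (isTRUE(concordant)) "matches" else "differs from",
            " the MOA annotation")
  }
  list(cluster = cl, grand_means = sort(gm), moa_concordant = concordant)
}

#' Cluster samples into response clusters from the mean-viability matrix
#'
#' @param mean_matrix sample x regimen mean-viability matrix (or the 2-column
#'   MOA-class mean variant).
#' @param k number of clusters (default 3).
#' @param distance,linkage see [cluster_treatments()].
#' @return named integer vector of arbitrary cluster indices (naming happens
#'   in [name_response_groups()]).
#' @export
cluster_samples <- function(mean_matrix, k = 3L,
                            distance = "euclidean", linkage = "ward.D2") {
  hclust_rows(mean_matrix, k, distance, linkage)
}

#' Collapse a mean-viability matrix to MOA-class means per sample
#'
#' @param mean_matrix sample x regimen matrix.
#' @param partition named regimen -> MOA class vector.
#' @return sample x MOA-class matrix of mean viabilities.
#' @export
moa_class_means <- function(mean_matrix, partition) {
  classes <- sort(unique(partition))
  out <- vapply(classes, function(cl) {
    rowMeans(mean_matrix[, names(partition)[partition == cl], drop = FALSE])
  }, numeric(nrow(mean_matrix)))
  colnames(out) <- classes
  out
}

#' Name sample clusters as chemotherapy response groups
#'
#' Computes the 3 x 2 centroid table (mean viability per cluster per MOA
#' class) and applies the semantic rule: the cluster with the lowest
#' anti-replication centroid is `double_sensitive` (it responds to both
#' classes), the cluster with the highest anti-microtubule centroid is
#' `not_sensitive` (it responds to neither), and the remaining cluster is
#' `single_sensitive`. If both rules select the same cluster the assignment
#' fails loudly with the centroid table in the message. Each sample is also
#' flagged `resistant` when its mean viability under the reference
#' 5-fluorouracil + oxaliplatin regimen exceeds `resistant_threshold`
#' (an annotation only; it plays no part in naming).
#'
#' @param clusters named sample -> cluster index vector (from
#'   [cluster_samples()]).
#' @param partition named regimen -> MOA class vector.
#' @param mean_matrix sample x regimen mean-viability matrix.
#' @param resistant_threshold viability above which the flag is set
#'   (default 0.75).
#' @param resistant_regimen regimen used for the flag; default picks the
#'   regimen whose composition is exactly 5-fluorouracil + oxaliplatin if a
#'   `composition` is supplied, else the first anti-replication regimen.
#' @param composition optional regimen composition (see [annotate_moa()])
#'   used to resolve the reference regimen.
#' @return list with `assignment` (data.frame sample, group,
#'   resistant_flag), `centroids` (3 x 2 matrix, rows named by group),
#'   `separation` (minimum between-centroid distance over mean within-cluster
#'   spread; small values flag unconvincing splits).
#' @export
name_response_groups <- function(clusters, partition, mean_matrix,
                                 resistant_threshold = 0.75,
                                 resistant_regimen = NULL,
                                 composition = NULL) {
  if (length(unique(clusters)) != 3L) {
    abort("exactly 3 sample clusters are required")
  }
  if (length(unique(partition)) != 2L) {
    abort("exactly 2 MOA classes are required")
  }
  cm <- moa_class_means(mean_matrix, partition)[names(clusters), ,
                                                drop = FALSE]
  centroids <- rbind(
    tapply(cm[, "anti_microtubule"], clusters, mean),
    tapply(cm[, "anti_replication"], clusters, mean)
  )
  rownames(centroids) <- c("anti_microtubule", "anti_replication")
  centroids <- t(centroids)  # cluster x MOA class

  dbl <- rownames(centroids)[which.min(centroids[, "anti_replication"])]
  nots <- rownames(centroids)[which.max(centroids[, "anti_microtubule"])]
  if (dbl == nots) {
    abort("response-group naming collision: the lowest anti-replication and ",
          "highest anti-microtubule centroids pick the same cluster.\n",
          paste(utils::capture.output(print(centroids)), collapse = "\n"))
  }
  sgl <- setdiff(rownames(centroids), c(dbl, nots))
  name_of <- stats::setNames(RESPONSE_GROUPS, c(dbl, sgl, nots))
  group <- unname(name_of[as.character(clusters)])

  rownames(centroids) <- name_of[rownames(centroids)]
  centroids <- centroids[RESPONSE_GROUPS, , drop = FALSE]

  ## separation: smallest centroid gap relative to mean within-cluster spread
  d <- as.matrix(stats::dist(centroids))
  gap <- min(d[upper.tri(d)])
  within <- mean(vapply(split(seq_along(clusters), clusters), function(idx) {
    if (length(idx) < 2L) return(0)
    mean(apply(cm[idx, , drop = FALSE], 2L, stats::sd))
  }, numeric(1)))
  separation <- if (within > 0) gap / within else Inf

  ref <- resolve_resistant_regimen(resistant_regimen, partition, composition,
                                   colnames(mean_matrix))
  flag <- mean_matrix[names(clusters), ref] > resistant_threshold

  list(
    assignment = data.frame(
      sample = names(clusters), group = group,
      resistant_flag = unname(flag), stringsAsFactors = FALSE
    ),
    centroids = centroids,
    separation = separation,
    resistant_regimen = ref
  )
}

resolve_resistant_regimen <- function(resistant_regimen, partition,
                                      composition, regimens) {
  if (!is.null(resistant_regimen)) {
    if (!resistant_regimen %in% regimens) {
      abort("resistant_regimen ", resistant_regimen, " not in the matrix")
    }
    return(resistant_regimen)
  }
  if (!is.null(composition)) {
    comp <- regimen_drug_list(composition)
    is_ref <- vapply(comp, function(d) {
      setequal(tolower(d), c("5-fluorouracil", "oxaliplatin")) ||
        setequal(tolower(d), c("5-fu", "oxaliplatin"))
    }, logical(1))
    if (any(is_ref)) return(names(comp)[which(is_ref)[1L]])
  }
  anti_rep <- names(partition)[partition == "anti_replication"]
  anti_rep <- intersect(regimens, anti_rep)
  if (!length(anti_rep)) abort("no anti-replication regimen for the flag")
  anti_rep[1L]
}

#' Classify a viability screen end to end
#'
#' Convenience wrapper: average replicates, annotate MOA (with a
#' data-driven cross-check), cluster samples, and name the response groups.
#'
#' @param screen long viability data.frame.
#' @param composition regimen composition (see [annotate_moa()]).
#' @param on_moa_means cluster samples on the 2-column MOA-class mean matrix
#'   instead of the full regimen matrix (default FALSE).
#' @param ... passed to [name_response_groups()].
#' @return the [name_response_groups()] result, plus `mean_matrix`,
#'   `partition` and `treatment_clustering`.
#' @export
classify_screen <- function(screen, composition, on_moa_means = FALSE, ...) {
  mean_matrix <- average_replicates(screen)
  partition <- annotate_moa(composition)
  partition <- partition[colnames(mean_matrix)]
  tc <- suppressMessages(
    cluster_treatments(mean_matrix, moa = partition)
  )
  feat <- if (on_moa_means) moa_class_means(mean_matrix, partition)
          else mean_matrix
  clusters <- cluster_samples(feat)
  res <- name_response_groups(clusters, partition, mean_matrix,
                              composition = composition, ...)
  res$mean_matrix <- mean_matrix
  res$partition <- partition
  res$treatment_clustering <- tc
  res
}
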