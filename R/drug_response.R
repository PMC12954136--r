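## Expression-based imputation of drug response (log10 IC50) by ridge
## regression trained on cell-line panels, plus per-drug IC50 scaling and
## response-group comparison.
##
## The training flow mirrors the standard expression-imputation recipe:
## intersect genes between training and target, keep the most variable
## training genes, quantile-map both matrices onto a training-derived
## reference distribution, then fit a closed-form ridge model with a
## seeded cross-validated penalty.

#' Homogenize training and target expression matrices
#'
#' Intersects genes, keeps the `n_top_genes` with the largest training
#' variance, and quantile-maps every sample (column) of both matrices onto
#' a common reference distribution (the mean sorted training profile).
#' Quantile mapping removes monotone per-sample distortions such as shifts
#' or scale differences between platforms.
#'
#' @param train_expr,target_expr gene x sample matrices (log scale).
#' @param n_top_genes genes kept by training variance (default 1000; pass
#'   `Inf` to keep all shared genes).
#' @param min_shared minimum acceptable gene overlap (default 100).
#' @return list with `train`, `target` (aligned, homogenized matrices),
#'   `genes`, and `ref_quantiles` (the reference distribution, sorted).
#' @export
homogenize_expression <- function(train_expr, target_expr,
                                  n_top_genes = 1000L, min_shared = 100L) {
  shared <- intersect(rownames(train_expr), rownames(target_expr))
  if (length(shared) < min_shared) {
    abort("only ", length(shared), " shared genes (< ", min_shared, ")")
  }
  tr <- train_expr[shared, , drop = FALSE]
  if (is.finite(n_top_genes) && n_top_genes < length(shared)) {
    v <- apply(tr, 1L, stats::var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(n_top_genes)]
    ## preserve input gene order for determinism
    shared <- shared[shared %in% keep]
  }
  tr <- train_expr[shared, , drop = FALSE]
  tg <- target_expr[shared, , drop = FALSE]
  ref <- rowMeans(apply(tr, 2L, sort))
  list(
    train = apply(tr, 2L, quantile_map, ref_sorted = ref),
    target = apply(tg, 2L, quantile_map, ref_sorted = ref),
    genes = shared,
    ref_quantiles = ref
  ) |> fix_dimnames(shared)
}

fix_dimnames <- function(h, genes) {
  rownames(h$train) <- genes
  rownames(h$target) <- genes
  h
}

## Map a vector onto a sorted reference distribution by rank; average ranks
## (ties) are linearly interpolated between reference quantiles.
quantile_map <- function(v, ref_sorted) {
  r <- rank(v, ties.method = "average")
  stats::approx(seq_along(ref_sorted), ref_sorted, xout = r)$y
}

## Closed-form ridge path via one SVD of the centered design: for each
## penalty, beta = V diag(d / (d^2 + lambda)) U' y. lambda = 0 on a
## full-column-rank design reproduces ordinary least squares.
ridge_path <- function(X, y, lambdas) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  ym <- mean(y)
  s <- svd(Xc)
  uty <- crossprod(s$u, y - ym)
  lapply(lambdas, function(l) {
    beta <- drop(s$v %*% ((s$d / (s$d^2 + l)) * uty))
    list(beta = beta, intercept = ym - sum(xm * beta), lambda = l)
  })
}

#' Fit a ridge-regression log-IC50 model for one drug
#'
#' Standardizes the (homogenized) training features, selects the penalty
#' from a log-spaced grid by seeded k-fold cross-validated squared error,
#' and refits on all lines at the chosen penalty with the closed-form
#' solution. Same seed, same folds, same penalty: the fit is deterministic.
#'
#' @param train_expr gene x line training matrix (homogenized).
#' @param response named (or drug x line matrix) log10-IC50 values.
#' @param drug drug name (row of `response`); ignored when `response` is a
#'   plain named vector.
#' @param lambda_grid penalty grid (default `10^seq(-3, 4, by = 0.5)`).
#' @param cv_folds folds (default 10; reduced with a warning when lines are
#'   scarce).
#' @param seed fold-assignment seed.
#' @param ref_quantiles optional homogenization reference to store for
#'   prediction-time mapping (see [homogenize_expression()]).
#' @return an object of class `ridge_predictor`.
#' @export
fit_ridge_model <- function(train_expr, response, drug = NULL,
                            lambda_grid = 10^seq(-3, 4, by = 0.5),
                            cv_folds = 10L, seed = 1L,
                            ref_quantiles = NULL) {
  y <- if (is.matrix(response)) {
    if (is.null(drug) || !drug %in% rownames(response)) {
      abort("drug not found in the response table")
    }
    response[drug, ]
  } else response
  lines <- intersect(colnames(train_expr), names(y))
  y <- y[lines]
  keep <- is.finite(y)
  y <- y[keep]; lines <- lines[keep]
  if (length(lines) < 3L) abort("too few lines with response for ", drug)
  X <- t(train_expr[, lines, drop = FALSE])

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  usable <- scl > 0
  Xs <- sweep(sweep(X[, usable, drop = FALSE], 2L, ctr[usable]), 2L,
              scl[usable], "/")

  if (cv_folds > length(lines)) {
    warning("reducing cv_folds to the number of lines (", length(lines), ")",
            call. = FALSE)
    cv_folds <- length(lines)
  }
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(cv_folds), length.out = length(lines)))
  cv_mse <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fits <- ridge_path(Xs[tr, , drop = FALSE], y[tr], lambda_grid)
    cv_mse[f, ] <- vapply(fits, function(m) {
      mean((y[!tr] - Xs[!tr, , drop = FALSE] %*% m$beta - m$intercept)^2)
    }, numeric(1))
  }
  lambda <- lambda_grid[which.min(colMeans(cv_mse))]
  fit <- ridge_path(Xs, y, lambda)[[1L]]
  pred_train <- drop(Xs %*% fit$beta) + fit$intercept

  structure(list(
    drug = drug %||% "drug",
    genes = colnames(Xs),
    coef = stats::setNames(fit$beta, colnames(Xs)),
    intercept = fit$intercept,
    lambda = lambda,
    cv_mse = stats::setNames(colMeans(cv_mse), signif(lambda_grid, 3)),
    center = ctr[usable],
    scale = scl[usable],
    ref_quantiles = ref_quantiles,
    train_r2 = 1 - mean((y - pred_train)^2) / stats::var(y) /
      ((length(y) - 1) / length(y)),
    n_train = length(y),
    seed = as.integer(seed)
  ), class = "ridge_predictor")
}

#' @export
print.ridge_predictor <- function(x, ...) {
  cat("ridge log-IC50 predictor for", x$drug, "\n",
      " genes:", length(x$genes),
      " lambda:", format(x$lambda),
      " training R2:", round(x$train_r2, 3),
      " n:", x$n_train, "\n")
  invisible(x)
}

#' Predict log-IC50 for target samples
#'
#' Applies the stored homogenization reference (when present) and training
#' standardization, then the linear model. Target samples missing more than
#' `max_missing` of the model genes are an error; below that, missing genes
#' are imputed at the training mean (standardized 0) with a warning.
#'
#' @param model a `ridge_predictor`.
#' @param target_expr gene x sample matrix.
#' @param max_missing tolerated missing-gene fraction (default 0.1).
#' @param homogenize apply the stored quantile reference (default TRUE when
#'   the model carries one).
#' @return named numeric vector of predicted log10 IC50 per sample.
#' @export
predict_log_ic50 <- function(model, target_expr, max_missing = 0.1,
                             homogenize = !is.null(model$ref_quantiles)) {
  stopifnot(inherits(model, "ridge_predictor"))
  present <- intersect(model$genes, rownames(target_expr))
  frac_missing <- 1 - length(present) / length(model$genes)
  if (frac_missing > max_missing) {
    abort(round(100 * frac_missing, 1),
          "% of model genes missing from the target (> ",
          round(100 * max_missing, 1), "%)")
  }
  tg <- target_expr[present, , drop = FALSE]
  if (homogenize) {
    if (is.null(model$ref_quantiles)) abort("model has no stored reference")
    tg <- apply(tg, 2L, quantile_map, ref_sorted = model$ref_quantiles)
    rownames(tg) <- present
  }
  X <- matrix(0, ncol(tg), length(model$genes),
              dimnames = list(colnames(tg), model$genes))
  X[, present] <- t((tg - model$center[present]) / model$scale[present])
  if (frac_missing > 0) {
    warning("mean-imputing ", length(model$genes) - length(present),
            " missing model gene(s)", call. = FALSE)
  }
  drop(X %*% model$coef) + model$intercept
}

#' Scale predicted IC50 values per drug (z-scores across samples)
#'
#' @param pred drug x sample matrix of predicted log-IC50 (a single named
#'   vector is treated as one drug).
#' @return matrix of the same shape with per-drug mean 0 and sd 1; drugs
#'   with zero variance come back all-zero with a warning.
#' @export
scale_ic50 <- function(pred) {
  if (!is.matrix(pred)) pred <- matrix(pred, 1L,
                                       dimnames = list("drug", names(pred)))
  if (ncol(pred) < 2L) abort("need >= 2 samples to scale")
  s <- apply(pred, 1L, stats::sd)
  if (any(s == 0)) {
    warning("zero-variance drug(s) scaled to 0: ",
            paste(rownames(pred)[s == 0], collapse = ", "), call. = FALSE)
  }
  z <- (pred - rowMeans(pred)) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Default MOA annotation of the screened drugs
#'
#' Taxanes are anti-microtubule; the other component drugs inhibit DNA
#' replication/transcription. Editable: pass any drug -> class vector to
#' [compare_groups_ic50()].
#' @return named character vector.
#' @export
default_drug_moa <- function() {
  c(docetaxel = "anti_microtubule", paclitaxel = "anti_microtubule",
    `5-fluorouracil` = "anti_replication", oxaliplatin = "anti_replication",
    irinotecan = "anti_replication", epirubicin = "anti_replication")
}

#' Compare scaled IC50 between response groups
#'
#' For each drug: Kruskal-Wallis across the defined groups (undefined
#' samples are excluded), then one-sided pairwise Wilcoxon tests in the
#' sensitivity direction double < single < not, BH-adjusted within drug.
#' Group means of the scaled IC50 are reported per drug and aggregated per
#' MOA class.
#'
#' @param scaled drug x sample matrix from [scale_ic50()].
#' @param assignment data.frame sample, label (from
#'   [assign_response_groups()]) or named sample -> label vector.
#' @param drug_moa named drug -> MOA class vector (default
#'   [default_drug_moa()]); drugs without annotation are reported as NA
#'   class.
#' @param min_group minimum defined-group size to test (default 3).
#' @return list with `per_drug` (drug, kruskal_p, group means),
#'   `pairwise` (drug, contrast, p, q) and `moa_means` (class x group).
#' @export
compare_groups_ic50 <- function(scaled, assignment,
                                drug_moa = default_drug_moa(),
                                min_group = 3L) {
  labels <- if (is.data.frame(assignment)) {
    stats::setNames(assignment$label, assignment$sample)
  } else assignment
  labels <- labels[intersect(names(labels), colnames(scaled))]
  labels <- labels[labels != "undefined"]
  if (!length(labels)) abort("all samples are undefined")
  groups <- intersect(RESPONSE_GROUPS, unique(labels))
  sizes <- table(labels)[groups]
  usable <- groups[sizes >= min_group]
  if (length(usable) < 2L) {
    abort("fewer than 2 groups with >= ", min_group, " defined samples")
  }
  contrasts <- list(
    c("double_sensitive", "single_sensitive"),
    c("double_sensitive", "not_sensitive"),
    c("single_sensitive", "not_sensitive")
  )
  per_drug <- list(); pairwise <- list()
  for (d in rownames(scaled)) {
    x <- scaled[d, names(labels)]
    kw <- stats::kruskal.test(split(x, factor(labels, levels = usable)))
    means <- tapply(x, factor(labels, levels = RESPONSE_GROUPS), mean)
    per_drug[[d]] <- data.frame(
      drug = d, moa = unname(drug_moa[d]), kruskal_p = kw$p.value,
      mean_double = means[["double_sensitive"]],
      mean_single = means[["single_sensitive"]],
      mean_not = means[["not_sensitive"]],
      stringsAsFactors = FALSE
    )
    pw <- lapply(contrasts, function(ct) {
      if (!all(ct %in% usable)) {
        return(data.frame(drug = d,
                          contrast = paste(ct, collapse = "<"),
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      p <- suppressWarnings(stats::wilcox.test(
        x[labels == ct[1L]], x[labels == ct[2L]],
        alternative = "less", exact = FALSE
      )$p.value)
      data.frame(drug = d, contrast = paste(ct, collapse = "<"), p = p,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, pw)
    pw$q <- stats::p.adjust(pw$p, method = "BH")
    pairwise[[d]] <- pw
  }
  per_drug <- do.call(rbind, per_drug)
  rownames(per_drug) <- NULL
  pairwise <- do.call(rbind, pairwise)
  rownames(pairwise) <- NULL

  moa_means <- NULL
  annotated <- per_drug[!is.na(per_drug$moa), , drop = FALSE]
  if (nrow(annotated)) {
    moa_means <- t(vapply(split(annotated, annotated$moa), function(df) {
      c(double_sensitive = mean(df$mean_double),
        single_sensitive = mean(df$mean_single),
        not_sensitive = mean(df$mean_not))
    }, numeric(3)))
  }
  list(per_drug = per_drug, pairwise = pairwise, moa_means = moa_means)
}
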