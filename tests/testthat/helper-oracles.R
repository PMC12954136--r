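## Independent oracles: brute-force implementations kept deliberately naive
## so they share no code path with the package.

## Exhaustive greedy Ward agglomeration straight from the points: at each
## step merge the pair of clusters with the smallest increase in total
## within-cluster sum of squares (first pair on ties). Returns labels for a
## k-cluster cut.
brute_ward_partition <- function(mat, k) {
  clusters <- lapply(seq_len(nrow(mat)), function(i) i)
  ward_cost <- function(ia, ib) {
    a <- mat[ia, , drop = FALSE]
    b <- mat[ib, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    (nrow(a) * nrow(b)) / (nrow(a) + nrow(b)) * sum((ma - mb)^2)
  }
  while (length(clusters) > k) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cost <- ward_cost(clusters[[i]], clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  labels <- integer(nrow(mat))
  for (c_idx in seq_along(clusters)) labels[clusters[[c_idx]]] <- c_idx
  labels
}

## Exact two-sided Wilcoxon rank-sum p by enumeration of every assignment
## of the pooled values to the two groups, reproducing the classic
## doubled-tail convention.
wilcox_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

## Two-sided Fisher exact p by summing hypergeometric point probabilities
## no larger than the observed table's (with the customary 1e-7 relative
## slack for floating-point equality).
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b          # row 1 total (mutated in group)
  n_ <- c_ + d
  kk <- a + c_        # column total
  x_all <- max(0, kk - n_):min(kk, m)
  dens <- stats::dhyper(x_all, m, n_, kk)
  sum(dens[dens <= stats::dhyper(a, m, n_, kk) * (1 + 1e-7)])
}

## Permutation reference distribution of the log-rank chi-square over all
## balanced stratum assignments of a small cohort.
logrank_perm_p <- function(surv, strata) {
  obs <- logrank_test(surv, strata)$chisq
  n <- nrow(surv)
  n_high <- sum(strata[surv$sample] == "high")
  combs <- utils::combn(n, n_high)
  stat <- apply(combs, 2L, function(idx) {
    s <- rep("low", n)
    s[idx] <- "high"
    logrank_test(surv, stats::setNames(s, surv$sample))$chisq
  })
  mean(stat >= obs - 1e-12)
}

## Jaccard overlap of two gene sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

## small helper: planted-group labels for a config
truth_groups <- function(screen_result) screen_result$truth$groups
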