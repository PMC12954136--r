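toy_expr <- function() {
  ## 4 genes x 3 samples with hand-computable z-scores
  m <- rbind(
    g1 = c(1, 2, 3),
    g2 = c(4, 4, 4),     # constant: contributes 0
    g3 = c(0, 10, 20),
    g4 = c(5, 3, 1)
  )
  colnames(m) <- c("a", "b", "c")
  m
}

test_that("geneset scores are mean z-scores with the sd-0 rule", {
  m <- toy_expr()
  sc <- score_genesets(m, list(s1 = c("g1"), s2 = c("g2"),
                               s3 = c("g1", "g2", "g3", "g4")))
  expect_equal(unname(sc["s1", ]), c(-1, 0, 1))          # single-gene z
  expect_equal(unname(sc["s2", ]), c(0, 0, 0))           # constant gene
  ## hand computation: z(g1)=(-1,0,1), z(g2)=0, z(g3)=(-1,0,1), z(g4)=(1,0,-1)
  expect_equal(unname(sc["s3", ]), c(-1, 0, 1) / 4 + c(-1, 0, 1) / 4 +
                 c(1, 0, -1) / 4)
  expect_error(score_genesets(m, list(bad = c("nope"))), "no genes")
})

test_that("scores are invariant to gene order and per-gene affine rescaling", {
  set.seed(4)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  set_genes <- c("g03", "g07", "g11", "g18")
  base <- score_genesets(m, list(s = set_genes))
  perm <- m[sample(nrow(m)), ]
  expect_equal(score_genesets(perm, list(s = set_genes)), base)
  rescaled <- m * runif(20, 0.5, 3) + rnorm(20)
  expect_equal(score_genesets(rescaled, list(s = set_genes)), base)
})

test_that("score-viability correlation has the documented sign convention", {
  set.seed(5)
  v <- stats::setNames(runif(10, 0.2, 1), sprintf("s%02d", 1:10))
  scores <- rbind(pos = v, neg = -v, noise = rnorm(10))
  colnames(scores) <- names(v)
  res <- correlate_scores_with_viability(scores, v)
  expect_equal(res$r[res$geneset == "pos"], 1)
  expect_equal(res$r[res$geneset == "neg"], -1)
  ## zero-variance score reported missing, not an error
  flat <- rbind(flat = rep(1, 10)); colnames(flat) <- names(v)
  expect_true(is.na(correlate_scores_with_viability(flat, v)$r))
  expect_error(correlate_scores_with_viability(scores[, 1:2], v[1:2]),
               "fewer than 3")
})

test_that("differential expression: exact Wilcoxon path matches enumeration", {
  set.seed(6)
  for (na in 2:5) {
    for (nb in 2:5) {
      a <- rnorm(na); b <- rnorm(nb)
      ours <- pdoresponse:::wilcox_p(a, b)
      expect_equal(ours, wilcox_enum_p(a, b), tolerance = 1e-12,
                   label = sprintf("sizes %d vs %d", na, nb))
    }
  }
})

test_that("differential expression contracts hold on edge cases", {
  m <- rbind(flat = rep(1, 6), up = c(5, 6, 7, 1, 2, 3))
  colnames(m) <- sprintf("s%d", 1:6)
  de <- differential_expression(m, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(de$p[de$gene == "flat"], 1)     # constant gene
  expect_equal(de$effect[de$gene == "up"], 4)
  expect_true(all(de$q >= de$p))
  expect_error(differential_expression(m, c("s1", "s2"), c("s2", "s3")),
               "overlap")
  expect_error(differential_expression(m, "s1", c("s2", "s3")), ">= 2")
})

test_that("BH adjustment is monotone and collapses equal p-values", {
  p <- c(0.02, 0.02, 0.02, 0.02)
  expect_equal(stats::p.adjust(p, method = "BH"), rep(0.02, 4))
  set.seed(7)
  p2 <- runif(50)
  q2 <- stats::p.adjust(p2, method = "BH")
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
})

test_that("marker panels recover planted programs and stay disjoint", {
  cfg <- sim_config(seed = 14, n_samples = 120L,
                    group_sizes = c(double_sensitive = 40L,
                                    single_sensitive = 40L,
                                    not_sensitive = 40L))
  cohort <- gen_expression_cohort(cfg)
  res <- derive_marker_panels(cohort$expr, cohort$truth$labels)
  expect_true(all(lengths(res$panels) <= 25))
  expect_equal(anyDuplicated(unlist(res$panels)), 0L)
  jac <- vapply(names(res$panels), function(g) {
    jaccard(res$panels[[g]], cohort$truth$programs[[g]])
  }, numeric(1))
  expect_true(all(jac >= 0.6))
  ## top_k = 1 truncation
  one <- derive_marker_panels(cohort$expr, cohort$truth$labels, top_k = 1L)
  expect_true(all(lengths(one$panels) <= 1L))
  ## permuted labels: panel sizes at the false-discovery expectation
  set.seed(15)
  perm <- stats::setNames(sample(cohort$truth$labels),
                          names(cohort$truth$labels))
  null_res <- derive_marker_panels(cohort$expr, perm)
  expect_lte(sum(lengths(null_res$panels)),
             0.05 * nrow(cohort$expr) * 3 + 5)
})

test_that("hypergeometric ORA matches the exact combinatorial count", {
  universe <- sprintf("u%02d", 1:20)
  set5 <- universe[1:5]
  res <- ora_enrichment(universe[1:5], list(s = set5), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## hits = universe -> p = 1
  res_all <- ora_enrichment(universe, list(s = set5), universe)
  expect_equal(res_all$p, 1)
  ## zero overlap with a small set -> upper tail includes 0 -> p = 1
  res0 <- ora_enrichment(universe[6:8], list(s = universe[1:2]), universe)
  expect_equal(res0$p, stats::phyper(-1, 2, 18, 3, lower.tail = FALSE))
  expect_error(ora_enrichment("a", list(s = "a"), character(0)), "universe")
})

test_that("ordination is deterministic with fixed sign and sane variance", {
  set.seed(8)
  m <- matrix(rnorm(120), 12, 10,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:10)))
  ## duplicated samples -> identical coordinates
  m2 <- cbind(m, dup = m[, 1]); colnames(m2)[11] <- "dup"
  ord <- ordinate_samples(m2)
  expect_equal(unname(ord$coordinates["dup", ]),
               unname(ord$coordinates["s01", ]))
  ## rank-1 matrix: first component carries all variance
  r1 <- outer(rnorm(12), rnorm(10))
  dimnames(r1) <- dimnames(m)
  ord1 <- ordinate_samples(r1)
  expect_equal(ord1$var_explained[1], 1, tolerance = 1e-9)
  ## sign convention: largest-magnitude loading positive
  expect_true(all(vapply(1:2, function(j) {
    ord$loadings[which.max(abs(ord$loadings[, j])), j] > 0
  }, logical(1))))
})
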