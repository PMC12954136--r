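test_that("quantile homogenization aligns matrices and removes shifts", {
  set.seed(30)
  genes <- sprintf("g%03d", 1:150)
  train <- matrix(rnorm(150 * 20), 150, 20,
                  dimnames = list(genes, sprintf("L%02d", 1:20)))
  ## target = train: the two homogenized matrices coincide
  hom <- homogenize_expression(train, train, n_top_genes = Inf)
  expect_equal(hom$train, hom$target, tolerance = 1e-8)
  ## target = train + 5: the location shift is removed entirely
  hom2 <- homogenize_expression(train, train + 5, n_top_genes = Inf)
  expect_equal(hom2$train, hom2$target, tolerance = 1e-8)
  ## differently-scaled cohorts move much closer after homogenization
  target <- train * 3 + 2 + matrix(rnorm(150 * 20, 0, 0.1), 150)
  before <- mean(abs(rowMeans(train) - rowMeans(target)))
  hom3 <- homogenize_expression(train, target, n_top_genes = Inf)
  after <- mean(abs(rowMeans(hom3$train) - rowMeans(hom3$target)))
  expect_lt(after, before / 10)
  expect_error(homogenize_expression(train[1:50, ], train, min_shared = 100),
               "shared genes")
})

test_that("ridge at lambda 0 equals least squares; large lambda shrinks to 0", {
  set.seed(31)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(10, 0, 0.1)
  fit0 <- pdoresponse:::ridge_path(X, y, 0)[[1]]
  ols <- stats::lm(y ~ X)
  expect_equal(unname(fit0$beta), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  fit_big <- pdoresponse:::ridge_path(X, y, 1e10)[[1]]
  expect_lt(max(abs(fit_big$beta)), 1e-6)
  expect_equal(fit_big$intercept, mean(y), tolerance = 1e-4)
})

test_that("ridge matches the closed-form normal-equations solution", {
  ## 3 lines x 2 genes, lambda = 1, centered by hand
  X <- cbind(c(1, 2, 3), c(0, 1, 4))
  y <- c(1, 2, 6)
  lambda <- 1
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  beta_direct <- solve(crossprod(Xc) + lambda * diag(2), crossprod(Xc, yc))
  fit <- pdoresponse:::ridge_path(X, y, lambda)[[1]]
  expect_equal(unname(fit$beta), drop(beta_direct), tolerance = 1e-10)
  expect_equal(fit$intercept,
               mean(y) - sum(colMeans(X) * beta_direct), tolerance = 1e-10)
})

small_training <- function(seed = 32) {
  cfg <- sim_config(seed = seed, n_genes = 300L, n_celllines = 60L,
                    n_causal_genes = 15L)
  gen_cellline_training(cfg)
}

test_that("model fitting is seed-deterministic and predicts sensibly", {
  tr <- small_training()
  m1 <- fit_ridge_model(tr$expr, tr$response, "drugA", seed = 5)
  m2 <- fit_ridge_model(tr$expr, tr$response, "drugA", seed = 5)
  expect_identical(m1$lambda, m2$lambda)
  expect_equal(m1$coef, m2$coef)
  expect_gt(m1$train_r2, 0.5)
  ## constant target sample predicts the intercept-plus-mean-term exactly
  const <- matrix(0, length(m1$genes), 2,
                  dimnames = list(m1$genes, c("c1", "c2")))
  p <- predict_log_ic50(m1, const, homogenize = FALSE)
  expect_equal(unname(p["c1"]), unname(p["c2"]))
  ## gene/sample order permutations change nothing but ordering
  tr2 <- tr
  perm <- sample(nrow(tr$expr))
  m3 <- fit_ridge_model(tr$expr[perm, ], tr$response, "drugA", seed = 5)
  expect_equal(sort(m3$coef), sort(m1$coef), tolerance = 1e-9)
})

test_that("flat response gives near-constant predictions", {
  tr <- small_training(seed = 33)
  flat <- tr$response
  flat["drugA", ] <- 3 + rnorm(ncol(flat), 0, 1e-6)
  m <- fit_ridge_model(tr$expr, flat, "drugA", seed = 1)
  p <- predict_log_ic50(m, tr$expr, homogenize = FALSE)
  expect_lt(stats::sd(p), 1e-3)
  expect_equal(unname(mean(p)), 3, tolerance = 1e-3)
})

test_that("prediction errors on heavy gene loss, warns and imputes light loss", {
  tr <- small_training(seed = 34)
  m <- fit_ridge_model(tr$expr, tr$response, "drugA", seed = 2)
  target <- tr$expr[, 1:5]
  expect_error(predict_log_ic50(m, target[1:100, ], homogenize = FALSE),
               "missing")
  keep <- seq_len(round(length(m$genes) * 0.95))
  expect_warning(
    predict_log_ic50(m, target[m$genes[keep], , drop = FALSE],
                     homogenize = FALSE),
    "mean-imputing")
})

test_that("IC50 scaling is a per-drug z-score", {
  pr <- rbind(d1 = c(1, 2, 3, 6))
  colnames(pr) <- sprintf("s%d", 1:4)
  z <- scale_ic50(pr)
  expect_equal(unname(z["d1", ]), unname(scale(c(1, 2, 3, 6))[, 1]))
  ## two samples: symmetric +-x
  two <- rbind(d = c(1, 5)); colnames(two) <- c("a", "b")
  z2 <- scale_ic50(two)
  expect_equal(unname(z2["d", "a"]), -unname(z2["d", "b"]))
  ## adding a constant changes nothing
  expect_equal(scale_ic50(pr + 7), z)
  flat <- rbind(d = rep(2, 4)); colnames(flat) <- colnames(pr)
  expect_warning(zf <- scale_ic50(flat), "zero-variance")
  expect_true(all(zf == 0))
})

test_that("group comparison recovers a planted sensitivity ordering", {
  set.seed(36)
  labels <- stats::setNames(
    rep(c("double_sensitive", "single_sensitive", "not_sensitive",
          "undefined"), each = 30),
    sprintf("s%03d", 1:120)
  )
  shift <- c(double_sensitive = -1, single_sensitive = 0,
             not_sensitive = 1, undefined = 0)
  pred <- rbind(oxaliplatin = rnorm(120, shift[labels], 0.5))
  colnames(pred) <- names(labels)
  res <- compare_groups_ic50(scale_ic50(pred), labels)
  expect_lt(res$per_drug$kruskal_p, 0.001)
  expect_true(res$per_drug$mean_double < res$per_drug$mean_single)
  expect_true(res$per_drug$mean_single < res$per_drug$mean_not)
  expect_true(all(res$pairwise$q < 0.05))
  expect_equal(res$per_drug$moa, "anti_replication")
  ## one group absent: its contrasts go missing, the rest still compute
  part <- labels[labels != "not_sensitive"]
  res2 <- compare_groups_ic50(scale_ic50(pred), part)
  expect_true(is.na(res2$per_drug$mean_not))
  expect_true(any(is.na(res2$pairwise$p)) && any(!is.na(res2$pairwise$p)))
  expect_error(compare_groups_ic50(scale_ic50(pred),
                                   stats::setNames(rep("undefined", 120),
                                                   names(labels))),
               "undefined")
})
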