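make_raw <- function() {
  data.frame(
    sample = rep(c("S1", "S2"), each = 4),
    regimen = rep(c("R1", "R1", "R2", "R2"), 2),
    replicate = rep(1:2, 4),
    signal = c(2500, 3500, 12000, 11000, 5000, 5000, 9000, 9000)
  )
}

test_that("normalization divides by the per-sample control mean", {
  raw <- make_raw()
  control <- data.frame(sample = rep(c("S1", "S2"), each = 2),
                        replicate = rep(1:2, 2),
                        signal = c(10000, 10000, 10000, 10000))
  v <- normalize_to_control(raw, control)
  expect_equal(v$viability[1], 0.25)
  expect_equal(v$viability[3], 1.2)  # not clamped at 1
  ## treated = control -> 1
  same <- normalize_to_control(
    data.frame(sample = "S1", regimen = "R1", replicate = 1, signal = 10000),
    control)
  expect_equal(same$viability, 1)
  ## zero control mean errors naming the sample
  badctrl <- data.frame(sample = "S1", replicate = 1, signal = 0)
  expect_error(normalize_to_control(raw[raw$sample == "S1", ], badctrl), "S1")
})

test_that("replicate averaging is exact and rejects empty cells", {
  screen <- data.frame(sample = "S1", regimen = "R1", replicate = 1:3,
                       viability = c(0.2, 0.3, 0.4))
  expect_equal(unname(average_replicates(screen)[1, 1]), 0.3)
  single <- data.frame(sample = "S1", regimen = "R1", replicate = 1,
                       viability = 0.7)
  expect_equal(unname(average_replicates(single)[1, 1]), 0.7)
  holey <- rbind(screen,
                 data.frame(sample = "S2", regimen = "R2", replicate = 1,
                            viability = 0.5))
  expect_error(average_replicates(holey), "empty")
  expect_error(average_replicates(transform(screen, viability = c(0.1, NA, 0.2))),
               "non-finite")
  expect_error(average_replicates(transform(screen, viability = c(-0.1, 0.2, 0.2))),
               "negative")
})

test_that("normalize -> average is invariant to replicate order and rescaling", {
  raw <- make_raw()
  control <- data.frame(sample = c("S1", "S2"), replicate = 1,
                        signal = c(8000, 12000))
  base <- average_replicates(normalize_to_control(raw, control))
  shuffled <- raw[sample(nrow(raw)), ]
  expect_equal(average_replicates(normalize_to_control(shuffled, control))[
    rownames(base), colnames(base)], base)
  ## uniform per-sample rescaling of raw signal cancels in the ratio
  scaled <- raw
  scaled$signal <- scaled$signal * ifelse(scaled$sample == "S1", 7, 0.3)
  control2 <- control
  control2$signal <- control2$signal * c(7, 0.3)
  expect_equal(average_replicates(normalize_to_control(scaled, control2)),
               base)
})

test_that("MOA annotation follows the taxane rule", {
  moa <- annotate_moa(default_regimens())
  expect_equal(unname(moa[c("Comb2", "Comb3")]),
               rep("anti_microtubule", 2))
  expect_equal(unname(moa[c("Comb1", "Comb4", "Comb5")]),
               rep("anti_replication", 3))
  expect_equal(unname(annotate_moa(list(r = "5-fu"))), "anti_replication")
  expect_equal(unname(annotate_moa(list(r = "paclitaxel"))),
               "anti_microtubule")
  expect_warning(annotate_moa(list(r = c("mystery-drug"))), "unknown")
})

test_that("treatment clustering co-clusters duplicate profiles", {
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  mm <- cbind(R1 = a, R2 = a, R3 = b, R4 = b, R5 = b)
  rownames(mm) <- sprintf("S%02d", 1:10)
  res <- cluster_treatments(mm)
  expect_equal(res$cluster[["R1"]], res$cluster[["R2"]])
  expect_equal(res$cluster[["R3"]], res$cluster[["R4"]])
  expect_equal(res$cluster[["R4"]], res$cluster[["R5"]])
  expect_false(res$cluster[["R1"]] == res$cluster[["R3"]])
  ## the lower-viability cluster gets index 1
  means_by_cluster <- tapply(colMeans(mm), res$cluster, mean)
  expect_equal(unname(which.min(means_by_cluster)), 1L)
  expect_error(cluster_treatments(mm, k = 6), "exceeds")
  ## all-identical columns: degenerate but deterministic
  same <- mm[, c(1, 1, 1)]
  colnames(same) <- c("A", "B", "C")
  expect_identical(cluster_treatments(same)$cluster,
                   cluster_treatments(same)$cluster)
})

test_that("sample clustering recovers exact triples and matches the oracle", {
  set.seed(2)
  proto <- matrix(rnorm(15), 3, 5)
  mm <- proto[rep(1:3, each = 3), ] + 0
  rownames(mm) <- sprintf("S%d", 1:9)
  cl <- cluster_samples(mm, k = 3)
  expect_equal(adjusted_rand_index(cl, rep(1:3, each = 3)), 1)
})

test_that("agglomerative clustering equals the exhaustive Ward oracle (<= 6 items)", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    k <- sample(2:(n - 1), 1)
    mat <- matrix(rnorm(n * 4), n)
    rownames(mat) <- sprintf("I%d", seq_len(n))
    ours <- cluster_samples(mat, k = k)
    oracle <- brute_ward_partition(mat, k)
    expect_equal(adjusted_rand_index(ours, oracle), 1)
  }
})

test_that("response-group naming follows the centroid rules", {
  ## forced ordering: A = double, B = single, C = not
  moa <- c(R1 = "anti_microtubule", R2 = "anti_replication")
  mm <- rbind(
    A1 = c(0.30, 0.35), A2 = c(0.30, 0.35),
    B1 = c(0.40, 0.80), B2 = c(0.40, 0.80),
    C1 = c(0.85, 0.90), C2 = c(0.85, 0.90)
  )
  colnames(mm) <- c("R1", "R2")
  cl <- stats::setNames(rep(1:3, each = 2), rownames(mm))
  res <- name_response_groups(cl, moa, mm, resistant_regimen = "R2")
  got <- stats::setNames(res$assignment$group, res$assignment$sample)
  expect_equal(unname(got[c("A1", "B1", "C1")]),
               c("double_sensitive", "single_sensitive", "not_sensitive"))
  expect_equal(res$centroids["double_sensitive", "anti_replication"], 0.35)
  ## resistant flag: viability above 0.75 under the reference regimen
  expect_equal(unname(res$assignment$resistant_flag),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  ## rule collision on degenerate centroids
  flat <- mm; flat[] <- 0.5
  expect_error(name_response_groups(cl, moa, flat, resistant_regimen = "R2"),
               "collision")
})

test_that("screen classification recovers planted groups and flags nulls", {
  cfg <- sim_config(seed = 8)
  scr <- gen_viability_screen(cfg)
  res <- classify_screen(scr$screen, cfg$regimens)
  got <- stats::setNames(res$assignment$group, res$assignment$sample)
  expect_equal(adjusted_rand_index(got[names(scr$truth$groups)],
                                   scr$truth$groups), 1)
  expect_gt(res$separation, 2)
  expect_true(isTRUE(res$treatment_clustering$moa_concordant))

  ## null screen (no planted effects): collision error or tiny separation,
  ## never silently confident labels
  cfg0 <- sim_config(seed = 8, effect_mt = 0, effect_rep = 0)
  scr0 <- gen_viability_screen(cfg0)
  res0 <- tryCatch(classify_screen(scr0$screen, cfg0$regimens),
                   error = function(e) e)
  if (!inherits(res0, "error")) expect_lt(res0$separation, 2)
})

test_that("stronger planted effects give monotonically better recovery", {
  ari_at <- function(effect) {
    median(vapply(1:15, function(s) {
      cfg <- sim_config(seed = 3000 + s, effect_mt = effect,
                        effect_rep = 0.75 * effect)
      scr <- gen_viability_screen(cfg)
      res <- tryCatch(classify_screen(scr$screen, cfg$regimens),
                      error = function(e) NULL)
      if (is.null(res)) return(0)
      got <- stats::setNames(res$assignment$group, res$assignment$sample)
      adjusted_rand_index(got[names(scr$truth$groups)], scr$truth$groups)
    }, numeric(1)))
  }
  a <- ari_at(0.05); b <- ari_at(0.15); c_ <- ari_at(0.40)
  expect_lte(a, b + 0.1)
  expect_lte(b, c_ + 1e-9)
  expect_equal(c_, 1)
})
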