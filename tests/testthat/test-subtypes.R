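two_group_matrix <- function(n_probes = 120, n_per_group = 8, delta = 0.4,
                             seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  base <- runif(n_probes, 0.2, 0.5)
  beta <- matrix(rep(base, n), n_probes, n) +
    matrix(rnorm(n_probes * n, 0, 0.03), n_probes, n)
  shifted <- seq_len(min(100, n_probes))
  beta[shifted, (n_per_group + 1):n] <-
    beta[shifted, (n_per_group + 1):n] + delta
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sprintf("cg%03d", seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n)))
  beta
}

test_that("consensus clustering separates well-separated groups", {
  ari <- vapply(1:10, function(s) {
    beta <- two_group_matrix(seed = s)
    res <- consensus_cluster(beta, k = 2, n_resamples = 200, seed = s)
    truth <- rep(1:2, each = 8)
    adjusted_rand_index(res$assignments, truth)
  }, 1)
  expect_gte(sum(ari == 1), 9)
})

test_that("consensus matrix is well-formed and order-invariant", {
  beta <- two_group_matrix(seed = 3)
  res <- consensus_cluster(beta, k = 2, n_resamples = 100, seed = 3)
  cm <- res$consensus
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(beta)))
  expect_true(all(cm >= 0 & cm <= 1))
  ## same seed-stream, permuted samples: same partition up to labels
  o <- sample(ncol(beta))
  res2 <- consensus_cluster(beta[, o], k = 2, n_resamples = 100, seed = 3)
  expect_equal(adjusted_rand_index(res$assignments[colnames(beta)],
                                   res2$assignments[colnames(beta)]), 1)
})

test_that("identical samples are flagged as degenerate", {
  beta <- matrix(0.4, 50, 6,
                 dimnames = list(sprintf("cg%02d", 1:50), letters[1:6]))
  res <- consensus_cluster(beta, k = 2, n_resamples = 50, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$k, 1L)
  expect_true(all(res$consensus == 1))
  expect_error(consensus_cluster(two_group_matrix(), k = 20, seed = 1),
               "exceeds")
})

test_that("classical MDS reproduces exact low-dimensional embeddings", {
  ## points generated in 2D: pairwise distances are reproduced exactly
  set.seed(9)
  pts <- matrix(rnorm(12 * 2), 12, 2)
  d_true <- as.matrix(dist(pts))
  beta <- t(cbind(pts, matrix(0, 12, 3)))  # 5 "probes" embedding the 2D data
  rownames(beta) <- sprintf("cg%d", 1:5)
  colnames(beta) <- sprintf("s%02d", 1:12)
  res <- mds_samples(beta, n_dims = 2)
  expect_equal(as.matrix(dist(res$coords)), d_true, tolerance = 1e-9,
               ignore_attr = TRUE)
  ## against the double-centering oracle (up to per-axis sign)
  oracle <- mds_oracle(d_true^2, 2)
  for (j in 1:2) {
    expect_equal(abs(res$coords[, j]), abs(oracle[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  ## sign convention: first nonzero coordinate of each axis positive
  for (j in 1:2) {
    nz <- which(abs(res$coords[, j]) > 1e-12)
    expect_gt(res$coords[nz[1], j], 0)
  }
})

test_that("collinear points embed in one dimension", {
  beta <- matrix(c(0.1, 0.2, 0.4), 1, 3,
                 dimnames = list("cg1", c("a", "b", "c")))
  beta <- rbind(beta, 2 * beta)
  rownames(beta) <- c("cg1", "cg2")
  res <- mds_samples(beta, n_dims = 2)
  expect_equal(res$n_dims_effective, 1)
  expect_error(mds_samples(beta[, 1:2, drop = FALSE]), "at least 3")
})

test_that("hypervariable groups disperse more in MDS space", {
  b <- small_cohort()
  ss <- b$samples
  top <- top_variable(b$beta, fraction = 0.02)
  res <- mds_samples(b$beta[top, ss$sample_id[ss$tissue != "EK"]])
  dispersion <- function(ids) {
    xy <- res$coords[ids, , drop = FALSE]
    ctr <- colMeans(xy)
    mean(sqrt(rowSums(sweep(xy, 2, ctr)^2)))
  }
  g1 <- ss$sample_id[ss$tissue == "WT" & ss$subgroup == "group1"]
  nk <- ss$sample_id[ss$tissue == "NK"]
  expect_gt(dispersion(g1), dispersion(nk))
})

test_that("per-probe Bartlett matches the closed form and stats::bartlett.test", {
  ## spec toy: A = {0.1, 0.2, 0.3}, B = {0.1, 0.5, 0.9}
  beta <- matrix(c(0.1, 0.2, 0.3, 0.1, 0.5, 0.9), 1, 6,
                 dimnames = list("cg1", sprintf("s%d", 1:6)))
  res <- bartlett_per_probe(beta, list(A = paste0("s", 1:3),
                                       B = paste0("s", 4:6)), alpha = 0.05)
  oracle <- bartlett_oracle(list(c(0.1, 0.2, 0.3), c(0.1, 0.5, 0.9)))
  expect_equal(res$table$K2, oracle$K2, tolerance = 1e-10)
  expect_equal(res$table$p, oracle$p, tolerance = 1e-10)

  set.seed(13)
  beta2 <- matrix(runif(50 * 14), 50, 14,
                  dimnames = list(sprintf("cg%02d", 1:50),
                                  sprintf("s%02d", 1:14)))
  groups <- list(g1 = sprintf("s%02d", 1:5), g2 = sprintf("s%02d", 6:10),
                 g3 = sprintf("s%02d", 11:14))
  res2 <- bartlett_per_probe(beta2, groups)
  for (i in sample(50, 10)) {
    bt <- bartlett.test(list(beta2[i, groups$g1], beta2[i, groups$g2],
                             beta2[i, groups$g3]))
    expect_equal(res2$table$K2[i], unname(bt$statistic), tolerance = 1e-10)
    expect_equal(res2$table$p[i], bt$p.value, tolerance = 1e-10)
  }
})

test_that("Bartlett handles degenerate variances by convention", {
  beta <- matrix(c(rep(0.3, 6), 0.3, 0.3, 0.3, 0.1, 0.5, 0.9), 2, 6,
                 byrow = TRUE,
                 dimnames = list(c("allzero", "onezero"), sprintf("s%d", 1:6)))
  res <- bartlett_per_probe(beta, list(A = paste0("s", 1:3),
                                       B = paste0("s", 4:6)))
  expect_equal(res$table$p[1], 1)
  expect_true(res$table$degenerate[1])
  expect_equal(res$table$p[2], 0)
  ## identical group variances: K2 = 0, p = 1
  beta2 <- matrix(c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7), 1, 6,
                  dimnames = list("cg1", sprintf("s%d", 1:6)))
  res2 <- bartlett_per_probe(beta2, list(A = paste0("s", 1:3),
                                         B = paste0("s", 4:6)))
  expect_equal(res2$table$K2, 0, tolerance = 1e-10)
  expect_equal(res2$table$p, 1)
})

test_that("Bartlett detects a fourfold variance ratio with high power", {
  ## exact two-group power at alpha 0.01: P(F(29,29) > qF(0.995)/4) ~ 0.83
  set.seed(17)
  n <- 1000
  beta <- cbind(matrix(rnorm(n * 30, 0.5, 0.05), n, 30),
                matrix(rnorm(n * 30, 0.5, 0.10), n, 30))
  beta <- pmin(pmax(beta, 0.001), 0.999)
  dimnames(beta) <- list(sprintf("cg%04d", 1:n), sprintf("s%02d", 1:60))
  res <- bartlett_per_probe(beta, list(lo = sprintf("s%02d", 1:30),
                                       hi = sprintf("s%02d", 31:60)),
                            alpha = 0.01)
  rejection <- res$n_significant / n
  expect_gte(rejection, 0.8)
  ## the larger-variance group carries (almost) all significant probes
  expect_gt(res$summary[["hi"]], 50 * max(1, res$summary[["lo"]]))
})

test_that("chi-square association matches the closed form", {
  res <- cluster_association(rep(c("c1", "c2"), each = 10),
                             rep(c("x", "y"), each = 10))
  expect_equal(res$chi2, 20, tolerance = 1e-10)
  expect_equal(res$df, 1)
  set.seed(19)
  a <- sample(c("c1", "c2", "c3"), 60, replace = TRUE)
  l <- sample(c("u", "b"), 60, replace = TRUE)
  res2 <- cluster_association(a, l)
  oracle <- chisq_oracle(table(a, l))
  expect_equal(res2$chi2, oracle$chi2, tolerance = 1e-10)
  expect_equal(res2$df, oracle$df)
  expect_error(cluster_association(rep("c1", 10), rep(c("u", "b"), 5)),
               "at least 2")
})

test_that("chi-square p-values are calibrated under permuted labels", {
  set.seed(23)
  p <- vapply(1:200, function(i) {
    a <- sample(rep(c("c1", "c2"), each = 30))
    l <- sample(rep(c("u", "b"), each = 30))
    cluster_association(a, l)$p
  }, 1)
  ## discrete statistic: check the rejection rate rather than KS
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.07)
})
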