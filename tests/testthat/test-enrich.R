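test_that("full-coverage features yield zero enrichment", {
  u <- toy_universe()
  all_gr <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1, max(u$ann$pos) + 1))
  res <- multisample_enrichment(u$ann$probe_id[1:100], u$ann$probe_id,
                                u$ann, list(all = all_gr), seed = 2)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$null_mean_fraction, 1)
  expect_equal(res$enrichment_pp, 0)
})

test_that("a fully in-feature query reaches the empirical p floor", {
  u <- toy_universe(n = 5000, feature_frac = 0.01, seed = 3)
  query <- u$inside
  res <- multisample_enrichment(query, u$ann$probe_id, u$ann, u$features,
                                n_resamples = 100, seed = 3)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$p, 1 / 101)
  expect_identical(res$side, "greater")
  ## null mean close to the hypergeometric expectation (= feature fraction)
  expect_lt(abs(res$null_mean_fraction - 0.01),
            3 * res$null_sd / sqrt(100) + 1e-9)
})

test_that("null mean tracks the hypergeometric expectation", {
  set.seed(5)
  for (i in 1:5) {
    u <- toy_universe(n = 1500, feature_frac = runif(1, 0.1, 0.4),
                      seed = 100 + i)
    q <- sample(u$ann$probe_id, 150)
    res <- multisample_enrichment(q, u$ann$probe_id, u$ann, u$features,
                                  n_resamples = 200, seed = i)
    expected <- length(u$inside) / 1500
    se <- res$null_sd / sqrt(200)
    expect_lt(abs(res$null_mean_fraction - expected), 3 * se + 1e-9)
  }
})

test_that("fixed-side empirical p is uniform under the null", {
  u <- toy_universe(n = 2000, feature_frac = 0.25, seed = 6)
  set.seed(6)
  p <- vapply(1:200, function(i) {
    q <- sample(u$ann$probe_id, 250)
    multisample_enrichment(q, u$ann$probe_id, u$ann, u$features,
                           n_resamples = 100, seed = 1000 + i)$p_greater
  }, 1)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("query validation and sign conventions hold", {
  u <- toy_universe(seed = 7)
  expect_error(multisample_enrichment(c("nope"), u$ann$probe_id, u$ann,
                                      u$features), "subset")
  ## an out-of-feature query is negatively enriched with side "less"
  query <- setdiff(u$ann$probe_id, u$inside)[1:200]
  res <- multisample_enrichment(query, u$ann$probe_id, u$ann, u$features,
                                n_resamples = 100, seed = 7)
  expect_identical(res$side, "less")
  expect_lt(res$enrichment_pp, 0)
  expect_equal(res$p, res$p_less)
})

test_that("hypermethylation calls follow the mean-plus-one-SD rule exactly", {
  ## reference per-sample means {0.4, 0.5, 0.6}: threshold 0.6, strict
  beta <- matrix(c(0.4, 0.5, 0.6, 0.65, 0.60), 1, 5,
                 dimnames = list("cg1",
                                 c("nr1", "nr2", "nr3", "wtA", "wtB")))
  res <- classify_hypermethylation(beta, list(DMR1 = "cg1"),
                                   tumour_samples = c("wtA", "wtB"),
                                   reference_samples = c("nr1", "nr2", "nr3"))
  expect_equal(res$frequency$threshold, 0.6)
  expect_identical(res$calls$hypermethylated, c(TRUE, FALSE))
  expect_identical(res$frequency$frequency, "1 of 2")
  expect_error(classify_hypermethylation(beta, list(DMR1 = "cg1"),
                                         c("wtA"), c("nr1")), ">= 2")
})

test_that("matched tumour and reference cohorts call at the Gaussian rate", {
  set.seed(29)
  n_dmr <- 400
  beta <- matrix(rnorm(n_dmr * 40, 0.5, 0.05), n_dmr, 40)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(sprintf("cg%04d", 1:n_dmr), sprintf("s%02d", 1:40))
  dmrs <- setNames(as.list(rownames(beta)), sprintf("DMR%04d", 1:n_dmr))
  res <- classify_hypermethylation(beta, dmrs,
                                   tumour_samples = sprintf("s%02d", 21:40),
                                   reference_samples = sprintf("s%02d", 1:20))
  rate <- mean(res$calls$hypermethylated)
  expect_lt(abs(rate - 0.16), 0.05)
})

test_that("classifier is invariant to probe order and NA-only probes", {
  set.seed(31)
  beta <- matrix(runif(5 * 8, 0.3, 0.7), 5, 8,
                 dimnames = list(sprintf("cg%d", 1:5), sprintf("s%d", 1:8)))
  dmr <- list(D = c("cg1", "cg2", "cg3"))
  r1 <- classify_hypermethylation(beta, dmr, sprintf("s%d", 6:8),
                                  sprintf("s%d", 1:5))
  r2 <- classify_hypermethylation(beta[5:1, ], list(D = c("cg3", "cg1", "cg2")),
                                  sprintf("s%d", 6:8), sprintf("s%d", 1:5))
  expect_equal(r1$calls$hypermethylated, r2$calls$hypermethylated)
  ## adding an all-NA probe changes nothing
  beta_na <- rbind(beta, cgNA = NA_real_)
  r3 <- classify_hypermethylation(beta_na, list(D = c("cg1", "cg2", "cg3",
                                                      "cgNA")),
                                  sprintf("s%d", 6:8), sprintf("s%d", 1:5))
  expect_equal(r1$calls$tumour_mean, r3$calls$tumour_mean)
})

test_that("planted tumour shifts produce a full-frequency call", {
  b <- small_cohort()
  ss <- b$samples
  g1_wt <- ss$sample_id[ss$tissue == "WT" & ss$subgroup == "group1"]
  nr <- ss$sample_id[ss$tissue == "NR"]
  truth <- b$truth$regions
  hyper_wt <- truth[truth$contrast == "WT" & truth$direction == "hyper", ]
  tp <- b$truth$probes
  sets <- lapply(hyper_wt$region_id, function(rid) {
    tp$probe_id[!is.na(tp$region_id) & tp$region_id == rid]
  })
  names(sets) <- hyper_wt$region_id
  res <- classify_hypermethylation(b$beta, sets, g1_wt, nr)
  expect_true(any(res$frequency$frequency ==
                    sprintf("%d of %d", length(g1_wt), length(g1_wt))))
  expect_gte(mean(res$calls$hypermethylated), 0.9)
})
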