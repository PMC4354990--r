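test_that("configuration validation rejects out-of-range settings", {
  expect_error(sim_config(frac_group1 = 1.2), "fraction")
  expect_error(sim_config(kr_delta = 0), "effect size")
  expect_error(sim_config(n_cell_types = 0), "n_cell_types")
  expect_error(sim_config(dmr_probes_min = 2), "at least 3 probes")
  ## planted probes exceeding the array size
  expect_error(sim_config(n_probes = 100, kr_dmr_count = 40,
                          wt_dmr_count = 40),
               "exceed n_probes")
  ## mixture concentrations must match the cell-type count
  cfg <- sim_config()
  cfg$mixture_alpha$NR <- c(1, 2)
  expect_error(methtrio:::validate_sim_config(cfg), "mixture_alpha")
})

test_that("simulation is deterministic given the seed and beta is bounded", {
  b1 <- simulate_cohort(sim_config(n_probes = 1500, kr_dmr_count = 4,
                                   wt_dmr_count = 3, ek_mvp_count = 20,
                                   seed = 9))
  b2 <- simulate_cohort(sim_config(n_probes = 1500, kr_dmr_count = 4,
                                   wt_dmr_count = 3, ek_mvp_count = 20,
                                   seed = 9))
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$truth$regions, b2$truth$regions)
  expect_true(all(b1$beta > 0 & b1$beta < 1))
  expect_false(anyNA(b1$beta))
})

test_that("truth manifest is internally consistent", {
  b <- small_cohort()
  expect_equal(unname(rowSums(b$truth$mixtures)), rep(1, nrow(b$truth$mixtures)),
               tolerance = 1e-12)
  expect_true(all(b$truth$regions$n_probes >= 3))
  expect_true(all(b$truth$regions$start < b$truth$regions$end))
  ## region intervals contain exactly their member probes
  tp <- b$truth$probes
  for (i in sample(nrow(b$truth$regions), 5)) {
    r <- b$truth$regions[i, ]
    members <- tp$probe_id[!is.na(tp$region_id) & tp$region_id == r$region_id]
    expect_equal(length(members), r$n_probes)
    ann <- b$ann[b$ann$probe_id %in% members, ]
    expect_true(all(ann$chrom == r$chrom))
    expect_true(all(ann$pos > r$start & ann$pos <= r$end))
  }
  ## planted fractions follow the configured hyper:hypo split exactly
  ## (up to rounding at small region counts)
  kr <- b$truth$regions[b$truth$regions$contrast == "KR", ]
  expect_equal(sum(kr$direction == "hyper"), round(0.55 * nrow(kr)))
  wt <- b$truth$regions[b$truth$regions$contrast == "WT", ]
  expect_equal(sum(wt$direction == "hypo"), round(0.736 * nrow(wt)))
})

test_that("planted effect sizes match the configuration (Monte Carlo)", {
  b <- small_cohort()
  tp <- b$truth$probes
  ss <- b$samples
  g1 <- unique(ss$patient_id[ss$tissue == "WT" & ss$subgroup == "group1"])
  wtp <- tp$probe_id[tp$role == "wt_dmr"]
  d_wt <- rowMeans(b$beta[wtp, paste0(g1, "_WT"), drop = FALSE]) -
    rowMeans(b$beta[wtp, paste0(g1, "_NR"), drop = FALSE])
  expect_equal(mean(abs(d_wt)), b$config$wt_delta, tolerance = 0.2 * b$config$wt_delta)
  krp <- tp$probe_id[tp$role == "kr_dmr"]
  pats <- unique(ss$patient_id[ss$tissue == "NR"])
  d_kr <- rowMeans(b$beta[krp, paste0(pats, "_NR"), drop = FALSE]) -
    rowMeans(b$beta[krp, paste0(pats, "_NK"), drop = FALSE])
  expect_equal(mean(abs(d_kr)), b$config$kr_delta, tolerance = 0.2 * b$config$kr_delta)
})

test_that("zero-effect configuration leaves WT indistinguishable from NR", {
  b <- null_cohort(seed = 77, n_probes = 4000)
  mvp <- fit_paired(b$beta, b$samples, "WT", "NR")
  expect_equal(sum(mvp$fdr < 0.01), 0)
  ## empirical type-I error at p < 0.05 within 3 SE of 0.05
  n <- nrow(mvp)
  expect_lt(abs(mean(mvp$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("group-1 hypervariability inflates probe-wise WT variance", {
  b <- small_cohort()
  ss <- b$samples
  g1 <- ss$sample_id[ss$tissue == "WT" & ss$subgroup == "group1"]
  g2 <- ss$sample_id[ss$tissue == "WT" & ss$subgroup == "group2"]
  v1 <- methtrio:::row_vars(b$beta[, g1])
  v2 <- methtrio:::row_vars(b$beta[, g2])
  expect_gt(mean(v1 > v2), 0.5)
})

test_that("mixture-sensitive probes respond to the true mixture proportions", {
  b <- small_cohort()
  tp <- b$truth$probes
  w <- b$truth$mixtures
  sens <- sample(tp$probe_id[tp$mixture_sensitive], 50)
  r2 <- vapply(sens, function(pid) {
    fit <- lm(b$beta[pid, rownames(w)] ~ w[, 1] + w[, 2])
    summary(fit)$r.squared
  }, 1)
  null_probes <- sample(tp$probe_id[!tp$mixture_sensitive & tp$role == "null"], 50)
  r2_null <- vapply(null_probes, function(pid) {
    fit <- lm(b$beta[pid, rownames(w)] ~ w[, 1] + w[, 2])
    summary(fit)$r.squared
  }, 1)
  expect_gt(mean(r2), mean(r2_null) + 0.2)
})

test_that("fixtures round-trip through the io module", {
  b <- simulate_cohort(sim_config(n_probes = 800, kr_dmr_count = 3,
                                  wt_dmr_count = 2, ek_mvp_count = 10,
                                  detection_fail_rate = 0.001, seed = 15))
  dir <- withr::local_tempdir()
  write_fixture(b, dir)
  loaded <- load_cohort(dir, verbose = FALSE)
  expect_equal(dim(loaded$beta), dim(b$beta))
  expect_setequal(rownames(loaded$beta), rownames(b$beta))
  expect_equal(loaded$beta[rownames(b$beta), colnames(b$beta)], b$beta,
               tolerance = 1e-9)
  expect_setequal(names(loaded$features), names(b$features))
  for (nm in names(b$features)) {
    expect_equal(GenomicRanges::start(loaded$features[[nm]]),
                 GenomicRanges::start(b$features[[nm]]))
    expect_equal(GenomicRanges::end(loaded$features[[nm]]),
                 GenomicRanges::end(b$features[[nm]]))
  }
  ## manifest consistency with the beta file
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$probes), nrow(b$beta))
  ## BED files are 0-based half-open and sorted
  bed <- read.table(file.path(dir, "features", "bivalent_domains.bed"))
  expect_true(all(bed$V2 < bed$V3))
  expect_true(all(bed$V2 >= 0))
  o <- order(bed$V1, bed$V2)
  expect_equal(o, seq_len(nrow(bed)))
})
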