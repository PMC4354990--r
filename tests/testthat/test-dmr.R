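fake_lassos <- function(dat) {
  list(radii = NULL, global_radius = NA, min_lasso_bp = 10,
       quantile_used = 0.5,
       probe_radius = setNames(dat$radius, dat$probe_id))
}

as_mvp <- function(dat) {
  dat[, c("probe_id", "delta_beta", "p", "fdr")]
}

test_that("lasso radii follow category nearest-neighbour quantiles", {
  ## equally spaced probes, one category: radius = spacing at quantile 0.5
  ann <- data.frame(
    probe_id = sprintf("cg%02d", 1:20), chrom = "chr1",
    pos = seq(100, by = 100, length.out = 20),
    gene_feature = "Body", cgi_relation = "open_sea"
  )
  spec <- compute_lassos(ann)
  expect_equal(unname(spec$radii[["Body|open_sea"]]), 100)
  expect_equal(unname(spec$probe_radius[["cg01"]]), 100)

  ## the 10 bp minimum floors the radius at 5 in ultra-dense spacing
  ann$pos <- seq(100, by = 4, length.out = 20)
  spec <- compute_lassos(ann, min_lasso_bp = 10)
  expect_equal(unname(spec$radii[["Body|open_sea"]]), 5)

  ## sparse categories inherit the global quantile
  ann2 <- ann
  ann2$pos <- seq(100, by = 100, length.out = 20)
  ann2$gene_feature[1] <- "TSS200"  # singleton category
  spec <- compute_lassos(ann2)
  expect_equal(unname(spec$radii[["TSS200|open_sea"]]), spec$global_radius)

  expect_error(compute_lassos(ann[0, ]), "empty")
})

test_that("the toy connectivity example resolves as specified", {
  ## significant probes at 100/150/200 (radius 100 each); non-significant
  ## probe at 1120 outside every member lasso; lone significant probe at
  ## 5000 whose component is too small
  dat <- data.frame(
    probe_id = paste0("cg", 1:5), chrom = "chr1",
    pos = c(100, 150, 200, 1120, 5000),
    delta_beta = c(0.3, 0.31, 0.29, 0.01, 0.4),
    p = c(1e-6, 1e-7, 1e-6, 0.6, 1e-6),
    fdr = c(0.001, 0.001, 0.001, 0.9, 0.001),
    radius = 100
  )
  dmrs <- call_dmrs(as_mvp(dat), dat[, c("probe_id", "chrom", "pos")],
                    fake_lassos(dat))
  expect_equal(nrow(dmrs), 1)
  expect_setequal(dmrs$probes[[1]]$probe_id, c("cg1", "cg2", "cg3"))
  expect_equal(dmrs$n_significant[1], 3)
  expect_equal(dmrs$start[1], 99)
  expect_equal(dmrs$end[1], 200)
  expect_identical(dmrs$direction[1], "hyper")
})

test_that("no significant probes produces an empty DMR set", {
  dat <- data.frame(
    probe_id = paste0("cg", 1:4), chrom = "chr1",
    pos = c(100, 200, 300, 400), delta_beta = 0.1,
    p = 0.5, fdr = 0.9, radius = 100
  )
  dmrs <- call_dmrs(as_mvp(dat), dat[, c("probe_id", "chrom", "pos")],
                    fake_lassos(dat))
  expect_equal(nrow(dmrs), 0)
})

test_that("nearby regions merge within the 1 kb rule", {
  ## two 3-probe clusters whose bounds are 900 bp apart -> one DMR
  dat <- data.frame(
    probe_id = paste0("cg", 1:6), chrom = "chr1",
    pos = c(9800, 9900, 10000, 10900, 11000, 11100),
    delta_beta = 0.3, p = 1e-6, fdr = 0.001, radius = 100
  )
  dmrs <- call_dmrs(as_mvp(dat), dat[, c("probe_id", "chrom", "pos")],
                    fake_lassos(dat))
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$merged_from[1], 2)
  expect_equal(dmrs$n_significant[1], 6)

  ## a gap of exactly 1000 bp (region bounds 10000 to 11000) stays split
  dat2 <- dat
  dat2$pos <- c(9800, 9900, 10000, 11001, 11101, 11201)
  dmrs2 <- call_dmrs(as_mvp(dat2), dat2[, c("probe_id", "chrom", "pos")],
                     fake_lassos(dat2))
  expect_equal(nrow(dmrs2), 2)
})

test_that("probe-lasso calls match the brute-force oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:40) {
    dat <- random_dmr_fixture(n_probes = sample(30:120, 1))
    dmrs <- call_dmrs(as_mvp(dat), dat[, c("probe_id", "chrom", "pos")],
                      fake_lassos(dat))
    oracle <- brute_force_dmrs(dat)
    expect_same_dmrs(dmrs, oracle)
  }
})

test_that("DMR output is invariant to input probe order and merge idempotent", {
  set.seed(99)
  dat <- random_dmr_fixture(n_probes = 100)
  dmrs1 <- call_dmrs(as_mvp(dat), dat[, c("probe_id", "chrom", "pos")],
                     fake_lassos(dat))
  o <- sample(nrow(dat))
  dmrs2 <- call_dmrs(as_mvp(dat[o, ]), dat[o, c("probe_id", "chrom", "pos")],
                     fake_lassos(dat))
  expect_equal(dmrs1$start, dmrs2$start)
  expect_equal(dmrs1$n_significant, dmrs2$n_significant)
  expect_equal(dmrs1$combined_p, dmrs2$combined_p)
  ## regions in the output are pairwise farther than the merge gap
  if (nrow(dmrs1) > 1) {
    by_chrom <- split(dmrs1, dmrs1$chrom)
    for (cc in by_chrom) {
      if (nrow(cc) < 2) next
      gaps <- cc$start[-1] - cc$end[-nrow(cc)]
      expect_true(all(gaps >= 1000))
    }
  }
})

test_that("DMR summaries tally directions and categories correctly", {
  b <- small_cohort()
  mvp <- fit_paired(b$beta, b$samples, "NR", "NK")
  lassos <- compute_lassos(b$ann)
  dmrs <- call_dmrs(mvp, b$ann, lassos)
  expect_gt(nrow(dmrs), 0)
  summ <- summarize_dmrs(dmrs, b$ann)
  expect_equal(sum(summ$by_direction$count), nrow(dmrs))
  expect_equal(sum(summ$by_direction$fraction), 1)
  ## per-direction fractions sum to 1 within each facet
  agg <- tapply(summ$by_gene_feature$fraction, summ$by_gene_feature$direction,
                sum)
  expect_equal(as.numeric(agg), rep(1, length(agg)))
  ## brute-force tally of one direction
  n_hyper <- sum(dmrs$direction == "hyper")
  expect_equal(summ$by_direction$count[summ$by_direction$direction == "hyper"],
               n_hyper)
  ## empty input
  empty <- summarize_dmrs(methtrio:::empty_dmr_frame(), b$ann)
  expect_equal(nrow(empty$by_direction), 0)
})

test_that("planted DMRs are recovered at region level", {
  b <- small_cohort()
  mvp <- fit_paired(b$beta, b$samples, "NR", "NK")
  lassos <- compute_lassos(b$ann)
  dmrs <- call_dmrs(mvp, b$ann, lassos)
  truth <- b$truth$regions[b$truth$regions$contrast == "KR", ]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(dmrs$chrom == truth$chrom[i] & dmrs$start < truth$end[i] &
          dmrs$end > truth$start[i])
  }, TRUE)
  expect_gte(mean(hit), 0.9)
  ## every called region is built from truly differential probes: planted
  ## NR-vs-NK probes or mixture-sensitive ones (NK composition differs, so
  ## those probes are genuinely shifted too)
  tp <- b$truth$probes
  true_diff <- tp$probe_id[tp$role %in% c("kr_dmr", "kr_mvp") |
                             tp$mixture_sensitive]
  precise <- vapply(seq_len(nrow(dmrs)), function(i) {
    pr <- dmrs$probes[[i]]
    mean(pr$probe_id[pr$significant] %in% true_diff) >= 0.5
  }, TRUE)
  expect_gte(mean(precise), 0.9)
  ## directions match the planted truth for matched regions
  ov <- which(hit)
  for (i in ov[1:min(5, length(ov))]) {
    called <- dmrs[dmrs$chrom == truth$chrom[i] & dmrs$start < truth$end[i] &
                     dmrs$end > truth$start[i], ]
    expect_true(truth$direction[i] %in% called$direction)
  }
})
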