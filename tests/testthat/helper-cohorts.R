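# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cohort_cache[[key]])) assign(key, build(), .cohort_cache)
  get(key, .cohort_cache)
}

## Mid-sized cohort with every structural element present.
small_cohort <- function() {
  cached("small", function() {
    simulate_cohort(sim_config(
      n_probes = 6000, kr_dmr_count = 12, wt_dmr_count = 10,
      kr_mvp_count = 300, wt_mvp_count = 300,
      ek_mvp_count = 100, seed = 101
    ))
  })
}

## Fully null WT-vs-NR arm: no planted WT effects, no hypervariability.
null_cohort <- function(seed = 202, n_probes = 6000) {
  simulate_cohort(sim_config(
    n_probes = n_probes, kr_dmr_count = 0, wt_dmr_count = 0,
    kr_mvp_count = 0, wt_mvp_count = 0,
    ek_mvp_count = 0, n_ek = 0, hypervariability = 1, seed = seed
  ))
}

## Minimal enrichment fixture: a universe of positioned probes with one
## feature set covering a known fraction of them.
toy_universe <- function(n = 2000, feature_frac = 0.25, seed = 1) {
  set.seed(seed)
  ann <- data.frame(
    probe_id = sprintf("cg%05d", seq_len(n)), chrom = "chr1",
    pos = sort(sample.int(n * 200, n)),
    gene_feature = "Body", cgi_relation = "open_sea",
    stringsAsFactors = FALSE
  )
  n_in <- round(feature_frac * n)
  inside <- sort(sample.int(n, n_in))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = ann$pos[inside], end = ann$pos[inside])
  ))
  list(ann = ann, features = list(set1 = gr), inside = ann$probe_id[inside])
}

## Strong tissue-correlated mixture confounding in the WT-vs-NR contrast:
## every pair confounded, ample within-tissue composition spread.
confounded_cohort <- function(seed = 303, n_probes = 8000,
                              wt_dmr_count = 20, wt_delta = 0.2) {
  cfg <- sim_config(
    n_probes = n_probes, n_patients = 20, frac_group1 = 1,
    kr_dmr_count = 0, wt_dmr_count = wt_dmr_count, wt_delta = wt_delta,
    kr_mvp_count = 0, wt_mvp_count = 0,
    ek_mvp_count = 0, n_ek = 0, hypervariability = 1,
    noise_sd = 0.3, mixture_sd = 1.5, mixture_sensitive_frac = 0.25,
    seed = seed
  )
  cfg$mixture_alpha$NR <- rep(1.2, 3)
  cfg$mixture_alpha$WT_group1 <- c(0.4, 1.2, 2.4)
  cfg$mixture_alpha$WT_group2 <- cfg$mixture_alpha$NR
  simulate_cohort(cfg)
}
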