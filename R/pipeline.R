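#' Pipeline run configuration
#'
#' Thresholds and seeds for [run_trio_analysis()] and
#' [run_ek_comparison()]. Defaults are the analysis operating points:
#' MVP significance FDR < 0.01; ANOVA genome-wide significance at raw
#' p < 5e-8; DMRs from >= 3 connected significant probes with a 10 bp
#' minimum lasso and 1 kb merging; top 1% most-variable probes for
#' unsupervised views; pheno-MVPs at bootstrap p < 0.01 (and, for the
#' embryonic-kidney contrasts, |delta beta| > 0.2).
#'
#' @param fdr MVP FDR threshold.
#' @param genomewide_p ANOVA raw-p threshold.
#' @param min_sig_probes,min_lasso_bp,merge_gap_bp DMR parameters.
#' @param top_frac fraction of most-variable probes.
#' @param reffree_p,reffree_delta_beta pheno-MVP thresholds.
#' @param d latent mixture dimension for the reference-free fit ("auto" or
#'   an integer).
#' @param n_bootstrap bootstrap replicates for the reference-free fit.
#' @param n_resamples_enrich multisampling draws for enrichment.
#' @param consensus_k clusters for the subtype clustering (3: the tissue
#'   classes NK / NR-like / tumour-distinct).
#' @param n_resamples_consensus consensus subsampling iterations.
#' @param nr_cluster_frac minimum NR fraction for a cluster to count as
#'   "NR-like" when assigning WT subgroups.
#' @param detection_threshold detection p-value cutoff.
#' @param seed master seed for all stochastic stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(fdr = 0.01, genomewide_p = 5e-8, min_sig_probes = 3,
                       min_lasso_bp = 10, merge_gap_bp = 1000,
                       top_frac = 0.01, reffree_p = 0.01,
                       reffree_delta_beta = 0.2, d = 3,
                       n_bootstrap = 100, n_resamples_enrich = 100,
                       consensus_k = 3, n_resamples_consensus = 1000,
                       nr_cluster_frac = 0.2, detection_threshold = 0.01,
                       seed = 1L) {
  cfg <- list(
    fdr = fdr, genomewide_p = genomewide_p,
    min_sig_probes = min_sig_probes, min_lasso_bp = min_lasso_bp,
    merge_gap_bp = merge_gap_bp, top_frac = top_frac,
    reffree_p = reffree_p, reffree_delta_beta = reffree_delta_beta,
    d = d, n_bootstrap = n_bootstrap,
    n_resamples_enrich = n_resamples_enrich, consensus_k = consensus_k,
    n_resamples_consensus = n_resamples_consensus,
    nr_cluster_frac = nr_cluster_frac,
    detection_threshold = detection_threshold, seed = as.integer(seed)
  )
  num <- c("fdr", "genomewide_p", "min_sig_probes", "min_lasso_bp",
           "merge_gap_bp", "top_frac", "reffree_p", "reffree_delta_beta",
           "n_bootstrap", "n_resamples_enrich", "consensus_k",
           "n_resamples_consensus", "detection_threshold")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("run_config: '", f, "' must be positive")
    }
  }
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

## Assign WT subgroups from a consensus clustering: WTs co-clustering with
## NRs are "group2", WTs in NR-poor clusters "group1".
assign_wt_subgroups <- function(assignments, samples, nr_cluster_frac = 0.2) {
  ss <- samples[match(names(assignments), samples$sample_id), , drop = FALSE]
  nr_frac <- tapply(ss$tissue == "NR", assignments, mean)
  nr_like <- names(nr_frac)[nr_frac >= nr_cluster_frac]
  wt <- ss$tissue == "WT"
  out <- ifelse(as.character(assignments[wt]) %in% nr_like, "group2", "group1")
  setNames(out, names(assignments)[wt])
}

#' Run the full matched-trio analysis
#'
#' Executes, in order: probe filtering; three-tissue moderated ANOVA over
#' the complete trios; consensus clustering of the genome-wide-significant
#' CpGs and WT subgroup assignment (WTs co-clustering with NRs form
#' "group2"); per-subgroup paired WT-NR differential methylation; probe-lasso
#' DMR calling on the group-1 contrast; paired NR-NK differential
#' methylation and KR-DMR calling; reference-free ("pheno-MVP") fits for
#' both contrasts with overlap statistics; multisampling feature enrichment
#' of hyper-KR-DMR probes; and mean-plus-one-SD hypermethylation
#' classification of group-1 tumours at hyper-WT-DMRs. Each stage's outputs
#' are returned (and written as TSV/BED plus a JSON provenance report when
#' `out_dir` is given).
#'
#' @param bundle cohort bundle from [simulate_cohort()] or [load_cohort()].
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param verbose log stage progress.
#' @return A run-report list; see the elements written to `report.json`.
#' @export
run_trio_analysis <- function(bundle, config = run_config(), out_dir = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage("validate", validate_cohort(bundle$beta, bundle$ann, bundle$samples))
  samples <- bundle$samples
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  filt <- stage("filter", filter_probes(
    bundle$beta, bundle$ann, detection_p = bundle$detection_p,
    detection_threshold = config$detection_threshold
  ))
  beta <- filt$beta
  ann <- bundle$ann[match(rownames(beta), bundle$ann$probe_id), , drop = FALSE]
  msg(sprintf("filter: %d -> %d probes", filt$report$probes_in,
              filt$report$probes_out), verbose = verbose)

  anova <- stage("anova", fit_anova3(beta, samples,
                                     genomewide_p = config$genomewide_p))
  sig_probes <- anova$probe_id[anova$p < config$genomewide_p]
  msg(sprintf("anova: %d genome-wide-significant CpGs (p < %g)",
              length(sig_probes), config$genomewide_p), verbose = verbose)

  cluster_input <- if (length(sig_probes) >= 10) {
    sig_probes
  } else {
    warning("run_trio_analysis: <10 genome-wide-significant CpGs; ",
            "clustering the top-variable probes instead")
    top_variable(beta, fraction = config$top_frac)
  }
  trio_ids <- samples$sample_id[samples$tissue %in% c("NK", "NR", "WT")]
  cons <- stage("cluster", consensus_cluster(
    beta[cluster_input, trio_ids, drop = FALSE], k = config$consensus_k,
    n_resamples = config$n_resamples_consensus, seed = config$seed
  ))
  subgroups <- stage("subgroups", assign_wt_subgroups(
    cons$assignments, samples, config$nr_cluster_frac
  ))
  g1_patients <- samples$patient_id[match(names(subgroups)[subgroups == "group1"],
                                          samples$sample_id)]
  g2_patients <- samples$patient_id[match(names(subgroups)[subgroups == "group2"],
                                          samples$sample_id)]
  msg(sprintf("subgroups: %d group-1, %d group-2 WT", length(g1_patients),
              length(g2_patients)), verbose = verbose)

  lassos <- stage("lassos", compute_lassos(ann,
                                           min_lasso_bp = config$min_lasso_bp))

  mvp_wt_g1 <- NULL
  dmr_wt <- empty_dmr_frame()
  if (length(g1_patients) >= 2) {
    mvp_wt_g1 <- stage("mvp_wt_group1", fit_paired(
      beta, samples, "WT", "NR", patients = g1_patients
    ))
    dmr_wt <- stage("dmr_wt", call_dmrs(
      mvp_wt_g1, ann, lassos, sig_fdr = config$fdr,
      min_sig_probes = config$min_sig_probes,
      merge_gap_bp = config$merge_gap_bp
    ))
  }
  mvp_wt_g2 <- if (length(g2_patients) >= 2) {
    stage("mvp_wt_group2", fit_paired(beta, samples, "WT", "NR",
                                      patients = g2_patients))
  } else NULL

  mvp_kr <- stage("mvp_kr", fit_paired(beta, samples, "NR", "NK"))
  dmr_kr <- stage("dmr_kr", call_dmrs(
    mvp_kr, ann, lassos, sig_fdr = config$fdr,
    min_sig_probes = config$min_sig_probes,
    merge_gap_bp = config$merge_gap_bp
  ))
  msg(sprintf("dmr: %d WT-DMRs (group-1), %d KR-DMRs", nrow(dmr_wt),
              nrow(dmr_kr)), verbose = verbose)

  ## the WT-NR adjustment runs within the discovered group-1 pairs: with
  ## the two subgroups pooled, the group-1-coherent tumour signature is
  ## indistinguishable from a latent composition axis and would be absorbed
  reffree_wt <- stage("reffree_wt", reffree_fit(
    beta, samples, "WT", "NR", d = config$d,
    patients = if (length(g1_patients) >= 2) g1_patients else NULL,
    paired = TRUE, n_bootstrap = config$n_bootstrap, seed = config$seed
  ))
  reffree_kr <- stage("reffree_kr", reffree_fit(
    beta, samples, "NR", "NK", d = config$d, paired = TRUE,
    n_bootstrap = config$n_bootstrap, seed = config$seed
  ))
  overlap_wt <- if (!is.null(mvp_wt_g1)) {
    overlap_mvps(mvp_wt_g1$probe_id[mvp_wt_g1$fdr < config$fdr],
                 reffree_wt$probe_id[reffree_wt$p < config$reffree_p])
  } else NULL
  overlap_kr <- overlap_mvps(mvp_kr$probe_id[mvp_kr$fdr < config$fdr],
                             reffree_kr$probe_id[reffree_kr$p < config$reffree_p])

  enrich_res <- NULL
  if (length(bundle$features) > 0 && nrow(dmr_kr) > 0) {
    hyper_kr_probes <- unique(unlist(lapply(
      which(dmr_kr$direction == "hyper"),
      function(i) dmr_kr$probes[[i]]$probe_id
    )))
    if (length(hyper_kr_probes) > 0) {
      enrich_res <- stage("enrichment", multisample_enrichment(
        hyper_kr_probes, rownames(beta), ann, bundle$features,
        n_resamples = config$n_resamples_enrich, seed = config$seed
      ))
    }
  }

  classifier <- NULL
  hyper_wt <- dmr_wt[dmr_wt$direction == "hyper", , drop = FALSE]
  g1_wt_samples <- names(subgroups)[subgroups == "group1"]
  nr_samples <- samples$sample_id[samples$tissue == "NR"]
  if (nrow(hyper_wt) > 0 && length(g1_wt_samples) > 0 &&
      length(nr_samples) >= 2) {
    classifier <- stage("classifier", classify_hypermethylation(
      beta, hyper_wt, g1_wt_samples, nr_samples
    ))
  }

  report <- list(
    parameters = unclass(config),
    seed = config$seed,
    input = list(n_probes = nrow(bundle$beta), n_samples = ncol(bundle$beta),
                 checksum = cohort_checksum(bundle$beta)),
    filter_report = filt$report,
    anova = list(n_tested = nrow(anova),
                 n_genomewide = attr(anova, "n_genomewide")),
    clustering = list(k = cons$k, assignments = as.list(cons$assignments)),
    subgroups = as.list(subgroups),
    counts = list(
      mvp_wt_group1 = if (!is.null(mvp_wt_g1)) sum(mvp_wt_g1$fdr < config$fdr) else NA,
      mvp_wt_group2 = if (!is.null(mvp_wt_g2)) sum(mvp_wt_g2$fdr < config$fdr) else NA,
      mvp_kr = sum(mvp_kr$fdr < config$fdr),
      dmr_wt = nrow(dmr_wt), dmr_kr = nrow(dmr_kr),
      pheno_mvp_wt = sum(reffree_wt$p < config$reffree_p),
      pheno_mvp_kr = sum(reffree_kr$p < config$reffree_p)
    ),
    overlap = list(wt = overlap_wt[c("n_overlap", "fraction_of_a")],
                   kr = overlap_kr[c("n_overlap", "fraction_of_a")])
  )

  out <- list(
    report = report, filter = filt$report, anova = anova,
    consensus = cons, subgroups = subgroups, lassos = lassos,
    mvp_wt_group1 = mvp_wt_g1, mvp_wt_group2 = mvp_wt_g2, mvp_kr = mvp_kr,
    dmr_wt = dmr_wt, dmr_kr = dmr_kr,
    reffree_wt = reffree_wt, reffree_kr = reffree_kr,
    overlap_wt = overlap_wt, overlap_kr = overlap_kr,
    enrichment = enrich_res, classifier = classifier
  )
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

cohort_checksum <- function(beta) {
  sprintf("%dx%d:%.6f:%.6f", nrow(beta), ncol(beta),
          sum(beta, na.rm = TRUE), sum(beta[, 1], na.rm = TRUE))
}

write_mvp_tsv <- function(mvp, path) {
  utils::write.table(mvp, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_run_outputs <- function(out, out_dir) {
  if (!is.null(out$mvp_wt_group1)) {
    write_mvp_tsv(out$mvp_wt_group1, file.path(out_dir, "mvp_wt_group1.tsv"))
  }
  if (!is.null(out$mvp_wt_group2)) {
    write_mvp_tsv(out$mvp_wt_group2, file.path(out_dir, "mvp_wt_group2.tsv"))
  }
  write_mvp_tsv(out$mvp_kr, file.path(out_dir, "mvp_kr.tsv"))
  write_mvp_tsv(out$anova, file.path(out_dir, "anova.tsv"))
  write_dmr_bed(out$dmr_wt, file.path(out_dir, "dmr_wt.bed"))
  write_dmr_bed(out$dmr_kr, file.path(out_dir, "dmr_kr.bed"))
  if (!is.null(out$enrichment)) {
    write_mvp_tsv(out$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(out$classifier)) {
    write_mvp_tsv(out$classifier$frequency,
                  file.path(out_dir, "hypermethylation_frequency.tsv"))
  }
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Embryonic-kidney comparison
#'
#' Unpaired reference-free contrasts NR-vs-EK and WT-vs-EK, with pheno-MVPs
#' filtered at `p < reffree_p` and `|delta beta| > reffree_delta_beta`,
#' followed by multisampling enrichment of the hyper-MVPs (hypermethylated
#' in the tissue with respect to EK) against the provided feature sets.
#'
#' @param bundle cohort bundle containing EK samples.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param verbose log stage progress.
#' @return list with per-contrast pheno-MVP tables, counts and enrichment.
#' @export
run_ek_comparison <- function(bundle, config = run_config(), out_dir = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage("validate", validate_cohort(bundle$beta, bundle$ann, bundle$samples))
  samples <- bundle$samples
  n_ek <- sum(samples$tissue == "EK")
  if (n_ek < 2) stop("run_ek_comparison: need at least 2 EK samples")

  filt <- stage("filter", filter_probes(
    bundle$beta, bundle$ann, detection_p = bundle$detection_p,
    detection_threshold = config$detection_threshold
  ))
  beta <- filt$beta
  ann <- bundle$ann[match(rownames(beta), bundle$ann$probe_id), , drop = FALSE]

  one_contrast <- function(tissue) {
    fit <- stage(paste0("reffree_", tolower(tissue), "_ek"), reffree_fit(
      beta, samples, tissue, "EK", d = config$d, paired = FALSE,
      n_bootstrap = config$n_bootstrap, seed = config$seed
    ))
    sel <- fit$p < config$reffree_p &
      abs(fit$coef) > config$reffree_delta_beta
    tab <- data.frame(
      probe_id = fit$probe_id, delta_beta = fit$coef, p = fit$p,
      direction = fit$direction, selected = sel, stringsAsFactors = FALSE
    )
    list(fit = fit, mvps = tab[sel, , drop = FALSE],
         n_hyper = sum(sel & fit$coef > 0), n_hypo = sum(sel & fit$coef < 0))
  }
  nr_ek <- one_contrast("NR")
  wt_ek <- one_contrast("WT")
  msg(sprintf("ek: NR-EK %d pheno-MVPs (%d hyper / %d hypo); WT-EK %d",
              nrow(nr_ek$mvps), nr_ek$n_hyper, nr_ek$n_hypo,
              nrow(wt_ek$mvps)), verbose = verbose)

  enrich_res <- NULL
  hyper_probes <- nr_ek$mvps$probe_id[nr_ek$mvps$delta_beta > 0]
  if (length(bundle$features) > 0 && length(hyper_probes) > 0) {
    enrich_res <- stage("enrichment", multisample_enrichment(
      hyper_probes, rownames(beta), ann, bundle$features,
      n_resamples = config$n_resamples_enrich, seed = config$seed
    ))
  }

  out <- list(
    nr_ek = nr_ek, wt_ek = wt_ek, enrichment = enrich_res,
    report = list(
      parameters = unclass(config),
      counts = list(
        nr_ek_mvps = nrow(nr_ek$mvps), nr_ek_hyper = nr_ek$n_hyper,
        nr_ek_hypo = nr_ek$n_hypo, wt_ek_mvps = nrow(wt_ek$mvps),
        wt_ek_hyper = wt_ek$n_hyper, wt_ek_hypo = wt_ek$n_hypo
      )
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mvp_tsv(nr_ek$mvps, file.path(out_dir, "pheno_mvp_nr_ek.tsv"))
    write_mvp_tsv(wt_ek$mvps, file.path(out_dir, "pheno_mvp_wt_ek.tsv"))
    if (!is.null(enrich_res)) {
      write_mvp_tsv(enrich_res, file.path(out_dir, "enrichment_ek.tsv"))
    }
    jsonlite::write_json(out$report, file.path(out_dir, "report_ek.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  out
}
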