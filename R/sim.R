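#' Configuration for the synthetic trio-cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' the statistical structure of a 20-trio nephrogenic-rest / Wilms-tumour
#' methylome study: 20 patients each contributing matched normal kidney (NK),
#' nephrogenic rest (NR) and Wilms tumour (WT) samples, a 13/20 "group-1"
#' tumour subgroup carrying planted WT-vs-NR effects and inflated probe-level
#' noise, planted NR-vs-NK ("KR") DMRs split 55:45 hyper:hypo, planted
#' WT-vs-NR DMRs 73.6% hypomethylated, three latent cell types mixed per
#' sample with Dirichlet weights, and four unmatched embryonic-kidney (EK)
#' samples.
#'
#' Beta-values are generated as logit-normal mixtures: per-cell-type baseline
#' methylomes are combined with per-sample Dirichlet mixture weights on the
#' beta scale, then patient random effects, planted tissue shifts and probe
#' noise are added on the logit scale, keeping every value strictly inside
#' (0, 1). Group-2 WT samples are drawn from the same distribution as their
#' NR (no planted WT effect, unit noise multiplier, identical mixture
#' concentration), so a paired WT-vs-NR contrast within group-2 is exactly
#' null.
#'
#' @param n_patients number of matched trios.
#' @param n_probes total number of array probes to simulate.
#' @param n_cell_types latent cell types `d` mixed into every sample.
#' @param frac_group1 fraction of WT samples assigned to group-1.
#' @param kr_dmr_count,wt_dmr_count number of planted NR-vs-NK and
#'   group-1-WT-vs-NR DMRs; defaults scale with the array size at the
#'   density of the full-array study (about 630 DMRs per contrast on 450k).
#' @param kr_mvp_count,wt_mvp_count scattered single-probe differential
#'   positions planted outside DMRs for the same two contrasts, default 5%
#'   of probes each (real tumour/precursor methylomes carry far more
#'   isolated MVPs than DMR-clustered ones); scattered probes are kept
#'   non-adjacent so they cannot form DMRs themselves.
#' @param dmr_probes_min,dmr_probes_max probes per planted DMR (uniform).
#' @param kr_delta,wt_delta planted absolute beta shifts, in (0, 1).
#' @param kr_hyper_frac fraction of KR-DMRs hypermethylated in NR vs NK.
#' @param wt_hypo_frac fraction of WT-DMRs hypomethylated in WT vs NR.
#' @param hypervariability probe-noise SD multiplier for group-1 WT samples.
#' @param feature_enrichment fraction of hyper-KR-DMRs placed inside the
#'   `bivalent_domains` feature set.
#' @param n_ek number of unmatched embryonic-kidney samples (0 to disable).
#' @param ek_mvp_count,ek_delta,ek_hyper_frac planted NR/WT-vs-EK
#'   single-probe effects: count, absolute shift, fraction hypermethylated in
#'   NR with respect to EK.
#' @param ek_prc2_frac fraction of hyper-EK probes placed inside the
#'   `prc2_targets` feature set.
#' @param mixture_sensitive_frac fraction of (null) probes whose methylation
#'   differs between latent cell types.
#' @param mixture_sd SD of per-cell-type logit offsets at mixture-sensitive
#'   probes.
#' @param mixture_alpha named list of Dirichlet concentration vectors (length
#'   `n_cell_types`) for `NK`, `NR`, `WT_group1`, `WT_group2`, `EK`. The
#'   default gives NR and both WT groups identical composition (tumour
#'   composition shift is a deliberate switch, see
#'   [confounded_config()]).
#' @param noise_sd probe-level logit-scale noise SD.
#' @param patient_sd SD of the patient random effect shared within a trio.
#' @param bilateral_frac fraction of group-1 patients with bilateral disease
#'   (group-2 patients are always unilateral).
#' @param detection_fail_rate per-entry probability of a failed detection
#'   p-value (> 0.01); 0 disables the detection matrix.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       n_probes = 20000,
                       n_cell_types = 3,
                       frac_group1 = 13 / 20,
                       kr_dmr_count = round(0.002 * n_probes),
                       wt_dmr_count = round(0.0015 * n_probes),
                       kr_mvp_count = round(0.05 * n_probes),
                       wt_mvp_count = round(0.05 * n_probes),
                       dmr_probes_min = 4,
                       dmr_probes_max = 8,
                       kr_delta = 0.3,
                       kr_hyper_frac = 0.55,
                       wt_delta = 0.35,
                       wt_hypo_frac = 0.736,
                       hypervariability = 1.5,
                       feature_enrichment = 0.15,
                       n_ek = 4,
                       ek_mvp_count = round(0.015 * n_probes),
                       ek_delta = 0.3,
                       ek_hyper_frac = 0.55,
                       ek_prc2_frac = 0.35,
                       mixture_sensitive_frac = 0.15,
                       mixture_sd = 1.2,
                       mixture_alpha = NULL,
                       noise_sd = 0.35,
                       patient_sd = 0.25,
                       bilateral_frac = 9 / 13,
                       detection_fail_rate = 0,
                       seed = 1L) {
  d <- n_cell_types
  if (is.null(mixture_alpha)) {
    nr_alpha <- rep(3, d)
    mixture_alpha <- list(
      NK = seq(d + 3, 1, length.out = d),
      NR = nr_alpha,
      WT_group1 = nr_alpha,
      WT_group2 = nr_alpha,
      EK = rev(seq(d + 3, 1, length.out = d))
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients), n_probes = as.integer(n_probes),
    n_cell_types = as.integer(d), frac_group1 = frac_group1,
    kr_dmr_count = as.integer(kr_dmr_count),
    wt_dmr_count = as.integer(wt_dmr_count),
    kr_mvp_count = as.integer(kr_mvp_count),
    wt_mvp_count = as.integer(wt_mvp_count),
    dmr_probes_min = as.integer(dmr_probes_min),
    dmr_probes_max = as.integer(dmr_probes_max),
    kr_delta = kr_delta, kr_hyper_frac = kr_hyper_frac,
    wt_delta = wt_delta, wt_hypo_frac = wt_hypo_frac,
    hypervariability = hypervariability,
    feature_enrichment = feature_enrichment,
    n_ek = as.integer(n_ek), ek_mvp_count = as.integer(ek_mvp_count),
    ek_delta = ek_delta, ek_hyper_frac = ek_hyper_frac,
    ek_prc2_frac = ek_prc2_frac,
    mixture_sensitive_frac = mixture_sensitive_frac,
    mixture_sd = mixture_sd, mixture_alpha = mixture_alpha,
    noise_sd = noise_sd, patient_sd = patient_sd,
    bilateral_frac = bilateral_frac,
    detection_fail_rate = detection_fail_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c("frac_group1", "kr_hyper_frac", "wt_hypo_frac",
          "feature_enrichment", "ek_hyper_frac", "ek_prc2_frac",
          "mixture_sensitive_frac", "bilateral_frac", "detection_fail_rate")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("sim_config: '%s' must be a fraction in [0, 1]", f))
    }
  }
  for (f in c("kr_delta", "wt_delta", "ek_delta")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("sim_config: effect size '%s' must lie in (0, 1)", f))
    }
  }
  if (cfg$n_cell_types < 1L) stop("sim_config: n_cell_types must be >= 1")
  if (cfg$n_patients < 2L) stop("sim_config: n_patients must be >= 2")
  if (cfg$dmr_probes_min < 3L) {
    stop("sim_config: planted DMRs need at least 3 probes to be recoverable")
  }
  if (cfg$dmr_probes_max < cfg$dmr_probes_min) {
    stop("sim_config: dmr_probes_max < dmr_probes_min")
  }
  if (cfg$hypervariability < 1) {
    stop("sim_config: hypervariability multiplier must be >= 1")
  }
  for (nm in c("NK", "NR", "WT_group1", "WT_group2", "EK")) {
    a <- cfg$mixture_alpha[[nm]]
    if (is.null(a) || length(a) != cfg$n_cell_types || any(a <= 0)) {
      stop(sprintf(
        "sim_config: mixture_alpha$%s must be %d positive concentrations",
        nm, cfg$n_cell_types
      ))
    }
  }
  planted <- (cfg$kr_dmr_count + cfg$wt_dmr_count) * cfg$dmr_probes_max +
    cfg$ek_mvp_count + cfg$kr_mvp_count + cfg$wt_mvp_count
  if (planted > cfg$n_probes) {
    stop(sprintf(
      "sim_config: planted probes (up to %d) exceed n_probes (%d)",
      planted, cfg$n_probes
    ))
  }
  invisible(cfg)
}

#' Tumour-composition-confounded variant of a configuration
#'
#' Returns `cfg` with the group-1 WT Dirichlet concentration shifted away
#' from NR's, so that the paired WT-vs-NR contrast is confounded by cell
#' composition at mixture-sensitive probes. Used to exercise the
#' reference-free adjustment.
#'
#' @param cfg a [sim_config()].
#' @param wt_alpha optional concentration vector for group-1 WT; default
#'   reverses the NR concentrations.
#' @return A modified `sim_config`.
#' @export
confounded_config <- function(cfg, wt_alpha = NULL) {
  d <- cfg$n_cell_types
  if (is.null(wt_alpha)) {
    wt_alpha <- rev(seq(d + 3, 1, length.out = d))
  }
  cfg$mixture_alpha$WT_group1 <- wt_alpha
  validate_sim_config(cfg)
  cfg
}

## Assemble probe positions along chromosomes as alternating CpG-island
## blocks (dense spacing, flanked by shores and shelves) and open-sea blocks
## (sparse spacing). Returns annotation plus an island registry used for
## DMR planting.
sim_annotation <- function(n_probes) {
  autosomes <- paste0("chr", 1:4)
  n_x <- max(0L, round(0.02 * n_probes))
  n_auto <- n_probes - n_x
  per_chrom <- diff(round(seq(0, n_auto, length.out = length(autosomes) + 1)))

  rows <- vector("list", 2048)
  nrows <- 0L
  islands <- vector("list", 512)
  nisl <- 0L
  add <- function(chrom, pos, feat, cgi) {
    nrows <<- nrows + 1L
    if (nrows > length(rows)) length(rows) <<- 2L * nrows
    rows[[nrows]] <<- list(chrom = chrom, pos = pos, feat = feat, cgi = cgi)
  }

  for (ci in seq_along(autosomes)) {
    chrom <- autosomes[ci]
    quota <- per_chrom[ci]
    emitted <- 0L
    pos <- 10000L
    while (emitted < quota) {
      ## shelf + shore, island, shore + shelf, then open sea
      pos <- pos + round(runif(1, 5000, 20000))
      add(chrom, pos, "Body", "shelf"); emitted <- emitted + 1L
      pos <- pos + round(runif(1, 1000, 2000))
      add(chrom, pos, sample(c("TSS1500", "5'UTR"), 1), "shore")
      emitted <- emitted + 1L
      ## two island density regimes, as on the array: tight TSS-type islands
      ## (where DMRs live) against looser ones; the category-wide
      ## nearest-neighbour median then sits between the two, so the lasso
      ## connects probes of dense islands but not chance pairs elsewhere
      dense <- runif(1) < 0.5
      n_is <- sample(5:14, 1)
      isl_idx <- integer(n_is)
      for (j in seq_len(n_is)) {
        pos <- pos + if (dense) round(runif(1, 15, 45)) else
          round(runif(1, 60, 200))
        add(chrom, pos,
            sample(c("TSS200", "TSS1500", "1stExon"), 1,
                   prob = c(0.5, 0.3, 0.2)), "island")
        emitted <- emitted + 1L
        isl_idx[j] <- nrows
      }
      nisl <- nisl + 1L
      islands[[nisl]] <- isl_idx
      attr(islands[[nisl]], "dense") <- dense
      pos <- pos + round(runif(1, 300, 900))
      add(chrom, pos, sample(c("TSS1500", "5'UTR"), 1), "shore")
      emitted <- emitted + 1L
      pos <- pos + round(runif(1, 1000, 2000))
      add(chrom, pos, "Body", "shelf"); emitted <- emitted + 1L
      n_os <- sample(1:5, 1)
      for (j in seq_len(n_os)) {
        pos <- pos + round(runif(1, 1500, 8000))
        add(chrom, pos,
            sample(c("Body", "IGR", "3'UTR"), 1, prob = c(0.4, 0.45, 0.15)),
            "open_sea")
        emitted <- emitted + 1L
      }
      if (emitted >= quota) break
    }
  }
  ## block generation overshoots per-chromosome quotas slightly; trim the
  ## tail so the autosome total is exact, keeping island indices valid
  islands <- islands[seq_len(nisl)]
  if (nrows > n_auto) {
    islands <- lapply(islands, function(ix) {
      dense <- attr(ix, "dense")
      ix <- ix[ix <= n_auto]
      attr(ix, "dense") <- dense
      ix
    })
    islands <- islands[lengths(islands) > 0]
    nrows <- n_auto
  }
  ## chrX probes: sparse, flagged as sex-chromosome probes downstream
  pos <- 10000L
  for (j in seq_len(n_x)) {
    pos <- pos + round(runif(1, 2000, 10000))
    add("chrX", pos, sample(c("Body", "IGR"), 1), "open_sea")
  }

  rows <- rows[seq_len(nrows)]
  ann <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(r) as.integer(r$pos), 1L),
    gene_feature = vapply(rows, `[[`, "", "feat"),
    cgi_relation = vapply(rows, `[[`, "", "cgi"),
    stringsAsFactors = FALSE
  )
  list(ann = ann, islands = islands)
}

#' Simulate a matched trio cohort with ground truth
#'
#' Generates a beta-value matrix, probe annotation, sample sheet, genomic
#' feature sets and a truth manifest under the generative model described in
#' [sim_config()]. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list (the "cohort bundle") with elements `beta` (probes x
#'   samples matrix), `ann` (probe annotation data frame), `samples` (sample
#'   sheet data frame), `features` (named list of `GRanges`), `detection_p`
#'   (matrix or `NULL`), `truth` (manifest: `$probes`, `$samples`,
#'   `$regions`, `$mixtures`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  d <- cfg$n_cell_types
  G <- cfg$n_probes

  built <- sim_annotation(G)
  ann <- built$ann
  islands <- built$islands
  G <- nrow(ann)

  ## --- planted regions -----------------------------------------------------
  sizes_needed <- cfg$kr_dmr_count + cfg$wt_dmr_count
  eligible <- which(lengths(islands) >= cfg$dmr_probes_max &
                      vapply(islands, function(ix) {
                        isTRUE(attr(ix, "dense")) &&
                          ann$chrom[ix[1]] != "chrX"
                      }, TRUE))
  if (length(eligible) < sizes_needed) {
    stop(sprintf(
      "simulate_cohort: only %d islands can host the %d requested DMRs; increase n_probes",
      length(eligible), sizes_needed
    ))
  }
  host <- sample(eligible, sizes_needed)

  probe_role <- rep("null", G)
  probe_region <- rep(NA_character_, G)
  probe_dir <- rep(NA_character_, G)
  probe_delta <- rep(0, G)

  n_regions <- sizes_needed
  regions <- data.frame(
    region_id = character(n_regions), contrast = character(n_regions),
    chrom = character(n_regions), start = integer(n_regions),
    end = integer(n_regions), n_probes = integer(n_regions),
    direction = character(n_regions), delta = numeric(n_regions),
    stringsAsFactors = FALSE
  )

  n_kr_hyper <- round(cfg$kr_hyper_frac * cfg$kr_dmr_count)
  n_wt_hypo <- round(cfg$wt_hypo_frac * cfg$wt_dmr_count)
  plant_one <- function(r, isl, contrast, direction, delta) {
    ix <- islands[[isl]]
    k <- sample(cfg$dmr_probes_min:cfg$dmr_probes_max, 1)
    start_at <- sample(seq_len(length(ix) - k + 1), 1)
    sel <- ix[start_at:(start_at + k - 1)]
    rid <- sprintf("%s_DMR_%03d", contrast, r)
    probe_role[sel] <<- paste0(tolower(contrast), "_dmr")
    probe_region[sel] <<- rid
    probe_dir[sel] <<- direction
    probe_delta[sel] <<- delta
    regions[r, ] <<- list(rid, contrast, ann$chrom[sel[1]],
                          min(ann$pos[sel]) - 1L, max(ann$pos[sel]),
                          k, direction, delta)
  }
  r <- 0L
  for (i in seq_len(cfg$kr_dmr_count)) {
    r <- r + 1L
    plant_one(r, host[r], "KR", if (i <= n_kr_hyper) "hyper" else "hypo",
              cfg$kr_delta)
  }
  for (i in seq_len(cfg$wt_dmr_count)) {
    r <- r + 1L
    plant_one(r, host[r], "WT", if (i <= n_wt_hypo) "hypo" else "hyper",
              cfg$wt_delta)
  }

  ## scattered single-probe MVPs: non-adjacent so they cannot connect into
  ## spurious DMRs (minimum index separation of 3 probes)
  pick_scattered <- function(count, min_gap = 3L) {
    free <- which(probe_role == "null" & ann$chrom != "chrX")
    if (count == 0) return(integer(0))
    pool <- sample(free)
    chosen <- integer(0)
    taken <- logical(G)
    for (idx in pool) {
      lo <- max(1L, idx - min_gap); hi <- min(G, idx + min_gap)
      if (!any(taken[lo:hi])) {
        chosen <- c(chosen, idx)
        taken[idx] <- TRUE
        if (length(chosen) == count) break
      }
    }
    if (length(chosen) < count) {
      stop("simulate_cohort: not enough free probes for scattered MVPs")
    }
    sort(chosen)
  }
  plant_scattered <- function(idx, role, hyper_frac, delta) {
    n_hyper <- round(hyper_frac * length(idx))
    dirs <- rep("hypo", length(idx))
    if (n_hyper > 0) dirs[sample(length(idx), n_hyper)] <- "hyper"
    probe_role[idx] <<- role
    probe_dir[idx] <<- dirs
    probe_delta[idx] <<- delta
  }
  plant_scattered(pick_scattered(cfg$kr_mvp_count), "kr_mvp",
                  cfg$kr_hyper_frac, cfg$kr_delta)
  plant_scattered(pick_scattered(cfg$wt_mvp_count), "wt_mvp",
                  1 - cfg$wt_hypo_frac, cfg$wt_delta)

  ## EK probes: scattered single CpGs on autosomes, disjoint from DMRs
  free <- which(probe_role == "null" & ann$chrom != "chrX")
  ek_probes <- integer(0)
  if (cfg$n_ek > 0 && cfg$ek_mvp_count > 0) {
    ek_probes <- sort(sample(free, cfg$ek_mvp_count))
    n_ek_hyper <- round(cfg$ek_hyper_frac * cfg$ek_mvp_count)
    ek_dir <- rep("hypo", cfg$ek_mvp_count)
    ek_dir[sample(cfg$ek_mvp_count, n_ek_hyper)] <- "hyper"
    probe_role[ek_probes] <- "ek_mvp"
    probe_dir[ek_probes] <- ek_dir
    probe_delta[ek_probes] <- cfg$ek_delta
  }

  ## mixture-sensitive probes: null probes only, so planted effect sizes are
  ## exactly the configured shifts
  free <- which(probe_role == "null")
  n_sens <- round(cfg$mixture_sensitive_frac * G)
  sens <- sort(sample(free, min(n_sens, length(free))))
  is_sens <- rep(FALSE, G)
  is_sens[sens] <- TRUE

  ## --- baseline methylomes -------------------------------------------------
  comp <- sample(1:3, G, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  base_logit <- c(rnorm(G, -2.2, 0.8), rnorm(G, 2.2, 0.8),
                  rnorm(G, 0, 1))[(comp - 1) * G + seq_len(G)]
  ## planted probes get mid-range baselines leaving room for the shift
  planted_hyper <- which(!is.na(probe_dir) & probe_dir == "hyper")
  planted_hypo <- which(!is.na(probe_dir) & probe_dir == "hypo")
  base_beta <- inv_logit(base_logit)
  base_beta[planted_hyper] <- runif(length(planted_hyper), 0.15,
                                    0.95 - probe_delta[planted_hyper])
  base_beta[planted_hypo] <- runif(length(planted_hypo),
                                   0.05 + probe_delta[planted_hypo], 0.85)

  ## cell-type profiles on the beta scale; cell-type-differential probes sit
  ## at intermediate methylation (as cell-composition markers do), where
  ## proportion-weighted mixing of beta-values is close to linear
  base_beta[sens] <- runif(length(sens), 0.35, 0.65)
  profiles <- matrix(rep(base_beta, d), nrow = G)
  offs <- matrix(rnorm(length(sens) * d, 0, cfg$mixture_sd),
                 nrow = length(sens))
  profiles[sens, ] <- inv_logit(logit(clamp01(base_beta[sens])) + offs)

  ## --- samples -------------------------------------------------------------
  np <- cfg$n_patients
  patients <- sprintf("P%02d", seq_len(np))
  n_g1 <- round(cfg$frac_group1 * np)
  g1 <- sort(sample(np, n_g1))
  subgroup <- ifelse(seq_len(np) %in% g1, "group1", "group2")
  n_bilat <- round(cfg$bilateral_frac * n_g1)
  bilat <- rep(FALSE, np)
  if (n_bilat > 0) bilat[sample(g1, n_bilat)] <- TRUE
  laterality <- ifelse(bilat, "bilateral", "unilateral")

  tissues <- c("NK", "NR", "WT")
  samples <- data.frame(
    sample_id = as.vector(t(outer(patients, tissues, paste, sep = "_"))),
    patient_id = rep(patients, each = 3),
    tissue = rep(tissues, np),
    laterality = rep(laterality, each = 3),
    subgroup = rep(subgroup, each = 3),
    stringsAsFactors = FALSE
  )
  if (cfg$n_ek > 0) {
    ek <- data.frame(
      sample_id = sprintf("EK%02d", seq_len(cfg$n_ek)),
      patient_id = sprintf("EKP%02d", seq_len(cfg$n_ek)),
      tissue = "EK", laterality = NA_character_,
      subgroup = NA_character_, stringsAsFactors = FALSE
    )
    samples <- rbind(samples, ek)
  }
  n_samp <- nrow(samples)

  alpha_of <- function(i) {
    t <- samples$tissue[i]
    if (t == "NK") return(cfg$mixture_alpha$NK)
    if (t == "NR") return(cfg$mixture_alpha$NR)
    if (t == "EK") return(cfg$mixture_alpha$EK)
    if (identical(samples$subgroup[i], "group1")) {
      cfg$mixture_alpha$WT_group1
    } else {
      cfg$mixture_alpha$WT_group2
    }
  }
  W <- t(vapply(seq_len(n_samp),
                function(i) as.numeric(rdirichlet(1, alpha_of(i))),
                numeric(d)))
  rownames(W) <- samples$sample_id
  colnames(W) <- sprintf("celltype_%d", seq_len(d))

  patient_eff <- matrix(rnorm(G * np, 0, cfg$patient_sd), nrow = G,
                        dimnames = list(NULL, patients))

  ## planted logit shifts, computed so the beta-scale shift at the baseline
  ## equals the configured delta
  shift_logit <- rep(0, G)
  pl <- which(!is.na(probe_dir))
  tgt <- base_beta[pl] + ifelse(probe_dir[pl] == "hyper", 1, -1) *
    probe_delta[pl]
  shift_logit[pl] <- logit(clamp01(tgt, 0.02)) - logit(clamp01(base_beta[pl], 0.02))

  is_kr <- probe_role %in% c("kr_dmr", "kr_mvp")
  is_wt <- probe_role %in% c("wt_dmr", "wt_mvp")
  is_ek <- probe_role == "ek_mvp"

  probe_ids <- sprintf("cg%07d", seq_len(G))
  beta <- matrix(NA_real_, nrow = G, ncol = n_samp,
                 dimnames = list(probe_ids, samples$sample_id))
  for (i in seq_len(n_samp)) {
    mu <- as.vector(profiles %*% W[i, ])
    z <- logit(clamp01(mu))
    tis <- samples$tissue[i]
    g1_wt <- tis == "WT" && identical(samples$subgroup[i], "group1")
    if (tis %in% c("NR", "WT")) z[is_kr] <- z[is_kr] + shift_logit[is_kr]
    if (g1_wt) z[is_wt] <- z[is_wt] + shift_logit[is_wt]
    if (tis == "EK") {
      z[is_ek] <- z[is_ek] - shift_logit[is_ek]
      z <- z + rnorm(G, 0, cfg$patient_sd)
    } else {
      z <- z + patient_eff[, samples$patient_id[i]]
    }
    sdev <- cfg$noise_sd * if (g1_wt) cfg$hypervariability else 1
    beta[, i] <- inv_logit(z + rnorm(G, 0, sdev))
  }

  ## --- annotation flags ----------------------------------------------------
  flag_sex <- ann$chrom == "chrX"
  flag_snp <- rep(FALSE, G)
  flag_multi <- rep(FALSE, G)
  unplanted <- which(probe_role == "null" & !flag_sex)
  flag_snp[sample(unplanted, min(length(unplanted), round(0.01 * G)))] <- TRUE
  rest <- which(probe_role == "null" & !flag_sex & !flag_snp)
  flag_multi[sample(rest, min(length(rest), round(0.01 * G)))] <- TRUE
  ann_out <- data.frame(
    probe_id = probe_ids, chrom = ann$chrom, pos = ann$pos,
    gene_feature = ann$gene_feature, cgi_relation = ann$cgi_relation,
    flag_sex_chromosome = flag_sex, flag_snp_at_target = flag_snp,
    flag_multimap = flag_multi, stringsAsFactors = FALSE
  )

  ## --- feature sets --------------------------------------------------------
  hyper_kr <- regions[regions$contrast == "KR" & regions$direction == "hyper", ]
  n_in <- round(cfg$feature_enrichment * nrow(hyper_kr))
  biv <- if (n_in > 0) {
    sel <- hyper_kr[sample(nrow(hyper_kr), n_in), ]
    data.frame(chrom = sel$chrom, start = pmax(0L, sel$start - 500L),
               end = sel$end + 500L)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  bg_islands <- setdiff(seq_along(islands), host)
  island_interval <- function(isl) {
    ix <- islands[[isl]]
    data.frame(chrom = ann$chrom[ix[1]],
               start = max(0L, min(ann$pos[ix]) - 201L),
               end = max(ann$pos[ix]) + 200L)
  }
  bg1 <- do.call(rbind, lapply(sample(bg_islands,
                                      round(0.04 * length(bg_islands))),
                               island_interval))
  bivalent <- make_feature_granges(rbind(biv, bg1))

  prc2 <- NULL
  if (length(ek_probes) > 0) {
    hyper_ek <- ek_probes[probe_dir[ek_probes] == "hyper"]
    n_in <- round(cfg$ek_prc2_frac * length(hyper_ek))
    covered <- if (n_in > 0) sort(sample(hyper_ek, n_in)) else integer(0)
    p1 <- if (length(covered)) {
      data.frame(chrom = ann$chrom[covered],
                 start = pmax(0L, ann$pos[covered] - 501L),
                 end = ann$pos[covered] + 500L)
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }
    bg2 <- do.call(rbind, lapply(sample(bg_islands,
                                        round(0.04 * length(bg_islands))),
                                 island_interval))
    prc2 <- make_feature_granges(rbind(p1, bg2))
  }
  features <- list(bivalent_domains = bivalent)
  if (!is.null(prc2)) features$prc2_targets <- prc2

  ## --- detection matrix ----------------------------------------------------
  detection_p <- NULL
  if (cfg$detection_fail_rate > 0) {
    detection_p <- matrix(1e-4, nrow = G, ncol = n_samp,
                          dimnames = dimnames(beta))
    fail <- runif(G * n_samp) < cfg$detection_fail_rate
    detection_p[fail] <- 0.02
  }

  truth_probes <- data.frame(
    probe_id = probe_ids, role = probe_role, region_id = probe_region,
    direction = probe_dir, true_delta = probe_delta,
    mixture_sensitive = is_sens, stringsAsFactors = FALSE
  )

  list(
    beta = beta, ann = ann_out, samples = samples, features = features,
    detection_p = detection_p,
    truth = list(probes = truth_probes, samples = samples,
                 regions = regions, mixtures = W),
    config = cfg
  )
}

## intervals: data.frame(chrom, start, end) in 0-based half-open convention.
make_feature_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = sort(unique(df$chrom))),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  GenomicRanges::sort(GenomicRanges::reduce(gr))
}

#' Write a simulated cohort bundle to disk
#'
#' Writes `beta.tsv`, `probes.csv`, `samples.csv`, one BED file per feature
#' set under `features/`, `truth.json` and (if present) `detection.tsv`.
#' Round-trips through [load_cohort()] within 1e-9.
#'
#' @param bundle output of [simulate_cohort()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_fixture: cannot create ", out_dir)
  paths <- c(
    beta = file.path(out_dir, "beta.tsv"),
    probes = file.path(out_dir, "probes.csv"),
    samples = file.path(out_dir, "samples.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_beta(bundle$beta, paths[["beta"]])
  utils::write.csv(bundle$ann, paths[["probes"]], row.names = FALSE)
  utils::write.csv(bundle$samples, paths[["samples"]], row.names = FALSE)
  feat_dir <- file.path(out_dir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  for (nm in names(bundle$features)) {
    p <- file.path(feat_dir, paste0(nm, ".bed"))
    write_bed(bundle$features[[nm]], p)
    paths[[paste0("feature_", nm)]] <- p
  }
  if (!is.null(bundle$detection_p)) {
    p <- file.path(out_dir, "detection.tsv")
    write_beta(bundle$detection_p, p, check_range = FALSE)
    paths[["detection"]] <- p
  }
  truth <- bundle$truth
  truth$mixtures <- data.frame(sample_id = rownames(truth$mixtures),
                               as.data.frame(truth$mixtures),
                               row.names = NULL)
  jsonlite::write_json(
    list(probes = truth$probes, samples = truth$samples,
         regions = truth$regions, mixtures = truth$mixtures,
         config = bundle$config[setdiff(names(bundle$config), "mixture_alpha")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}
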