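#' Multisampling enrichment of a probe set in genomic features
#'
#' For each feature set, compares the fraction of query probes falling
#' inside the features against equal-sized draws (without replacement) from
#' the probe universe - the post-filtering array content. Enrichment is
#' reported in percentage points (observed minus null mean); the empirical
#' p-value is one-sided on the side indicated by the enrichment sign, with
#' the add-one correction, so its floor is `1/(n_resamples + 1)`. Fixed-side
#' p-values (`p_greater`, `p_less`) are also returned; `p_greater` is the
#' calibration-friendly quantity (uniform under the null).
#'
#' @param query_probes character vector of probe ids (subset of universe).
#' @param universe character vector of all eligible probe ids.
#' @param ann probe annotation (positions for the overlap).
#' @param features named list of `GRanges` feature sets.
#' @param n_resamples number of multisamples (default 100, giving the
#'   customary p floor of ~0.01).
#' @param seed RNG seed.
#' @return An `EnrichmentResult` data frame, one row per feature:
#'   `feature`, `observed_fraction`, `null_mean_fraction`, `null_sd`,
#'   `enrichment_pp`, `p`, `side`, `p_greater`, `p_less`, `n_resamples`,
#'   `query_size`.
#' @export
multisample_enrichment <- function(query_probes, universe, ann, features,
                                   n_resamples = 100, seed = 1L) {
  stopifnot(is.list(features), !is.null(names(features)))
  query_probes <- unique(query_probes)
  universe <- unique(universe)
  if (!all(query_probes %in% universe)) {
    stop("multisample_enrichment: query probes must be a subset of the universe")
  }
  if (length(query_probes) > length(universe)) {
    stop("multisample_enrichment: query larger than universe")
  }
  idx <- match(universe, ann$probe_id)
  if (anyNA(idx)) {
    stop("multisample_enrichment: universe probes missing from annotation")
  }
  chrom <- ann$chrom[idx]
  pos <- ann$pos[idx]
  member <- vapply(features, function(gr) probes_in_features(chrom, pos, gr),
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(universe))
  colnames(member) <- names(features)

  q_idx <- match(query_probes, universe)
  nq <- length(query_probes)
  observed <- colMeans(member[q_idx, , drop = FALSE])

  null_frac <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      draw <- sample.int(length(universe), nq)
      colMeans(member[draw, , drop = FALSE])
    }, numeric(length(features)))
  })
  if (is.null(dim(null_frac))) {
    null_frac <- matrix(null_frac, nrow = length(features))
  }

  null_mean <- rowMeans(null_frac)
  null_sd <- apply(null_frac, 1L, sd)
  p_greater <- (1 + rowSums(null_frac >= observed)) / (1 + n_resamples)
  p_less <- (1 + rowSums(null_frac <= observed)) / (1 + n_resamples)
  side <- ifelse(observed >= null_mean, "greater", "less")
  p <- ifelse(side == "greater", p_greater, p_less)

  data.frame(
    feature = names(features),
    observed_fraction = unname(observed),
    null_mean_fraction = unname(null_mean),
    null_sd = unname(null_sd),
    enrichment_pp = unname(100 * (observed - null_mean)),
    p = unname(p),
    side = unname(side),
    p_greater = unname(p_greater),
    p_less = unname(p_less),
    n_resamples = n_resamples,
    query_size = nq,
    stringsAsFactors = FALSE
  )
}

#' Mean-plus-one-SD DMR hypermethylation classifier
#'
#' A tumour is classed as hypermethylated at a DMR when its mean beta over
#' the DMR's member probes strictly exceeds the reference (NR) cohort mean
#' plus one standard deviation, where mean and SD are taken over the
#' per-reference-sample DMR means (sample SD, n - 1). Reports the per-DMR
#' frequency as an "x of n" string.
#'
#' @param beta probes x samples matrix.
#' @param dmrs output of [call_dmrs()], or a list of character vectors of
#'   probe ids named by DMR id.
#' @param tumour_samples,reference_samples sample-id vectors; the reference
#'   cohort needs at least 2 samples.
#' @return list with `calls` (long data frame: `dmr_id`, `sample_id`,
#'   `tumour_mean`, `threshold`, `hypermethylated`) and `frequency` (per-DMR
#'   data frame with `n_hyper`, `n_tumours`, `frequency` string,
#'   `reference_mean`, `reference_sd`).
#' @export
classify_hypermethylation <- function(beta, dmrs, tumour_samples,
                                      reference_samples) {
  if (length(reference_samples) < 2) {
    stop("classify_hypermethylation: reference cohort needs >= 2 samples (SD undefined)")
  }
  probe_sets <- if (is.data.frame(dmrs)) {
    setNames(lapply(dmrs$probes, function(p) p$probe_id), dmrs$dmr_id)
  } else {
    dmrs
  }
  stopifnot(!is.null(names(probe_sets)))
  miss <- setdiff(c(tumour_samples, reference_samples), colnames(beta))
  if (length(miss) > 0) {
    stop("classify_hypermethylation: samples not in matrix: ",
         paste(miss, collapse = ", "))
  }

  calls <- list()
  freq <- list()
  for (id in names(probe_sets)) {
    probes <- intersect(probe_sets[[id]], rownames(beta))
    if (length(probes) == 0) {
      stop("classify_hypermethylation: DMR '", id,
           "' has no probes in the matrix")
    }
    sub <- beta[probes, , drop = FALSE]
    sample_means <- colMeans(sub, na.rm = TRUE)
    ref <- sample_means[reference_samples]
    mu <- mean(ref)
    sdev <- sd(ref)
    thr <- mu + sdev
    tum <- sample_means[tumour_samples]
    hyper <- !is.na(tum) & tum > thr
    calls[[id]] <- data.frame(
      dmr_id = id, sample_id = tumour_samples, tumour_mean = unname(tum),
      threshold = thr, hypermethylated = unname(hyper),
      stringsAsFactors = FALSE
    )
    freq[[id]] <- data.frame(
      dmr_id = id, n_hyper = sum(hyper), n_tumours = length(tumour_samples),
      frequency = sprintf("%d of %d", sum(hyper), length(tumour_samples)),
      reference_mean = mu, reference_sd = sdev, threshold = thr,
      stringsAsFactors = FALSE
    )
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       frequency = do.call(rbind, c(freq, list(make.row.names = FALSE))))
}
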