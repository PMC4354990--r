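#' Filter probes by detection quality and annotation flags
#'
#' A probe is removed if any sample exceeds the detection p-value threshold
#' (mirroring removal of all probes where at least one sample shows poor
#' detection), or if any of the requested annotation flags is set
#' (sex-chromosome probes, probes with a SNP at the target site, multi-mapping
#' probes).
#'
#' @param beta probes x samples matrix.
#' @param ann probe annotation with `probe_id` and `flag_*` columns.
#' @param detection_p optional matrix aligned to `beta`.
#' @param drop_flags character subset of
#'   `c("sex_chromosome", "snp_at_target", "multimap")`.
#' @param detection_threshold detection p-value cutoff (default 0.01).
#' @return list with `beta` (filtered matrix) and `report` (a
#'   `FilterReport`-style list of counts).
#' @export
filter_probes <- function(beta, ann, detection_p = NULL,
                          drop_flags = c("sex_chromosome", "snp_at_target",
                                         "multimap"),
                          detection_threshold = 0.01) {
  stopifnot(is.matrix(beta))
  drop_flags <- match.arg(drop_flags, several.ok = TRUE)
  ann <- ann[match(rownames(beta), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) {
    stop("filter_probes: probes missing from annotation")
  }
  probes_in <- nrow(beta)
  drop_det <- rep(FALSE, probes_in)
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)) ||
        !identical(rownames(detection_p), rownames(beta))) {
      stop("filter_probes: detection matrix not aligned to beta matrix")
    }
    drop_det <- apply(detection_p > detection_threshold, 1L, any)
  }
  by_flag <- list()
  drop_flag <- rep(FALSE, probes_in)
  for (f in drop_flags) {
    col <- paste0("flag_", f)
    v <- if (col %in% colnames(ann)) as.logical(ann[[col]]) else rep(FALSE, probes_in)
    v[is.na(v)] <- FALSE
    by_flag[[f]] <- sum(v)
    drop_flag <- drop_flag | v
  }
  keep <- !(drop_det | drop_flag)
  report <- list(
    probes_in = probes_in,
    probes_removed_by_detection = sum(drop_det),
    probes_removed_by_flag = by_flag,
    probes_removed = sum(!keep),
    probes_out = sum(keep),
    samples_removed = 0L
  )
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' Select the most variable probes
#'
#' Ranks probes by interquartile range across all samples and returns the
#' top fraction (default the top 1%, the usual choice for unsupervised views
#' of a methylome). Ties are broken by probe id (lexicographic) so the
#' selection is deterministic.
#'
#' @param beta probes x samples matrix.
#' @param fraction fraction of probes to keep, in (0, 1].
#' @param statistic only `"IQR"` is implemented.
#' @return character vector of selected probe ids, in ranking order.
#' @export
top_variable <- function(beta, fraction = 0.01, statistic = c("IQR")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(beta))
  if (nrow(beta) == 0) stop("top_variable: empty matrix")
  if (!(fraction > 0 && fraction <= 1)) {
    stop("top_variable: fraction must be in (0, 1]")
  }
  n_keep <- ceiling(fraction * nrow(beta))
  iqr <- row_iqr(beta)
  ord <- order(-iqr, rownames(beta))
  rownames(beta)[ord[seq_len(n_keep)]]
}

#' Beta to M-value conversion (and back)
#'
#' `m = log2(beta / (1 - beta))`, with beta clipped to
#' `[eps, 1 - eps]` first so the transform stays finite. The pair is
#' involutive away from the clip bounds.
#'
#' @param beta,m numeric input (vector or matrix).
#' @param eps clipping bound (default 1e-6).
#' @return transformed values, same shape as input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Array / bisulfite-sequencing concordance
#'
#' Compares array beta-values to proportions derived from bisulfite
#' sequencing read counts (methylated reads over total reads per CpG).
#' Returns the Pearson correlation and the median absolute difference over
#' the CpGs with coverage.
#'
#' @param array_beta named numeric vector of array beta-values per CpG.
#' @param meth_reads,total_reads integer vectors parallel to `array_beta`.
#' @return list with `pearson_r`, `median_abs_diff`, `n_used`,
#'   `n_zero_coverage` and the per-CpG `table`.
#' @export
concordance <- function(array_beta, meth_reads, total_reads) {
  stopifnot(length(array_beta) == length(meth_reads),
            length(meth_reads) == length(total_reads))
  zero <- total_reads <= 0
  n_zero <- sum(zero)
  b <- array_beta[!zero]
  prop <- meth_reads[!zero] / total_reads[!zero]
  if (length(b) < 2) {
    stop("concordance: need at least 2 covered CpGs (correlation undefined)")
  }
  tab <- data.frame(
    array_beta = b, bs_proportion = prop, abs_diff = abs(prop - b)
  )
  if (!is.null(names(array_beta))) tab$cpg <- names(array_beta)[!zero]
  list(
    pearson_r = cor(b, prop),
    median_abs_diff = median(tab$abs_diff),
    n_used = length(b),
    n_zero_coverage = n_zero,
    table = tab
  )
}
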