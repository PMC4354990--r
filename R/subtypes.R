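#' Consensus clustering of samples
#'
#' Monti-style consensus clustering: samples are repeatedly subsampled,
#' hierarchically clustered (average linkage on 1 - Pearson correlation
#' distance across the supplied probes), and the consensus matrix records
#' the fraction of co-sampled resamples in which each sample pair
#' co-clustered. The final assignment hierarchically clusters
#' `1 - consensus`; `k` is either fixed or selected by the largest relative
#' change in the area under the consensus CDF.
#'
#' @param beta_subset probes x samples matrix (e.g. the top-variable probes).
#' @param k number of clusters, or `"auto"` to select from `k_range`.
#' @param k_range candidate cluster counts for auto selection (default 2:6).
#' @param n_resamples subsampling iterations (default 1000).
#' @param subsample fraction of samples per iteration (default 0.8).
#' @param linkage hierarchical linkage (default "average").
#' @param seed RNG seed.
#' @return A `ConsensusResult` list: `k`, `assignments` (named integer
#'   vector), `consensus` (samples x samples), `cdf_area` (per candidate k),
#'   `n_resamples`, `subsample`, `seed`.
#' @export
consensus_cluster <- function(beta_subset, k = "auto", k_range = 2:6,
                              n_resamples = 1000, subsample = 0.8,
                              linkage = "average", seed = 1L) {
  stopifnot(is.matrix(beta_subset))
  n <- ncol(beta_subset)
  ids <- colnames(beta_subset)
  k_cand <- if (identical(k, "auto")) k_range else as.integer(k)
  if (any(k_cand > n)) stop("consensus_cluster: k exceeds the sample count")

  full_dist <- one_minus_pearson(beta_subset)
  degenerate <- all(full_dist < 1e-12)
  if (degenerate) {
    ## identical samples: consensus is trivially all-ones; flag and return
    cons <- matrix(1, n, n, dimnames = list(ids, ids))
    res <- list(k = 1L, assignments = setNames(rep(1L, n), ids),
                consensus = cons, cdf_area = NULL,
                n_resamples = n_resamples, subsample = subsample,
                seed = seed, degenerate = TRUE)
    return(res)
  }

  m <- floor(subsample * n)
  count_pair <- matrix(0, n, n)
  conn <- lapply(k_cand, function(kk) matrix(0, n, n))
  names(conn) <- as.character(k_cand)

  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample(n, m))
      count_pair[idx, idx] <- count_pair[idx, idx] + 1
      hc <- hclust(as.dist(full_dist[idx, idx]), method = linkage)
      for (kk in k_cand) {
        cl <- cutree(hc, k = kk)
        same <- outer(cl, cl, "==")
        conn[[as.character(kk)]][idx, idx] <-
          conn[[as.character(kk)]][idx, idx] + same
      }
    }
  })

  consensus_for <- function(kk) {
    cm <- conn[[as.character(kk)]] / pmax(count_pair, 1)
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  }

  cdf_area <- vapply(k_cand, function(kk) {
    cm <- consensus_for(kk)
    v <- sort(cm[upper.tri(cm)])
    ## area under the empirical CDF of consensus entries
    mean(ecdf(v)(seq(0, 1, length.out = 200)))
  }, numeric(1))
  names(cdf_area) <- as.character(k_cand)

  if (identical(k, "auto")) {
    if (length(k_cand) == 1) {
      k_sel <- k_cand
    } else {
      delta <- diff(c(0, cdf_area)) / c(1, cdf_area[-length(cdf_area)])
      k_sel <- k_cand[which.max(delta)]
    }
  } else {
    k_sel <- as.integer(k)
  }

  cons <- consensus_for(k_sel)
  hc_final <- hclust(as.dist(1 - cons), method = linkage)
  assignments <- setNames(cutree(hc_final, k = k_sel), ids)
  list(k = k_sel, assignments = assignments, consensus = cons,
       cdf_area = cdf_area, n_resamples = n_resamples,
       subsample = subsample, seed = seed, degenerate = FALSE)
}

one_minus_pearson <- function(beta_subset) {
  if (nrow(beta_subset) < 2) {
    stop("consensus_cluster: need at least 2 probes for correlation distance")
  }
  cc <- suppressWarnings(cor(beta_subset))
  d <- 1 - cc
  if (anyNA(d)) {
    ## constant profiles have undefined correlation; identical columns get
    ## distance 0, otherwise maximal distance
    na_pairs <- which(is.na(d), arr.ind = TRUE)
    for (k in seq_len(nrow(na_pairs))) {
      i <- na_pairs[k, 1]; j <- na_pairs[k, 2]
      same <- max(abs(beta_subset[, i] - beta_subset[, j])) < 1e-12
      d[i, j] <- if (same) 0 else 1
    }
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson scaling of the Euclidean inter-sample distances, centred, with
#' axes ordered by eigenvalue and a fixed sign convention (the first
#' nonzero coordinate of each axis is positive) so embeddings are
#' reproducible.
#'
#' @param beta_subset probes x samples matrix.
#' @param n_dims number of dimensions (default 2).
#' @return list with `coords` (samples x dims), `eig` (all eigenvalues) and
#'   `n_dims_effective`.
#' @export
mds_samples <- function(beta_subset, n_dims = 2) {
  stopifnot(is.matrix(beta_subset))
  n <- ncol(beta_subset)
  if (n < 3) stop("mds_samples: need at least 3 samples")
  dd <- dist(t(beta_subset))
  fit <- cmdscale(dd, k = min(n_dims, n - 1), eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  n_eff <- sum(fit$eig > max(fit$eig) * 1e-9)
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(beta_subset)
  colnames(coords) <- sprintf("MDS%d", seq_len(ncol(coords)))
  list(coords = coords, eig = fit$eig,
       n_dims_effective = min(n_eff, ncol(coords)))
}

#' Per-probe Bartlett test of variance homogeneity
#'
#' Vectorized Bartlett K-squared across probes for two or more sample
#' groups, with the cohort-level summary used for hypervariability claims:
#' among probes significant at `alpha`, which group carries the largest
#' sample variance.
#'
#' @param beta probes x samples matrix.
#' @param groups named list of sample-id vectors (each of length >= 2).
#' @param alpha significance threshold for the summary counts (default 0.01).
#' @return A `VarianceComparison` list: `table` (per-probe data frame with
#'   group variances, `K2`, `df`, `p`, `degenerate` flag) and `summary`
#'   (significant-probe counts per larger-variance group).
#' @export
bartlett_per_probe <- function(beta, groups, alpha = 0.01) {
  stopifnot(is.matrix(beta), is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- sprintf("group%d", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("bartlett_per_probe: every group needs >= 2 samples")
  miss <- setdiff(unlist(groups), colnames(beta))
  if (length(miss) > 0) {
    stop("bartlett_per_probe: samples not in matrix: ",
         paste(head(miss, 5), collapse = ", "))
  }
  kgr <- length(groups)
  nn <- sum(sizes)
  vars <- vapply(groups, function(g) {
    sub <- beta[, g, drop = FALSE]
    row_vars(sub)
  }, numeric(nrow(beta)))
  if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1)
  colnames(vars) <- names(groups)

  df_w <- sizes - 1
  sp2 <- as.vector(vars %*% df_w) / (nn - kgr)
  all_zero <- apply(vars, 1L, function(v) all(v < 1e-300))
  some_zero <- !all_zero & apply(vars, 1L, function(v) any(v < 1e-300))

  c_corr <- 1 + (sum(1 / df_w) - 1 / (nn - kgr)) / (3 * (kgr - 1))
  log_vars <- log(pmax(vars, 1e-300))
  k2 <- ((nn - kgr) * log(pmax(sp2, 1e-300)) -
           as.vector(log_vars %*% df_w)) / c_corr
  k2[all_zero] <- 0
  k2[some_zero] <- Inf
  p <- pchisq(k2, df = kgr - 1, lower.tail = FALSE)
  p[all_zero] <- 1

  tab <- data.frame(probe_id = rownames(beta), vars, K2 = k2,
                    df = kgr - 1, p = p,
                    degenerate = all_zero | some_zero,
                    stringsAsFactors = FALSE, check.names = FALSE)
  sig <- which(p < alpha)
  larger <- names(groups)[max.col(vars[sig, , drop = FALSE], "first")]
  summary <- setNames(integer(kgr), names(groups))
  cnt <- table(factor(larger, levels = names(groups)))
  summary[names(cnt)] <- as.integer(cnt)
  list(table = tab, summary = summary, alpha = alpha,
       n_significant = length(sig))
}

#' Cluster-by-clinical-label association
#'
#' Pearson chi-square test (no continuity correction by default) between a
#' cluster assignment and a clinical label, returning the contingency table
#' for audit.
#'
#' @param assignments vector of cluster labels.
#' @param clinical_labels parallel vector of clinical labels.
#' @param yates apply Yates continuity correction (default FALSE).
#' @return list with `chi2`, `df`, `p` and `table`.
#' @export
cluster_association <- function(assignments, clinical_labels, yates = FALSE) {
  stopifnot(length(assignments) == length(clinical_labels))
  keep <- !is.na(assignments) & !is.na(clinical_labels)
  tab <- table(cluster = assignments[keep], label = clinical_labels[keep])
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("cluster_association: need at least 2 clusters and 2 labels (df >= 1)")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
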