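#' Estimate the latent cell-mixture dimension
#'
#' Permutation parallel analysis on a residual matrix: the observed singular
#' values are compared, component by component, to the chosen percentile of
#' singular values obtained from matrices with every column independently
#' permuted (which preserves marginal distributions but destroys cross-probe
#' structure). `d` is the number of leading components exceeding their
#' threshold before the first failure.
#'
#' @param residuals probes x samples matrix of residuals from the
#'   design-only fit.
#' @param n_perm number of permuted matrices (default 20).
#' @param quantile_used percentile of the permuted singular values
#'   (default 0.95).
#' @param max_d cap on the returned dimension (default 10).
#' @param seed RNG seed.
#' @return integer `d >= 0` with the observed and threshold singular values
#'   in attributes `singular_values` and `thresholds`.
#' @export
estimate_dimension <- function(residuals, n_perm = 20, quantile_used = 0.95,
                               max_d = 10, seed = 1L) {
  stopifnot(is.matrix(residuals))
  if (all(abs(residuals) < 1e-12)) {
    out <- 0L
    attr(out, "singular_values") <- numeric(0)
    attr(out, "thresholds") <- numeric(0)
    return(out)
  }
  k <- min(max_d, dim(residuals))
  sv_obs <- svd_singular_values(residuals, k)
  with_seed(seed, {
    perm_sv <- vapply(seq_len(n_perm), function(b) {
      perm <- apply(residuals, 2L, sample)
      svd_singular_values(perm, k)
    }, numeric(k))
  })
  thresholds <- apply(perm_sv, 1L, quantile, probs = quantile_used,
                      names = FALSE)
  exceed <- sv_obs > thresholds
  d <- if (all(exceed)) k else which(!exceed)[1] - 1L
  out <- as.integer(d)
  attr(out, "singular_values") <- sv_obs
  attr(out, "thresholds") <- thresholds
  out
}

## Leading k singular values via the sample-space crossproduct (n is small).
svd_singular_values <- function(x, k) {
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev[seq_len(k)], 0))
}

## Build the design matrix for a two-group contrast; the group coefficient
## is always the last column.
build_design <- function(samples, group_col = "tissue", levels_ab,
                         paired = TRUE) {
  grp <- factor(samples[[group_col]], levels = levels_ab)
  if (anyNA(grp)) stop("reffree_fit: samples outside the contrast levels")
  if (paired) {
    block <- factor(samples$patient_id)
    x <- model.matrix(~ block)
  } else {
    x <- matrix(1, nrow(samples), 1)
  }
  cbind(x, group = as.numeric(grp == levels_ab[1]))
}

## One pass of the reference-free fit. Per-probe OLS gives design
## coefficients and residuals; the SVD of the residual matrix estimates the
## latent loading span (probe space); per-sample mixture scores are then
## re-estimated by regressing the centred data - not the residuals - on the
## loadings, so they retain the design-correlated component of cell
## composition; the per-probe re-fit on [design | scores] finally separates
## the direct effect from the mixture-mediated one.
reffree_pass <- function(y, x, d) {
  xtx_inv <- solve(crossprod(x))
  b <- y %*% x %*% xtx_inv              # probes x p coefficients
  coef_raw <- as.vector(b[, ncol(b)])
  if (d == 0) {
    e <- y - b %*% t(x)
    df <- ncol(y) - qr(x)$rank
    se <- sqrt(rowSums(e^2) / df * xtx_inv[ncol(x), ncol(x)])
    return(list(coef = coef_raw, coef_raw = coef_raw, se = se, df = df,
                loadings = matrix(0, nrow(y), 0),
                scores = matrix(0, ncol(y), 0)))
  }
  e <- y - b %*% t(x)                   # residuals
  ev <- eigen(crossprod(e), symmetric = TRUE)
  d_eff <- min(d, sum(ev$values > 1e-12))
  v <- ev$vectors[, seq_len(d_eff), drop = FALSE]        # samples x d
  loadings <- e %*% v                                     # probes x d
  ## score re-estimation on the centred data: regressing the centred
  ## beta-values (not the residuals) on the loadings lets the scores keep
  ## the design-correlated component of cell composition, so the re-fit
  ## can separate direct from mixture-mediated effects
  yc <- y - rowMeans(y)
  ltl <- diag(crossprod(loadings))                       # = eigenvalues 1..d
  scores <- crossprod(yc, loadings) %*% diag(1 / ltl, d_eff)
  x2 <- cbind(x, scores)
  xtx2_inv <- solve(crossprod(x2))
  b2 <- y %*% x2 %*% xtx2_inv
  e2 <- y - b2 %*% t(x2)
  df <- ncol(y) - qr(x2)$rank
  se <- sqrt(rowSums(e2^2) / df * xtx2_inv[ncol(x), ncol(x)])
  list(coef = as.vector(b2[, ncol(x)]), coef_raw = coef_raw, se = se,
       df = df, loadings = loadings, scores = scores)
}

#' Reference-free cell-mixture-adjusted differential methylation
#'
#' Estimates "pheno-MVP" effects for a two-group contrast while adjusting
#' for latent cell-mixture structure, without reference methylomes. Per
#' probe, an OLS fit of the design (patient blocks plus group for the paired
#' design; intercept plus group otherwise) yields coefficients and
#' residuals; the top `d` singular vectors of the residual matrix estimate
#' the latent loading span; per-sample mixture scores are re-estimated from
#' the centred data on those loadings (retaining the design-correlated
#' composition component); and a per-probe re-fit on
#' \[design | scores\] separates the direct effect from the
#' mixture-mediated one. P-values are bootstrap-derived: patients (paired)
#' or samples within groups (unpaired) are resampled with replacement and
#' the entire fit repeated. The default `"bootstrap_t"` studentizes each
#' replicate (second-order accurate, well calibrated at cohort-scale n);
#' `"normal"` is the plain normal approximation from the bootstrap SE;
#' `"fraction"` the centred raw exceedance fraction.
#'
#' @param beta probes x samples matrix.
#' @param samples sample sheet rows for the samples entering the contrast.
#' @param tissue_a,tissue_b the contrast (`a - b` on the beta scale).
#' @param d latent dimension; `"auto"` runs [estimate_dimension()] on the
#'   design-only residuals.
#' @param patients optional subset of patient ids to use (paired designs).
#' @param paired patient-paired design (default) or unpaired.
#' @param n_bootstrap bootstrap replicates (default 100; minimum 10).
#' @param p_method `"bootstrap_t"` (default), `"normal"` or `"fraction"`.
#' @param seed RNG seed; results are deterministic given it.
#' @return A `DeconvResult` list: `d`, `coef` (adjusted delta-beta),
#'   `coef_unadjusted`, `se` (model SE of the adjusted fit), `se_boot`,
#'   `p`, `direction`, `loadings`, `scores`, `n_bootstrap`, `p_method`,
#'   `probe_id`.
#' @export
reffree_fit <- function(beta, samples, tissue_a, tissue_b, d = "auto",
                        patients = NULL, paired = TRUE, n_bootstrap = 100,
                        p_method = c("bootstrap_t", "normal", "fraction"),
                        seed = 1L) {
  p_method <- match.arg(p_method)
  if (n_bootstrap < 10) stop("reffree_fit: n_bootstrap must be >= 10")
  ss <- samples[samples$tissue %in% c(tissue_a, tissue_b), , drop = FALSE]
  if (!is.null(patients)) ss <- ss[ss$patient_id %in% patients, , drop = FALSE]
  if (paired) {
    tab <- table(ss$patient_id, ss$tissue)
    ok <- rownames(tab)[tab[, tissue_a] == 1 & tab[, tissue_b] == 1]
    if (length(ok) < 2) stop("reffree_fit: need at least 2 complete pairs")
    ss <- ss[ss$patient_id %in% ok, , drop = FALSE]
  } else if (any(table(ss$tissue) < 2)) {
    stop("reffree_fit: need at least 2 samples per group")
  }
  y <- beta[, ss$sample_id, drop = FALSE]
  use <- complete.cases(y)
  y <- y[use, , drop = FALSE]

  x <- build_design(ss, levels_ab = c(tissue_a, tissue_b), paired = paired)
  if (qr(x)$rank < ncol(x)) stop("reffree_fit: design matrix is rank deficient")

  if (identical(d, "auto")) {
    xtx_inv <- solve(crossprod(x))
    e0 <- y - (y %*% x %*% xtx_inv) %*% t(x)
    d <- as.integer(estimate_dimension(e0, seed = seed))
  }
  d <- as.integer(d)
  if (d >= ncol(y) - ncol(x) + 1) {
    stop("reffree_fit: d must be smaller than the residual rank")
  }

  obs <- reffree_pass(y, x, d)

  units <- if (paired) unique(ss$patient_id) else seq_len(nrow(ss))
  t_obs <- abs(obs$coef) / pmax(obs$se, 1e-300)
  boot_coef <- matrix(NA_real_, nrow(y), n_bootstrap)
  exceed <- rep(0, nrow(y))
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      if (paired) {
        draw <- sample(units, replace = TRUE)
        rows <- unlist(lapply(seq_along(draw), function(i) {
          which(ss$patient_id == draw[i])
        }))
        ss_b <- ss[rows, , drop = FALSE]
        ## each resampled patient becomes its own block
        ss_b$patient_id <- rep(sprintf("B%03d", seq_along(draw)), each = 2L)
      } else {
        rows <- unlist(lapply(c(tissue_a, tissue_b), function(tt) {
          i <- which(ss$tissue == tt)
          sample(i, replace = TRUE)
        }))
        ss_b <- ss[rows, , drop = FALSE]
      }
      x_b <- build_design(ss_b, levels_ab = c(tissue_a, tissue_b),
                          paired = paired)
      fit_b <- reffree_pass(y[, rows, drop = FALSE], x_b, d)
      boot_coef[, b] <- fit_b$coef
      t_b <- abs(fit_b$coef - obs$coef) / pmax(fit_b$se, 1e-300)
      exceed <- exceed + (t_b >= t_obs)
    }
  })

  se_boot <- apply(boot_coef, 1L, sd)
  p <- switch(p_method,
    bootstrap_t = (1 + exceed) / (1 + n_bootstrap),
    normal = {
      pp <- 2 * pnorm(-abs(obs$coef) / se_boot)
      pp[se_boot == 0] <- ifelse(obs$coef[se_boot == 0] == 0, 1, 0)
      pp
    },
    fraction = {
      centred <- boot_coef - rowMeans(boot_coef)
      (1 + rowSums(abs(centred) >= abs(obs$coef))) / (1 + n_bootstrap)
    }
  )
  list(
    d = d,
    probe_id = rownames(y),
    coef = obs$coef,
    coef_unadjusted = obs$coef_raw,
    se = obs$se,
    se_boot = se_boot,
    p = p,
    direction = ifelse(obs$coef >= 0, "hyper", "hypo"),
    loadings = obs$loadings,
    scores = obs$scores,
    n_bootstrap = n_bootstrap,
    p_method = p_method,
    contrast = c(tissue_a, tissue_b),
    paired = paired
  )
}

#' Overlap between two MVP probe sets
#'
#' @param mvp_a,mvp_b character vectors of probe ids from the same universe.
#' @return list with `n_overlap`, `fraction_of_a`, and the intersection.
#' @export
overlap_mvps <- function(mvp_a, mvp_b) {
  common <- intersect(mvp_a, mvp_b)
  list(
    n_overlap = length(common),
    fraction_of_a = if (length(mvp_a) > 0) length(common) / length(unique(mvp_a)) else NA_real_,
    probes = common
  )
}
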