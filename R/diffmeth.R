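#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks per-probe sample variances towards a common prior using the
#' standard hierarchical model for array data: \eqn{s_g^2 | \sigma_g^2} is
#' scaled chi-square with `df` degrees of freedom and
#' \eqn{1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0 s_0^2)}. The hyper-parameters
#' \eqn{(d_0, s_0^2)} are fitted by method-of-moments on the log variances
#' (digamma/trigamma inversion with bounded Newton steps); the posterior
#' variance is the df-weighted average
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + df\, s_g^2)/(d_0 + df)}.
#'
#' @param s2 per-probe sample variances (non-negative).
#' @param df residual degrees of freedom (scalar; all probes equal).
#' @return list with `d0` (prior df, possibly `Inf`), `s02` (prior
#'   variance), `df` and `posterior` (moderated variances).
#' @export
moderate_variances <- function(s2, df) {
  stopifnot(df >= 1, all(s2 >= -1e-12))
  s2 <- pmax(s2, 0)
  ok <- s2 > 1e-12
  if (sum(ok) < 2 || var(log(s2[ok])) < 1e-12) {
    ## (near-)constant variances: infinite prior df, common value
    s02 <- mean(s2)
    return(list(d0 = Inf, s02 = s02, df = df,
                posterior = rep(s02, length(s2))))
  }
  z <- log(pmax(s2, min(s2[ok]) * 1e-3))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (evar <= 0) {
    s02 <- exp(emean)
    return(list(d0 = Inf, s02 = s02, df = df,
                posterior = rep(s02, length(s2))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  posterior <- (d0 * s02 + df * s2) / (d0 + df)
  list(d0 = d0, s02 = s02, df = df, posterior = posterior)
}

## Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
## near-linear), bounded away from 0; standard approach for the
## log-variance method of moments.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (x <= 0) x <- 1e-8
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; thin wrapper over [stats::p.adjust()] with input
#' validation.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

## Internal core: one-sample moderated t on a matrix of within-pair
## differences (probes x pairs).
moderated_one_sample <- function(diffs, moderate = TRUE) {
  n <- ncol(diffs)
  if (n < 2) stop("paired fit: need at least 2 complete pairs")
  delta <- rowMeans(diffs)
  s2 <- row_vars(diffs, delta)
  df <- n - 1
  if (moderate) {
    mod <- moderate_variances(s2, df)
  } else {
    mod <- list(d0 = 0, s02 = NA_real_, df = df, posterior = s2)
  }
  df_total <- if (is.finite(mod$d0)) mod$d0 + df else Inf
  se <- sqrt(mod$posterior / n)
  t_stat <- delta / se
  p <- 2 * pt(-abs(t_stat), df = df_total)
  list(delta = delta, t = t_stat, p = p, df_total = df_total, mod = mod)
}

#' Paired differential methylation (moderated t)
#'
#' Computes, per CpG, within-patient beta differences
#' `tissue_a - tissue_b`, then a one-sample empirical-Bayes moderated
#' t-statistic across patients (exactly equivalent to the patient-blocked
#' two-group linear model for complete pairs), with BH adjustment across all
#' tested probes. Probes with any NA among the used samples are dropped from
#' fitting.
#'
#' @param beta probes x samples matrix.
#' @param samples sample sheet (`sample_id`, `patient_id`, `tissue`).
#' @param tissue_a,tissue_b the contrast, reported as `a - b`; "hyper" means
#'   higher methylation in `tissue_a` than in the reference `tissue_b`.
#' @param patients optional subset of patient ids to use.
#' @param moderate empirical-Bayes moderation on/off (off gives the ordinary
#'   paired t-test).
#' @return An `MVPTable` data frame: `probe_id`, `delta_beta`, `t`,
#'   `df_total`, `p`, `fdr`, `direction`, with the moderation parameters in
#'   `attr(, "moderation")` and the number of pairs in `attr(, "n_pairs")`.
#' @export
fit_paired <- function(beta, samples, tissue_a, tissue_b, patients = NULL,
                       moderate = TRUE) {
  stopifnot(is.matrix(beta))
  ss <- samples[samples$tissue %in% c(tissue_a, tissue_b), , drop = FALSE]
  if (!is.null(patients)) ss <- ss[ss$patient_id %in% patients, , drop = FALSE]
  if (!all(c(tissue_a, tissue_b) %in% ss$tissue)) {
    stop("fit_paired: tissue(s) not present in sample sheet")
  }
  tab <- table(ss$patient_id, ss$tissue)
  ok <- rownames(tab)[tab[, tissue_a] == 1 & tab[, tissue_b] == 1]
  if (length(ok) < 2) stop("fit_paired: need at least 2 complete pairs")
  id_a <- ss$sample_id[match(paste(ok, tissue_a), paste(ss$patient_id, ss$tissue))]
  id_b <- ss$sample_id[match(paste(ok, tissue_b), paste(ss$patient_id, ss$tissue))]
  diffs <- beta[, id_a, drop = FALSE] - beta[, id_b, drop = FALSE]
  use <- complete.cases(diffs)
  fit <- moderated_one_sample(diffs[use, , drop = FALSE], moderate = moderate)
  out <- data.frame(
    probe_id = rownames(beta)[use],
    delta_beta = fit$delta,
    t = fit$t,
    df_total = fit$df_total,
    p = fit$p,
    fdr = bh_adjust(fit$p),
    direction = ifelse(fit$delta >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "moderation") <- fit$mod
  attr(out, "n_pairs") <- length(ok)
  attr(out, "contrast") <- c(tissue_a, tissue_b)
  out
}

#' Three-tissue moderated ANOVA, patient-blocked
#'
#' Per CpG, fits a linear model with tissue (NK/NR/WT, 2 df) and patient
#' (block) effects over the complete trios, squeezes the residual variances
#' with [moderate_variances()], and tests the tissue term with a moderated
#' F-statistic. Patients missing any tissue are dropped (and reported).
#'
#' @param beta probes x samples matrix.
#' @param samples sample sheet.
#' @param blocked include patient block effects (default); `FALSE` pools
#'   samples across patients.
#' @param moderate empirical-Bayes moderation on/off.
#' @param genomewide_p threshold reported in the summary attribute (count of
#'   probes with raw `p` below it; default 5e-8).
#' @return An `MVPTable` data frame with `probe_id`, `delta_beta` (largest
#'   pairwise tissue-mean difference), `F`, `df1`, `df_total`, `p`, `fdr`.
#' @export
fit_anova3 <- function(beta, samples, blocked = TRUE, moderate = TRUE,
                       genomewide_p = 5e-8) {
  stopifnot(is.matrix(beta))
  trios <- complete_trios(samples)
  if (length(trios) < 2) stop("fit_anova3: need at least 2 complete trios")
  dropped <- setdiff(unique(samples$patient_id[samples$tissue != "EK"]), trios)
  if (length(dropped) > 0) {
    message("fit_anova3: dropping patients without a full trio: ",
            paste(dropped, collapse = ", "))
  }
  ss <- samples[samples$patient_id %in% trios &
                  samples$tissue %in% c("NK", "NR", "WT"), , drop = FALSE]
  y <- beta[, ss$sample_id, drop = FALSE]
  use <- complete.cases(y)
  y <- y[use, , drop = FALSE]

  tissue <- factor(ss$tissue, levels = c("NK", "NR", "WT"))
  patient <- factor(ss$patient_id)
  x_full <- if (blocked) {
    model.matrix(~ patient + tissue)
  } else {
    model.matrix(~ tissue)
  }
  n <- ncol(y)
  x_red <- if (blocked) model.matrix(~ patient) else matrix(1, n, 1)
  h_full <- x_full %*% solve(crossprod(x_full), t(x_full))
  h_red <- x_red %*% solve(crossprod(x_red), t(x_red))
  rss_full <- pmax(rowSums((y %*% (diag(n) - h_full)) * y), 0)
  rss_red <- pmax(rowSums((y %*% (diag(n) - h_red)) * y), 0)
  ss_tissue <- pmax(rss_red - rss_full, 0)
  df1 <- 2L
  df2 <- n - qr(x_full)$rank
  s2 <- rss_full / df2
  if (moderate) {
    mod <- moderate_variances(s2, df2)
  } else {
    mod <- list(d0 = 0, s02 = NA_real_, df = df2, posterior = s2)
  }
  df_total <- if (is.finite(mod$d0)) mod$d0 + df2 else Inf
  ## numerical zeros from the projections must not produce spurious F values
  eps <- 1e-10 * (rowMeans(y^2) + 1e-300)
  ss_tissue[ss_tissue <= eps] <- 0
  posterior <- mod$posterior
  f_stat <- (ss_tissue / df1) / posterior
  f_stat[ss_tissue == 0] <- 0
  f_stat[ss_tissue > 0 & posterior <= eps] <- Inf
  p <- pf(f_stat, df1, df_total, lower.tail = FALSE)
  p[is.infinite(f_stat)] <- 0

  means <- vapply(levels(tissue),
                  function(l) rowMeans(y[, tissue == l, drop = FALSE]),
                  numeric(nrow(y)))
  delta <- apply(means, 1L, function(m) max(m) - min(m))

  out <- data.frame(
    probe_id = rownames(y),
    delta_beta = delta,
    F = f_stat,
    df1 = df1,
    df_total = df_total,
    p = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "moderation") <- mod
  attr(out, "n_trios") <- length(trios)
  attr(out, "n_genomewide") <- sum(p < genomewide_p, na.rm = TRUE)
  attr(out, "genomewide_p") <- genomewide_p
  out
}
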