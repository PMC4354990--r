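# Independent brute-force / closed-form oracles used to cross-check the
# package implementations. These deliberately re-derive everything from
# first principles and share no code with the package internals.

## Step-up FDR adjustment, straight from the definition.
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Bartlett K^2 for one probe, textbook formula.
bartlett_oracle <- function(groups_values) {
  k <- length(groups_values)
  ni <- vapply(groups_values, length, 1L)
  vi <- vapply(groups_values, var, 1)
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  K2 <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi))) / C
  list(K2 = K2, p = pchisq(K2, k - 1, lower.tail = FALSE))
}

## Pearson chi-square without continuity correction, from the definition.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

## Classical (Torgerson) MDS via explicit double centering.
mds_oracle <- function(d2, k) {
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d2 %*% j
  ev <- eigen(b, symmetric = TRUE)
  keep <- seq_len(k)
  coords <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[keep], 0)), k)
  coords
}

## Brute-force probe-lasso DMR caller: O(n^2) pairwise connectivity, BFS
## components, naive merging loop iterated to a fixed point.
brute_force_dmrs <- function(dat, sig_fdr = 0.01, min_sig = 3,
                             merge_gap = 1000) {
  dat <- dat[order(dat$chrom, dat$pos, dat$probe_id), , drop = FALSE]
  regions <- list()
  for (ch in unique(dat$chrom)) {
    cd <- dat[dat$chrom == ch, , drop = FALSE]
    sig <- which(!is.na(cd$fdr) & cd$fdr < sig_fdr)
    if (length(sig) < min_sig) next
    ns <- length(sig)
    adj <- matrix(FALSE, ns, ns)
    for (i in seq_len(ns)) {
      for (j in seq_len(ns)) {
        if (i == j) next
        di <- abs(cd$pos[sig[i]] - cd$pos[sig[j]])
        adj[i, j] <- di <= cd$radius[sig[i]] && di <= cd$radius[sig[j]]
      }
    }
    seen <- rep(FALSE, ns)
    for (s in seq_len(ns)) {
      if (seen[s]) next
      comp <- s
      queue <- s
      seen[s] <- TRUE
      while (length(queue) > 0) {
        cur <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[cur, ] & !seen)
        seen[nb] <- TRUE
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
      if (length(comp) < min_sig) next
      members <- sig[comp]
      in_any <- rep(FALSE, nrow(cd))
      for (m in members) {
        lo <- cd$pos[m] - cd$radius[m]
        hi <- cd$pos[m] + cd$radius[m]
        in_any <- in_any | (cd$pos >= lo & cd$pos <= hi)
      }
      regions[[length(regions) + 1]] <- list(
        chrom = ch,
        probe_ids = cd$probe_id[in_any],
        pos = cd$pos[in_any],
        delta = cd$delta_beta[in_any],
        p = cd$p[in_any],
        sig = !is.na(cd$fdr[in_any]) & cd$fdr[in_any] < sig_fdr,
        n_significant = length(members),
        merged_from = 1L
      )
    }
  }
  ## naive merge to fixed point
  repeat {
    if (length(regions) < 2) break
    spans <- t(vapply(regions, function(r) range(r$pos), numeric(2)))
    chs <- vapply(regions, function(r) r$chrom, "")
    o <- order(chs, spans[, 1], spans[, 2])
    regions <- regions[o]
    spans <- spans[o, , drop = FALSE]
    chs <- chs[o]
    merged_any <- FALSE
    out <- list(regions[[1]])
    for (k in seq_along(regions)[-1]) {
      prev <- out[[length(out)]]
      gap <- (spans[k, 1] - 1) - max(prev$pos)
      if (chs[k] == prev$chrom && gap < merge_gap) {
        keep <- !(regions[[k]]$probe_ids %in% prev$probe_ids)
        comb <- list(
          chrom = prev$chrom,
          probe_ids = c(prev$probe_ids, regions[[k]]$probe_ids[keep]),
          pos = c(prev$pos, regions[[k]]$pos[keep]),
          delta = c(prev$delta, regions[[k]]$delta[keep]),
          p = c(prev$p, regions[[k]]$p[keep]),
          sig = c(prev$sig, regions[[k]]$sig[keep]),
          n_significant = prev$n_significant + regions[[k]]$n_significant,
          merged_from = prev$merged_from + regions[[k]]$merged_from
        )
        oo <- order(comb$pos, comb$probe_ids)
        for (f in c("probe_ids", "pos", "delta", "p", "sig")) {
          comb[[f]] <- comb[[f]][oo]
        }
        out[[length(out)]] <- comb
        merged_any <- TRUE
      } else {
        out[[length(out) + 1]] <- regions[[k]]
      }
    }
    regions <- out
    if (!merged_any) break
  }
  lapply(regions, function(r) {
    mean_delta <- mean(r$delta[r$sig])
    dir <- if (mean_delta >= 0) "hyper" else "hypo"
    sgn <- if (dir == "hyper") 1 else -1
    p1 <- ifelse(sign(r$delta) == sgn, r$p / 2, 1 - r$p / 2)
    p1 <- pmin(pmax(p1, 1e-300), 1 - 1e-16)
    z <- qnorm(p1, lower.tail = FALSE)
    r$direction <- dir
    r$combined_p <- pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
    r$start <- min(r$pos) - 1L
    r$end <- max(r$pos)
    r
  })
}

## Random small DMR fixture: annotation, per-probe radii, significance.
random_dmr_fixture <- function(n_probes = 60, n_chrom = 2) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_probes,
                       replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    n <- sum(chrom == ch)
    sort(sample.int(20000, n))
  }))
  p <- runif(n_probes)
  hot <- runif(n_probes) < 0.35
  p[hot] <- p[hot] * 1e-4
  fdr <- bh_step_up(p)
  data.frame(
    probe_id = sprintf("cg%05d", sample.int(99999, n_probes)),
    chrom = chrom, pos = pos,
    delta_beta = rnorm(n_probes, 0, 0.2),
    p = p, fdr = fdr,
    radius = sample(c(50, 150, 400, 1200), n_probes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

## Compare package DMR output with the oracle, field by field.
expect_same_dmrs <- function(dmrs, oracle) {
  expect_equal(nrow(dmrs), length(oracle))
  if (nrow(dmrs) == 0) return(invisible(TRUE))
  key <- function(chrom, start) paste(chrom, start)
  ok <- order(vapply(oracle, function(r) r$chrom, ""),
              vapply(oracle, function(r) r$start, 1))
  oracle <- oracle[ok]
  for (i in seq_len(nrow(dmrs))) {
    r <- oracle[[i]]
    expect_identical(dmrs$chrom[i], r$chrom)
    expect_equal(dmrs$start[i], r$start)
    expect_equal(dmrs$end[i], r$end)
    expect_equal(dmrs$n_significant[i], r$n_significant)
    expect_equal(dmrs$merged_from[i], r$merged_from)
    expect_identical(dmrs$direction[i], r$direction)
    expect_setequal(dmrs$probes[[i]]$probe_id, r$probe_ids)
    expect_equal(dmrs$combined_p[i], r$combined_p, tolerance = 1e-12)
  }
  invisible(TRUE)
}
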