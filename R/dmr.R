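#' Category-specific probe-lasso radii
#'
#' For every gene-feature x CpG-island-relation category, computes the
#' distribution of nearest-neighbour distances between probes of that
#' category (within chromosomes) and sets the lasso radius to the chosen
#' quantile of that distribution, floored at half the global minimum lasso
#' size. This adapts the window to local probe density: small lassos in
#' dense TSS/island categories, large ones in intergenic open sea.
#' Categories with fewer than two probes inherit the global
#' nearest-neighbour quantile.
#'
#' @param ann probe annotation (`probe_id`, `chrom`, `pos`, `gene_feature`,
#'   `cgi_relation`).
#' @param min_lasso_bp global minimum lasso size in bp (default 10, i.e.
#'   radius floor 5 bp).
#' @param quantile_used quantile of the nearest-neighbour distance
#'   distribution (default 0.5, the category median).
#' @return A `LassoSpec` list: `radii` (named per category), `global_radius`,
#'   `min_lasso_bp`, `quantile_used`, and `probe_radius` (named per probe).
#' @export
compute_lassos <- function(ann, min_lasso_bp = 10, quantile_used = 0.5) {
  if (nrow(ann) == 0) stop("compute_lassos: empty annotation")
  stopifnot(min_lasso_bp > 0, quantile_used > 0, quantile_used <= 1)
  cat_of <- paste(ann$gene_feature, ann$cgi_relation, sep = "|")

  nn_dist <- function(idx) {
    ## nearest-neighbour distance among probes idx, per chromosome
    out <- numeric(0)
    for (ch in unique(ann$chrom[idx])) {
      p <- sort(ann$pos[idx][ann$chrom[idx] == ch])
      if (length(p) < 2) next
      gaps <- diff(p)
      out <- c(out, pmin(c(Inf, gaps), c(gaps, Inf)))
    }
    out
  }

  global_nn <- nn_dist(seq_len(nrow(ann)))
  global_radius <- max(
    if (length(global_nn) > 0) quantile(global_nn, quantile_used, names = FALSE)
    else min_lasso_bp / 2,
    min_lasso_bp / 2
  )

  cats <- sort(unique(cat_of))
  radii <- setNames(numeric(length(cats)), cats)
  for (cc in cats) {
    idx <- which(cat_of == cc)
    d <- nn_dist(idx)
    radii[cc] <- if (length(d) == 0) {
      global_radius
    } else {
      max(quantile(d, quantile_used, names = FALSE), min_lasso_bp / 2)
    }
  }
  probe_radius <- setNames(radii[cat_of], ann$probe_id)
  list(radii = radii, global_radius = global_radius,
       min_lasso_bp = min_lasso_bp, quantile_used = quantile_used,
       probe_radius = probe_radius)
}

#' Probe-lasso DMR calling
#'
#' Implements the density-adaptive probe-lasso procedure: (1) probes with
#' `fdr < sig_fdr` are significant; (2) two significant probes are connected
#' when each lies within the other's lasso interval `[pos - r, pos + r]`
#' (mutual containment; symmetric and order-independent), and connected
#' components with at least `min_sig_probes` significant probes become
#' candidate regions; (3) every probe - significant or not - whose position
#' falls in the union of the component members' lassos is added to the
#' region; (4) regions on one chromosome closer than `merge_gap_bp`
#' (end-to-start, half-open) are merged, summing significant-probe counts;
#' (5) a combined region p-value is computed by Stouffer's method over all
#' member probes' one-sided p-values aligned to the region direction (sign
#' of the mean delta-beta over significant members).
#'
#' @param mvp an `MVPTable` from [fit_paired()] (columns `probe_id`,
#'   `delta_beta`, `p`, `fdr`).
#' @param ann probe annotation sharing `mvp$probe_id`.
#' @param lassos a `LassoSpec` from [compute_lassos()].
#' @param sig_fdr significance cutoff on FDR (default 0.01).
#' @param min_sig_probes minimum connected significant probes (default 3).
#' @param merge_gap_bp merge regions closer than this (default 1000).
#' @return data frame of DMRs: `dmr_id`, `chrom`, `start`, `end` (0-based
#'   half-open spanning first to last member probe), `n_probes`,
#'   `n_significant`, `direction`, `mean_delta_beta`, `combined_p`,
#'   `merged_from`, plus a list-column `probes` of per-member data frames.
#' @export
call_dmrs <- function(mvp, ann, lassos, sig_fdr = 0.01, min_sig_probes = 3,
                      merge_gap_bp = 1000) {
  common <- intersect(mvp$probe_id, ann$probe_id)
  if (length(common) != nrow(mvp)) {
    stop("call_dmrs: ", nrow(mvp) - length(common),
         " probes in the MVP table are missing from the annotation")
  }
  ann <- ann[match(mvp$probe_id, ann$probe_id), , drop = FALSE]
  dat <- data.frame(
    probe_id = mvp$probe_id, chrom = ann$chrom, pos = ann$pos,
    delta_beta = mvp$delta_beta, p = mvp$p,
    significant = !is.na(mvp$fdr) & mvp$fdr < sig_fdr,
    radius = unname(lassos$probe_radius[mvp$probe_id]),
    stringsAsFactors = FALSE
  )
  if (anyNA(dat$radius)) stop("call_dmrs: probes missing from the lasso spec")
  dat <- dat[order(dat$chrom, dat$pos, dat$probe_id), , drop = FALSE]

  regions <- list()
  for (ch in unique(dat$chrom)) {
    cd <- dat[dat$chrom == ch, , drop = FALSE]
    sig <- which(cd$significant)
    if (length(sig) < min_sig_probes) next
    pos <- cd$pos[sig]
    rad <- cd$radius[sig]
    ## union-find over mutual-containment edges; only forward scans needed
    parent <- seq_along(sig)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_along(sig)) {
      j <- i + 1L
      while (j <= length(sig) && pos[j] - pos[i] <= rad[i]) {
        if (pos[j] - pos[i] <= rad[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_along(sig), find, 1L)
    for (cid in unique(comp)) {
      members <- sig[comp == cid]
      if (length(members) < min_sig_probes) next
      ## union of member lassos -> pull in interior probes
      lo <- cd$pos[members] - cd$radius[members]
      hi <- cd$pos[members] + cd$radius[members]
      in_lasso <- rep(FALSE, nrow(cd))
      for (k in seq_along(members)) {
        in_lasso <- in_lasso | (cd$pos >= lo[k] & cd$pos <= hi[k])
      }
      keep <- which(in_lasso)
      regions[[length(regions) + 1L]] <- list(
        chrom = ch,
        probes = cd[keep, c("probe_id", "pos", "delta_beta", "p",
                            "significant")],
        n_significant = length(members),
        merged_from = 1L
      )
    }
  }
  if (length(regions) == 0) return(empty_dmr_frame())

  ## merge regions within merge_gap_bp (bounds spanning member probes)
  span <- t(vapply(regions, function(r) {
    c(min(r$probes$pos) - 1, max(r$probes$pos))
  }, numeric(2)))
  chroms <- vapply(regions, `[[`, "", "chrom")
  ord <- order(chroms, span[, 1], span[, 2])
  merged <- list()
  cur <- regions[[ord[1]]]
  cur_span <- span[ord[1], ]
  for (k in ord[-1]) {
    gap <- span[k, 1] - cur_span[2]
    if (chroms_equal(regions[[k]]$chrom, cur$chrom) && gap < merge_gap_bp) {
      probes <- rbind(cur$probes, regions[[k]]$probes)
      probes <- probes[!duplicated(probes$probe_id), , drop = FALSE]
      cur$probes <- probes[order(probes$pos, probes$probe_id), , drop = FALSE]
      cur$n_significant <- cur$n_significant + regions[[k]]$n_significant
      cur$merged_from <- cur$merged_from + regions[[k]]$merged_from
      cur_span <- c(min(cur_span[1], span[k, 1]), max(cur_span[2], span[k, 2]))
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- regions[[k]]
      cur_span <- span[k, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur

  out <- lapply(seq_along(merged), function(i) {
    r <- merged[[i]]
    pr <- r$probes
    mean_delta <- mean(pr$delta_beta[pr$significant])
    direction <- if (mean_delta >= 0) "hyper" else "hypo"
    sgn <- if (direction == "hyper") 1 else -1
    one_sided <- ifelse(sign(pr$delta_beta) == sgn, pr$p / 2, 1 - pr$p / 2)
    data.frame(
      dmr_id = NA_character_, chrom = r$chrom,
      start = min(pr$pos) - 1L, end = max(pr$pos),
      n_probes = nrow(pr), n_significant = r$n_significant,
      direction = direction, mean_delta_beta = mean_delta,
      combined_p = stouffer_p(one_sided), merged_from = r$merged_from,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  ord <- order(res$chrom, res$start, res$end)
  res <- res[ord, , drop = FALSE]
  res$dmr_id <- sprintf("DMR_%04d", seq_len(nrow(res)))
  res$probes <- I(lapply(merged[ord], function(r) {
    pr <- r$probes
    rownames(pr) <- NULL
    pr
  }))
  rownames(res) <- NULL
  res
}

chroms_equal <- function(a, b) identical(as.character(a), as.character(b))

empty_dmr_frame <- function() {
  res <- data.frame(
    dmr_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), n_probes = integer(0), n_significant = integer(0),
    direction = character(0), mean_delta_beta = numeric(0),
    combined_p = numeric(0), merged_from = integer(0),
    stringsAsFactors = FALSE
  )
  res$probes <- I(list())
  res
}

#' Summarize a DMR set for enrichment-style reporting
#'
#' Tallies DMRs by direction, gene-feature and CpG-island-relation category
#' (a DMR contributes its member probes), and summarizes region sizes.
#'
#' @param dmrs output of [call_dmrs()].
#' @param ann probe annotation.
#' @return list of data frames: `by_direction`, `by_gene_feature`,
#'   `by_cgi_relation` (counts and within-facet fractions), and `sizes`.
#' @export
summarize_dmrs <- function(dmrs, ann) {
  if (nrow(dmrs) == 0) {
    empty <- data.frame(level = character(0), direction = character(0),
                        count = integer(0), fraction = numeric(0))
    return(list(by_direction = empty, by_gene_feature = empty,
                by_cgi_relation = empty,
                sizes = data.frame(dmr_id = character(0), width = integer(0))))
  }
  by_dir <- as.data.frame(table(direction = dmrs$direction),
                          stringsAsFactors = FALSE)
  colnames(by_dir)[2] <- "count"
  by_dir$fraction <- by_dir$count / sum(by_dir$count)

  probe_rows <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
    data.frame(probe_id = dmrs$probes[[i]]$probe_id,
               direction = dmrs$direction[i], stringsAsFactors = FALSE)
  }))
  probe_rows$gene_feature <-
    ann$gene_feature[match(probe_rows$probe_id, ann$probe_id)]
  probe_rows$cgi_relation <-
    ann$cgi_relation[match(probe_rows$probe_id, ann$probe_id)]

  facet <- function(col) {
    tab <- as.data.frame(table(level = probe_rows[[col]],
                               direction = probe_rows$direction),
                         stringsAsFactors = FALSE)
    colnames(tab)[3] <- "count"
    tot <- tapply(tab$count, tab$direction, sum)
    tab$fraction <- tab$count / as.numeric(tot[tab$direction])
    tab
  }
  list(
    by_direction = by_dir,
    by_gene_feature = facet("gene_feature"),
    by_cgi_relation = facet("cgi_relation"),
    sizes = data.frame(dmr_id = dmrs$dmr_id,
                       width = dmrs$end - dmrs$start,
                       direction = dmrs$direction, stringsAsFactors = FALSE)
  )
}

#' Export DMRs as BED4+
#'
#' Writes `chrom, start, end, dmr_id, n_significant, direction, combined_p`
#' in 0-based half-open coordinates.
#'
#' @param dmrs output of [call_dmrs()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dmrs$chrom,
    ranges = IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end)
  )
  names(gr) <- dmrs$dmr_id
  write_bed(gr, path, extra = data.frame(
    n_sig = dmrs$n_significant, direction = dmrs$direction,
    combined_p = signif(dmrs$combined_p, 6)
  ))
  invisible(path)
}
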