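#' Read a beta-value matrix from TSV
#'
#' The file must have a header row of sample ids and one row per probe, first
#' column the probe id. Values must be numeric and inside \[0, 1\] (or NA);
#' the first offending cell is named in the error.
#'
#' @param path TSV path.
#' @return numeric matrix, probes x samples, with dimnames.
#' @export
read_beta <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(df[[1]])
  if (anyDuplicated(probe_ids)) {
    stop("read_beta: duplicate probe id '",
         probe_ids[duplicated(probe_ids)][1], "' in ", path)
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("read_beta: duplicate sample id '",
         sample_ids[duplicated(sample_ids)][1], "' in ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop("read_beta: non-numeric values in column '", sample_ids[bad], "'")
  }
  dimnames(m) <- list(probe_ids, sample_ids)
  out_of_range <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    i <- out_of_range[1, 1]; j <- out_of_range[1, 2]
    stop(sprintf(
      "read_beta: value %g outside [0, 1] at probe '%s', sample '%s'",
      m[i, j], probe_ids[i], sample_ids[j]
    ))
  }
  m
}

#' Write a beta-value matrix to TSV
#'
#' Ten decimal places, so that read/write round-trips are stable to 1e-9.
#'
#' @param beta probes x samples matrix with dimnames.
#' @param path output path.
#' @param check_range validate values in \[0, 1\] before writing.
#' @return Invisibly, `path`.
#' @export
write_beta <- function(beta, path, check_range = TRUE) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (check_range && any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("write_beta: values outside [0, 1]")
  }
  fmt <- matrix(sprintf("%.10f", beta), nrow = nrow(beta))
  fmt[is.na(beta)] <- "NA"
  df <- data.frame(probe_id = rownames(beta), fmt, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3+ columns (chrom, start, end, \[name, ...\]) in the BED 0-based
#' half-open convention; returns a sorted `GRanges` (1-based closed
#' internally, as usual for Bioconductor containers). A probe at 1-based
#' position `pos` overlaps interval `[start, end)` iff `start < pos <= end`.
#' Malformed lines are reported with their line number.
#'
#' @param path BED path.
#' @return A sorted `GRanges`; interval names from column 4 if present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("read_bed: line ", which(nf < 3)[1], " of ", basename(path),
         " has fewer than 3 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("read_bed: malformed interval on line ", bad[1], " of ",
         basename(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  has_name <- nf >= 4
  if (all(has_name)) names(gr) <- vapply(parts, `[[`, "", 4L)
  GenomicRanges::sort(gr)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open coordinates, sorted. Extra numeric columns can be
#' appended after the name column (BED4+).
#'
#' @param gr a `GRanges` (optionally named).
#' @param path output path.
#' @param extra optional data frame of additional columns, parallel to `gr`.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, extra = NULL) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr <- gr[o]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(names(gr))) {
    df$name <- names(gr)
  } else if (!is.null(extra)) {
    df$name <- sprintf("region_%d", seq_along(gr))
  }
  if (!is.null(extra)) df <- cbind(df, extra[o, , drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Membership of 1-based probe positions in a feature GRanges.
probes_in_features <- function(chrom, pos, gr) {
  if (length(gr) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = pos, end = pos))
  IRanges::overlapsAny(q, gr)
}

#' Load and validate a cohort from disk
#'
#' Reads the beta matrix, probe annotation and sample sheet (plus optional
#' feature BEDs and detection matrix), cross-checks ids, and returns a bundle
#' ordered by (chrom, pos). Patients without a complete trio are reported;
#' paired analyses drop them later.
#'
#' @param dir directory holding `beta.tsv`, `probes.csv`, `samples.csv` and
#'   optionally `features/*.bed`, `detection.tsv` (as written by
#'   [write_fixture()]); alternatively supply explicit paths.
#' @param beta,probes,samples,features_dir,detection explicit path overrides.
#' @param verbose log counts via `message()`.
#' @return A cohort bundle list (`beta`, `ann`, `samples`, `features`,
#'   `detection_p`).
#' @export
load_cohort <- function(dir = NULL, beta = NULL, probes = NULL,
                        samples = NULL, features_dir = NULL,
                        detection = NULL, verbose = TRUE) {
  if (!is.null(dir)) {
    if (is.null(beta)) beta <- file.path(dir, "beta.tsv")
    if (is.null(probes)) probes <- file.path(dir, "probes.csv")
    if (is.null(samples)) samples <- file.path(dir, "samples.csv")
    if (is.null(features_dir)) {
      fd <- file.path(dir, "features")
      if (dir.exists(fd)) features_dir <- fd
    }
    if (is.null(detection)) {
      dp <- file.path(dir, "detection.tsv")
      if (file.exists(dp)) detection <- dp
    }
  }
  b <- read_beta(beta)
  ann <- utils::read.csv(probes, stringsAsFactors = FALSE)
  ss <- utils::read.csv(samples, stringsAsFactors = FALSE)
  validate_cohort(b, ann, ss)

  missing_in_beta <- setdiff(ss$sample_id, colnames(b))
  if (length(missing_in_beta) > 0) {
    stop("load_cohort: samples in sheet missing from beta matrix: ",
         paste(missing_in_beta, collapse = ", "))
  }
  extra_in_beta <- setdiff(colnames(b), ss$sample_id)
  if (length(extra_in_beta) > 0) {
    stop("load_cohort: samples in beta matrix missing from sheet: ",
         paste(extra_in_beta, collapse = ", "))
  }

  ord <- order(ann$chrom, ann$pos, ann$probe_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  b <- b[ann$probe_id, ss$sample_id, drop = FALSE]

  features <- list()
  if (!is.null(features_dir)) {
    beds <- list.files(features_dir, pattern = "\\.bed$", full.names = TRUE)
    features <- lapply(beds, read_bed)
    names(features) <- sub("\\.bed$", "", basename(beds))
  }
  detection_p <- NULL
  if (!is.null(detection)) {
    detection_p <- read_beta(detection)
    detection_p <- detection_p[ann$probe_id, ss$sample_id, drop = FALSE]
  }

  trios <- complete_trios(ss)
  incomplete <- setdiff(unique(ss$patient_id[ss$tissue != "EK"]), trios)
  if (length(incomplete) > 0) {
    warning("load_cohort: incomplete trio(s), excluded from paired ",
            "analyses: ", paste(incomplete, collapse = ", "))
  }
  msg(sprintf(
    "load_cohort: %d probes x %d samples; %d complete trio(s); %d feature set(s)",
    nrow(b), ncol(b), length(trios), length(features)
  ), verbose = verbose)

  list(beta = b, ann = ann, samples = ss, features = features,
       detection_p = detection_p)
}

validate_cohort <- function(beta, ann, samples) {
  stopifnot(is.matrix(beta))
  need_ann <- c("probe_id", "chrom", "pos", "gene_feature", "cgi_relation")
  miss <- setdiff(need_ann, colnames(ann))
  if (length(miss) > 0) {
    stop("cohort: annotation missing columns: ", paste(miss, collapse = ", "))
  }
  need_ss <- c("sample_id", "patient_id", "tissue")
  miss <- setdiff(need_ss, colnames(samples))
  if (length(miss) > 0) {
    stop("cohort: sample sheet missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(samples$tissue), c("NK", "NR", "WT", "EK"))
  if (length(bad) > 0) {
    stop("cohort: unknown tissue label(s): ", paste(bad, collapse = ", "))
  }
  if (any(ann$pos < 1)) stop("cohort: probe positions must be >= 1")
  miss <- setdiff(rownames(beta), ann$probe_id)
  if (length(miss) > 0) {
    stop("cohort: probes in beta matrix missing from annotation: ",
         paste(head(miss, 5), collapse = ", "))
  }
  invisible(TRUE)
}

## Patients with exactly one NK, one NR, one WT sample.
complete_trios <- function(samples) {
  tab <- table(samples$patient_id, samples$tissue)
  want <- c("NK", "NR", "WT")
  if (!all(want %in% colnames(tab))) return(character(0))
  ok <- rowSums(tab[, want, drop = FALSE] == 1) == 3 &
    rowSums(tab[, want, drop = FALSE]) == 3
  rownames(tab)[ok]
}
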