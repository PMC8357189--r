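#' Quantification settings
#'
#' @param variant_fraction_threshold mismatch fraction at or above which a
#'   position is masked as a variant (inclusive threshold).
#' @param min_conversions_labeled minimum T>C conversions for a read to be
#'   called labeled.
#' @param min_coverage_for_variant_call minimum pooled coverage before a
#'   position can be masked.
#' @param min_base_coverage_for_rate minimum coverage for a position to
#'   enter the per-UTR conversion-rate average.
#' @return a `quant_config` list.
#' @export
quant_config <- function(variant_fraction_threshold = 0.2,
                         min_conversions_labeled = 2L,
                         min_coverage_for_variant_call = 10L,
                         min_base_coverage_for_rate = 1L) {
  stopifnot(variant_fraction_threshold > 0,
            variant_fraction_threshold <= 1,
            min_conversions_labeled >= 1)
  structure(list(
    variant_fraction_threshold = variant_fraction_threshold,
    min_conversions_labeled = as.integer(min_conversions_labeled),
    min_coverage_for_variant_call = as.integer(min_coverage_for_variant_call),
    min_base_coverage_for_rate = as.integer(min_base_coverage_for_rate)
  ), class = "quant_config")
}

#' Call variant positions pooled across samples
#'
#' A position whose mismatch fraction (reads carrying any substitution over
#' reads covering it) reaches the threshold at sufficient pooled coverage is
#' masked from all downstream conversion accounting. Pooling across the
#' whole experiment reflects that variants are genotype properties; the mask
#' is sample-independent thereafter. The threshold is inclusive: fraction
#' exactly at the threshold masks.
#'
#' @param read_sets a single `read_set` or list of them (all samples of one
#'   experiment).
#' @param reference the matching reference.
#' @param config a [quant_config()].
#' @return a `variant_mask`: data.frame (contig, pos, mismatch_frac,
#'   coverage) of masked positions, with the full per-position mismatch
#'   table as attribute `site_table`.
#' @export
detect_variants <- function(read_sets, reference, config = quant_config()) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  genes <- reference$genes

  # pooled coverage per window = total spanning reads across samples
  cov_by_gene <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  ev_all <- list()
  for (rs in read_sets) {
    if (nrow(rs$reads) == 0L) next
    tab <- table(rs$reads$gene_id)
    cov_by_gene[names(tab)] <- cov_by_gene[names(tab)] + as.numeric(tab)
    if (nrow(rs$events)) {
      ev_all[[length(ev_all) + 1L]] <-
        data.frame(contig = rs$reads$contig[rs$events$read],
                   gene_id = rs$reads$gene_id[rs$events$read],
                   pos = rs$events$pos, stringsAsFactors = FALSE)
    }
  }
  if (sum(cov_by_gene) == 0) {
    warning("empty read set: returning an empty variant mask")
    mask <- data.frame(contig = character(), pos = integer(),
                       mismatch_frac = numeric(), coverage = numeric())
    class(mask) <- c("variant_mask", "data.frame")
    return(mask)
  }
  ev <- if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(contig = character(), gene_id = character(), pos = integer())

  if (nrow(ev)) {
    key <- paste(ev$contig, ev$pos)
    cnt <- table(key)
    first <- !duplicated(key)
    sites <- data.frame(contig = ev$contig[first], pos = ev$pos[first],
                        gene_id = ev$gene_id[first],
                        stringsAsFactors = FALSE)
    sites$mismatch <- as.numeric(cnt[paste(sites$contig, sites$pos)])
    sites$coverage <- cov_by_gene[sites$gene_id]
    sites$mismatch_frac <- sites$mismatch / sites$coverage
    sites <- sites[order(sites$contig, sites$pos), ]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(contig = character(), pos = integer(),
                        gene_id = character(), mismatch = numeric(),
                        coverage = numeric(), mismatch_frac = numeric())
  }
  keep <- sites$mismatch_frac >= config$variant_fraction_threshold &
    sites$coverage >= config$min_coverage_for_variant_call
  mask <- sites[keep, c("contig", "pos", "mismatch_frac", "coverage")]
  mask <- mask[order(mask$contig, mask$pos), ]
  rownames(mask) <- NULL
  attr(mask, "site_table") <- sites
  class(mask) <- c("variant_mask", "data.frame")
  mask
}

empty_mask <- function() {
  m <- data.frame(contig = character(), pos = integer(),
                  mismatch_frac = numeric(), coverage = numeric())
  class(m) <- c("variant_mask", "data.frame")
  m
}

mask_key <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0L) character(0) else
    paste(mask$contig, mask$pos)
}

#' Count strand-aware T>C conversions per read
#'
#' A conversion is a reference T read as C on the transcribed strand; for
#' minus-strand genes this appears as reference A read as G on the reference
#' strand. Masked positions contribute neither to the conversion count nor
#' to the convertible-T tally.
#'
#' @param read_set a `read_set`.
#' @param reference the matching reference.
#' @param mask a `variant_mask` (possibly empty).
#' @return data.frame, one row per read: read_id, gene_id, n_t_positions,
#'   n_tc_conversions, n_other_mismatches.
#' @export
count_conversions <- function(read_set, reference, mask = empty_mask()) {
  reads <- read_set$reads
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id, gene_id = reads$gene_id,
                    n_t_positions = integer(n),
                    n_tc_conversions = integer(n),
                    n_other_mismatches = integer(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  mk <- mask_key(mask)
  genes <- reference$genes

  # unmasked convertible-T count per gene
  gidx <- match(reads$gene_id, genes$gene_id)
  if (anyNA(gidx)) {
    stopf("read %s is not on any known counting window",
          reads$read_id[which(is.na(gidx))[1]])
  }
  ug <- unique(gidx)
  t_avail <- integer(max(ug))
  conv_key <- new.env(parent = emptyenv())
  for (g in ug) {
    cand <- convertible_positions(reference, g)
    keep <- !(paste(genes$contig[g], cand) %in% mk)
    t_avail[g] <- sum(keep)
    assign(genes$gene_id[g], cand[keep], envir = conv_key)
  }
  out$n_t_positions <- t_avail[gidx]

  ev <- read_set$events
  if (nrow(ev)) {
    ev_gidx <- gidx[ev$read]
    ev_contig <- reads$contig[ev$read]
    ev_strand <- reads$strand[ev$read]
    masked <- paste(ev_contig, ev$pos) %in% mk
    conv_base <- ifelse(ev_strand == "+", "C", "G")
    at_t <- logical(nrow(ev))
    for (g in ug) {
      sel <- which(ev_gidx == g)
      if (length(sel)) {
        at_t[sel] <- ev$pos[sel] %in% get(genes$gene_id[g], envir = conv_key)
      }
    }
    is_conv <- !masked & at_t & ev$alt == conv_base
    is_other <- !masked & !is_conv
    out$n_tc_conversions <- tabulate(ev$read[is_conv], nbins = n)
    out$n_other_mismatches <- tabulate(ev$read[is_other], nbins = n)
  }
  out
}

#' Call reads labeled or unlabeled
#'
#' A read is labeled iff it carries at least `min_conversions_labeled`
#' unmasked T>C conversions.
#'
#' @param counts data.frame from [count_conversions()].
#' @param config a [quant_config()].
#' @return logical vector, one per read.
#' @export
classify_reads <- function(counts, config = quant_config()) {
  counts$n_tc_conversions >= config$min_conversions_labeled
}

#' Per-window conversion profile and per-UTR conversion rate
#'
#' For every unmasked convertible position with coverage at or above
#' `min_base_coverage_for_rate`, the position rate is conversions/coverage;
#' the per-UTR rate is the unweighted mean over qualifying positions
#' (normalization to genomic T content and per-position coverage, averaged
#' across the window). Windows with no qualifying position report `NA`,
#' never 0.
#'
#' @param read_set a `read_set` (one sample).
#' @param reference the matching reference.
#' @param mask a `variant_mask`.
#' @param config a [quant_config()].
#' @return data.frame per gene: gene_id, t_content, n_positions_used,
#'   coverage, utr_rate.
#' @export
utr_conversion_rate <- function(read_set, reference, mask = empty_mask(),
                                config = quant_config()) {
  genes <- reference$genes
  mk <- mask_key(mask)
  reads <- read_set$reads
  cov <- table(reads$gene_id)
  ev <- read_set$events
  ev_gene <- if (nrow(ev)) reads$gene_id[ev$read] else character(0)
  ev_strand <- if (nrow(ev)) reads$strand[ev$read] else character(0)
  conv_base <- ifelse(ev_strand == "+", "C", "G")
  is_conv <- if (nrow(ev)) ev$alt == conv_base else logical(0)

  conv_idx <- which(is_conv)
  conv_by_gene <- split(conv_idx, ev_gene[conv_idx])

  out <- data.frame(gene_id = genes$gene_id, t_content = genes$t_count,
                    n_positions_used = 0L, coverage = 0,
                    utr_rate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ci <- as.numeric(cov[gid])
    if (is.na(ci)) ci <- 0
    out$coverage[i] <- ci
    if (ci < config$min_base_coverage_for_rate) next
    cand <- convertible_positions(reference, i)
    cand <- cand[!(paste(genes$contig[i], cand) %in% mk)]
    if (!length(cand)) next
    sel <- conv_by_gene[[gid]]
    conv_at <- if (length(sel))
      tabulate(match(ev$pos[sel], cand), nbins = length(cand)) else
      integer(length(cand))
    out$n_positions_used[i] <- length(cand)
    out$utr_rate[i] <- mean(conv_at / ci)
  }
  out
}

#' Build the labeled count matrix over all samples
#'
#' Counts, per gene and sample, reads passing the minimum-conversion filter
#' (labeled) and all reads (total), against one shared variant mask.
#'
#' @param read_sets named list of `read_set` objects.
#' @param reference the matching reference.
#' @param mask a `variant_mask` shared across samples.
#' @param config a [quant_config()].
#' @param samples sample sheet data.frame (sample_id, arm, time_h,
#'   replicate); defaults to the sheet attached to `read_sets`. Every sheet
#'   row must have a read set and vice versa.
#' @return a `slam_counts`: list(labeled, total, samples, lib_size), genes
#'   in reference order, samples in sheet order.
#' @export
build_count_matrix <- function(read_sets, reference, mask = empty_mask(),
                               config = quant_config(),
                               samples = attr(read_sets, "sample_sheet")) {
  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(read_sets), arm = NA, time_h = NA,
                          replicate = NA, stringsAsFactors = FALSE)
  }
  missing_sets <- setdiff(samples$sample_id, names(read_sets))
  if (length(missing_sets)) {
    stopf("sample sheet lists samples with no reads: %s",
          paste(missing_sets, collapse = ", "))
  }
  genes <- reference$genes
  labeled <- matrix(0L, nrow(genes), nrow(samples),
                    dimnames = list(genes$gene_id, samples$sample_id))
  total <- labeled
  for (j in seq_len(nrow(samples))) {
    rs <- read_sets[[samples$sample_id[j]]]
    cc <- count_conversions(rs, reference, mask)
    lab <- classify_reads(cc, config)
    total[, j] <- tabulate(match(cc$gene_id, genes$gene_id),
                           nbins = nrow(genes))
    labeled[, j] <- tabulate(match(cc$gene_id[lab], genes$gene_id),
                             nbins = nrow(genes))
  }
  new_slam_counts(labeled, total, samples)
}

#' Write the count matrix and metadata as TSV
#'
#' @param counts a `slam_counts`.
#' @param dir output directory.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- data.frame(gene_id = rownames(counts$labeled), counts$labeled,
                    check.names = FALSE)
  tot <- data.frame(gene_id = rownames(counts$total), counts$total,
                    check.names = FALSE)
  write_tsv(lab, file.path(dir, "labeled_counts.tsv"))
  write_tsv(tot, file.path(dir, "total_counts.tsv"))
  write_tsv(counts$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir directory with labeled_counts.tsv, total_counts.tsv,
#'   samples.tsv.
#' @return a `slam_counts`.
#' @export
read_count_matrix <- function(dir) {
  lab <- read_tsv(file.path(dir, "labeled_counts.tsv"))
  tot <- read_tsv(file.path(dir, "total_counts.tsv"))
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  l <- as.matrix(lab[, -1]); rownames(l) <- lab$gene_id
  t <- as.matrix(tot[, -1]); rownames(t) <- tot$gene_id
  new_slam_counts(l, t, samples)
}
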