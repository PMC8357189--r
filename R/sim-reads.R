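#' Simulate aligned labeled reads for every sample
#'
#' Each read spans its gene's full counting window (read length equals
#' window length, so alignment is unambiguous). Per gene and sample, labeled
#' reads are drawn Poisson with mean `mean_depth * expr_mult * l(t)` where
#' `l(t)` is the planted labeled abundance, and unlabeled reads Poisson with
#' mean `mean_depth * expr_mult * (1 - base_label_frac)`; induction thus
#' adds labeled read mass. Labeled reads acquire T>C conversions at
#' convertible positions with probability `p_conv` (strand-aware: reference
#' A read as G for minus-strand genes); every read acquires background
#' substitutions at `p_err` per position, uniform over the three alternative
#' bases; planted variant positions carry the alternative allele in every
#' covering read.
#'
#' Reads are held sparsely as substitution events against the reference;
#' full sequences are materialized only when writing SAM/TSV.
#'
#' @param truth a [simulate_timecourse()] result.
#' @param reference the matching [build_reference()] result.
#' @param config optional override config.
#' @param samples optional character vector of sample_ids to generate
#'   (default: all in [sample_sheet()]); unknown ids are an error.
#' @return a named list of `read_set` objects (one per sample) with
#'   attribute `sample_sheet`. Each `read_set` has `sample_id`, `reads`
#'   (read_id, gene_id, contig, start, strand, length), `events`
#'   (read: row index into reads, pos: 1-based genomic, alt), and `n_labeled`
#'   (true labeled read count per gene, for diagnostics).
#' @export
simulate_reads <- function(truth, reference, config = truth$config,
                           samples = NULL) {
  validate_config(config)
  sheet <- sample_sheet(config)
  if (is.null(samples)) samples <- sheet$sample_id
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown)) {
    stopf("unknown sample(s) not in the configured design: %s",
          paste(unknown, collapse = ", "))
  }
  sets <- lapply(samples, function(sid) {
    row <- sheet[sheet$sample_id == sid, ]
    simulate_sample_reads(truth, reference, config, sid, row$arm, row$time_h)
  })
  names(sets) <- samples
  attr(sets, "sample_sheet") <- sheet[match(samples, sheet$sample_id), ]
  sets
}

simulate_sample_reads <- function(truth, reference, config, sample_id, arm,
                                  time_h) {
  genes <- truth$genes
  n <- nrow(genes)
  tp_idx <- match(time_h, truth$time_points_h)
  l <- truth$labeled_abundance[, tp_idx, arm]
  l0 <- config$base_label_frac
  L <- config$window_length

  snp_of <- match(genes$gene_id, truth$snps$gene_id)

  with_stream(config$seed, paste0("reads/", sample_id), {
    mu <- config$mean_depth * genes$expr_mult
    n_lab <- rpois(n, mu * l)
    n_unl <- rpois(n, mu * (1 - l0))
    n_tot <- n_lab + n_unl

    reads_list <- vector("list", n)
    events_list <- vector("list", n)
    offset <- 0L
    for (i in seq_len(n)) {
      ni <- n_tot[i]
      if (ni == 0L) next
      g <- genes[i, ]
      conv_alt <- if (g$strand == "+") "C" else "G"
      cand <- convertible_positions(reference, i)
      # exclude the planted variant position from conversion draws: it is
      # already altered to the conversion base in every read
      if (!is.na(snp_of[i])) cand <- setdiff(cand, truth$snps$pos[snp_of[i]])
      nT <- length(cand)

      ev_pos <- integer(0); ev_read <- integer(0); ev_alt <- character(0)

      # conversions in labeled reads (reads 1..n_lab of this gene)
      if (n_lab[i] > 0L && nT > 0L && config$p_conv > 0) {
        k <- rbinom(n_lab[i], nT, config$p_conv)
        tot <- sum(k)
        if (tot > 0L) {
          rd <- rep.int(seq_len(n_lab[i]), k)
          ps <- unlist(lapply(k[k > 0L], function(kk)
            cand[sample.int(nT, kk)]), use.names = FALSE)
          ev_read <- c(ev_read, rd)
          ev_pos <- c(ev_pos, ps)
          ev_alt <- c(ev_alt, rep.int(conv_alt, tot))
        }
      }

      # background errors in all reads
      if (config$p_err > 0) {
        ke <- rbinom(ni, L, config$p_err)
        tot <- sum(ke)
        if (tot > 0L) {
          rd <- rep.int(seq_len(ni), ke)
          off <- unlist(lapply(ke[ke > 0L], function(kk)
            sample.int(L, kk)), use.names = FALSE)
          ps <- g$win_start - 1L + off
          refb <- substring(window_seq(reference, i), off, off)
          alt <- vapply(refb, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
            USE.NAMES = FALSE)
          # conversions take precedence over a colliding background error
          key_conv <- paste(ev_read, ev_pos)
          keep <- !(paste(rd, ps) %in% key_conv)
          ev_read <- c(ev_read, rd[keep])
          ev_pos <- c(ev_pos, ps[keep])
          ev_alt <- c(ev_alt, alt[keep])
        }
      }

      # planted variant: alternative allele in every covering read
      if (!is.na(snp_of[i])) {
        sp <- truth$snps$pos[snp_of[i]]
        sa <- truth$snps$alt[snp_of[i]]
        key_prev <- paste(ev_read, ev_pos)
        rd <- seq_len(ni)
        keep <- !(paste(rd, sp) %in% key_prev)
        ev_read <- c(ev_read, rd[keep])
        ev_pos <- c(ev_pos, rep.int(sp, sum(keep)))
        ev_alt <- c(ev_alt, rep.int(sa, sum(keep)))
      }

      reads_list[[i]] <- data.frame(
        read_id = sprintf("%s.%s.%d", sample_id, genes$gene_id[i],
                          seq_len(ni)),
        gene_id = genes$gene_id[i], contig = g$contig,
        start = g$win_start, strand = g$strand,
        stringsAsFactors = FALSE
      )
      if (length(ev_read)) {
        events_list[[i]] <- data.frame(read = ev_read + offset,
                                       pos = ev_pos, alt = ev_alt,
                                       stringsAsFactors = FALSE)
      }
      offset <- offset + ni
    }
  })

  reads <- do.call(rbind, reads_list[!vapply(reads_list, is.null, TRUE)])
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), gene_id = character(),
                        contig = character(), start = integer(),
                        strand = character())
  }
  events <- do.call(rbind, events_list[!vapply(events_list, is.null, TRUE)])
  if (is.null(events)) {
    events <- data.frame(read = integer(), pos = integer(),
                         alt = character())
  }
  structure(list(sample_id = sample_id, reads = reads, events = events,
                 length = L,
                 n_labeled = stats::setNames(n_lab, genes$gene_id),
                 n_total = stats::setNames(n_tot, genes$gene_id)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set %s: %d reads (%d bp), %d substitution events\n",
              x$sample_id, nrow(x$reads), x$length, nrow(x$events)))
  invisible(x)
}

# Materialize full read sequences (reference strand) for a read_set.
read_sequences <- function(read_set, reference) {
  reads <- read_set$reads
  L <- read_set$length
  n <- nrow(reads)
  if (n == 0L) return(character(0))
  win_of <- reference$genes[match(reads$gene_id, reference$genes$gene_id), ]
  out <- character(n)
  # per gene: replicate the window sequence and patch substitution bytes
  ev <- read_set$events
  split_idx <- split(seq_len(n), reads$gene_id)
  ev_split <- if (nrow(ev)) split(ev, reads$gene_id[ev$read]) else list()
  for (gid in names(split_idx)) {
    rows <- split_idx[[gid]]
    gi <- match(gid, reference$genes$gene_id)
    ws <- reference$genes$win_start[gi]
    raw <- charToRaw(strrep(window_seq(reference, gi), length(rows)))
    e <- ev_split[[gid]]
    if (!is.null(e) && nrow(e)) {
      local_read <- match(e$read, rows)
      off <- (local_read - 1L) * L + (e$pos - ws + 1L)
      raw[off] <- as.raw(vapply(e$alt, utf8ToInt, integer(1),
                                USE.NAMES = FALSE))
    }
    big <- rawToChar(raw)
    starts <- (seq_along(rows) - 1L) * L + 1L
    out[rows] <- substring(big, starts, starts + L - 1L)
  }
  out
}

#' Write a read set as the tabular read dialect (TSV)
#'
#' Columns: read_id, contig, start (0-based), strand, sequence (reference
#' strand). One read per line.
#'
#' @param read_set a `read_set`.
#' @param reference the matching reference.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_reads_tsv <- function(read_set, reference, path) {
  seqs <- read_sequences(read_set, reference)
  df <- data.frame(read_id = read_set$reads$read_id,
                   contig = read_set$reads$contig,
                   start = read_set$reads$start - 1L,
                   strand = read_set$reads$strand,
                   sequence = seqs, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a read set as coordinate-sorted SAM
#'
#' Flag 16 marks minus-strand reads; SEQ is stored on the reference strand
#' per the SAM convention; CIGAR is a full-length match.
#'
#' @inheritParams write_reads_tsv
#' @export
write_reads_sam <- function(read_set, reference, path) {
  seqs <- read_sequences(read_set, reference)
  reads <- read_set$reads
  ord <- order(reads$contig, reads$start, reads$read_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ctg in names(reference$sequences)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg,
                       nchar(reference$sequences[[ctg]])), con)
  }
  if (length(ord)) {
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     reads$read_id[ord],
                     ifelse(reads$strand[ord] == "-", 16L, 0L),
                     reads$contig[ord], reads$start[ord],
                     read_set$length, seqs[ord])
    writeLines(lines, con)
  }
  invisible(path)
}

# Build a read_set from (read_id, contig, start, strand, sequence) records by
# diffing each sequence against its counting window.
reads_from_records <- function(df, reference, sample_id = "sample") {
  genes <- reference$genes
  key <- paste(genes$contig, genes$win_start)
  gi <- match(paste(df$contig, df$start), key)
  if (anyNA(gi)) {
    bad <- df$read_id[which(is.na(gi))[1]]
    stopf("read %s does not lie on any counting window", bad)
  }
  L <- reference$config$window_length
  reads <- data.frame(read_id = df$read_id, gene_id = genes$gene_id[gi],
                      contig = df$contig, start = df$start,
                      strand = genes$strand[gi], stringsAsFactors = FALSE)
  # vectorized per-gene byte comparison of reads vs window sequence
  ev_read <- integer(0); ev_pos <- integer(0); ev_alt <- character(0)
  for (g in unique(gi)) {
    rows <- which(gi == g)
    refraw <- charToRaw(strrep(window_seq(reference, g), length(rows)))
    rdraw <- charToRaw(paste(df$sequence[rows], collapse = ""))
    if (length(rdraw) != length(refraw)) {
      stopf("read length mismatch in window %s", genes$gene_id[g])
    }
    d <- which(rdraw != refraw)
    if (length(d)) {
      local_read <- (d - 1L) %/% L + 1L
      off <- (d - 1L) %% L + 1L
      ev_read <- c(ev_read, rows[local_read])
      ev_pos <- c(ev_pos, genes$win_start[g] - 1L + off)
      ev_alt <- c(ev_alt, strsplit(rawToChar(rdraw[d]), "")[[1]])
    }
  }
  events <- data.frame(read = ev_read, pos = ev_pos, alt = ev_alt,
                       stringsAsFactors = FALSE)
  events <- events[order(events$read, events$pos), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(sample_id = sample_id, reads = reads, events = events,
                 length = L, n_labeled = NULL, n_total = NULL),
            class = "read_set")
}

#' Read a TSV read-dialect file back into a read set
#'
#' @param path TSV file written by [write_reads_tsv()].
#' @param reference the matching reference.
#' @param sample_id sample label to attach.
#' @return a `read_set`.
#' @export
read_reads_tsv <- function(path, reference, sample_id = NULL) {
  df <- read_tsv(path)
  df$start <- df$start + 1L
  reads_from_records(df, reference,
                     sample_id %||% sub("\\.tsv$", "", basename(path)))
}

#' Read a SAM file back into a read set
#'
#' Uses Rsamtools (SAM is converted to a temporary BAM for parsing).
#'
#' @param path SAM file written by [write_reads_sam()].
#' @inheritParams read_reads_tsv
#' @return a `read_set`.
#' @export
read_reads_sam <- function(path, reference, sample_id = NULL) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "seq")))[[1]]
  df <- data.frame(read_id = res$qname,
                   contig = as.character(res$rname),
                   start = res$pos,
                   sequence = as.character(res$seq),
                   stringsAsFactors = FALSE)
  reads_from_records(df, reference,
                     sample_id %||% sub("\\.sam$", "", basename(path)))
}

#' Write all samples of a simulated experiment to disk
#'
#' Emits, per sample, both the SAM and the TSV dialect, plus the sample
#' sheet and per-sample read-count log.
#'
#' @param read_sets result of [simulate_reads()].
#' @param reference the matching reference.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_reads <- function(read_sets, reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- attr(read_sets, "sample_sheet")
  for (sid in names(read_sets)) {
    write_reads_tsv(read_sets[[sid]], reference,
                    file.path(dir, paste0(sid, ".reads.tsv")))
    write_reads_sam(read_sets[[sid]], reference,
                    file.path(dir, paste0(sid, ".sam")))
  }
  write_tsv(sheet, file.path(dir, "samples.tsv"))
  log <- data.frame(sample_id = names(read_sets),
                    n_reads = vapply(read_sets, function(s) nrow(s$reads),
                                     integer(1)))
  write_tsv(log, file.path(dir, "read_counts.tsv"))
  invisible(dir)
}
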