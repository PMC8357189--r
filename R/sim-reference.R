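#' Build a synthetic reference genome with counting windows
#'
#' Lays genes out on chromosome-like contigs with wide spacing (so every
#' occupancy peak is unambiguously nearest its own gene's TSS), draws uniform
#' random base composition, and records each gene's counting window — the
#' 3'-most `window_length` bases of the gene span, emulating 3'-UTR-anchored
#' quantification — together with its strand-aware convertible-T content.
#'
#' Internally all coordinates are 1-based closed (the R/Bioconductor
#' convention); BED output converts to 0-based half-open on write.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `slam_reference`: list with `sequences`
#'   (named character vector of contig sequences), `genes` (data.frame with
#'   gene_id, contig, start, end, strand, tss, win_start, win_end, t_count),
#'   and the config.
#' @export
build_reference <- function(config) {
  validate_config(config)
  n <- config$n_genes
  per <- config$genes_per_contig
  n_contig <- ceiling(n / per)
  contig_ids <- sprintf("ctg%02d", seq_len(n_contig))

  gene_idx <- seq_len(n) - 1L
  contig_of <- gene_idx %/% per + 1L
  slot_of <- gene_idx %% per

  # leading flank leaves room for promoter/flank peaks of the first gene
  flank <- 3000L
  start <- flank + slot_of * config$gene_spacing + 1L
  end <- start + config$gene_span - 1L

  # contig length: gene block + a gene-free tail where decoy peaks can sit
  # farther than any assignment distance from every TSS
  n_on <- tabulate(contig_of, nbins = n_contig)
  contig_len <- flank + n_on * config$gene_spacing + 60000L

  with_stream(config$seed, "reference", {
    sequences <- vapply(seq_len(n_contig), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_len[i], replace = TRUE),
            collapse = "")
    }, character(1))
    names(sequences) <- contig_ids
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })

  tss <- ifelse(strand == "+", start, end)
  win_start <- ifelse(strand == "+", end - config$window_length + 1L, start)
  win_end <- win_start + config$window_length - 1L

  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    contig = contig_ids[contig_of],
    start = as.integer(start), end = as.integer(end),
    strand = strand, tss = as.integer(tss),
    win_start = as.integer(win_start), win_end = as.integer(win_end),
    stringsAsFactors = FALSE
  )
  genes$t_count <- t_content(sequences, genes)

  structure(list(sequences = sequences, genes = genes, config = config),
            class = "slam_reference")
}

# Convertible-T count per counting window: reference T for plus-strand genes,
# reference A (a T on the transcribed strand) for minus-strand genes.
t_content <- function(sequences, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    s <- substr(sequences[[genes$contig[i]]], genes$win_start[i],
                genes$win_end[i])
    base <- if (genes$strand[i] == "+") "T" else "A"
    sum(charToRaw(s) == charToRaw(base))
  }, integer(1))
}

# Window sequence (reference strand) for gene row i.
window_seq <- function(reference, i) {
  g <- reference$genes[i, ]
  substr(reference$sequences[[g$contig]], g$win_start, g$win_end)
}

# Genomic positions (1-based) of convertible T positions in window i.
convertible_positions <- function(reference, i) {
  g <- reference$genes[i, ]
  s <- window_seq(reference, i)
  base <- if (g$strand == "+") "T" else "A"
  g$win_start - 1L + which(charToRaw(s) == charToRaw(base))
}

#' @export
print.slam_reference <- function(x, ...) {
  cat(sprintf("slam_reference: %d contigs, %d genes, windows %d bp\n",
              length(x$sequences), nrow(x$genes), x$config$window_length))
  invisible(x)
}

#' Write reference FASTA and window/gene BED files
#'
#' @param reference a `slam_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (fasta, windows_bed, genes_bed).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(dna, fa, width = 80L)

  g <- reference$genes
  wbed <- file.path(dir, "windows.bed")
  write_bed(data.frame(contig = g$contig, start = g$win_start,
                       end = g$win_end, name = g$gene_id, score = 0L,
                       strand = g$strand),
            wbed, seqlengths = nchar(reference$sequences))
  gbed <- file.path(dir, "genes.bed")
  write_bed(data.frame(contig = g$contig, start = g$start, end = g$end,
                       name = g$gene_id, score = 0L, strand = g$strand),
            gbed, seqlengths = nchar(reference$sequences))
  invisible(c(fasta = fa, windows_bed = wbed, genes_bed = gbed))
}
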