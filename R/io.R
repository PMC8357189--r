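# File I/O for the standard formats the pipeline exchanges.
# Internal coordinates are 1-based closed; BED files are 0-based half-open
# (rtracklayer does the conversion), SAM is 1-based, truth/read TSV files
# are 0-based half-open.

# df: contig, start, end (1-based closed), name, score, strand
write_bed <- function(df, path, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  gr$name <- df$name
  gr$score <- if ("score" %in% names(df)) df$score else 0L
  if (!is.null(seqlengths)) {
    GenomeInfoDb_ok <- try({
      GenomicRanges::seqlengths(gr) <-
        seqlengths[GenomicRanges::seqlevels(gr)]
    }, silent = TRUE)
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Returns contig, start, end (1-based closed), name, score, strand
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else 0L,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  s <- as.character(dna)
  # FASTA headers may carry descriptions; keep the first token
  names(s) <- sub("\\s.*$", "", names(dna))
  s
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  showProgress = FALSE))
}
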