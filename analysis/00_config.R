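# Shared study configuration for the analysis workflow.
# Each numbered script sources this file, then reads its inputs from and
# writes its outputs under results/.

library(slamwave)

OUT <- "results"

study_config <- function(seed = 20260926 %% 100000) {
  sim_config(
    n_genes = 200,           # genes, one 3'-anchored counting window each
    window_length = 250,     # bases per counting window
    mean_depth = 150,        # reads per window per sample
    snp_fraction = 0.1,      # windows carrying a planted T>C variant
    class_mix = c(IE_transient = 0.10, IE_sustained = 0.10, delayed = 0.15,
                  secondary = 0.15, unresponsive = 0.50),
    effect_size_log2 = 1.0,
    decoy_peaks = 20,        # intergenic decoys far from every gene
    seed = seed
  )
}

read_table <- function(path) utils::read.delim(path, check.names = FALSE)

write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

dir_of <- function(...) {
  d <- file.path(OUT, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
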