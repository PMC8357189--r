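#' Configuration for a synthetic labeling time-course study
#'
#' Bundles every knob of the synthetic-data generator: genome geometry,
#' sampling design, conversion chemistry, planted gene classes and occupancy.
#' Defaults mirror the study design the package emulates: six time points
#' (0, 0.5, 1, 2, 4, 8 h) after inducible TF activation, two replicates per
#' time point in each of two arms (TF-induced and control), a 15-min
#' 4-thiouridine pulse giving ~2.5% T>C incorporation per T position in
#' labeled reads over ~0.1% background substitution noise, and occupancy
#' peaks placed in the promoter for 61.2% of direct targets.
#'
#' @param n_genes number of genes (one counting window each).
#' @param window_length counting-window length in bases (>= 50 so the
#'   two-conversion labeled-read rule has enough convertible positions).
#' @param time_points_h sampled time points in hours; strictly increasing and
#'   including 0.
#' @param n_replicates replicates per time point per arm.
#' @param p_conv probability of T>C conversion per convertible T position in
#'   a labeled read.
#' @param p_err background substitution probability per position in any read
#'   (uniform over the three alternative bases).
#' @param snp_fraction fraction of windows carrying one planted
#'   homozygous-like variant (always T>C at a convertible position, the case
#'   the variant filter must catch).
#' @param mean_depth expected reads per window per sample at baseline.
#' @param class_mix named proportions over gene classes
#'   (IE_transient, IE_sustained, delayed, secondary, unresponsive);
#'   must sum to 1.
#' @param effect_size_log2 induced log2 change in labeled-transcript
#'   abundance for responsive genes.
#' @param base_label_frac baseline fraction of reads drawn from labeled
#'   (nascent) RNA; chosen so aggregate incorporation falls in the
#'   empirically observed 1.5--3.5% window.
#' @param promoter_peak_fraction fraction of direct-target occupancy peaks
#'   placed inside the promoter window.
#' @param delayed_onset_h candidate first-change times for delayed and
#'   secondary genes (all >= 2 h).
#' @param delayed_onset_w sampling weights over `delayed_onset_h`.
#' @param gene_span gene length in bases (TSS to 3' end).
#' @param gene_spacing distance between consecutive gene starts on a contig.
#' @param genes_per_contig genes placed per chromosome-like contig.
#' @param peak_width occupancy peak width in bases.
#' @param decoy_peaks number of intergenic decoy peaks placed far from all
#'   genes.
#' @param promoter_up,promoter_down promoter window extent around the TSS in
#'   bases (used when placing promoter peaks).
#' @param expr_sd_log2 gene-to-gene log2 SD of baseline expression depth.
#' @param seed master seed; all generator streams derive from it.
#'
#' @return an object of class `slam_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200,
                       window_length = 250,
                       time_points_h = c(0, 0.5, 1, 2, 4, 8),
                       n_replicates = 2,
                       p_conv = 0.025,
                       p_err = 0.001,
                       snp_fraction = 0.1,
                       mean_depth = 100,
                       class_mix = c(IE_transient = 0.10, IE_sustained = 0.10,
                                     delayed = 0.15, secondary = 0.15,
                                     unresponsive = 0.50),
                       effect_size_log2 = 1.0,
                       base_label_frac = 0.8,
                       promoter_peak_fraction = 0.612,
                       delayed_onset_h = c(2, 4, 8),
                       delayed_onset_w = c(0.5, 0.3, 0.2),
                       gene_span = 2000,
                       gene_spacing = 12000,
                       genes_per_contig = 50,
                       peak_width = 200,
                       decoy_peaks = 0,
                       promoter_up = 2000,
                       promoter_down = 500,
                       expr_sd_log2 = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), window_length = as.integer(window_length),
    time_points_h = as.numeric(time_points_h),
    n_replicates = as.integer(n_replicates),
    p_conv = p_conv, p_err = p_err, snp_fraction = snp_fraction,
    mean_depth = mean_depth, class_mix = class_mix,
    effect_size_log2 = effect_size_log2, base_label_frac = base_label_frac,
    promoter_peak_fraction = promoter_peak_fraction,
    delayed_onset_h = as.numeric(delayed_onset_h),
    delayed_onset_w = as.numeric(delayed_onset_w),
    gene_span = as.integer(gene_span), gene_spacing = as.integer(gene_spacing),
    genes_per_contig = as.integer(genes_per_contig),
    peak_width = as.integer(peak_width), decoy_peaks = as.integer(decoy_peaks),
    promoter_up = as.integer(promoter_up),
    promoter_down = as.integer(promoter_down),
    expr_sd_log2 = expr_sd_log2,
    seed = as.integer(seed)
  )
  class(cfg) <- "slam_config"
  validate_config(cfg)
  cfg
}

gene_classes <- c("IE_transient", "IE_sustained", "delayed", "secondary",
                  "unresponsive")

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "slam_config"))
  if (cfg$n_genes < 1) stopf("n_genes must be >= 1")
  if (cfg$window_length < 50) {
    stopf(paste("window_length %d < 50: too few convertible positions for",
                "the >=2-conversion labeled-read rule to be meaningful"),
          cfg$window_length)
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) {
    stopf("class_mix must sum to 1 (got %.12f)", sum(cfg$class_mix))
  }
  if (!all(names(cfg$class_mix) %in% gene_classes) ||
      is.null(names(cfg$class_mix))) {
    stopf("class_mix names must be among: %s",
          paste(gene_classes, collapse = ", "))
  }
  if (any(cfg$class_mix < 0)) stopf("class_mix proportions must be >= 0")
  # p_conv = p_err = 0 is allowed as the degenerate no-chemistry control
  ok_chem <- cfg$p_err >= 0 && cfg$p_conv <= 1 &&
    (cfg$p_err < cfg$p_conv || (cfg$p_err == 0 && cfg$p_conv == 0))
  if (!ok_chem) {
    stopf("require 0 <= p_err < p_conv <= 1 (got p_err=%g, p_conv=%g)",
          cfg$p_err, cfg$p_conv)
  }
  tp <- cfg$time_points_h
  if (!(all(diff(tp) > 0) && 0 %in% tp)) {
    stopf("time_points_h must be strictly increasing and include 0")
  }
  if (any(cfg$delayed_onset_h < 2)) {
    stopf("delayed_onset_h must all be >= 2 h")
  }
  if (length(cfg$delayed_onset_w) != length(cfg$delayed_onset_h)) {
    stopf("delayed_onset_w must match delayed_onset_h in length")
  }
  if (cfg$base_label_frac <= 0 || cfg$base_label_frac > 1) {
    stopf("base_label_frac must be in (0, 1]")
  }
  if (cfg$gene_span < cfg$window_length) {
    stopf("gene_span must be >= window_length")
  }
  invisible(cfg)
}

#' @export
print.slam_config <- function(x, ...) {
  cat(sprintf(
    "slam_config: %d genes, windows %d bp, %d time points x %d reps x 2 arms\n",
    x$n_genes, x$window_length, length(x$time_points_h), x$n_replicates))
  cat(sprintf("  p_conv=%g p_err=%g depth=%g label_frac=%g effect=%g log2\n",
              x$p_conv, x$p_err, x$mean_depth, x$base_label_frac,
              x$effect_size_log2))
  cat(sprintf("  class mix: %s\n",
              paste(sprintf("%s=%.2f", names(x$class_mix), x$class_mix),
                    collapse = " ")))
  invisible(x)
}
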