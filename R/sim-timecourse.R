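#' Plant gene classes and kinetic profiles of labeled-transcript abundance
#'
#' Assigns every gene one of five classes and a direction, derives the
#' step-function kinetic profile of its labeled (nascent) transcript level
#' across the time grid, plants homozygous-like T>C variants in a fraction
#' of windows, and fixes occupancy status by class: immediate-early and
#' delayed genes are TF-bound, secondary and unresponsive genes are not.
#'
#' Kinetics on the sampled grid (log2 change vs 0 h, `e` = effect size):
#' immediate-early transient: e at 0.5 and 1 h, back to 0 from 2 h on;
#' immediate-early sustained: e from 0.5 h on; delayed and secondary: e from
#' a randomly drawn onset >= 2 h on; unresponsive: flat. The control arm is
#' flat at the 0 h level for every gene.
#'
#' @param reference a [build_reference()] result.
#' @param config optional override config (defaults to the reference's).
#' @return an object of class `slam_truth`: `genes` (with true_class,
#'   direction, bound, onset_h, expr_mult), `labeled_abundance` (gene x time
#'   x arm array of expected labeled levels relative to total), `snps`
#'   (contig, pos, ref, alt, gene_id), `time_points_h`, `arms`.
#' @export
simulate_timecourse <- function(reference, config = reference$config) {
  validate_config(config)
  genes <- reference$genes
  n <- nrow(genes)
  tp <- config$time_points_h
  e <- config$effect_size_log2

  # exact class composition (largest-remainder rounding), shuffled over genes
  mix <- config$class_mix[gene_classes[gene_classes %in% names(config$class_mix)]]
  mix <- mix[!is.na(mix)]
  n_per <- floor(mix * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    frac <- mix * n - n_per
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_per[add] <- n_per[add] + 1L
  }
  classes <- rep(names(n_per), n_per)

  with_stream(config$seed, "timecourse", {
    classes <- sample(classes)
    direction <- sample(c("up", "down"), n, replace = TRUE)
    onset <- rep(NA_real_, n)
    late <- classes %in% c("delayed", "secondary")
    onset[late] <- sample(config$delayed_onset_h, sum(late), replace = TRUE,
                          prob = config$delayed_onset_w)
    expr_mult <- 2^stats::rnorm(n, 0, config$expr_sd_log2)

    # planted variants: one per selected window, at a convertible position,
    # altered to the conversion base (indistinguishable from labeling)
    n_snp <- round(config$snp_fraction * n)
    snp_genes <- sort(sample.int(n, n_snp))
    snps <- if (n_snp > 0) {
      pos <- vapply(snp_genes, function(i) {
        cand <- convertible_positions(reference, i)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      data.frame(
        contig = genes$contig[snp_genes],
        pos = pos,
        ref = ifelse(genes$strand[snp_genes] == "+", "T", "A"),
        alt = ifelse(genes$strand[snp_genes] == "+", "C", "G"),
        gene_id = genes$gene_id[snp_genes],
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), gene_id = character())
    }
  })

  direction[classes == "unresponsive"] <- NA_character_
  bound <- classes %in% c("IE_transient", "IE_sustained", "delayed")

  # log2 deviation from baseline per gene x time (induced arm)
  delta <- matrix(0, n, length(tp), dimnames = list(genes$gene_id, tp))
  sgn <- ifelse(direction == "up", 1, -1)
  for (j in seq_along(tp)) {
    t <- tp[j]
    on <- (classes %in% c("IE_transient") & t >= 0.5 & t < 2) |
      (classes %in% c("IE_sustained") & t >= 0.5) |
      (late & !is.na(onset) & t >= onset)
    delta[on, j] <- e * sgn[on]
  }

  l0 <- config$base_label_frac
  ab <- array(l0, dim = c(n, length(tp), 2),
              dimnames = list(genes$gene_id, tp, c("tf", "ctrl")))
  ab[, , "tf"] <- l0 * 2^delta

  genes$true_class <- classes
  genes$direction <- direction
  genes$bound <- bound
  genes$onset_h <- onset
  genes$expr_mult <- expr_mult

  structure(list(genes = genes, labeled_abundance = ab, snps = snps,
                 time_points_h = tp, arms = c("tf", "ctrl"),
                 config = config),
            class = "slam_truth")
}

#' @export
print.slam_truth <- function(x, ...) {
  cat(sprintf("slam_truth: %d genes, %d planted variants\n",
              nrow(x$genes), nrow(x$snps)))
  print(table(x$genes$true_class))
  invisible(x)
}

#' Sample sheet for a configured study
#'
#' @param config a [sim_config()] object.
#' @return data.frame with sample_id, arm, time_h, replicate; one row per
#'   arm x time point x replicate.
#' @export
sample_sheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      time_h = config$time_points_h,
                      arm = c("tf", "ctrl"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("arm", "time_h", "replicate")]
  grid$sample_id <- sprintf("%s_t%g_r%d", grid$arm, grid$time_h,
                            grid$replicate)
  grid[, c("sample_id", "arm", "time_h", "replicate")]
}

#' Write ground truth as plain-text TSV files
#'
#' Coordinates in the files are 0-based half-open (variant positions are
#' 0-based); [read_truth()] restores the in-memory 1-based representation.
#'
#' @param truth a `slam_truth`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- truth$genes
  gf <- file.path(dir, "truth_genes.tsv")
  out <- g
  out$start <- out$start - 1L       # to 0-based half-open
  out$win_start <- out$win_start - 1L
  write_tsv(out, gf)

  sf <- file.path(dir, "truth_snps.tsv")
  snp <- truth$snps
  snp$pos <- snp$pos - 1L
  write_tsv(snp, sf)

  af <- file.path(dir, "truth_abundance.tsv")
  ab <- truth$labeled_abundance
  long <- expand.grid(gene_id = dimnames(ab)[[1]],
                      time_h = as.numeric(dimnames(ab)[[2]]),
                      arm = dimnames(ab)[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$labeled_abundance <- as.vector(ab)
  write_tsv(long, af)
  invisible(c(genes = gf, snps = sf, abundance = af))
}

#' Read ground truth written by [write_truth()]
#'
#' @param dir directory holding the truth TSV files.
#' @return a `slam_truth` (without the config element).
#' @export
read_truth <- function(dir) {
  g <- read_tsv(file.path(dir, "truth_genes.tsv"))
  g$start <- g$start + 1L
  g$win_start <- g$win_start + 1L
  for (col in c("direction")) g[[col]][g[[col]] == ""] <- NA_character_
  snp <- read_tsv(file.path(dir, "truth_snps.tsv"))
  if (nrow(snp)) snp$pos <- snp$pos + 1L
  long <- read_tsv(file.path(dir, "truth_abundance.tsv"))
  tp <- sort(unique(long$time_h))
  arms <- unique(long$arm)
  ab <- array(NA_real_, dim = c(nrow(g), length(tp), length(arms)),
              dimnames = list(g$gene_id, tp, arms))
  idx <- cbind(match(long$gene_id, g$gene_id), match(long$time_h, tp),
               match(long$arm, arms))
  ab[idx] <- long$labeled_abundance
  structure(list(genes = g, labeled_abundance = ab, snps = snp,
                 time_points_h = tp, arms = arms, config = NULL),
            class = "slam_truth")
}
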