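#' Simulate the labeled count matrix directly (count-level shortcut)
#'
#' Draws per-gene, per-sample labeled and total read counts from the same
#' generative model as [simulate_reads()], skipping per-base read synthesis:
#' labeled reads are Poisson with mean `depth * expr_mult * l(t)`, unlabeled
#' reads Poisson with mean `depth * expr_mult * (1 - base_label_frac)`, and
#' each labeled read passes the >=2-conversion filter with the binomial tail
#' probability implied by its window's convertible-T content. Useful for
#' testing-stage simulations (calibration, power) at sizes where
#' materializing reads would be wasteful; conversion-level behavior is
#' exercised by the read-level path.
#'
#' Background-only reads essentially never reach two T>C substitutions
#' (probability ~ (L*p_err/3)^2 per read) and are counted as unlabeled.
#'
#' @param truth a [simulate_timecourse()] result.
#' @param config optional override config.
#' @return a `slam_counts` object (see [build_count_matrix()]).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  validate_config(config)
  sheet <- sample_sheet(config)
  genes <- truth$genes
  n <- nrow(genes)
  l0 <- config$base_label_frac
  # per-gene probability that a labeled read carries >= 2 conversions
  p2 <- 1 - pbinom(1, genes$t_count, config$p_conv)

  labeled <- matrix(0L, n, nrow(sheet),
                    dimnames = list(genes$gene_id, sheet$sample_id))
  total <- labeled
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    tp_idx <- match(sheet$time_h[j], truth$time_points_h)
    l <- truth$labeled_abundance[, tp_idx, sheet$arm[j]]
    with_stream(config$seed, paste0("counts/", sid), {
      mu <- config$mean_depth * genes$expr_mult
      n_lab <- rpois(n, mu * l)
      n_unl <- rpois(n, mu * (1 - l0))
      labeled[, j] <- rbinom(n, n_lab, p2)
      total[, j] <- n_lab + n_unl
    })
  }
  new_slam_counts(labeled, total, sheet)
}

new_slam_counts <- function(labeled, total, samples) {
  stopifnot(all(labeled <= total), all(labeled >= 0))
  structure(list(labeled = labeled, total = total, samples = samples,
                 lib_size = colSums(total)),
            class = "slam_counts")
}

#' @export
print.slam_counts <- function(x, ...) {
  cat(sprintf("slam_counts: %d genes x %d samples; median library %g\n",
              nrow(x$labeled), ncol(x$labeled),
              stats::median(x$lib_size)))
  invisible(x)
}

#' Subset a count matrix to selected samples
#'
#' @param counts a `slam_counts`.
#' @param sample_ids character vector of sample ids to keep (order kept).
#' @return a `slam_counts` restricted to those samples.
#' @export
subset_counts <- function(counts, sample_ids) {
  miss <- setdiff(sample_ids, counts$samples$sample_id)
  if (length(miss)) {
    stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
  }
  idx <- match(sample_ids, counts$samples$sample_id)
  new_slam_counts(counts$labeled[, idx, drop = FALSE],
                  counts$total[, idx, drop = FALSE],
                  counts$samples[idx, ])
}
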