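#' log2 counts-per-million of labeled reads
#'
#' `log2((labeled + 0.5) / (library + 1) * 1e6)` with the library size taken
#' as the column sum of total counts, so labeled fold changes are measured
#' against overall sequencing depth rather than shifting labeled mass.
#'
#' @param counts a `slam_counts`.
#' @param prior_count pseudocount added to counts (0.5; set 0 for exact
#'   scale invariance checks).
#' @return matrix of log2-CPM values, genes x samples.
#' @export
normalize_counts <- function(counts, prior_count = 0.5) {
  lib <- counts$lib_size
  if (any(lib == 0)) {
    stopf("all-zero library for sample(s): %s",
          paste(colnames(counts$labeled)[lib == 0], collapse = ", "))
  }
  off <- if (prior_count > 0) 1 else 0
  log2(t((t(counts$labeled) + prior_count) / (lib + off)) * 1e6)
}

#' Describe the linear-model design for the time course
#'
#' Group-means parameterization over arm x time-point cells.
#'
#' @param samples sample sheet (sample_id, arm, time_h, replicate).
#' @return a `design_spec`: list with `design` (model matrix, samples x
#'   groups), `groups` (per-sample group labels), `levels`.
#' @export
design_spec <- function(samples) {
  groups <- factor(paste0(samples$arm, "_t", samples$time_h),
                   levels = unique(paste0(samples$arm, "_t",
                                          samples$time_h)))
  if (any(table(groups) < 2)) {
    stopf("every arm x time group needs >= 2 replicates for variance estimation")
  }
  X <- stats::model.matrix(~ 0 + groups)
  colnames(X) <- levels(groups)
  rownames(X) <- samples$sample_id
  structure(list(design = X, groups = groups, levels = levels(groups),
                 samples = samples),
            class = "design_spec")
}

#' Fit per-gene ordinary least squares under a shared design
#'
#' @param logcpm matrix of log2-CPM values (genes x samples).
#' @param spec a [design_spec()] (or a bare model matrix).
#' @return a `gene_fit`: coefficients (genes x groups), sigma (residual SD
#'   per gene), df_residual, cov_unscaled (groups x groups unscaled
#'   covariance), design.
#' @export
fit_models <- function(logcpm, spec) {
  X <- if (inherits(spec, "design_spec")) spec$design else spec
  if (qr(X)$rank < ncol(X)) {
    stopf("design matrix is rank-deficient: columns %s are collinear",
          paste(colnames(X), collapse = ", "))
  }
  qrX <- qr(X)
  Y <- t(logcpm)                     # samples x genes
  coef <- qr.coef(qrX, Y)            # groups x genes
  res <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cov_unscaled <- chol2inv(qr.R(qrX))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  structure(list(coefficients = t(coef), sigma = sqrt(sigma2),
                 df_residual = df, cov_unscaled = cov_unscaled,
                 design = X,
                 spec = if (inherits(spec, "design_spec")) spec else NULL),
            class = "gene_fit")
}

# Newton inversion of the trigamma function (for the prior-df moment fit).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Models the gene-wise sample variances as scaled F draws around a global
#' prior variance s0^2 with prior degrees of freedom d0, estimated by the
#' method of moments on log variances: with z = log(s^2), E z = log(s0^2) +
#' digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2) and Var z =
#' trigamma(d/2) + trigamma(d0/2). Posterior variances shrink each gene
#' toward the prior: s~^2 = (d0 s0^2 + d s^2) / (d0 + d). When the residual
#' moment is non-positive the prior df are infinite and every posterior
#' variance equals the fully pooled variance mean(s^2). Genes with zero
#' sample variance are excluded from
#' hyperparameter estimation but still receive a posterior variance.
#'
#' @param fit a [fit_models()] result.
#' @param d0_override force prior df (0 disables shrinkage; Inf pools
#'   fully); default NULL estimates them.
#' @return a `moderated_var`: list(d0, s0_2, s2_post, df_total).
#' @export
ebayes <- function(fit, d0_override = NULL) {
  s2 <- fit$sigma^2
  d <- fit$df_residual
  if (length(s2) < 20 && is.null(d0_override)) {
    stopf("need >= 20 genes to estimate moderation hyperparameters (got %d)",
          length(s2))
  }
  pos <- s2 > 0
  if (!any(pos)) stopf("all gene variances are zero: degenerate ensemble")

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (is.finite(d0) && d0 > 0) {
      # moment-match the prior scale given fixed d0
      z <- log(s2[pos])
      exp(mean(z) - digamma(d / 2) + log(d / 2) + digamma(d0 / 2) -
            log(d0 / 2))
    } else if (d0 == 0) {
      mean(s2)   # unused: no shrinkage
    } else {
      mean(s2)   # d0 = Inf: pooled variance
    }
  } else {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- var(e)
    evar_resid <- evar - trigamma(d / 2)
    if (is.na(evar_resid) || evar_resid <= 0) {
      # no excess dispersion beyond chi-squared sampling noise: variances are
      # exchangeable; pool them fully
      d0 <- Inf
      s0_2 <- mean(s2)
    } else {
      d0 <- 2 * trigamma_inverse(evar_resid)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  names(s2_post) <- names(s2)
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post,
                 df_total = d0 + d),
            class = "moderated_var")
}

# Moderated statistics for one contrast vector over group coefficients.
contrast_stats <- function(fit, mod, cvec) {
  lfc <- as.numeric(fit$coefficients %*% cvec)
  se_unscaled <- sqrt(as.numeric(t(cvec) %*% fit$cov_unscaled %*% cvec))
  se <- sqrt(mod$s2_post) * se_unscaled
  t <- ifelse(se > 0, lfc / se, 0)
  df <- mod$df_total
  p <- 2 * pt(-abs(t), df = if (is.finite(df)) df else 1e6)
  data.frame(gene_id = rownames(fit$coefficients), log2FC = lfc, t = t,
             p = p, stringsAsFactors = FALSE)
}

#' Moderated contrasts across the time course
#'
#' Emits, per arm, both contrast families the analysis uses: consecutive
#' time points (0.5 vs 0, 1 vs 0.5, ...) and every time point against 0 h.
#' Significance requires BH q below `fdr` AND |log2FC| above `lfc`; BH is
#' applied within each contrast.
#'
#' @param counts a `slam_counts`.
#' @param fdr BH q-value threshold.
#' @param lfc absolute log2 fold-change threshold.
#' @param d0_override passed to [ebayes()].
#' @return a `timecourse_stats`: list with `table` (long data.frame: family,
#'   arm, contrast, time_h, gene_id, log2FC, t, p, q, significant),
#'   `hyper` (d0, s0_2), `fit`, `mod`.
#' @export
run_contrasts <- function(counts, fdr = 0.05, lfc = 0.5,
                          d0_override = NULL) {
  spec <- design_spec(counts$samples)
  logcpm <- normalize_counts(counts)
  fit <- fit_models(logcpm, spec)
  mod <- ebayes(fit, d0_override)

  arms <- unique(counts$samples$arm)
  out <- list()
  for (arm in arms) {
    tps <- sort(unique(counts$samples$time_h[counts$samples$arm == arm]))
    lev <- paste0(arm, "_t", tps)
    # vs-0h family
    for (j in seq_along(tps)[-1]) {
      cvec <- stats::setNames(numeric(length(spec$levels)), spec$levels)
      cvec[lev[j]] <- 1; cvec[lev[1]] <- -1
      st <- contrast_stats(fit, mod, cvec)
      st$family <- "vs0"; st$arm <- arm; st$time_h <- tps[j]
      st$contrast <- sprintf("%s: %gh vs 0h", arm, tps[j])
      out[[length(out) + 1L]] <- st
    }
    # consecutive family
    for (j in seq_along(tps)[-1]) {
      cvec <- stats::setNames(numeric(length(spec$levels)), spec$levels)
      cvec[lev[j]] <- 1; cvec[lev[j - 1]] <- -1
      st <- contrast_stats(fit, mod, cvec)
      st$family <- "consecutive"; st$arm <- arm; st$time_h <- tps[j]
      st$contrast <- sprintf("%s: %gh vs %gh", arm, tps[j], tps[j - 1])
      out[[length(out) + 1L]] <- st
    }
  }
  tab <- do.call(rbind, out)
  tab$q <- NA_real_
  for (ct in unique(tab$contrast)) {
    sel <- tab$contrast == ct
    tab$q[sel] <- p.adjust(tab$p[sel], method = "BH")
  }
  tab$significant <- tab$q < fdr & abs(tab$log2FC) > lfc
  tab <- tab[, c("family", "arm", "contrast", "time_h", "gene_id",
                 "log2FC", "t", "p", "q", "significant")]
  rownames(tab) <- NULL
  structure(list(table = tab, hyper = list(d0 = mod$d0, s0_2 = mod$s0_2),
                 fit = fit, mod = mod, fdr = fdr, lfc = lfc),
            class = "timecourse_stats")
}

#' @export
print.timecourse_stats <- function(x, ...) {
  cat(sprintf("timecourse_stats: %d contrasts, d0=%.2f s0^2=%.4g\n",
              length(unique(x$table$contrast)), x$hyper$d0, x$hyper$s0_2))
  sig <- tapply(x$table$significant, x$table$contrast, sum)
  for (ct in names(sig)) cat(sprintf("  %-22s %4d significant\n", ct, sig[ct]))
  invisible(x)
}

#' Write per-contrast tables and the hyperparameter report
#'
#' @param stats a `timecourse_stats`.
#' @param dir output directory.
#' @export
write_contrasts <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(stats$table, file.path(dir, "contrasts.tsv"))
  jsonlite::write_json(
    list(d0 = if (is.finite(stats$hyper$d0)) stats$hyper$d0 else "Inf",
         s0_2 = stats$hyper$s0_2,
         fdr = stats$fdr, lfc = stats$lfc),
    file.path(dir, "hyperparameters.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
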