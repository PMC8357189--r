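toy_counts <- function(labeled, total, arm, time_h, replicate) {
  samples <- data.frame(
    sample_id = sprintf("%s_t%g_r%d", arm, time_h, replicate),
    arm = arm, time_h = time_h, replicate = replicate,
    stringsAsFactors = FALSE)
  colnames(labeled) <- samples$sample_id
  colnames(total) <- samples$sample_id
  slamwave:::new_slam_counts(labeled, total, samples)
}

test_that("log2-CPM normalization matches its closed form", {
  lab <- matrix(c(0L, 10L, 100L,
                  5L, 20L, 50L), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), NULL))
  tot <- matrix(c(999890L, 10L, 100L,
                  99925L, 20L, 55L), nrow = 3)
  cnt <- toy_counts(lab, tot, arm = "tf", time_h = c(0, 0),
                    replicate = c(1, 2))
  lc <- normalize_counts(cnt)
  # hand-computed: log2((count + 0.5) / (lib + 1) * 1e6)
  lib <- colSums(tot)
  expect_equal(lc[1, 1], log2(0.5 / (lib[1] + 1) * 1e6))
  expect_equal(lc[3, 2], log2(50.5 / (lib[2] + 1) * 1e6))
  expect_equal(unname(lc), log2(t(t(lab + 0.5) / (lib + 1)) * 1e6),
               ignore_attr = TRUE)

  # exact scale invariance with pseudocounts zeroed
  lab1 <- lab + 1L   # keep counts positive: zeros are -Inf without pseudocount
  tot1 <- tot + 1L
  cnt2 <- toy_counts(2L * lab1, 2L * tot1, arm = "tf", time_h = c(0, 0),
                     replicate = c(1, 2))
  diff <- normalize_counts(cnt2, prior_count = 0) -
    normalize_counts(toy_counts(lab1, tot1, "tf", c(0, 0), 1:2),
                     prior_count = 0)
  expect_equal(unname(diff), matrix(0, 3, 2), tolerance = 1e-12)

  # all-zero library is an error naming the sample
  bad <- toy_counts(matrix(0L, 2, 2), matrix(0L, 2, 2), "tf", c(0, 0), 1:2)
  expect_error(normalize_counts(bad), "tf_t0_r1")
})

test_that("group-means OLS reproduces group means and the normal equations", {
  set.seed(1)
  samples <- data.frame(sample_id = paste0("s", 1:4), arm = "tf",
                        time_h = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2))
  y <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), samples$sample_id))
  spec <- design_spec(samples)
  fit <- fit_models(y, spec)

  # coefficients are group means; residual df = n - p
  expect_equal(unname(fit$coefficients[, "tf_t0"]),
               unname(rowMeans(y[, 1:2])))
  expect_equal(unname(fit$coefficients[, "tf_t1"]),
               unname(rowMeans(y[, 3:4])))
  expect_equal(fit$df_residual, 2)

  # residuals orthogonal to the design columns
  res <- t(y) - spec$design %*% t(fit$coefficients)
  expect_lt(max(abs(t(spec$design) %*% res)), 1e-10)

  # brute-force normal-equations solve, gene by gene
  X <- spec$design
  XtXinv <- solve(t(X) %*% X)
  for (i in sample(1:50, 10)) {
    beta <- XtXinv %*% t(X) %*% y[i, ]
    expect_equal(unname(fit$coefficients[i, ]), unname(drop(beta)),
                 tolerance = 1e-10)
  }
  expect_equal(unname(fit$cov_unscaled), unname(XtXinv), tolerance = 1e-12)

  # rank-deficient design is refused
  X2 <- cbind(X, X[, 1])
  colnames(X2)[3] <- "dup"
  expect_error(fit_models(y, X2), "collinear")
})

test_that("variance moderation obeys its limits and bracketing", {
  set.seed(2)
  samples <- data.frame(sample_id = paste0("s", 1:4), arm = "tf",
                        time_h = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2))
  y <- matrix(rnorm(200 * 4, sd = rep(sqrt(rchisq(200, 5) / 5), 4)), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), samples$sample_id))
  fit <- fit_models(y, design_spec(samples))
  mod <- ebayes(fit)

  # shrinkage bracketing: posterior between gene and prior variance
  s2 <- fit$sigma^2
  expect_true(all(mod$s2_post >= pmin(s2, mod$s0_2) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(s2, mod$s0_2) + 1e-12))

  # d0 = 0 imposed: moderated t equals ordinary t exactly
  mod0 <- ebayes(fit, d0_override = 0)
  expect_equal(mod0$s2_post, stats::setNames(s2, names(mod0$s2_post)))

  # identical variances: estimated d0 diverges, posterior equals the common value
  y2 <- y
  y2[] <- rep(rowMeans(y), 4)
  y2 <- y2 + rep(c(-1, 1, -1, 1), each = nrow(y2)) * 0.5  # equal spread
  fit2 <- fit_models(y2, design_spec(samples))
  mod2 <- ebayes(fit2)
  expect_true(is.infinite(mod2$d0))
  expect_equal(unname(mod2$s2_post),
               unname(rep(fit2$sigma[1]^2, nrow(y2))))

  # degenerate ensemble: all zero variances
  y3 <- y2 * 0
  fit3 <- fit_models(y3, design_spec(samples))
  expect_error(ebayes(fit3), "degenerate")
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(3)
  samples <- data.frame(sample_id = paste0("s", 1:6), arm = "tf",
                        time_h = rep(c(0, 1, 2), each = 2),
                        replicate = rep(1:2, 3))
  y <- matrix(rnorm(300 * 6, sd = rep(sqrt(rchisq(300, 4) / 4), 6)), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), samples$sample_id))
  spec <- design_spec(samples)
  fit <- fit_models(y, spec)
  mod <- ebayes(fit)

  lfit <- limma::lmFit(y, spec$design)
  lfit <- limma::contrasts.fit(
    lfit, stats::setNames(c(-1, 1, 0), colnames(spec$design)))
  leb <- limma::eBayes(lfit)

  expect_equal(mod$d0, leb$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, leb$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$s2_post), unname(leb$s2.post), tolerance = 1e-8)

  cvec <- stats::setNames(c(-1, 1, 0), colnames(spec$design))
  st <- slamwave:::contrast_stats(fit, mod, cvec)
  expect_equal(st$t, unname(leb$t[, 1]), tolerance = 1e-8)
  expect_equal(st$p, unname(leb$p.value[, 1]), tolerance = 1e-8)
})

test_that("contrast tables apply BH within contrast and flag by q and lfc", {
  # BH hand check through the pipeline: 4 genes, one contrast
  set.seed(4)
  # construct data whose per-gene p-values we then BH-adjust by hand
  samples <- data.frame(sample_id = paste0("s", 1:4), arm = "tf",
                        time_h = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2))
  lab <- matrix(rpois(16, 400), 4, 4,
                dimnames = list(paste0("g", 1:4), samples$sample_id))
  cnt <- toy_counts(lab, lab + 100L, "tf", c(0, 0, 1, 1), c(1, 2, 1, 2))
  st <- run_contrasts(cnt, d0_override = 0)   # 4 genes: no ensemble to fit
  tab <- st$table[st$table$family == "vs0", ]
  expect_equal(tab$q, p.adjust(tab$p, method = "BH"))

  # the documented BH step-up example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))

  # a gene with identical values in both groups: log2FC exactly 0, never
  # significant (columns balanced so library sizes are equal)
  lab2 <- rbind(g1 = c(100L, 100L, 100L, 100L),
                g2 = c(210L, 190L, 220L, 180L),
                g3 = c(190L, 210L, 180L, 220L))
  stopifnot(length(unique(colSums(lab2))) == 1)
  cnt2 <- toy_counts(lab2, lab2 + 50L, "tf", c(0, 0, 1, 1), c(1, 2, 1, 2))
  st2 <- run_contrasts(cnt2, d0_override = 0)
  g1row <- st2$table[st2$table$gene_id == "g1" & st2$table$family == "vs0", ]
  expect_equal(g1row$log2FC, 0)
  expect_false(g1row$significant)
})

test_that("a planted 1-log2 effect is recovered within 0.2 on average", {
  cfg <- sim_config(n_genes = 300, window_length = 250, mean_depth = 200,
                    seed = 17,
                    class_mix = c(IE_sustained = 0.3, unresponsive = 0.7))
  ref <- build_reference(cfg)
  truth <- simulate_timecourse(ref)
  counts <- simulate_counts(truth)
  st <- run_contrasts(counts)
  tab <- st$table[st$table$family == "vs0" & st$table$arm == "tf" &
                    st$table$time_h == 4, ]
  resp <- truth$genes$gene_id[truth$genes$true_class == "IE_sustained"]
  est <- abs(tab$log2FC[match(resp, tab$gene_id)])
  expect_lt(abs(mean(est) - 1), 0.2)
})

test_that("null p-values are calibrated and power grows with depth", {
  frac_p05 <- function(depth, n_genes = 400, seed = 5, effect = 0) {
    mix <- if (effect > 0) {
      c(IE_sustained = 0.3, unresponsive = 0.7)
    } else c(unresponsive = 1)
    cfg <- sim_config(n_genes = n_genes, mean_depth = depth, seed = seed,
                      class_mix = mix, effect_size_log2 = max(effect, 1),
                      time_points_h = c(0, 1))
    ref <- build_reference(cfg)
    truth <- simulate_timecourse(ref)
    counts <- simulate_counts(truth)
    counts <- subset_counts(counts,
                            counts$samples$sample_id[counts$samples$arm == "tf"])
    st <- run_contrasts(counts)
    tab <- st$table[st$table$family == "vs0", ]
    if (effect > 0) {
      resp <- truth$genes$gene_id[truth$genes$true_class != "unresponsive"]
      mean(tab$significant[match(resp, tab$gene_id)])
    } else {
      mean(tab$p < 0.05)
    }
  }
  # approximate uniformity under the null
  expect_lt(abs(frac_p05(200) - 0.05), 0.03)
  # monotone power in depth on planted effects
  pw <- vapply(c(30, 100, 300), frac_p05, numeric(1), effect = 1)
  expect_true(all(diff(pw) >= -0.02))
  expect_gt(pw[3], pw[1])
})
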