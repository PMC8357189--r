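make_manual_reads <- function(ref, gene_idx, alt_at = list()) {
  # build a read_set by hand: one entry per read, events as (pos, alt)
  g <- ref$genes[gene_idx, ]
  n <- length(alt_at)
  if (n == 0) {
    return(structure(list(
      sample_id = "manual",
      reads = data.frame(read_id = character(), gene_id = character(),
                         contig = character(), start = integer(),
                         strand = character()),
      events = data.frame(read = integer(), pos = integer(),
                          alt = character()),
      length = ref$config$window_length, n_labeled = NULL,
      n_total = NULL), class = "read_set"))
  }
  reads <- data.frame(
    read_id = sprintf("m%03d", seq_len(n)), gene_id = g$gene_id,
    contig = g$contig, start = g$win_start, strand = g$strand,
    stringsAsFactors = FALSE)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- alt_at[[i]]
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(read = i, pos = e$pos, alt = e$alt, stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) ev <- data.frame(read = integer(), pos = integer(),
                                    alt = character())
  structure(list(sample_id = "manual", reads = reads, events = ev,
                 length = ref$config$window_length, n_labeled = NULL,
                 n_total = NULL), class = "read_set")
}

test_that("variant calling masks at the inclusive 0.2 threshold", {
  cfg <- sim_config(n_genes = 5, window_length = 100, seed = 3,
                    snp_fraction = 0)
  ref <- build_reference(cfg)
  gi <- which(ref$genes$strand == "+")[1]
  tpos <- slamwave:::convertible_positions(ref, gi)

  # 100 reads; position tpos[1] altered in all, tpos[2] in 20, tpos[3] in 19
  alt <- lapply(1:100, function(i) {
    pos <- c(tpos[1],
             if (i <= 20) tpos[2],
             if (i <= 19) tpos[3])
    data.frame(pos = pos, alt = rep("C", length(pos)))
  })
  rs <- make_manual_reads(ref, gi, alt)
  mask <- detect_variants(rs, ref)
  ctg <- ref$genes$contig[gi]
  expect_true(paste(ctg, tpos[1]) %in% paste(mask$contig, mask$pos))
  expect_true(paste(ctg, tpos[2]) %in% paste(mask$contig, mask$pos))  # 0.20
  expect_false(paste(ctg, tpos[3]) %in% paste(mask$contig, mask$pos)) # 0.19

  # empty input: empty mask with a warning
  empty <- make_manual_reads(ref, gi, list())
  expect_warning(m0 <- detect_variants(empty, ref), "empty")
  expect_equal(nrow(m0), 0)
})

test_that("planted SNPs are recovered exactly when p_err = 0 at depth >= 10", {
  cfg <- sim_config(n_genes = 40, window_length = 150, mean_depth = 40,
                    p_err = 0, snp_fraction = 0.25, seed = 9,
                    class_mix = c(unresponsive = 1))
  ref <- build_reference(cfg)
  truth <- simulate_timecourse(ref)
  reads <- simulate_reads(truth, ref,
                          samples = c("tf_t0_r1", "tf_t0_r2"))
  mask <- detect_variants(reads, ref)
  got <- sort(paste(mask$contig, mask$pos))
  want <- sort(paste(truth$snps$contig, truth$snps$pos))
  expect_identical(got, want)   # sensitivity 1, zero false positives
})

test_that("conversion counting is strand-aware and mask-aware", {
  cfg <- sim_config(n_genes = 10, window_length = 100, seed = 3,
                    snp_fraction = 0)
  ref <- build_reference(cfg)
  for (strand in c("+", "-")) {
    gi <- which(ref$genes$strand == strand)[1]
    tpos <- slamwave:::convertible_positions(ref, gi)
    conv_alt <- if (strand == "+") "C" else "G"
    rs <- make_manual_reads(ref, gi, list(
      data.frame(pos = integer(), alt = character()),       # reference read
      data.frame(pos = tpos[1:2], alt = rep(conv_alt, 2)),  # 2 conversions
      data.frame(pos = tpos[1:2], alt = rep("A", 2))        # other mismatch
    ))
    cc <- count_conversions(rs, ref)
    expect_equal(cc$n_t_positions, rep(length(tpos), 3))
    expect_equal(cc$n_tc_conversions, c(0, 2, 0))
    # "A" at a reference A position (minus strand) is no mismatch at all
    n_other <- if (strand == "+") c(0, 0, 2) else c(0, 0, 0)
    if (strand == "-") {
      # alt A equals reference base: not representable as an event; use G->A
      rs <- make_manual_reads(ref, gi, list(
        data.frame(pos = integer(), alt = character()),
        data.frame(pos = tpos[1:2], alt = rep("G", 2)),
        data.frame(pos = tpos[1:2], alt = rep("C", 2))
      ))
      cc <- count_conversions(rs, ref)
      expect_equal(cc$n_tc_conversions, c(0, 2, 0))
      expect_equal(cc$n_other_mismatches, c(0, 0, 2))
    } else {
      expect_equal(cc$n_other_mismatches, n_other)
    }
  }
})

test_that("labeled-read calling applies the minimum-conversion boundary", {
  cfg <- sim_config(n_genes = 5, window_length = 100, seed = 3,
                    snp_fraction = 0)
  ref <- build_reference(cfg)
  gi <- which(ref$genes$strand == "+")[1]
  tpos <- slamwave:::convertible_positions(ref, gi)
  rs <- make_manual_reads(ref, gi, list(
    data.frame(pos = tpos[1:2], alt = c("C", "C")),   # 2 conversions
    data.frame(pos = tpos[1], alt = "C"),             # 1 conversion
    data.frame(pos = tpos[1:2], alt = c("C", "C"))    # one will be masked
  ))
  cc <- count_conversions(rs, ref)
  expect_equal(classify_reads(cc), c(TRUE, FALSE, TRUE))

  # mask tpos[1]: read 3 drops to a single countable conversion
  mask <- data.frame(contig = ref$genes$contig[gi], pos = tpos[1],
                     mismatch_frac = 1, coverage = 100)
  class(mask) <- c("variant_mask", "data.frame")
  cc2 <- count_conversions(rs, ref, mask)
  expect_equal(cc2$n_t_positions, rep(length(tpos) - 1L, 3))
  expect_equal(classify_reads(cc2), c(FALSE, FALSE, FALSE))

  # raising the threshold never increases labeled calls (monotonicity)
  stricter <- quant_config(min_conversions_labeled = 3)
  expect_true(all(classify_reads(cc, stricter) <= classify_reads(cc)))
})

test_that("event-based conversion counts equal the per-base oracle", {
  w <- small_world()
  rs <- w$reads[["tf_t0.5_r1"]]
  mask <- detect_variants(w$reads, w$ref)
  cc <- count_conversions(rs, w$ref, mask)
  idx <- seq_len(min(nrow(rs$reads), 1000))
  oracle <- t(vapply(idx, function(i) oracle_count_read(rs, w$ref, i, mask),
                     c(n_t_positions = 0L, n_tc_conversions = 0L,
                       n_other_mismatches = 0L)))
  expect_equal(cc$n_t_positions[idx], unname(oracle[, 1]))
  expect_equal(cc$n_tc_conversions[idx], unname(oracle[, 2]))
  expect_equal(cc$n_other_mismatches[idx], unname(oracle[, 3]))
})

test_that("per-UTR conversion rates recover the simulated chemistry", {
  # all reads reference-identical: rate exactly 0; empty window: NA
  cfg <- sim_config(n_genes = 10, window_length = 100, seed = 3,
                    snp_fraction = 0)
  ref <- build_reference(cfg)
  rs <- make_manual_reads(ref, 1, list(
    data.frame(pos = integer(), alt = character()),
    data.frame(pos = integer(), alt = character())))
  prof <- utr_conversion_rate(rs, ref)
  expect_equal(prof$utr_rate[1], 0)
  expect_true(all(is.na(prof$utr_rate[-1])))   # missing, not 0

  # labeled-only sample at p_conv 0.025, p_err 0, depth 200
  cfg2 <- sim_config(n_genes = 30, window_length = 250, mean_depth = 200,
                     p_err = 0, snp_fraction = 0, base_label_frac = 1,
                     class_mix = c(unresponsive = 1), seed = 21)
  ref2 <- build_reference(cfg2)
  truth2 <- simulate_timecourse(ref2)
  rs2 <- simulate_reads(truth2, ref2, samples = "tf_t0_r1")[[1]]
  prof2 <- utr_conversion_rate(rs2, ref2)
  est <- mean(prof2$utr_rate, na.rm = TRUE)
  n_obs <- sum(prof2$coverage * prof2$t_content)
  se <- sqrt(0.025 * 0.975 / n_obs)
  expect_lt(abs(est - 0.025), 3 * se)
})

test_that("count matrix conserves reads and tracks the planted labeling", {
  w <- small_world()
  mask <- detect_variants(w$reads, w$ref)
  counts <- build_count_matrix(w$reads, w$ref, mask)
  # conservation: column sums equal per-sample read totals
  for (sid in colnames(counts$total)) {
    expect_equal(sum(counts$total[, sid]), nrow(w$reads[[sid]]$reads))
  }
  expect_true(all(counts$labeled <= counts$total))
  expect_equal(counts$lib_size, colSums(counts$total))

  # expected labeled counts ~ depth x labeled abundance x P(>=2 conversions)
  p2 <- 1 - pbinom(1, w$ref$genes$t_count, w$cfg$p_conv)
  sid <- "tf_t0_r1"
  mu <- w$cfg$mean_depth * w$truth$genes$expr_mult *
    w$truth$labeled_abundance[, 1, "tf"] * p2
  obs <- counts$labeled[, sid]
  resid <- (obs - mu) / sqrt(pmax(mu, 1))
  expect_lt(abs(mean(resid)), 0.6)   # centered, Poisson-binomial scatter

  # missing sample in sheet -> error listing it
  sheet <- rbind(counts$samples,
                 data.frame(sample_id = "tf_t9_r1", arm = "tf", time_h = 9,
                            replicate = 1))
  expect_error(build_count_matrix(w$reads, w$ref, mask, samples = sheet),
               "tf_t9_r1")
})

test_that("variant mask is independent of sample order", {
  w <- small_world()
  m1 <- detect_variants(w$reads, w$ref)
  m2 <- detect_variants(rev(w$reads), w$ref)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("reverse-complementing a window leaves conversion counts unchanged", {
  # build two references identical except one window's strand and sequence
  # are flipped; counts of strand-aware conversions must agree
  cfg <- sim_config(n_genes = 4, window_length = 100, seed = 13,
                    snp_fraction = 0)
  ref <- build_reference(cfg)
  gi <- which(ref$genes$strand == "+")[1]
  g <- ref$genes[gi, ]
  tpos <- slamwave:::convertible_positions(ref, gi)

  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  ref2 <- ref
  win <- slamwave:::window_seq(ref, gi)
  seqfull <- ref2$sequences[[g$contig]]
  substr(seqfull, g$win_start, g$win_end) <- rc(win)
  ref2$sequences[[g$contig]] <- seqfull
  ref2$genes$strand[gi] <- "-"
  ref2$genes$t_count <- slamwave:::t_content(ref2$sequences, ref2$genes)

  # conversions at mirrored positions: position p (ref T>C) maps to
  # win_end - (p - win_start) with ref A>G
  mirror <- function(p) g$win_end - (p - g$win_start)
  rs1 <- make_manual_reads(ref, gi, list(
    data.frame(pos = tpos[1:3], alt = rep("C", 3))))
  rs2 <- make_manual_reads(ref2, gi, list(
    data.frame(pos = mirror(tpos[1:3]), alt = rep("G", 3))))
  cc1 <- count_conversions(rs1, ref)
  cc2 <- count_conversions(rs2, ref2)
  expect_equal(cc1$n_t_positions, cc2$n_t_positions)
  expect_equal(cc1$n_tc_conversions, cc2$n_tc_conversions)
  expect_equal(cc1$n_other_mismatches, cc2$n_other_mismatches)
})
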