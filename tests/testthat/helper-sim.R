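# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small balanced study used by most read-level tests; ... overrides defaults.
small_config <- function(...) {
  args <- list(n_genes = 30, window_length = 120, mean_depth = 60,
               snp_fraction = 0.2, seed = 42,
               class_mix = c(IE_transient = 0.2, IE_sustained = 0.2,
                             delayed = 0.2, secondary = 0.2,
                             unresponsive = 0.2))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_world <- function() {
  cached("small_world", function() {
    cfg <- small_config()
    ref <- build_reference(cfg)
    truth <- simulate_timecourse(ref)
    reads <- simulate_reads(truth, ref)
    list(cfg = cfg, ref = ref, truth = truth, reads = reads)
  })
}

# Naive per-base oracle: recount conversions for one read by materializing
# its sequence and walking every position with an explicit double loop over
# window offsets. Completely independent of the event-based path.
oracle_count_read <- function(read_set, reference, idx,
                              mask = data.frame(contig = character(),
                                                pos = integer())) {
  seqs <- slamwave:::read_sequences(read_set, reference)
  r <- read_set$reads[idx, ]
  gi <- match(r$gene_id, reference$genes$gene_id)
  g <- reference$genes[gi, ]
  refseq <- strsplit(slamwave:::window_seq(reference, gi), "")[[1]]
  rdseq <- strsplit(seqs[idx], "")[[1]]
  conv_ref <- if (g$strand == "+") "T" else "A"
  conv_alt <- if (g$strand == "+") "C" else "G"
  masked_pos <- mask$pos[mask$contig == g$contig]
  n_t <- 0L; n_tc <- 0L; n_other <- 0L
  for (off in seq_along(refseq)) {
    pos <- g$win_start - 1L + off
    if (pos %in% masked_pos) next
    if (refseq[off] == conv_ref) n_t <- n_t + 1L
    if (rdseq[off] != refseq[off]) {
      if (refseq[off] == conv_ref && rdseq[off] == conv_alt) {
        n_tc <- n_tc + 1L
      } else {
        n_other <- n_other + 1L
      }
    }
  }
  c(n_t_positions = n_t, n_tc_conversions = n_tc,
    n_other_mismatches = n_other)
}

# Exhaustive nearest-TSS scan with the same tie rule (lexicographic gene id).
oracle_nearest_tss <- function(mid, contig, genes, max_distance_bp = 10000) {
  g <- genes[genes$contig == contig, ]
  if (nrow(g) == 0) return(NA_character_)
  d <- abs(mid - g$tss)
  best <- which(d == min(d))
  gid <- sort(g$gene_id[best])[1]
  if (min(d) > max_distance_bp) NA_character_ else gid
}

# Brute-force hypergeometric upper tail by enumerating all choose(N, nb)
# draws of set B positions within a universe with m marked elements.
oracle_hyper_p <- function(k, m, N, nb) {
  draws <- utils::combn(N, nb)
  marked <- seq_len(m)
  hits <- apply(draws, 2, function(cols) sum(cols %in% marked))
  mean(hits >= k)
}
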