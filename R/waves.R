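wave_classes <- c("IE_direct_transient", "IE_direct_sustained",
                  "delayed_direct", "secondary", "IE_unbound",
                  "unresponsive")

#' Classify genes into temporal target waves
#'
#' Integrates per-gene significance across the vs-0h contrast family with
#' binary occupancy. First significant time `t1` is taken on the vs-0h
#' family (induced arm, after removing genes significant in the matching
#' control-arm contrasts):
#' bound and `t1` at 0.5 or 1 h gives an immediate-early direct target,
#' transient if every vs-0h call at >= 2 h reverts to non-significant, else
#' sustained; bound and `t1 >= 2` h gives a delayed direct target; unbound
#' and `t1 >= 2` h a secondary-response gene; unbound but significant
#' already at 0.5/1 h a flagged immediate-early unbound gene (possible
#' direct target without detected occupancy); no significant call anywhere
#' gives unresponsive. Direction is the fold-change sign at `t1`; later sign
#' flips are recorded as a warning annotation, not a class.
#'
#' @param sig_flags logical matrix, genes x time points (vs-0h family,
#'   induced arm); column names are the post-0 time points in hours.
#' @param lfc matrix of log2 fold changes, same shape.
#' @param bound logical vector per gene.
#' @param control_flags optional logical matrix of control-arm vs-0h
#'   significance; genes significant in any control contrast are set
#'   unresponsive (negative-control filter).
#' @param ie_max_h latest first-significant time still called
#'   immediate-early (default 1 h).
#' @param expected_times time points that must be present in the flag
#'   columns (default: those of the column names); a missing time point is
#'   an error.
#' @return a `wave_assignment` data.frame: gene_id, class, direction,
#'   first_significant_time_h, significant_times, sustained, bound,
#'   control_filtered, sign_flip.
#' @export
classify_genes <- function(sig_flags, lfc, bound, control_flags = NULL,
                           ie_max_h = 1, expected_times = NULL) {
  times <- as.numeric(colnames(sig_flags))
  if (anyNA(times)) stopf("sig_flags must have numeric time column names")
  if (!is.null(expected_times)) {
    miss <- setdiff(expected_times, times)
    if (length(miss)) {
      stopf("missing time point(s) in significance flags: %s h",
            paste(miss, collapse = ", "))
    }
  }
  n <- nrow(sig_flags)
  gene_id <- rownames(sig_flags) %||% sprintf("gene%04d", seq_len(n))
  stopifnot(length(bound) == n, all(dim(lfc) == dim(sig_flags)))

  filtered <- if (!is.null(control_flags)) {
    rowSums(control_flags, na.rm = TRUE) > 0
  } else rep(FALSE, n)
  flags <- sig_flags
  flags[filtered, ] <- FALSE

  out <- data.frame(gene_id = gene_id, class = "unresponsive",
                    direction = NA_character_,
                    first_significant_time_h = NA_real_,
                    significant_times = "", sustained = FALSE,
                    bound = bound, control_filtered = filtered,
                    sign_flip = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sig_t <- times[which(flags[i, ])]
    if (!length(sig_t)) next
    t1 <- sig_t[1]
    late <- times[times >= 2]
    late_sig <- any(flags[i, as.character(late)])
    out$first_significant_time_h[i] <- t1
    out$significant_times[i] <- paste(sig_t, collapse = ",")
    out$sustained[i] <- length(sig_t) >= 2 && late_sig
    out$class[i] <- if (t1 <= ie_max_h) {
      if (bound[i]) {
        if (late_sig) "IE_direct_sustained" else "IE_direct_transient"
      } else "IE_unbound"
    } else {
      if (bound[i]) "delayed_direct" else "secondary"
    }
    l1 <- lfc[i, as.character(t1)]
    out$direction[i] <- if (l1 >= 0) "up" else "down"
    signs <- sign(lfc[i, as.character(sig_t)])
    out$sign_flip[i] <- length(unique(signs[signs != 0])) > 1
  }
  class(out) <- c("wave_assignment", "data.frame")
  out
}

#' Wave assignments from pipeline outputs
#'
#' Convenience wrapper extracting the vs-0h significance/log2FC matrices for
#' both arms from a [run_contrasts()] result and the bound flags from an
#' [assign_peaks()] result.
#'
#' @param stats a `timecourse_stats`.
#' @param occ an `occupancy_result` (or a logical vector of bound flags
#'   named by gene).
#' @param induced_arm,control_arm arm labels in the sample sheet.
#' @param ... passed to [classify_genes()].
#' @return a `wave_assignment`.
#' @export
classify_waves <- function(stats, occ, induced_arm = "tf",
                           control_arm = "ctrl", ...) {
  tab <- stats$table[stats$table$family == "vs0", ]
  pivot <- function(arm, value) {
    sub <- tab[tab$arm == arm, ]
    tps <- sort(unique(sub$time_h))
    m <- matrix(NA, length(unique(sub$gene_id)), length(tps),
                dimnames = list(sort(unique(sub$gene_id)), tps))
    idx <- cbind(match(sub$gene_id, rownames(m)), match(sub$time_h, tps))
    m[idx] <- sub[[value]]
    m
  }
  sig <- pivot(induced_arm, "significant")
  lfc <- pivot(induced_arm, "log2FC")
  ctrl <- if (control_arm %in% tab$arm) pivot(control_arm, "significant")
          else NULL
  bound <- if (inherits(occ, "occupancy_result")) {
    stats::setNames(occ$genes$bound, occ$genes$gene_id)[rownames(sig)]
  } else occ[rownames(sig)]
  classify_genes(sig, lfc, bound, control_flags = ctrl, ...)
}

#' Fraction of bound genes per first-significant time point
#'
#' Over regulated genes (any class except unresponsive), the fraction
#' detectably occupied among those first significant at each time point.
#'
#' @param assignment a `wave_assignment`.
#' @param time_points_h time grid to report (default: observed).
#' @return data.frame: time_h, n_regulated, n_bound, bound_fraction
#'   (NA where no gene is first significant at that time).
#' @export
bound_fraction_by_first_time <- function(assignment, time_points_h = NULL) {
  reg <- assignment[assignment$class != "unresponsive", ]
  tps <- time_points_h %||% sort(unique(reg$first_significant_time_h))
  res <- data.frame(time_h = tps, n_regulated = 0L, n_bound = 0L,
                    bound_fraction = NA_real_)
  for (k in seq_along(tps)) {
    sel <- reg$first_significant_time_h == tps[k]
    res$n_regulated[k] <- sum(sel)
    res$n_bound[k] <- sum(reg$bound[sel])
    if (res$n_regulated[k] > 0) {
      res$bound_fraction[k] <- res$n_bound[k] / res$n_regulated[k]
    }
  }
  res
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail (cumulative) hypergeometric probability of observing at least
#' the realized overlap when drawing `|B|` genes from the universe with
#' `|A|` marked. Exact via the hypergeometric distribution.
#'
#' @param set_a,set_b character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector of all eligible genes.
#' @return one-row data.frame: n_a, n_b, n_universe, overlap, expected, p.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad)) {
    stopf("identifiers outside the universe: %s",
          paste(unique(bad), collapse = ", "))
  }
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); nb <- length(set_b); N <- length(universe)
  p <- phyper(k - 1, m, N - m, nb, lower.tail = FALSE)
  data.frame(n_a = m, n_b = nb, n_universe = N, overlap = k,
             expected = m * nb / N, p = p)
}

#' Pairwise overlaps with BH correction
#'
#' @param sets named list of gene-id vectors.
#' @param universe the common universe.
#' @return data.frame of all unordered pairs with overlap statistics and
#'   BH-adjusted q.
#' @export
pairwise_overlaps <- function(sets, universe) {
  nm <- names(sets)
  rows <- list()
  for (i in seq_along(sets)) for (j in seq_len(i - 1)) {
    st <- overlap_stats(sets[[i]], sets[[j]], universe)
    st$set_a <- nm[i]; st$set_b <- nm[j]
    rows[[length(rows) + 1L]] <- st
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[, c("set_a", "set_b", "n_a", "n_b", "n_universe", "overlap",
          "expected", "p", "q")]
}
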