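#' Assign occupancy peaks to genes by nearest TSS
#'
#' Each peak is anchored at its midpoint and assigned to the gene with the
#' nearest TSS on the same contig (ties broken by lexicographic gene id, so
#' output never depends on input order). The signed distance is negative
#' upstream of the TSS in the gene's reading direction. Feature class:
#' `promoter` if the midpoint lies within `promoter_up` bp upstream to
#' `promoter_down` bp downstream of the TSS (strand-aware), else
#' `gene_body` if inside the gene span, else `intergenic`. Peaks farther
#' than `max_distance_bp` from every TSS stay unassigned.
#'
#' @param peaks data.frame: peak_id, contig, start, end (1-based closed).
#' @param genes data.frame: gene_id, contig, start, end, strand, tss.
#' @param promoter_up,promoter_down promoter window extent in bp (both >= 0,
#'   not both 0).
#' @param max_distance_bp maximum midpoint-to-TSS distance for assignment.
#' @return an `occupancy_result`: list with `peaks` (per-peak annotation:
#'   peak_id, contig, midpoint, gene_id, distance_to_tss, feature, assigned)
#'   and `genes` (per-gene occupancy table: gene_id, bound, n_peaks,
#'   peak_ids, nearest_peak_distance).
#' @export
assign_peaks <- function(peaks, genes, promoter_up = 2000,
                         promoter_down = 500, max_distance_bp = 10000) {
  stopifnot(promoter_up >= 0, promoter_down >= 0,
            promoter_up + promoter_down > 0)
  if (any(peaks$start > peaks$end)) stopf("peaks must have positive width")
  unknown <- setdiff(unique(peaks$contig), unique(genes$contig))
  if (length(unknown)) {
    stopf("peak contigs absent from gene annotation: %s",
          paste(unknown, collapse = ", "))
  }

  mid <- (peaks$start + peaks$end) %/% 2
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_integer_, nrow(peaks))
  feature <- rep(NA_character_, nrow(peaks))

  for (ctg in unique(peaks$contig)) {
    g <- genes[genes$contig == ctg, ]
    pk <- which(peaks$contig == ctg)
    if (nrow(g) == 0) next
    # per unique TSS position keep the lexicographically first gene id
    ord <- order(g$tss, g$gene_id)
    g <- g[ord, ]
    upos <- unique(g$tss)
    rep_gene <- g$gene_id[match(upos, g$tss)]
    for (p in pk) {
      i <- findInterval(mid[p], upos)
      cand <- unique(pmin(pmax(c(i, i + 1L), 1L), length(upos)))
      dd <- abs(mid[p] - upos[cand])
      best <- which(dd == min(dd))
      # equidistant TSSs: lexicographic gene id wins
      chosen <- cand[best][order(rep_gene[cand[best]])][1]
      if (abs(mid[p] - upos[chosen]) <= max_distance_bp) {
        gi <- match(rep_gene[chosen], genes$gene_id)
        gene_id[p] <- genes$gene_id[gi]
        plus <- genes$strand[gi] == "+"
        d <- if (plus) mid[p] - genes$tss[gi] else genes$tss[gi] - mid[p]
        dist[p] <- d
        feature[p] <- if (d >= -promoter_up && d <= promoter_down) {
          "promoter"
        } else if (mid[p] >= genes$start[gi] && mid[p] <= genes$end[gi]) {
          "gene_body"
        } else {
          "intergenic"
        }
      }
    }
  }

  peak_ann <- data.frame(peak_id = peaks$peak_id, contig = peaks$contig,
                         midpoint = mid, gene_id = gene_id,
                         distance_to_tss = dist, feature = feature,
                         assigned = !is.na(gene_id),
                         stringsAsFactors = FALSE)

  per_gene <- data.frame(gene_id = genes$gene_id, bound = FALSE,
                         n_peaks = 0L, peak_ids = "",
                         nearest_peak_distance = NA_real_,
                         stringsAsFactors = FALSE)
  asg <- peak_ann[peak_ann$assigned, ]
  if (nrow(asg)) {
    sp <- split(asg, asg$gene_id)
    gi <- match(names(sp), per_gene$gene_id)
    per_gene$bound[gi] <- TRUE
    per_gene$n_peaks[gi] <- vapply(sp, nrow, integer(1))
    per_gene$peak_ids[gi] <- vapply(sp, function(d)
      paste(sort(d$peak_id), collapse = ","), character(1))
    per_gene$nearest_peak_distance[gi] <- vapply(sp, function(d)
      as.numeric(d$distance_to_tss[which.min(abs(d$distance_to_tss))]),
      numeric(1))
  }
  structure(list(peaks = peak_ann, genes = per_gene,
                 params = list(promoter_up = promoter_up,
                               promoter_down = promoter_down,
                               max_distance_bp = max_distance_bp)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy_result: %d peaks (%d assigned), %d/%d genes bound\n",
              nrow(x$peaks), sum(x$peaks$assigned), sum(x$genes$bound),
              nrow(x$genes)))
  invisible(x)
}

#' Distribution of assigned peaks over feature classes
#'
#' @param occ an `occupancy_result` (or its per-peak annotation table).
#' @return list with `fractions` (named numeric over promoter, gene_body,
#'   intergenic; sums to 1 over assigned peaks), `counts`, `n_assigned`,
#'   `n_unassigned`.
#' @export
feature_distribution <- function(occ) {
  ann <- if (inherits(occ, "occupancy_result")) occ$peaks else occ
  if (nrow(ann) == 0) stopf("no peaks to summarize")
  asg <- ann[ann$assigned, ]
  lev <- c("promoter", "gene_body", "intergenic")
  counts <- stats::setNames(
    as.numeric(table(factor(asg$feature, levels = lev))), lev)
  list(fractions = counts / sum(counts), counts = counts,
       n_assigned = nrow(asg), n_unassigned = sum(!ann$assigned))
}

#' Write occupancy annotation tables
#'
#' @param occ an `occupancy_result`.
#' @param dir output directory.
#' @export
write_occupancy <- function(occ, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(occ$peaks, file.path(dir, "peak_annotation.tsv"))
  write_tsv(occ$genes, file.path(dir, "gene_occupancy.tsv"))
  fd <- feature_distribution(occ)
  jsonlite::write_json(
    list(fractions = as.list(fd$fractions), counts = as.list(fd$counts),
         n_assigned = fd$n_assigned, n_unassigned = fd$n_unassigned,
         params = occ$params),
    file.path(dir, "feature_distribution.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
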