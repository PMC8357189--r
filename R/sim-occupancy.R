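#' Simulate TF occupancy peaks for bound genes
#'
#' Every bound gene (immediate-early or delayed class) receives exactly one
#' peak. With probability `promoter_peak_fraction` the peak midpoint falls
#' inside the gene's promoter window (strand-aware, `promoter_up` bp
#' upstream to `promoter_down` bp downstream of the TSS); otherwise it falls
#' in the gene body (70% of the remainder) or the 3' flank (30%), which a
#' nearest-TSS annotator scores as gene_body and intergenic respectively.
#' Unbound genes get no peak. Optional decoy peaks are placed in gene-free
#' contig tails, farther than any assignment cutoff from every TSS.
#'
#' @param truth a [simulate_timecourse()] result.
#' @param reference the matching reference.
#' @param config optional override config.
#' @return data.frame of peaks: peak_id, contig, start, end (1-based
#'   closed), score, plus hidden truth columns gene_id and placement.
#' @export
simulate_occupancy <- function(truth, reference, config = truth$config) {
  validate_config(config)
  genes <- truth$genes
  bound <- which(genes$bound)
  w <- config$peak_width
  half <- w %/% 2

  with_stream(config$seed, "occupancy", {
    placement <- character(length(bound))
    mid <- integer(length(bound))
    u <- runif(length(bound))
    body_vs_flank <- runif(length(bound))
    for (k in seq_along(bound)) {
      g <- genes[bound[k], ]
      plus <- g$strand == "+"
      if (u[k] < config$promoter_peak_fraction) {
        placement[k] <- "promoter"
        lo <- if (plus) g$tss - config$promoter_up else g$tss - config$promoter_down
        hi <- if (plus) g$tss + config$promoter_down else g$tss + config$promoter_up
      } else if (body_vs_flank[k] < 0.7) {
        placement[k] <- "gene_body"
        # inside the span but clear of the promoter window's downstream reach
        lo <- if (plus) g$start + config$promoter_down + half + 1L else g$start + half
        hi <- if (plus) g$end - half else g$end - config$promoter_down - half - 1L
      } else {
        placement[k] <- "flank"
        # 3' flank: outside span and promoter, still near this gene's TSS
        if (plus) {
          lo <- g$end + half + 1L
          hi <- g$end + 1500L
        } else {
          lo <- g$start - 1500L
          hi <- g$start - half - 1L
        }
      }
      mid[k] <- lo + floor(runif(1) * (hi - lo + 1))
    }

    decoys <- NULL
    if (config$decoy_peaks > 0) {
      # gene-free tail of each contig, >10 kb past the last gene
      tails <- lapply(names(reference$sequences), function(ctg) {
        gmax <- max(genes$end[genes$contig == ctg])
        c(gmax + 15000L, nchar(reference$sequences[[ctg]]) - 1000L)
      })
      ci <- sample.int(length(tails), config$decoy_peaks, replace = TRUE)
      dm <- vapply(ci, function(j) {
        tl <- tails[[j]]
        as.integer(tl[1] + floor(runif(1) * (tl[2] - tl[1] + 1)))
      }, integer(1))
      decoys <- data.frame(contig = names(reference$sequences)[ci], mid = dm,
                           gene_id = NA_character_, placement = "decoy",
                           stringsAsFactors = FALSE)
    }
  })

  df <- data.frame(contig = genes$contig[bound], mid = mid,
                   gene_id = genes$gene_id[bound], placement = placement,
                   stringsAsFactors = FALSE)
  if (!is.null(decoys)) df <- rbind(df, decoys)
  out <- data.frame(
    peak_id = sprintf("peak%04d", seq_len(nrow(df))),
    contig = df$contig,
    start = df$mid - half, end = df$mid + half,
    score = 100L,
    gene_id = df$gene_id, placement = df$placement,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start), ]
  out$peak_id <- sprintf("peak%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write peaks as BED
#'
#' @param peaks data.frame from [simulate_occupancy()] (or any with contig,
#'   start, end 1-based closed, peak_id, score).
#' @param path output BED path.
#' @export
write_peaks <- function(peaks, path) {
  write_bed(data.frame(contig = peaks$contig, start = peaks$start,
                       end = peaks$end, name = peaks$peak_id,
                       score = peaks$score %||% 0L, strand = "*"),
            path)
}

#' Read peaks from BED
#'
#' @param path BED file of peaks.
#' @return data.frame: peak_id, contig, start, end (1-based closed), score.
#' @export
read_peaks <- function(path) {
  b <- read_bed(path)
  data.frame(peak_id = b$name, contig = b$contig, start = b$start,
             end = b$end, score = b$score, stringsAsFactors = FALSE)
}
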