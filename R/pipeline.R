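#' Run the full synthetic-study pipeline
#'
#' Executes simulate (reference, truth, reads or counts, occupancy peaks),
#' quantify (variant mask, labeled count matrix), differential testing,
#' peak-to-gene annotation and wave classification, then scores the
#' recovered classes against the planted truth.
#'
#' @param config a [sim_config()].
#' @param quant a [quant_config()].
#' @param read_level if TRUE, synthesize per-base reads and quantify them;
#'   if FALSE, draw the labeled count matrix directly from the generative
#'   model (faster; no variant-masking stage exercised).
#' @param fdr,lfc significance thresholds for the time-course contrasts.
#' @param outdir optional directory: when given, every stage's files are
#'   written (FASTA/BED/SAM/TSV/JSON) along with a run log.
#' @return a `slam_run`: list with truth, counts, stats, occupancy, waves,
#'   report (confusion matrix, class recovery, bound fractions, feature
#'   distribution, conversion-rate summary), log.
#' @export
run_pipeline <- function(config, quant = quant_config(), read_level = TRUE,
                         fdr = 0.05, lfc = 0.5, outdir = NULL) {
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  say("run_pipeline seed=%d config=%s", config$seed, config_hash(config))

  reference <- stage("reference", build_reference(config))
  truth <- stage("timecourse", simulate_timecourse(reference))
  say("simulated %d genes (%s)", nrow(truth$genes),
      paste(sprintf("%s=%d", names(table(truth$genes$true_class)),
                    table(truth$genes$true_class)), collapse = " "))

  rate_summary <- NULL
  if (read_level) {
    reads <- stage("reads", simulate_reads(truth, reference))
    say("simulated %d reads over %d samples",
        sum(vapply(reads, function(r) nrow(r$reads), integer(1))),
        length(reads))
    mask <- stage("variants", detect_variants(reads, reference, quant))
    say("masked %d variant positions (planted %d)", nrow(mask),
        nrow(truth$snps))
    counts <- stage("quantify",
                    build_count_matrix(reads, reference, mask, quant))
    # conversion-rate diagnostics on the induced 0 h sample
    sid <- counts$samples$sample_id[counts$samples$arm == "tf" &
                                      counts$samples$time_h == 0][1]
    prof <- stage("rates",
                  utr_conversion_rate(reads[[sid]], reference, mask, quant))
    rate_summary <- list(sample_id = sid,
                         mean_utr_rate = mean(prof$utr_rate, na.rm = TRUE))
    say("mean per-UTR conversion rate in %s: %.4f", sid,
        rate_summary$mean_utr_rate)
  } else {
    reads <- NULL
    mask <- empty_mask()
    counts <- stage("quantify", simulate_counts(truth))
    say("simulated count matrix directly (%d x %d)", nrow(counts$labeled),
        ncol(counts$labeled))
  }

  stats <- stage("difftx", run_contrasts(counts, fdr = fdr, lfc = lfc))
  say("moderation: d0=%.2f s0^2=%.4g", stats$hyper$d0, stats$hyper$s0_2)

  peaks <- stage("occupancy", simulate_occupancy(truth, reference))
  occ <- stage("annotate",
               assign_peaks(peaks[, c("peak_id", "contig", "start", "end")],
                            reference$genes,
                            promoter_up = config$promoter_up,
                            promoter_down = config$promoter_down))
  fd <- feature_distribution(occ)
  say("peaks: %d, promoter fraction %.3f", nrow(peaks),
      fd$fractions[["promoter"]])

  waves <- stage("classify", classify_waves(stats, occ))

  truth_class <- map_truth_class(truth$genes$true_class)
  confusion <- table(truth = truth_class,
                     recovered = factor(waves$class, levels = wave_classes))
  resp <- truth_class != "unresponsive"
  recovery <- mean(waves$class[resp] == truth_class[resp])
  direct_secondary <- confusion[c("IE_direct_transient", "IE_direct_sustained",
                                  "delayed_direct"), "secondary"]
  secondary_direct <- confusion["secondary",
                                c("IE_direct_transient",
                                  "IE_direct_sustained", "delayed_direct")]
  say("class recovery among responsive genes: %.1f%%", 100 * recovery)

  bf <- bound_fraction_by_first_time(waves,
                                     config$time_points_h[config$time_points_h > 0])
  report <- list(
    confusion = confusion,
    class_recovery = recovery,
    n_responsive_true = sum(resp),
    direct_to_secondary = sum(direct_secondary),
    secondary_to_direct = sum(secondary_direct),
    bound_fractions = bf,
    feature_distribution = fd,
    conversion_rates = rate_summary,
    hyper = stats$hyper,
    seed = config$seed,
    config_hash = config_hash(config)
  )

  run <- structure(list(reference = reference, truth = truth, reads = reads,
                        mask = mask, counts = counts, stats = stats,
                        peaks = peaks, occupancy = occ, waves = waves,
                        report = report, log = log),
                   class = "slam_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Truth class labels -> recovered wave-class labels (bound by construction
# for IE/delayed, unbound for secondary).
map_truth_class <- function(true_class) {
  factor(c(IE_transient = "IE_direct_transient",
           IE_sustained = "IE_direct_sustained",
           delayed = "delayed_direct",
           secondary = "secondary",
           unresponsive = "unresponsive")[true_class],
         levels = wave_classes)
}

#' @export
print.slam_run <- function(x, ...) {
  cat("slam_run\n")
  cat(sprintf("  class recovery: %.1f%% of %d responsive genes\n",
              100 * x$report$class_recovery, x$report$n_responsive_true))
  cat(sprintf("  direct->secondary confusions: %d; secondary->direct: %d\n",
              x$report$direct_to_secondary, x$report$secondary_to_direct))
  invisible(x)
}

#' Write every stage's outputs of a pipeline run
#'
#' @param run a `slam_run`.
#' @param dir output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(run$reference, file.path(dir, "reference"))
  write_truth(run$truth, file.path(dir, "truth"))
  if (!is.null(run$reads)) {
    write_reads(run$reads, run$reference, file.path(dir, "reads"))
    write_tsv(as.data.frame(run$mask)[, c("contig", "pos", "mismatch_frac",
                                          "coverage")],
              file.path(dir, "variant_mask.tsv"))
  }
  write_count_matrix(run$counts, file.path(dir, "counts"))
  write_contrasts(run$stats, file.path(dir, "difftx"))
  write_peaks(run$peaks, file.path(dir, "peaks.bed"))
  write_occupancy(run$occupancy, file.path(dir, "occupancy"))
  write_tsv(as.data.frame(run$waves), file.path(dir, "wave_assignment.tsv"))
  bf <- run$report$bound_fractions
  write_tsv(bf, file.path(dir, "bound_fractions.tsv"))
  jsonlite::write_json(
    list(class_recovery = run$report$class_recovery,
         n_responsive_true = run$report$n_responsive_true,
         direct_to_secondary = run$report$direct_to_secondary,
         secondary_to_direct = run$report$secondary_to_direct,
         class_counts = as.list(table(run$waves$class)),
         promoter_fraction =
           run$report$feature_distribution$fractions[["promoter"]],
         seed = run$report$seed, config_hash = run$report$config_hash),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}
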