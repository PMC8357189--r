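#!/usr/bin/env Rscript
# Step 1 -- simulate the study: reference genome with counting windows,
# planted gene classes and kinetics, aligned labeled reads for
# 6 time points x 2 replicates x 2 arms, occupancy peaks, ground truth.

source("analysis/00_config.R")

cfg <- study_config()
print(cfg)

ref <- build_reference(cfg)
truth <- simulate_timecourse(ref)
cat("\nPlanted class composition:\n")
print(table(truth$genes$true_class))
cat(sprintf("Planted variants: %d windows (%.0f%%)\n", nrow(truth$snps),
            100 * nrow(truth$snps) / nrow(truth$genes)))

write_reference(ref, dir_of("sim", "reference"))
write_truth(truth, dir_of("sim", "truth"))

reads <- simulate_reads(truth, ref)
n_reads <- vapply(reads, function(r) nrow(r$reads), integer(1))
cat(sprintf("\nSimulated %d reads across %d samples (median %d per sample)\n",
            sum(n_reads), length(reads), as.integer(median(n_reads))))
write_reads(reads, ref, dir_of("sim", "reads"))

peaks <- simulate_occupancy(truth, ref)
cat(sprintf("Simulated %d occupancy peaks (%d decoys)\n", nrow(peaks),
            sum(peaks$placement == "decoy")))
write_peaks(peaks, file.path(dir_of("sim"), "peaks.bed"))

cat("\nStep 1 done: study written under", file.path(OUT, "sim"), "\n")
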