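#!/usr/bin/env Rscript
# Generate the paired control/treated study datasets with recorded ground
# truth and write them in plain-text exchange formats under results/data/.
# Every downstream script regenerates from the same master seed, so the
# whole analysis is reproducible end to end.

suppressPackageStartupMessages(library(topoperturb))

master <- 20260101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- study_simulation_config(seed = master, n_bins = 400L, depth = 4e6)
pert <- perturbation_preset("treated")

ctrl <- simulate_contact_map(sim)
trt <- simulate_contact_map(sim, pert)
write_triplets(ctrl$map, file.path(out, "control.triplets.tsv"),
               file.path(out, "bins.bed"))
write_triplets(trt$map, file.path(out, "treated.triplets.tsv"),
               file.path(out, "bins.bed"))

peaks <- simulate_peak_sets(sim, pert, n_peaks = 1000L)
write_bed(peaks$control, file.path(out, "peaks_control.bed"))
write_bed(peaks$treated, file.path(out, "peaks_treated.bed"))

anno <- simulate_genome_annotation(
  sim, deserts = data.frame(start = c(2.0e6, 5.6e6), end = c(3.0e6, 6.6e6)))
write_bed(anno$genes, file.path(out, "genes.bed"))
n <- length(anno$rna)
utils::write.table(data.frame(chrom = "chrS",
                              start = (seq_len(n) - 1) * sim$resolution,
                              end = seq_len(n) * sim$resolution,
                              count = anno$rna),
                   file.path(out, "rna.bedgraph"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

for (p in c("minus_drug", "plus_drug", "free_dna")) {
  ev <- simulate_fret_events(fret_preset(p), fret_preset(p)$n_default,
                             seed = sub_seed(master, p))
  write_fret_events(ev, file.path(out, sprintf("fret_%s.tsv", p)))
}

truth <- list(
  tads = ctrl$truth$true_tads,
  treated_tads = trt$truth$true_tads,
  dropped_peaks = peaks$truth$dropped_peak_ids,
  deserts = anno$deserts)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("control map: %d bins, %.0f read pairs\n",
            nrow(ctrl$map$counts), sum(ctrl$map$counts) / 2))
cat(sprintf("treated map: %.0f read pairs\n", sum(trt$map$counts) / 2))
cat(sprintf("peaks: %d control, %d treated (%d dropped in truth)\n",
            nrow(peaks$control), nrow(peaks$treated),
            length(peaks$truth$dropped_peak_ids)))
cat(sprintf("genes: %d placed around %d deserts (%.1f Mb)\n",
            nrow(anno$genes), nrow(anno$deserts),
            sum(anno$deserts$end - anno$deserts$start) / 1e6))
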