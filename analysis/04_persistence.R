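#!/usr/bin/env Rscript
# Persistence of distal contacts and of protein-binding peaks between
# conditions. Contacts are called on each balanced map with the
# domain-conditioned over-expected caller (control TADs for both), then
# matched one-to-one at 1-bin anchor tolerance; peaks are classified with
# the strict >50% percent-of-intersection rule.

suppressPackageStartupMessages(library(topoperturb))

dat <- "results/data"
ctrl <- read_triplets(file.path(dat, "control.triplets.tsv"),
                      file.path(dat, "bins.bed"))
trt <- read_triplets(file.path(dat, "treated.triplets.tsv"),
                     file.path(dat, "bins.bed"))

bal_c <- iterative_correction(ctrl)
bal_t <- iterative_correction(trt)
seg <- armatus_segment(bal_c, gamma = 0.3)

calls_c <- call_contacts(bal_c, seg, fdr = 0.05, min_sep = 40000)
calls_t <- call_contacts(bal_t, seg, fdr = 0.05, min_sep = 40000)
cat(sprintf("contacts called: %d control (of %d tested), %d treated\n",
            nrow(calls_c), attr(calls_c, "n_tested"), nrow(calls_t)))
pers <- classify_persistence(calls_c, calls_t, tol_bins = 1L)
cat(sprintf("contact persistence: %d preserved (%.0f%%), %d lost, %d de novo\n",
            pers$counts["preserved"], 100 * pers$fractions["preserved"],
            pers$counts["lost"], pers$counts["de_novo"]))

genes <- read_bed(file.path(dat, "genes.bed"))
lost_contacts <- if (nrow(pers$matches))
  calls_c[-pers$matches$ci, , drop = FALSE] else calls_c
changed <- anchor_gene_overlap(lost_contacts, genes,
                               resolution = ctrl$resolution)
cat(sprintf("genes with a lost contact at an anchor: %d of %d\n",
            sum(changed$n_contacts > 0), nrow(genes)))

pk_c <- read_bed(file.path(dat, "peaks_control.bed"))
pk_t <- read_bed(file.path(dat, "peaks_treated.bed"))
rep <- classify_peaks(pk_c, pk_t, threshold = 0.5)
cat(sprintf("peaks: %d control, %d remaining (%.0f%%), %d lost, %d novel\n",
            rep$n_control, rep$n_remaining,
            100 * rep$n_remaining / rep$n_control, rep$n_lost, rep$n_novel))
dc <- differential_counts(pk_c, pk_t)
cat(sprintf("differential sites: %d control-only, %d treated-only\n",
            dc["control_only"], dc["treated_only"]))

dir.create("results", showWarnings = FALSE)
utils::write.csv(as.data.frame(calls_c), "results/contacts_control.csv",
                 row.names = FALSE)
utils::write.csv(as.data.frame(calls_t), "results/contacts_treated.csv",
                 row.names = FALSE)
utils::write.csv(rep$per_peak, "results/peak_persistence.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(contacts = as.list(pers$counts), peaks = list(
    n_control = rep$n_control, n_remaining = rep$n_remaining,
    n_lost = rep$n_lost, n_novel = rep$n_novel)),
  "results/persistence_summary.json", auto_unbox = TRUE, pretty = TRUE)
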