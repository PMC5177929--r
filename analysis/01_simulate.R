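#!/usr/bin/env Rscript

## Step 1: generate the synthetic stress time-course experiment.
##
## 72 small RNA libraries (4 treatments x 3 replicates x 6 time points),
## 50 hairpin-borne miRNAs with star partners, 200 ncRNA/chloroplast
## contaminant tags, 300 precursor-less 24-nt siRNA-like tags, and a
## heat-dominated planted effect pattern (mostly downregulation at 0-1
## days after treatment).  FASTQ and reference files go to
## scratch/simdata; a summary of the planted truth goes to results/.

suppressPackageStartupMessages(library(stressmir))

simdir <- "scratch/simdata"
dir.create("results", showWarnings = FALSE)
unlink(simdir, recursive = TRUE)

message("simulating 72 libraries with planted truth ...")
sim <- simulate_experiment(simdir, n_mirnas = 50, n_decoy_tags = 200,
                           n_sirna24 = 300, seed = 20160712)

tt <- sim$tag_truth
message(sprintf("planted: %d matures, %d stars, %d contaminant tags, %d siRNA tags",
                sum(tt$kind == "mature"), sum(tt$kind == "star"),
                sum(tt$kind == "decoy"), sum(tt$kind == "sirna24")))
message(sprintf("planted effects: %d (tag, treatment, time) entries",
                nrow(sim$truth$effects)))
message(sprintf("library depth: %d-%d reads",
                min(colSums(sim$counts)), max(colSums(sim$counts))))

summary <- data.frame(
  quantity = c("n_libraries", "n_planted_mirnas", "n_star_tags",
               "n_contaminant_tags", "n_sirna_tags", "n_effect_entries",
               "min_library_reads", "max_library_reads"),
  value = c(nrow(sim$design), sum(tt$kind == "mature"), sum(tt$kind == "star"),
            sum(tt$kind == "decoy"), sum(tt$kind == "sirna24"),
            nrow(sim$truth$effects),
            min(colSums(sim$counts)), max(colSums(sim$counts))))
write.table(summary, "results/01_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/01_truth_summary.tsv; raw data under ", simdir)
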