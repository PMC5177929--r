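#!/usr/bin/env Rscript

## Step 2: raw FASTQ -> named distinct tags with counts and RPM.
##
## Adapter trimming, mean-quality gate, 18-24 nt size selection,
## cross-library collapsing, RPM normalization, removal of tags matching
## the ncRNA/chloroplast decoy references, and the >= 10 RPM expression
## filter.  Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(stressmir))

simdir <- "scratch/simdata"
if (!dir.exists(simdir)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

design <- read_design(file.path(simdir, "design.tsv"))
fastq <- setNames(file.path(simdir, "fastq", paste0(design$library_id, ".fastq")),
                  design$library_id)

message("preprocessing ", length(fastq), " libraries ...")
pp <- preprocess_fastq(fastq, design,
                       decoys = file.path(simdir, "ref", "decoys.fa"),
                       min_rpm = 10)

st <- pp$stats
message(sprintf("raw reads: %d; retained 18-24 nt: %d; after decoy removal: %d",
                sum(st$raw_reads), sum(st$retained_reads), sum(st$after_decoy)))
message(sprintf("distinct tags: %d collapsed, %d after decoy removal, %d at >= 10 RPM",
                length(pp$tags_collapsed$tag_id), length(pp$tags_post_decoy$tag_id),
                length(pp$tags$tag_id)))

write.table(st, "results/02_library_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pp$size_dist, "results/02_size_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_tags(pp$tags, "results/02_tags_min10rpm.tsv")
message("wrote results/02_library_stats.tsv, 02_size_distribution.tsv, ",
        "02_tags_min10rpm.tsv")
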