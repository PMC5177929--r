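#!/usr/bin/env Rscript

## Step 3: classify the filtered distinct tags as genuine conserved
## miRNAs: perfect precursor match, hairpin passing the MFE/nt < -0.2
## kcal/mol/nt gate, and valid star geometry (2-nt 3' overhangs), with
## star-expression support and family assignment from the known-mature
## catalog.  Requires analysis/02_preprocess.R.

suppressPackageStartupMessages(library(stressmir))

simdir <- "scratch/simdata"
if (!file.exists("results/02_tags_min10rpm.tsv")) {
  stop("run analysis/02_preprocess.R first")
}

tags <- read_tags("results/02_tags_min10rpm.tsv")
message("classifying ", length(tags$tag_id), " tags ...")
ann <- classify_mirna(tags,
                      file.path(simdir, "ref", "precursors.fa"),
                      catalog = file.path(simdir, "ref", "known_matures.fa"))

a <- ann$annotations
message(sprintf("accepted: %d miRNAs (%d star-supported, %d families)",
                nrow(a), sum(a$star_supported), length(unique(a$family))))
message("rejection reasons:")
print(table(ann$rejections$reason))

write_annotation(ann, "results/03_annotation.tsv",
                 "results/03_rejections.tsv")
write.table(family_summary(ann), "results/03_family_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## counts of the accepted miRNAs, for the differential expression stage
idx <- match(a$tag_id, tags$tag_id)
mir_counts <- tags$counts[idx, , drop = FALSE]
rownames(mir_counts) <- a$tag_id
write.table(data.frame(tag_id = rownames(mir_counts), mir_counts,
                       check.names = FALSE),
            "results/03_mirna_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/03_annotation.tsv, 03_rejections.tsv, ",
        "03_family_summary.tsv, 03_mirna_counts.tsv")
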