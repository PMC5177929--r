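#!/usr/bin/env Rscript

## Step 4: differential expression of the annotated miRNAs over the
## treatment x time design: TMM normalization, NB dispersion
## estimation, per-treatment likelihood-ratio tests with BH-FDR,
## per-time direction calls, Venn overlap and the log2 heat-map matrix.
## Requires analysis/03_annotate.R.

suppressPackageStartupMessages(library(stressmir))

simdir <- "scratch/simdata"
if (!file.exists("results/03_mirna_counts.tsv")) {
  stop("run analysis/03_annotate.R first")
}

design <- read_design(file.path(simdir, "design.tsv"))
tab <- read.table("results/03_mirna_counts.tsv", sep = "\t", header = TRUE,
                  check.names = FALSE)
counts <- as.matrix(tab[, -1])
rownames(counts) <- tab$tag_id
storage.mode(counts) <- "integer"

message("running DE on ", nrow(counts), " miRNAs x ", ncol(counts),
        " libraries ...")
de <- run_de(counts, design, alpha = 0.05)

message(sprintf("common dispersion: %.4f", de$dispersion$common))
message("DE miRNAs per treatment (FDR < 0.05):")
print(vapply(de$sets, length, integer(1)))
message("Venn regions:")
print(de$venn)
message("direction by time (heat):")
print(de$direction[de$direction$treatment == "heat", ])

write.table(de$results, "results/04_de_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(region = names(de$venn), count = as.integer(de$venn)),
            "results/04_venn.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(de$direction)) {
  write.table(de$direction, "results/04_direction_by_time.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
if (!is.null(de$heatmap)) {
  hm <- de$heatmap
  ord <- hm$matrix[hm$row_order, hm$col_order]
  write.table(data.frame(tag_id = rownames(ord), round(ord, 4),
                         check.names = FALSE),
              "results/04_heatmap_log2.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
fac <- de$factors
write.table(data.frame(library_id = names(fac$tmm_factor),
                       tmm_factor = fac$tmm_factor,
                       effective_size = fac$effective_size),
            "results/04_tmm_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/04_de_results.tsv, 04_venn.tsv, ",
        "04_direction_by_time.tsv, 04_heatmap_log2.tsv, 04_tmm_factors.tsv")
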