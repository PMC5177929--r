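#!/usr/bin/env Rscript

## Step 5: miRNA target prediction on synthetic transcripts.
##
## Builds a set of synthetic unigene-like transcripts with antisense
## sites planted for a subset of the differentially expressed miRNAs,
## then scans all DE miRNAs against them with the penalty-based
## complementarity score (expectation <= 3).  Requires
## analysis/04_diffexpr.R.

suppressPackageStartupMessages(library(stressmir))

if (!file.exists("results/04_de_results.tsv") ||
    !file.exists("results/03_annotation.tsv")) {
  stop("run analysis/04_diffexpr.R first")
}
set.seed(20160713)

ann <- read.table("results/03_annotation.tsv", sep = "\t", header = TRUE)
de <- read.table("results/04_de_results.tsv", sep = "\t", header = TRUE)
de_tags <- unique(de$tag_id[de$scope == "overall" & !is.na(de$fdr) &
                            de$fdr < 0.05])
mirnas <- ann[ann$tag_id %in% de_tags, c("tag_id", "name", "sequence")]
message(nrow(mirnas), " DE miRNAs to scan")

## synthetic transcripts: planted perfect or near-perfect antisense
## sites for half of the DE miRNAs, plus unrelated background
n_tx <- 60
tx <- setNames(random_seq(n_tx, sample(300:800, n_tx, replace = TRUE)),
               sprintf("unigene_%03d", seq_len(n_tx)))
with_site <- mirnas[seq_len(min(nrow(mirnas), n_tx %/% 2)), ]
for (k in seq_len(nrow(with_site))) {
  site <- as_dna(revcomp(with_site$sequence[k]))
  host <- names(tx)[k]
  pos <- sample(50:200, 1)
  substr(tx[[host]], pos, pos + nchar(site) - 1L) <- site
}
write_fasta_seqs(tx, "results/05_synthetic_transcripts.fa")

hits <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(k) {
  scan_transcripts(mirnas$sequence[k], tx, cutoff = 3,
                   mirna_id = mirnas$name[k])
}))
if (is.null(hits)) hits <- data.frame()
message(nrow(hits), " target sites at expectation <= 3 for ",
        length(unique(hits$mirna_id)), " miRNAs")
print(head(hits[, c("mirna_id", "transcript_id", "expectation",
                    "t_start", "t_end")]))
write.table(hits, "results/05_target_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/05_target_hits.tsv and 05_synthetic_transcripts.fa")
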