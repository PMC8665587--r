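#!/usr/bin/env Rscript
# Classify the exon/intron divergence mechanism of every simulated paralog
# sibling pair and score the calls against the planted mechanisms.

library(dupdiverge)

ds <- "results/dataset"
dir.create("results/structdiv", showWarnings = FALSE, recursive = TRUE)

gm <- read_gff3(file.path(ds, "struct_pairs.gff3"),
                fasta = file.path(ds, "struct_pairs.fa"))
pairs <- read.delim(file.path(ds, "struct_pairs.tsv"))
truth <- jsonlite::read_json(file.path(ds, "ground_truth.json"),
                             simplifyVector = TRUE)$structdiv

to_classifier <- c(NONE = "NONE",
                   EXON_INTRON_GAIN_LOSS = "EXON_INTRON_GAIN_LOSS",
                   INTRON_ELONGATION = "INTRON_ELONGATION",
                   EXONIZATION = "EXONIZATION_PSEUDOEXONIZATION",
                   BOUNDARY_SHIFT = "BOUNDARY_ALTERATION",
                   EXON_SPLIT = "EXON_SPLIT")

rows <- lapply(seq_len(nrow(pairs)), function(i) {
  a <- gm$models[[pairs$geneA[i]]]
  b <- gm$models[[pairs$geneB[i]]]
  dv <- classify_pair(build_correspondence(a, b), a, b)
  data.frame(geneA = a$gene_id, geneB = b$gene_id, primary = dv$primary,
             n_events = nrow(dv$events),
             planted = truth$mechanism[truth$geneA == a$gene_id])
})
calls <- do.call(rbind, rows)
calls$correct <- calls$primary == to_classifier[calls$planted]

cat(sprintf("primary mechanism correct for %d/%d pairs\n",
            sum(calls$correct), nrow(calls)))
print(table(planted = calls$planted, called = calls$primary))
write.table(calls, "results/structdiv/calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
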