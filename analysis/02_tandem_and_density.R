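#!/usr/bin/env Rscript
# Tandem-duplication clustering of the planted gene family and its 1-Mb
# density profile: how much of a duplicated family sits in tandem arrays?

library(dupdiverge)

ds <- "results/dataset"
dir.create("results/tandem", showWarnings = FALSE, recursive = TRUE)

catalog <- read_catalog_tsv(file.path(ds, "catalog.tsv"))
family <- readLines(file.path(ds, "family_ids.txt"))

tcs <- cluster_tandem(catalog, family, max_gap = 20)
smry <- summarize_tandem(tcs, length(family))
cat(sprintf("family of %d genes: %d tandem, %d single (%d%% tandem)\n",
            length(family), smry$n_tandem, smry$n_single, smry$percent_tandem))

big <- big_clusters(tcs, min_size = 5)
cat(nrow(big), "cluster(s) with five or more members\n")

truth <- jsonlite::read_json(file.path(ds, "ground_truth.json"),
                             simplifyVector = TRUE)$tandem
cat(sprintf("planted partition recovered for %d/%d family genes\n",
            length(intersect(tcs$clusters$gene_id,
                             truth$gene_id[!is.na(truth$cluster)])) +
              length(intersect(tcs$singletons,
                               truth$gene_id[is.na(truth$cluster)])),
            length(family)))

write.table(tcs$clusters, "results/tandem/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(n_single = smry$n_single, n_tandem = smry$n_tandem,
                       percent_tandem = smry$percent_tandem),
            "results/tandem/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(density_track(catalog, family), "results/tandem/density.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
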