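#!/usr/bin/env Rscript
# Step 3 -- genomic context of the TCS genes.
#
# Partitions each genome's TCS genes into orphan/paired/complex clusters
# using the distance (< 200 bp), orientation (same or divergent) and
# contiguity rules, and writes the per-cluster table plus the per-genome
# organization summary with orphan/paired/complex fractions.

suppressMessages(library(tcscensus))

tcs <- readRDS("results/classified_tcs.rds")

clusters <- do.call(rbind, lapply(split(tcs, tcs$genome_id), build_clusters))
rownames(clusters) <- NULL
write_clusters(clusters, "results/clusters.tsv")

org <- do.call(rbind, lapply(split(clusters, clusters$genome_id),
                             organization_summary))
org <- cbind(org, organization_fractions(org)[, -1])
write.table(org, "results/organization.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

complexes <- clusters[clusters$size > 2, ]
message("built ", nrow(clusters), " clusters over ", sum(clusters$size),
        " TCS genes; orphan fraction ", min(org$orphan_pct), "-",
        max(org$orphan_pct), "% across genomes; complex clusters: ",
        paste(sprintf("%s (%s)", complexes$composition, complexes$genome_id),
              collapse = ", "))
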