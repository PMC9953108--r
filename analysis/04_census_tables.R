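#!/usr/bin/env Rscript
# Step 4 -- census tables and summary statistics.
#
# Aggregates the classified panel into the five census tables (genome
# summary with ORF fractions and receiver/transmitter ratios, genetic
# organization, sensing domains, HK architectures, RR output families) and
# recomputes the reference-panel statistics from the bundled printed counts:
# per-genome receiver/transmitter ratios, orphan/paired/ORF-fraction ranges,
# and the TCS-count vs genome-size correlation.

suppressMessages(library(tcscensus))

tcs <- readRDS("results/classified_tcs.rds")
genomes <- split(tcs, tcs$genome_id)

gs <- do.call(rbind, lapply(names(genomes), function(g)
  genome_summary(genomes[[g]][genomes[[g]]$category != "NONE", ],
                 n_cds = nrow(genomes[[g]]), genome_id = g)))
clusters <- do.call(rbind, lapply(genomes, build_clusters))
org <- do.call(rbind, lapply(split(clusters, clusters$genome_id),
                             organization_summary))
rr <- do.call(rbind, lapply(names(genomes), function(g)
  cbind(genome_id = g, rr_family_table(genomes[[g]]))))
arch <- architecture_census(tcs)

paths <- write_census_tables(
  list(genome_summary = gs, organization = org, sensing = sensing_census(tcs),
       architectures = cbind(genome_id = "panel", arch$architectures),
       rr_families = rr),
  "results/census", config = census_config())

# reference-panel statistics from the bundled printed counts
ref <- thermophile_reference_tables()
counts <- ref$counts
rt <- vapply(seq_len(nrow(counts)), function(k)
  rt_ratio(category_count_fixture(cHK = counts$cHK[k], hyHK = counts$hyHK[k],
                                  RR = counts$RR[k])), 0)
orf <- vapply(seq_len(nrow(counts)), function(k) {
  genome_summary(category_count_fixture(counts$cHK[k], counts$hyHK[k],
                                        counts$uHK[k], counts$CheA[k],
                                        counts$RR[k], counts$PP_HisKA[k],
                                        counts$PP_Hpt[k]),
                 n_cds = counts$n_cds[k])$orf_fraction
}, 0)
fr <- organization_fractions(
  ref$organization[ref$organization$group == "thermophile", ])
total <- counts$cHK + counts$hyHK + counts$uHK + counts$CheA + counts$RR +
  counts$PP_HisKA + counts$PP_Hpt
pc <- pearson_cor(counts$genome_size_mb, total)

ref_stats <- data.frame(
  statistic = c("rt_ratio_min", "rt_ratio_max", "orf_fraction_min",
                "orf_fraction_max", "orphan_pct_min", "orphan_pct_max",
                "paired_pct_min", "paired_pct_max",
                "pearson_r_size_vs_tcs", "pearson_p"),
  value = c(min(rt), max(rt), min(orf), max(orf), min(fr$orphan_pct),
            max(fr$orphan_pct), min(fr$paired_pct), max(fr$paired_pct),
            round(pc$r, 3), signif(pc$p, 3)))
write.table(ref_stats, "results/reference_statistics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("census tables under results/census; panel: ",
        arch$n_distinct, " distinct HK architectures, ",
        arch$no_sensing_pct, "% of HKs without a sensing domain. ",
        "Reference panel: ORF fraction ", min(orf), "-", max(orf),
        "%, orphan ", min(fr$orphan_pct), "-", max(fr$orphan_pct),
        "%, paired ", min(fr$paired_pct), "-", max(fr$paired_pct),
        "%, r(size, TCS count) = ", round(pc$r, 2))
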