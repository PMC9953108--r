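#!/usr/bin/env Rscript
# Step 2 -- identify and classify TCS proteins.
#
# Reads each simulated genome's FASTA/coordinates/domain tables back from
# disk, resolves domain hits into ordered role strings, and classifies every
# protein into the TCS categories (cHK, hyHK, unorthodox HK, CheA, RR, PP)
# including the lone-HisKA rescue rule, RR output families and the
# hydropathy-based localization call.

suppressMessages(library(tcscensus))

in_dir <- "results/panel_inputs"
out_dir <- "results"
genome_ids <- sub("_coords\\.tsv$", "",
                  basename(Sys.glob(file.path(in_dir, "*_coords.tsv"))))

all_cls <- list()
for (g in genome_ids) {
  inp <- read_genome_inputs(file.path(in_dir, paste0(g, ".faa")),
                            file.path(in_dir, paste0(g, "_coords.tsv")),
                            file.path(in_dir, paste0(g, "_domains.tsv")),
                            genome_id = g)
  all_cls[[g]] <- classify_proteins(inp$proteins, inp$domains)
}
tcs <- do.call(rbind, all_cls)

flat <- tcs[tcs$category != "NONE",
            c("genome_id", "protein_id", "contig_id", "start", "end", "strand",
              "category", "label", "n_rec", "n_transmitter", "rr_family",
              "tm_count", "localization", "hiska_rescue")]
flat$roles <- vapply(tcs$roles[tcs$category != "NONE"], paste, "", collapse = ",")
write.table(flat, file.path(out_dir, "classified_tcs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(tcs, file.path(out_dir, "classified_tcs.rds"))

message("classified ", nrow(tcs), " proteins across ", length(genome_ids),
        " genomes: ", sum(tcs$category != "NONE"), " TCS genes (",
        paste(names(table(flat$label)), table(flat$label),
              sep = "=", collapse = ", "), "); ",
        round(100 * mean(flat$localization == "cytosolic")),
        "% of TCS proteins predicted cytosolic")
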