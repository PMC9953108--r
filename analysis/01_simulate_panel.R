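#!/usr/bin/env Rscript
# Step 1 -- simulate the study panel.
#
# Builds a synthetic six-genome panel of thermophile-like genomes carrying
# planted TCS content: a shared core of families, accessory families with
# known gain/loss histories on the guide tree, one within-genome duplication,
# and one genome with planted multi-gene clusters (pair/triad/pentad) to
# exercise the genomic-context rules. Inputs are written in the pipeline's
# external formats (protein FASTA, coordinate TSV, domain TSV, ANI TSV) so
# the later steps consume files exactly as a real run would.

suppressMessages(library(tcscensus))

out_dir <- "results/panel_inputs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Guide tree: two cherries plus two outer genomes, depths chosen so pairwise
# protein identity stays in the 75-95% band typical of congeneric strains.
newick <- "(((G1:0.03,G2:0.03):0.03,(G3:0.03,G4:0.03):0.03):0.04,(G5:0.05,G6:0.05):0.05);"

ps <- panel_spec(
  newick,
  core = c("cHK", "cHK_plain", "hyHK", "uHK", "CheA",
           "RR", "RR", "RR_CheY", "RR_CheY", "RR_NarL", "cHK", "hyHK"),
  accessory = list(
    list(template = "RR",       gains = "node9"),           # G1/G2 stem
    list(template = "RR_CheY",  gains = "root", losses = "G4"),
    list(template = "cHK",      gains = "node11"),          # G5/G6 stem
    list(template = "RR_NarL",  gains = "G1"),              # strain-specific
    list(template = "hyHK",     gains = c("G2", "G5"))      # independent gains
  ),
  duplications = list(list(genome = "G1", family = 8, divergence = 0)),
  seed = 1L)

pan <- generate_panel(ps)

for (g in names(pan$genomes)) {
  gen <- c(pan$genomes[[g]], list(truth = list()))
  write_genome_inputs(list(proteins = pan$genomes[[g]]$proteins,
                           domains = pan$genomes[[g]]$domains,
                           truth = pan$truth$membership[
                             pan$truth$membership$genome_id == g, ]),
                      out_dir, prefix = g)
}
write_ani_matrix(pan$ani, file.path(out_dir, "ani_matrix.tsv"))
ape::write.tree(pan$tree, file.path(out_dir, "guide_tree.nwk"))
jsonlite::write_json(
  list(presence = as.data.frame(pan$truth$presence),
       events = pan$truth$events,
       n_core = pan$truth$n_core),
  file.path(out_dir, "panel_truth.json"), auto_unbox = TRUE, pretty = TRUE)

# a separate single genome with planted multi-gene clusters
ctx <- generate_genome(genome_spec(
  "GCTX",
  clusters = list("cHK", "RR", "RR_CheY", "hyHK",
                  c("cHK", "RR"), c("RR", "RR", "cHK"),
                  c("RR", "RR", "hyHK", "hyHK", "hyHK")),
  seed = 2L))
write_genome_inputs(ctx, out_dir, prefix = "GCTX")

n_tcs <- sum(pan$truth$presence) + 1L
message("simulated ", length(pan$genomes), "-genome panel with ",
        nrow(pan$truth$presence), " planted families (", n_tcs,
        " TCS genes incl. 1 duplicate) plus a cluster-bearing genome; ",
        "inputs under ", out_dir)
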