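# tcscensus

A genomic census of **two-component signal transduction systems (TCS)** for
bacterial genome panels, built for the scale and questions of thermophilic
cyanobacteria surveys (panels of ~2.5–8 Mb genomes carrying 40–240 TCS genes
each).

A TCS couples a sensor **histidine kinase (HK)** — autophosphorylating on a
conserved His via its HisKA + HATPase transmitter module — to a **response
regulator (RR)** that receives the phosphate on the Asp of its receiver (REC)
domain and acts through an output domain. From per-genome domain annotations
(which this package consumes, not computes), `tcscensus` derives the census
layers such surveys report:

* **Classification** — a deterministic decision ladder over ordered domain
  roles: classic HK (`cHK`, ≥1 HisKA+HATPase transmitter unit), hybrid HK
  (`hyHK`, transmitter + REC), unorthodox HK (transmitter + REC + Hpt),
  CheA-type chemotaxis kinase (HATPase + Hpt + CheW, no HisKA), RR (REC, no
  HATPase), and phosphotransfer proteins (stand-alone HisKA or Hpt), with the
  incomplete-HK rescue: a lone HisKA adjacent to another TCS gene counts as a
  cHK. RRs are assigned output families (CheY, NarL, OmpR, CheB, RpfG, PleD,
  PleD-VieA, RsbU, TrxB, YesN, CyC-C) and HKs a cytosolic/membrane call from
  a Kyte–Doolittle transmembrane screen (window 19, cutoff 1.6).
* **Genomic context** — orphan/paired/complex clusters: consecutive TCS genes
  chain when the intergenic distance is < 200 bp, orientations are the same
  or divergent (convergent `→ ←` excluded), and no other gene intervenes;
  composition strings like `RR-RR-hyHK-hyHK-hyHK` come out in genomic order.
* **Census statistics** — per-genome category counts, ORF fractions
  (100·TCS/CDS), and the receiver/transmitter ratio
  `Σ REC(RRs, hyHKs) / Σ transmitters(cHKs, hyHKs)`, plus sensing-domain and
  domain-architecture tallies (architectures as S/T/R token strings) and RR
  family tables.
* **Orthology** — exact Smith–Waterman alignment (BLOSUM62, gap 11/1),
  bidirectional best hits at identity > 40% and query coverage > 75%,
  ortholog families as connected components, the core / accessory /
  strain-specific partition, and within-genome duplication flagging.
* **Gain/loss inference** — a UPGMA tree from a 100 − ANI distance matrix and
  per-family minimum-cost ancestral reconstruction (Sankoff DP; gain 2,
  loss 1, absent root prior), with per-branch event summaries.
* **Synthetic genomes** — a generator planting TCS content, cluster
  structure, divergence and gain/loss histories with truth records, so every
  stage is testable without downloads.

## Worked example

Simulate a four-genome panel with four core families and one accessory
family gained on an internal branch, then run the full census:

```r
library(tcscensus)

pan <- generate_panel(panel_spec(
  "((A:0.04,B:0.04):0.03,(C:0.04,D:0.04):0.03);",
  core = c("cHK", "hyHK", "RR", "RR_CheY"),
  accessory = list(list(template = "RR_NarL", gains = "node6")),
  seed = 1))
res <- run_tcs_census(pan$genomes, ani = pan$ani)

res$genome_summary[, c("genome_id", "cHK", "hyHK", "RR", "total_tcs", "rt_ratio")]
#>   genome_id cHK hyHK RR total_tcs rt_ratio
#> 1         A   1    1  3         5      2.0
#> 2         B   1    1  3         5      2.0
#> 3         C   1    1  2         4      1.5
#> 4         D   1    1  2         4      1.5
```

Each genome carries its planted counts; the receiver/transmitter ratio for
A is (3 RR RECs + 1 hyHK REC) / (1 cHK + 1 hyHK transmitter) = 4/2 = 2.0.
The orthology layer recovers the planted partition and the parsimony layer
places the accessory family's single gain on the A/B stem:

```r
res$orthology$summary[, c("core_families", "accessory_families", "core_gene_pct")]
#>   core_families accessory_families core_gene_pct
#> 1             4                  1          88.9

ape::write.tree(res$tree)
#> [1] "((A:4,B:4):3,(C:4,D:4):3);"

subset(res$events_summary$per_branch, gains + losses > 0)
#>   branch gains losses
#> 5   root     4      0
#> 6  node6     1      0
```

The four root-branch gains are the core families (the root prior is
"absent", so a family conserved across the panel is explained by one
ancestral gain); `node6` is the A/B ancestor.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_panel.R` … `06_gainloss.R`); run them in order from the
repository root to regenerate the tables under `results/`. The bundled
reference counts for the 17-genome thermophilic cyanobacteria panel are
available via `thermophile_reference_tables()`.

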