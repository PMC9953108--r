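---
title: "Methods: a rule-based census of two-component signal transduction systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based census of two-component signal transduction systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcscensus)
```

## Scope and model

Two-component systems (TCS) are the dominant signal-transduction modules of
bacteria: a sensor histidine kinase (HK) autophosphorylates on a conserved
histidine of its HisKA (dimerization/phosphoacceptor) domain using the
HATPase catalytic domain, and transfers the phosphate to the aspartate of a
receiver (REC) domain on a response regulator (RR), whose output domain then
effects the response. `tcscensus` implements a genome-panel census of these
proteins from *pre-computed domain annotations*: it does not call genes or
run HMM scans, it consumes per-genome protein FASTA, gene coordinates and
domain-hit tables, and produces the classification, genomic-organization,
domain-architecture, orthology and gain/loss layers of such a census. The
intended panel scale is tens of genomes of the size typical for
thermophilic cyanobacteria (2.5–8 Mb, 40–240 TCS genes each).

## Classification rules

Domain hits are first reduced to an ordered role string per protein
(`canonicalize()`): hits with e-value above the inclusion threshold
(default `1e-4`) are dropped, overlapping hits are resolved greedily by
descending bit-score (a hit loses when it overlaps an accepted hit by more
than half the shorter hit's length), and survivors are ordered N→C. Raw
domain names map to canonical roles through an overridable vocabulary
(`default_vocabulary()`); the shipped table covers the common Pfam names
(HisKA/HisKA_2/HisKA_3 → HISKA, HATPase_c → HATPASE, Response_reg → REC,
Hpt, CheW, the sensing families PAS/PAC, HAMP, GAF, PHY, CHASE, MASE,
Cache, cNMP_binding, S_TKc, NIT, FHA, CBS, Pkinase, and the RR output
families). PAS and PAC share one tag, as the two are conventionally counted
jointly; S_TKc and Pkinase are kept distinct.

`classify()` is a total, deterministic decision ladder. A *transmitter
unit* is a HISKA with an HATPASE downstream of it before the next HISKA:

1. ≥ 1 transmitter unit — with ≥ 1 REC and an Hpt: unorthodox HK; with
   ≥ 1 REC: hybrid HK (hyHK); otherwise classic HK (cHK).
2. HATPase + Hpt + CheW without HisKA: CheA-type chemotaxis kinase.
3. ≥ 1 REC without HATPase: response regulator.
4. Lone HisKA: rescued to cHK when its gene neighbours another TCS gene,
   otherwise a phosphotransfer protein (PP). "Neighbours" re-uses the
   clustering rules below (immediately adjacent CDS, gap < 200 bp,
   orientation-compatible) — the rescue criterion is stated in the
   literature only as adjacency, so the package anchors it to its own
   distance rule rather than inventing a second threshold.
5. Lone Hpt: PP.
6. Otherwise not a TCS protein.

The unorthodox category (transmitter + REC + Hpt on one chain) follows
standard usage; no formal definition exists in the source literature for
this panel, so it is an explicit modelling assumption.

RR output families (`rr_family()`): a REC-only protein is a stand-alone
receiver (CheY family); otherwise the family comes from the first output
role C-terminal of the first REC (NarL, OmpR, CheB, RpfG, PleD, RsbU,
TrxB, YesN, CyC-C). A protein carrying both diguanylate-cyclase (GGDEF)
and phosphodiesterase (EAL) outputs is the bifunctional PleD-VieA family;
outputs missing from the table give `Unclassified`. The RR column of the
genome summary includes the chemotaxis RRs (CheB), so family counts sum to
the RR total.

## Localization

The census labels an HK cytosolic exactly when it has no predicted
transmembrane segment. The predictor is a deliberate stand-in (the upstream
tool used for the published localization numbers is unstated): a
Kyte–Doolittle sliding window of 19 residues, window mean > 1.6 marking a
candidate, candidates closer than 5 residues merged, segments counted.
These are the classical single-helix screening parameters. When external
TM annotations exist they can be supplied as a seventh column of the
domain TSV and bypass prediction entirely. Non-standard residues get
hydropathy 0 with a warning.

## Genomic context

`build_clusters()` partitions each genome's TCS genes per contig: two
consecutive TCS genes chain when (i) the intergenic distance
`start_b − end_a − 1` is strictly less than 200 bp (overlaps count as
distance < 200), (ii) their orientations are the same or divergent — of
the four strand arrangements only convergent `→ ←` is excluded, the only
reading under which the stated rule excludes anything — and (iii) no
non-TCS gene lies between them (configurable off). The orientation rule is
applied pairwise along the chain, not to the whole cluster. Chains are
maximal, never span contigs, and form a partition: sizes 1–5 are
orphan/pair/triad/tetrad/pentad, larger chains are `complex-n`. The
composition string joins member labels in coordinate order
(`"RR-RR-cHK-RR"`).

## Census statistics

* ORF fraction: `100 · total_TCS / n_CDS`.
* Receiver/transmitter ratio: receivers are the REC domains of RRs and
  hyHKs; transmitters are the transmitter units of cHKs and hyHKs;
  unorthodox HKs and CheA are excluded on both sides. Counting is per
  domain, not per protein (a hyHK with three RECs contributes three). A
  zero denominator reports `NA`.
* Architecture strings reduce an HK N→C to `S` (any sensing domain), `T`
  (transmitter unit) and `R` (REC); tandem-repeat architectures with many
  sensing domains are representable without limit.
* All printed ratios and percentages round half-up to one decimal —
  matching the printed precision of the reference tables, where base R's
  round-half-to-even would disagree on exact .05 boundaries.
* The TCS-count/genome-size correlation uses the product-moment
  coefficient with the two-sided t-transform p-value (`stats::cor.test`).

The package bundles the printed per-genome category and organization
counts for a 17-genome thermophilic cyanobacteria panel
(`thermophile_reference_tables()`). These are *inputs*: the census
arithmetic recomputes totals, ratios and range statistics from them, and
the test suite asserts the recomputed values. The five mesophilic
reference genomes in the organization table are flagged
`group = "reference"` and excluded from range statistics, which are
defined over the thermophile panel.

## Orthology

Pairwise alignment is exact local (Smith–Waterman) alignment under
BLOSUM62 with affine gaps, open 11 / extend 1 — the BLASTP defaults —
delegated to `Biostrings::pairwiseAlignment` and cross-checked in the
test suite against a brute-force dynamic-programming oracle. Identity is
the percentage of identical aligned pairs over aligned *columns* (gap
columns in the denominator); query coverage is the percentage of query
residues inside the locally aligned region. Exact alignment replaces the
heuristic search of a production BLASTP because panel sizes here are
hundreds of proteins, where O(n²·L²) is entirely feasible; an adapter for
pre-computed tabular alignments is unnecessary at this scale.

Bidirectional best hits (`bbh()`) keep, for each query, the best-scoring
subject passing identity > 40% **and** query coverage > 75% (both
strict), with score ties broken by higher identity then lexicographically
smaller subject id; a pair survives iff reciprocal. Families
(`build_families()`) are connected components of the union reciprocal-hit
graph over all genome pairs — the weakest faithful formalization of "sets
of orthologous proteins", chosen over reference-anchored clustering
because no reference genome is singled out. Within-genome mutual best
hits passing the same thresholds are added as edges so that recent
paralogs co-cluster with their source family; without them a duplicate
can never join its family, since cross-genome best hits are unique.
`find_duplicates()` then flags within-genome family members at ≥ 95%
identity (configurable; 100% is the single-acquisition-then-duplication
signature). Families present in every genome are core, in ≥ 2 but not
all accessory, in one strain-specific; the core percentage is reported
over genes, not families.

## Tree and gain/loss inference

`upgma()` agglomerates the distance `100 − ANI` with size-weighted
arithmetic-mean linkage; a merge at distance d sits at height d/2, so the
tree is ultrametric by construction. Merge ties break deterministically
toward the pair containing the lexicographically smallest genome id. The
implementation is the package's own because the tie-break and exact d/2
heights are part of its determinism contract; it is cross-checked against
`phangorn::upgma` on random matrices in the tests.

Gain/loss inference (`infer_events()`) is minimum-cost binary ancestral
reconstruction by Sankoff dynamic programming with asymmetric costs:
absent→present (gain) costs 2, present→absent (loss) costs 1 by default,
and the root prior is *absent*, so every family pays for at least one
gain — core families take a single root-branch gain, mirroring the
framing of conserved families as ancestrally present, while accessory
families may prefer multiple independent terminal gains when cheaper than
one deep gain plus losses. The published account never states a formal
decision rule (events are described as "might be acquired/lost"); this
parsimony formalization is the package's own, and the penalty asymmetry
(acquisitions rarer than losses) is configurable — an infinite gain
penalty degenerates to Dollo parsimony. Cost ties resolve
deterministically by lexicographic minimisation of (cost, number of
gains, summed depth of event branches), i.e. toward fewer gains, then
toward events nearer the root. Replaying any event set from the root must
reproduce the leaf presences exactly; this is enforced as a hard
invariant at inference time.

## Synthetic data

`generate_genome()`/`generate_panel()` emulate the study conditions at
desk scale: genomes carry planted TCS loci with controlled domain
content, intergenic spacing, strand patterns, between-genome divergence
and planted gain/loss histories, with machine-readable truth records.
Design choices:

* Domain-hit rows are emitted directly from the architecture templates —
  the pipeline consumes annotation tables, so emulating an HMM scan would
  only add noise the classifier never sees. Sequence content matters only
  to alignment and TM prediction; sequences are random amino-acid strings
  (polar-biased, so spurious hydrophobic windows are rare) with a
  25-residue Leu/Ile/Val/Phe anchor for membrane templates.
* Family sequences evolve down the guide tree by i.i.d. substitutions
  with per-site probability `1 − exp(−t)` for branch length `t` (expected
  substitutions/site). Guide-tree depths around 0.05–0.1 put pairwise
  identities in the 75–95% band typical of congeneric strains — far above
  the 40% BBH floor — while depths ≳ 0.6 push pairs below the floor to
  exercise family splitting.
* The ANI matrix derives from cophenetic guide-tree distance t by the
  fixed monotone map `ANI = 100 − min(30, 100·t)` (cap 30, documented in
  the truth record). Only the ordering matters for UPGMA recovery.
* Within-cluster gaps default to 50–150 bp and between-locus gaps to
  300–800 bp with filler genes in between, so planted organization is
  unambiguous under the < 200 bp rule. Gaps are bounded below at −50 bp
  (mild overlaps).

What the generator does **not** emulate: codon-level evolution, indels,
rearrangements, annotation noise (wrong or missing domain calls),
contig fragmentation of clusters, or compositional bias. Passing the
recovery tests therefore demonstrates the correctness of the rules and
inference on clean annotations, not robustness to annotation error —
on real genomes the classifier is only as good as its domain table.

## Problem sizes and runtime choices

The test suite and the analysis scripts run at desk scale, chosen so the
full suite completes in well under a minute of alignment work: recovery
panels of 4–6 genomes with 60–85 planted TCS genes; exhaustive Sankoff
verification on all 63 presence vectors of 6-leaf trees against a
2^(internal nodes) enumeration oracle; 50 random ≤ 30-mer alignment pairs
against the DP oracle; 1,000 random gene layouts for the partition
identity. Determinism is end-to-end: generators take explicit seeds and
restore the caller's RNG state, and no pipeline stage uses randomness.

## Known limitations

* Classification quality is bounded by the input domain annotations; the
  package deliberately has no fallback homology search for missed
  domains (Hpt domains in particular are often under-annotated upstream).
* The TM predictor is a hydropathy heuristic, not a topology model; its
  per-protein counts should be treated as a cytosolic/membrane screen.
* Component-based families can chain distinct sub-families through an
  intermediate genome at panel scales far larger than studied here.
* The parsimony reconstruction reports one minimum-cost scenario under
  the documented tie-breaks; co-optimal scenarios are not enumerated.
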