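# Cross-genome orthology: pairwise local alignment, bidirectional best hits
# at fixed identity/coverage thresholds, ortholog-family construction as
# connected components of the reciprocal-hit graph, and the
# core/accessory/strain-specific partition of the panel.
#
# Alignments are exact Smith-Waterman (BLOSUM62, gap open 11 / extend 1 --
# the BLASTP defaults) via Biostrings; identity is percent identical residue
# pairs over aligned columns (gap columns count in the denominator), query
# coverage is the percent of query residues inside the aligned region.

#' Local alignment of two protein sequences
#'
#' @param a_seq query amino-acid string (non-empty).
#' @param b_seq subject amino-acid string (non-empty).
#' @return list: `score`, `identity` (percent), `query_coverage` (percent).
#'   A pair with no positive-scoring local alignment returns all zeros.
#' @export
align_pair <- function(a_seq, b_seq) {
  r <- align_many(a_seq, b_seq)
  list(score = r$score[1], identity = r$identity[1],
       query_coverage = r$query_coverage[1])
}

# Vectorised local alignment of many queries against one subject.
align_many <- function(a_seqs, b_seq) {
  if (any(!nzchar(a_seqs)) || !nzchar(b_seq))
    stop("alignment requires non-empty sequences")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a_seqs), b_seq, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  )
  score <- Biostrings::score(pa)
  cols <- nchar(as.character(Biostrings::pattern(pa)))  # aligned columns
  ident <- ifelse(cols > 0, 100 * Biostrings::nmatch(pa) / cols, 0)
  qwidth <- IRanges::width(Biostrings::pattern(pa))  # query residues aligned
  ngaps <- cols - qwidth
  qres <- qwidth  # width() of the pattern view is on the query
  cov <- 100 * (qres - 0) / nchar(a_seqs)
  # degenerate: empty alignment
  empty <- cols == 0 | score <= 0
  data.frame(score = ifelse(empty, 0, score),
             identity = ifelse(empty, 0, ident),
             query_coverage = ifelse(empty, 0, cov))
}

#' Bidirectional best hits between two genomes
#'
#' For every protein of genome A, the best hit in genome B by alignment score
#' among hits passing the thresholds (identity strictly greater than
#' `identity_min` AND query coverage strictly greater than `coverage_min`);
#' score ties are broken by higher identity, then lexicographically smaller
#' subject id. A pair is kept iff it is reciprocal.
#'
#' @param a,b data.frames with columns `protein_id` and `sequence`.
#' @param identity_min identity threshold in percent (default 40, strict).
#' @param coverage_min query-coverage threshold in percent (default 75,
#'   strict).
#' @return data.frame of reciprocal pairs: `a_id`, `b_id`, `score`,
#'   `identity_ab`, `identity_ba`.
#' @export
bbh <- function(a, b, identity_min = 40, coverage_min = 75) {
  stopifnot(nrow(a) >= 1, nrow(b) >= 1)
  na <- nrow(a); nb <- nrow(b)
  score_ab <- ident_ab <- cov_ab <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    r <- align_many(a$sequence, b$sequence[j])
    score_ab[, j] <- r$score
    ident_ab[, j] <- r$identity
    cov_ab[, j] <- r$query_coverage
  }
  # reverse direction: identity/score symmetric, but query coverage is not
  cov_ba <- matrix(0, nb, na)
  for (i in seq_len(na)) {
    r <- align_many(b$sequence, a$sequence[i])
    cov_ba[, i] <- r$query_coverage
  }
  best_hit <- function(scores, idents, pass, ids) {
    # returns index of best passing hit or NA
    cand <- which(pass)
    if (!length(cand)) return(NA_integer_)
    o <- order(-scores[cand], -idents[cand], ids[cand])
    cand[o[1]]
  }
  best_ab <- integer(na)
  for (i in seq_len(na)) {
    pass <- ident_ab[i, ] > identity_min & cov_ab[i, ] > coverage_min
    best_ab[i] <- best_hit(score_ab[i, ], ident_ab[i, ], pass, b$protein_id)
  }
  best_ba <- integer(nb)
  for (j in seq_len(nb)) {
    pass <- ident_ab[, j] > identity_min & cov_ba[j, ] > coverage_min
    best_ba[j] <- best_hit(score_ab[, j], ident_ab[, j], pass, a$protein_id)
  }
  keep <- which(!is.na(best_ab) &
                  vapply(seq_len(na), function(i) {
                    j <- best_ab[i]
                    !is.na(j) && !is.na(best_ba[j]) && best_ba[j] == i
                  }, TRUE))
  data.frame(
    a_id = a$protein_id[keep],
    b_id = b$protein_id[best_ab[keep]],
    score = score_ab[cbind(keep, best_ab[keep])],
    identity_ab = ident_ab[cbind(keep, best_ab[keep])],
    coverage_ab = cov_ab[cbind(keep, best_ab[keep])],
    stringsAsFactors = FALSE
  )
}

# Within one genome, mutual best non-self hits passing the thresholds.
# These edges let recent paralogs (duplications) co-cluster with their
# source family, which cross-genome reciprocal hits alone cannot do.
within_genome_links <- function(g, identity_min, coverage_min) {
  n <- nrow(g)
  if (n < 2) return(character(0))
  score <- ident <- cov <- matrix(0, n, n)
  for (j in seq_len(n)) {
    r <- align_many(g$sequence, g$sequence[j])
    score[, j] <- r$score; ident[, j] <- r$identity; cov[, j] <- r$query_coverage
  }
  best <- integer(n)
  for (i in seq_len(n)) {
    pass <- ident[i, ] > identity_min & cov[i, ] > coverage_min
    pass[i] <- FALSE
    cand <- which(pass)
    if (!length(cand)) { best[i] <- NA_integer_; next }
    o <- order(-score[i, cand], -ident[i, cand], g$protein_id[cand])
    best[i] <- cand[o[1]]
  }
  edges <- character(0)
  for (i in seq_len(n)) {
    j <- best[i]
    if (!is.na(j) && !is.na(best[j]) && best[j] == i && i < j)
      edges <- c(edges, g$uid[i], g$uid[j])
  }
  edges
}

#' Build ortholog families across a genome panel
#'
#' Runs [bbh()] over every genome pair and takes connected components of the
#' union reciprocal-hit graph as ortholog families; within-genome mutual
#' best hits passing the same thresholds are added as edges so that recent
#' paralogs co-cluster with their source family. Proteins without any
#' reciprocal hit form singleton families.
#'
#' @param tcs_panel classified protein table over >= 2 genomes (TCS rows
#'   only are used: `category != "NONE"`); needs `protein_id`, `genome_id`,
#'   `sequence`.
#' @param identity_min,coverage_min BBH thresholds (see [bbh()]).
#' @return list: `families` (data.frame `family_id`, `uid`, `genome_id`,
#'   `protein_id`), `presence` (families x genomes 0/1 matrix), `summary`
#'   ([partition_summary()] output).
#' @export
build_families <- function(tcs_panel, identity_min = 40, coverage_min = 75) {
  panel <- tcs_panel[tcs_panel$category != "NONE", , drop = FALSE]
  stopifnot(nrow(panel) > 0)
  panel$uid <- paste(panel$genome_id, panel$protein_id, sep = ":")
  genomes <- sort(unique(panel$genome_id))
  edges <- character(0)
  if (length(genomes) >= 2) {
    for (gi in seq_along(genomes)[-length(genomes)]) {
      for (gj in (gi + 1):length(genomes)) {
        a <- panel[panel$genome_id == genomes[gi], , drop = FALSE]
        b <- panel[panel$genome_id == genomes[gj], , drop = FALSE]
        hits <- bbh(a, b, identity_min, coverage_min)
        if (nrow(hits)) {
          edges <- c(edges, rbind(paste(genomes[gi], hits$a_id, sep = ":"),
                                  paste(genomes[gj], hits$b_id, sep = ":")))
        }
      }
    }
  }
  for (g in genomes) {
    gdf <- panel[panel$genome_id == g, , drop = FALSE]
    edges <- c(edges, within_genome_links(gdf, identity_min, coverage_min))
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(panel$uid)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  membership <- comp$membership[panel$uid]
  # deterministic family ids: order components by smallest member uid
  fam_key <- tapply(panel$uid, membership, min)
  fam_rank <- rank(fam_key)
  fam_id <- sprintf("fam%03d", fam_rank[as.character(membership)])
  families <- data.frame(
    family_id = fam_id, uid = panel$uid,
    genome_id = panel$genome_id, protein_id = panel$protein_id,
    stringsAsFactors = FALSE
  )
  families <- families[order(families$family_id, families$uid), , drop = FALSE]
  rownames(families) <- NULL
  presence <- presence_matrix(families, genomes)
  list(families = families, presence = presence,
       summary = partition_summary(families, genomes))
}

#' Presence/absence matrix of families over genomes
#'
#' @param families family table ([build_families()]`$families`).
#' @param genome_ids genome panel (columns).
#' @return 0/1 integer matrix, families x genomes.
#' @export
presence_matrix <- function(families, genome_ids) {
  fams <- sort(unique(families$family_id))
  m <- matrix(0L, length(fams), length(genome_ids),
              dimnames = list(fams, genome_ids))
  m[cbind(families$family_id, families$genome_id)] <- 1L
  m
}

#' Core / accessory / strain-specific partition
#'
#' A family is core when present in every genome of the panel, accessory when
#' present in at least two but not all, and strain-specific when confined to
#' a single genome. Gene counts follow family membership; the core percentage
#' is `100 * core_genes / total_genes` (half-up, 1 decimal).
#'
#' @param families family table.
#' @param genome_ids genome panel.
#' @return one-row data.frame: family and gene counts per class, `total_genes`
#'   and `core_gene_pct`.
#' @export
partition_summary <- function(families, genome_ids) {
  n_gen <- length(genome_ids)
  by_fam <- split(families$genome_id, families$family_id)
  n_present <- vapply(by_fam, function(g) length(unique(g)), 0L)
  cls <- ifelse(n_present == n_gen & n_gen > 1, "core",
                ifelse(n_present >= 2, "accessory", "strain_specific"))
  sizes <- vapply(by_fam, length, 0L)
  genes <- function(k) sum(sizes[cls == k])
  fams <- function(k) sum(cls == k)
  total <- sum(sizes)
  data.frame(
    core_families = fams("core"), accessory_families = fams("accessory"),
    strain_specific_families = fams("strain_specific"),
    core_genes = genes("core"), accessory_genes = genes("accessory"),
    strain_specific_genes = genes("strain_specific"),
    total_genes = total,
    core_gene_pct = round_half_up(100 * genes("core") / total, 1),
    stringsAsFactors = FALSE
  )
}

#' Family classes per family
#'
#' @param families family table.
#' @param genome_ids genome panel.
#' @return named character vector family_id -> class.
#' @export
family_classes <- function(families, genome_ids) {
  n_gen <- length(genome_ids)
  by_fam <- split(families$genome_id, families$family_id)
  n_present <- vapply(by_fam, function(g) length(unique(g)), 0L)
  stats::setNames(
    ifelse(n_present == n_gen & n_gen > 1, "core",
           ifelse(n_present >= 2, "accessory", "strain_specific")),
    names(by_fam)
  )
}

#' Flag putative within-genome duplications
#'
#' Within each family and genome, member pairs whose alignment identity is at
#' least `identity_min` are flagged as putative duplications (a pair at 100%
#' identity is the single-acquisition-then-duplication signature).
#'
#' @param families family table.
#' @param tcs_panel classified panel with sequences (`genome_id`,
#'   `protein_id`, `sequence`).
#' @param identity_min flagging threshold in percent (default 95, inclusive).
#' @return data.frame `family_id`, `genome_id`, `protein_a`, `protein_b`,
#'   `identity`.
#' @export
find_duplicates <- function(families, tcs_panel, identity_min = 95) {
  seqs <- stats::setNames(tcs_panel$sequence,
                          paste(tcs_panel$genome_id, tcs_panel$protein_id, sep = ":"))
  out <- list()
  for (fid in unique(families$family_id)) {
    f <- families[families$family_id == fid, , drop = FALSE]
    for (g in unique(f$genome_id)) {
      ids <- f$uid[f$genome_id == g]
      if (length(ids) < 2) next
      for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
        r <- align_pair(seqs[[ids[i]]], seqs[[ids[j]]])
        if (r$identity >= identity_min) {
          out[[length(out) + 1L]] <- data.frame(
            family_id = fid, genome_id = g,
            protein_a = ids[i], protein_b = ids[j],
            identity = r$identity, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(family_id = character(), genome_id = character(),
                      protein_a = character(), protein_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
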