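test_that("self-alignment and dissimilar peptides hit the identity/coverage bounds", {
  with_seed(12, {
    s <- random_aa(100)
    r <- align_pair(s, s)
    expect_equal(r$identity, 100)
    expect_equal(r$query_coverage, 100)
    expect_gt(r$score, 0)
  })
  r0 <- align_pair("WWWW", "DDDD")
  expect_equal(r0$score, 0)
  expect_equal(r0$identity, 0)
  expect_equal(r0$query_coverage, 0)
  expect_error(align_pair("", "MKT"), "non-empty")
})

test_that("planted mismatches give the expected identity and a hand-summed score", {
  with_seed(34, {
    a <- random_aa(40)
    b <- a
    # plant 4 conservative-but-different residues away from the ends
    pos <- c(8, 17, 26, 35)
    av <- strsplit(a, "")[[1]]
    bv <- av
    for (p in pos) bv[p] <- if (av[p] == "K") "R" else "K"
    b <- paste(bv, collapse = "")
    r <- align_pair(a, b)
    blosum <- get_blosum62()
    hand_score <- sum(vapply(1:40, function(i) blosum[av[i], bv[i]], 0))
    # the ungapped full-length alignment is optimal for near-identical pairs
    expect_equal(r$identity, 90)
    expect_equal(r$query_coverage, 100)
    expect_equal(r$score, hand_score)
  })
})

test_that("alignment scores match a brute-force affine-gap DP oracle", {
  with_seed(56, {
    for (i in 1:20) {
      a <- random_aa(sample(5:30, 1))
      b <- random_aa(sample(5:30, 1))
      expect_equal(align_pair(a, b)$score, sw_oracle(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("alignment is symmetric in score and identity", {
  with_seed(78, {
    for (i in 1:10) {
      a <- random_aa(sample(10:60, 1))
      b <- random_aa(sample(10:60, 1))
      ra <- align_pair(a, b); rb <- align_pair(b, a)
      expect_equal(ra$score, rb$score)
      expect_equal(ra$identity, rb$identity)
    }
  })
})

test_that("bbh pairs a duplicated panel one-to-one and applies strict thresholds", {
  with_seed(90, {
    a <- data.frame(protein_id = paste0("a", 1:5),
                    sequence = vapply(1:5, function(i) random_aa(80), ""),
                    stringsAsFactors = FALSE)
    b <- a; b$protein_id <- paste0("b", 1:5)
    hits <- bbh(a, b)
    expect_equal(nrow(hits), 5)
    expect_equal(sub("a", "", hits$a_id), sub("b", "", hits$b_id))
    expect_true(all(hits$identity_ab == 100))
    # thresholds are strict: a best hit exactly at the bound is excluded
    one <- a[1, , drop = FALSE]
    partner <- b[1, , drop = FALSE]
    id_obs <- align_pair(one$sequence, partner$sequence)$identity
    expect_equal(nrow(bbh(one, partner, identity_min = id_obs)), 0)
    expect_equal(nrow(bbh(one, partner, identity_min = id_obs - 1e-9)), 1)
    cov_obs <- align_pair(one$sequence, partner$sequence)$query_coverage
    expect_equal(nrow(bbh(one, partner, coverage_min = cov_obs)), 0)
  })
})

test_that("families equal a brute-force reciprocal-best-hit closure on a small panel", {
  ps <- panel_spec("((A:0.06,B:0.06):0.04,C:0.1);",
                   core = c("cHK", "RR_CheY", "RR"),
                   accessory = list(list(template = "hyHK", gains = "node5")),
                   seed = 21)
  pan <- generate_panel(ps)
  tcs <- do.call(rbind, lapply(names(pan$genomes), function(g)
    classify_proteins(pan$genomes[[g]]$proteins, pan$genomes[[g]]$domains)))
  fams <- build_families(tcs)

  # brute-force oracle: all-pairs alignments, per-protein best passing hit,
  # reciprocal pairs, then transitive closure by union-find
  panel <- tcs[tcs$category != "NONE", ]
  panel$uid <- paste(panel$genome_id, panel$protein_id, sep = ":")
  n <- nrow(panel)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) { parent[find(i)] <<- find(j) }
  for (gi in unique(panel$genome_id)) for (gj in unique(panel$genome_id)) {
    if (gi >= gj) next
    ia <- which(panel$genome_id == gi); ib <- which(panel$genome_id == gj)
    best_ab <- sapply(ia, function(i) {
      sc <- sapply(ib, function(j) {
        r <- align_pair(panel$sequence[i], panel$sequence[j])
        if (r$identity > 40 && r$query_coverage > 75) r$score else -Inf
      })
      if (all(sc == -Inf)) NA else ib[which.max(sc)]
    })
    best_ba <- sapply(ib, function(j) {
      sc <- sapply(ia, function(i) {
        r <- align_pair(panel$sequence[j], panel$sequence[i])
        if (r$identity > 40 && r$query_coverage > 75) r$score else -Inf
      })
      if (all(sc == -Inf)) NA else ia[which.max(sc)]
    })
    for (k in seq_along(ia)) {
      j <- best_ab[k]
      if (!is.na(j) && !is.na(best_ba[match(j, ib)]) &&
          best_ba[match(j, ib)] == ia[k]) union(ia[k], j)
    }
  }
  oracle_groups <- split(panel$uid, vapply(seq_len(n), find, 0L))
  oracle_key <- sort(vapply(oracle_groups, function(x) paste(sort(x), collapse = ","), ""))
  found_key <- sort(vapply(split(fams$families$uid, fams$families$family_id),
                           function(x) paste(sort(x), collapse = ","), ""))
  expect_equal(unname(found_key), unname(oracle_key))
})

test_that("panel partition separates core, accessory and strain-specific families", {
  # identical genomes: everything core
  ps0 <- panel_spec("(A:0,B:0);", core = c("cHK", "RR", "RR_CheY"), seed = 8)
  pan0 <- generate_panel(ps0)
  tcs0 <- do.call(rbind, lapply(names(pan0$genomes), function(g)
    classify_proteins(pan0$genomes[[g]]$proteins, pan0$genomes[[g]]$domains)))
  f0 <- build_families(tcs0)
  expect_equal(f0$summary$core_gene_pct, 100)
  expect_equal(f0$summary$accessory_families, 0L)

  # one genome given one extra unique protein: exactly one strain-specific family
  ps1 <- panel_spec("(A:0.02,B:0.02);", core = c("cHK", "RR"),
                    accessory = list(list(template = "RR_NarL", gains = "A")),
                    seed = 9)
  pan1 <- generate_panel(ps1)
  tcs1 <- do.call(rbind, lapply(names(pan1$genomes), function(g)
    classify_proteins(pan1$genomes[[g]]$proteins, pan1$genomes[[g]]$domains)))
  f1 <- build_families(tcs1)
  expect_equal(f1$summary$strain_specific_families, 1L)
  expect_equal(f1$summary$core_families, 2L)
  cls <- family_classes(f1$families, c("A", "B"))
  expect_equal(sum(cls == "strain_specific"), 1L)
})

test_that("within-genome duplications are flagged at the identity threshold", {
  ps <- panel_spec("(A:0.03,B:0.03);", core = c("RR", "cHK"),
                   duplications = list(list(genome = "A", family = 1,
                                            divergence = 0.03)),
                   seed = 10)
  pan <- generate_panel(ps)
  tcs <- do.call(rbind, lapply(names(pan$genomes), function(g)
    classify_proteins(pan$genomes[[g]]$proteins, pan$genomes[[g]]$domains)))
  fams <- build_families(tcs)
  # measure the realised duplicate identity, then check both threshold sides
  dup_uid <- pan$truth$membership$uid[pan$truth$membership$duplicate]
  src_uid <- setdiff(pan$truth$membership$uid[
    pan$truth$membership$family_id == "pfam01" &
      pan$truth$membership$genome_id == "A"], dup_uid)
  seqs <- setNames(tcs$sequence, paste(tcs$genome_id, tcs$protein_id, sep = ":"))
  id_obs <- align_pair(seqs[[dup_uid]], seqs[[src_uid]])$identity
  expect_gt(id_obs, 90); expect_lt(id_obs, 100)
  flagged <- find_duplicates(fams$families, tcs, identity_min = id_obs - 1)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$genome_id, "A")
  not_flagged <- find_duplicates(fams$families, tcs, identity_min = id_obs + 0.5)
  expect_equal(nrow(not_flagged), 0)
  # identical duplicates are flagged at 100
  ps2 <- panel_spec("(A:0.03,B:0.03);", core = c("RR", "cHK"),
                    duplications = list(list(genome = "A", family = 1,
                                             divergence = 0)),
                    seed = 10)
  pan2 <- generate_panel(ps2)
  tcs2 <- do.call(rbind, lapply(names(pan2$genomes), function(g)
    classify_proteins(pan2$genomes[[g]]$proteins, pan2$genomes[[g]]$domains)))
  fams2 <- build_families(tcs2)
  fl2 <- find_duplicates(fams2$families, tcs2, identity_min = 100)
  expect_equal(nrow(fl2), 1)
  expect_equal(fl2$identity, 100)
})
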