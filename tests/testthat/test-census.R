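test_that("genome summary reproduces printed totals and ORF fractions", {
  # Leptodesmis A121 counts: total 131, 131/4917 -> 2.7%
  a121 <- category_count_fixture(cHK = 42, hyHK = 23, uHK = 1, CheA = 2,
                                 RR = 61, PP_HisKA = 1, PP_Hpt = 1)
  gs <- genome_summary(a121, n_cds = 4917, genome_size_mb = 5.35, genome_id = "A121")
  expect_equal(gs$total_tcs, 131L)
  expect_equal(gs$orf_fraction, 2.7)
  expect_equal(gs$cHK, 42L)
  expect_equal(gs$RR, 61L)

  # Thermosynechococcus BP-1: total 42, 42/2475 -> 1.7%
  bp1 <- category_count_fixture(cHK = 10, hyHK = 4, CheA = 3, RR = 23,
                                PP_HisKA = 1, PP_Hpt = 1)
  gs2 <- genome_summary(bp1, n_cds = 2475)
  expect_equal(gs2$total_tcs, 42L)
  expect_equal(gs2$orf_fraction, 1.7)

  empty <- category_count_fixture()
  gs3 <- genome_summary(empty, n_cds = 100)
  expect_equal(gs3$total_tcs, 0L)
  expect_equal(gs3$orf_fraction, 0)
  expect_error(genome_summary(empty, n_cds = 0), "positive")
})

test_that("receiver/transmitter ratios reproduce the printed per-genome values", {
  rt <- function(cHK, hyHK, RR)
    rt_ratio(category_count_fixture(cHK = cHK, hyHK = hyHK, RR = RR))
  expect_equal(rt(8, 3, 32), 3.2)    # PCC 6715: 35/11
  expect_equal(rt(51, 15, 46), 0.9)  # A183: 61/66
  expect_equal(rt(42, 23, 61), 1.3)  # A121: 84/65
  expect_equal(rt(5, 0, 0), 0)       # receivers absent
  expect_true(is.na(rt(0, 0, 10)))   # no transmitters: undefined
  # unorthodox HKs and CheA are excluded from both sides
  mixed <- rbind(category_count_fixture(cHK = 8, hyHK = 3, RR = 32),
                 category_count_fixture(uHK = 5, CheA = 4))
  expect_equal(rt_ratio(mixed), 3.2)
  # multi-REC hybrids contribute every REC
  multi <- category_count_fixture(cHK = 9, hyHK = 1, RR = 0)
  multi$n_rec[multi$category == "HYHK"] <- 3L
  expect_equal(rt_ratio(multi), 0.3)
})

test_that("organization summary aggregates cluster sizes to the printed totals", {
  jsc1 <- organization_count_fixture(orphan = 137, pair = 35, triad = 9,
                                     pentad = 1, genome_id = "JSC-1")
  org <- organization_summary(jsc1)
  expect_equal(org$total_tcs, 239L)
  expect_equal(org$orphan, 137L)
  expect_equal(org$pentad, 1L)
  single <- organization_summary(organization_count_fixture(orphan = 1))
  expect_equal(single$total_tcs, 1L)
  fr <- organization_fractions(org)
  expect_equal(fr$orphan_pct, 57.3)
  expect_equal(fr$paired_pct, 29.3)
})

test_that("sum over size classes always recovers the gene count", {
  with_seed(2718, {
    for (i in 1:50) {
      counts <- sample(0:12, 5, replace = TRUE)
      if (sum(counts) == 0) counts[1] <- 1
      fx <- organization_count_fixture(counts[1], counts[2], counts[3],
                                       counts[4], counts[5])
      org <- organization_summary(fx)
      expect_equal(org$total_tcs, sum(1:5 * counts))
    }
  })
})

test_that("sensing census counts domain occurrences split by HK class", {
  tcs <- data.frame(category = c("CHK", "HYHK", "RR"), stringsAsFactors = FALSE)
  tcs$sensing <- I(list(c("PAS", "PAS", "GAF"), "HAMP", "PAS"))
  sc <- sensing_census(tcs)
  expect_equal(sc$cHK[sc$tag == "PAS"], 2L)
  expect_equal(sc$hyHK[sc$tag == "PAS"], 0L)
  expect_equal(sc$cHK[sc$tag == "GAF"], 1L)
  expect_equal(sc$hyHK[sc$tag == "HAMP"], 1L)
  expect_false("RR" %in% tcs$category[tcs$category %in% sc$tag])
})

test_that("architecture strings reduce roles to sensing/transmitter/receiver tokens", {
  expect_equal(architecture_string(c("SENSING:GAF", "HISKA", "HATPASE")), "S-T")
  expect_equal(architecture_string(c("HISKA", "HATPASE", "REC")), "T-R")
  expect_equal(architecture_string(c("HISKA", "HATPASE")), "T")
  # 12 tandem HAMP-GAF repeats then transmitter + receiver: 24 sensing tokens
  big <- c(rep(c("SENSING:HAMP", "SENSING:GAF"), 12), "HISKA", "HATPASE", "REC")
  expect_equal(architecture_string(big),
               paste(c(rep("S", 24), "T", "R"), collapse = "-"))
  # two transmitters
  expect_equal(architecture_string(c("HISKA", "HATPASE", "HISKA", "HATPASE", "REC")),
               "T-T-R")
})

test_that("architecture census tallies distinct architectures and the no-sensing share", {
  tcs <- data.frame(category = c("CHK", "CHK", "HYHK", "RR"),
                    stringsAsFactors = FALSE)
  tcs$roles <- I(list(
    c("SENSING:PAS", "HISKA", "HATPASE"),
    c("HISKA", "HATPASE"),
    c("SENSING:PAS", "HISKA", "HATPASE", "REC"),
    "REC"))
  ac <- architecture_census(tcs)
  expect_equal(ac$n_hk, 3L)
  expect_equal(ac$n_distinct, 3L)
  expect_equal(ac$no_sensing_n, 1L)
  expect_equal(ac$no_sensing_pct, 33.3)
  expect_equal(ac$architectures$n[ac$architectures$architecture == "S-T"], 1L)
  expect_equal(sum(ac$architectures$n), 3L)
})

test_that("RR family table partitions the RR count", {
  g <- generate_genome(genome_spec("gF", clusters = list(
    "RR", "RR_CheY", "RR_NarL", "RR", "cHK"), seed = 3))
  cls <- classify_proteins(g$proteins, g$domains)
  tab <- rr_family_table(cls)
  expect_equal(sum(tab$n), sum(cls$category == "RR"))
  expect_equal(tab$n[tab$family == "OmpR"], 2L)
  expect_equal(tab$n[tab$family == "CheY"], 1L)
  expect_equal(tab$n[tab$family == "NarL"], 1L)
})

test_that("Pearson correlation matches direct arithmetic and cor.test", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, -1, -1, 1))$r, 0,
               tolerance = 1e-12)
  x2 <- c(2.3, 4.1, 5.9, 3.3, 8.8, 7.2, 1.1, 6.4, 9.5, 5.0)
  y2 <- c(1.2, 3.9, 4.1, 2.8, 9.9, 6.1, 0.4, 5.5, 8.7, 4.4)
  r_hand <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  pc <- pearson_cor(x2, y2)
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(pc$p, 2 * pt(abs(t_stat), df = 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(pearson_cor(rep(1, 5), 1:5), "variance")
})

test_that("reference tables are internally consistent (shared totals)", {
  ref <- thermophile_reference_tables()
  cats <- ref$counts
  t1_total <- rowSums(cats[, c("cHK", "hyHK", "uHK", "CheA", "RR",
                               "PP_HisKA", "PP_Hpt")])
  org <- ref$organization[ref$organization$group == "thermophile", ]
  t2_total <- org$orphan + 2 * org$pair + 3 * org$triad + 4 * org$tetrad +
    5 * org$pentad
  expect_equal(unname(t1_total), org$total_tcs)
  expect_equal(org$total_tcs, t2_total)
})
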