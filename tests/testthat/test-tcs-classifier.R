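hit <- function(name, s, e, score = 50, evalue = 1e-10) {
  data.frame(protein_id = "P", raw_name = name, ali_start = s, ali_end = e,
             score = score, evalue = evalue, stringsAsFactors = FALSE)
}

test_that("canonicalize orders hits, resolves overlaps greedily, filters by e-value", {
  h <- rbind(hit("HATPase_c", 200, 300), hit("Response_reg", 5, 115),
             hit("HisKA", 130, 195))
  expect_equal(canonicalize(h), c("REC", "HISKA", "HATPASE"))

  # two fully overlapping GAF hits: higher score wins, one role survives
  ov <- rbind(hit("GAF", 10, 100, score = 50), hit("GAF", 12, 98, score = 30))
  expect_equal(canonicalize(ov), "SENSING:GAF")

  # partial overlap below half the shorter hit keeps both
  part <- rbind(hit("PAS", 1, 60, score = 40), hit("GAF", 50, 140, score = 60))
  expect_equal(canonicalize(part), c("SENSING:PAS", "SENSING:GAF"))

  # e-value filter
  weak <- rbind(hit("HisKA", 1, 60), hit("HATPase_c", 70, 150, evalue = 1e-2))
  expect_equal(canonicalize(weak), "HISKA")
  expect_equal(canonicalize(weak, evalue_max = 1), c("HISKA", "HATPASE"))
  expect_equal(canonicalize(NULL), character())
})

test_that("canonicalized order equals coordinate order for any input permutation", {
  with_seed(421, {
    starts <- sort(sample(1:2000, 10)) * 3
    doms <- sample(c("PAS", "GAF", "HisKA", "HATPase_c", "Response_reg"),
                   10, replace = TRUE)
    h <- do.call(rbind, lapply(1:10, function(i)
      hit(doms[i], starts[i], starts[i] + 50, score = runif(1, 20, 90))))
    ref <- canonicalize(h)
    for (k in 1:8) {
      expect_equal(canonicalize(h[sample(10), ]), ref)
    }
  })
})

test_that("classification ladder assigns every category and is total", {
  expect_equal(classify(c("HISKA", "HATPASE"))$category, "CHK")
  expect_equal(classify(c("SENSING:GAF", "HISKA", "HATPASE", "REC"))$category, "HYHK")
  expect_equal(classify(c("HISKA", "HATPASE", "REC", "HPT"))$category, "UNORTHODOX_HK")
  expect_equal(classify(c("HPT", "HATPASE", "CHEW"))$category, "CHEA")
  expect_equal(classify("REC")$category, "RR")
  expect_equal(classify(c("REC", "REC", "OUTPUT:OmpR"))$n_rec, 2L)
  cls <- classify("HISKA", has_adjacent_tcs_gene = TRUE)
  expect_equal(cls$category, "CHK")
  expect_true(cls$hiska_rescue)
  expect_equal(classify("HISKA", has_adjacent_tcs_gene = FALSE)$category, "PP_HISKA")
  expect_equal(classify("HPT")$category, "PP_HPT")
  expect_equal(classify(character())$category, "NONE")
  expect_equal(classify(c("SENSING:PAS", "OTHER"))$category, "NONE")
  # a lone HATPase does not make a transmitter
  expect_equal(count_transmitters(c("HATPASE")), 0L)
  expect_equal(count_transmitters(c("HISKA", "HATPASE", "HISKA", "HATPASE")), 2L)
  expect_equal(count_transmitters(c("HISKA", "HISKA", "HATPASE")), 1L)
})

test_that("every role combination yields exactly one category", {
  pool <- c("HISKA", "HATPASE", "REC", "HPT", "CHEW", "SENSING:PAS", "OUTPUT:NarL")
  with_seed(77, {
    for (i in 1:200) {
      roles <- sample(pool, sample(0:6, 1), replace = TRUE)
      cls <- classify(roles)
      expect_true(cls$category %in% c("CHK", "HYHK", "UNORTHODOX_HK", "CHEA",
                                      "RR", "PP_HISKA", "PP_HPT", "NONE"))
    }
  })
})

test_that("RR output families follow the output-domain table", {
  expect_equal(rr_family("REC"), "CheY")
  expect_equal(rr_family(c("REC", "REC")), "CheY")
  expect_equal(rr_family(c("REC", "OUTPUT:OmpR")), "OmpR")
  expect_equal(rr_family(c("REC", "OUTPUT:NarL")), "NarL")
  expect_equal(rr_family(c("SENSING:PAS", "REC", "OUTPUT:RsbU")), "RsbU")
  # bifunctional c-di-GMP turnover: GGDEF + EAL on one protein
  expect_equal(rr_family(c("REC", "OUTPUT:PleD", "OUTPUT:EAL")), "PleD-VieA")
  expect_equal(rr_family(c("REC", "OUTPUT:PleD")), "PleD")
  # an output domain missing from the family table falls through
  expect_equal(rr_family(c("REC", "OUTPUT:EAL")), "Unclassified")
  expect_equal(rr_family(c("REC", "SENSING:GAF")), "Unclassified")
  expect_error(rr_family(c("HISKA", "HATPASE")), "response regulator")
})

test_that("hydropathy TM predictor counts merged hydrophobic segments", {
  expect_gte(tm_count(strrep("L", 30)), 1L)
  expect_equal(tm_count(strrep("D", 30)), 0L)
  two_block <- paste0(strrep("L", 25), strrep("S", 40), strrep("I", 25))
  expect_equal(tm_count(two_block), 2L)
  expect_equal(tm_count(two_block), kd_oracle(two_block))
  expect_warning(n <- tm_count(paste0(strrep("L", 25), "XXX")), "non-standard")
  expect_gte(n, 1L)
  expect_error(tm_count(""), "non-empty")
})

test_that("TM predictor agrees with a direct sliding-window computation", {
  with_seed(99, {
    for (i in 1:25) {
      len <- sample(20:400, 1)
      s <- random_aa(len)
      # sprinkle hydrophobic blocks into some sequences
      if (i %% 2 == 0) {
        pos <- sample(1:(len - 19), 1)
        substr(s, pos, pos + 18) <- strrep("L", 19)
      }
      expect_equal(tm_count(s), kd_oracle(s), info = paste("case", i))
    }
  })
})

test_that("localization follows the TM count", {
  expect_equal(localize(0), "cytosolic")
  expect_equal(localize(1), "membrane")
  expect_equal(localize(7), "membrane")
  expect_equal(localize(c(0, 2)), c("cytosolic", "membrane"))
})

test_that("classify_proteins recovers planted categories and applies the lone-HisKA rescue", {
  g <- generate_genome(genome_spec("gT", clusters = list(
    "cHK", c("RR", "hyHK"), "uHK", "CheA", "RR_CheY", "PP", "cHK_tm"), seed = 5))
  cls <- classify_proteins(g$proteins, g$domains)
  got <- cls[match(g$truth$proteins$protein_id, cls$protein_id), ]
  expect_equal(got$category, g$truth$proteins$category)
  # filler genes are NONE
  expect_true(all(cls$category[grepl("_f", cls$protein_id)] == "NONE"))
  # membrane-anchored template is membrane-localised, plain templates cytosolic
  expect_equal(cls$localization[cls$protein_id ==
    g$truth$proteins$protein_id[g$truth$proteins$template == "cHK_tm"]], "membrane")

  # lone HisKA next to an RR (within the distance rule) is rescued to cHK;
  # an isolated lone HisKA stays a phosphotransfer protein
  prot <- data.frame(
    protein_id = c("h1", "r1", "h2"), genome_id = "gR", contig_id = "c1",
    start = c(1000L, 1700L, 9000L), end = c(1600L, 2500L, 9600L),
    strand = "+", sequence = NA_character_, stringsAsFactors = FALSE)
  dom <- data.frame(
    protein_id = c("h1", "r1", "h2"),
    raw_name = c("HisKA", "Response_reg", "HisKA"),
    ali_start = c(10L, 10L, 10L), ali_end = c(70L, 70L, 70L),
    score = 50, evalue = 1e-9, stringsAsFactors = FALSE)
  cls2 <- classify_proteins(prot, dom)
  expect_equal(cls2$category[cls2$protein_id == "h1"], "CHK")
  expect_true(cls2$hiska_rescue[cls2$protein_id == "h1"])
  expect_equal(cls2$category[cls2$protein_id == "h2"], "PP_HISKA")
})

test_that("external TM annotations in the domain table override prediction", {
  fasta <- tempfile(fileext = ".faa")
  writeLines(c(">P1", strrep("L", 40)), fasta)
  coords <- tempfile(); writeLines("P1\tc1\t1\t120\t+", coords)
  doms <- tempfile()
  writeLines("P1\tResponse_reg\t2\t35\t80\t1e-12\t3", doms)
  inp <- read_genome_inputs(fasta, coords, doms)
  cls <- classify_proteins(inp$proteins, inp$domains)
  expect_equal(cls$tm_count, 3L)
  expect_equal(cls$localization, "membrane")
})
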