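# Reference census counts for the 17-genome thermophilic cyanobacteria
# panel (plus five mesophilic reference genomes for the organization table).
# These printed per-genome category and cluster counts are inputs to the
# summary-statistics layer: the package's arithmetic (totals, ORF fractions,
# receiver/transmitter ratios, organization fractions, range statistics) is
# checked against them.

#' Reference thermophilic-cyanobacteria census tables
#'
#' Loads the bundled per-genome TCS category counts (17 thermophilic
#' cyanobacteria: genome size, CDS count and counts of classic/hybrid/
#' unorthodox HKs, CheA kinases, RRs and phosphotransfer proteins) and the
#' genetic-organization table (cluster counts per size class; the five
#' mesophilic reference genomes are flagged `group = "reference"`).
#'
#' @return list with data.frames `counts` and `organization`.
#' @export
thermophile_reference_tables <- function() {
  counts <- utils::read.delim(
    system.file("extdata", "thermophile_tcs_counts.tsv", package = "tcscensus"),
    check.names = FALSE)
  organization <- utils::read.delim(
    system.file("extdata", "thermophile_tcs_organization.tsv", package = "tcscensus"),
    check.names = FALSE)
  list(counts = counts, organization = organization)
}

#' Expand printed category counts into a per-protein fixture table
#'
#' Builds the minimal classified-protein table implied by per-category
#' counts under the one-domain-per-protein convention: each RR carries one
#' REC, each hybrid HK one REC and one transmitter, each classic HK one
#' transmitter. This is the input convention for recomputing
#' receiver/transmitter ratios and summary totals from printed counts.
#'
#' @param cHK,hyHK,uHK,CheA,RR,PP_HisKA,PP_Hpt per-category gene counts.
#' @return data.frame with columns `category`, `n_rec`, `n_transmitter`.
#' @export
category_count_fixture <- function(cHK = 0, hyHK = 0, uHK = 0, CheA = 0,
                                   RR = 0, PP_HisKA = 0, PP_Hpt = 0) {
  cats <- c(rep("CHK", cHK), rep("HYHK", hyHK), rep("UNORTHODOX_HK", uHK),
            rep("CHEA", CheA), rep("RR", RR), rep("PP_HISKA", PP_HisKA),
            rep("PP_HPT", PP_Hpt))
  data.frame(
    category = cats,
    n_rec = as.integer(cats %in% c("RR", "HYHK", "UNORTHODOX_HK")),
    n_transmitter = as.integer(cats %in% c("CHK", "HYHK", "UNORTHODOX_HK")),
    stringsAsFactors = FALSE
  )
}

#' Expand printed organization counts into a cluster fixture table
#'
#' @param orphan,pair,triad,tetrad,pentad cluster counts per size class.
#' @param genome_id genome identifier attached to the fixture rows.
#' @return data.frame with `genome_id` and `size` columns, one row per
#'   cluster, suitable for [organization_summary()].
#' @export
organization_count_fixture <- function(orphan = 0, pair = 0, triad = 0,
                                       tetrad = 0, pentad = 0,
                                       genome_id = "genome") {
  sizes <- rep(1:5, times = c(orphan, pair, triad, tetrad, pentad))
  data.frame(genome_id = genome_id, size = sizes, stringsAsFactors = FALSE)
}
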