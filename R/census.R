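# Aggregation of classified proteins and clusters into per-genome summary
# tables: category counts, ORF fractions, receiver/transmitter ratios,
# genetic-organization counts, sensing-domain and architecture censuses, RR
# output-family tables, and the TCS-count vs genome-size correlation.

#' Per-genome summary of TCS gene content
#'
#' Counts per category, total TCS genes, the percentage of ORFs devoted to
#' TCS genes (`100 * total / n_cds`, half-up to 1 decimal) and the
#' receiver/transmitter ratio.
#'
#' @param tcs classified protein table ([classify_proteins()]) or a fixture
#'   with columns `category`, `n_rec`, `n_transmitter`.
#' @param n_cds number of protein-coding genes in the genome (> 0).
#' @param genome_size_mb genome size in Mb (optional, NA allowed).
#' @param genome_id genome identifier (defaults to the table's).
#' @return one-row data.frame: `genome_id`, `genome_size_mb`, `n_cds`,
#'   `cHK`, `hyHK`, `uHK`, `CheA`, `RR`, `PP_HisKA`, `PP_Hpt`, `total_tcs`,
#'   `orf_fraction`, `rt_ratio`.
#' @export
genome_summary <- function(tcs, n_cds, genome_size_mb = NA_real_,
                           genome_id = NULL) {
  if (is.na(n_cds) || n_cds <= 0) stop("n_cds must be a positive count")
  genome_id <- genome_id %||%
    (if (nrow(tcs) && !is.null(tcs$genome_id)) tcs$genome_id[1] else "genome")
  n <- function(cat) sum(tcs$category == cat)
  counts <- c(cHK = n("CHK"), hyHK = n("HYHK"), uHK = n("UNORTHODOX_HK"),
              CheA = n("CHEA"), RR = n("RR"), PP_HisKA = n("PP_HISKA"),
              PP_Hpt = n("PP_HPT"))
  total <- sum(counts)
  data.frame(
    genome_id = genome_id, genome_size_mb = genome_size_mb, n_cds = n_cds,
    as.list(counts), total_tcs = total,
    orf_fraction = round_half_up(100 * total / n_cds, 1),
    rt_ratio = rt_ratio(tcs),
    stringsAsFactors = FALSE
  )
}

#' Receiver/transmitter ratio
#'
#' Ratio of receiver domains (REC domains carried by RRs and hybrid HKs) to
#' transmitter units (HisKA + HATPase pairs carried by classic and hybrid
#' HKs), counted per domain (a multi-REC hybrid contributes each REC).
#' Unorthodox HKs and CheA-type kinases are excluded on both sides. Rounded
#' half-up to one decimal; a zero denominator yields `NA`.
#'
#' @param tcs table with columns `category`, `n_rec`, `n_transmitter`.
#' @return numeric ratio (1 decimal) or `NA`.
#' @export
rt_ratio <- function(tcs) {
  receivers <- sum(tcs$n_rec[tcs$category %in% c("RR", "HYHK")])
  transmitters <- sum(tcs$n_transmitter[tcs$category %in% c("CHK", "HYHK")])
  if (transmitters == 0) return(NA_real_)
  round_half_up(receivers / transmitters, 1)
}

#' Genetic-organization summary
#'
#' Counts of orphan/pair/triad/tetrad/pentad clusters (plus clusters larger
#' than 5) and the total number of TCS genes they contain
#' (`total = sum(size_k * count_k)`).
#'
#' @param clusters cluster table ([build_clusters()]), one genome.
#' @param genome_id genome identifier (defaults to the table's).
#' @return one-row data.frame: `genome_id`, `orphan`, `pair`, `triad`,
#'   `tetrad`, `pentad`, `complex_gt5`, `total_tcs`.
#' @export
organization_summary <- function(clusters, genome_id = NULL) {
  genome_id <- genome_id %||% (if (nrow(clusters)) clusters$genome_id[1] else "genome")
  sz <- clusters$size
  data.frame(
    genome_id = genome_id,
    orphan = sum(sz == 1), pair = sum(sz == 2), triad = sum(sz == 3),
    tetrad = sum(sz == 4), pentad = sum(sz == 5), complex_gt5 = sum(sz > 5),
    total_tcs = sum(sz),
    stringsAsFactors = FALSE
  )
}

#' Organization fractions
#'
#' Percentage of a genome's TCS genes that are orphans, members of pairs, or
#' members of complex (size > 2) clusters, half-up to 1 decimal.
#'
#' @param org one-or-more-row organization summary ([organization_summary()]).
#' @return data.frame with `genome_id`, `orphan_pct`, `paired_pct`,
#'   `complex_pct`.
#' @export
organization_fractions <- function(org) {
  genes_complex <- org$total_tcs - org$orphan - 2 * org$pair
  data.frame(
    genome_id = org$genome_id,
    orphan_pct = round_half_up(100 * org$orphan / org$total_tcs, 1),
    paired_pct = round_half_up(100 * 2 * org$pair / org$total_tcs, 1),
    complex_pct = round_half_up(100 * genes_complex / org$total_tcs, 1),
    stringsAsFactors = FALSE
  )
}

#' Sensing-domain census of histidine kinases
#'
#' Occurrence counts of each sensing-domain tag, split between classic and
#' hybrid HKs. Counts are domain occurrences, not proteins (a kinase with two
#' PAS domains contributes 2).
#'
#' @param tcs classified protein table.
#' @return data.frame with columns `tag`, `cHK`, `hyHK`, sorted by
#'   decreasing total then tag.
#' @export
sensing_census <- function(tcs) {
  hk <- tcs[tcs$category %in% c("CHK", "HYHK"), , drop = FALSE]
  tally <- function(cat) {
    tags <- unlist(hk$sensing[hk$category == cat], use.names = FALSE)
    table(factor(tags))
  }
  tc <- tally("CHK"); th <- tally("HYHK")
  tags <- sort(union(names(tc), names(th)))
  out <- data.frame(
    tag = tags,
    cHK = as.integer(tc[tags]), hyHK = as.integer(th[tags]),
    stringsAsFactors = FALSE
  )
  out$cHK[is.na(out$cHK)] <- 0L
  out$hyHK[is.na(out$hyHK)] <- 0L
  out[order(-(out$cHK + out$hyHK), out$tag), , drop = FALSE]
}

#' Reduce an ordered role string to an architecture token string
#'
#' Tokens, N-to-C: `S` for any sensing domain, `T` for a transmitter unit
#' (the HisKA..HATPase pair is consumed as one token; a lone rescued HisKA
#' also counts as the transmitter region), `R` for a receiver domain. Other
#' roles are ignored.
#'
#' @param roles role tokens in N-to-C order.
#' @return architecture string such as `"S-S-T-R"`.
#' @export
architecture_string <- function(roles) {
  base <- base_role(roles)
  tok <- character()
  i <- 1L
  while (i <= length(base)) {
    b <- base[i]
    if (b == "SENSING") {
      tok <- c(tok, "S")
    } else if (b == "REC") {
      tok <- c(tok, "R")
    } else if (b == "HISKA") {
      tok <- c(tok, "T")
      nxt_his <- which(base == "HISKA" & seq_along(base) > i)
      bound <- if (length(nxt_his)) nxt_his[1] - 1L else length(base)
      hat <- which(base == "HATPASE" & seq_along(base) > i & seq_along(base) <= bound)
      if (length(hat)) base[hat[1]] <- "CONSUMED"
    }
    i <- i + 1L
  }
  paste(tok, collapse = "-")
}

#' Domain-architecture census of histidine kinases
#'
#' Counts of distinct sensing/transmitter/receiver token strings
#' ([architecture_string()]) over classic and hybrid HKs, plus the number and
#' percentage of HKs containing no sensing domain.
#'
#' @param tcs classified protein table (one or more genomes).
#' @return list: `architectures` (data.frame `architecture`, `cHK`, `hyHK`,
#'   `n`), `n_distinct`, `n_hk`, `no_sensing_n`, `no_sensing_pct`.
#' @export
architecture_census <- function(tcs) {
  hk <- tcs[tcs$category %in% c("CHK", "HYHK"), , drop = FALSE]
  if (!nrow(hk)) {
    return(list(architectures = data.frame(architecture = character(),
                                           cHK = integer(), hyHK = integer(),
                                           n = integer()),
                n_distinct = 0L, n_hk = 0L, no_sensing_n = 0L,
                no_sensing_pct = NA_real_))
  }
  arch <- vapply(hk$roles, architecture_string, "")
  tab <- table(arch, factor(hk$category, levels = c("CHK", "HYHK")))
  out <- data.frame(
    architecture = rownames(tab),
    cHK = as.integer(tab[, "CHK"]), hyHK = as.integer(tab[, "HYHK"]),
    stringsAsFactors = FALSE
  )
  out$n <- out$cHK + out$hyHK
  out <- out[order(-out$n, out$architecture), , drop = FALSE]
  rownames(out) <- NULL
  no_sensing <- !grepl("S", arch, fixed = TRUE)
  list(architectures = out, n_distinct = nrow(out), n_hk = nrow(hk),
       no_sensing_n = sum(no_sensing),
       no_sensing_pct = round_half_up(100 * mean(no_sensing), 1))
}

#' RR output-family table
#'
#' Counts of response regulators per output family. Families sum to the RR
#' total of the genome.
#'
#' @param tcs classified protein table, one genome.
#' @return data.frame `family`, `n`, ordered by the canonical family list.
#' @export
rr_family_table <- function(tcs) {
  fam <- tcs$rr_family[tcs$category == "RR"]
  counts <- table(factor(fam, levels = RR_FAMILIES))
  data.frame(family = RR_FAMILIES, n = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between TCS gene number and genome size (or any
#' two numeric vectors), with the p-value from the t transform on n - 2
#' degrees of freedom ([stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
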