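# Genomic-context organization of TCS genes: orphan / paired / complex
# clusters built from intergenic distance, transcription orientation and
# contiguity rules.

CLUSTER_CATEGORIES <- c("orphan", "pair", "triad", "tetrad", "pentad")

#' Intergenic distance between two genes
#'
#' For gene `a` preceding gene `b` on the same contig (1-based inclusive
#' coordinates), the number of base pairs strictly between them:
#' `b_start - a_end - 1`. Overlapping genes give a negative value, which
#' always satisfies the "< 200 bp" clustering rule.
#'
#' @param a_end end coordinate of the upstream gene (or a protein row).
#' @param b_start start coordinate of the downstream gene.
#' @return integer distance in bp (vectorised).
#' @export
intergenic_distance <- function(a_end, b_start) {
  as.integer(b_start) - as.integer(a_end) - 1L
}

#' Orientation compatibility of two neighbouring genes
#'
#' Genes may be co-clustered when they lie in the same transcription
#' direction or point away from each other (divergent, `<- ->`); the
#' convergent arrangement (`-> <-`) is excluded. For upstream gene `a` and
#' downstream gene `b`: compatible unless `a` is `+` and `b` is `-`.
#'
#' @param strand_a strand of the upstream gene (`"+"` or `"-"`).
#' @param strand_b strand of the downstream gene.
#' @return logical (vectorised).
#' @export
orientation_compatible <- function(strand_a, strand_b) {
  !(strand_a == "+" & strand_b == "-")
}

#' Cluster-size category
#'
#' @param size cluster size (>= 1).
#' @return `"orphan"`, `"pair"`, `"triad"`, `"tetrad"`, `"pentad"` or
#'   `"complex-n"` for n > 5.
#' @export
cluster_category <- function(size) {
  ifelse(size <= 5, CLUSTER_CATEGORIES[pmax(size, 1)], paste0("complex-", size))
}

#' Composition string of a cluster
#'
#' Category labels of the members joined by hyphens in genomic order, e.g.
#' `"RR-RR-cHK-RR"`.
#'
#' @param labels character vector of member labels (`cHK`, `hyHK`, `uHK`,
#'   `CheA`, `RR`, `PP`) in coordinate order.
#' @return single string.
#' @export
composition <- function(labels) paste(labels, collapse = "-")

#' Partition a genome's TCS genes into clusters
#'
#' Per contig, genes are sorted by start coordinate and consecutive TCS genes
#' are chained when (i) their intergenic distance is strictly less than
#' `max_gap`, (ii) their orientations are compatible
#' ([orientation_compatible()]), and (iii) no non-TCS gene lies between them.
#' Chains are maximal; every TCS gene belongs to exactly one cluster and
#' singletons are orphans. The result is independent of input row order.
#'
#' @param tcs classified protein table ([classify_proteins()]); rows with
#'   `category == "NONE"` are the non-TCS genes used for rule (iii).
#' @param max_gap intergenic distance threshold in bp (strictly less-than;
#'   default 200).
#' @param break_on_intervening should an intervening non-TCS gene break a
#'   chain (default TRUE)?
#' @return data.frame with one row per cluster: `genome_id`, `contig_id`,
#'   `cluster_id`, list-column `members` (protein ids in genomic order),
#'   `size`, `category`, `composition`.
#' @export
build_clusters <- function(tcs, max_gap = 200, break_on_intervening = TRUE) {
  need <- c("protein_id", "genome_id", "contig_id", "start", "end", "strand",
            "category", "label")
  stopifnot(all(need %in% names(tcs)))
  ok <- !is.na(tcs$start) & !is.na(tcs$end)
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) without coordinates excluded from clustering")
    tcs <- tcs[ok, , drop = FALSE]
  }
  tcs <- tcs[order(tcs$contig_id, tcs$start, tcs$end, tcs$protein_id), , drop = FALSE]

  clusters <- list()
  for (contig in unique(tcs$contig_id)) {
    g <- tcs[tcs$contig_id == contig, , drop = FALSE]
    is_tcs <- g$category != "NONE"
    idx <- which(is_tcs)
    if (!length(idx)) next
    chain <- idx[1]
    flush <- function(chain) {
      clusters[[length(clusters) + 1L]] <<- data.frame(
        genome_id = g$genome_id[chain[1]],
        contig_id = contig,
        size = length(chain),
        category = cluster_category(length(chain)),
        composition = composition(g$label[chain]),
        members = I(list(g$protein_id[chain])),
        stringsAsFactors = FALSE
      )
    }
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        i <- idx[k - 1]; j <- idx[k]
        chainable <-
          intergenic_distance(g$end[i], g$start[j]) < max_gap &&
          orientation_compatible(g$strand[i], g$strand[j]) &&
          (!break_on_intervening || j == i + 1L)
        if (chainable) chain <- c(chain, j) else { flush(chain); chain <- j }
      }
    }
    flush(chain)
  }
  if (!length(clusters)) {
    return(data.frame(genome_id = character(), contig_id = character(),
                      cluster_id = character(), size = integer(),
                      category = character(), composition = character(),
                      members = I(list())))
  }
  out <- do.call(rbind, clusters)
  out$cluster_id <- paste0(out$genome_id, ":cl", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("genome_id", "contig_id", "cluster_id", "size", "category",
          "composition", "members")]
}

#' Write a clusters table to TSV
#'
#' @param clusters result of [build_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  flat <- clusters
  flat$members <- vapply(clusters$members, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
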