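# Rule-based classification of two-component-system proteins from canonical
# domain-role strings.
#
# Categories:
#   CHK            classic histidine kinase (>= 1 transmitter unit, no REC)
#   HYHK           hybrid HK (transmitter + >= 1 REC)
#   UNORTHODOX_HK  hybrid HK additionally carrying an Hpt domain
#   CHEA           chemotaxis-type kinase (HATPase + Hpt + CheW, no HisKA)
#   RR             response regulator (>= 1 REC, no HATPase)
#   PP_HISKA       phosphotransfer protein: stand-alone HisKA
#   PP_HPT         phosphotransfer protein: stand-alone Hpt
#   NONE           not a TCS protein
#
# A "transmitter unit" is a HisKA role with an HATPase role downstream of it
# before the next HisKA.

TCS_CATEGORIES <- c("CHK", "HYHK", "UNORTHODOX_HK", "CHEA", "RR",
                    "PP_HISKA", "PP_HPT", "NONE")

CATEGORY_LABELS <- c(CHK = "cHK", HYHK = "hyHK", UNORTHODOX_HK = "uHK",
                     CHEA = "CheA", RR = "RR", PP_HISKA = "PP", PP_HPT = "PP",
                     NONE = "none")

RR_FAMILIES <- c("CheY", "NarL", "OmpR", "CheB", "RpfG", "PleD", "PleD-VieA",
                 "RsbU", "TrxB", "YesN", "CyC-C", "Unclassified")

#' Resolve a protein's domain hits into an ordered role string
#'
#' Hits above the e-value inclusion threshold are dropped; overlapping hits
#' are resolved greedily by descending bit-score (a hit is discarded when it
#' overlaps an already-accepted hit by more than half the shorter hit's
#' length); survivors are ordered N-to-C by alignment start.
#'
#' @param hits data.frame of domain hits for a single protein (columns
#'   `raw_name`, `ali_start`, `ali_end`, `score`, `evalue`).
#' @param vocab domain vocabulary (see [default_vocabulary()]).
#' @param evalue_max inclusion threshold (default 1e-4).
#' @return character vector of role tokens ordered by position, e.g.
#'   `c("SENSING:PAS", "HISKA", "HATPASE")`.
#' @export
canonicalize <- function(hits, vocab = default_vocabulary(), evalue_max = 1e-4) {
  if (is.null(hits) || !nrow(hits)) return(character())
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(character())
  # greedy overlap resolution, best score first (ties: longer hit, then start)
  len <- hits$ali_end - hits$ali_start + 1L
  ord <- order(-hits$score, -len, hits$ali_start)
  hits <- hits[ord, , drop = FALSE]
  len <- len[ord]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$ali_end[i], hits$ali_end[j]) -
        max(hits$ali_start[i], hits$ali_start[j]) + 1L
      if (ov > 0 && ov > 0.5 * min(len[i], len[j])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$ali_start, hits$ali_end), , drop = FALSE]
  role_token(hits$raw_name, vocab)
}

base_role <- function(tokens) sub(":.*$", "", tokens)
token_tag <- function(tokens) ifelse(grepl(":", tokens), sub("^[^:]*:", "", tokens), "")

#' Count transmitter units in an ordered role string
#'
#' One transmitter unit = a HISKA role followed by an HATPASE role before the
#' next HISKA. A lone HATPase (no HisKA anywhere) does not form a transmitter.
#'
#' @param roles character vector of role tokens, N-to-C order.
#' @return integer count.
#' @export
count_transmitters <- function(roles) {
  base <- base_role(roles)
  his <- which(base == "HISKA")
  if (!length(his)) return(0L)
  hat <- which(base == "HATPASE")
  n <- 0L
  bounds <- c(his[-1] - 1L, length(base))
  for (k in seq_along(his)) {
    if (any(hat > his[k] & hat <= bounds[k])) n <- n + 1L
  }
  n
}

#' Classify an ordered role string into a TCS category
#'
#' Decision ladder:
#' 1. >= 1 transmitter unit: with >= 1 REC and >= 1 Hpt -> `UNORTHODOX_HK`;
#'    with >= 1 REC -> `HYHK`; otherwise `CHK`.
#' 2. HATPase + Hpt + CheW without HisKA -> `CHEA`.
#' 3. >= 1 REC and no HATPase -> `RR`.
#' 4. Lone HisKA (no HATPase): `CHK` when the gene neighbours another TCS
#'    gene (the incomplete-HK rescue), else `PP_HISKA`.
#' 5. Lone Hpt -> `PP_HPT`.
#' 6. Otherwise `NONE`.
#'
#' Classification is total and deterministic: exactly one category results.
#'
#' @param roles role tokens in N-to-C order (see [canonicalize()]).
#' @param has_adjacent_tcs_gene logical; is the encoding gene adjacent to
#'   another TCS gene (used only by the lone-HisKA rescue rule)?
#' @return list with `category`, `n_rec`, `n_transmitter`, `hiska_rescue`.
#' @export
classify <- function(roles, has_adjacent_tcs_gene = FALSE) {
  base <- base_role(roles)
  n_rec <- sum(base == "REC")
  n_tr <- count_transmitters(roles)
  has_hiska <- any(base == "HISKA")
  has_hat <- any(base == "HATPASE")
  has_hpt <- any(base == "HPT")
  has_chew <- any(base == "CHEW")
  rescue <- FALSE
  category <-
    if (n_tr >= 1) {
      if (n_rec >= 1 && has_hpt) "UNORTHODOX_HK"
      else if (n_rec >= 1) "HYHK"
      else "CHK"
    } else if (has_hat && has_hpt && has_chew && !has_hiska) {
      "CHEA"
    } else if (n_rec >= 1 && !has_hat) {
      "RR"
    } else if (has_hiska && !has_hat) {
      if (has_adjacent_tcs_gene) { rescue <- TRUE; "CHK" } else "PP_HISKA"
    } else if (has_hpt && length(roles) >= 1 && all(base %in% c("HPT", "SENSING", "OTHER"))) {
      "PP_HPT"
    } else {
      "NONE"
    }
  list(category = category, n_rec = n_rec, n_transmitter = n_tr,
       hiska_rescue = rescue)
}

#' Assign a response regulator to an output-domain family
#'
#' A REC-only protein is a stand-alone receiver (CheY family). Otherwise the
#' family comes from the first OUTPUT role C-terminal of the first REC; a
#' protein carrying both diguanylate-cyclase (GGDEF) and phosphodiesterase
#' (EAL) outputs is the bifunctional PleD-VieA family. Output domains not in
#' the family table give `Unclassified`.
#'
#' @param roles role tokens in N-to-C order; must classify as `RR`.
#' @return family name (one of the RR output families or `"Unclassified"`).
#' @export
rr_family <- function(roles) {
  base <- base_role(roles)
  if (!any(base == "REC") || any(base == "HATPASE"))
    stop("rr_family() requires a response regulator role string")
  if (all(base == "REC")) return("CheY")
  tags <- token_tag(roles)
  out_idx <- which(base == "OUTPUT")
  if (!length(out_idx)) return("Unclassified")
  out_tags <- tags[out_idx]
  if (all(c("PleD", "EAL") %in% out_tags)) return("PleD-VieA")
  first_rec <- which(base == "REC")[1]
  cterm <- out_idx[out_idx > first_rec]
  tag <- if (length(cterm)) tags[cterm[1]] else out_tags[1]
  if (tag %in% RR_FAMILIES) tag else "Unclassified"
}

#' Count putative transmembrane segments (Kyte-Doolittle stand-in)
#'
#' Sliding-window hydropathy predictor: window means over `window` residues
#' exceeding `threshold` mark candidate positions; candidate runs fewer than
#' `merge_gap` residues apart are merged and the number of merged segments is
#' returned. Non-standard residues contribute hydropathy 0 (with a warning).
#'
#' @param sequence amino-acid string.
#' @param window window length in residues (default 19).
#' @param threshold window-mean hydropathy cutoff (default 1.6).
#' @param merge_gap merge candidate runs separated by fewer than this many
#'   residues (default 5).
#' @return integer segment count.
#' @export
tm_count <- function(sequence, window = 19, threshold = 1.6, merge_gap = 5) {
  if (is.na(sequence) || !nzchar(sequence)) stop("tm_count() requires a non-empty sequence")
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  h <- unname(KD_SCALE[aa])
  if (anyNA(h)) {
    warning("non-standard residues in sequence; hydropathy 0 assumed")
    h[is.na(h)] <- 0
  }
  n <- length(h)
  if (n < window) return(0L)
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 1))
  starts <- which(means[window:n] > threshold)  # window start positions
  if (!length(starts)) return(0L)
  gaps <- diff(starts)
  sum(c(TRUE, gaps >= merge_gap))
}

#' Subcellular localization from transmembrane-segment count
#'
#' @param tm integer TM-segment count (>= 0).
#' @return `"cytosolic"` when 0, `"membrane"` otherwise.
#' @export
localize <- function(tm) {
  stopifnot(all(tm >= 0))
  ifelse(tm == 0, "cytosolic", "membrane")
}

#' Classify all proteins of one genome
#'
#' Applies [canonicalize()] and [classify()] to every protein, resolving the
#' lone-HisKA rescue rule in a second pass: a lone-HisKA protein is rescued to
#' classic HK when an immediately neighbouring CDS on the same contig is a TCS
#' gene (first-pass category other than `NONE`), lies closer than the cluster
#' gap threshold and is orientation-compatible. Transmembrane counts come from
#' the Kyte-Doolittle predictor unless the domain table carried external
#' overrides.
#'
#' @param proteins protein table (see [read_genome_inputs()]).
#' @param domains domain-hit table.
#' @param vocab domain vocabulary.
#' @param config [census_config()] object.
#' @return data.frame with one row per protein: coordinates, `category`,
#'   `label`, list-columns `roles` and `sensing`, `n_rec`, `n_transmitter`,
#'   `rr_family`, `tm_count`, `localization`, `hiska_rescue`.
#' @export
classify_proteins <- function(proteins, domains, vocab = default_vocabulary(),
                              config = census_config()) {
  stopifnot(all(c("protein_id", "contig_id", "start", "end", "strand") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id within genome")
  hits_by <- if (nrow(domains)) split(domains, domains$protein_id) else list()
  roles <- lapply(proteins$protein_id, function(id) {
    canonicalize(hits_by[[id]], vocab, evalue_max = config$domain_evalue_max)
  })
  first <- lapply(roles, classify, has_adjacent_tcs_gene = FALSE)
  cat1 <- vapply(first, `[[`, "", "category")

  # second pass: lone-HisKA rescue using first-pass TCS calls of neighbours
  is_tcs1 <- cat1 != "NONE"
  ord <- order(proteins$contig_id, proteins$start, proteins$end)
  pos <- match(seq_len(nrow(proteins)), ord)
  adjacent <- logical(nrow(proteins))
  for (i in which(cat1 == "PP_HISKA")) {
    k <- pos[i]
    for (dk in c(-1L, 1L)) {
      j <- if (k + dk >= 1 && k + dk <= length(ord)) ord[k + dk] else NA_integer_
      if (is.na(j) || proteins$contig_id[j] != proteins$contig_id[i] || !is_tcs1[j]) next
      a <- if (dk < 0) j else i
      b <- if (dk < 0) i else j
      gap <- intergenic_distance(proteins$end[a], proteins$start[b])
      if (gap < config$cluster_max_gap &&
          orientation_compatible(proteins$strand[a], proteins$strand[b])) {
        adjacent[i] <- TRUE
        break
      }
    }
  }
  final <- lapply(seq_along(roles), function(i)
    classify(roles[[i]], has_adjacent_tcs_gene = adjacent[i]))

  category <- vapply(final, `[[`, "", "category")
  n_rec <- vapply(final, `[[`, 0L, "n_rec")
  n_tr <- vapply(final, `[[`, 0L, "n_transmitter")
  rescue <- vapply(final, `[[`, FALSE, "hiska_rescue")
  sensing <- lapply(roles, function(r) token_tag(r)[base_role(r) == "SENSING"])
  fam <- rep(NA_character_, length(category))
  rr_idx <- which(category == "RR")
  if (length(rr_idx)) fam[rr_idx] <- vapply(roles[rr_idx], rr_family, "")

  tm_override <- attr(domains, "tm_override")
  tm <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$protein_id[i]
    if (!is.null(tm_override) && id %in% names(tm_override)) {
      tm[i] <- tm_override[[id]]
    } else if (!is.null(proteins$sequence) && !is.na(proteins$sequence[i]) &&
               nzchar(proteins$sequence[i]) && category[i] != "NONE") {
      tm[i] <- tm_count(proteins$sequence[i], window = config$tm_window,
                        threshold = config$tm_threshold,
                        merge_gap = config$tm_merge_gap)
    } else {
      tm[i] <- 0L
    }
  }

  out <- proteins
  out$category <- category
  out$label <- unname(CATEGORY_LABELS[category])
  out$roles <- I(roles)
  out$n_rec <- n_rec
  out$n_transmitter <- n_tr
  out$sensing <- I(sensing)
  out$rr_family <- fam
  out$tm_count <- tm
  out$localization <- localize(tm)
  out$hiska_rescue <- rescue
  out
}
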