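# Domain vocabulary: mapping from raw (Pfam/SMART-style) domain names onto the
# canonical roles used by the classifier.
#
# Roles:
#   HISKA    dimerization/phosphoacceptor domain of a histidine kinase
#   HATPASE  HK ATPase catalytic domain (one HISKA + downstream HATPASE = one
#            "transmitter" unit)
#   REC      receiver domain (phospho-accepting aspartate)
#   HPT      histidine phosphotransfer domain
#   CHEW     CheW docking module (chemotaxis kinases)
#   SENSING  input/sensing module; `tag` carries the family (PAS, GAF, ...)
#   OUTPUT   RR output/effector module; `tag` carries the family (OmpR, ...)
#   OTHER    recognised but unused

TCS_ROLES <- c("HISKA", "HATPASE", "REC", "HPT", "CHEW",
               "SENSING", "OUTPUT", "OTHER")

#' Default domain-name vocabulary
#'
#' Maps common Pfam domain names onto canonical two-component-system roles.
#' Sensing tags follow the families reported in cyanobacterial HK surveys
#' (PAS, HAMP, GAF, PHY, CHASE, MASE, Cache, cNMP_binding, S_TKc, NIT, FHA,
#' CBS, Pkinase); output tags follow the standard RR output families (NarL,
#' OmpR, CheB, RpfG, PleD, RsbU, TrxB, YesN, CyC-C; GGDEF + EAL on the same
#' protein yields the bifunctional PleD-VieA family). PAS and PAC map to the
#' same PAS tag, as the two are conventionally counted jointly.
#'
#' @return data.frame with columns `raw_name`, `role`, `tag`.
#' @export
default_vocabulary <- function() {
  v <- rbind(
    c("HisKA",          "HISKA",   ""),
    c("HisKA_2",        "HISKA",   ""),
    c("HisKA_3",        "HISKA",   ""),
    c("HATPase_c",      "HATPASE", ""),
    c("Response_reg",   "REC",     ""),
    c("Hpt",            "HPT",     ""),
    c("CheW",           "CHEW",    ""),
    # sensing modules
    c("PAS",            "SENSING", "PAS"),
    c("PAC",            "SENSING", "PAS"),
    c("PAS_3",          "SENSING", "PAS"),
    c("PAS_4",          "SENSING", "PAS"),
    c("PAS_9",          "SENSING", "PAS"),
    c("HAMP",           "SENSING", "HAMP"),
    c("GAF",            "SENSING", "GAF"),
    c("GAF_2",          "SENSING", "GAF"),
    c("PHY",            "SENSING", "PHY"),
    c("CHASE",          "SENSING", "CHASE"),
    c("CHASE2",         "SENSING", "CHASE"),
    c("CHASE3",         "SENSING", "CHASE"),
    c("MASE1",          "SENSING", "MASE"),
    c("MASE2",          "SENSING", "MASE"),
    c("Cache_1",        "SENSING", "Cache"),
    c("Cache_2",        "SENSING", "Cache"),
    c("cNMP_binding",   "SENSING", "cNMP_binding"),
    c("S_TKc",          "SENSING", "S_TKc"),
    c("NIT",            "SENSING", "NIT"),
    c("FHA",            "SENSING", "FHA"),
    c("CBS",            "SENSING", "CBS"),
    c("Pkinase",        "SENSING", "Pkinase"),
    # RR output modules
    c("GerE",           "OUTPUT",  "NarL"),
    c("Trans_reg_C",    "OUTPUT",  "OmpR"),
    c("CheB_methylest", "OUTPUT",  "CheB"),
    c("HD",             "OUTPUT",  "RpfG"),
    c("GGDEF",          "OUTPUT",  "PleD"),
    c("EAL",            "OUTPUT",  "EAL"),
    c("PP2C",           "OUTPUT",  "RsbU"),
    c("Pyr_redox",      "OUTPUT",  "TrxB"),
    c("Pyr_redox_2",    "OUTPUT",  "TrxB"),
    c("HTH_AraC",       "OUTPUT",  "YesN"),
    c("Guanylate_cyc",  "OUTPUT",  "CyC-C")
  )
  data.frame(raw_name = v[, 1], role = v[, 2], tag = v[, 3],
             stringsAsFactors = FALSE)
}

#' Read a vocabulary override file
#'
#' Tab-separated file `raw_name<TAB>role<TAB>tag` (header optional). Rows
#' override or extend the default vocabulary; a raw name may map to exactly
#' one role.
#'
#' @param path path to the TSV file.
#' @param base vocabulary to extend (default [default_vocabulary()]).
#' @return data.frame with columns `raw_name`, `role`, `tag`.
#' @export
read_vocabulary <- function(path, base = default_vocabulary()) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  if (ncol(raw) == 2) raw$V3 <- ""
  if (ncol(raw) < 2) stop("vocabulary file must have 2-3 tab-separated columns")
  raw <- raw[, 1:3]
  names(raw) <- c("raw_name", "role", "tag")
  if (identical(tolower(raw$raw_name[1]), "raw_name")) raw <- raw[-1, , drop = FALSE]
  raw$tag[is.na(raw$tag)] <- ""
  bad <- setdiff(unique(raw$role), TCS_ROLES)
  if (length(bad)) stop("unknown role(s) in vocabulary: ", paste(bad, collapse = ", "))
  out <- rbind(base[!base$raw_name %in% raw$raw_name, ], raw)
  if (anyDuplicated(out$raw_name))
    stop("duplicate raw_name in vocabulary: ",
         paste(unique(out$raw_name[duplicated(out$raw_name)]), collapse = ", "))
  rownames(out) <- NULL
  out
}

# Map raw domain names to role tokens ("HISKA", "SENSING:PAS", ...).
# Unknown names become "OTHER".
role_token <- function(raw_name, vocab) {
  i <- match(raw_name, vocab$raw_name)
  role <- ifelse(is.na(i), "OTHER", vocab$role[i])
  tag <- ifelse(is.na(i), "", vocab$tag[i])
  ifelse(tag == "", role, paste(role, tag, sep = ":"))
}
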