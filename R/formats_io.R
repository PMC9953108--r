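# Readers and writers for the pipeline's external formats:
#   - protein FASTA (Biostrings)
#   - gene coordinates: GFF3 CDS features (rtracklayer) or 5-column TSV
#   - domain hits: hmmscan --domtblout or 6/7-column TSV
#   - square ANI matrix TSV
#   - census result tables (TSV) + JSON run manifest
#
# Coordinates are 1-based inclusive throughout (GFF3 convention); the TSV
# dialects use the same convention.

#' Read per-genome inputs
#'
#' Joins a protein FASTA, a coordinate table and a domain-hit table on
#' `protein_id` into the protein/domain tables the pipeline consumes.
#'
#' @param fasta_path protein FASTA.
#' @param coords_path GFF3 file (`.gff`/`.gff3`, CDS features, `ID=` attribute
#'   used as protein id) or TSV with columns
#'   `protein_id, contig, start, end, strand`.
#' @param domains_path hmmscan `--domtblout` file or TSV with columns
#'   `protein_id, domain, ali_start, ali_end, score, evalue` (optional 7th
#'   column `tm_count` supplies external transmembrane-segment counts).
#' @param genome_id genome identifier attached to every record.
#' @param domain_coords `"env"` (envelope, default) or `"ali"` coordinates
#'   when parsing domtblout.
#' @return list with elements `proteins` (data.frame: protein_id, genome_id,
#'   contig_id, start, end, strand, sequence) and `domains` (data.frame:
#'   protein_id, raw_name, ali_start, ali_end, score, evalue). A named
#'   integer attribute `tm_override` on `domains` carries external TM counts
#'   when the 7-column dialect is used.
#' @export
read_genome_inputs <- function(fasta_path, coords_path, domains_path,
                               genome_id = "genome", domain_coords = c("env", "ali")) {
  domain_coords <- match.arg(domain_coords)
  for (p in c(fasta_path, coords_path, domains_path))
    if (!file.exists(p)) stop("input file not found: ", p)

  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seq_chr <- stats::setNames(as.character(seqs), ids)

  coords <- read_coords(coords_path)
  if (anyDuplicated(coords$protein_id))
    stop("duplicate protein_id in coordinate table: ",
         paste(unique(coords$protein_id[duplicated(coords$protein_id)]), collapse = ", "))
  missing <- !coords$protein_id %in% ids
  if (any(missing)) {
    warning(sum(missing), " coordinate row(s) with protein_id absent from FASTA skipped: ",
            paste(utils::head(coords$protein_id[missing], 5), collapse = ", "))
    coords <- coords[!missing, , drop = FALSE]
  }

  proteins <- data.frame(
    protein_id = coords$protein_id,
    genome_id = genome_id,
    contig_id = coords$contig_id,
    start = coords$start,
    end = coords$end,
    strand = coords$strand,
    sequence = unname(seq_chr[coords$protein_id]),
    stringsAsFactors = FALSE
  )

  domains <- read_domains(domains_path, domain_coords = domain_coords)
  unknown <- !domains$protein_id %in% proteins$protein_id
  if (any(unknown)) {
    warning(sum(unknown), " domain hit(s) for unknown protein_id skipped: ",
            paste(utils::head(unique(domains$protein_id[unknown]), 5), collapse = ", "))
    ov <- attr(domains, "tm_override")
    domains <- domains[!unknown, , drop = FALSE]
    attr(domains, "tm_override") <- ov
  }
  list(proteins = proteins, domains = domains)
}

# Coordinate table: GFF3 or 5-column TSV.
read_coords <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    if (!length(gr)) stop("no CDS features in GFF: ", path)
    id <- gr$ID
    if (is.null(id) || anyNA(id)) stop("GFF CDS features must carry an ID attribute: ", path)
    out <- data.frame(
      protein_id = as.character(id),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    lines <- read_text_lines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(parts)
    if (any(n < 5)) stop("coordinate TSV needs 5 columns (protein_id, contig, start, end, strand); line ",
                         which(n < 5)[1])
    m <- do.call(rbind, lapply(parts, function(p) p[1:5]))
    hdr <- tolower(m[1, 1]) %in% c("protein_id", "id")
    if (hdr) m <- m[-1, , drop = FALSE]
    out <- data.frame(
      protein_id = trimws(m[, 1]),
      contig_id = trimws(m[, 2]),
      start = as.integer(m[, 3]),
      end = as.integer(m[, 4]),
      strand = trimws(m[, 5]),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad))
    stop("invalid coordinates (start > end or non-numeric) at row ", bad[1],
         " of ", path)
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  out
}

# Domain hits: hmmscan --domtblout (>= 22 whitespace-separated fields) or
# 6/7-column TSV. For domtblout, hmmscan convention: target = domain model,
# query = protein; per-domain i-Evalue and domain score are used.
read_domains <- function(path, domain_coords = c("env", "ali")) {
  domain_coords <- match.arg(domain_coords)
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), raw_name = character(),
                      ali_start = integer(), ali_end = integer(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)

  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) >= 22) {
    # hmmscan --domtblout
    parts <- strsplit(trimws(lines), "\\s+")
    short <- which(lengths(parts) < 22)
    if (length(short)) stop("malformed domtblout line ", short[1], " in ", path)
    m <- do.call(rbind, lapply(parts, function(p) p[1:22]))
    from_col <- if (domain_coords == "env") 20L else 18L
    to_col <- if (domain_coords == "env") 21L else 19L
    out <- data.frame(
      protein_id = m[, 4],
      raw_name = m[, 1],
      ali_start = as.integer(m[, from_col]),
      ali_end = as.integer(m[, to_col]),
      score = as.numeric(m[, 14]),
      evalue = as.numeric(m[, 13]),
      stringsAsFactors = FALSE
    )
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(parts)
    if (any(n < 6)) stop("domain TSV needs >= 6 columns; line ", which(n < 6)[1], " of ", path)
    width <- max(n)
    m <- do.call(rbind, lapply(parts, function(p) { length(p) <- width; p }))
    if (tolower(trimws(m[1, 1])) == "protein_id") m <- m[-1, , drop = FALSE]
    out <- data.frame(
      protein_id = trimws(m[, 1]),
      raw_name = trimws(m[, 2]),
      ali_start = as.integer(m[, 3]),
      ali_end = as.integer(m[, 4]),
      score = as.numeric(m[, 5]),
      evalue = as.numeric(m[, 6]),
      stringsAsFactors = FALSE
    )
    if (width >= 7) {
      tm <- suppressWarnings(as.integer(trimws(m[, 7])))
      keep <- !is.na(tm)
      if (any(keep)) {
        ov <- tapply(tm[keep], out$protein_id[keep], function(x) x[1])
        attr(out, "tm_override") <- stats::setNames(as.integer(ov), names(ov))
      }
    }
  }
  bad <- which(is.na(out$ali_start) | is.na(out$ali_end) | out$ali_start > out$ali_end)
  if (length(bad)) stop("invalid domain coordinates at data line ", bad[1], " of ", path)
  if (any(out$evalue < 0, na.rm = TRUE)) stop("negative evalue in ", path)
  out
}

# Line reader tolerant of CRLF / trailing whitespace.
read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("[\r[:space:]]+$", "", lines)
}

#' Read a square ANI matrix
#'
#' Tab-separated square matrix of average-nucleotide-identity percentages
#' with genome ids as header row and first column. Must be symmetric (within
#' 1e-9) with exactly 100 on the diagonal.
#'
#' @param path TSV path.
#' @return list of class `ani_matrix` with `genome_ids` and `values`.
#' @export
read_ani_matrix <- function(path) {
  if (!file.exists(path)) stop("ANI matrix not found: ", path)
  m <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  values <- as.matrix(m)
  ani_matrix(rownames(values), values)
}

#' Construct/validate an ANI matrix object
#'
#' @param genome_ids ordered genome identifiers.
#' @param values square numeric matrix of ANI percentages.
#' @return list of class `ani_matrix`.
#' @export
ani_matrix <- function(genome_ids, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("ANI matrix must be square")
  if (length(genome_ids) != nrow(values)) stop("genome_ids do not match matrix dimension")
  if (!is.null(colnames(values)) && !identical(colnames(values), as.character(genome_ids)))
    stop("ANI matrix column names do not match row names")
  if (max(abs(values - t(values))) > 1e-9) stop("ANI matrix is not symmetric")
  if (any(values < 0 | values > 100)) stop("ANI values must lie in [0, 100]")
  if (any(diag(values) != 100)) stop("ANI matrix diagonal must be exactly 100")
  dimnames(values) <- list(genome_ids, genome_ids)
  structure(list(genome_ids = as.character(genome_ids), values = values),
            class = "ani_matrix")
}

#' Write an ANI matrix to TSV
#'
#' @param ani `ani_matrix` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ani_matrix <- function(ani, path) {
  df <- data.frame(genome = ani$genome_ids, ani$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the census result tables
#'
#' Emits the five census TSVs (genome summary, genetic organization, sensing
#' domains, HK architectures, RR output families) plus a JSON run manifest
#' recording package version and parameters.
#'
#' @param results list as returned by [run_tcs_census()]; any of the five
#'   table elements may be absent or empty.
#' @param out_dir output directory (created if needed).
#' @param config optional [census_config()] recorded in the manifest.
#' @return named character vector of written paths, invisibly.
#' @export
write_census_tables <- function(results, out_dir, config = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tables <- list(
    genome_summary = results$genome_summary,
    organization = results$organization,
    sensing = results$sensing,
    architectures = results$architectures,
    rr_families = results$rr_families
  )
  skel <- list(
    genome_summary = genome_summary_skeleton(),
    organization = organization_skeleton(),
    sensing = data.frame(tag = character(), cHK = integer(), hyHK = integer()),
    architectures = data.frame(genome_id = character(), architecture = character(),
                               cHK = integer(), hyHK = integer()),
    rr_families = data.frame(genome_id = character(), family = character(), n = integer())
  )
  paths <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab) || !nrow(tab)) tab <- skel[[nm]]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  manifest <- list(
    package = "tcscensus",
    version = as.character(utils::packageVersion("tcscensus")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = if (!is.null(config)) unclass(config) else NULL,
    seed = config$seed %||% NULL,
    tables = as.list(basename(paths))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths["manifest"] <- mp
  invisible(paths)
}

genome_summary_skeleton <- function() {
  data.frame(genome_id = character(), genome_size_mb = numeric(),
             n_cds = integer(), cHK = integer(), hyHK = integer(),
             uHK = integer(), CheA = integer(), RR = integer(),
             PP_HisKA = integer(), PP_Hpt = integer(), total_tcs = integer(),
             orf_fraction = numeric(), rt_ratio = numeric())
}

organization_skeleton <- function() {
  data.frame(genome_id = character(), orphan = integer(), pair = integer(),
             triad = integer(), tetrad = integer(), pentad = integer(),
             complex_gt5 = integer(), total_tcs = integer())
}
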