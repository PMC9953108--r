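# Stage orchestration: a single configuration object holding every tunable
# threshold, and an end-to-end runner that takes per-genome inputs (plus an
# optional ANI matrix) through classification, genomic-context clustering,
# the census tables, orthology and gain/loss inference.

#' Pipeline configuration
#'
#' All thresholds of the census pipeline with their defaults. Distance and
#' identity/coverage thresholds are strict inequalities (`< 200 bp`,
#' `> 40%`, `> 75%`).
#'
#' @param cluster_max_gap intergenic distance bound in bp (strict less-than).
#' @param bbh_identity_min BBH identity threshold in percent (strict
#'   greater-than).
#' @param bbh_coverage_min BBH query-coverage threshold in percent (strict
#'   greater-than).
#' @param domain_evalue_max domain-hit inclusion e-value.
#' @param tm_window,tm_threshold,tm_merge_gap Kyte-Doolittle predictor
#'   parameters (window length, window-mean cutoff, merge distance).
#' @param gain_penalty,loss_penalty parsimony transition costs.
#' @param duplicate_identity_min within-genome duplication flagging identity
#'   (percent, inclusive).
#' @param break_on_intervening do intervening non-TCS genes break clusters?
#' @param precision printed decimal places for ratios/fractions.
#' @param seed integer seed recorded in the run manifest.
#' @return object of class `census_config`.
#' @export
census_config <- function(cluster_max_gap = 200, bbh_identity_min = 40,
                          bbh_coverage_min = 75, domain_evalue_max = 1e-4,
                          tm_window = 19, tm_threshold = 1.6, tm_merge_gap = 5,
                          gain_penalty = 2, loss_penalty = 1,
                          duplicate_identity_min = 95,
                          break_on_intervening = TRUE, precision = 1,
                          seed = 1L) {
  cfg <- list(cluster_max_gap = cluster_max_gap,
              bbh_identity_min = bbh_identity_min,
              bbh_coverage_min = bbh_coverage_min,
              domain_evalue_max = domain_evalue_max,
              tm_window = tm_window, tm_threshold = tm_threshold,
              tm_merge_gap = tm_merge_gap, gain_penalty = gain_penalty,
              loss_penalty = loss_penalty,
              duplicate_identity_min = duplicate_identity_min,
              break_on_intervening = break_on_intervening,
              precision = precision, seed = seed)
  num <- cfg[c("cluster_max_gap", "bbh_identity_min", "bbh_coverage_min",
               "domain_evalue_max", "tm_window", "tm_threshold",
               "tm_merge_gap", "gain_penalty", "loss_penalty",
               "duplicate_identity_min")]
  if (any(unlist(num) <= 0)) stop("all thresholds must be positive")
  if (precision < 0) stop("precision must be >= 0")
  structure(cfg, class = "census_config")
}

#' Run the full census pipeline over a genome panel
#'
#' @param genomes named list (genome_id -> `list(proteins, domains)`, as
#'   produced by [read_genome_inputs()] or [generate_panel()]); protein
#'   tables may carry an optional attribute `genome_size_mb`.
#' @param ani optional `ani_matrix` over the panel; when supplied (and >= 2
#'   genomes), the UPGMA tree and per-family gain/loss events are inferred.
#' @param config [census_config()].
#' @param vocab domain vocabulary.
#' @return list with elements `tcs` (classified panel), `clusters`,
#'   `genome_summary`, `organization`, `sensing`, `architectures` (per-genome
#'   long table), `architecture_census` (panel-wide), `rr_families`,
#'   `orthology` (families/presence/summary; NULL for single genomes),
#'   `tree`, `events`, `events_summary`, `duplicates`.
#' @export
run_tcs_census <- function(genomes, ani = NULL, config = census_config(),
                           vocab = default_vocabulary()) {
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  tcs_list <- list(); cluster_list <- list()
  gs_rows <- list(); org_rows <- list(); rr_rows <- list(); arch_rows <- list()
  for (g in names(genomes)) {
    inp <- genomes[[g]]
    cls <- classify_proteins(inp$proteins, inp$domains, vocab, config)
    cl <- build_clusters(cls, max_gap = config$cluster_max_gap,
                         break_on_intervening = config$break_on_intervening)
    tcs_list[[g]] <- cls
    cluster_list[[g]] <- cl
    size_mb <- attr(inp$proteins, "genome_size_mb") %||% NA_real_
    gs_rows[[g]] <- genome_summary(cls[cls$category != "NONE", , drop = FALSE],
                                   n_cds = nrow(inp$proteins),
                                   genome_size_mb = size_mb, genome_id = g)
    org_rows[[g]] <- organization_summary(cl, genome_id = g)
    rr <- rr_family_table(cls)
    rr_rows[[g]] <- data.frame(genome_id = g, rr, stringsAsFactors = FALSE)
    ac <- architecture_census(cls)
    if (nrow(ac$architectures))
      arch_rows[[g]] <- data.frame(genome_id = g, ac$architectures,
                                   stringsAsFactors = FALSE)
  }
  tcs_all <- do.call(rbind, tcs_list)
  rownames(tcs_all) <- NULL
  panel_arch <- architecture_census(tcs_all)

  ortho <- NULL; dup <- NULL; tree <- NULL; events <- NULL; ev_sum <- NULL
  if (length(genomes) >= 2) {
    ortho <- build_families(tcs_all,
                            identity_min = config$bbh_identity_min,
                            coverage_min = config$bbh_coverage_min)
    dup <- find_duplicates(ortho$families, tcs_all,
                           identity_min = config$duplicate_identity_min)
    if (!is.null(ani)) {
      if (!setequal(ani$genome_ids, names(genomes)))
        stop("ANI matrix genomes do not match the panel")
      tree <- upgma(ani)
      events <- infer_all_events(ortho$presence, tree,
                                 gain_penalty = config$gain_penalty,
                                 loss_penalty = config$loss_penalty)
      ev_sum <- events_summary(events, tree)
    }
  }

  list(
    tcs = tcs_all,
    clusters = do.call(rbind, c(cluster_list, list(make.row.names = FALSE))),
    genome_summary = do.call(rbind, c(gs_rows, list(make.row.names = FALSE))),
    organization = do.call(rbind, c(org_rows, list(make.row.names = FALSE))),
    sensing = sensing_census(tcs_all),
    architectures = do.call(rbind, c(arch_rows, list(make.row.names = FALSE))),
    architecture_census = panel_arch,
    rr_families = do.call(rbind, c(rr_rows, list(make.row.names = FALSE))),
    orthology = ortho,
    duplicates = dup,
    tree = tree,
    events = events,
    events_summary = ev_sum,
    config = config
  )
}
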