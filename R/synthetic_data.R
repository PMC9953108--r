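# Synthetic genome panels with planted TCS content, genomic organization,
# sequence divergence and gain/loss histories, plus machine-readable truth
# records. Domain tables are emitted directly from the planted architecture
# templates (the pipeline consumes annotation tables, not HMM scans);
# sequence content matters only to the alignment and transmembrane stages,
# so sequences are random amino-acid strings with optional hydrophobic
# marker segments.

#' Built-in protein architecture templates
#'
#' Each template is an ordered raw-domain-name list realising one planted
#' protein class; `tm` plants a hydrophobic membrane anchor.
#'
#' @return named list of templates (`domains`, `tm`).
#' @export
default_templates <- function() {
  list(
    cHK = list(domains = c("PAS", "HisKA", "HATPase_c"), tm = FALSE),
    cHK_plain = list(domains = c("HisKA", "HATPase_c"), tm = FALSE),
    cHK_tm = list(domains = c("PAS", "HisKA", "HATPase_c"), tm = TRUE),
    hyHK = list(domains = c("GAF", "HisKA", "HATPase_c", "Response_reg"), tm = FALSE),
    uHK = list(domains = c("PAS", "HisKA", "HATPase_c", "Response_reg", "Hpt"), tm = FALSE),
    CheA = list(domains = c("Hpt", "HATPase_c", "CheW"), tm = FALSE),
    RR = list(domains = c("Response_reg", "Trans_reg_C"), tm = FALSE),
    RR_CheY = list(domains = c("Response_reg"), tm = FALSE),
    RR_NarL = list(domains = c("Response_reg", "GerE"), tm = FALSE),
    PP = list(domains = c("Hpt"), tm = FALSE),
    PP_HisKA = list(domains = c("HisKA"), tm = FALSE)
  )
}

DOMAIN_AA_LEN <- 60L
DOMAIN_AA_GAP <- 10L

template_length <- function(tpl) {
  DOMAIN_AA_GAP + length(tpl$domains) * (DOMAIN_AA_LEN + DOMAIN_AA_GAP) + 10L +
    if (isTRUE(tpl$tm)) 30L else 0L
}

# Polar-biased residue sampling keeps spurious hydrophobic windows rare.
random_protein <- function(len, tm = FALSE) {
  w <- rep(1, 20)
  w[AA_ALPHABET20 %in% c("I", "L", "V", "F", "M", "C", "A")] <- 0.5
  aa <- sample(AA_ALPHABET20, len, replace = TRUE, prob = w / sum(w))
  if (tm) aa[3:27] <- sample(c("L", "I", "V", "F"), 25, replace = TRUE)
  paste(aa, collapse = "")
}

mutate_sequence <- function(seq, p_sub) {
  if (p_sub <= 0) return(seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(aa)) < p_sub)
  if (length(hit)) {
    repl <- sample(AA_ALPHABET20, length(hit), replace = TRUE)
    same <- repl == aa[hit]
    while (any(same)) {
      repl[same] <- sample(AA_ALPHABET20, sum(same), replace = TRUE)
      same <- repl == aa[hit]
    }
    aa[hit] <- repl
  }
  paste(aa, collapse = "")
}

# Domain-hit rows for one planted protein (coordinates follow the template
# layout used by random sequence generation).
template_domain_rows <- function(protein_id, tpl) {
  offset <- DOMAIN_AA_GAP + if (isTRUE(tpl$tm)) 30L else 0L
  n <- length(tpl$domains)
  starts <- offset + (seq_len(n) - 1L) * (DOMAIN_AA_LEN + DOMAIN_AA_GAP) + 1L
  data.frame(
    protein_id = protein_id,
    raw_name = tpl$domains,
    ali_start = starts,
    ali_end = starts + DOMAIN_AA_LEN - 1L,
    score = 120 - 5 * (seq_len(n) - 1L),
    evalue = 1e-10,
    stringsAsFactors = FALSE
  )
}

#' Specification for one synthetic genome
#'
#' @param genome_id genome identifier.
#' @param clusters list of character vectors of template names
#'   ([default_templates()]); each vector is one planted cluster laid out in
#'   the given order (singletons are orphans).
#' @param seed integer seed; generation is fully deterministic given it.
#' @param gap_tcs intergenic gap range (bp) inside clusters; must respect
#'   the clustering distance rule to be recoverable.
#' @param gap_between gap range (bp) between clusters/fillers.
#' @param n_filler_between non-TCS filler genes between clusters.
#' @param strands optional list parallel to `clusters` of strand vectors;
#'   default all `"+"`.
#' @param contig_id contig name.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(genome_id, clusters, seed = 1L,
                        gap_tcs = c(50L, 150L), gap_between = c(300L, 800L),
                        n_filler_between = 1L, strands = NULL,
                        contig_id = NULL) {
  stopifnot(length(clusters) >= 1, all(lengths(clusters) >= 1))
  if (gap_tcs[1] < -50L) stop("planted overlaps are bounded at -50 bp")
  if (!is.null(strands)) stopifnot(length(strands) == length(clusters))
  structure(list(genome_id = genome_id, clusters = clusters, seed = seed,
                 gap_tcs = gap_tcs, gap_between = gap_between,
                 n_filler_between = n_filler_between, strands = strands,
                 contig_id = contig_id %||% paste0(genome_id, "_c1")),
            class = "genome_spec")
}

#' Generate a synthetic annotated genome
#'
#' Lays out the planted clusters along one contig (fillers and large gaps
#' separate clusters, so the planted partition is recoverable by the
#' distance/orientation/contiguity rules), emits per-protein sequences and
#' domain-hit rows from the architecture templates, and records the ground
#' truth.
#'
#' @param spec a [genome_spec()].
#' @param templates template registry (default [default_templates()]).
#' @return list: `proteins` (incl. filler genes), `domains`, `truth`
#'   (list with `proteins` and `clusters` data.frames).
#' @export
generate_genome <- function(spec, templates = default_templates()) {
  stopifnot(inherits(spec, "genome_spec"))
  unknown <- setdiff(unlist(spec$clusters), names(templates))
  if (length(unknown)) stop("unknown template(s): ", paste(unknown, collapse = ", "))
  with_seed(spec$seed, {
    cursor <- 1000L
    prot <- list(); dom <- list(); truth_p <- list(); truth_c <- list()
    kp <- 0L; kf <- 0L
    rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
      sample(seq.int(rng[1], rng[2]), 1L)
    add_filler <- function() {
      kf <<- kf + 1L
      len <- rint(c(100L, 250L))
      id <- sprintf("%s_f%03d", spec$genome_id, kf)
      bp <- 3L * len
      prot[[length(prot) + 1L]] <<- data.frame(
        protein_id = id, genome_id = spec$genome_id, contig_id = spec$contig_id,
        start = cursor, end = cursor + bp - 1L, strand = "+",
        sequence = random_protein(len), stringsAsFactors = FALSE)
      cursor <<- cursor + bp + rint(spec$gap_between)
    }
    for (ci in seq_along(spec$clusters)) {
      members <- spec$clusters[[ci]]
      strands <- if (is.null(spec$strands)) rep("+", length(members)) else spec$strands[[ci]]
      cluster_ids <- character(length(members))
      for (mi in seq_along(members)) {
        kp <- kp + 1L
        tpl <- templates[[members[mi]]]
        len <- template_length(tpl)
        id <- sprintf("%s_p%03d", spec$genome_id, kp)
        cluster_ids[mi] <- id
        bp <- 3L * len
        prot[[length(prot) + 1L]] <- data.frame(
          protein_id = id, genome_id = spec$genome_id, contig_id = spec$contig_id,
          start = cursor, end = cursor + bp - 1L, strand = strands[mi],
          sequence = random_protein(len, tm = isTRUE(tpl$tm)),
          stringsAsFactors = FALSE)
        dom[[length(dom) + 1L]] <- template_domain_rows(id, tpl)
        gap <- if (mi < length(members)) rint(spec$gap_tcs) else rint(spec$gap_between)
        cursor <- cursor + bp + gap
        roles <- role_token(tpl$domains, default_vocabulary())
        cls <- classify(roles, has_adjacent_tcs_gene = length(members) > 1)
        truth_p[[length(truth_p) + 1L]] <- data.frame(
          protein_id = id, template = members[mi], category = cls$category,
          label = unname(CATEGORY_LABELS[cls$category]),
          cluster_id = sprintf("truth_cl%02d", ci), stringsAsFactors = FALSE)
      }
      truth_c[[length(truth_c) + 1L]] <- data.frame(
        cluster_id = sprintf("truth_cl%02d", ci), size = length(members),
        category = cluster_category(length(members)),
        composition = composition(vapply(truth_p[(kp - length(members) + 1):kp],
                                         function(x) x$label, "")),
        stringsAsFactors = FALSE)
      for (f in seq_len(spec$n_filler_between)) add_filler()
    }
    list(
      proteins = do.call(rbind, prot),
      domains = do.call(rbind, dom),
      truth = list(proteins = do.call(rbind, truth_p),
                   clusters = do.call(rbind, truth_c))
    )
  })
}

#' Write a generated genome to disk in the pipeline's input formats
#'
#' @param genome result of [generate_genome()] (or one genome of a panel).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the genome id).
#' @return named character vector of paths (`fasta`, `coords`, `domains`,
#'   `truth`), invisibly.
#' @export
write_genome_inputs <- function(genome, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% genome$proteins$genome_id[1]
  p <- genome$proteins
  fasta <- file.path(dir, paste0(prefix, ".faa"))
  seqs <- Biostrings::AAStringSet(stats::setNames(p$sequence, p$protein_id))
  Biostrings::writeXStringSet(seqs, fasta)
  coords <- file.path(dir, paste0(prefix, "_coords.tsv"))
  utils::write.table(
    data.frame(protein_id = p$protein_id, contig = p$contig_id,
               start = p$start, end = p$end, strand = p$strand),
    coords, sep = "\t", quote = FALSE, row.names = FALSE)
  domains <- file.path(dir, paste0(prefix, "_domains.tsv"))
  utils::write.table(genome$domains, domains, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(genome$truth, truth, dataframe = "rows", pretty = TRUE)
  invisible(c(fasta = fasta, coords = coords, domains = domains, truth = truth))
}

#' Specification for a synthetic genome panel
#'
#' @param newick rooted guide tree with branch lengths in expected
#'   substitutions per site; tip labels are genome ids.
#' @param core character vector of template names, one per core family
#'   (present in every genome; a single root-branch gain).
#' @param accessory list of accessory family plants:
#'   `list(template =, gains = <branch labels>, losses = <branch labels>)`.
#'   Branch labels are `"root"`, tip labels, or `"node<k>"` in the tree's
#'   internal numbering (root = ntip + 1). Planted events must be
#'   consistent: a loss needs a present parent state.
#' @param duplications list of `list(genome =, family = <index>,
#'   divergence = <subs/site>)` planting a within-genome duplicate of that
#'   family's member.
#' @param seed integer seed.
#' @param ani_cap cap (percentage points) of the tree-distance-to-ANI map
#'   `ANI = 100 - min(ani_cap, 100 * t)`.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(newick, core, accessory = list(), duplications = list(),
                       seed = 1L, ani_cap = 30) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse guide tree")
  structure(list(newick = newick, tree = tree, core = core,
                 accessory = accessory, duplications = duplications,
                 seed = seed, ani_cap = ani_cap),
            class = "panel_spec")
}

# Resolve a branch label to a node number.
resolve_branch <- function(tree, label) {
  ntip <- length(tree$tip.label)
  if (label == "root") return(ntip + 1L)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (grepl("^node[0-9]+$", label)) {
    v <- as.integer(sub("^node", "", label))
    if (v > ntip && v <= ntip + tree$Nnode) return(v)
  }
  stop("unknown branch label: ", label)
}

# Leaf presence vector implied by planted gain/loss branches; errors on an
# inconsistent plant (loss below an absent state, gain below a present one).
planted_presence <- function(tree, gains, losses) {
  tt <- tree_tables(tree)
  nn <- tt$ntip + tree$Nnode
  flip <- rep(FALSE, nn)
  type <- rep(NA_character_, nn)
  for (b in gains) { v <- resolve_branch(tree, b); flip[v] <- TRUE; type[v] <- "GAIN" }
  for (b in losses) {
    v <- resolve_branch(tree, b)
    if (flip[v]) stop("gain and loss planted on the same branch: ", b)
    flip[v] <- TRUE; type[v] <- "LOSS"
  }
  states <- integer(nn)
  parent_state <- function(v, s_par) {
    s <- if (flip[v]) {
      if (type[v] == "GAIN" && s_par == 1L) stop("planted gain below a present state")
      if (type[v] == "LOSS" && s_par == 0L) stop("planted loss below an absent state")
      1L - s_par
    } else s_par
    states[v] <<- s
    for (ch in tt$children[[v]]) parent_state(ch, s)
  }
  parent_state(tt$root, 0L)
  stats::setNames(states[seq_len(tt$ntip)], tree$tip.label)
}

#' Generate a synthetic genome panel with planted families and histories
#'
#' Evolves one ancestral random sequence per family down the guide tree by
#' i.i.d. substitutions (`p = 1 - exp(-branch_length)` per site), drops or
#' adds families per the planted events, plants within-genome duplicates,
#' lays each genome out as orphans with filler genes, and derives the ANI
#' matrix from cophenetic guide-tree distances by the fixed monotone map
#' `ANI = 100 - min(cap, 100 * t)`. Fully deterministic given the seed.
#'
#' @param spec a [panel_spec()].
#' @param templates template registry.
#' @return list: `genomes` (named list of `list(proteins, domains)`), `ani`
#'   (`ani_matrix`), `tree` (guide tree), `truth` (planted families, events,
#'   presence matrix, duplications).
#' @export
generate_panel <- function(spec, templates = default_templates()) {
  stopifnot(inherits(spec, "panel_spec"))
  tree <- spec$tree
  tt <- tree_tables(tree)
  ntip <- tt$ntip
  genomes <- tree$tip.label

  fam_templates <- c(spec$core, vapply(spec$accessory, `[[`, "", "template"))
  n_core <- length(spec$core)
  fam_ids <- sprintf("pfam%02d", seq_along(fam_templates))

  presence <- matrix(0L, length(fam_ids), ntip,
                     dimnames = list(fam_ids, genomes))
  planted_events <- vector("list", length(fam_ids))
  for (k in seq_along(fam_ids)) {
    if (k <= n_core) {
      presence[k, ] <- 1L
      planted_events[[k]] <- list(gains = "root", losses = character())
    } else {
      acc <- spec$accessory[[k - n_core]]
      gains <- acc$gains %||% "root"
      losses <- acc$losses %||% character()
      presence[k, ] <- planted_presence(tree, gains, losses)
      planted_events[[k]] <- list(gains = gains, losses = losses)
    }
  }

  with_seed(spec$seed, {
    # evolve each family down the tree
    leaf_seqs <- vector("list", length(fam_ids))
    for (k in seq_along(fam_ids)) {
      tpl <- templates[[fam_templates[k]]]
      node_seq <- character(ntip + tree$Nnode)
      node_seq[tt$root] <- random_protein(template_length(tpl))
      for (e in rev(ape::postorder(tree))) {  # preorder: parent before child
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        t_br <- tree$edge.length[e]
        node_seq[ch] <- mutate_sequence(node_seq[p], 1 - exp(-t_br))
      }
      leaf_seqs[[k]] <- stats::setNames(node_seq[seq_len(ntip)], genomes)
    }

    # duplicates
    dup_truth <- list()
    extra <- lapply(genomes, function(g) list())
    names(extra) <- genomes
    for (d in spec$duplications) {
      k <- d$family
      g <- d$genome
      if (presence[k, g] != 1L) stop("cannot duplicate an absent family in ", g)
      div <- d$divergence %||% 0
      extra[[g]][[length(extra[[g]]) + 1L]] <- list(
        family = k, sequence = mutate_sequence(leaf_seqs[[k]][[g]], 1 - exp(-div)))
      dup_truth[[length(dup_truth) + 1L]] <- data.frame(
        genome_id = g, family_id = fam_ids[k], divergence = div,
        stringsAsFactors = FALSE)
    }

    # assemble genomes: all families as orphans with fillers in between
    out_genomes <- list()
    membership <- list()
    for (g in genomes) {
      cursor <- 1000L
      prot <- list(); dom <- list(); kf <- 0L
      contig <- paste0(g, "_c1")
      add_protein <- function(id, seq, tpl) {
        bp <- 3L * nchar(seq)
        prot[[length(prot) + 1L]] <<- data.frame(
          protein_id = id, genome_id = g, contig_id = contig,
          start = cursor, end = cursor + bp - 1L, strand = "+",
          sequence = seq, stringsAsFactors = FALSE)
        dom[[length(dom) + 1L]] <<- template_domain_rows(id, tpl)
        cursor <<- cursor + bp + 500L
      }
      add_filler <- function() {
        kf <<- kf + 1L
        len <- 120L
        id <- sprintf("%s_f%03d", g, kf)
        bp <- 3L * len
        prot[[length(prot) + 1L]] <<- data.frame(
          protein_id = id, genome_id = g, contig_id = contig,
          start = cursor, end = cursor + bp - 1L, strand = "+",
          sequence = random_protein(len), stringsAsFactors = FALSE)
        cursor <<- cursor + bp + 500L
      }
      for (k in seq_along(fam_ids)) {
        if (presence[k, g] != 1L) next
        id <- sprintf("%s_%s", g, fam_ids[k])
        add_protein(id, leaf_seqs[[k]][[g]], templates[[fam_templates[k]]])
        membership[[length(membership) + 1L]] <- data.frame(
          family_id = fam_ids[k], genome_id = g, protein_id = id,
          uid = paste(g, id, sep = ":"), duplicate = FALSE,
          stringsAsFactors = FALSE)
        if (k %% 3 == 0) add_filler()
      }
      for (x in extra[[g]]) {
        id <- sprintf("%s_%s_dup", g, fam_ids[x$family])
        add_protein(id, x$sequence, templates[[fam_templates[x$family]]])
        membership[[length(membership) + 1L]] <- data.frame(
          family_id = fam_ids[x$family], genome_id = g, protein_id = id,
          uid = paste(g, id, sep = ":"), duplicate = TRUE,
          stringsAsFactors = FALSE)
      }
      out_genomes[[g]] <- list(proteins = do.call(rbind, prot),
                               domains = do.call(rbind, dom))
    }

    # ANI from cophenetic tree distance
    Dt <- ape::cophenetic.phylo(tree)[genomes, genomes]
    vals <- 100 - pmin(100 * Dt, spec$ani_cap)
    diag(vals) <- 100
    ani <- ani_matrix(genomes, vals)

    truth <- list(
      family_templates = stats::setNames(fam_templates, fam_ids),
      membership = do.call(rbind, membership),
      presence = presence,
      events = stats::setNames(planted_events, fam_ids),
      n_core = n_core,
      duplications = if (length(dup_truth)) do.call(rbind, dup_truth) else NULL
    )
    list(genomes = out_genomes, ani = ani, tree = tree, truth = truth)
  })
}
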