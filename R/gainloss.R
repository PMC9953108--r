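# Gene gain/loss inference: UPGMA tree from an ANI matrix, then minimum-cost
# binary ancestral-state reconstruction (Sankoff dynamic programming with
# asymmetric gain/loss penalties and an "absent" root prior) per ortholog
# family, plus per-branch event summaries.

#' UPGMA tree from an ANI matrix
#'
#' Distances are `100 - ANI`. Standard size-weighted arithmetic-mean
#' agglomeration; a merge at distance d places the new node at height d/2, so
#' the tree is ultrametric. Merge ties are broken deterministically by the
#' lexicographically smallest member id of the candidate pair.
#'
#' @param ani `ani_matrix` object ([ani_matrix()]), >= 2 genomes.
#' @return rooted ultrametric `phylo` tree with genome ids as tip labels.
#' @export
upgma <- function(ani) {
  stopifnot(inherits(ani, "ani_matrix"))
  ids <- ani$genome_ids
  n <- length(ids)
  if (n < 2) stop("UPGMA requires at least 2 genomes")
  D <- 100 - ani$values
  dimnames(D) <- list(ids, ids)

  active <- seq_len(n)
  nwk <- ids
  height <- rep(0, n)
  size <- rep(1L, n)
  key <- ids  # lexicographically smallest member id per cluster

  while (length(active) > 1) {
    # minimal distance among active pairs, ties by (min key, max key)
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        d <- D[i, j]
        k1 <- min(key[i], key[j]); k2 <- max(key[i], key[j])
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (k1 < best$k1 || (k1 == best$k1 && k2 < best$k2)))) {
          best <- list(i = i, j = j, d = d, k1 = k1, k2 = k2)
        }
      }
    }
    i <- best$i; j <- best$j
    if (key[j] < key[i]) { tmp <- i; i <- j; j <- tmp }
    h <- best$d / 2
    new <- length(nwk) + 1L
    nwk[new] <- sprintf("(%s:%.12g,%s:%.12g)",
                        nwk[i], h - height[i], nwk[j], h - height[j])
    height[new] <- h
    size[new] <- size[i] + size[j]
    key[new] <- min(key[i], key[j])
    # size-weighted average linkage to the remaining clusters
    D <- rbind(D, 0); D <- cbind(D, 0)
    for (k in setdiff(active, c(i, j))) {
      dk <- (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
      D[new, k] <- dk; D[k, new] <- dk
    }
    active <- c(setdiff(active, c(i, j)), new)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

# Children of each node from the edge matrix, and node depths (edges from root).
tree_tables <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  children <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    children[[p]] <- c(children[[p]], c)
  }
  depth <- rep(NA_integer_, ntip + nnode)
  depth[root] <- 0L
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    depth[c] <- depth[p] + 1L
  }
  list(ntip = ntip, root = root, children = children, depth = depth)
}

branch_label <- function(tree, node, ntip) {
  if (node == ntip + 1L) "root"  # the root node's incoming (virtual) branch
  else if (node <= ntip) tree$tip.label[node]
  else paste0("node", node)
}

#' Infer gain/loss events for one presence/absence vector
#'
#' Minimum-cost binary ancestral reconstruction by Sankoff dynamic
#' programming. Transition costs are asymmetric: absent-to-present (a gain)
#' costs `gain_penalty`, present-to-absent (a loss) costs `loss_penalty`.
#' The root prior is "absent", so a family present anywhere needs at least
#' one gain (possibly on the root branch); multiple independent gains are
#' permitted when cheaper. Cost ties are resolved deterministically toward
#' fewer gains, then toward events nearer the root (lexicographic
#' minimisation of (cost, gains, summed event depth)).
#'
#' @param tree rooted `phylo` tree (e.g. from [upgma()]).
#' @param presence named 0/1 (or logical) vector over the tree's tip labels,
#'   not all zero.
#' @param gain_penalty cost of a gain (default 2).
#' @param loss_penalty cost of a loss (default 1).
#' @return list: `events` (data.frame `branch`, `node`, `type`), `cost`,
#'   `n_gains`, `n_losses`, `states` (named 0/1 per node, tips first).
#' @export
infer_events <- function(tree, presence, gain_penalty = 2, loss_penalty = 1) {
  tt <- tree_tables(tree)
  ntip <- tt$ntip
  if (is.logical(presence)) presence <- as.integer(presence)
  if (is.null(names(presence)) || !setequal(names(presence), tree$tip.label))
    stop("presence vector names must match the tree's tip labels")
  leaf_state <- as.integer(presence[tree$tip.label])
  if (all(leaf_state == 0)) stop("presence vector is all-zero")

  nn <- ntip + tree$Nnode
  INF <- .Machine$double.xmax / 4
  cost <- matrix(INF, nn, 2)
  gains <- matrix(0L, nn, 2)
  depths <- matrix(0L, nn, 2)
  trans <- function(s, s2) if (s == s2) 0 else if (s == 0) gain_penalty else loss_penalty

  # postorder over edges gives children before parents
  node_order <- unique(tree$edge[ape::postorder(tree), 2])
  for (v in c(node_order, tt$root)) {
    if (v <= ntip) {
      s <- leaf_state[v]
      cost[v, s + 1] <- 0
      next
    }
    for (s in 0:1) {
      tot <- 0; tg <- 0L; td <- 0L
      for (ch in tt$children[[v]]) {
        bc <- bg <- bd <- NULL
        for (s2 in 0:1) {
          cc <- cost[ch, s2 + 1] + trans(s, s2)
          cg <- gains[ch, s2 + 1] + as.integer(s == 0 && s2 == 1)
          cd <- depths[ch, s2 + 1] + if (s != s2) tt$depth[ch] else 0L
          if (is.null(bc) || cc < bc - 1e-9 ||
              (abs(cc - bc) <= 1e-9 && (cg < bg || (cg == bg && cd < bd)))) {
            bc <- cc; bg <- cg; bd <- cd
          }
        }
        tot <- tot + bc; tg <- tg + bg; td <- td + bd
      }
      cost[v, s + 1] <- tot; gains[v, s + 1] <- tg; depths[v, s + 1] <- td
    }
  }

  # root prior: absent above the root (a present root is a gain on the root branch)
  pick <- function(par_state, v) {
    bc <- bg <- bd <- NULL; bs <- NA_integer_
    for (s2 in 0:1) {
      cc <- cost[v, s2 + 1] + trans(par_state, s2)
      cg <- gains[v, s2 + 1] + as.integer(par_state == 0 && s2 == 1)
      cd <- depths[v, s2 + 1] + if (par_state != s2) tt$depth[v] else 0L
      better <- is.null(bc) || cc < bc - 1e-9 ||
        (abs(cc - bc) <= 1e-9 &&
           (cg < bg || (cg == bg && (cd < bd ||
              (cd == bd && s2 == par_state)))))
      if (better) { bc <- cc; bg <- cg; bd <- cd; bs <- s2 }
    }
    list(state = bs, cost = bc)
  }
  root_choice <- pick(0L, tt$root)

  states <- integer(nn)
  events <- list()
  add_event <- function(node, type) {
    events[[length(events) + 1L]] <<- data.frame(
      branch = branch_label(tree, node, ntip), node = node, type = type,
      stringsAsFactors = FALSE)
  }
  states[tt$root] <- root_choice$state
  if (states[tt$root] == 1L) add_event(tt$root, "GAIN")
  # preorder traceback
  stack <- tt$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in tt$children[[v]]) {
      chc <- pick(states[v], ch)
      states[ch] <- chc$state
      if (states[ch] != states[v])
        add_event(ch, if (states[ch] == 1L) "GAIN" else "LOSS")
      if (ch > ntip) stack <- c(stack, ch)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), node = integer(), type = character(),
               stringsAsFactors = FALSE)

  # hard invariant: replaying the events reproduces the leaf presences
  replayed <- replay_events(tree, events)
  if (!identical(unname(replayed[tree$tip.label]), leaf_state))
    stop("internal error: event replay does not reproduce the presence vector")

  names(states) <- c(tree$tip.label, paste0("node", (ntip + 1):nn))
  list(events = events, cost = root_choice$cost,
       n_gains = sum(events$type == "GAIN"),
       n_losses = sum(events$type == "LOSS"),
       states = states)
}

#' Replay an event set down a tree
#'
#' Starting from an absent state above the root, flips the state along every
#' branch carrying an event and returns the resulting leaf states.
#'
#' @param tree rooted `phylo` tree.
#' @param events data.frame with columns `node` and `type` (as produced by
#'   [infer_events()]; the root-branch event has `node` = root).
#' @return named 0/1 integer vector over tip labels.
#' @export
replay_events <- function(tree, events) {
  tt <- tree_tables(tree)
  nn <- tt$ntip + tree$Nnode
  flip <- rep(FALSE, nn)
  flip[events$node] <- TRUE
  states <- integer(nn)
  states[tt$root] <- as.integer(flip[tt$root])
  stack <- tt$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in tt$children[[v]]) {
      states[ch] <- if (flip[ch]) 1L - states[v] else states[v]
      if (ch > tt$ntip) stack <- c(stack, ch)
    }
  }
  stats::setNames(states[seq_len(tt$ntip)], tree$tip.label)
}

#' Infer events for every family of a presence/absence matrix
#'
#' @param presence families x genomes 0/1 matrix ([presence_matrix()]).
#' @param tree rooted `phylo` over the genome panel.
#' @param gain_penalty,loss_penalty see [infer_events()].
#' @return named list of [infer_events()] results, one per family.
#' @export
infer_all_events <- function(presence, tree, gain_penalty = 2, loss_penalty = 1) {
  out <- lapply(rownames(presence), function(f)
    infer_events(tree, presence[f, ], gain_penalty, loss_penalty))
  stats::setNames(out, rownames(presence))
}

#' Per-branch gain/loss summary
#'
#' @param event_sets named list of [infer_events()] results (per family).
#' @param tree the tree the events were inferred on.
#' @return list: `per_branch` (data.frame `branch`, `gains`, `losses` over
#'   all branches incl. the root branch), `per_family` (long data.frame
#'   `family_id`, `branch`, `type`), `total_gains`, `total_losses`.
#' @export
events_summary <- function(event_sets, tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  branches <- vapply(seq_len(nn), function(v) branch_label(tree, v, ntip), "")
  per_family <- if (length(event_sets)) {
    do.call(rbind, lapply(names(event_sets), function(f) {
      ev <- event_sets[[f]]$events
      if (!nrow(ev)) return(NULL)
      data.frame(family_id = f, branch = ev$branch, type = ev$type,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(per_family))
    per_family <- data.frame(family_id = character(), branch = character(),
                             type = character(), stringsAsFactors = FALSE)
  per_branch <- data.frame(
    branch = branches,
    gains = vapply(branches, function(b)
      sum(per_family$type == "GAIN" & per_family$branch == b), 0L),
    losses = vapply(branches, function(b)
      sum(per_family$type == "LOSS" & per_family$branch == b), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_branch = per_branch, per_family = per_family,
       total_gains = sum(per_branch$gains),
       total_losses = sum(per_branch$losses))
}
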