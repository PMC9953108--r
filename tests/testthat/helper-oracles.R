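# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. Kept deliberately naive and separate from
# the code paths they verify.

# Gotoh local alignment (affine gaps) in plain R. A gap of length L costs
# open + L * ext, matching BLASTP's gap-existence/extension convention.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  sub <- get_blosum62()
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Brute-force chain finder over one contig: sorts genes, checks every
# consecutive pair of TCS genes against the three rules, splits into maximal
# runs. Returns the list of member-id vectors.
chain_oracle <- function(genes, max_gap = 200) {
  genes <- genes[order(genes$start), , drop = FALSE]
  tcs <- which(genes$category != "NONE")
  if (!length(tcs)) return(list())
  chains <- list(genes$protein_id[tcs[1]])
  if (length(tcs) > 1) {
    for (k in 2:length(tcs)) {
      i <- tcs[k - 1]; j <- tcs[k]
      ok <- (genes$start[j] - genes$end[i] - 1) < max_gap &&
        !(genes$strand[i] == "+" && genes$strand[j] == "-") &&
        j == i + 1
      if (ok) {
        chains[[length(chains)]] <- c(chains[[length(chains)]], genes$protein_id[j])
      } else {
        chains[[length(chains) + 1]] <- genes$protein_id[j]
      }
    }
  }
  chains
}

# Exhaustive minimum-cost ancestral reconstruction: enumerates every binary
# state assignment to the internal nodes and scores transitions (root prior
# absent; the root branch transition counts).
sankoff_oracle <- function(tree, presence, gain = 2, loss = 1) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  leaf_state <- as.integer(presence[tree$tip.label])
  trans <- function(s, s2) if (s == s2) 0 else if (s == 0) gain else loss
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[1:nnode]
    state <- c(leaf_state, internal)
    cost <- trans(0L, state[root])
    for (e in seq_len(nrow(tree$edge))) {
      cost <- cost + trans(state[tree$edge[e, 1]], state[tree$edge[e, 2]])
    }
    if (cost < best) best <- cost
  }
  best
}

# Direct sliding-window hydropathy segment counter (independent loop-based
# implementation of the Kyte-Doolittle stand-in).
kd_oracle <- function(sequence, window = 19, threshold = 1.6, merge_gap = 5) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  h <- kd[aa]; h[is.na(h)] <- 0
  n <- length(h)
  if (n < window) return(0L)
  hits <- integer(0)
  for (s in 1:(n - window + 1)) {
    if (mean(h[s:(s + window - 1)]) > threshold) hits <- c(hits, s)
  }
  if (!length(hits)) return(0L)
  sum(c(TRUE, diff(hits) >= merge_gap))
}

# Random ultrametric ANI matrix generated by a random merge order; the
# implied distances are exactly tree-like, so UPGMA must reconstruct them.
rand_ultrametric_ani <- function(ids) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  groups <- as.list(seq_len(n))
  h <- 0
  while (length(groups) > 1) {
    h <- h + runif(1, 0.5, 3)
    pick <- sample(length(groups), 2)
    for (i in groups[[pick[1]]]) for (j in groups[[pick[2]]]) {
      D[i, j] <- D[j, i] <- 2 * h
    }
    groups[[pick[1]]] <- c(groups[[pick[1]]], groups[[pick[2]]])
    groups[[pick[2]]] <- NULL
  }
  ani_matrix(ids, 100 - D)
}

random_aa <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
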