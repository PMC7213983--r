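# Independent oracles used by the unit and acceptance tests. These stay
# deliberately brute-force: exhaustive enumeration over all internal-state
# assignments, so they share no code path with the pruning/Fitch
# implementations they check.

AAS <- aa_states()

# Exhaustive marginal posteriors at one site: sums the joint probability
# pi(root) * prod(edge transition probs) over every assignment of the 20
# states to every internal node, tips fixed at their observed states.
brute_force_asr_site <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:20), m)))
  prob <- rep(1 / 20, nrow(grid))      # uniform prior at the root
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    P <- poisson_transition_matrix(tree$edge.length[i])
    su <- grid[, u - ntip]
    sv <- if (v <= ntip) {
      rep(match(tip_states[[tree$tip.label[v]]], AAS), nrow(grid))
    } else grid[, v - ntip]
    prob <- prob * P[cbind(su, sv)]
  }
  post <- matrix(0, m, 20, dimnames = list(NULL, AAS))
  for (j in seq_len(m)) {
    sums <- rowsum(prob, grid[, j])
    post[j, as.integer(rownames(sums))] <- sums
  }
  post / rowSums(post)
}

# Minimum change count by enumerating every labeling of the internal nodes
# with the observed state alphabet.
brute_force_fitch <- function(tree, traits) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  states <- sort(unique(unname(traits)))
  tip_idx <- match(traits[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)), m)))
  changes <- rep(0L, nrow(grid))
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    su <- grid[, u - ntip]
    sv <- if (v <= ntip) rep(tip_idx[v], nrow(grid)) else grid[, v - ntip]
    changes <- changes + (su != sv)
  }
  min(changes)
}

# random rooted binary tree with given tips and exponential-ish branch
# lengths, via ape
random_tree <- function(n, max_bl = 0.5) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, max_bl)
  tr
}

# time grids scaled to the decay rate so curves span the informative range
decay_times <- function(k, n = 10) seq(0, 3 / k, length.out = n)
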