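# Independent oracles used across the suite. Deliberately naive: direct
# enumeration and path-walking, no reuse of the package's algorithms.

# MRCA age by exhaustive path comparison: walk each tip's ancestor chain to
# the root, take the deepest shared ancestor, convert depth to age.
oracle_mrca_age <- function(tree, a, b) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  chain <- function(tip) {
    path <- tip
    while (path[length(path)] != root)
      path <- c(path, parent_of(path[length(path)]))
    path
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  shared <- intersect(chain(ia), chain(ib))
  depth <- function(node) {
    d <- 0
    while (node != root) {
      row <- which(tree$edge[, 2] == node)
      d <- d + tree$edge.length[row]
      node <- tree$edge[row, 1]
    }
    d
  }
  height <- max(vapply(seq_len(ntip), depth, 0))
  height - max(vapply(shared, depth, 0))
}

# Exact two-sided rank-sum p-value by enumeration of all C(n, nx) rank
# assignments (tie-free samples only): 2 * min(P(W <= w), P(W >= w)),
# capped at 1, with W the rank sum of the first sample.
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- colSums(matrix(seq_len(n)[combos], nrow = nx))
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# Brute-force biogeographic likelihood for 2- and 3-tip trees: explicit
# sums over root state, cladogenetic event choices and (for 3 tips) the
# internal node's arriving state, with branch transition probabilities from
# Matrix::expm directly. Equal root weight 1 per non-null state.
oracle_biogeo_lik <- function(tree, tip_masks, config, states) {
  Q <- anagenetic_Q(config, states)
  masks_full <- c(0L, states$masks)
  midx <- function(m) match(m, masks_full)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  ntip <- ape::Ntip(tree)
  stopifnot(ntip %in% c(2L, 3L))
  edge <- tree$edge
  len <- tree$edge.length
  obs <- lapply(tip_masks[tree$tip.label], function(r)
    if (is.character(r)) sisterdiv:::areas_to_mask(r, states$areas)
    else as.integer(r))
  root <- ntip + 1L
  kids_of <- function(nd) which(edge[, 1] == nd)
  lik_subtree <- function(node, start_mask, t) {
    # probability of the data below `node` given the lineage starts its
    # branch (of length t) in start_mask
    Pt <- P(t)
    if (node <= ntip)
      return(Pt[midx(start_mask), midx(obs[[node]])])
    tot <- 0
    for (arrive in states$masks) {
      pa <- Pt[midx(start_mask), midx(arrive)]
      if (pa == 0) next
      ct <- clado_table(config, arrive, states)
      rows <- kids_of(node)
      s <- 0
      for (ei in seq_len(nrow(ct))) {
        s <- s + ct$prob[ei] *
          lik_subtree(edge[rows[1], 2], ct$left_mask[ei], len[rows[1]]) *
          lik_subtree(edge[rows[2], 2], ct$right_mask[ei], len[rows[2]])
      }
      tot <- tot + pa * s
    }
    tot
  }
  total <- 0
  for (S in states$masks) {
    ct <- clado_table(config, S, states)
    rows <- kids_of(root)
    s <- 0
    for (ei in seq_len(nrow(ct))) {
      s <- s + ct$prob[ei] *
        lik_subtree(edge[rows[1], 2], ct$left_mask[ei], len[rows[1]]) *
        lik_subtree(edge[rows[2], 2], ct$right_mask[ei], len[rows[2]])
    }
    total <- total + s   # root weight 1 per non-null state
  }
  total
}

# Brute-force marginal root-state posterior for the same small trees:
# P(root = S | data) by normalising the per-root-state contributions.
oracle_root_marginal <- function(tree, tip_masks, config, states) {
  per_state <- vapply(states$masks, function(S) {
    Q <- anagenetic_Q(config, states)
    masks_full <- c(0L, states$masks)
    midx <- function(m) match(m, masks_full)
    P <- function(t) as.matrix(Matrix::expm(Q * t))
    ntip <- ape::Ntip(tree)
    edge <- tree$edge
    len <- tree$edge.length
    obs <- lapply(tip_masks[tree$tip.label], function(r)
      if (is.character(r)) sisterdiv:::areas_to_mask(r, states$areas)
      else as.integer(r))
    kids <- which(edge[, 1] == ntip + 1L)
    lik_below <- function(node, start_mask, t) {
      Pt <- P(t)
      if (node <= ntip)
        return(Pt[midx(start_mask), midx(obs[[node]])])
      tot <- 0
      for (arrive in states$masks) {
        pa <- Pt[midx(start_mask), midx(arrive)]
        if (pa == 0) next
        ct <- clado_table(config, arrive, states)
        rows <- which(edge[, 1] == node)
        s <- 0
        for (ei in seq_len(nrow(ct)))
          s <- s + ct$prob[ei] *
            lik_below(edge[rows[1], 2], ct$left_mask[ei], len[rows[1]]) *
            lik_below(edge[rows[2], 2], ct$right_mask[ei], len[rows[2]])
        tot <- tot + pa * s
      }
      tot
    }
    ct <- clado_table(config, S, states)
    s <- 0
    for (ei in seq_len(nrow(ct)))
      s <- s + ct$prob[ei] *
        lik_below(edge[kids[1], 2], ct$left_mask[ei], len[kids[1]]) *
        lik_below(edge[kids[2], 2], ct$right_mask[ei], len[kids[2]])
    s
  }, 0)
  stats::setNames(per_state / sum(per_state), states$labels)
}
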