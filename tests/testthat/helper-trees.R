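# shared helpers: random tree batches and node-time profiles

# n simulated trees under (S, E, T); optionally only trees with at least
# `min_extant` lineages alive at the present (rejection with fresh seeds)
random_trees <- function(n, S, E, T, seed, min_extant = 0L) {
  out <- vector("list", n)
  k <- 0L
  idx <- 0L
  while (k < n) {
    idx <- idx + 1L
    tr <- simulate_tree(bd_params(S, E, T, seed = seed + idx * 7919L))
    if (n_extant(tr) >= min_extant) {
      k <- k + 1L
      out[[k]] <- tr
    }
    if (idx > 1000L * n) stop("random_trees: rejection loop ran away")
  }
  out
}

# sorted multiset of all node times (births and lineage ends), for
# comparing trees up to label ordering
node_time_profile <- function(tree) {
  ends <- ifelse(tree$extant, tree$present, tree$death)
  sort(c(tree$birth, ends))
}

extant_ids <- function(tree) which(tree$extant)
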