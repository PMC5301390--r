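# Independent oracles used across the suite. These deliberately avoid the
# package's own split machinery: bipartitions are found by deleting each edge
# of the tree and flood-filling the component on one side.

oracle_splits <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  ntip <- length(labs)
  edges <- tree$edge
  nnode <- max(edges)
  adj <- vector("list", nnode)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]
    b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  anchor <- sort(labs, method = "radix")[1L]
  out <- character(0L)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]
    b <- edges[r, 2L]
    seen <- rep(FALSE, nnode)
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == b && w == a) next
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    tips <- labs[which(seen[seq_len(ntip)])]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    if (anchor %in% tips) tips <- setdiff(labs, tips)
    out <- c(out, paste(sort(tips, method = "radix"), collapse = ","))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1)
  s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Random binary tree with fixed labels a, b, c, ...
random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, tip.label = letters[seq_len(n_leaves)])
  ape::write.tree(tr)
}

# All 15 unrooted binary 5-leaf topologies, as Newick strings.
all_five_leaf_trees <- function() {
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  vapply(trees, ape::write.tree, character(1L))
}

# Exact two-sided Mann-Whitney p by enumeration, counting x > y pairs
# directly (no rank sums), independent of the implementation's route.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- min(u_of(x, y), u_of(y, x))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2L, function(ix) {
    xs <- pooled[ix]
    ys <- pooled[-ix]
    min(u_of(xs, ys), u_of(ys, xs))
  })
  mean(u_all <= u_obs + 1e-9)
}
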