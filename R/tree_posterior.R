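#' Parse a Newick tree string
#'
#' Thin validating wrapper around [ape::read.tree()]: the string must be a
#' single well-formed Newick description ending in `;` (trailing whitespace
#' tolerated). Branch lengths and quoted labels are supported; branch lengths
#' are carried along but ignored by all topology-identity operations.
#'
#' @param text A Newick string.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!endsWith(s, ";")) {
    stop(sprintf("Newick parse error at position %d: missing terminating ';'",
                 nchar(s) + 1L))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop(sprintf("Newick parse error at position %d: unbalanced ')'",
                 which(depth < 0)[1L]))
  }
  if (depth[length(depth)] != 0L) {
    stop(sprintf("Newick parse error at position %d: %d unclosed '('",
                 nchar(s), depth[length(depth)]))
  }
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: ", s)
  }
  tr
}

# Canonical non-trivial splits of an unrooted topology, as strings.
# Each bipartition is represented by the side NOT containing the
# lexicographically smallest leaf label, its labels sorted and joined by ",".
tree_splits <- function(tree) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  labs_all <- tree$tip.label
  n <- length(labs_all)
  if (n < 3L) stop("topology operations require at least 3 leaves")
  if (anyDuplicated(labs_all)) stop("duplicate leaf labels")
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  anchor <- sort(labs, method = "radix")[1L]
  clades <- ape::prop.part(tree)
  out <- character(0L)
  for (cl in clades) {
    if (length(cl) <= 1L || length(cl) >= n - 1L) next
    side <- labs[cl]
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side, method = "radix"), collapse = ","))
  }
  unique(out)
}

#' Canonical identity of an unrooted tree topology
#'
#' Maps a tree to a string key that is identical for two trees exactly when
#' they describe the same unrooted topology: branch lengths, node rotations
#' and root placement are all ignored (a degree-2 root is suppressed). The
#' key serializes the leaf set together with the sorted set of non-trivial
#' leaf bipartitions, each bipartition canonicalized as the side not
#' containing the lexicographically smallest leaf label.
#'
#' Identity is deliberately unrooted even for rooted input, matching the
#' unweighted Robinson-Foulds metric used in tree-space analysis; rooted
#' traces whose topologies differ only in root placement therefore collapse
#' to one key.
#'
#' @param tree A Newick string or an [ape::phylo] object with at least 3
#'   uniquely-labelled leaves.
#' @return A character scalar usable as a hash/table key.
#' @examples
#' topology_key("((a,b),c);") == topology_key("(c,(b,a));") # TRUE
#' @export
topology_key <- function(tree) {
  if (is.character(tree)) tree <- parse_newick(tree)
  labs <- sort(tree$tip.label, method = "radix")
  sp <- tree_splits(tree)
  paste0(paste(labs, collapse = ","), ";",
         paste(sort(sp, method = "radix"), collapse = "|"))
}

# Topology-only Newick: branch lengths and node labels stripped.
strip_lengths <- function(newick) {
  tr <- parse_newick(newick)
  tr$edge.length <- NULL
  tr$node.label <- NULL
  ape::write.tree(tr)
}

# Keys for a vector of Newick strings, computed once per unique string.
keys_for <- function(newicks) {
  u <- unique(newicks)
  k <- vapply(u, topology_key, character(1L))
  unname(k[match(newicks, u)])
}

#' Tabulate the tree posterior
#'
#' Counts unique unrooted topologies among the post-burn-in tree samples and
#' returns them sorted by posterior probability (descending; ties broken by
#' first occurrence in the trace, for determinism). The exemplar Newick for
#' each topology is its first occurrence, with branch lengths stripped.
#'
#' @param trees Character vector of Newick strings (the ordered tree trace).
#' @param burnin Number of leading samples to discard.
#' @return A `tree_posterior` list: `entries` (data frame with `newick`,
#'   `count`, `probability`, `first_index`, `key`), `splits` (list of
#'   canonical split sets, parallel to `entries`), `n_total`.
#' @export
topology_frequencies <- function(trees, burnin = 0) {
  if (burnin >= length(trees)) stop("empty tree trace after burn-in")
  trees <- trees[seq.int(burnin + 1L, length(trees))]
  keys <- keys_for(trees)
  first <- !duplicated(keys)
  ord_keys <- keys[first]
  counts <- as.integer(table(keys)[ord_keys])
  o <- order(-counts, seq_along(counts))
  entries <- data.frame(newick = vapply(trees[first][o], strip_lengths,
                                        character(1L)),
                        count = counts[o],
                        probability = counts[o] / length(trees),
                        first_index = which(first)[o] - 1L,
                        key = ord_keys[o],
                        stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(entries = entries,
                 splits = lapply(entries$newick, tree_splits),
                 n_total = length(trees)),
            class = "tree_posterior")
}

#' @export
print.tree_posterior <- function(x, n = 10L, ...) {
  cat(sprintf("Tree posterior: %d unique topologies over %d samples\n",
              nrow(x$entries), x$n_total))
  top <- utils::head(x$entries, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %5.3f (%d)  %s\n", top$probability[i], top$count[i],
                abbreviate_newick(top$newick[i])))
  }
  if (nrow(x$entries) > n) cat(sprintf("  ... %d more\n", nrow(x$entries) - n))
  invisible(x)
}

abbreviate_newick <- function(s, width = 60L) {
  if (nchar(s) > width) paste0(substr(s, 1L, width - 3L), "...") else s
}

#' Weighted majority-rule consensus tree
#'
#' Builds the majority-rule consensus of a weighted selection of trees: a
#' bipartition is retained exactly when its weight-averaged frequency exceeds
#' 0.5 (strictly -- splits at exactly one half are dropped, which guarantees
#' the retained splits are pairwise compatible without any greedy
#' tie-breaking). Regions not resolved by a majority split appear as
#' polytomies. Support values are the weighted split frequencies, computed
#' from the selected trees only, and are written as internal node labels in
#' the returned Newick string.
#'
#' @param trees List/vector of Newick strings or `phylo` objects over the
#'   same leaf set.
#' @param weights Positive weights, one per tree (renormalized to sum to 1).
#'   Defaults to equal weights.
#' @return A `consensus_tree` list: `newick` (with supports as node labels),
#'   `splits` (data frame of retained `split` and `support`), `leaves`.
#' @examples
#' cons <- majority_consensus(c("((a,b),(c,d));", "((a,b),(c,d));"))
#' cons$newick
#' @export
majority_consensus <- function(trees, weights = NULL) {
  trees <- as.list(trees)
  if (length(trees) == 0L) stop("no trees selected")
  if (is.null(weights)) weights <- rep(1, length(trees))
  stopifnot(length(weights) == length(trees), all(weights > 0))
  weights <- weights / sum(weights)

  split_sets <- lapply(trees, tree_splits)
  leaf_sets <- lapply(trees, function(t) {
    if (is.character(t)) t <- parse_newick(t)
    sort(t$tip.label, method = "radix")
  })
  for (ls in leaf_sets[-1L]) {
    if (!identical(ls, leaf_sets[[1L]])) {
      stop("all selected trees must share the same leaf set")
    }
  }
  leaves <- leaf_sets[[1L]]

  freq <- new.env(parent = emptyenv())
  for (i in seq_along(split_sets)) {
    for (s in split_sets[[i]]) {
      assign(s, weights[i] + mget(s, envir = freq, ifnotfound = 0)[[1L]],
             envir = freq)
    }
  }
  all_splits <- ls(freq)
  support <- vapply(all_splits, function(s) get(s, envir = freq), numeric(1L))
  keep <- support > 0.5 + 1e-9
  retained <- all_splits[keep]
  support <- pmin(support[keep], 1)

  newick <- assemble_consensus(leaves, retained, support)
  structure(list(newick = newick,
                 splits = data.frame(split = retained, support = support,
                                     stringsAsFactors = FALSE,
                                     row.names = NULL),
                 leaves = leaves),
            class = "consensus_tree")
}

# Assemble a Newick string from pairwise-compatible canonical splits.
# Splits are clades when the tree is rooted at the lexicographically smallest
# leaf (the canonical side never contains it), so they nest and can be built
# recursively, largest first.
assemble_consensus <- function(leaves, splits, support) {
  anchor <- leaves[1L]
  clades <- lapply(splits, function(s) strsplit(s, ",", fixed = TRUE)[[1L]])
  sizes <- lengths(clades)
  o <- order(-sizes)
  clades <- clades[o]
  support <- support[o]

  build <- function(members, clade_idx) {
    # children: maximal clades strictly inside this node, plus free leaves
    used <- logical(length(members))
    names(used) <- members
    parts <- character(0L)
    for (i in clade_idx) {
      cl <- clades[[i]]
      if (any(used[cl])) next # nested inside an earlier (larger) child clade
      inner <- clade_idx[vapply(clade_idx, function(j) {
        j != i && length(clades[[j]]) < length(cl) && all(clades[[j]] %in% cl)
      }, logical(1L))]
      parts <- c(parts, paste0(build(cl, inner),
                               format_support(support[i])))
      used[cl] <- TRUE
    }
    singles <- members[!used]
    paste0("(", paste(c(singles, parts), collapse = ","), ")")
  }

  rest <- setdiff(leaves, anchor)
  idx <- seq_along(clades)
  top <- vapply(idx, function(i) !any(vapply(idx, function(j) {
    j != i && length(clades[[i]]) < length(clades[[j]]) &&
      all(clades[[i]] %in% clades[[j]])
  }, logical(1L))), logical(1L))
  used <- logical(length(rest))
  names(used) <- rest
  parts <- character(0L)
  for (i in idx[top]) {
    inner <- idx[vapply(idx, function(j) {
      j != i && length(clades[[j]]) < length(clades[[i]]) &&
        all(clades[[j]] %in% clades[[i]])
    }, logical(1L))]
    parts <- c(parts, paste0(build(clades[[i]], inner),
                             format_support(support[i])))
    used[clades[[i]]] <- TRUE
  }
  singles <- rest[!used]
  paste0("(", paste(c(anchor, singles, parts), collapse = ","), ");")
}

format_support <- function(x) {
  sub("\\.$", "", sub("0+$", "", sprintf("%.6f", x)))
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Majority-rule consensus tree\n")
  cat(" ", x$newick, "\n")
  if (nrow(x$splits)) {
    cat(sprintf("  %d retained splits, support range [%.3f, %.3f]\n",
                nrow(x$splits), min(x$splits$support), max(x$splits$support)))
  } else {
    cat("  no majority splits (star tree)\n")
  }
  invisible(x)
}

#' Locate selected topologies along the trace
#'
#' For each selected topology, returns the sorted 0-based sample indices at
#' which it occurs in the tree trace -- the information behind "mark
#' selection in graph" style displays that color a numeric trace wherever a
#' chosen topology was sampled, a direct visual check of tree mixing.
#'
#' @param trees Character vector of Newick strings (the ordered tree trace).
#' @param selected Character vector of topology keys (from [topology_key()])
#'   or Newick strings (converted with [topology_key()] if they do not look
#'   like keys).
#' @return Named list (by key) of integer index vectors; a key absent from
#'   the trace maps to an empty vector.
#' @export
mark_occurrences <- function(trees, selected) {
  keys <- keys_for(trees)
  sel <- vapply(selected, function(s) {
    if (grepl("(", s, fixed = TRUE)) topology_key(s) else s
  }, character(1L))
  out <- lapply(sel, function(k) which(keys == k) - 1L)
  names(out) <- sel
  out
}
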