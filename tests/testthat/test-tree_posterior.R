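test_that("parse_newick validates structure and reports positions", {
  tr <- parse_newick("((a,b),c);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))

  # branch lengths parsed but irrelevant to identity
  expect_equal(topology_key("((a:1.0,b:2.0):0.5,c:1.0);"),
               topology_key("((a,b),c);"))

  expect_error(parse_newick("((a,b),c)"), "missing terminating ';'")
  expect_error(parse_newick("((a,b),c));"), "unbalanced")
  expect_error(parse_newick("(((a,b),c);"), "unclosed")
})

test_that("topology_key ignores rotation, rooting and branch lengths", {
  expect_equal(topology_key("((a,b),c);"), topology_key("(c,(b,a));"))
  expect_false(topology_key("((a,b),(c,d));") == topology_key("((a,c),(b,d));"))

  # rerooting anywhere leaves the key unchanged
  base <- "(((a,b),c),(d,e));"
  tr <- parse_newick(base)
  for (node in c("a", "c", "e")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(topology_key(rerooted), topology_key(base))
  }

  expect_error(topology_key("(a,b);"), "3 leaves")
})

test_that("all 15 unrooted 5-leaf binary topologies get distinct keys", {
  trees <- all_five_leaf_trees()
  keys <- vapply(trees, topology_key, character(1))
  expect_equal(length(unique(keys)), 15L)
})

test_that("keys survive serialize/parse round trips on random trees", {
  for (seed in 1:100) {
    nk <- random_tree(8, seed)
    reparsed <- ape::write.tree(parse_newick(nk))
    expect_equal(topology_key(reparsed), topology_key(nk))
  }
})

test_that("topology_frequencies counts, sorts and respects burn-in", {
  ta <- "((a,b),(c,d));"
  tb <- "((a,c),(b,d));"
  post <- topology_frequencies(c(ta, ta, tb, ta))
  expect_equal(post$entries$probability, c(0.75, 0.25))
  expect_equal(post$entries$count, c(3L, 1L))
  expect_equal(sum(post$entries$count), post$n_total)

  post <- topology_frequencies(c(ta, ta, tb, ta), burnin = 2)
  expect_equal(post$entries$probability, c(0.5, 0.5))
  # tie broken by first occurrence: tb appears first post burn-in
  expect_equal(topology_key(post$entries$newick[1]), topology_key(tb))

  expect_error(topology_frequencies(c(ta, tb), burnin = 2), "empty")
})

test_that("estimated topology frequencies converge to the sampling weights", {
  tops <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  probs <- c(0.6, 0.3, 0.1)
  trace <- gen_tree_trace(tops, probs, 10000, seed = 5)
  post <- topology_frequencies(trace)
  est <- post$entries$probability[match(vapply(tops, topology_key, character(1)),
                                        post$entries$key)]
  expect_true(all(abs(est - probs) < 0.02))
  expect_equal(sum(post$entries$probability), 1, tolerance = 1e-9)
})

test_that("majority consensus reproduces single trees with full support", {
  nk <- "(((a,b),c),(d,e));"
  cons <- majority_consensus(nk)
  expect_equal(topology_key(cons$newick), topology_key(nk))
  expect_true(all(cons$splits$support == 1))
  # every split of the input is retained
  expect_setequal(cons$splits$split, oracle_splits(nk))
})

test_that("weighted consensus keeps majority splits with their frequencies", {
  t1 <- "(((a,b),c),(d,e));" # splits: {c,d,e}, {d,e}
  t2 <- "(((a,c),b),(d,e));" # splits: {b,d,e}, {d,e}
  cons <- majority_consensus(c(t1, t2), weights = c(0.6, 0.4))
  expect_equal(topology_key(cons$newick), topology_key(t1))
  sup <- setNames(cons$splits$support, cons$splits$split)
  expect_equal(sup[["d,e"]], 1.0)
  expect_equal(sup[["c,d,e"]], 0.6)
  expect_false("b,d,e" %in% names(sup))
  expect_true(all(cons$splits$support > 0.5 & cons$splits$support <= 1))

  # exact 0.5/0.5 tie: conflicting splits dropped, polytomy remains
  cons <- majority_consensus(c(t1, t2), weights = c(0.5, 0.5))
  expect_setequal(cons$splits$split, "d,e")
  expect_equal(topology_key(cons$newick), topology_key("((a,b,c),(d,e));"))

  expect_error(majority_consensus(c(t1, "((x,y),z);")), "leaf set")
})

test_that("consensus supports match direct split-frequency computation", {
  trees <- vapply(1:6, function(s) random_tree(7, s), character(1))
  w <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  cons <- majority_consensus(trees, weights = w)
  # oracle: accumulate weighted frequencies over brute-force splits
  freq <- list()
  for (i in seq_along(trees)) {
    for (s in oracle_splits(trees[i])) {
      freq[[s]] <- (if (is.null(freq[[s]])) 0 else freq[[s]]) + w[i]
    }
  }
  keep <- names(freq)[unlist(freq) > 0.5]
  expect_setequal(cons$splits$split, keep)
  for (s in keep) {
    expect_equal(cons$splits$support[cons$splits$split == s], freq[[s]],
                 tolerance = 1e-12)
  }
})

test_that("mark_occurrences partitions the trace by topology", {
  ta <- "((a,b),(c,d));"
  tb <- "((a,c),(b,d));"
  m <- mark_occurrences(c(ta, tb, ta), topology_key(ta))
  expect_equal(m[[1]], c(0L, 2L))
  expect_equal(mark_occurrences(c(ta, ta), topology_key(tb))[[1]], integer(0))
  # Newick selections are accepted too
  expect_equal(mark_occurrences(c(ta, tb, ta), ta)[[1]], c(0L, 2L))

  trace <- gen_tree_trace(c(ta, tb, "((a,d),(b,c));"), c(0.5, 0.3, 0.2),
                          300, seed = 8)
  keys <- unique(vapply(trace, topology_key, character(1)))
  marks <- mark_occurrences(trace, keys)
  all_idx <- unname(sort(unlist(marks)))
  expect_equal(all_idx, 0:(length(trace) - 1L)) # disjoint union of all indices
})
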