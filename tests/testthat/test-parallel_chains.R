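test_that("mann_whitney reproduces exact enumeration on small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1) # 2 of the 20 labelings are as extreme

  # independent enumeration oracle, including tied data
  cases <- list(list(x = c(1, 2, 3), y = c(4, 5, 6)),
                list(x = c(1, 1, 2), y = c(2, 3, 3)),
                list(x = c(5, 7), y = c(1, 2, 3)),
                list(x = c(2, 4, 6, 8), y = c(1, 3, 5)))
  for (cs in cases) {
    expect_equal(mann_whitney(cs$x, cs$y)$p_value,
                 oracle_mw_exact_p(cs$x, cs$y))
  }

  # identical samples: U split evenly by midranks
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$u1, 4.5)
  expect_equal(r$u2, 4.5)
  expect_equal(r$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney is symmetric and matches wilcox.test asymptotics", {
  set.seed(41)
  x <- rnorm(80)
  y <- rnorm(60, mean = 0.3)
  a <- mann_whitney(x, y)
  b <- mann_whitney(y, x)
  expect_false(a$exact)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(a$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(min(ref$statistic, length(x) * length(y) - ref$statistic),
               a$statistic)

  # large shift: decisive rejection
  expect_lt(mann_whitney(rnorm(200), rnorm(200, mean = 10))$p_value, 1e-6)
})

test_that("split_chisq detects homogeneity and total separation", {
  ta <- "((a,b),(c,d));"
  tb <- "((a,c),(b,d));"
  trace1 <- gen_tree_trace(c(ta, tb), c(0.7, 0.3), 200, seed = 3)

  st <- split_table(trace1, trace1)
  r <- split_chisq(st)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # chains concentrated on disjoint splits
  st2 <- split_table(rep(ta, 100), rep(tb, 100))
  r2 <- split_chisq(st2)
  expect_gt(r2$statistic, 50)
  expect_lt(r2$p_value, 1e-10)

  # single shared split: not testable
  expect_error(split_chisq(split_table(rep(ta, 10), rep(ta, 10))),
               "not applicable")
})

test_that("split_chisq is invariant to split ordering", {
  tops <- all_five_leaf_trees()[1:4]
  x <- gen_tree_trace(tops, c(0.4, 0.3, 0.2, 0.1), 400, seed = 5)
  y <- gen_tree_trace(tops, c(0.4, 0.3, 0.2, 0.1), 400, seed = 6)
  st <- split_table(x, y)
  r1 <- split_chisq(st)
  perm <- rev(seq_along(st$splits))
  st2 <- structure(list(splits = st$splits[perm],
                        counts1 = st$counts1[perm],
                        counts2 = st$counts2[perm],
                        n1 = st$n1, n2 = st$n2),
                   class = "split_table")
  r2 <- split_chisq(st2)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("split counts agree with per-topology bookkeeping", {
  tops <- c("((a,b),(c,d));", "((a,c),(b,d));")
  x <- gen_tree_trace(tops, c(0.6, 0.4), 500, seed = 9)
  y <- gen_tree_trace(tops, c(0.6, 0.4), 300, seed = 10)
  st <- split_table(x, y, burnin1 = 100, burnin2 = 0)
  expect_equal(st$n1, 400)
  expect_equal(st$n2, 300)
  n_ta_1 <- sum(x[101:500] == tops[1])
  expect_equal(unname(st$counts1[st$splits == "c,d"]), n_ta_1)
  expect_equal(unname(st$counts1[st$splits == "b,d"]), 400 - n_ta_1)
  expect_true(all(st$counts1 <= st$n1 & st$counts2 <= st$n2))
})

test_that("combine_chains concatenates post-burn-in samples", {
  t1 <- trace_table(numeric = list(x = as.numeric(1:10)),
                    trees = list(tree = rep("((a,b),(c,d));", 10)))
  t2 <- trace_table(numeric = list(x = as.numeric(101:108)),
                    trees = list(tree = rep("((a,c),(b,d));", 8)))
  j <- combine_chains(t1, t2, 2, 3)
  expect_equal(j$n_samples, 13L)
  expect_equal(j$numeric$x, c(3:10, 104:108))
  expect_equal(combine_chains(t1, t2)$n_samples, 18L)

  # joint mean is the weighted mean of the post-burn-in chain means
  m <- summarize_series(j$numeric$x)$mean
  expect_equal(m, (8 * mean(3:10) + 5 * mean(104:108)) / 13)

  # joint tree posterior = count-wise sum of per-chain posteriors
  post <- topology_frequencies(j$trees$tree)
  expect_equal(sort(post$entries$count), sort(c(8L, 5L)))

  t3 <- trace_table(numeric = list(y = as.numeric(1:10)))
  expect_error(combine_chains(t1, t3), "mismatching columns")
})
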