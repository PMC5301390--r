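#' Mann-Whitney U test for two parameter traces
#'
#' Compares the post-burn-in samples of one continuous parameter from two
#' independent chains. Ranks are midranks (average ranks for ties) and the
#' reported statistic is `U = min(U1, U2)`. For `n1 * n2 >= 20` the two-sided
#' p-value uses the normal approximation with tie-corrected variance and a
#' continuity correction of 1/2; for smaller problems the exact two-sided
#' p-value is obtained by enumerating all `choose(n1 + n2, n1)` labelings of
#' the pooled midranks (which also handles ties exactly).
#'
#' A significant result says the two chains are sampling different
#' distributions for this parameter -- either at least one has not reached the
#' stationary distribution, or the two runs are stuck in different modes.
#'
#' @param x,y Numeric sample vectors (`NA`s removed).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   default `NULL` selects by the `n1 * n2 < 20` rule.
#' @return A `two_sample_test` list: `statistic` (U), `u1`, `u2`, `p_value`,
#'   `method`, `exact`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1, by enumeration
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- n1 * n2 < 20L
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    ranksum <- colSums(matrix(r[combs], nrow = n1))
    u_all <- ranksum - n1 * (n1 + 1) / 2
    u_min_all <- pmin(u_all, n1 * n2 - u_all)
    # folding U onto min(U, n1*n2 - U) already pools both tails, so the
    # tail probability of the folded distribution is the two-sided p
    p <- min(1, mean(u_min_all <= u + 1e-9))
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  structure(list(statistic = u, u1 = u1, u2 = u2, p_value = p,
                 method = "mann_whitney_u", exact = exact,
                 n1 = n1, n2 = n2),
            class = "two_sample_test")
}

#' Tabulate split occurrences in two tree traces
#'
#' Counts, for every non-trivial bipartition observed in either chain's
#' post-burn-in trees, how many sampled trees of each chain contain it. This
#' is the contingency material for [split_chisq()].
#'
#' @param trees1,trees2 Character vectors of Newick strings.
#' @param burnin1,burnin2 Leading samples of each chain to discard.
#' @return A `split_table` list: `splits` (character), `counts1`, `counts2`
#'   (integer vectors), `n1`, `n2` (post-burn-in tree counts).
#' @export
split_table <- function(trees1, trees2, burnin1 = 0, burnin2 = 0) {
  count_chain <- function(trees, burnin) {
    if (burnin >= length(trees)) stop("empty tree trace after burn-in")
    trees <- trees[seq.int(burnin + 1L, length(trees))]
    u <- unique(trees)
    usplits <- lapply(u, tree_splits)
    idx <- match(trees, u)
    counts <- new.env(parent = emptyenv())
    tab <- tabulate(idx, nbins = length(u))
    for (i in seq_along(u)) {
      for (s in usplits[[i]]) {
        assign(s, tab[i] + mget(s, envir = counts, ifnotfound = 0)[[1L]],
               envir = counts)
      }
    }
    list(counts = counts, n = length(trees))
  }
  c1 <- count_chain(trees1, burnin1)
  c2 <- count_chain(trees2, burnin2)
  splits <- sort(union(ls(c1$counts), ls(c2$counts)), method = "radix")
  get0n <- function(s, env) mget(s, envir = env, ifnotfound = 0)[[1L]]
  structure(list(splits = splits,
                 counts1 = vapply(splits, get0n, env = c1$counts,
                                  FUN.VALUE = numeric(1L)),
                 counts2 = vapply(splits, get0n, env = c2$counts,
                                  FUN.VALUE = numeric(1L)),
                 n1 = c1$n, n2 = c2$n),
            class = "split_table")
}

#' Two-sample chi-square test on tree split frequencies
#'
#' Tests whether two chains sample tree splits with the same frequencies.
#' For each split the expected per-chain count under homogeneity comes from
#' the pooled proportion `(c1 + c2) / (n1 + n2)` scaled by each chain's tree
#' count; the statistic sums `(O - E)^2 / E` over splits and chains, with
#' `df = (number of categories - 1)` and the p-value from the chi-square
#' upper tail. Splits whose smaller expected count falls below 5 are merged
#' into a single "other" category first (the standard validity rule for
#' chi-square approximations).
#'
#' The test treats split-presence counts as categorical counts even though
#' splits within one tree co-occur, so it is an approximation; simulation
#' under the null shows its size stays near the nominal level for tree
#' posteriors of the scale this package targets (see the package tests).
#'
#' @param table A `split_table`.
#' @return A `two_sample_test` list with `statistic`, `df`, `p_value`,
#'   `n_categories`, `method = "chisq_splits"`, `n1`, `n2`.
#' @export
split_chisq <- function(table) {
  stopifnot(inherits(table, "split_table"))
  n1 <- table$n1
  n2 <- table$n2
  if (n1 <= 0 || n2 <= 0) stop("both chains need post-burn-in trees")
  if (length(table$splits) < 2L) stop("test not applicable: fewer than 2 splits")
  pooled <- (table$counts1 + table$counts2) / (n1 + n2)
  e1 <- n1 * pooled
  e2 <- n2 * pooled
  small <- pmin(e1, e2) < 5
  o1 <- c(table$counts1[!small],
          if (any(small)) sum(table$counts1[small]))
  o2 <- c(table$counts2[!small],
          if (any(small)) sum(table$counts2[small]))
  k <- length(o1)
  if (k < 2L) stop("test not applicable: fewer than 2 categories after merging")
  pooled_m <- (o1 + o2) / (n1 + n2)
  stat <- sum((o1 - n1 * pooled_m)^2 / (n1 * pooled_m),
              (o2 - n2 * pooled_m)^2 / (n2 * pooled_m))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n_categories = k, method = "chisq_splits",
                 n1 = n1, n2 = n2),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  if (x$method == "mann_whitney_u") {
    cat(sprintf("Mann-Whitney U test (%s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
                if (isTRUE(x$exact)) "exact" else "normal approximation",
                x$statistic, x$p_value, x$n1, x$n2))
  } else {
    cat(sprintf("Split-frequency chi-square: X2 = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Concatenate two chains after per-chain burn-in removal
#'
#' Appends the post-burn-in samples of the second trace to the post-burn-in
#' samples of the first, column by column, so that downstream statistics and
#' tree posteriors can be computed on the joint trace. Both traces must have
#' identical column names and kinds. The generation column of the result is
#' renumbered `0, 1, 2, ...` since the original iteration numbers of two
#' independent runs do not concatenate meaningfully.
#'
#' @param t1,t2 `trace_table` objects with matching columns.
#' @param burnin1,burnin2 Leading samples to drop from each chain.
#' @return A `trace_table` with `(n1 - burnin1) + (n2 - burnin2)` samples.
#' @export
combine_chains <- function(t1, t2, burnin1 = 0, burnin2 = 0) {
  stopifnot(inherits(t1, "trace_table"), inherits(t2, "trace_table"))
  if (!identical(t1$columns$name, t2$columns$name) ||
      !identical(t1$columns$kind, t2$columns$kind)) {
    stop("chains have mismatching columns")
  }
  a <- extract_interval(t1, burnin1, t1$n_samples)
  b <- extract_interval(t2, burnin2, t2$n_samples)
  n <- a$n_samples + b$n_samples
  numeric_data <- Map(c, a$numeric, b$numeric)
  tree_data <- Map(c, a$trees, b$trees)
  gen <- if (!is.null(t1$generation) || !is.null(t2$generation)) {
    seq_len(n) - 1L
  }
  new_trace_table(paste(t1$source, t2$source, sep = " + "),
                  n, t1$columns, numeric_data, tree_data, gen)
}
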