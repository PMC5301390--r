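# Run a block with a private, seeded RNG stream; the caller's global
# .Random.seed is left untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a (possibly shifted) AR(1) series
#'
#' Simulates `x_t = mu + rho * (x_{t-1} - mu) + sigma * e_t` with standard
#' normal innovations and `x_0` drawn from the stationary distribution
#' `N(mu, sigma^2 / (1 - rho^2))`, so the whole series is stationary. An
#' optional non-stationary prefix -- an additive offset on the first
#' `prefix_frac * n` samples -- emulates a chain that starts away from the
#' posterior and makes a known "true" burn-in available to tests of the
#' burn-in estimators. The generator is a pure function of its arguments:
#' the same seed always yields the same series and the caller's RNG state is
#' untouched.
#'
#' @param n Series length.
#' @param rho AR(1) coefficient, `|rho| < 1`. The stationary lag-1
#'   autocorrelation equals `rho` and the iid-equivalent ESS fraction is
#'   `(1 - rho) / (1 + rho)`.
#' @param mu Stationary mean.
#' @param sigma Innovation standard deviation.
#' @param shift Optional `list(prefix_frac =, offset =)` adding `offset` to
#'   the first `floor(prefix_frac * n)` samples; `0 <= prefix_frac < 1`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_ar1(1000, rho = 0.5, seed = 42)
#' @export
gen_ar1 <- function(n, rho = 0, mu = 0, sigma = 1, shift = NULL, seed = 1) {
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  stopifnot(n >= 1, sigma >= 0)
  if (!is.null(shift)) {
    stopifnot(is.list(shift), shift$prefix_frac >= 0, shift$prefix_frac < 1)
  }
  x <- with_seed(seed, {
    e <- rnorm(n)
    out <- numeric(n)
    out[1L] <- mu + sigma / sqrt(1 - rho^2) * e[1L]
    for (t in seq_len(n - 1L) + 1L) {
      out[t] <- mu + rho * (out[t - 1L] - mu) + sigma * e[t]
    }
    out
  })
  if (!is.null(shift) && shift$prefix_frac > 0) {
    k <- floor(shift$prefix_frac * n)
    if (k >= 1L) x[seq_len(k)] <- x[seq_len(k)] + shift$offset
  }
  x
}

#' Generate a tree trace with known topology frequencies
#'
#' Draws `n` iid samples from a given discrete distribution over topologies
#' and returns the corresponding Newick strings. Being iid, the trace mixes
#' perfectly; it is intended for testing frequency estimation, consensus
#' construction and tree-space analysis, not for emulating the autocorrelated
#' topology sequences of a real chain.
#'
#' @param topologies Character vector of Newick strings with pairwise
#'   distinct unrooted topologies (checked via [topology_key()]).
#' @param probabilities Sampling probabilities, summing to 1 (within 1e-12).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Character vector of `n` Newick strings.
#' @export
gen_tree_trace <- function(topologies, probabilities, n, seed = 1) {
  if (length(topologies) != length(probabilities)) {
    stop("topologies and probabilities must have the same length")
  }
  if (abs(sum(probabilities) - 1) > 1e-12 || any(probabilities < 0)) {
    stop("probabilities must be non-negative and sum to 1")
  }
  keys <- vapply(topologies, topology_key, character(1L))
  if (anyDuplicated(keys)) stop("topologies must have pairwise distinct keys")
  idx <- with_seed(seed, sample.int(length(topologies), n, replace = TRUE,
                                    prob = probabilities))
  unname(topologies[idx])
}

#' Write a trace table to disk
#'
#' Writes a `trace_table` in one of the supported dialects so that
#' [parse_trace()] reads it back value-identically. The tabular dialect emits
#' a tab-separated file with a `Gen` column (the stored generation index, or
#' `0, 1, 2, ...`) and numeric values at full `%.17g` precision, so numeric
#' round-trips are exact. The `nexus_trees` dialect writes a NEXUS `trees`
#' block with a `Translate` table and requires the trace to contain exactly
#' one tree column and nothing else; the round-trip contract there is
#' topology identity (equal [topology_key()] sequences), not byte identity.
#'
#' @param table A `trace_table`.
#' @param path Output file path.
#' @param dialect `"tabular"` or `"nexus_trees"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(table, path, dialect = c("tabular", "nexus_trees")) {
  stopifnot(inherits(table, "trace_table"))
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    gen <- table$generation
    if (is.null(gen)) gen <- seq_len(table$n_samples) - 1L
    cols <- list(Gen = format_full(gen))
    for (i in seq_len(nrow(table$columns))) {
      nm <- table$columns$name[i]
      cols[[nm]] <- switch(table$columns$kind[i],
                           numeric = format_full(table$numeric[[nm]]),
                           tree = table$trees[[nm]],
                           stop("cannot write a column of kind 'ignored'"))
    }
    lines <- c(paste(names(cols), collapse = "\t"),
               do.call(paste, c(cols, sep = "\t")))
    writeLines(lines, path)
  } else {
    if (length(table$trees) != 1L || nrow(table$columns) != 1L) {
      stop("nexus_trees dialect requires a trace with exactly one tree column")
    }
    write_nexus_trees(table$trees[[1L]], path)
  }
  invisible(path)
}

format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_nexus_trees <- function(newicks, path) {
  first <- parse_newick(newicks[1L])
  labels <- sort(first$tip.label, method = "radix")
  translate <- paste0("\t\t", seq_along(labels), " ", labels,
                      c(rep(",", length(labels) - 1L), ";"))
  stmts <- vapply(seq_along(newicks), function(i) {
    tr <- parse_newick(newicks[i])
    m <- match(tr$tip.label, labels)
    if (anyNA(m)) stop("all trees must share the leaf set of the first tree")
    tr$tip.label <- as.character(m)
    sprintf("\ttree STATE_%d = %s", i - 1L, ape::write.tree(tr))
  }, character(1L))
  writeLines(c("#NEXUS",
               "begin trees;",
               "\ttranslate",
               translate,
               stmts,
               "end;"), path)
  invisible(path)
}
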