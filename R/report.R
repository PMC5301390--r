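resolve_trace <- function(input) {
  if (inherits(input, "trace_table")) input else parse_trace(input)
}

# burnin argument: "auto", a fraction in [0, 1), or an absolute sample count.
resolve_burnin <- function(burnin, n) {
  if (identical(burnin, "auto")) return(NA_integer_)
  b <- as.numeric(burnin)
  if (is.na(b) || b < 0) stop("invalid burnin: ", format(burnin))
  b <- if (b < 1) floor(b * n) else floor(b)
  if (b >= n) stop("burnin leaves no samples")
  as.integer(b)
}

#' Analyze a single MCMC trace
#'
#' The one-stop analysis behind the command-line `analyze` subcommand: parses
#' the trace, determines the burn-in (a fixed count, a fraction of the chain,
#' or `"auto"` -- the per-parameter suggested burn-in maximized over all
#' numeric parameters), then assembles per-parameter summaries and
#' convergence diagnostics plus, for every tree column, the tree posterior
#' and its weighted majority-rule consensus.
#'
#' @param input Path to a trace file, trace text, or a `trace_table`.
#' @param burnin `"auto"` (default), a fraction below 1, or a sample count.
#' @param ess_min Convergence floor on the post-burn-in ESS (see
#'   [diagnose_series()]).
#' @param top_trees Number of top topologies reported per tree column (the
#'   posterior object holds all of them).
#' @param tree_threshold Posterior-probability filter used for the tree-space
#'   distance matrix block of the report.
#' @param grid_step Burn-in grid resolution.
#' @return An `mcmc_report` list; see [report_json()] for the serialized
#'   form. The `converged` element is `TRUE`/`FALSE`/`NA` (NA when the chain
#'   is too short for diagnostics).
#' @export
run_analyze <- function(input, burnin = "auto", ess_min = 200,
                        top_trees = 10L, tree_threshold = 0.002,
                        grid_step = 0.01) {
  tab <- resolve_trace(input)
  n <- tab$n_samples
  num_names <- names(tab$numeric)
  b_fixed <- resolve_burnin(burnin, n)

  diagnostics <- list()
  if (n >= 200L) {
    for (nm in num_names) {
      diagnostics[[nm]] <- diagnose_series(tab$numeric[[nm]],
                                           ess_min = ess_min,
                                           grid_step = grid_step, name = nm)
    }
  }
  b <- if (is.na(b_fixed)) {
    if (length(diagnostics)) {
      max(vapply(diagnostics, `[[`, integer(1L), "burnin_suggested"))
    } else 0L
  } else b_fixed

  parameters <- list()
  for (nm in num_names) {
    parameters[[nm]] <- list(
      summary = summarize_series(tab$numeric[[nm]], burnin = b, name = nm),
      diagnostics = diagnostics[[nm]])
  }

  trees <- list()
  for (nm in names(tab$trees)) {
    post <- topology_frequencies(tab$trees[[nm]], burnin = b)
    k <- min(top_trees, nrow(post$entries))
    cons <- majority_consensus(post$entries$newick,
                               weights = post$entries$probability)
    trees[[nm]] <- list(posterior = post,
                        top = utils::head(post$entries[, c("newick", "count",
                                                           "probability")], k),
                        n_unique = nrow(post$entries),
                        consensus = cons,
                        threshold = tree_threshold)
  }

  conv <- if (length(diagnostics)) {
    all(vapply(diagnostics, `[[`, logical(1L), "converged"))
  } else NA

  structure(list(input = tab$source,
                 n_samples = n,
                 burnin = b,
                 burnin_mode = if (is.na(b_fixed)) "auto" else "fixed",
                 parameters = parameters,
                 trees = trees,
                 converged = conv),
            class = "mcmc_report")
}

#' @export
print.mcmc_report <- function(x, ...) {
  cat(sprintf("MCMC analysis of %s: %d samples, burn-in %d (%s)\n",
              x$input, x$n_samples, x$burnin, x$burnin_mode))
  for (p in x$parameters) {
    print(p$summary)
    if (!is.null(p$diagnostics)) print(p$diagnostics)
  }
  for (nm in names(x$trees)) {
    print(x$trees[[nm]]$posterior, n = 5L)
    print(x$trees[[nm]]$consensus)
  }
  if (!is.na(x$converged)) {
    cat(sprintf("Overall verdict: %s\n",
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Compare two parallel chains
#'
#' Implements the two-chain analysis behind the `compare` subcommand: after
#' per-chain burn-in removal, every shared numeric parameter is compared with
#' a Mann-Whitney U test, tree columns are compared with the split-frequency
#' chi-square test, and the two chains are concatenated ([combine_chains()])
#' so joint summaries can be reported. Disagreement between two independent
#' runs on the same data is evidence that at least one of them is not yet
#' sampling the stationary distribution (or that the posterior is multimodal
#' and the runs are stuck in different modes).
#'
#' @param input1,input2 Paths, trace text, or `trace_table` objects with
#'   matching columns.
#' @param burnin1,burnin2 Per-chain burn-in (fraction below 1 or count).
#' @return An `mcmc_comparison` list with `tests` (per-parameter
#'   `two_sample_test`s), `split_tests` (per tree column), and `joint`
#'   (summaries on the combined trace).
#' @export
run_compare <- function(input1, input2, burnin1 = 0, burnin2 = 0) {
  t1 <- resolve_trace(input1)
  t2 <- resolve_trace(input2)
  b1 <- resolve_burnin(burnin1, t1$n_samples)
  b2 <- resolve_burnin(burnin2, t2$n_samples)
  if (is.na(b1) || is.na(b2)) stop("compare requires explicit burn-ins")
  if (!identical(t1$columns$name, t2$columns$name) ||
      !identical(t1$columns$kind, t2$columns$kind)) {
    stop("chains have mismatching columns")
  }
  tests <- list()
  for (nm in names(t1$numeric)) {
    x <- t1$numeric[[nm]][seq.int(b1 + 1L, t1$n_samples)]
    y <- t2$numeric[[nm]][seq.int(b2 + 1L, t2$n_samples)]
    tests[[nm]] <- mann_whitney(x, y)
  }
  split_tests <- list()
  for (nm in names(t1$trees)) {
    st <- split_table(t1$trees[[nm]], t2$trees[[nm]], b1, b2)
    split_tests[[nm]] <- tryCatch(split_chisq(st), error = function(e) {
      structure(list(statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_, n_categories = length(st$splits),
                     method = "chisq_splits", n1 = st$n1, n2 = st$n2,
                     note = conditionMessage(e)),
                class = "two_sample_test")
    })
  }
  joint <- combine_chains(t1, t2, b1, b2)
  joint_summaries <- lapply(names(joint$numeric), function(nm) {
    summarize_series(joint$numeric[[nm]], burnin = 0, name = nm)
  })
  names(joint_summaries) <- names(joint$numeric)
  structure(list(input1 = t1$source, input2 = t2$source,
                 burnin1 = b1, burnin2 = b2,
                 tests = tests,
                 split_tests = split_tests,
                 joint = joint_summaries,
                 n_joint = joint$n_samples),
            class = "mcmc_comparison")
}

#' @export
print.mcmc_comparison <- function(x, ...) {
  cat(sprintf("Parallel-chain comparison (%s vs %s), burn-ins %d / %d\n",
              x$input1, x$input2, x$burnin1, x$burnin2))
  for (nm in names(x$tests)) {
    cat(sprintf("  %s: ", nm))
    print(x$tests[[nm]])
  }
  for (nm in names(x$split_tests)) {
    cat(sprintf("  %s (splits): ", nm))
    print(x$split_tests[[nm]])
  }
  invisible(x)
}

# Recursively: drop S3 classes, round numerics to 6 significant digits,
# and sort list names, so serialization is byte-reproducible.
canonical_report <- function(x) {
  if (inherits(x, "data.frame")) {
    x <- lapply(as.list(x), canonical_report)
    return(x[order(names(x))])
  }
  if (is.list(x)) {
    x <- lapply(unclass(x), canonical_report)
    if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[order(names(x))]
    return(x)
  }
  if (is.double(x)) return(signif(x, 6))
  x
}

#' Serialize a report to reproducible JSON
#'
#' Converts an `mcmc_report` or `mcmc_comparison` (or any nested list) to
#' JSON with sorted keys and floats fixed at 6 significant digits, so that
#' identical inputs and flags always produce byte-identical output --
#' convenient for pipelines that diff or cache reports.
#'
#' @param report The object to serialize.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  doc <- canonical_report(report)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Trace plot of one numeric parameter
#'
#' Plots a parameter trace against the sample index, optionally shading the
#' burn-in region and coloring the samples at which selected tree topologies
#' occur (see [mark_occurrences()]) -- the standard visual check of mixing and
#' of tree/parameter dependence.
#'
#' @param table A `trace_table`.
#' @param parameter Name of the numeric column (default: first one).
#' @param burnin Burn-in count to shade (0 for none).
#' @param marks Optional list of index vectors (as from [mark_occurrences()])
#'   to color.
#' @param ... Passed to [plot.default()].
#' @return Invisibly, the plotted values.
#' @export
traceplot <- function(table, parameter = names(table$numeric)[1L], burnin = 0,
                      marks = NULL, ...) {
  stopifnot(inherits(table, "trace_table"))
  x <- table$numeric[[parameter]]
  if (is.null(x)) stop("no numeric parameter named '", parameter, "'")
  idx <- seq_along(x) - 1L
  plot(idx, x, type = "l", col = "grey40", xlab = "sample",
       ylab = parameter, ...)
  if (burnin > 0) {
    graphics::abline(v = burnin, lty = 2, col = "red3")
  }
  if (!is.null(marks)) {
    cols <- grDevices::hcl.colors(max(2L, length(marks)), "Dark 3")
    for (i in seq_along(marks)) {
      sel <- marks[[i]] + 1L
      graphics::points(idx[sel], x[sel], col = cols[i], pch = 16, cex = 0.4)
    }
  }
  invisible(x)
}
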