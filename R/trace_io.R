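# Column names (case-insensitive) treated as the iteration counter, not a parameter.
GENERATION_NAMES <- c("gen", "state", "sample", "iteration")

#' Parse an MCMC trace file
#'
#' Reads a tab-delimited MCMC trace in the dialects written by MrBayes (`.p`),
#' BEAST (`.log`) and PrIMe/JPrIME, or a NEXUS tree-trace file (`.t`) with an
#' optional `Translate` block. Comment lines -- lines whose first non-blank
#' character is `#` (BEAST-style preambles) or, before the header, `[` (the
#' MrBayes ID line) -- are skipped; the exact set of preamble quirks accepted
#' by individual MCMC programs is not standardised, so this rule is a
#' deliberately permissive superset. The first remaining line is the
#' tab-separated header; every subsequent non-empty line is one sample.
#'
#' A column named (case-insensitively) `Gen`, `state`, `Sample` or `Iteration`
#' becomes the generation index. Every other column is classified `numeric` if
#' all of its values parse as decimal numbers (scientific notation and
#' `NA`/`NaN` tokens allowed), `tree` if all of its non-empty values parse as
#' Newick strings ending in `;`, and `ignored` otherwise.
#'
#' Fields are split on tab characters only; runs of spaces are not separators,
#' which keeps Newick strings containing spaces intact.
#'
#' @param input Path to a trace file, or the trace content itself as a single
#'   string containing newlines (or a character vector of lines).
#' @param dialect `"auto"` (default), `"tabular"` or `"nexus_trees"`. Under
#'   `"auto"`, content whose first non-whitespace characters are `#NEXUS` is
#'   read as a NEXUS tree trace; anything else as a tabular trace.
#' @return A `trace_table`: a list with elements `source`, `n_samples`,
#'   `columns` (data frame of `name`, `kind`), `numeric` (named list of numeric
#'   vectors), `trees` (named list of Newick character vectors) and
#'   `generation` (integer vector or `NULL`).
#' @examples
#' tab <- parse_trace("Gen\tlnL\n0\t-10.0\n100\t-9.5\n")
#' tab$n_samples
#' tab$numeric$lnL
#' @seealso [extract_interval()], [write_trace()]
#' @export
parse_trace <- function(input, dialect = c("auto", "tabular", "nexus_trees")) {
  dialect <- match.arg(dialect)
  src <- "<text>"
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    src <- input
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE))
  }
  if (dialect == "auto") {
    first <- trimws(paste(lines, collapse = "\n"))
    dialect <- if (startsWith(first, "#NEXUS")) "nexus_trees" else "tabular"
  }
  if (dialect == "nexus_trees") {
    parse_nexus_trees(lines, src)
  } else {
    parse_tabular(lines, src)
  }
}

parse_tabular <- function(lines, src) {
  is_blank <- !nzchar(trimws(lines))
  first_char <- substr(trimws(lines), 1L, 1L)
  keep <- !is_blank & first_char != "#"
  # MrBayes-style bracketed ID lines are only legal before the header.
  header_at <- which(keep & first_char != "[")
  if (length(header_at) == 0L) stop("no samples: input contains no header line")
  header_at <- header_at[1L]
  header <- strsplit(lines[header_at], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (anyDuplicated(header)) stop("duplicate column names in header")
  body_idx <- which(keep)
  body_idx <- body_idx[body_idx > header_at]
  if (length(body_idx) == 0L) stop("no samples: header present but no data rows")

  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop(sprintf("ragged row at line %d: expected %d fields, got %d",
                 body_idx[bad[1L]], length(header), nf[bad[1L]]))
  }
  n <- length(rows)
  cells <- matrix(unlist(rows), nrow = n, byrow = TRUE)

  generation <- NULL
  gen_col <- which(tolower(header) %in% GENERATION_NAMES)
  columns <- data.frame(name = character(0), kind = character(0),
                        stringsAsFactors = FALSE)
  numeric_data <- list()
  tree_data <- list()
  for (j in seq_along(header)) {
    vals <- trimws(cells[, j])
    if (length(gen_col) && j == gen_col[1L]) {
      g <- suppressWarnings(as.numeric(vals))
      if (anyNA(g)) stop("generation column contains non-numeric values")
      if (n > 1L && any(diff(g) <= 0)) {
        stop("generation column is not strictly increasing")
      }
      generation <- g
      next
    }
    kind <- classify_column(vals)
    columns <- rbind(columns, data.frame(name = header[j], kind = kind,
                                         stringsAsFactors = FALSE))
    if (kind == "numeric") {
      numeric_data[[header[j]]] <- suppressWarnings(as.numeric(vals))
    } else if (kind == "tree") {
      tree_data[[header[j]]] <- vals
    }
  }
  new_trace_table(src, n, columns, numeric_data, tree_data, generation)
}

classify_column <- function(vals) {
  num <- suppressWarnings(as.numeric(vals))
  na_tok <- toupper(vals) %in% c("NA", "NAN")
  if (all(!is.na(num) | na_tok)) return("numeric")
  nonempty <- vals[nzchar(vals)]
  if (length(nonempty) && all(grepl(";\\s*$", nonempty)) &&
      all(vapply(nonempty, is_newick, logical(1L)))) {
    return("tree")
  }
  "ignored"
}

is_newick <- function(x) {
  tr <- tryCatch(ape::read.tree(text = x), error = function(e) NULL)
  !is.null(tr) && inherits(tr, "phylo")
}

parse_nexus_trees <- function(lines, src) {
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  trees <- tryCatch(ape::read.nexus(tmp, force.multi = TRUE),
                    error = function(e) {
                      stop("unparseable NEXUS input: ", conditionMessage(e))
                    })
  if (length(trees) == 0L) stop("no samples: NEXUS file contains no trees")
  newicks <- vapply(trees, ape::write.tree, character(1L))
  columns <- data.frame(name = "tree", kind = "tree", stringsAsFactors = FALSE)
  new_trace_table(src, length(newicks), columns, list(),
                  list(tree = unname(newicks)), NULL)
}

#' Construct a trace table in memory
#'
#' Builds a `trace_table` directly from vectors, the same structure that
#' [parse_trace()] produces from a file. Mainly useful together with the
#' synthetic generators ([gen_ar1()], [gen_tree_trace()]) and [write_trace()].
#'
#' @param numeric Named list of numeric sample vectors.
#' @param trees Named list of Newick character vectors.
#' @param generation Optional strictly increasing iteration numbers.
#' @param source Label recorded as the table's origin.
#' @return A `trace_table`.
#' @examples
#' tab <- trace_table(numeric = list(lnL = rnorm(10)))
#' @export
trace_table <- function(numeric = list(), trees = list(), generation = NULL,
                        source = "<memory>") {
  stopifnot(is.list(numeric), is.list(trees))
  lens <- c(lengths(numeric), lengths(trees),
            if (!is.null(generation)) length(generation))
  if (length(lens) == 0L) stop("no columns")
  n <- unique(lens)
  if (length(n) != 1L) stop("all columns must have the same length")
  if (!is.null(generation) && n > 1L && any(diff(generation) <= 0)) {
    stop("generation must be strictly increasing")
  }
  columns <- data.frame(
    name = c(names(numeric), names(trees)),
    kind = c(rep("numeric", length(numeric)), rep("tree", length(trees))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(columns$name) || any(!nzchar(columns$name))) {
    stop("columns must have unique non-empty names")
  }
  new_trace_table(source, n, columns, numeric, trees, generation)
}

new_trace_table <- function(src, n, columns, numeric_data, tree_data,
                            generation) {
  structure(list(source = src,
                 n_samples = as.integer(n),
                 columns = columns,
                 numeric = numeric_data,
                 trees = tree_data,
                 generation = generation),
            class = "trace_table")
}

#' Extract a sub-interval of a trace
#'
#' Returns the samples in the half-open, 0-based interval `[start, end)` of
#' every column, order preserved. `extract_interval(x, 0, x$n_samples)` is the
#' identity.
#'
#' @param table A `trace_table` from [parse_trace()].
#' @param start First sample to keep (0-based, inclusive).
#' @param end First sample to drop (exclusive). Defaults to the end.
#' @return A `trace_table` with `end - start` samples.
#' @export
extract_interval <- function(table, start, end = table$n_samples) {
  stopifnot(inherits(table, "trace_table"))
  n <- table$n_samples
  if (!(start >= 0 && start < end && end <= n)) {
    stop(sprintf("invalid interval [%s, %s) for a trace of %d samples",
                 format(start), format(end), n))
  }
  idx <- seq.int(start + 1L, end)
  new_trace_table(table$source, length(idx), table$columns,
                  lapply(table$numeric, `[`, idx),
                  lapply(table$trees, `[`, idx),
                  if (!is.null(table$generation)) table$generation[idx])
}

#' @export
print.trace_table <- function(x, ...) {
  cat(sprintf("MCMC trace (%s): %d samples\n", x$source, x$n_samples))
  if (!is.null(x$generation)) {
    cat(sprintf("  generation: %s .. %s\n",
                format(x$generation[1L]),
                format(x$generation[x$n_samples])))
  }
  for (i in seq_len(nrow(x$columns))) {
    cat(sprintf("  %-24s %s\n", x$columns$name[i], x$columns$kind[i]))
  }
  invisible(x)
}
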