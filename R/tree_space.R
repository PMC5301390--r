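#' Unweighted Robinson-Foulds distance
#'
#' The size of the symmetric difference between the two trees' sets of
#' non-trivial leaf bipartitions. Branch lengths and rootings are ignored;
#' both trees must carry exactly the same leaf labels. For fully binary trees
#' the distance is always even and at most `2 * (L - 3)`; polytomies are
#' allowed, in which case odd values can occur.
#'
#' @param t1,t2 Newick strings or [ape::phylo] objects on the same leaf set.
#' @return A non-negative integer; 0 exactly when the unrooted topologies are
#'   identical.
#' @examples
#' rf_distance("((a,b),(c,d));", "((a,c),(b,d));") # 2
#' @export
rf_distance <- function(t1, t2) {
  if (is.character(t1)) t1 <- parse_newick(t1)
  if (is.character(t2)) t2 <- parse_newick(t2)
  l1 <- sort(t1$tip.label, method = "radix")
  l2 <- sort(t2$tip.label, method = "radix")
  if (!identical(l1, l2)) stop("trees must have identical leaf label sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

rf_from_splits <- function(s1, s2) {
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Robinson-Foulds distance matrix over the frequent topologies
#'
#' Builds the pairwise unweighted RF distance matrix over the unique
#' topologies of a tree posterior whose posterior probability reaches
#' `threshold` (default 0.002, i.e. 0.2% -- topologies below that carry
#' negligible posterior mass and only slow the quadratic distance
#' computation). When more than `warn_limit` topologies qualify a warning is
#' emitted -- the computation still runs, the warning just flags that
#' downstream tree-space analysis will be slow and crowded.
#'
#' @param posterior A `tree_posterior` from [topology_frequencies()].
#' @param threshold Minimum posterior probability for inclusion.
#' @param warn_limit Topology count above which the delay warning fires.
#' @return An `rf_matrix` list: `d` (symmetric integer matrix), `newick`,
#'   `probability`, `key` (parallel vectors describing the retained
#'   topologies), `threshold`, `warn_limit`.
#' @export
rf_matrix <- function(posterior, threshold = 0.002, warn_limit = 45L) {
  stopifnot(inherits(posterior, "tree_posterior"))
  keep <- which(posterior$entries$probability >= threshold)
  if (length(keep) == 0L) {
    stop(sprintf("no topology reaches the %g posterior-probability threshold",
                 threshold))
  }
  if (length(keep) > warn_limit) {
    warning(sprintf(paste("tree space contains %d topologies above the %g",
                          "frequency threshold (> %d); expect a delay"),
                    length(keep), threshold, warn_limit))
  }
  splits <- posterior$splits[keep]
  m <- length(keep)
  d <- matrix(0L, m, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        d[i, j] <- d[j, i] <- rf_from_splits(splits[[i]], splits[[j]])
      }
    }
  }
  structure(list(d = d,
                 newick = posterior$entries$newick[keep],
                 probability = posterior$entries$probability[keep],
                 key = posterior$entries$key[keep],
                 threshold = threshold,
                 warn_limit = as.integer(warn_limit)),
            class = "rf_matrix")
}

#' @export
print.rf_matrix <- function(x, ...) {
  cat(sprintf("RF distance matrix over %d topologies (threshold %g)\n",
              nrow(x$d), x$threshold))
  if (nrow(x$d) > 1L) {
    cat(sprintf("  distances: min %d, max %d\n",
                min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  }
  invisible(x)
}

#' Write an RF distance matrix as tab-separated text
#'
#' @param x An `rf_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rf_matrix <- function(x, path) {
  stopifnot(inherits(x, "rf_matrix"))
  m <- x$d
  dimnames(m) <- list(paste0("T", seq_len(nrow(m)) - 1L),
                      paste0("T", seq_len(nrow(m)) - 1L))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Two-dimensional tree-space embedding by classical MDS
#'
#' Projects the topologies of an RF distance matrix into the plane with
#' classical (Torgerson) multidimensional scaling: the doubly-centered matrix
#' `B = -1/2 * J %*% D^2 %*% J` is eigendecomposed and the top two
#' non-negative eigenpairs give the coordinates (negative eigenvalues are
#' clamped to zero, so non-Euclidean distance sets lose their residual).
#' Similar topologies land near each other; point sizes in the companion
#' [plot()] method reflect posterior probability, so well-separated heavy
#' clusters are the visual signature of a multimodal tree posterior.
#'
#' The eigenvector sign indeterminacy is resolved by making the first nonzero
#' coordinate of each axis positive, so the embedding is reproducible;
#' comparisons against other MDS implementations should still be made up to
#' rotation/reflection.
#'
#' @param dm An `rf_matrix`, or a bare symmetric distance matrix.
#' @return A `tree_embedding` data frame with columns `topology_index`
#'   (0-based, matching the matrix order), `x`, `y`, `probability`.
#' @export
mds_2d <- function(dm) {
  if (inherits(dm, "rf_matrix")) {
    d <- dm$d
    prob <- dm$probability
  } else {
    d <- as.matrix(dm)
    prob <- rep(NA_real_, nrow(d))
  }
  n <- nrow(d)
  coords <- matrix(0, n, 2L)
  if (n > 1L && any(d != 0)) {
    fit <- suppressWarnings(stats::cmdscale(d, k = min(2L, n - 1L),
                                            eig = TRUE))
    pts <- fit$points
    if (!is.null(pts) && ncol(pts) > 0L) {
      keep <- seq_len(min(2L, ncol(pts)))
      coords[, keep] <- pts[, keep, drop = FALSE]
    }
  }
  for (j in 1:2) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1L], j] < 0) coords[, j] <- -coords[, j]
  }
  structure(data.frame(topology_index = seq_len(n) - 1L,
                       x = coords[, 1L],
                       y = coords[, 2L],
                       probability = prob),
            class = c("tree_embedding", "data.frame"))
}

#' Scatter plot of a tree-space embedding
#'
#' @param x A `tree_embedding` from [mds_2d()].
#' @param ... Further arguments passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.tree_embedding <- function(x, ...) {
  size <- if (all(is.na(x$probability))) rep(1, nrow(x)) else
    0.5 + 4 * sqrt(x$probability)
  plot(x$x, x$y, cex = size, pch = 21, bg = "steelblue",
       xlab = "MDS axis 1", ylab = "MDS axis 2",
       main = "Tree space (classical MDS of RF distances)", asp = 1, ...)
  graphics::text(x$x, x$y, labels = paste0("T", x$topology_index),
                 pos = 3, cex = 0.7)
  invisible(x)
}
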