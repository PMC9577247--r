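#' Z-standardize a metric matrix
#'
#' Centres to mean zero and scales to unit sample standard deviation along
#' the chosen axis (`"metrics"`: each column; `"samples"`: each row).
#' Zero-spread columns/rows are mapped to all zeros and recorded in the
#' `"flagged"` attribute rather than failing.
#'
#' @param m a [metric_matrix()] (or plain labelled matrix).
#' @param axis `"metrics"` (default) or `"samples"`.
#' @return A [metric_matrix()] with attribute `flagged` (labels with zero
#'   spread).
#' @export
standardize <- function(m, axis = c("metrics", "samples")) {
  axis <- match.arg(axis)
  x <- unclass(as.matrix(m))
  if (axis == "samples") x <- t(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  flagged <- colnames(x)[sdv == 0]
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  z[, colnames(x) %in% flagged] <- 0
  if (axis == "samples") z <- t(z)
  out <- metric_matrix(z, directions = attr(m, "directions"))
  attr(out, "flagged") <- flagged
  out
}

#' Pairwise distance matrix
#'
#' Distances between samples (rows) or metrics (columns) of a matrix, taken
#' as given (standardize first for the usual pipeline). `"euclidean"` is the
#' plain L2 distance; `"correlation"` is `1 - Pearson r` (identical profiles
#' at 0, perfect anti-correlation at 2).
#'
#' @param m a [metric_matrix()] (or plain labelled matrix).
#' @param axis `"samples"` or `"metrics"`.
#' @param measure `"euclidean"` or `"correlation"`.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
pairwise_distance <- function(m, axis = c("samples", "metrics"),
                              measure = c("euclidean", "correlation")) {
  axis <- match.arg(axis)
  measure <- match.arg(measure)
  x <- unclass(as.matrix(m))
  if (axis == "metrics") x <- t(x)
  if (nrow(x) < 2L) {
    stop("need at least 2 items on the chosen axis", call. = FALSE)
  }
  d <- if (measure == "euclidean") {
    as.matrix(stats::dist(x, method = "euclidean"))
  } else {
    1 - stats::cor(t(x))
  }
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, class = c("dist_matrix", "matrix", "array"),
            measure = measure)
}

#' Agglomerative hierarchical clustering
#'
#' Standard Lance-Williams agglomeration over a distance matrix. Labels are
#' sorted lexicographically before merging, so equal-distance ties always
#' break towards the smallest label pair and the dendrogram is reproducible
#' regardless of input order. `"ward"` is Ward's minimum-variance criterion
#' on distances (ward.D2).
#'
#' @param dist a [pairwise_distance()] matrix (any symmetric non-negative
#'   labelled matrix with zero diagonal works).
#' @param linkage `"average"`, `"complete"`, `"single"` or `"ward"`.
#' @return An object of class `dendro` wrapping the merge tree: `$merges`
#'   (n-1 rows: node, node, height; negative entries are leaves), `$labels`,
#'   `$linkage`, and the underlying `stats::hclust` fit in `$hclust`.
#' @export
agglomerate <- function(dist, linkage = c("average", "complete", "single",
                                          "ward")) {
  linkage <- match.arg(linkage)
  d <- unclass(as.matrix(dist))
  if (is.null(rownames(d)) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(diag(d) != 0) || any(d < 0)) {
    stop("dist must be a labelled symmetric non-negative matrix with zero ",
         "diagonal", call. = FALSE)
  }
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d),
                      method = switch(linkage, ward = "ward.D2", linkage))
  structure(
    list(
      merges = cbind(hc$merge, height = hc$height),
      labels = hc$labels,
      linkage = linkage,
      hclust = hc
    ),
    class = "dendro"
  )
}

#' @export
print.dendro <- function(x, ...) {
  cat("Dendrogram: ", length(x$labels), " leaves, ", x$linkage,
      " linkage, top height ", format(max(x$merges[, "height"])), "\n",
      sep = "")
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' Removes the k-1 highest merges. Group labels are deterministic: the group
#' containing the lexicographically smallest leaf is 1, the group with the
#' smallest leaf among the rest is 2, and so on.
#'
#' @param x a `dendro` from [agglomerate()].
#' @param k number of groups, `1 <= k <= n`.
#' @param ... unused.
#' @return Named integer vector: leaf -> group in `1..k`.
#' @export
cut.dendro <- function(x, k, ...) {
  n <- length(x$labels)
  if (k < 1L || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  raw <- stats::cutree(x$hclust, k = k)
  first_leaf <- vapply(split(names(raw), raw),
                       function(lv) min(lv), character(1))
  relabel <- match(names(sort(first_leaf, method = "radix")),
                   names(first_leaf))
  out <- match(raw, relabel)
  names(out) <- names(raw)
  out[order(names(out), method = "radix")]
}

# Newick subtree for merge-tree node i (negative = leaf index). Children
# are ordered by their lexicographically smallest leaf, so the string is
# canonical. Returns c(newick, smallest leaf label).
newick_node <- function(node, merges, labels, parent_height) {
  if (node < 0) {
    lab <- gsub("[(),:;[:space:]]", "_", labels[-node])
    return(c(sprintf("%s:%.15g", lab, parent_height), lab))
  }
  h <- merges[node, 3L]
  a <- newick_node(merges[node, 1L], merges, labels, h)
  b <- newick_node(merges[node, 2L], merges, labels, h)
  if (b[2L] < a[2L]) { tmp <- a; a <- b; b <- tmp }
  c(sprintf("(%s,%s):%.15g", a[1L], b[1L], parent_height - h),
    a[2L])
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths are height differences: a leaf's branch is its parent's
#' merge height (leaves sit at height 0), an internal node's branch is its
#' parent's height minus its own, so root-to-leaf path length equals the top
#' merge height. Label characters that would break the format are replaced
#' with underscores.
#'
#' @param x a `dendro` from [agglomerate()].
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(x) {
  merges <- x$merges
  n <- nrow(merges)
  h <- merges[n, 3L]
  a <- newick_node(merges[n, 1L], merges, x$labels, h)
  b <- newick_node(merges[n, 2L], merges, x$labels, h)
  if (b[2L] < a[2L]) { tmp <- a; a <- b; b <- tmp }
  sprintf("(%s,%s);", a[1L], b[1L])
}

#' Default clustering pipelines
#'
#' `cluster_metrics()`: z-standardize metrics, correlation distance between
#' metrics, average linkage. `cluster_samples()`: z-standardize metrics,
#' Euclidean distance between samples, Ward linkage. Both are the
#' field-standard defaults and fully overridable.
#'
#' @param m a [metric_matrix()].
#' @param measure,linkage see [pairwise_distance()] and [agglomerate()].
#' @return A `dendro`.
#' @export
cluster_metrics <- function(m, measure = "correlation",
                            linkage = "average") {
  agglomerate(pairwise_distance(standardize(m, "metrics"), "metrics",
                                measure), linkage)
}

#' @rdname cluster_metrics
#' @export
cluster_samples <- function(m, measure = "euclidean", linkage = "ward") {
  agglomerate(pairwise_distance(standardize(m, "metrics"), "samples",
                                measure), linkage)
}
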