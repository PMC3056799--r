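#' Average-linkage (UPGMA) agglomeration of a dissimilarity matrix
#'
#' Wrapper over [stats::hclust()] with `method = "average"`, where the
#' inter-cluster distance is the mean of all pairwise dissimilarities.
#' Merge heights are non-decreasing on a valid dissimilarity.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix with labels.
#' @return An `hclust` tree.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  stats::hclust(d, method = "average")
}

#' Hierarchical clustering of arrays
#'
#' Clusters the samples of an experiment by average linkage on pairwise
#' dissimilarities of their log2 expression profiles. The default metric is
#' 1 - Pearson correlation (standard for arrays); Euclidean distance is
#' available by flag. The probe universe defaults to the per-group present
#' filter (present on at least half of the arrays of some single group).
#' Samples are ordered lexicographically by id before clustering so that
#' input order never affects tie-breaking.
#'
#' @param exp An `"expression_experiment"` with >= 3 samples.
#' @param probes Probe universe; `NULL` uses
#'   `present_filter(exp, per_group_conditions())`.
#' @param metric `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param floor Signal floor for [log_transform()].
#' @return An object of classes `"array_dendrogram"` and `"hclust"`.
#' @export
cluster_arrays <- function(exp, probes = NULL,
                           metric = c("correlation", "euclidean"),
                           floor = 1) {
  metric <- match.arg(metric)
  if (ncol(exp$signal) < 3L)
    stop("need >= 3 samples to cluster", call. = FALSE)
  if (is.null(probes))
    probes <- present_filter(exp, per_group_conditions())$retained_probe_ids
  logm <- log_transform(exp, floor)[probes, , drop = FALSE]
  logm <- logm[, order(colnames(logm)), drop = FALSE]
  if (metric == "correlation") {
    sds <- apply(logm, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant expression profile, correlation undefined for sample: ",
           colnames(logm)[which(sds == 0)[1L]], call. = FALSE)
    d <- stats::as.dist(1 - stats::cor(logm))
  } else {
    d <- stats::dist(t(logm))
  }
  tree <- upgma(d)
  class(tree) <- c("array_dendrogram", "hclust")
  tree
}

#' Cut a dendrogram into k groups
#'
#' Removes the k - 1 highest merges.
#'
#' @param tree An `hclust`/`"array_dendrogram"` tree.
#' @param k Number of groups, between 1 and the number of samples.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n)
    stop("k must be between 1 and the number of samples", call. = FALSE)
  stats::cutree(tree, k = k)
}

#' Serialize a dendrogram as Newick with branch lengths
#'
#' @param tree An `hclust`/`"array_dendrogram"` tree.
#' @return A single Newick string.
#' @export
as_newick <- function(tree) {
  class(tree) <- "hclust"
  ape::write.tree(ape::as.phylo(tree))
}
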