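#' Single-linkage clusters at a similarity threshold
#'
#' Drug libraries contain many near-duplicates optimized from the same
#' lead; keeping them all makes cross-validation trivially easy. Cutting a
#' single-linkage dendrogram at similarity `threshold` is equivalent to
#' taking connected components of the graph with an edge wherever pairwise
#' similarity is strictly greater than the threshold — two drugs land in
#' the same cluster iff they are connected by a chain of similarities
#' above it. The comparison is strict: ties at exactly the threshold do
#' not merge.
#'
#' @param S Symmetric similarity matrix with entity row names.
#' @param threshold Similarity cut in (0, 1\].
#' @return Named integer vector of cluster labels (1-based, in order of
#'   first appearance over sorted entity ids).
#' @export
single_linkage_clusters <- function(S, threshold) {
  stopifnot(isSymmetric(unname(S), tol = 1e-8), !is.null(rownames(S)))
  ids <- sort(rownames(S))
  A <- S[ids, ids] > threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  memb <- igraph::components(g)$membership
  names(memb) <- ids
  memb
}

#' Pick one representative drug per cluster
#'
#' One member is chosen uniformly at random from each cluster (seeded, so
#' reproducible). Selection depends only on sorted cluster membership, not
#' on input order.
#'
#' @param clusters Named cluster label vector from
#'   [single_linkage_clusters()].
#' @param seed RNG seed.
#' @return Character vector of representative drug ids, sorted.
#' @export
select_representatives <- function(clusters, seed = 1) {
  stopifnot(!is.null(names(clusters)))
  ord <- order(names(clusters))
  clusters <- clusters[ord]
  set.seed(seed)
  reps <- vapply(split(names(clusters), clusters), function(members) {
    stopifnot(length(members) > 0)
    members[sample.int(length(members), 1)]
  }, character(1))
  sort(unname(reps))
}

#' Sweep representative selection over a threshold grid
#'
#' Runs the cluster/select procedure at each threshold (default 0.1 to 1.0
#' in 0.1 steps). Because single-linkage components nest, the number of
#' clusters — hence representatives — is non-decreasing in the threshold.
#'
#' @param S Symmetric similarity matrix.
#' @param thresholds Numeric vector of cuts in (0, 1\].
#' @param seed RNG seed for the per-threshold representative draws.
#' @return Data-frame-free list: one element per threshold with fields
#'   `threshold`, `clusters`, `representatives`.
#' @export
representative_sweep <- function(S, thresholds = seq(0.1, 1, by = 0.1),
                                 seed = 1) {
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  lapply(thresholds, function(t) {
    cl <- single_linkage_clusters(S, t)
    list(threshold = t, clusters = cl,
         representatives = select_representatives(cl, seed = seed))
  })
}

#' Write a representative sweep as TSV
#'
#' One row per (threshold, drug): `drug_id`, `cluster_id`,
#' `is_representative`, `threshold`.
#'
#' @param sweep Result of [representative_sweep()].
#' @param path Output path.
#' @export
write_representatives <- function(sweep, path) {
  rows <- do.call(rbind, lapply(sweep, function(s)
    data.frame(drug_id = names(s$clusters),
               cluster_id = unname(s$clusters),
               is_representative = names(s$clusters) %in% s$representatives,
               threshold = s$threshold)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
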