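#' Inter-sample Spearman similarity matrix
#'
#' Pairwise Spearman rank-order correlation between sample expression
#' profiles, computed across genes with midranks for ties. Being rank-based,
#' the similarity is invariant to any strictly increasing per-sample
#' transform of expression.
#'
#' @param expr expression matrix with at least 2 genes and 2 samples.
#' @return symmetric samples x samples matrix with unit diagonal.
#' @export
spearman_similarity <- function(expr) {
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  const <- apply(expr, 2L, function(x) max(x) == min(x))
  if (any(const))
    stop("constant expression profile, Spearman undefined for sample(s): ",
         paste(colnames(expr)[const], collapse = ", "), call. = FALSE)
  s <- cor(expr, method = "spearman")
  diag(s) <- 1
  s
}

#' Ward hierarchical clustering of a similarity matrix
#'
#' Agglomerates samples by Ward's minimum variance method on Euclidean
#' distances computed between the ROWS of the similarity matrix (each sample
#' is represented by its vector of similarities to all samples). The
#' alternative reading, `distance = "one-minus-cor"`, uses `1 - similarity`
#' directly as the dissimilarity.
#'
#' @param sim symmetric similarity matrix with sample identifiers as
#'   dimnames (e.g. from [spearman_similarity()]).
#' @param k number of clusters to cut, `2 <= k <= n - 1`.
#' @param distance `"euclidean"` (rows of the similarity matrix, default) or
#'   `"one-minus-cor"`.
#' @return a list with `assignment` (named integer cluster labels),
#'   `hclust` (the dendrogram) and `newick` (the dendrogram serialized as a
#'   Newick string).
#' @export
ward_cluster <- function(sim, k, distance = c("euclidean", "one-minus-cor")) {
  distance <- match.arg(distance)
  n <- ncol(sim)
  if (k < 2L || k > n - 1L)
    stop("k must satisfy 2 <= k <= n - 1", call. = FALSE)
  d <- if (distance == "euclidean") dist(sim) else stats::as.dist(1 - sim)
  hc <- hclust(d, method = "ward.D2")
  assignment <- cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(assignment = assignment, hclust = hc, newick = newick)
}

#' Concordance between a clustering and the response labels
#'
#' Adjusted Rand index between a cluster assignment and the binary response;
#' 1 means the clustering recovers the responder split exactly, values near
#' 0 mean chance-level agreement. The degenerate single-cluster partition
#' returns 0.
#'
#' @param assignment named vector of cluster labels (names are sample ids).
#' @param labels a [response_table()] covering the same samples.
#' @return the adjusted Rand index.
#' @export
cluster_label_concordance <- function(assignment, labels) {
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by sample id", call. = FALSE)
  miss <- setdiff(ids, labels$sample_id)
  if (length(miss))
    stop("samples missing from response table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- labels$response[match(ids, labels$sample_id)]
  ari <- mclust::adjustedRandIndex(assignment, y)
  if (is.nan(ari)) 0 else ari
}
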