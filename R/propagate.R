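#' UMAP embedding of the marker expression matrix
#'
#' Projects all retained cells (representative and leftover alike) to two
#' dimensions from the marker-restricted log-normalized matrix, so that
#' leftover cells can be labelled by their nearest annotated neighbour in
#' a space that preserves the local structure of the data.
#'
#' @param sce SingleCellExperiment with `logcounts`; at least 3 cells.
#' @param nNeighbors UMAP neighbourhood size (default 15, clamped to
#'   n - 1 with a warning when the data are smaller).
#' @param minDist UMAP `min_dist` (default 0.1).
#' @param seed RNG seed; fixed seed gives identical coordinates.
#' @return numeric matrix (cells x 2) with cell ids as rownames.
#' @export
embed2D <- function(sce, nNeighbors = 15L, minDist = 0.1, seed = 1L) {
  X <- t(SummarizedExperiment::assay(sce, "logcounts"))
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 cells to embed")
  if (nNeighbors >= n) {
    warning("n_neighbors clamped from ", nNeighbors, " to ", n - 1L)
    nNeighbors <- n - 1L
  }
  set.seed(seed)
  # spectral initialization needs a non-degenerate neighbour graph;
  # fall back to random placement for very small inputs
  init <- if (n < 20L) "random" else "spectral"
  coords <- uwot::umap(X, n_neighbors = nNeighbors, min_dist = minDist,
                       metric = "euclidean", n_threads = 1,
                       n_sgd_threads = 0, init = init)
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Propagate labels to unlabelled cells by k nearest neighbours
#'
#' Each unlabelled cell receives the majority label of its k nearest
#' labelled cells by Euclidean distance in the embedding (default k = 1:
#' the single nearest annotated cell). Distance ties are broken by the
#' smallest cell index in the labelled set, majority ties by the closest
#' of the tied labels; both rules are deterministic.
#'
#' @param emb coordinate matrix with cell ids as rownames (any
#'   dimensionality; typically the 2-D embedding from [embed2D()]).
#' @param labeled named character vector: labels of the annotated cells.
#' @param unlabeled character vector of cell ids to annotate; must be
#'   disjoint from `names(labeled)`.
#' @param k number of neighbours (default 1).
#' @return named character vector of labels for `unlabeled`.
#' @export
knnAssign <- function(emb, labeled, unlabeled, k = 1L) {
  stopifnot(length(labeled) >= 1L, k >= 1L)
  if (length(intersect(names(labeled), unlabeled)))
    stop("labeled and unlabeled cell sets overlap")
  if (length(unlabeled) == 0L)
    return(stats::setNames(character(), character()))
  k <- min(k, length(labeled))
  L <- emb[names(labeled), , drop = FALSE]
  Q <- emb[unlabeled, , drop = FALSE]
  # squared Euclidean distances via the expansion |q|^2 + |l|^2 - 2 q.l
  d2 <- outer(rowSums(Q^2), rowSums(L^2), "+") - 2 * tcrossprod(Q, L)
  out <- vapply(seq_len(nrow(Q)), function(i) {
    ord <- order(d2[i, ], seq_along(labeled))  # ties: smallest cell index
    nn <- ord[seq_len(k)]
    votes <- table(labeled[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # majority tie: the tied label whose member appears earliest by distance
    labeled[nn][match(TRUE, labeled[nn] %in% top)]
  }, "")
  stats::setNames(out, unlabeled)
}
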