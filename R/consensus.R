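#' @describeIn ari Hubert-Arabie adjusted Rand index computed from the
#'   contingency table of the two assignments. When the chance-corrected
#'   denominator is zero (both partitions all-in-one, or both all
#'   singletons), the partitions are identical and 1 is returned.
#' @export
setMethod("ari", signature("Partition", "Partition"), function(p, q) {
  cells <- names(clusterLabels(p))
  if (!setequal(cells, names(clusterLabels(q))))
    stop("partitions are over different cell sets")
  ariVectors(clusterLabels(p)[cells], clusterLabels(q)[cells])
})

# ARI on two aligned label vectors
ariVectors <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  choose2 <- function(v) v * (v - 1) / 2
  idx <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  expected <- a * b / choose2(n)
  maximum <- (a + b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * n^2) return(1)
  (idx - expected) / (maximum - expected)
}

#' Pairwise ARI matrix over a list of partitions
#'
#' @param partitions list of [Partition-class] objects over the same cells.
#' @return symmetric numeric matrix with unit diagonal, dimnames taken
#'   from the backend names.
#' @export
ariMatrix <- function(partitions) {
  k <- length(partitions)
  nm <- vapply(partitions, function(p) p@methodName, "")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  R <- diag(1, k)
  dimnames(R) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    R[i, j] <- R[j, i] <- ari(partitions[[i]], partitions[[j]])
  }
  R
}

#' Drop the least diverse clustering by ARI row variance
#'
#' Builds the pairwise ARI matrix, computes for each method the variance of
#' its ARI against the other methods (off-diagonal entries only), and
#' removes exactly the method with minimum row variance — the one that
#' agrees most uniformly with the rest and so contributes least diversity.
#' Ties are broken by the earliest backend (logged).
#'
#' @param partitions list of at least 3 [Partition-class] objects.
#' @return the input list minus the removed method, original order kept;
#'   the ARI matrix and removed index are attached as attributes
#'   `ariMatrix` and `removed`.
#' @export
selectDiverse <- function(partitions) {
  if (length(partitions) < 3L)
    stop("need at least 3 partitions to select a diverse subset")
  R <- ariMatrix(partitions)
  rv <- rowVarOffDiag(R)
  drop_i <- which.min(rv)  # which.min takes the first on ties
  if (sum(rv == rv[drop_i]) > 1L)
    acam_log("tie in minimum ARI row variance; removing earliest backend '",
             rownames(R)[drop_i], "'", stage = "select_diverse")
  acam_log("removed backend '", rownames(R)[drop_i],
           "' (row variance ", signif(rv[drop_i], 4), ")",
           stage = "select_diverse")
  out <- partitions[-drop_i]
  attr(out, "ariMatrix") <- R
  attr(out, "removed") <- unname(drop_i)
  out
}

# per-row variance of the off-diagonal entries of a square matrix
rowVarOffDiag <- function(R) {
  vapply(seq_len(nrow(R)), function(i) stats::var(R[i, -i]), 1.0)
}

#' Unanimous co-clustering consensus graph
#'
#' Cells u and v are connected iff they share a cluster in every supplied
#' partition — the intersection of the co-clustering relations, i.e. the
#' cell pairs whose summed co-clustering indicator equals the number of
#' retained methods. Because the AND of equivalence relations is itself an
#' equivalence relation, the graph is a disjoint union of cliques, one per
#' class of the meet partition; the graph is built from those classes.
#'
#' @param partitions list of at least 2 [Partition-class] objects over the
#'   same cell set.
#' @return an [igraph::graph] whose vertices are the cell ids.
#' @export
consensusAdjacency <- function(partitions) {
  if (length(partitions) < 2L)
    stop("need at least 2 partitions for a consensus")
  cells <- names(clusterLabels(partitions[[1]]))
  labs <- lapply(partitions, function(p) {
    l <- clusterLabels(p)
    if (!setequal(names(l), cells))
      stop("partition '", p@methodName, "' covers a different cell set")
    l[cells]
  })
  meet <- interaction(as.data.frame(labs), drop = TRUE)
  edges <- do.call(rbind, lapply(split(seq_along(cells), meet), function(ix) {
    if (length(ix) < 2L) return(NULL)
    t(utils::combn(ix, 2))
  }))
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = cells)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

#' Extract representative clusters from the consensus graph
#'
#' Runs Louvain community detection on the consensus graph and keeps the
#' communities whose size strictly exceeds `threshold` as representative
#' clusters; all other cells become leftover and are labelled later by
#' nearest-neighbour propagation.
#'
#' @param g consensus graph from [consensusAdjacency()].
#' @param threshold minimum community size (strictly greater; default 10).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed for the community detection.
#' @return a [RepresentativeClusters-class] object.
#' @export
representativeClusters <- function(g, threshold = 10, resolution = 1,
                                   seed = 1L) {
  stopifnot(threshold >= 1)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  groups <- split(names(memb), memb)
  keep <- lengths(groups) > threshold
  if (!any(keep))
    stop("no consensus community exceeds the size threshold (",
         threshold, "); consider lowering it")
  clusters <- unname(groups[keep])
  names(clusters) <- paste0("P", seq_along(clusters))
  leftover <- unlist(groups[!keep], use.names = FALSE)
  new("RepresentativeClusters",
      clusters = clusters,
      leftover = if (is.null(leftover)) character() else leftover,
      threshold = as.integer(threshold))
}
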