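#' Run the clustering backends
#'
#' Each backend clusters the cells of the marker-restricted log-normalized
#' matrix independently and returns one [Partition-class]. The default set
#' of five gives diverse co-clustering relations:
#' \describe{
#'   \item{`graph_louvain`}{Louvain communities of a shared-nearest-
#'     neighbour graph built on the top principal components.}
#'   \item{`tsne_kmeans`}{k-means on a 2-D t-SNE embedding, k chosen by a
#'     silhouette scan.}
#'   \item{`pca_kmeans`}{k-means on the principal components, silhouette
#'     scan for k.}
#'   \item{`pca_gmm`}{Gaussian mixture on the principal components, number
#'     of components chosen by BIC.}
#'   \item{`pca_ward`}{agglomerative Ward clustering on the principal
#'     components, cut chosen by a silhouette scan.}
#' }
#' Any clustering can stand in for any of these: external partitions can
#' be supplied directly to the consensus step via [readPartition()].
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param backends character vector naming at least 3 backends.
#' @param seed global seed; each backend derives its own via
#'   [deriveSeed()].
#' @param kMax largest number of clusters considered by the k scans.
#' @param nPCs number of principal components (clamped to the data).
#' @return a list of [Partition-class] objects, one per backend.
#' @export
runClusterings <- function(sce,
                           backends = c("graph_louvain", "tsne_kmeans",
                                        "pca_kmeans", "pca_gmm",
                                        "pca_ward"),
                           seed = 1L, kMax = 10L, nPCs = 20L) {
  if (length(backends) < 3L)
    stop("need at least 3 backends (", length(backends), " supplied)")
  known <- c("graph_louvain", "tsne_kmeans", "pca_kmeans", "pca_gmm",
             "pca_ward")
  bad <- setdiff(backends, known)
  if (length(bad)) stop("unknown backend(s): ", paste(bad, collapse = ", "))

  X <- t(SummarizedExperiment::assay(sce, "logcounts"))  # cells x genes
  cells <- rownames(X)
  n <- nrow(X)
  kMax <- max(2L, min(kMax, n - 1L))

  pcs <- local({
    set.seed(deriveSeed(seed, "pca"))
    d <- min(nPCs, ncol(X), n - 1L)
    pr <- stats::prcomp(X, rank. = d, center = TRUE, scale. = FALSE)
    pr$x
  })

  lapply(backends, function(b) {
    set.seed(deriveSeed(seed, b))
    labs <- switch(b,
      graph_louvain = backendGraphLouvain(pcs),
      tsne_kmeans   = backendTsneKmeans(X, kMax),
      pca_kmeans    = backendKmeans(pcs, kMax),
      pca_gmm       = backendGmm(pcs, kMax),
      pca_ward      = backendWard(pcs, kMax))
    if (length(labs) != n) stop("backend '", b, "' dropped cells")
    Partition(labs, methodName = b, cells = cells)
  })
}

# silhouette-maximizing k over 2..kMax for a label-producing closure
bestKBySilhouette <- function(emb, kMax, clusterFun) {
  d <- stats::dist(emb)
  widths <- rep(NA_real_, kMax)
  labs_by_k <- vector("list", kMax)
  for (k in 2:kMax) {
    labs <- clusterFun(k)
    labs_by_k[[k]] <- labs
    if (length(unique(labs)) < 2L) next
    widths[k] <- mean(cluster::silhouette(labs, d)[, "sil_width"])
  }
  if (all(is.na(widths))) return(rep(1L, nrow(emb)))
  labs_by_k[[which.max(widths)]]
}

backendGraphLouvain <- function(pcs, k = 15L) {
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(pcs, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  as.integer(igraph::membership(igraph::cluster_louvain(g)))
}

backendTsneKmeans <- function(X, kMax) {
  n <- nrow(X)
  perplexity <- max(2, min(30, floor((n - 1) / 3)))
  emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE,
                      num_threads = 1)$Y
  bestKBySilhouette(emb, kMax,
                    function(k) stats::kmeans(emb, k, nstart = 10)$cluster)
}

backendKmeans <- function(pcs, kMax) {
  bestKBySilhouette(pcs, kMax,
                    function(k) stats::kmeans(pcs, k, nstart = 10)$cluster)
}

backendGmm <- function(pcs, kMax) {
  # Mclust() looks helpers up in the calling frame, so evaluate the call
  # in an environment that can see the mclust namespace
  fit <- eval(quote(Mclust(dat, G = 2:kMax0, verbose = FALSE)),
              envir = list2env(list(dat = pcs, kMax0 = kMax),
                               parent = asNamespace("mclust")))
  if (is.null(fit)) return(rep(1L, nrow(pcs)))
  as.integer(fit$classification)
}

backendWard <- function(pcs, kMax) {
  hc <- stats::hclust(stats::dist(pcs), method = "ward.D2")
  bestKBySilhouette(pcs, kMax, function(k) stats::cutree(hc, k))
}

#' Read / write a partition as two-column TSV
#'
#' The TSV bridge (`cell_id`, `cluster`) lets externally computed
#' clusterings be injected into the consensus step in place of a backend.
#'
#' @param path TSV file with columns `cell_id` and `cluster`.
#' @param methodName name recorded on the partition.
#' @return a [Partition-class].
#' @export
readPartition <- function(path, methodName = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% colnames(tab)))
    stop("partition file needs columns 'cell_id' and 'cluster'")
  Partition(tab$cluster, methodName = methodName, cells = tab$cell_id)
}

#' @rdname readPartition
#' @param p a [Partition-class] to write.
#' @export
writePartition <- function(p, path) {
  utils::write.table(
    data.frame(cell_id = names(clusterLabels(p)),
               cluster = unname(clusterLabels(p))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
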