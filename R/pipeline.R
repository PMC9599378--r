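#' Run the full annotation pipeline
#'
#' Orchestrates the whole method: log-normalization, restriction to marker
#' genes (flagging zero-marker cells as `"unknown"`), independent
#' clustering backends, removal of the least diverse backend by ARI row
#' variance, unanimous consensus graph, Louvain representative clusters
#' above the size threshold, per-cluster annotation by boosted-stump
#' marker importance, and nearest-neighbour label propagation in a 2-D
#' UMAP embedding. A single global seed fans out to per-stage seeds via
#' [deriveSeed()], so any stage can be reproduced in isolation.
#'
#' @param x a gene x cell matrix of counts, or a SingleCellExperiment
#'   with a `counts` assay.
#' @param markers a [MarkerDB-class] (see [loadMarkerDB()]).
#' @param truth optional true labels named by cell id; when supplied the
#'   evaluation metrics are computed on all input cells.
#' @param backends clustering backends (see [runClusterings()]); at least
#'   3. Pre-computed partitions can be supplied in `partitions` instead.
#' @param partitions optional list of [Partition-class] objects used
#'   directly in place of running `backends`.
#' @param threshold representative-cluster size threshold (strictly
#'   greater; default 10).
#' @param k neighbours for label propagation (default 1).
#' @param resolution Louvain resolution (default 1).
#' @param normalization `"size-factor-log"` or `"passthrough"`.
#' @param nrounds,eta booster parameters.
#' @param nNeighbors,minDist UMAP parameters.
#' @param seed global seed.
#' @param outDir optional directory; when given, all intermediate
#'   artifacts (partitions, ARI matrix, consensus edges, score tables,
#'   embedding, labels) are written there as TSV for audit.
#' @return an [AcamResult-class] object.
#' @examples
#' sim <- simulateCellTypes(nCellsPerType = 60, nTypes = 2,
#'                          foldChange = 10, seed = 1)
#' res <- runACAM(sim$counts, sim$markers, truth = sim$labels, seed = 1)
#' res
#' @export
runACAM <- function(x, markers, truth = NULL,
                    backends = c("graph_louvain", "tsne_kmeans",
                                 "pca_kmeans", "pca_gmm", "pca_ward"),
                    partitions = NULL,
                    threshold = 10, k = 1, resolution = 1,
                    normalization = "size-factor-log",
                    nrounds = 100L, eta = 0.3,
                    nNeighbors = 15L, minDist = 0.1,
                    seed = 1L, outDir = NULL) {
  stopifnot(threshold >= 1, k >= 1)
  if (length(cellTypes(markers)) < 2L)
    stop("need at least 2 cell types in the marker database")
  if (is.matrix(x))
    x <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = x))
  input_cells <- colnames(x)
  if (is.null(input_cells)) stop("cells must be named")
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  acam_log(length(input_cells), " cells, ", nrow(x), " genes in",
           stage = "input")
  sce <- withStage("normalize", logNormalize(x, normalization))
  sce <- withStage("restrict", restrictToMarkers(sce, markers))
  db <- S4Vectors::metadata(sce)$marker_db
  unknown <- unknownCells(sce)
  acam_log(nrow(sce), " marker genes x ", ncol(sce), " cells retained; ",
           length(unknown), " unknown cell(s)", stage = "restrict")

  if (is.null(partitions)) {
    partitions <- withStage(
      "clustering",
      runClusterings(sce, backends = backends,
                     seed = deriveSeed(seed, "clustering")))
  }
  kept <- withStage("select_diverse", selectDiverse(partitions))
  R <- attr(kept, "ariMatrix")
  g <- withStage("consensus", consensusAdjacency(kept))
  reps <- withStage(
    "representative",
    representativeClusters(g, threshold = threshold,
                           resolution = resolution,
                           seed = deriveSeed(seed, "louvain")))
  acam_log(length(reps), " representative clusters (sizes ",
           paste(lengths(repClusters(reps)), collapse = ", "), "), ",
           length(leftoverCells(reps)), " leftover",
           stage = "representative")

  ann <- withStage(
    "annotate",
    annotateRepresentativeClusters(sce, reps, db, nrounds = nrounds,
                                   eta = eta,
                                   seed = deriveSeed(seed, "annotate")))
  emb <- withStage(
    "embed",
    embed2D(sce, nNeighbors = nNeighbors, minDist = minDist,
            seed = deriveSeed(seed, "umap")))
  leftover <- leftoverCells(reps)
  propagated <- withStage(
    "propagate",
    knnAssign(emb, ann$labels, leftover, k = k))

  cl <- repClusters(reps)
  cluster_of <- stats::setNames(rep(names(cl), lengths(cl)),
                                unlist(cl, use.names = FALSE))
  cd <- S4Vectors::DataFrame(
    cell_id = input_cells,
    label = NA_character_,
    provenance = NA_character_,
    cluster_id = NA_character_,
    row.names = input_cells)
  cd[names(ann$labels), "label"] <- unname(ann$labels)
  cd[names(ann$labels), "provenance"] <- "representative"
  cd[names(cluster_of), "cluster_id"] <- unname(cluster_of)
  if (length(propagated)) {
    cd[names(propagated), "label"] <- unname(propagated)
    cd[names(propagated), "provenance"] <- "propagated"
  }
  if (length(unknown)) {
    cd[unknown, "label"] <- "unknown"
    cd[unknown, "provenance"] <- "unknown"
  }
  dropped <- is.na(cd$label)  # zero-total cells removed at normalization
  if (any(dropped)) {
    cd[dropped, "label"] <- "unknown"
    cd[dropped, "provenance"] <- "unknown"
  }

  metrics <- numeric()
  if (!is.null(truth)) {
    cmat <- confusionMatrix(truth[input_cells],
                            stats::setNames(cd$label, cd$cell_id))
    metrics <- evaluateAnnotation(cmat)
    acam_log(paste(names(metrics), sprintf("%.4f", metrics), sep = "=",
                   collapse = ", "), stage = "evaluate")
  }

  res <- new("AcamResult",
             cellData = cd,
             scoreTable = S4Vectors::DataFrame(ann$scoreTable),
             ariMatrix = R,
             embedding = emb,
             metrics = metrics,
             params = list(backends = backends, threshold = threshold,
                           k = k, resolution = resolution,
                           normalization = normalization,
                           nrounds = nrounds, eta = eta,
                           nNeighbors = nNeighbors, minDist = minDist,
                           seed = seed))
  if (!is.null(outDir)) exportArtifacts(res, partitions, g, outDir)
  res
}

# run an expression under a stage tag so errors name the failing stage
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

exportArtifacts <- function(res, partitions, g, outDir) {
  for (p in partitions)
    writePartition(p, file.path(outDir,
                                paste0("partition_", p@methodName, ".tsv")))
  utils::write.table(res@ariMatrix, file.path(outDir, "ari_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  el <- igraph::as_edgelist(g)
  utils::write.table(data.frame(u = el[, 1], v = el[, 2]),
                     file.path(outDir, "consensus_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(res@scoreTable),
                     file.path(outDir, "score_tables.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(cell_id = rownames(res@embedding), res@embedding),
    file.path(outDir, "embedding.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(as.data.frame(res@cellData),
                     file.path(outDir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (length(res@metrics))
    utils::write.table(t(res@metrics), file.path(outDir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(outDir)
}
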