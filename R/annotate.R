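#' Oversample a cluster to a target size
#'
#' Balances the one-vs-rest fit: the target group (a representative
#' cluster) is padded by drawing its cells uniformly with replacement
#' until it matches the adversarial group's size. Every original cell is
#' included exactly once before any duplicate is drawn.
#'
#' @param cluster character vector of cell ids (nonempty).
#' @param targetSize desired multiset size, at least `length(cluster)`.
#' @param seed RNG seed.
#' @return character vector of length `targetSize` (a multiset).
#' @export
oversample <- function(cluster, targetSize, seed = 1L) {
  stopifnot(length(cluster) >= 1L, targetSize >= length(cluster))
  extra <- targetSize - length(cluster)
  if (extra == 0L) return(cluster)
  set.seed(seed)
  c(cluster, sample(cluster, extra, replace = TRUE))
}

#' Keep genes up-regulated in the target cluster
#'
#' A gene enters the boosting model only if its mean log-normalized
#' expression over the cluster strictly exceeds its mean over all other
#' cells: markers of the cluster's type are expected to be high inside and
#' low outside, so genes failing this test cannot be its markers. Means
#' are computed on the original cluster, not the oversampled multiset
#' (uniform oversampling leaves the expected mean unchanged; using the
#' originals removes seed dependence from the filter).
#'
#' @param sce a SingleCellExperiment with `logcounts`.
#' @param cluster character vector of cell ids, a subset of the columns.
#' @return character vector of retained genes (may be empty).
#' @export
prefilterGenes <- function(sce, cluster) {
  m <- SummarizedExperiment::assay(sce, "logcounts")
  stopifnot(all(cluster %in% colnames(m)))
  rest <- setdiff(colnames(m), cluster)
  inMean <- rowMeans(m[, cluster, drop = FALSE])
  outMean <- rowMeans(m[, rest, drop = FALSE])
  rownames(m)[inMean > outMean]
}

#' Gradient-boosted stump feature importance for one cluster
#'
#' Trains an XGBoost ensemble of depth-1 trees (stumps) with the hinge
#' objective to discriminate the (oversampled) target cells from the
#' adversarial cells, and returns the total gain accumulated by each gene
#' across all splits. Genes never split on get importance 0. Depth 1
#' matches the marker-gene intuition: a single expression threshold on a
#' marker should separate the cluster from the rest.
#'
#' @param sce a SingleCellExperiment with `logcounts`.
#' @param target cell ids of the target multiset (duplicates allowed).
#' @param adversarial cell ids of the adversarial group.
#' @param genes genes admitted to the model (from [prefilterGenes()]).
#' @param nrounds,eta boosting rounds and learning rate.
#' @param seed RNG seed passed to the booster.
#' @return named numeric vector of nonnegative importances over `genes`.
#' @export
featureImportance <- function(sce, target, adversarial, genes,
                              nrounds = 100L, eta = 0.3, seed = 1L) {
  m <- SummarizedExperiment::assay(sce, "logcounts")
  stopifnot(length(genes) >= 1L)
  X <- t(m[genes, c(target, adversarial), drop = FALSE])
  # xgboost needs >= 2 columns to keep feature names in the dump
  y <- c(rep(1, length(target)), rep(0, length(adversarial)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(max_depth = 1, objective = "binary:hinge",
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  w <- stats::setNames(numeric(length(genes)), genes)
  tr <- xgboost::xgb.model.dt.tree(model = bst)
  splits <- tr[tr$Feature != "Leaf", , drop = FALSE]
  if (nrow(splits)) {
    gain <- tapply(splits$Gain, splits$Feature, sum)
    w[names(gain)] <- pmax(gain, 0)
  }
  w
}

#' Score cell types against an importance vector
#'
#' The score of cell type \eqn{t} is the sum of the importances of its
#' marker genes, \eqn{Score_t = \sum_{m \in G_t} w_m}, with \eqn{w_m = 0}
#' for genes absent from the vector. The winning type attains the maximum
#' score; ties are broken by the lexicographically smallest type name
#' (deterministic, logged with the margin). If every score is zero the
#' cluster has no marker signal and the label is `"unassigned"`.
#'
#' @param w named importance vector from [featureImportance()].
#' @param db a [MarkerDB-class].
#' @param clusterId identifier recorded in the returned table.
#' @return a data.frame with columns `cluster_id`, `cell_type`, `score`,
#'   `winner`; attributes `winner` (the chosen label) and `margin`
#'   (winner minus runner-up score).
#' @export
scoreCellTypes <- function(w, db, clusterId = NA_character_) {
  types <- cellTypes(db)
  scores <- vapply(geneSets(db), function(g) {
    sum(w[intersect(g, names(w))])
  }, 1.0)
  if (all(scores == 0)) {
    winner <- "unassigned"
    margin <- 0
  } else {
    top <- which(scores == max(scores))
    if (length(top) > 1L)
      acam_log("score tie in cluster ", clusterId, "; choosing '",
               min(types[top]), "'", stage = "annotate")
    winner <- min(types[top])  # lexicographic tie-break
    margin <- if (length(scores) > 1L)
      max(scores) - max(scores[types != winner]) else max(scores)
  }
  out <- data.frame(cluster_id = clusterId, cell_type = types,
                    score = unname(scores),
                    winner = types == winner & winner != "unassigned",
                    stringsAsFactors = FALSE)
  attr(out, "winner") <- winner
  attr(out, "margin") <- margin
  out
}

#' Annotate every representative cluster
#'
#' For each representative cluster: oversample it to the adversarial
#' group's size, prefilter genes by the mean-expression rule, fit the
#' stump ensemble, sum importances per cell type's marker set, and label
#' all of the cluster's cells with the winning type. Clusters are
#' annotated independently and may receive the same type. A cluster with
#' no up-regulated gene or no importance mass is labelled `"unassigned"`.
#'
#' @param sce SingleCellExperiment with `logcounts` (marker-restricted).
#' @param reps a [RepresentativeClusters-class].
#' @param db a [MarkerDB-class].
#' @param nrounds,eta booster parameters (see [featureImportance()]).
#' @param seed global seed; per-cluster seeds are derived from it.
#' @return a list with `labels` (cell id to label, over the cells of the
#'   representative clusters), `clusterLabels` (per-cluster winner) and
#'   `scoreTable` (row-bound score tables of all clusters).
#' @export
annotateRepresentativeClusters <- function(sce, reps, db,
                                           nrounds = 100L, eta = 0.3,
                                           seed = 1L) {
  all_cells <- colnames(sce)
  cl <- repClusters(reps)
  tables <- vector("list", length(cl))
  winners <- character(length(cl))
  for (c_i in seq_along(cl)) {
    cells <- cl[[c_i]]
    cid <- names(cl)[c_i]
    adversarial <- setdiff(all_cells, cells)
    genes <- prefilterGenes(sce, cells)
    if (length(genes) == 0L) {
      warning("cluster ", cid,
              " has no up-regulated gene; labelled 'unassigned'")
      winners[c_i] <- "unassigned"
      tables[[c_i]] <- scoreCellTypes(numeric(), db, clusterId = cid)
      next
    }
    tgt <- oversample(cells, max(length(adversarial), length(cells)),
                      seed = deriveSeed(seed, paste0("oversample_", cid)))
    w <- featureImportance(sce, tgt, adversarial, genes,
                           nrounds = nrounds, eta = eta,
                           seed = deriveSeed(seed, paste0("xgb_", cid)))
    if (all(w == 0))
      warning("cluster ", cid,
              " received no importance mass; labelled 'unassigned'")
    tab <- scoreCellTypes(w, db, clusterId = cid)
    winners[c_i] <- attr(tab, "winner")
    tables[[c_i]] <- tab
  }
  names(winners) <- names(cl)
  labels <- stats::setNames(rep(winners, lengths(cl)),
                            unlist(cl, use.names = FALSE))
  list(labels = labels, clusterLabels = winners,
       scoreTable = do.call(rbind, tables))
}
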