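#' @rdname MarkerDB-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname MarkerDB-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname MarkerDB-accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname Partition-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname Partition-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Adjusted Rand index between two partitions
#'
#' @param p,q [Partition-class] objects over the same cell set.
#' @return a number in \[-1, 1\]; 1 for identical partitions.
#' @export
setGeneric("ari", function(p, q) standardGeneric("ari"))

#' @rdname RepresentativeClusters-accessors
#' @export
setGeneric("repClusters", function(x) standardGeneric("repClusters"))

#' @rdname RepresentativeClusters-accessors
#' @export
setGeneric("leftoverCells", function(x) standardGeneric("leftoverCells"))

#' @rdname AcamResult-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname AcamResult-accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

# ---- accessor methods ------------------------------------------------------

#' Accessors for MarkerDB
#'
#' `cellTypes` returns the cell type names, `geneSets` the named list of
#' marker sets, `markerGenes` the union of all marker symbols.
#'
#' @param x a [MarkerDB-class].
#' @name MarkerDB-accessors
NULL

#' @rdname MarkerDB-accessors
setMethod("cellTypes", "MarkerDB", function(x) x@cellTypes)

#' @rdname MarkerDB-accessors
setMethod("geneSets", "MarkerDB", function(x) x@geneSets)

#' @rdname MarkerDB-accessors
setMethod("markerGenes", "MarkerDB",
          function(x) unique(unlist(x@geneSets, use.names = FALSE)))

setMethod("length", "MarkerDB", function(x) length(x@cellTypes))

setMethod("show", "MarkerDB", function(object) {
  cat("MarkerDB:", length(object@cellTypes), "cell types,",
      length(unique(unlist(object@geneSets, use.names = FALSE))),
      "distinct marker genes\n")
  if (!is.na(object@species)) cat("  species:", object@species, "\n")
  if (!is.na(object@tissue))  cat("  tissue: ", object@tissue, "\n")
  n <- min(length(object@cellTypes), 5L)
  for (t in object@cellTypes[seq_len(n)]) {
    g <- object@geneSets[[t]]
    cat("  ", t, " (", length(g), "): ",
        paste(utils::head(g, 5L), collapse = ", "),
        if (length(g) > 5L) ", ..." else "", "\n", sep = "")
  }
  if (length(object@cellTypes) > n) cat("  ...\n")
})

#' Accessors for Partition
#'
#' @param x a [Partition-class].
#' @name Partition-accessors
NULL

#' @rdname Partition-accessors
setMethod("clusterLabels", "Partition", function(x) x@labels)

#' @rdname Partition-accessors
setMethod("nClusters", "Partition", function(x) length(unique(x@labels)))

setMethod("length", "Partition", function(x) length(x@labels))

setMethod("show", "Partition", function(object) {
  cat("Partition '", object@methodName, "': ", length(object@labels),
      " cells in ", nClusters(object), " clusters\n", sep = "")
})

#' Accessors for RepresentativeClusters
#'
#' @param x a [RepresentativeClusters-class].
#' @name RepresentativeClusters-accessors
NULL

#' @rdname RepresentativeClusters-accessors
setMethod("repClusters", "RepresentativeClusters", function(x) x@clusters)

#' @rdname RepresentativeClusters-accessors
setMethod("leftoverCells", "RepresentativeClusters", function(x) x@leftover)

setMethod("length", "RepresentativeClusters", function(x) length(x@clusters))

setMethod("show", "RepresentativeClusters", function(object) {
  cat("RepresentativeClusters:", length(object@clusters),
      "clusters (size >", object@threshold, "),",
      length(object@leftover), "leftover cells\n")
  cat("  sizes:", paste(lengths(object@clusters), collapse = ", "), "\n")
})

#' Accessors for AcamResult
#'
#' `cellLabels` returns the per-cell label vector named by cell id;
#' `scoreTable` the per-cluster cell-type score table.
#'
#' @param x an [AcamResult-class].
#' @name AcamResult-accessors
NULL

#' @rdname AcamResult-accessors
setMethod("cellLabels", "AcamResult", function(x) {
  stats::setNames(x@cellData$label, x@cellData$cell_id)
})

#' @rdname AcamResult-accessors
setMethod("scoreTable", "AcamResult", function(x) x@scoreTable)

setMethod("show", "AcamResult", function(object) {
  cd <- object@cellData
  cat("AcamResult:", nrow(cd), "cells\n")
  tab <- table(cd$label)
  cat("  labels: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  prov <- table(cd$provenance)
  cat("  provenance: ",
      paste(names(prov), prov, sep = "=", collapse = ", "), "\n", sep = "")
  if (length(object@metrics))
    cat("  metrics: ",
        paste(names(object@metrics),
              sprintf("%.4f", object@metrics), sep = "=", collapse = ", "),
        "\n", sep = "")
})
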