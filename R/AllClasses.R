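#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MarkerDB: a cell-type to marker-gene mapping
#'
#' Holds the prior knowledge the annotation step matches against: for each
#' cell type \eqn{t} a set of marker gene symbols \eqn{G_t}. A gene may
#' belong to several types' sets; duplicates within a set are not allowed.
#'
#' @slot cellTypes character vector of cell type names (defines the order).
#' @slot geneSets named list of character vectors, one per cell type.
#' @slot species species the markers were selected for.
#' @slot tissue tissue the markers were selected for.
#'
#' @seealso [loadMarkerDB()], [scoreCellTypes()]
#' @export
setClass("MarkerDB",
  representation(
    cellTypes = "character",
    geneSets  = "list",
    species   = "character",
    tissue    = "character"
  )
)

setValidity("MarkerDB", function(object) {
  msg <- character()
  if (length(object@cellTypes) < 1L)
    msg <- c(msg, "MarkerDB must contain at least one cell type")
  if (anyDuplicated(object@cellTypes))
    msg <- c(msg, "duplicated cell type names")
  if (!identical(names(object@geneSets), object@cellTypes))
    msg <- c(msg, "names(geneSets) must equal cellTypes")
  empty <- vapply(object@geneSets, length, 1L) == 0L
  if (any(empty))
    msg <- c(msg, paste0("empty gene set for: ",
                         paste(object@cellTypes[empty], collapse = ", ")))
  dup <- vapply(object@geneSets, anyDuplicated, 1L) > 0L
  if (any(dup))
    msg <- c(msg, "duplicated gene symbols within a gene set")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerDB from a named list of gene sets
#'
#' @param geneSets named list; names are cell types, elements are character
#'   vectors of marker gene symbols. Duplicates within a set are removed.
#' @param species,tissue optional annotations carried along for provenance.
#' @return a [MarkerDB-class] object.
#' @examples
#' db <- MarkerDB(list(Tcell = c("CD3D", "CD3E"), Bcell = c("CD79A", "MS4A1")))
#' cellTypes(db)
#' @export
MarkerDB <- function(geneSets, species = NA_character_, tissue = NA_character_) {
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  geneSets <- lapply(geneSets, function(g) unique(as.character(g)))
  new("MarkerDB",
      cellTypes = names(geneSets),
      geneSets  = geneSets,
      species   = as.character(species),
      tissue    = as.character(tissue))
}

#' Partition: one clustering's assignment of cells to clusters
#'
#' @slot labels integer cluster ids named by cell id.
#' @slot methodName the backend that produced the partition.
#' @export
setClass("Partition",
  representation(labels = "integer", methodName = "character")
)

setValidity("Partition", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "labels must be named by unique cell ids")
  if (length(object@labels) == 0L)
    msg <- c(msg, "empty partition")
  if (anyNA(object@labels))
    msg <- c(msg, "NA cluster labels")
  if (length(msg)) msg else TRUE
})

#' Construct a Partition
#'
#' @param labels cluster assignment: a vector (factor, character or integer)
#'   named by cell id, or unnamed with `cells` supplied.
#' @param methodName name of the clustering backend.
#' @param cells cell ids, if `labels` is unnamed.
#' @return a [Partition-class] object.
#' @export
Partition <- function(labels, methodName = "unknown", cells = names(labels)) {
  lab <- as.integer(factor(labels))
  names(lab) <- cells
  new("Partition", labels = lab, methodName = as.character(methodName))
}

#' RepresentativeClusters: consensus communities above the size threshold
#'
#' @slot clusters named list of character vectors (cell ids), pairwise
#'   disjoint, each of size strictly greater than `threshold`.
#' @slot leftover cell ids in no representative cluster.
#' @slot threshold the minimum size used (strictly-greater comparison).
#' @export
setClass("RepresentativeClusters",
  representation(clusters = "list", leftover = "character",
                 threshold = "integer")
)

setValidity("RepresentativeClusters", function(object) {
  msg <- character()
  all_cells <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(c(all_cells, object@leftover)))
    msg <- c(msg, "clusters and leftover must be pairwise disjoint")
  sizes <- lengths(object@clusters)
  if (any(sizes <= object@threshold))
    msg <- c(msg, "every representative cluster must exceed the threshold")
  if (length(msg)) msg else TRUE
})

#' AcamResult: the full annotation output
#'
#' @slot cellData a [S4Vectors::DataFrame] with one row per input cell:
#'   `cell_id`, `label`, `provenance` (representative / propagated /
#'   unknown) and `cluster_id` (NA outside representative clusters).
#' @slot scoreTable per-cluster, per-cell-type score table.
#' @slot ariMatrix pairwise adjusted Rand index matrix over backends.
#' @slot embedding 2-D coordinates of retained cells.
#' @slot metrics named numeric of evaluation metrics (empty without truth).
#' @slot params the configuration the run used.
#' @export
setClass("AcamResult",
  representation(
    cellData  = "DataFrame",
    scoreTable = "DataFrame",
    ariMatrix = "matrix",
    embedding = "matrix",
    metrics   = "numeric",
    params    = "list"
  )
)
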