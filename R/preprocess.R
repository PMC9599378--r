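#' Read an expression matrix into a SingleCellExperiment
#'
#' Supports a dense delimited matrix (header row = cell ids, first column =
#' gene ids) or a MatrixMarket triplet (`.mtx` plus `genes.tsv` /
#' `barcodes.tsv` files in CellRanger style). The internal orientation is
#' genes x cells; files stored cells x genes are transposed via
#' `orientation = "cells_x_genes"` rather than guessed.
#'
#' @param path dense matrix file, or the `.mtx` file of a triplet.
#' @param format `"dense"` or `"mtx"`.
#' @param genesFile,barcodesFile row/column name files for `"mtx"`;
#'   default to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @param orientation orientation of the stored matrix.
#' @param sep field separator for `"dense"`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (raw values as stored; normalize with [logNormalize()]).
#' @export
readExpression <- function(path, format = c("dense", "mtx"),
                           genesFile = NULL, barcodesFile = NULL,
                           orientation = c("genes_x_cells", "cells_x_genes"),
                           sep = "\t") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE,
                             comment.char = "")
    m <- as.matrix(tab)
  } else {
    dir <- dirname(path)
    if (is.null(genesFile)) genesFile <- file.path(dir, "genes.tsv")
    if (is.null(barcodesFile)) barcodesFile <- file.path(dir, "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    rn <- utils::read.table(genesFile, header = FALSE,
                            stringsAsFactors = FALSE)[, 1]
    cn <- utils::read.table(barcodesFile, header = FALSE,
                            stringsAsFactors = FALSE)[, 1]
    dimnames(m) <- list(rn, cn)
  }
  if (orientation == "cells_x_genes") m <- t(m)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative entries in expression matrix")
  if (anyDuplicated(rownames(m))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicated cell ids")
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Log-normalize counts with a median size factor
#'
#' Scales each cell's column so its total equals the median of per-cell
#' totals, then applies `log1p`. Cells with total zero have an undefined
#' size factor and are dropped with a warning (they carry no information
#' and are unannotatable). `normalization = "passthrough"` copies counts to
#' `logcounts` unchanged for input that is already normalized.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param normalization `"size-factor-log"` (default) or `"passthrough"`.
#' @return the SingleCellExperiment with a `logcounts` assay added and the
#'   normalization mode recorded in `metadata(sce)$normalization`.
#' @export
logNormalize <- function(sce, normalization = c("size-factor-log",
                                                "passthrough")) {
  normalization <- match.arg(normalization)
  m <- SummarizedExperiment::assay(sce, "counts")
  if (normalization == "passthrough") {
    SummarizedExperiment::assay(sce, "logcounts") <- m
  } else {
    totals <- colSums(m)
    zero <- totals == 0
    if (any(zero)) {
      warning(sum(zero), " cell(s) with zero total counts dropped")
      sce <- sce[, !zero]
      m <- m[, !zero, drop = FALSE]
      totals <- totals[!zero]
    }
    if (ncol(m) == 0L) stop("no cells left after dropping zero-total cells")
    target <- stats::median(totals)
    scaled <- sweep(m, 2L, target / totals, "*")
    SummarizedExperiment::assay(sce, "logcounts") <- log1p(scaled)
  }
  S4Vectors::metadata(sce)$normalization <- normalization
  sce
}

#' Restrict an expression matrix to marker genes and flag unknown cells
#'
#' Keeps only the genes appearing in the marker database, drops marker
#' genes with zero expression in every cell, and removes cells with zero
#' expression across all retained marker genes. Removed cells are recorded
#' in `metadata(sce)$unknown_cells` and surface in the final annotation
#' with the label `"unknown"` (they cannot be matched to any cell type).
#'
#' @param sce a SingleCellExperiment (any assays; restriction uses
#'   `counts` if present, else the first assay).
#' @param db a [MarkerDB-class].
#' @param caseFold if `TRUE`, match gene symbols case-insensitively.
#' @return the restricted SingleCellExperiment; the possibly-reduced
#'   MarkerDB is stored in `metadata(sce)$marker_db`.
#' @export
restrictToMarkers <- function(sce, db, caseFold = FALSE) {
  a <- if ("counts" %in% SummarizedExperiment::assayNames(sce)) "counts"
       else SummarizedExperiment::assayNames(sce)[1]
  m <- SummarizedExperiment::assay(sce, a)
  ids <- rownames(m)
  markers <- markerGenes(db)
  hit <- if (caseFold) toupper(ids) %in% toupper(markers)
         else ids %in% markers
  if (!any(hit))
    stop("none of the ", length(markers),
         " marker genes were found in the expression data")
  sce2 <- sce[hit, ]
  m2 <- SummarizedExperiment::assay(sce2, a)
  nonzero_gene <- rowSums(m2 != 0) > 0
  if (!all(nonzero_gene)) sce2 <- sce2[nonzero_gene, ]
  m2 <- SummarizedExperiment::assay(sce2, a)
  zero_cell <- colSums(m2 != 0) == 0
  unknown <- colnames(sce2)[zero_cell]
  if (length(unknown))
    warning(length(unknown),
            " cell(s) with zero expression across all markers flagged 'unknown'")
  sce2 <- sce2[, !zero_cell]
  if (ncol(sce2) == 0L) stop("all cells have zero marker expression")
  prev <- S4Vectors::metadata(sce)$unknown_cells
  S4Vectors::metadata(sce2)$unknown_cells <- union(prev, unknown)
  S4Vectors::metadata(sce2)$marker_db <- filterMarkerDB(db, rownames(sce2))
  sce2
}

#' Cells flagged unannotatable during marker restriction
#'
#' @param sce a SingleCellExperiment processed by [restrictToMarkers()].
#' @return character vector of cell ids (possibly empty).
#' @export
unknownCells <- function(sce) {
  u <- S4Vectors::metadata(sce)$unknown_cells
  if (is.null(u)) character() else u
}
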