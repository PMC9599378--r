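#' Simulate an scRNA-seq count matrix with planted cell types
#'
#' Generates negative-binomial counts for `nTypes` cell types. Every type
#' gets `markersPerType` dedicated marker genes whose mean is multiplied
#' by `foldChange` in that type's cells; `nBackgroundGenes` genes carry no
#' type signal. Per-cell library sizes are log-normal with coefficient of
#' variation `librarySizeCV`, and each entry is independently zeroed with
#' probability `dropoutRate` (dropout). With `markerOverlapFrac > 0` a
#' fraction of each type's markers is also listed (and up-regulated) for
#' the adjacent type, mimicking marker databases in which related types
#' share genes.
#'
#' The defaults (three types of 150 cells, 10 markers each, fold change
#' 10, baseline mean 2, dispersion 2, 20% dropout, 60 background genes)
#' describe a moderately sparse, overdispersed dataset in which the
#' planted types are recoverable but not trivially separable.
#'
#' @param nCellsPerType integer scalar or vector of length `nTypes`.
#' @param nTypes number of planted cell types (at least 2).
#' @param markersPerType markers dedicated to each type.
#' @param nBackgroundGenes genes with no type signal.
#' @param foldChange marker over-expression factor, strictly > 1.
#' @param baselineMean negative-binomial mean of an unregulated gene.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param dropoutRate probability in \[0, 1) of zeroing an entry.
#' @param markerOverlapFrac fraction in \[0, 1) of each type's markers
#'   shared with the next type.
#' @param librarySizeCV coefficient of variation of the per-cell library
#'   size factor (0 = identical depths).
#' @param seed RNG seed; identical seeds give identical output.
#' @return a list with `counts` (gene x cell matrix with dimnames),
#'   `labels` (true type per cell, named by cell id) and `markers`
#'   (the planted [MarkerDB-class]).
#' @export
simulateCellTypes <- function(nCellsPerType = 150L, nTypes = 3L,
                              markersPerType = 10L, nBackgroundGenes = 60L,
                              foldChange = 10, baselineMean = 2,
                              dispersion = 2, dropoutRate = 0.2,
                              markerOverlapFrac = 0, librarySizeCV = 0.2,
                              seed = 1L) {
  stopifnot(nTypes >= 2L, markersPerType >= 1L, nBackgroundGenes >= 0L,
            baselineMean > 0, dispersion > 0, librarySizeCV >= 0)
  if (foldChange <= 1) stop("foldChange must be strictly greater than 1")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must be in [0, 1)")
  if (markerOverlapFrac < 0 || markerOverlapFrac >= 1)
    stop("markerOverlapFrac must be in [0, 1)")
  if (length(nCellsPerType) == 1L)
    nCellsPerType <- rep(as.integer(nCellsPerType), nTypes)
  stopifnot(length(nCellsPerType) == nTypes, all(nCellsPerType >= 1L))

  set.seed(seed)
  types <- paste0("type", seq_len(nTypes))
  n <- sum(nCellsPerType)
  labels <- rep(types, nCellsPerType)
  cells <- sprintf("cell%04d", seq_len(n))
  names(labels) <- cells

  marker_ids <- matrix(
    sprintf("MK%d_%d", rep(seq_len(nTypes), each = markersPerType),
            rep(seq_len(markersPerType), nTypes)),
    nrow = markersPerType)
  bg_ids <- if (nBackgroundGenes > 0) sprintf("BG%03d", seq_len(nBackgroundGenes))
            else character()
  genes <- c(as.vector(marker_ids), bg_ids)

  # per-gene x per-cell mean: baseline, lifted by foldChange for a type's
  # markers in that type's cells
  mu <- matrix(baselineMean, nrow = length(genes), ncol = n,
               dimnames = list(genes, cells))
  n_shared <- floor(markerOverlapFrac * markersPerType)
  gene_sets <- stats::setNames(
    lapply(seq_len(nTypes), function(t_i) marker_ids[, t_i]), types)
  for (t_i in seq_len(nTypes)) {
    own <- marker_ids[, t_i]
    mu[own, labels == types[t_i]] <- baselineMean * foldChange
    if (n_shared > 0) {
      nxt <- if (t_i == nTypes) 1L else t_i + 1L
      shared <- own[seq_len(n_shared)]
      gene_sets[[nxt]] <- c(gene_sets[[nxt]], shared)
      mu[shared, labels == types[nxt]] <- baselineMean * foldChange
    }
  }
  gene_sets <- lapply(gene_sets, unique)

  lib <- if (librarySizeCV > 0) {
    sdlog <- sqrt(log(1 + librarySizeCV^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, n)
  mu <- sweep(mu, 2L, lib, "*")

  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu))
  if (dropoutRate > 0) {
    keep <- stats::runif(length(counts)) >= dropoutRate
    counts <- counts * keep
  }
  storage.mode(counts) <- "double"

  list(counts = counts,
       labels = labels,
       markers = MarkerDB(gene_sets, species = "Synthetic",
                          tissue = "Synthetic"))
}

#' Write a simulation to disk in the formats the readers accept
#'
#' Emits a dense TSV expression matrix (or an MTX triplet), the marker
#' table in CellMatch layout, and the true labels, so synthetic fixtures
#' exercise the same input path as real data.
#'
#' @param sim output of [simulateCellTypes()].
#' @param dir output directory (created if needed).
#' @param format `"dense"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, format = c("dense", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "dense") {
    df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(sim$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  }
  writeMarkerDB(sim$markers, file.path(dir, "markers.tsv"))
  utils::write.table(
    data.frame(cell_id = names(sim$labels), label = unname(sim$labels)),
    file.path(dir, "truth.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
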