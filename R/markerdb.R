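#' Load a marker-gene database from a CellMatch-style table
#'
#' Reads a delimited marker table, filters to an exact species and tissue
#' match (and to the single-cell resource when a resource column is
#' present), and builds a [MarkerDB-class] mapping each cell type to its
#' deduplicated marker gene symbols. A gene may appear under several cell
#' types; types left with zero genes are dropped with a warning.
#'
#' @param path a TSV/CSV file with at least species, tissue, cell type and
#'   gene symbol columns.
#' @param species,tissue values to filter on (exact, case-sensitive match
#'   unless `caseFold`).
#' @param columns named character vector mapping the roles
#'   `species`, `tissue`, `cellType`, `gene` and optionally `resource` to
#'   the file's column names. Defaults follow the CellMatch layout.
#' @param resource when the table has a resource column, keep rows whose
#'   resource equals this value (default `"Single-cell sequencing"`); set
#'   to `NULL` to keep all rows.
#' @param caseFold if `TRUE`, species/tissue/gene matching is done on
#'   upper-cased strings. Default `FALSE`: silent fuzzy matching hides
#'   errors, so matching is exact unless asked for.
#' @param sep field separator, default tab.
#' @return a [MarkerDB-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(speciesType = "Mouse", tissueType = "Kidney",
#'              cellName = c("T cell", "B cell"),
#'              cellMarker = c("Cd3e", "Cd79a")),
#'   tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' loadMarkerDB(tf, species = "Mouse", tissue = "Kidney")
#' @export
loadMarkerDB <- function(path, species, tissue,
                         columns = c(species = "speciesType",
                                     tissue = "tissueType",
                                     cellType = "cellName",
                                     gene = "cellMarker",
                                     resource = "markerResource"),
                         resource = "Single-cell sequencing",
                         caseFold = FALSE,
                         sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE, comment.char = "")
  required <- columns[c("species", "tissue", "cellType", "gene")]
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols))
    stop("marker table is missing required columns: ",
         paste(missing_cols, collapse = ", "))

  fold <- if (caseFold) toupper else identity
  keep <- fold(tab[[columns[["species"]]]]) == fold(species) &
          fold(tab[[columns[["tissue"]]]])  == fold(tissue)
  res_col <- columns["resource"]
  if (!is.na(res_col) && res_col %in% colnames(tab) && !is.null(resource))
    keep <- keep & tab[[res_col]] == resource
  tab <- tab[keep & !is.na(keep), , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no markers for species '", species, "' and tissue '", tissue, "'")

  genes <- if (caseFold) toupper(tab[[columns[["gene"]]]])
           else tab[[columns[["gene"]]]]
  sets <- split(genes, tab[[columns[["cellType"]]]])
  sets <- lapply(sets, function(g) unique(g[!is.na(g) & nzchar(g)]))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warning("dropping cell types with no marker genes: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0L)
    stop("no cell type retained any marker genes after filtering")
  MarkerDB(sets, species = species, tissue = tissue)
}

#' Restrict a MarkerDB to genes present in the data
#'
#' Drops marker symbols absent from `genes`; cell types whose set becomes
#' empty are removed with a warning.
#'
#' @param db a [MarkerDB-class].
#' @param genes character vector of gene ids present in the data.
#' @return a filtered [MarkerDB-class].
#' @export
filterMarkerDB <- function(db, genes) {
  sets <- lapply(geneSets(db), intersect, genes)
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    warning("cell types with no markers in the data dropped: ",
            paste(cellTypes(db)[empty], collapse = ", "))
  sets <- sets[!empty]
  if (length(sets) == 0L)
    stop("no marker genes found in the expression data; cannot annotate")
  MarkerDB(sets, species = db@species, tissue = db@tissue)
}

#' Write a MarkerDB as a CellMatch-style TSV
#'
#' Inverse of [loadMarkerDB()]; used by the synthetic-data generator so
#' simulated fixtures exercise the reader.
#'
#' @param db a [MarkerDB-class].
#' @param path output file.
#' @export
writeMarkerDB <- function(db, path) {
  rows <- do.call(rbind, lapply(cellTypes(db), function(t) {
    data.frame(speciesType = db@species, tissueType = db@tissue,
               markerResource = "Single-cell sequencing",
               cellName = t, cellMarker = geneSets(db)[[t]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
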