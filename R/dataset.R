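#' Construct a spatial transcriptomics dataset
#'
#' The basic data container of the package: a spots x genes UMI count
#' matrix with per-spot spatial coordinates.  Normalized log expression
#' (`expr`) is added by [normalize_log()].
#'
#' @param counts integer matrix, spots x genes, non-negative UMI counts.
#'   Sparse `Matrix` input is accepted and densified.
#' @param coords numeric matrix, spots x 2, spatial coordinates in the
#'   platform's pixel/array units.
#' @param spot_ids,gene_ids optional character identifiers; default to the
#'   dimnames of `counts`.
#' @param in_tissue optional logical vector; spots flagged `FALSE` are
#'   dropped.
#' @param expr optional spots x genes matrix of normalized log expression.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts`, `expr` (or `NULL`), `coords`, `spot_ids`, `gene_ids`.
#' @export
spatial_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                            in_tissue = NULL, expr = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(counts) <- "double"
  storage.mode(coords) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop2("`counts` must be non-negative integral values")
  if (ncol(coords) != 2L)
    stop2("`coords` must have two columns")
  if (nrow(counts) != nrow(coords))
    stop2(sprintf("counts has %d spots but coords has %d rows",
                  nrow(counts), nrow(coords)))
  spot_ids <- spot_ids %||% rownames(counts) %||% sprintf("spot%04d", seq_len(nrow(counts)))
  gene_ids <- gene_ids %||% colnames(counts) %||% sprintf("gene%04d", seq_len(ncol(counts)))
  if (length(spot_ids) != nrow(counts)) stop2("spot_ids length mismatch")
  if (length(gene_ids) != ncol(counts)) stop2("gene_ids length mismatch")
  if (anyDuplicated(spot_ids)) stop2("duplicate spot identifiers")
  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    if (!all(dim(expr) == dim(counts))) stop2("`expr` dimensions must match `counts`")
    if (any(!is.finite(expr))) stop2("`expr` must be finite")
    dimnames(expr) <- dimnames(counts)
  }
  ds <- structure(
    list(counts = counts, expr = expr, coords = coords,
         spot_ids = spot_ids, gene_ids = gene_ids),
    class = "spatial_dataset"
  )
  if (!is.null(in_tissue)) {
    if (length(in_tissue) != nrow(counts)) stop2("in_tissue length mismatch")
    ds <- subset_dataset(ds, spots = which(as.logical(in_tissue)))
  }
  ds
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$expr)) "raw counts" else "normalized"))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

# row/column subsetting that keeps all fields aligned
subset_dataset <- function(ds, spots = NULL, genes = NULL) {
  if (!is.null(spots)) {
    ds$counts <- ds$counts[spots, , drop = FALSE]
    if (!is.null(ds$expr)) ds$expr <- ds$expr[spots, , drop = FALSE]
    ds$coords <- ds$coords[spots, , drop = FALSE]
    ds$spot_ids <- ds$spot_ids[spots]
  }
  if (!is.null(genes)) {
    ds$counts <- ds$counts[, genes, drop = FALSE]
    if (!is.null(ds$expr)) ds$expr <- ds$expr[, genes, drop = FALSE]
    ds$gene_ids <- ds$gene_ids[genes]
  }
  if (nrow(ds$counts) == 0L || ncol(ds$counts) == 0L)
    stop2("filtering removed all spots or all genes")
  ds
}

#' Read a Visium-style dataset from disk
#'
#' Supports a 10x-style MatrixMarket directory (`matrix.mtx` features x
#' barcodes, `barcodes.tsv`, `features.tsv`, and a `tissue_positions`
#' table in either the headered or the legacy headerless dialect) and a
#' plain CSV pair (spots x genes count matrix plus a coordinate table).
#'
#' @param path directory (format `"mtx_dir"`) or the counts CSV file
#'   (format `"csv"`).
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5"`.
#' @param coords_path for `format = "csv"`, the coordinate CSV
#'   (columns barcode, x, y); defaults to `<path dir>/coords.csv`.
#' @return A [spatial_dataset()].  Spots flagged not-in-tissue are dropped
#'   when the positions table carries an `in_tissue` column.
#' @export
read_visium <- function(path, format = c("mtx_dir", "csv", "h5"),
                        coords_path = NULL) {
  format <- match.arg(format)
  if (format == "h5")
    stop2("HDF5 input is not supported by this build; export the matrix as ",
          "an MTX directory or CSV and use format = 'mtx_dir' or 'csv'")
  if (format == "mtx_dir") read_visium_mtx(path) else read_visium_csv(path, coords_path)
}

find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_visium_mtx <- function(dir) {
  if (!dir.exists(dir)) stop2("directory not found: ", dir)
  mtx <- find_file(dir, c("matrix.mtx", "matrix.mtx.gz"))
  bc <- find_file(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft <- find_file(dir, c("features.tsv", "genes.tsv", "features.tsv.gz", "genes.tsv.gz"))
  pos <- find_file(dir, c("tissue_positions.csv", "tissue_positions_list.csv",
                          "positions.csv"))
  for (need in list(c("matrix.mtx", mtx), c("barcodes.tsv", bc),
                    c("features.tsv", ft), c("tissue_positions.csv", pos)))
    if (is.null(need[[2]])) stop2("missing required file in ", dir, ": ", need[[1]])
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop2("ill-formed MatrixMarket file ", mtx, ": ",
                                          conditionMessage(e)))
  barcodes <- readLines(bc)
  feat <- utils::read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(feat) || ncol(m) != length(barcodes))
    stop2(sprintf("matrix is %d x %d but features/barcodes have %d/%d entries",
                  nrow(m), ncol(m), nrow(feat), length(barcodes)))
  counts <- t(as.matrix(m))              # spots x genes
  rownames(counts) <- barcodes
  colnames(counts) <- make.unique(as.character(feat[[1]]))
  posdf <- read_positions(pos)
  missing_bc <- setdiff(barcodes, posdf$barcode)
  if (length(missing_bc) > 0)
    stop2(sprintf("%d matrix barcode(s) absent from positions file (e.g. %s)",
                  length(missing_bc), missing_bc[1]))
  posdf <- posdf[match(barcodes, posdf$barcode), ]
  spatial_dataset(counts,
                  coords = cbind(x = posdf$x, y = posdf$y),
                  in_tissue = posdf$in_tissue)
}

# headered (tissue_positions.csv) or legacy headerless 6-column dialect
read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 6L) stop2("ill-formed positions file ", path,
                             ": expected 6 headerless columns")
    names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  names(df) <- tolower(names(df))
  if (!"barcode" %in% names(df)) stop2("positions file ", path, " has no barcode column")
  xcol <- intersect(c("pxl_col_in_fullres", "x"), names(df))[1]
  ycol <- intersect(c("pxl_row_in_fullres", "y"), names(df))[1]
  if (is.na(xcol) || is.na(ycol))
    stop2("positions file ", path, " has no recognizable coordinate columns")
  data.frame(barcode = as.character(df$barcode),
             x = as.numeric(df[[xcol]]), y = as.numeric(df[[ycol]]),
             in_tissue = if ("in_tissue" %in% names(df)) df$in_tissue == 1 else TRUE,
             stringsAsFactors = FALSE)
}

read_visium_csv <- function(path, coords_path = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  coords_path <- coords_path %||% file.path(dirname(path), "coords.csv")
  if (!file.exists(coords_path)) stop2("coordinate file not found: ", coords_path)
  counts <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  cdf <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  names(cdf) <- tolower(names(cdf))
  if (!all(c("barcode", "x", "y") %in% names(cdf)))
    stop2("coordinate file must have columns barcode, x, y")
  missing_bc <- setdiff(rownames(counts), cdf$barcode)
  if (length(missing_bc) > 0)
    stop2(sprintf("%d matrix barcode(s) absent from coordinate file (e.g. %s)",
                  length(missing_bc), missing_bc[1]))
  cdf <- cdf[match(rownames(counts), cdf$barcode), ]
  spatial_dataset(counts, coords = cbind(x = cdf$x, y = cdf$y),
                  in_tissue = if ("in_tissue" %in% names(cdf)) cdf$in_tissue == 1)
}

#' Write a dataset as a 10x-style MTX directory
#'
#' Writes `matrix.mtx` (features x barcodes), `barcodes.tsv`,
#' `features.tsv` and a headered `tissue_positions.csv`, the same dialect
#' [read_visium()] reads back.
#'
#' @param ds a [spatial_dataset()]
#' @param dir output directory, created if needed
#' @return `dir`, invisibly.
#' @export
write_visium_mtx <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(ds$gene_ids, ds$gene_ids, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  pos <- data.frame(barcode = ds$spot_ids, in_tissue = 1L,
                    array_row = 0L, array_col = 0L,
                    pxl_row_in_fullres = ds$coords[, 2],
                    pxl_col_in_fullres = ds$coords[, 1])
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  invisible(dir)
}
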