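# Reading, validation and scale normalization of expression / signature
# matrices. Text dialect: first row = sample (or cell-type) ids, first
# column = gene ids, tab-delimited by default.

.readMatrixFile <- function(path, delimiter = "\t", what = "expression") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # optional directives: comment lines "# key: value" ahead of the header
  directives <- character()
  while (length(lines) && grepl("^#", lines[1])) {
    directives <- c(directives, sub("^#\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  if (!length(lines)) stop("malformed header: file ", path, " has no header row")
  header <- strsplit(lines[1], delimiter, fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("malformed header: expected a gene-id column plus at least one ",
         "data column in ", path)
  colIds <- trimws(header[-1])
  if (any(!nzchar(colIds))) stop("malformed header: empty column id in ", path)
  dup <- colIds[duplicated(colIds)]
  if (length(dup))
    stop("duplicate ", if (what == "expression") "sample" else "cell-type",
         " id in header: ", paste(unique(dup), collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  cells <- strsplit(body, delimiter, fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(header)))
    stop("malformed row ", which(nc != length(header))[1] + 1L, " in ", path,
         ": expected ", length(header), " fields")
  genes <- trimws(vapply(cells, `[[`, "", 1L))
  raw <- vapply(cells, function(x) trimws(x[-1]), character(length(colIds)))
  raw <- matrix(raw, nrow = length(colIds))   # columns = rows of the file
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    bad <- which(is.na(matrix(num, nrow = length(colIds))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', column '%s' in %s",
                 raw[bad[1], bad[2]], genes[bad[2]], colIds[bad[1]], path))
  }
  values <- t(matrix(num, nrow = length(colIds),
                     dimnames = list(colIds, genes)))
  list(values = values, directives = directives)
}

.parseScaleDirective <- function(directives) {
  hit <- grep("^scale\\s*[:=]", directives, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub("^scale\\s*[:=]\\s*", "", hit[1]))
}

#' Read a gene-by-sample expression matrix
#'
#' Parses a delimited text matrix (first column gene symbols, first row
#' sample ids). Duplicate gene rows are collapsed by their arithmetic mean.
#' A leading comment line of the form \code{# scale: log2p1} marks a
#' log2(TPM+1)-encoded matrix; otherwise values are taken as linear TPM.
#'
#' @param path path to the matrix file.
#' @param delimiter field delimiter, \code{"\t"} (default) or \code{","}.
#' @param scale override the scale tag (\code{"linear"} or \code{"log2p1"});
#'   default honours the file directive and falls back to linear.
#' @return A [BulkExpression-class] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, delimiter = "\t", scale = NULL) {
  parsed <- .readMatrixFile(path, delimiter, "expression")
  tag <- scale %||% .parseScaleDirective(parsed$directives) %||% "linear"
  if (!tag %in% .EXPR_SCALES)
    stop("unknown scale tag '", tag, "'")
  values <- parsed$values
  if (identical(tag, "linear") && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (anyDuplicated(rownames(values))) {
    g <- factor(rownames(values), levels = unique(rownames(values)))
    values <- rowsum(values, g, reorder = FALSE) /
      as.vector(table(g)[levels(g)])
    rownames(values) <- levels(g)
  }
  BulkExpression(values, scaleTag = tag)
}

#' Read an LM22-layout signature matrix
#'
#' Parses a delimited reference-profile matrix (gene column named
#' \code{"Gene symbol"} or simply the first column; one column per cell
#' type) and records which columns constitute CD3+ T cells and which single
#' column is the CD8+ subset.
#'
#' @param path path to the signature file.
#' @param tCellTypes character vector of column names declared as pan-T
#'   (CD3+) subsets.
#' @param cd8Type the single CD8+ column name; must be in \code{tCellTypes}.
#' @param delimiter field delimiter (tab default).
#' @return A [SignatureMatrix-class] object.
#' @export
readSignatureMatrix <- function(path, tCellTypes, cd8Type, delimiter = "\t") {
  parsed <- .readMatrixFile(path, delimiter, "signature")
  values <- parsed$values
  unknown <- setdiff(c(tCellTypes, cd8Type), colnames(values))
  if (length(unknown))
    stop("declared cell type(s) absent from signature columns: ",
         paste(unique(unknown), collapse = ", "))
  SignatureMatrix(values, tCellTypes = tCellTypes, cd8Type = cd8Type)
}

#' Convert an expression matrix to linear TPM
#'
#' Inverts the log2(TPM+1) encoding (2^x - 1 per cell) when the matrix
#' carries the \code{"log2p1"} tag; linear matrices pass through unchanged.
#' Tiny negative values produced by rounding are clamped to zero.
#'
#' @param x a [BulkExpression-class] object.
#' @return A [BulkExpression-class] on linear TPM scale.
#' @examples
#' m <- matrix(3, 1, 1, dimnames = list("A", "s1"))
#' exprValues(toLinearTPM(BulkExpression(m, "log2p1")))  # 2^3 - 1 = 7
#' @export
toLinearTPM <- function(x) {
  stopifnot(is(x, "BulkExpression"))
  if (identical(x@scaleTag, "linear")) return(x)
  if (!identical(x@scaleTag, "log2p1"))
    stop("unknown scale tag '", x@scaleTag, "'")
  v <- 2^x@values - 1
  v[v < 0] <- 0
  BulkExpression(v, scaleTag = "linear")
}

#' Write a matrix in the package's delimited dialect
#'
#' First row sample/cell-type ids, first column gene ids. Lossless partner
#' of [readExpressionMatrix()] / [readSignatureMatrix()].
#'
#' @param x a [BulkExpression-class], [SignatureMatrix-class], or plain
#'   matrix with dimnames.
#' @param path output file path.
#' @param delimiter field delimiter (tab default).
#' @param geneColumn header of the gene-id column.
#' @return Invisibly, \code{path}.
#' @export
writeMatrixTSV <- function(x, path, delimiter = "\t", geneColumn = "gene") {
  v <- if (is.matrix(x)) x else exprValues(x)
  directive <- if (is(x, "BulkExpression") && !identical(x@scaleTag, "linear"))
    sprintf("# scale: %s", x@scaleTag) else character()
  header <- paste(c(geneColumn, colnames(v)), collapse = delimiter)
  rows <- paste(rownames(v),
                apply(v, 1, function(r)
                  paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
                        collapse = delimiter)),
                sep = delimiter)
  writeLines(c(directive, header, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
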