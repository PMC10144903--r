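#' Construct an expression matrix
#'
#' The central container of the package: a cells x genes matrix of
#' non-negative values (raw counts or log-normalized expression) together
#' with per-cell metadata. Values are held as a sparse \code{dgCMatrix} so
#' large, mostly-zero single-cell matrices stay cheap.
#'
#' @param values numeric matrix or \code{Matrix} sparse matrix, cells as
#'   rows, genes as columns. All entries must be non-negative; for
#'   \code{layer = "counts"} they must be integer-valued.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames of \code{values}).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames of \code{values}).
#' @param layer either \code{"counts"} or \code{"lognorm"}.
#' @param batch optional per-cell batch identifier (length = number of cells).
#' @param label optional per-cell cell-type label.
#' @return an object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values} (sparse cells x genes matrix with dimnames),
#'   \code{layer}, \code{batch}, \code{label}.
#' @export
ExpressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values),
                             layer = c("counts", "lognorm"),
                             batch = NULL, label = NULL) {
  layer <- match.arg(layer)
  if (is.matrix(values)) {
    storage.mode(values) <- "double"
    values <- Matrix::Matrix(values, sparse = TRUE)
  }
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) {
    stop("cell_ids are required (none given and `values` has no rownames)")
  }
  if (is.null(gene_ids)) {
    stop("gene_ids are required (none given and `values` has no colnames)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) != number of rows in `values`")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) != number of columns in `values`")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  }
  if (length(values@x) && min(values@x) < 0) {
    tr <- as(values, "TsparseMatrix")
    k <- which.min(tr@x)
    stop(sprintf("negative value at cell '%s', gene '%s'",
                 cell_ids[tr@i[k] + 1L], gene_ids[tr@j[k] + 1L]))
  }
  if (layer == "counts" && length(values@x) &&
      max(abs(values@x - round(values@x))) > 1e-8) {
    stop("layer = 'counts' requires integer-valued entries")
  }
  for (nm in c("batch", "label")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != nrow(values)) {
      stop(sprintf("`%s` must have exactly one entry per cell", nm))
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, layer = layer,
                 batch = if (is.null(batch)) NULL else as.character(batch),
                 label = if (is.null(label)) NULL else as.character(label)),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(names(table(x$batch)), collapse = ", "), "\n")
  }
  if (!is.null(x$label)) {
    cat("  labels: ", length(unique(x$label)), "distinct\n")
  }
  invisible(x)
}

#' Cell and gene identifiers
#'
#' @param x an \code{ExpressionMatrix}
#' @return character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an \code{ExpressionMatrix}
#' @param cells,genes index vectors (integer, logical, or character ids)
#' @return a new \code{ExpressionMatrix} with metadata subset alongside.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(nrow(x$values)) else cells
  if (is.character(ci)) ci <- match(ci, cell_ids(x))
  if (is.logical(ci)) ci <- which(ci)
  gi <- if (is.null(genes)) seq_len(ncol(x$values)) else genes
  if (is.character(gi)) gi <- match(gi, gene_ids(x))
  if (is.logical(gi)) gi <- which(gi)
  if (anyNA(ci) || anyNA(gi)) stop("unknown cell or gene identifier in subset")
  ExpressionMatrix(x$values[ci, gi, drop = FALSE],
                   layer = x$layer,
                   batch = x$batch[ci], label = x$label[ci])
}
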