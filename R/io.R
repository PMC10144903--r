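#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported: a Matrix Market directory
#' (\code{matrix.mtx} + \code{barcodes.tsv} + \code{features.tsv}, the
#' common 10x-style export) and a dense CSV with a header row of gene
#' identifiers and a first column of cell identifiers.
#'
#' Matrix Market files in the wild are written either genes x cells (the
#' 10x convention) or cells x genes; the orientation is detected by
#' matching the matrix dimensions against the barcode and feature counts.
#' A square matrix is ambiguous and requires an explicit
#' \code{orientation}.
#'
#' @param path directory (for \code{mtx_dir}) or CSV file path.
#' @param format \code{"mtx_dir"} or \code{"csv"}.
#' @param orientation for \code{mtx_dir}: \code{"auto"} (default),
#'   \code{"genes_x_cells"} or \code{"cells_x_genes"}.
#' @param layer layer of the stored values, \code{"counts"} (default) or
#'   \code{"lognorm"}.
#' @return an \code{ExpressionMatrix} (cells x genes internally).
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv"),
                            orientation = c("auto", "genes_x_cells",
                                            "cells_x_genes"),
                            layer = "counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_dir") {
    files <- file.path(path, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("missing file(s): ", paste(missing, collapse = ", "))
    }
    m <- Matrix::readMM(files[1L])
    barcodes <- utils::read.delim(files[2L], header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    features <- utils::read.delim(files[3L], header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    if (orientation == "auto") {
      if (nrow(m) == ncol(m)) {
        stop("square matrix: orientation is ambiguous, pass `orientation`")
      }
      if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
        orientation <- "genes_x_cells"
      } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
        orientation <- "cells_x_genes"
      } else {
        stop(sprintf(paste0("matrix is %d x %d but there are %d barcodes ",
                            "and %d features"),
                     nrow(m), ncol(m), length(barcodes), length(features)))
      }
    }
    if (orientation == "genes_x_cells") m <- Matrix::t(m)
    if (nrow(m) != length(barcodes) || ncol(m) != length(features)) {
      stop("matrix dimensions do not match barcode/feature counts")
    }
    ExpressionMatrix(m, cell_ids = barcodes, gene_ids = features,
                     layer = layer)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
    cells <- as.character(df[[1L]])
    genes <- colnames(df)[-1L]   # as.matrix would silently uniquify dups
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- genes[!vapply(df[, -1L, drop = FALSE], is.numeric,
                           logical(1))][1L]
      stop(sprintf("non-numeric entries in gene column '%s'", bad))
    }
    ExpressionMatrix(vals, cell_ids = cells, gene_ids = genes,
                     layer = layer)
  }
}

#' Write an expression matrix to disk
#'
#' \code{mtx_dir} writes \code{matrix.mtx} in the genes x cells (10x)
#' orientation plus \code{barcodes.tsv} and \code{features.tsv}; \code{csv}
#' writes a dense cells x genes table. \code{read_expression} parses either
#' back to an equal object.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path output directory (\code{mtx_dir}) or file (\code{csv}).
#' @param format \code{"mtx_dir"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(x$values), file.path(path, "matrix.mtx"))
    writeLines(cell_ids(x), file.path(path, "barcodes.tsv"))
    writeLines(gene_ids(x), file.path(path, "features.tsv"))
  } else {
    df <- data.frame(cell_id = cell_ids(x),
                     as.matrix(x$values), check.names = FALSE)
    colnames(df) <- c("cell_id", gene_ids(x))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read or write per-cell metadata
#'
#' Metadata is a TSV with header columns \code{cell_id}, \code{batch} and
#' optionally \code{label}. \code{attach_metadata} joins it onto an
#' \code{ExpressionMatrix} by cell identifier.
#'
#' @param path TSV file path.
#' @return \code{read_metadata}: a data.frame with one row per cell.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% colnames(df)) stop("metadata must have a cell_id column")
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id in metadata: ",
         df$cell_id[duplicated(df$cell_id)][1L])
  }
  df
}

#' @rdname read_metadata
#' @param x an \code{ExpressionMatrix}.
#' @param meta data.frame as returned by \code{read_metadata}.
#' @return \code{attach_metadata}: \code{x} with \code{batch}/\code{label}
#'   filled in.
#' @export
attach_metadata <- function(x, meta) {
  idx <- match(cell_ids(x), meta$cell_id)
  if (anyNA(idx)) {
    stop("metadata is missing cell(s): ",
         paste(utils::head(cell_ids(x)[is.na(idx)], 5), collapse = ", "))
  }
  if (!is.null(meta$batch)) x$batch <- as.character(meta$batch[idx])
  if (!is.null(meta$label)) x$label <- as.character(meta$label[idx])
  x
}

#' Read a marker table from CSV
#'
#' The CSV header row holds cell-type names; each column lists that type's
#' marker genes in rank order. Columns may be ragged: trailing empty cells
#' are dropped.
#'
#' @param path CSV file path.
#' @return a \code{MarkerTable}.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = "character")
  if (anyDuplicated(colnames(df))) {
    stop("duplicate cell-type column names: ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  }
  entries <- lapply(df, function(col) {
    col <- trimws(col)
    col[!is.na(col) & col != ""]
  })
  empty <- names(entries)[lengths(entries) == 0L]
  if (length(empty)) {
    stop("empty marker column(s): ", paste(empty, collapse = ", "))
  }
  MarkerTable(entries)
}

#' @rdname read_marker_table
#' @param table a \code{MarkerTable}.
#' @return \code{write_marker_table}: \code{path}, invisibly.
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "MarkerTable"))
  n <- max(lengths(table$entries))
  cols <- lapply(table$entries, function(g) c(g, rep("", n - length(g))))
  utils::write.csv(as.data.frame(cols, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a cell-type score matrix
#'
#' Stored as CSV with a \code{cell_id} first column and one column per
#' cell type.
#'
#' @param path CSV file path.
#' @param variant score variant tag, \code{"raw"} or \code{"pliner"}.
#' @return \code{read_scores}: a \code{CellTypeScoreMatrix}.
#' @export
read_scores <- function(path, variant = "raw") {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  CellTypeScoreMatrix(m, variant = variant)
}

#' @rdname read_scores
#' @param scores a \code{CellTypeScoreMatrix}.
#' @return \code{write_scores}: \code{path}, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "CellTypeScoreMatrix"))
  df <- data.frame(cell_id = rownames(scores$scores), scores$scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write an annotation result
#'
#' TSV with columns \code{cell_id}, \code{label} and (when certainty was
#' computed) \code{certainty}.
#'
#' @param path TSV file path.
#' @return \code{read_annotation}: a data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_annotation
#' @param result an \code{AnnotationResult}.
#' @return \code{write_annotation}: \code{path}, invisibly.
#' @export
write_annotation <- function(result, path) {
  stopifnot(inherits(result, "AnnotationResult"))
  df <- data.frame(cell_id = result$cell_ids, label = result$label,
                   stringsAsFactors = FALSE)
  if (!is.null(result$certainty)) df$certainty <- result$certainty
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
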