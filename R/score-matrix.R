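#' Cell-type score matrix
#'
#' The integrated low-dimensional representation: one row per cell, one
#' column per cell type, each entry a weighted sum of the cell's expression
#' over that type's markers. Two variants exist: \code{"raw"} (weighted sum
#' of log-normalized expression) and \code{"pliner"} (percentile
#' thresholding plus TF-IDF applied to marker expression first).
#'
#' @param scores numeric matrix, cells x cell types, with cell ids as
#'   rownames and type names as colnames.
#' @param variant \code{"raw"} or \code{"pliner"}.
#' @param coverage optional named numeric: per cell type, the fraction of
#'   marker weight mass found in the scored data's gene set.
#' @return an object of class \code{CellTypeScoreMatrix}.
#' @export
CellTypeScoreMatrix <- function(scores, variant = c("raw", "pliner"),
                                coverage = NULL) {
  variant <- match.arg(variant)
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("`scores` needs cell ids as rownames and type names as colnames")
  }
  if (anyDuplicated(colnames(scores))) stop("duplicate cell-type columns")
  structure(list(scores = scores, variant = variant, coverage = coverage),
            class = "CellTypeScoreMatrix")
}

#' @export
dim.CellTypeScoreMatrix <- function(x) dim(x$scores)

#' @export
print.CellTypeScoreMatrix <- function(x, ...) {
  cat(sprintf("CellTypeScoreMatrix [%s]: %d cells x %d types\n",
              x$variant, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Annotation result
#'
#' Per-cell final label plus, when available, the certainty score, the
#' member labelings from each clustering run of the consensus grid, and the
#' distances behind the certainty score.
#'
#' @param cell_ids character vector of cell identifiers.
#' @param label per-cell label (cell types plus \code{"unassigned"}).
#' @param certainty optional per-cell certainty in [0, 1].
#' @param member_labelings optional cells x runs character matrix.
#' @param d_first,d_last optional per-cell distances to the nearest and
#'   farthest reference centroid.
#' @return an object of class \code{AnnotationResult}.
#' @export
AnnotationResult <- function(cell_ids, label, certainty = NULL,
                             member_labelings = NULL,
                             d_first = NULL, d_last = NULL) {
  stopifnot(length(cell_ids) == length(label))
  if (!is.null(certainty)) {
    stopifnot(length(certainty) == length(label))
    if (any(certainty < -1e-12 | certainty > 1 + 1e-12, na.rm = TRUE)) {
      stop("certainty must lie in [0, 1]")
    }
    certainty <- pmin(pmax(certainty, 0), 1)
  }
  structure(list(cell_ids = as.character(cell_ids),
                 label = as.character(label), certainty = certainty,
                 member_labelings = member_labelings,
                 d_first = d_first, d_last = d_last),
            class = "AnnotationResult")
}

#' @export
print.AnnotationResult <- function(x, ...) {
  cat(sprintf("AnnotationResult: %d cells, %d distinct labels\n",
              length(x$label), length(unique(x$label))))
  if (!is.null(x$certainty)) {
    cat(sprintf("  certainty: median %.3f, %d unassigned\n",
                stats::median(x$certainty), sum(x$label == "unassigned")))
  }
  invisible(x)
}

#' Metrics report
#'
#' A named container for the evaluation metrics: overall accuracy, macro
#' F1, rescaled cell-type silhouette, batch-mixing entropy, ARI, NMI and
#' the weighted aggregate scores. All fields are optional; aggregation
#' checks for the ones it needs.
#'
#' @param ... named numeric fields among \code{acc}, \code{macro_f1},
#'   \code{s_celltype}, \code{s_batch}, \code{ari}, \code{nmi},
#'   \code{s_integration}, \code{s_annotation}, \code{s_overall}.
#' @return an object of class \code{MetricsReport} (a named list).
#' @export
MetricsReport <- function(...) {
  fields <- list(...)
  allowed <- c("acc", "macro_f1", "s_celltype", "s_batch", "s_batch_raw",
               "ari", "nmi", "s_integration", "s_annotation", "s_overall")
  bad <- setdiff(names(fields), allowed)
  if (length(bad)) stop("unknown metric field(s): ", paste(bad, collapse = ", "))
  unit <- c("acc", "macro_f1", "s_celltype", "ari", "nmi")
  for (nm in intersect(names(fields), unit)) {
    v <- fields[[nm]]
    if (!is.null(v) && (v < -1e-9 || v > 1 + 1e-9) && nm != "ari") {
      stop(sprintf("metric '%s' = %g outside [0, 1]", nm, v))
    }
  }
  structure(fields, class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport:\n")
  for (nm in names(x)) cat(sprintf("  %-13s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
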