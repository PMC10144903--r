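#' Log-normalize a count matrix
#'
#' Divides each count by its cell's total, multiplies by a scale factor
#' (10,000 by default) and log-transforms: value = ln(1 + count / total *
#' scale). The identity sum(exp(value) - 1) = scale then holds per cell.
#'
#' @param counts \code{ExpressionMatrix} with \code{layer = "counts"}.
#' @param scale scale factor (default 10000).
#' @return \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @export
log_normalize <- function(counts, scale = 10000) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts") stop("input layer must be 'counts'")
  totals <- Matrix::rowSums(counts$values)
  if (any(totals == 0)) {
    stop("cell(s) with zero total count: ",
         paste(utils::head(cell_ids(counts)[totals == 0], 10), collapse = ", "))
  }
  v <- counts$values
  # dgCMatrix stores nonzeros column-wise; @i gives the 0-based row (cell)
  v@x <- log1p(v@x / totals[v@i + 1L] * scale)
  out <- counts
  out$values <- v
  out$layer <- "lognorm"
  out
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion of their log-normalized values:
#' dispersion = variance / mean, standardized (z-scored) within 20 bins of
#' genes grouped by mean expression, so highly expressed genes do not
#' dominate. With \code{by_batch = TRUE} the top \code{n_top} set is
#' computed per batch and the intersection (shared HVGs) is returned.
#'
#' @param data \code{ExpressionMatrix}, log-normalized.
#' @param n_top how many genes to keep (per batch when
#'   \code{by_batch = TRUE}).
#' @param by_batch select per batch and intersect (requires batch
#'   metadata).
#' @return character vector of selected gene ids (in the data's gene
#'   order).
#' @export
highly_variable_genes <- function(data, n_top = 5000, by_batch = FALSE) {
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (data$layer != "lognorm") stop("data must be log-normalized")
  if (n_top <= 0) stop("n_top must be positive")
  if (by_batch && is.null(data$batch)) {
    stop("by_batch = TRUE requires batch metadata")
  }
  pick <- function(v) {
    mu <- Matrix::colMeans(v)
    ex2 <- Matrix::colMeans(v^2)
    va <- (ex2 - mu^2) * nrow(v) / max(nrow(v) - 1, 1)
    disp <- ifelse(mu > 0, va / mu, 0)
    bins <- cut(mu, breaks = 20, include.lowest = TRUE)
    z <- stats::ave(disp, bins, FUN = function(d) {
      s <- stats::sd(d)
      if (!is.finite(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
    })
    ord <- order(-z, seq_along(z))
    colnames(v)[ord[seq_len(min(n_top, ncol(v)))]]
  }
  if (!by_batch || length(unique(data$batch)) == 1L) {
    sel <- pick(data$values)
  } else {
    per_batch <- lapply(unique(data$batch), function(b) {
      pick(data$values[data$batch == b, , drop = FALSE])
    })
    sel <- Reduce(intersect, per_batch)
    if (!length(sel)) {
      stop("no genes shared across per-batch HVG sets; increase n_top")
    }
  }
  gene_ids(data)[gene_ids(data) %in% sel]
}

#' Percentile-threshold and TF-IDF transform marker expression
#'
#' The preprocessing behind the thresholded score variant: per marker gene,
#' expression values below the gene's percentile threshold (computed over
#' all cells, or over nonzero values only) are suppressed to zero, and the
#' surviving values are scaled by an inverse-document-frequency term
#' idf = ln(1 + n_cells / (1 + n_cells expressing after thresholding)),
#' which up-weights selectively expressed markers.
#'
#' @param data \code{ExpressionMatrix}, log-normalized.
#' @param markers character vector of marker genes to transform (must be
#'   present in \code{data}).
#' @param percentile threshold percentile in [0, 1] (default 0.25);
#'   percentiles use linear interpolation between order statistics.
#' @param percentile_over \code{"all"} (default) or \code{"nonzero"}: which
#'   values the percentile is taken over.
#' @return sparse cells x markers matrix of transformed values.
#' @export
pliner_transform <- function(data, markers, percentile = 0.25,
                             percentile_over = c("all", "nonzero")) {
  percentile_over <- match.arg(percentile_over)
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (data$layer != "lognorm") stop("data must be log-normalized")
  if (percentile < 0 || percentile > 1) stop("percentile must be in [0, 1]")
  absent <- setdiff(markers, gene_ids(data))
  if (length(absent)) {
    stop("marker gene(s) not in data: ", paste(utils::head(absent, 5),
                                               collapse = ", "))
  }
  v <- data$values[, markers, drop = FALSE]
  n <- nrow(v)
  out <- as.matrix(v)
  for (j in seq_along(markers)) {
    x <- out[, j]
    vals <- if (percentile_over == "all") x else x[x > 0]
    thr <- if (length(vals)) {
      unname(stats::quantile(vals, percentile, type = 7))
    } else 0
    x[x < thr] <- 0
    idf <- log(1 + n / (1 + sum(x > 0)))
    out[, j] <- x * idf
  }
  methods::as(out, "CsparseMatrix")
}

#' Convert expression to a cell-type score matrix
#'
#' The core representation change: for every cell and cell type, the score
#' is the weighted sum of the cell's (log-normalized or
#' percentile-thresholded TF-IDF) expression over that type's ranked
#' markers. Markers absent from the data's gene set are dropped without
#' renormalizing the remaining weights; per-type coverage (fraction of
#' weight mass present) is attached to the result so poorly covered types
#' are visible.
#'
#' @param data \code{ExpressionMatrix}, log-normalized.
#' @param wmarkers a \code{WeightedMarkerTable} (a plain
#'   \code{MarkerTable} is weighted with the default scheme first).
#' @param variant \code{"raw"} or \code{"pliner"}.
#' @param pliner_percentile,percentile_over passed to
#'   \code{\link{pliner_transform}} for the pliner variant.
#' @param use_weights set \code{FALSE} to ignore rank weights (plain sums).
#' @return a \code{CellTypeScoreMatrix} with per-type \code{coverage}.
#' @export
score_cells <- function(data, wmarkers, variant = c("raw", "pliner"),
                        pliner_percentile = 0.25,
                        percentile_over = "all", use_weights = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (data$layer != "lognorm") stop("data must be log-normalized")
  if (inherits(wmarkers, "MarkerTable")) wmarkers <- weigh_markers(wmarkers)
  stopifnot(inherits(wmarkers, "WeightedMarkerTable"))

  genes <- gene_ids(data)
  types <- names(wmarkers$entries)
  coverage <- numeric(length(types)); names(coverage) <- types
  present <- lapply(types, function(ct) {
    e <- wmarkers$entries[[ct]]
    keep <- e$gene %in% genes
    coverage[ct] <<- sum(e$weight[keep]) / sum(e$weight)
    e[keep, , drop = FALSE]
  })
  names(present) <- types
  none <- types[vapply(present, nrow, integer(1)) == 0L]
  if (length(none)) {
    stop("cell type(s) with no markers present in the data: ",
         paste(none, collapse = ", "))
  }

  used_genes <- unique(unlist(lapply(present, `[[`, "gene")))
  V <- if (variant == "raw") {
    data$values[, used_genes, drop = FALSE]
  } else {
    pliner_transform(data, used_genes, percentile = pliner_percentile,
                     percentile_over = percentile_over)
  }
  W <- matrix(0, length(used_genes), length(types),
              dimnames = list(used_genes, types))
  for (ct in types) {
    e <- present[[ct]]
    W[e$gene, ct] <- if (use_weights) e$weight else 1
  }
  scores <- as.matrix(V %*% W)
  rownames(scores) <- cell_ids(data)
  CellTypeScoreMatrix(scores, variant = variant, coverage = coverage)
}

#' Pipeline configuration for building a representation
#'
#' Captures the data-processing variants compared in the method's ablation:
#' which features are used (all-data HVGs, shared per-batch HVGs, or marker
#' genes) and whether the representation stays in gene space or is
#' converted to a cell-type score matrix (raw or thresholded TF-IDF
#' variant). Score representations require marker features.
#'
#' @param feature_source \code{"hvg_all"}, \code{"hvg_by_batch"} or
#'   \code{"markers"}.
#' @param representation \code{"genes"}, \code{"raw_score"} or
#'   \code{"pliner_score"}.
#' @param n_hvg HVGs to select (default 5000).
#' @param pliner_percentile threshold percentile (default 0.25).
#' @param percentile_over \code{"all"} or \code{"nonzero"}.
#' @param use_weights apply rank-based marker weights in scoring.
#' @return a \code{PipelineConfig} list.
#' @export
PipelineConfig <- function(feature_source = c("markers", "hvg_all",
                                              "hvg_by_batch"),
                           representation = c("pliner_score", "raw_score",
                                              "genes"),
                           n_hvg = 5000, pliner_percentile = 0.25,
                           percentile_over = "all", use_weights = TRUE) {
  feature_source <- match.arg(feature_source)
  representation <- match.arg(representation)
  if (representation %in% c("raw_score", "pliner_score") &&
      feature_source != "markers") {
    stop("score representations require feature_source = 'markers'")
  }
  structure(list(feature_source = feature_source,
                 representation = representation, n_hvg = n_hvg,
                 pliner_percentile = pliner_percentile,
                 percentile_over = percentile_over,
                 use_weights = use_weights),
            class = "PipelineConfig")
}

#' Build the configured representation of a dataset
#'
#' Dispatches over \code{\link{PipelineConfig}}: gene-space
#' representations return an \code{ExpressionMatrix} restricted to the
#' selected features (all-data HVGs, shared per-batch HVGs, or the union
#' of marker genes); score representations return the
#' \code{CellTypeScoreMatrix} from \code{\link{score_cells}}.
#'
#' @param data \code{ExpressionMatrix}, log-normalized.
#' @param markers \code{MarkerTable} or \code{WeightedMarkerTable}
#'   (required unless \code{feature_source} is HVG-based).
#' @param config a \code{PipelineConfig}.
#' @return \code{ExpressionMatrix} or \code{CellTypeScoreMatrix}.
#' @export
build_representation <- function(data, markers = NULL, config = PipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (config$feature_source != "markers") {
    sel <- highly_variable_genes(data, n_top = config$n_hvg,
                                 by_batch = config$feature_source == "hvg_by_batch")
    return(subset_cells(data, genes = sel))
  }
  if (is.null(markers)) stop("marker features requested but no marker table given")
  if (inherits(markers, "MarkerTable") && config$representation != "genes") {
    markers <- weigh_markers(markers)
  }
  if (config$representation == "genes") {
    mt <- if (inherits(markers, "WeightedMarkerTable")) {
      lapply(markers$entries, `[[`, "gene")
    } else markers$entries
    sel <- intersect(gene_ids(data), unique(unlist(mt)))
    if (!length(sel)) stop("no marker genes present in the data")
    return(subset_cells(data, genes = sel))
  }
  score_cells(data, markers,
              variant = if (config$representation == "raw_score") "raw" else "pliner",
              pliner_percentile = config$pliner_percentile,
              percentile_over = config$percentile_over,
              use_weights = config$use_weights)
}
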