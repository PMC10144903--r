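#' Construct a marker table
#'
#' A marker table maps each cell type to an ordered list of marker genes,
#' rank 1 being the most specific marker. Different cell types may share
#' genes (subtypes often share common markers) but a gene may not appear
#' twice within one type's list.
#'
#' @param entries named list; names are cell-type names, elements are
#'   character vectors of gene symbols in rank order.
#' @return an object of class \code{MarkerTable}.
#' @export
MarkerTable <- function(entries) {
  if (!length(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    stop("`entries` must be a non-empty named list of gene vectors")
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicate cell-type names: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  }
  entries <- lapply(entries, as.character)
  for (ct in names(entries)) {
    g <- entries[[ct]]
    if (!length(g)) stop(sprintf("cell type '%s' has an empty marker list", ct))
    if (anyDuplicated(g)) {
      stop(sprintf("cell type '%s' lists gene '%s' more than once",
                   ct, g[duplicated(g)][1L]))
    }
  }
  structure(list(entries = entries), class = "MarkerTable")
}

#' @export
print.MarkerTable <- function(x, ...) {
  cat(sprintf("MarkerTable: %d cell types\n", length(x$entries)))
  for (ct in names(x$entries)) {
    g <- x$entries[[ct]]
    cat(sprintf("  %s (%d): %s%s\n", ct, length(g),
                paste(utils::head(g, 5), collapse = ", "),
                if (length(g) > 5) ", ..." else ""))
  }
  invisible(x)
}

#' Merge two marker tables
#'
#' Marker tables are column-oriented, so assembling references is a column
#' concatenation: the union of the two tables' cell types. When both tables
#' define the same cell type, \code{on_conflict} decides whether that is an
#' error or whether \code{a}'s ranking wins.
#'
#' @param a,b \code{MarkerTable} objects.
#' @param on_conflict \code{"error"} (default) or \code{"prefer_a"}.
#' @return merged \code{MarkerTable}.
#' @export
merge_marker_tables <- function(a, b, on_conflict = c("error", "prefer_a")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(inherits(a, "MarkerTable"), inherits(b, "MarkerTable"))
  shared <- intersect(names(a$entries), names(b$entries))
  if (length(shared) && on_conflict == "error") {
    stop("cell types present in both tables: ", paste(shared, collapse = ", "))
  }
  out <- a$entries
  for (ct in setdiff(names(b$entries), names(a$entries))) {
    out[[ct]] <- b$entries[[ct]]
  }
  MarkerTable(out)
}

#' Attach rank-based weights to a marker table
#'
#' For a cell type with N ranked markers the top marker contributes 100% of
#' its expression to the cell-type score and the Nth (last) marker 50%; the
#' i-th marker for i >= 2 gets weight \code{1 - (i/N) * (1/2)}. With a
#' single marker (N = 1) the weight is 1.
#'
#' @param table a \code{MarkerTable}.
#' @param scheme weighting scheme: \code{"rank_discount"} (the default
#'   linear discount above), \code{"rank_order_centroid"}
#'   (w_i proportional to sum_{k=i}^{N} 1/k, rescaled to [0.5, 1]), or
#'   \code{"ratio"} (linear from 1 at rank 1 to 0.5 at rank N).
#' @return a \code{WeightedMarkerTable}: list with element \code{entries},
#'   per cell type a data.frame with columns \code{gene}, \code{rank},
#'   \code{weight}.
#' @export
weigh_markers <- function(table,
                          scheme = c("rank_discount", "rank_order_centroid",
                                     "ratio")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "MarkerTable"))
  entries <- lapply(names(table$entries), function(ct) {
    g <- table$entries[[ct]]
    n <- length(g)
    i <- seq_len(n)
    w <- switch(scheme,
      rank_discount = {
        w <- 1 - (i / n) * 0.5
        w[1L] <- 1   # top marker contributes its full expression
        w
      },
      rank_order_centroid = {
        roc <- rev(cumsum(1 / rev(i))) / n      # classic ROC weights, sum 1
        if (n == 1L) 1 else 0.5 + 0.5 * (roc - roc[n]) / (roc[1L] - roc[n])
      },
      ratio = if (n == 1L) 1 else 1 - 0.5 * (i - 1) / (n - 1)
    )
    data.frame(gene = g, rank = i, weight = w, stringsAsFactors = FALSE)
  })
  names(entries) <- names(table$entries)
  structure(list(entries = entries, scheme = scheme),
            class = "WeightedMarkerTable")
}

#' @export
print.WeightedMarkerTable <- function(x, ...) {
  cat(sprintf("WeightedMarkerTable (%s): %d cell types\n",
              x$scheme, length(x$entries)))
  invisible(x)
}
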