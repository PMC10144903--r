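#' One-vs-rest differential expression across all cell types
#'
#' For every label, tests each gene for higher expression in that label's
#' cells versus all remaining cells. Three tests are built in:
#' \describe{
#'   \item{wilcoxon}{rank-sum with tie correction; exact null distribution
#'     when both groups are small (< 50) and the gene has no tied values,
#'     normal approximation otherwise; one-sided (greater in target). The
#'     reported statistic is the standardized U.}
#'   \item{welch_t}{unequal-variance t statistic, one-sided.}
#'   \item{log2fc}{log2((mean_target + eps) / (mean_rest + eps)) with
#'     eps = 1e-9; a pure ranking statistic, p-values are set to 1.}
#' }
#' P-values are Benjamini-Hochberg adjusted within each (cell type,
#' method). Genes are ranked per type by descending statistic, ties broken
#' by gene index.
#'
#' @param data an \code{ExpressionMatrix} with \code{layer = "lognorm"}.
#' @param labels per-cell labels (defaults to \code{data$label}).
#' @param method one of \code{"wilcoxon"}, \code{"welch_t"},
#'   \code{"log2fc"}.
#' @return a \code{DEResult}: list with \code{method} and \code{results}, a
#'   named list (one per cell type) of data.frames with columns
#'   \code{gene}, \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{rank}.
#' @export
de_one_vs_rest <- function(data, labels = data$label,
                           method = c("wilcoxon", "welch_t", "log2fc")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (data$layer != "lognorm") {
    stop("data must be log-normalized (run log_normalize first)")
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(data$values))
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("group(s) with < 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (length(tab) < 2) stop("one-vs-rest needs at least 2 distinct labels")

  X <- as.matrix(data$values)
  genes <- gene_ids(data)
  n <- nrow(X)
  types <- sort(names(tab))

  if (method == "wilcoxon") {
    # ranks over all cells are shared by every one-vs-rest comparison
    R <- apply(X, 2L, rank)
    tie_term <- apply(X, 2L, function(v) {
      t <- tabulate(match(v, unique(v)))
      sum(t^3 - t)
    })
    has_ties <- tie_term > 0
  }

  results <- lapply(types, function(ct) {
    grp <- labels == ct
    n1 <- sum(grp); n2 <- n - n1
    if (method == "wilcoxon") {
      U <- colSums(R[grp, , drop = FALSE]) - n1 * (n1 + 1) / 2
      v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- ifelse(v > 0, (U - n1 * n2 / 2) / sqrt(v), 0)
      p <- ifelse(v > 0, stats::pnorm(z, lower.tail = FALSE), 0.5)
      if (max(n1, n2) < 50) {
        exact <- !has_ties
        if (any(exact)) {
          p[exact] <- stats::pwilcox(U[exact] - 1, n1, n2,
                                     lower.tail = FALSE)
        }
      }
      stat <- z
    } else if (method == "welch_t") {
      m1 <- colMeans(X[grp, , drop = FALSE])
      m2 <- colMeans(X[!grp, , drop = FALSE])
      v1 <- .col_vars(X[grp, , drop = FALSE], m1)
      v2 <- .col_vars(X[!grp, , drop = FALSE], m2)
      se2 <- v1 / n1 + v2 / n2
      stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                     sign(m1 - m2) * Inf)
      stat[se2 == 0 & m1 == m2] <- 0
      df <- ifelse(se2 > 0,
                   se2^2 / (v1^2 / (n1^2 * (n1 - 1)) +
                            v2^2 / (n2^2 * (n2 - 1))), 1)
      p <- ifelse(is.finite(stat), stats::pt(stat, df, lower.tail = FALSE),
                  ifelse(stat > 0, 0, 1))
      p[se2 == 0 & m1 == m2] <- 0.5
    } else {
      eps <- 1e-9
      m1 <- colMeans(X[grp, , drop = FALSE])
      m2 <- colMeans(X[!grp, , drop = FALSE])
      stat <- log2((m1 + eps) / (m2 + eps))
      p <- rep(1, length(stat))
    }
    padj <- stats::p.adjust(p, method = "BH")
    ord <- order(-stat, seq_along(stat))
    rk <- integer(length(stat)); rk[ord] <- seq_along(stat)
    data.frame(gene = genes, statistic = unname(stat),
               p_value = unname(p), p_adjusted = unname(padj),
               rank = rk, stringsAsFactors = FALSE)
  })
  names(results) <- types
  structure(list(method = method, results = results), class = "DEResult")
}

.col_vars <- function(m, means) {
  colSums(sweep(m, 2L, means)^2) / (nrow(m) - 1)
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult [%s]: %d cell types x %d genes\n", x$method,
              length(x$results), nrow(x$results[[1L]])))
  invisible(x)
}
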