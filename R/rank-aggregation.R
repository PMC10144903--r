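#' Robust rank aggregation of top-k gene lists
#'
#' Consensus ranking across m ranked lists. Each list is truncated to its
#' \code{top_k} entries; for every gene in the union of the input lists,
#' the normalized rank in list j is r_j = rank_j / universe, or 1 when the
#' gene is absent from that list's top k. With the m normalized ranks
#' sorted ascending r(1) <= ... <= r(m), the aggregation score is
#' \deqn{\rho = \min_k P(\mathrm{Beta}(k, m - k + 1) \le r_{(k)}),}
#' the smallest tail probability among the uniform order-statistic
#' distributions — small when a gene sits unusually high in several lists.
#' Genes are returned sorted ascending by \eqn{\rho}, ties broken by mean
#' normalized rank then by gene index.
#'
#' @param rank_lists list of character vectors, each a ranked gene list
#'   (rank 1 first).
#' @param top_k how many leading entries of each list to use (default 20).
#' @param universe total number of genes ranks are normalized against.
#' @param gene_index optional named integer vector giving a stable index
#'   per gene for tie-breaking; defaults to first-appearance order.
#' @return data.frame with columns \code{gene}, \code{rho},
#'   \code{rho_corrected} (Bonferroni over the m order statistics, capped
#'   at 1; informational only, ranking uses raw \code{rho}) and
#'   \code{mean_rank} (mean normalized rank), sorted ascending by
#'   \code{rho}.
#' @export
aggregate_topk_rra <- function(rank_lists, top_k = 20, universe,
                               gene_index = NULL) {
  if (!length(rank_lists)) stop("need at least one rank list")
  if (top_k <= 0) stop("top_k must be positive")
  if (missing(universe) || universe < top_k) {
    stop("universe must be given and >= top_k")
  }
  rank_lists <- lapply(rank_lists, as.character)
  all_genes <- unique(unlist(rank_lists))
  if (!length(all_genes)) stop("rank lists are empty")
  if (is.null(gene_index)) {
    gene_index <- stats::setNames(seq_along(all_genes), all_genes)
  }
  m <- length(rank_lists)
  trunc_lists <- lapply(rank_lists, utils::head, top_k)

  rmat <- vapply(trunc_lists, function(lst) {
    r <- match(all_genes, lst) / universe
    r[is.na(r)] <- 1
    r
  }, numeric(length(all_genes)))
  rmat <- matrix(rmat, nrow = length(all_genes))

  rho <- apply(rmat, 1L, function(r) {
    r <- sort(r)
    min(stats::pbeta(r, seq_len(m), m - seq_len(m) + 1))
  })
  mean_rank <- rowMeans(rmat)
  ord <- order(rho, mean_rank, gene_index[all_genes])
  data.frame(gene = all_genes[ord], rho = rho[ord],
             rho_corrected = pmin(rho[ord] * m, 1),
             mean_rank = mean_rank[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lancaster combination of significant DE p-values
#'
#' The weighted generalization of Fisher's method: each method's p-value
#' p_i is transformed through the upper quantile of a chi-square with
#' w_i degrees of freedom, the transforms are summed, and the sum is
#' referred to a chi-square with \eqn{\sum w_i} degrees of freedom. With
#' all weights equal to 2 this is exactly Fisher's method. Only methods in
#' which a gene is significant after Benjamini-Hochberg adjustment
#' (\code{p_adjusted < alpha}) contribute; genes significant in no method
#' are excluded.
#'
#' @param de_results list of per-gene test tables for one cell type: each
#'   element a data.frame with columns \code{gene}, \code{p_value},
#'   \code{p_adjusted} (as produced per type by
#'   \code{\link{de_one_vs_rest}}).
#' @param alpha significance cutoff on the adjusted p-value (default 0.05).
#' @param weights per-method chi-square weights, recycled to the number of
#'   methods (default 2 for every method).
#' @param gene_index optional named integer vector for tie-breaking.
#' @return data.frame with columns \code{gene}, \code{p_combined},
#'   \code{n_methods} (how many methods contributed), sorted ascending by
#'   \code{p_combined}, ties by gene index.
#' @export
aggregate_significant_lancaster <- function(de_results, alpha = 0.05,
                                            weights = 2, gene_index = NULL) {
  if (!length(de_results)) stop("need at least one DE result")
  weights <- rep_len(weights, length(de_results))
  if (all(weights <= 0)) stop("all weights are <= 0")
  genes <- de_results[[1L]]$gene
  if (is.null(gene_index)) {
    gene_index <- stats::setNames(seq_along(genes), genes)
  }
  pmat <- vapply(de_results, function(df) {
    df$p_value[match(genes, df$gene)]
  }, numeric(length(genes)))
  pmat <- matrix(pmat, nrow = length(genes))
  sigmat <- vapply(de_results, function(df) {
    df$p_adjusted[match(genes, df$gene)] < alpha
  }, logical(length(genes)))
  sigmat <- matrix(sigmat, nrow = length(genes))

  keep <- rowSums(sigmat) > 0
  if (!any(keep)) {
    return(data.frame(gene = character(), p_combined = numeric(),
                      n_methods = integer(), stringsAsFactors = FALSE))
  }
  p_comb <- vapply(which(keep), function(i) {
    use <- sigmat[i, ]
    tt <- sum(stats::qchisq(pmat[i, use], df = weights[use],
                            lower.tail = FALSE))
    stats::pchisq(tt, df = sum(weights[use]), lower.tail = FALSE)
  }, numeric(1))
  g <- genes[keep]
  ord <- order(p_comb, gene_index[g])
  data.frame(gene = g[ord], p_combined = p_comb[ord],
             n_methods = rowSums(sigmat)[keep][ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify ranked cell-type markers from annotated reference data
#'
#' Runs an ensemble of one-vs-rest DE tests per cell type and aggregates
#' their outcomes into one ranked marker list per type, using either of
#' two schemes: compiling each test's top 20 genes and searching the
#' consensus by robust rank aggregation (\code{"rra_top20"}), or keeping
#' only genes significant after multiple-testing correction and combining
#' their p-values by the Lancaster method
#' (\code{"lancaster_significant"}).
#'
#' @param reference \code{ExpressionMatrix}, log-normalized, with labels.
#' @param scheme \code{"rra_top20"} or \code{"lancaster_significant"}.
#' @param methods DE methods for the ensemble (see
#'   \code{\link{de_one_vs_rest}}).
#' @param n_markers markers to keep per cell type (default 20).
#' @param labels per-cell labels (defaults to \code{reference$label}).
#' @param top_k per-test compilation depth for the RRA scheme (default 20).
#' @param alpha significance cutoff for the Lancaster scheme.
#' @return a \code{MarkerTable} with up to \code{n_markers} genes per type.
#' @export
identify_markers <- function(reference,
                             scheme = c("rra_top20", "lancaster_significant"),
                             methods = c("wilcoxon", "welch_t", "log2fc"),
                             n_markers = 20, labels = reference$label,
                             top_k = 20, alpha = 0.05) {
  scheme <- match.arg(scheme)
  de <- lapply(methods, function(m) de_one_vs_rest(reference, labels, m))
  types <- names(de[[1L]]$results)
  genes <- gene_ids(reference)
  gidx <- stats::setNames(seq_along(genes), genes)

  entries <- lapply(types, function(ct) {
    per_method <- lapply(de, function(d) d$results[[ct]])
    if (scheme == "rra_top20") {
      lists <- lapply(per_method, function(df) df$gene[order(df$rank)])
      agg <- aggregate_topk_rra(lists, top_k = min(top_k, length(genes)),
                                universe = length(genes), gene_index = gidx)
      picked <- agg$gene
    } else {
      # log2fc carries no p-values (all 1); it cannot vote here
      agg <- aggregate_significant_lancaster(per_method, alpha = alpha,
                                             gene_index = gidx)
      if (!nrow(agg)) {
        stop(sprintf(
          "cell type '%s' has no significant genes under any DE method", ct))
      }
      picked <- agg$gene
    }
    if (length(picked) < n_markers) {
      warning(sprintf("cell type '%s': only %d aggregated genes available (%d requested)",
                      ct, length(picked), n_markers))
    }
    utils::head(picked, n_markers)
  })
  names(entries) <- types
  MarkerTable(entries)
}
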