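#' Overall annotation accuracy
#'
#' Fraction of cells whose predicted label equals the truth label.
#'
#' @param pred,truth character vectors of equal length.
#' @return accuracy in [0, 1].
#' @export
overall_accuracy <- function(pred, truth) {
  .check_paired(pred, truth)
  mean(pred == truth)
}

#' Macro-averaged F1 score
#'
#' Per truth class, F1 = 2 * precision * recall / (precision + recall)
#' (0 when undefined, e.g. a class never predicted); the macro F1 is the
#' unweighted mean over classes present in the truth, so minority cell
#' types count as much as dominant ones. Classes predicted but absent
#' from the truth are ignored.
#'
#' @param pred,truth character vectors of equal length.
#' @return macro F1 in [0, 1].
#' @export
macro_f1 <- function(pred, truth) {
  .check_paired(pred, truth)
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Rescaled cell-type silhouette score
#'
#' Mean silhouette width S of the cells under Euclidean distance on the
#' given representation, grouped by label, rescaled from [-1, 1] to
#' [0, 1] as (1 + S) / 2. Quantifies how well the representation keeps
#' cell types separated; 0.5 is the "no structure" point.
#'
#' @param representation numeric matrix, cells as rows (a score matrix's
#'   \code{$scores} or any embedding).
#' @param labels per-cell labels, >= 2 distinct.
#' @return rescaled silhouette in [0, 1].
#' @export
celltype_silhouette <- function(representation, labels) {
  representation <- as.matrix(representation)
  stopifnot(nrow(representation) == length(labels))
  if (length(unique(labels)) < 2) stop("silhouette needs >= 2 labels")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(representation))
  s <- mean(sil[, "sil_width"])
  (1 + s) / 2
}

#' Batch-mixing entropy
#'
#' Embeds the representation to two dimensions with UMAP (cosine metric,
#' min_dist 0.1, 15 neighbors, seeded), samples cells, and around each
#' sampled cell takes its \code{region_k} nearest neighbors in the
#' embedding as a region. Per region the Shannon entropy of batch
#' proportions E = -sum_i x_i ln x_i is computed (0 ln 0 := 0); the score
#' is the mean over regions, divided by ln(number of batches) when
#' \code{normalized} so that perfect mixing gives 1. A dataset from a
#' single batch scores 0.
#'
#' @param representation numeric matrix, cells as rows.
#' @param batches per-cell batch labels.
#' @param n_regions number of sampled region centers (default 500, capped
#'   at the number of cells).
#' @param region_k region size in cells (default 100; must be smaller
#'   than the number of cells).
#' @param seed integer seed (UMAP and the region sample).
#' @param normalized divide by ln(c) (default TRUE).
#' @return mean region entropy (raw, or normalized to [0, 1]).
#' @export
batch_entropy_mixing <- function(representation, batches, n_regions = 500,
                                 region_k = 100, seed = 0,
                                 normalized = TRUE) {
  representation <- as.matrix(representation)
  n <- nrow(representation)
  stopifnot(n == length(batches))
  if (region_k >= n) stop("region_k must be smaller than the number of cells")
  batches <- as.character(batches)
  c_batches <- length(unique(batches))
  if (c_batches < 2) return(0)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  emb <- uwot::umap(representation, n_neighbors = 15, min_dist = 0.1,
                    metric = "cosine", n_threads = 1, n_sgd_threads = 1)
  centers <- sample.int(n, min(n_regions, n))
  nn <- .euclidean_knn(emb, centers, region_k)
  ent <- vapply(seq_along(centers), function(r) {
    x <- tabulate(factor(batches[nn[r, ]], levels = unique(batches)),
                  nbins = c_batches) / region_k
    -sum(ifelse(x > 0, x * log(x), 0))
  }, numeric(1))
  e <- mean(ent)
  if (normalized) e / log(c_batches) else e
}

# region_k nearest neighbors (self included) of selected rows in `emb`
.euclidean_knn <- function(emb, centers, k) {
  out <- matrix(0L, length(centers), k)
  for (r in seq_along(centers)) {
    d2 <- colSums((t(emb) - emb[centers[r], ])^2)
    out[r, ] <- order(d2, seq_len(nrow(emb)))[seq_len(k)]
  }
  out
}

#' Adjusted Rand index
#'
#' Agreement between two labelings corrected for chance, via the
#' contingency-table formula: ARI = (RI - E[RI]) / (max(RI) - E[RI]).
#' 1 means identical partitions (up to renaming), 0 the chance level;
#' values below 0 indicate worse-than-random agreement.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (<= 1).
#' @export
ari <- function(a, b) {
  .check_paired(a, b)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  if (n2 == 0) return(1)   # a single cell: partitions trivially agree
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' I(P, T) / sqrt(H(P) H(T)) with natural logarithms, where P and T are
#' the empirical label distributions. When either entropy is zero (a
#' one-class labeling) the value is 1 if the partitions are identical as
#' partitions, else 0.
#'
#' @param a,b label vectors of equal length.
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b) {
  .check_paired(a, b)
  tab <- table(a, b)
  n <- length(a)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 || hb == 0) {
    same <- ari(a, b) == 1
    return(if (same) 1 else 0)
  }
  outer_p <- outer(pa, pb)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer_p), 0))
  mi / sqrt(ha * hb)
}

#' Aggregate evaluation scores
#'
#' Combines the component metrics into the weighted summary scores:
#' integration = 0.7 * cell-type silhouette + 0.3 * batch-mixing entropy,
#' annotation = 0.7 * macro F1 + 0.3 * accuracy, overall = their mean.
#' The heavier weights deliberately favor preserving cell-type structure
#' over batch mixing, and balanced per-type accuracy over raw accuracy.
#'
#' @param report a \code{MetricsReport} with the needed component fields.
#' @return the report with \code{s_integration}, \code{s_annotation} and
#'   (when both are computable) \code{s_overall} filled in.
#' @export
aggregate_scores <- function(report) {
  stopifnot(inherits(report, "MetricsReport"))
  if (!is.null(report$s_celltype) && !is.null(report$s_batch)) {
    report$s_integration <- 0.7 * report$s_celltype + 0.3 * report$s_batch
  } else if (is.null(report$s_integration)) {
    missing <- c("s_celltype", "s_batch")[c(is.null(report$s_celltype),
                                            is.null(report$s_batch))]
    stop("cannot aggregate, missing: ", paste(missing, collapse = ", "))
  }
  if (!is.null(report$macro_f1) && !is.null(report$acc)) {
    report$s_annotation <- 0.7 * report$macro_f1 + 0.3 * report$acc
  } else if (is.null(report$s_annotation)) {
    missing <- c("macro_f1", "acc")[c(is.null(report$macro_f1),
                                      is.null(report$acc))]
    stop("cannot aggregate, missing: ", paste(missing, collapse = ", "))
  }
  report$s_overall <- (report$s_integration + report$s_annotation) / 2
  report
}

.check_paired <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)))
  }
  if (!length(a)) stop("empty label vectors")
  invisible(TRUE)
}
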