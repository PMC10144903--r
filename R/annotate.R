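#' Consensus annotation configuration
#'
#' The over-clustering grid: Louvain community detection is run at every
#' combination of clustering resolution and k-nearest-neighbor
#' neighborhood size (defaults 3/5/7 x 5/10/15, a 9-run grid), each run's
#' clusters are mapped to cell-type labels, and the per-cell majority
#' across runs is the final call. Cosine distance on score rows is the
#' fixed metric. Seeds for the grid runs are derived as
#' \code{seed + 1000 * grid_index} so runs are reproducible but not
#' correlated.
#'
#' @param resolutions Louvain resolutions (> 0).
#' @param neighbor_sizes kNN graph neighborhood sizes (>= 2).
#' @param seed base integer seed.
#' @param n_chunks default chunk count for
#'   \code{\link{annotate_parallel}}.
#' @param tie_break \code{"mean_score"} (tied types resolved by higher
#'   column mean, then lexicographic) or \code{"lexicographic"}.
#' @return a \code{ConsensusConfig} list.
#' @export
ConsensusConfig <- function(resolutions = c(3, 5, 7),
                            neighbor_sizes = c(5, 10, 15),
                            seed = 0, n_chunks = 1,
                            tie_break = c("mean_score", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  stopifnot(all(resolutions > 0), all(neighbor_sizes >= 2), n_chunks >= 1)
  structure(list(resolutions = resolutions,
                 neighbor_sizes = neighbor_sizes, seed = seed,
                 n_chunks = n_chunks, tie_break = tie_break),
            class = "ConsensusConfig")
}

#' Per-cell argmax labels from a score matrix
#'
#' "Label 1" of the consensus scheme: each cell gets the cell type with
#' its highest score. Exact ties follow the tie-break rule; a cell whose
#' scores are all zero is \code{"unassigned"}.
#'
#' @param scores a \code{CellTypeScoreMatrix}.
#' @param tie_break see \code{\link{ConsensusConfig}}.
#' @return character vector of per-cell labels.
#' @export
per_cell_labels <- function(scores, tie_break = c("mean_score",
                                                  "lexicographic")) {
  tie_break <- match.arg(tie_break)
  m <- scores$scores
  types <- colnames(m)
  col_pref <- if (tie_break == "mean_score") {
    order(-colMeans(m), types)     # preferred column first
  } else {
    order(types)
  }
  mp <- m[, col_pref, drop = FALSE]
  lab <- colnames(mp)[max.col(mp, ties.method = "first")]
  lab[Matrix::rowSums(m != 0) == 0L] <- "unassigned"
  lab
}

#' Over-cluster cells by Louvain on a cosine kNN graph
#'
#' "Label 2": builds the k-nearest-neighbor graph of score rows under
#' cosine distance (ties in neighbor selection broken by cell index),
#' then runs Louvain modularity optimization at the given resolution.
#' High resolutions deliberately over-cluster so that each cluster is
#' small and pure.
#'
#' @param scores a \code{CellTypeScoreMatrix}.
#' @param resolution Louvain resolution.
#' @param k neighborhood size (needs \code{n_cells > k}).
#' @param seed integer seed (Louvain vertex order is randomized).
#' @return integer vector of cluster ids.
#' @export
overcluster <- function(scores, resolution, k, seed = 0) {
  m <- scores$scores
  n <- nrow(m)
  if (n <= k) stop(sprintf("need more than k = %d cells, have %d", k, n))
  nn <- .cosine_knn(m, k)
  from <- rep(seq_len(n), each = k)
  g <- igraph::graph_from_edgelist(cbind(from, as.vector(t(nn$idx))),
                                   directed = FALSE)
  igraph::E(g)$weight <- pmax(as.vector(t(nn$sim)), 0)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  as.integer(igraph::membership(cl))
}

# k nearest neighbors under cosine distance, self excluded, ties by index;
# zero rows have similarity 0 to everything.
.cosine_knn <- function(m, k, block = 1024L) {
  n <- nrow(m)
  norms <- sqrt(rowSums(m^2))
  u <- m / ifelse(norms > 0, norms, 1)
  idx <- matrix(0L, n, k)
  sim <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    s <- u[rows, , drop = FALSE] %*% t(u)
    for (r in seq_along(rows)) {
      i <- rows[r]
      si <- s[r, ]
      si[i] <- -Inf
      ord <- order(-si, seq_len(n))[seq_len(k)]
      idx[i, ] <- ord
      sim[i, ] <- si[ord]
    }
  }
  list(idx = idx, sim = sim)
}

#' Map cluster ids to cell-type labels
#'
#' Each cluster is assigned the modal per-cell label among its members
#' (\code{"unassigned"} is excluded from the vote unless the cluster is
#' unanimously unassigned); modal ties are broken by the higher mean score
#' of the tied types within the cluster, then lexicographically. All cells
#' of a cluster receive its label.
#'
#' @param clusters integer cluster ids per cell.
#' @param label1 per-cell labels from \code{\link{per_cell_labels}}.
#' @param scores the \code{CellTypeScoreMatrix} the labels came from.
#' @return character vector of mapped per-cell labels.
#' @export
map_clusters_to_types <- function(clusters, label1, scores) {
  stopifnot(length(clusters) == length(label1),
            length(label1) == nrow(scores$scores))
  m <- scores$scores
  out <- character(length(label1))
  for (cl in unique(clusters)) {
    members <- which(clusters == cl)
    votes <- label1[members]
    votes <- votes[votes != "unassigned"]
    if (!length(votes)) {
      out[members] <- "unassigned"
      next
    }
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      mean_sc <- colMeans(m[members, top, drop = FALSE])
      top <- top[order(-mean_sc, top)][1L]
    }
    out[members] <- top
  }
  out
}

#' Consensus annotation across the over-clustering grid
#'
#' Runs \code{\link{overcluster}} for every (resolution, neighborhood
#' size) pair, maps each partition to cell-type labels through
#' \code{\link{map_clusters_to_types}}, and takes the per-cell majority
#' across the grid as the final label. Majority ties are broken by the
#' cell's own score of the tied types, then lexicographically
#' (\code{"unassigned"} loses any tie against a real type).
#'
#' @param scores a \code{CellTypeScoreMatrix}.
#' @param config a \code{ConsensusConfig}.
#' @return an \code{AnnotationResult} with \code{member_labelings} (one
#'   column per grid run).
#' @export
consensus_annotate <- function(scores, config = ConsensusConfig()) {
  stopifnot(inherits(config, "ConsensusConfig"))
  label1 <- per_cell_labels(scores, tie_break = config$tie_break)
  grid <- expand.grid(k = config$neighbor_sizes,
                      resolution = config$resolutions,
                      KEEP.OUT.ATTRS = FALSE)
  members <- matrix(NA_character_, nrow(scores$scores), nrow(grid))
  colnames(members) <- sprintf("res%g_k%d", grid$resolution, grid$k)
  for (j in seq_len(nrow(grid))) {
    cl <- overcluster(scores, resolution = grid$resolution[j],
                      k = grid$k[j], seed = config$seed + 1000L * (j - 1L))
    members[, j] <- map_clusters_to_types(cl, label1, scores)
  }
  final <- .majority_vote(members, scores$scores)
  AnnotationResult(cell_ids = rownames(scores$scores), label = final,
                   member_labelings = members)
}

.majority_vote <- function(members, m) {
  apply_row <- function(i) {
    tab <- table(members[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    sc <- ifelse(top %in% colnames(m), m[i, ][match(top, colnames(m))], -Inf)
    top[order(-sc, top)][1L]
  }
  vapply(seq_len(nrow(members)), apply_row, character(1))
}

#' Chunked consensus annotation
#'
#' Splits cells into contiguous index chunks and runs
#' \code{\link{consensus_annotate}} on each chunk independently (the
#' parallelization contract of the method: no cross-chunk graph). With
#' \code{n_chunks = 1} the result is bit-identical to the unchunked path.
#' Deterministic given (config seed, n_chunks).
#'
#' @param scores a \code{CellTypeScoreMatrix}.
#' @param config a \code{ConsensusConfig}.
#' @param n_chunks number of contiguous chunks (default from config).
#' @return an \code{AnnotationResult}.
#' @export
annotate_parallel <- function(scores, config = ConsensusConfig(),
                              n_chunks = config$n_chunks) {
  stopifnot(n_chunks >= 1)
  n <- nrow(scores$scores)
  chunk_id <- rep(seq_len(n_chunks),
                  times = diff(floor(seq(0, n, length.out = n_chunks + 1))))
  min_size <- min(tabulate(chunk_id, n_chunks))
  if (min_size <= max(config$neighbor_sizes)) {
    stop(sprintf("chunk of %d cells is too small for neighbor size %d",
                 min_size, max(config$neighbor_sizes)))
  }
  parts <- lapply(seq_len(n_chunks), function(ch) {
    idx <- which(chunk_id == ch)
    sub <- CellTypeScoreMatrix(scores$scores[idx, , drop = FALSE],
                               variant = scores$variant)
    consensus_annotate(sub, config)
  })
  AnnotationResult(
    cell_ids = unlist(lapply(parts, `[[`, "cell_ids")),
    label = unlist(lapply(parts, `[[`, "label")),
    member_labelings = do.call(rbind, lapply(parts, `[[`, "member_labelings")))
}

#' Certainty score against reference centroids
#'
#' For each query cell, Euclidean distances in score space to the mean
#' score vector (centroid) of every reference cell type are computed; the
#' certainty is C = 1 - D_1st / D_Nth where D_1st is the distance to the
#' closest centroid and D_Nth to the farthest. C is near 1 for cells
#' sitting on a centroid and near 0 for cells equidistant from all
#' centroids — the signature of a cell type the reference has never seen.
#' A cell coinciding with all centroids (D_Nth = 0) gets C = 1.
#'
#' @param query_scores \code{CellTypeScoreMatrix} for the query cells.
#' @param reference_scores \code{CellTypeScoreMatrix} for the reference
#'   cells (same type columns).
#' @param reference_labels per-cell labels of the reference (>= 2 distinct).
#' @return list with per-query-cell \code{certainty}, \code{d_first},
#'   \code{d_last}.
#' @export
compute_certainty <- function(query_scores, reference_scores,
                              reference_labels) {
  stopifnot(inherits(query_scores, "CellTypeScoreMatrix"),
            inherits(reference_scores, "CellTypeScoreMatrix"),
            length(reference_labels) == nrow(reference_scores$scores))
  labs <- unique(reference_labels)
  if (length(labs) < 2) {
    stop("certainty needs >= 2 distinct reference labels")
  }
  if (!identical(colnames(query_scores$scores),
                 colnames(reference_scores$scores))) {
    stop("query and reference score matrices must share type columns")
  }
  cent <- t(vapply(labs, function(l) {
    colMeans(reference_scores$scores[reference_labels == l, , drop = FALSE])
  }, numeric(ncol(reference_scores$scores))))
  q <- query_scores$scores
  # squared Euclidean distances via the expansion ||q||^2 - 2 q.c + ||c||^2
  d2 <- outer(rowSums(q^2), rep(1, nrow(cent))) -
    2 * q %*% t(cent) + outer(rep(1, nrow(q)), rowSums(cent^2))
  d <- sqrt(pmax(d2, 0))
  d_first <- apply(d, 1L, min)
  d_last <- apply(d, 1L, max)
  certainty <- ifelse(d_last > 0, 1 - d_first / d_last, 1)
  list(certainty = unname(certainty), d_first = unname(d_first),
       d_last = unname(d_last))
}

#' Flag low-certainty cells as unassigned
#'
#' Relabels cells whose certainty falls below the threshold as
#' \code{"unassigned"}; others are unchanged. Thresholds between 0.5 and
#' 0.6 work well for retrieving cell types absent from the reference.
#'
#' @param result an \code{AnnotationResult} with certainty present.
#' @param threshold certainty cutoff in [0, 1] (default 0.55).
#' @return the modified \code{AnnotationResult}.
#' @export
apply_unassigned <- function(result, threshold = 0.55) {
  stopifnot(inherits(result, "AnnotationResult"))
  if (is.null(result$certainty)) stop("result has no certainty scores")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  result$label[result$certainty < threshold] <- "unassigned"
  result
}
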