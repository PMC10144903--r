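#' Configuration for the multi-batch count simulator
#'
#' Defines the generative model used throughout the test-bench: gene-wise
#' negative-binomial counts with cell-type-exclusive planted markers and
#' multiplicative per-batch gene effects. Counts for cell c, gene g are
#' drawn as NB(mean = libsize(c) * batch_factor(batch(c), g) * base_mean(g)
#' * fold(g, type(c)), shape = dispersion), where fold is
#' \code{marker_fold} when g is a planted marker of c's type and 1
#' otherwise. Batch factors are log-normal with SD \code{batch_sigma} on
#' the log scale, so \code{batch_sigma = 0} means no batch effect.
#'
#' Defaults describe a moderate-size benchmark: 6 cell types across 3
#' batches with 100 cells per type per batch (300 cells per type), 2000
#' genes, 15 exclusive markers per type at fold 4, log-normal batch effects
#' with sigma 0.5.
#'
#' @param n_types number of cell types.
#' @param n_batches number of batches.
#' @param cells_per_type_per_batch cells drawn for every (type, batch) pair.
#' @param n_genes total genes.
#' @param markers_per_type planted exclusive markers per type.
#' @param marker_fold multiplicative expression boost of a marker in its
#'   own type (> 1).
#' @param batch_sigma SD of the per-batch per-gene log-normal factor (>= 0).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene baseline mean expression.
#' @param libsize_log_sd SD of the per-cell log-normal library-size factor.
#' @param dispersion negative-binomial shape theta (> 0); variance is
#'   mean + mean^2 / theta.
#' @param holdout_types type names to exclude from the reference split
#'   (used by \code{\link{split_reference_query}}).
#' @param hierarchy optional list \code{(n_subtypes_per_type,
#'   sub_markers_per_subtype)}; subtypes inherit the parent's markers and
#'   add exclusive markers at fold \code{sqrt(marker_fold)}.
#' @param seed integer seed; the only source of randomness.
#' @return a \code{SimulationConfig} list.
#' @export
SimulationConfig <- function(n_types = 6, n_batches = 3,
                             cells_per_type_per_batch = 100,
                             n_genes = 2000, markers_per_type = 15,
                             marker_fold = 4, batch_sigma = 0.5,
                             baseline_log_mean = -0.5, baseline_log_sd = 1,
                             libsize_log_sd = 0.3, dispersion = 5,
                             holdout_types = character(),
                             hierarchy = NULL, seed = 0) {
  cfg <- list(n_types = n_types, n_batches = n_batches,
              cells_per_type_per_batch = cells_per_type_per_batch,
              n_genes = n_genes, markers_per_type = markers_per_type,
              marker_fold = marker_fold, batch_sigma = batch_sigma,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              libsize_log_sd = libsize_log_sd, dispersion = dispersion,
              holdout_types = holdout_types, hierarchy = hierarchy,
              seed = seed)
  stopifnot(n_types >= 1, n_batches >= 1, cells_per_type_per_batch >= 1,
            marker_fold > 1, batch_sigma >= 0, dispersion > 0)
  n_marker_genes <- markers_per_type * n_types
  if (!is.null(hierarchy)) {
    n_marker_genes <- n_marker_genes +
      hierarchy$n_subtypes_per_type * n_types * hierarchy$sub_markers_per_subtype
  }
  if (n_marker_genes > n_genes) {
    stop(sprintf("marker sets need %d genes but n_genes = %d",
                 n_marker_genes, n_genes))
  }
  structure(cfg, class = "SimulationConfig")
}

#' Simulate multi-batch single-cell counts with planted markers
#'
#' Draws counts under the generative model described in
#' \code{\link{SimulationConfig}} and returns them together with the
#' ground-truth marker table. Marker sets are disjoint across types; within
#' a type, all planted markers share the configured fold, so the planted
#' ranking falls back to gene index (the documented tie-break).
#'
#' @param config a \code{SimulationConfig}.
#' @return a list with elements:
#'   \item{data}{\code{ExpressionMatrix} (counts) with \code{batch} and
#'     \code{label}; in hierarchy mode the label is the subtype.}
#'   \item{markers}{\code{MarkerTable} of planted type-level markers.}
#'   \item{markers_low}{(hierarchy mode only) subtype-level
#'     \code{MarkerTable}: parent markers followed by the subtype's own.}
#'   \item{label_high}{(hierarchy mode only) per-cell parent-type label.}
#' @export
simulate_multibatch <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  G <- config$n_genes
  types <- sprintf("T%d", seq_len(config$n_types))
  batches <- sprintf("B%d", seq_len(config$n_batches))
  genes <- sprintf("g%04d", seq_len(G))

  # disjoint marker blocks over a random gene permutation
  perm <- sample.int(G)
  k <- config$markers_per_type
  marker_idx <- lapply(seq_along(types), function(t) {
    sort(perm[((t - 1) * k + 1):(t * k)])
  })
  names(marker_idx) <- types
  used <- (config$n_types * k)

  hier <- config$hierarchy
  sub_idx <- NULL
  subtypes_of <- NULL
  if (!is.null(hier)) {
    ns <- hier$n_subtypes_per_type
    ks <- hier$sub_markers_per_subtype
    subtypes_of <- lapply(types, function(t) {
      sprintf("%s.s%d", t, seq_len(ns))
    })
    names(subtypes_of) <- types
    sub_idx <- list()
    for (t in seq_along(types)) {
      for (s in seq_len(ns)) {
        sub_idx[[subtypes_of[[t]][s]]] <-
          sort(perm[(used + 1):(used + ks)])
        used <- used + ks
      }
    }
  }

  base_mean <- exp(stats::rnorm(G, config$baseline_log_mean,
                                config$baseline_log_sd))
  batch_factor <- matrix(1, config$n_batches, G)
  if (config$batch_sigma > 0) {
    batch_factor[] <- exp(stats::rnorm(config$n_batches * G, 0,
                                       config$batch_sigma))
  }

  cpb <- config$cells_per_type_per_batch
  cell_type <- rep(types, each = config$n_batches * cpb)
  cell_batch <- rep(rep(batches, each = cpb), times = config$n_types)
  n_cells <- length(cell_type)
  cell_sub <- NULL
  if (!is.null(hier)) {
    ns <- hier$n_subtypes_per_type
    # cycle subtypes within each (type, batch) block
    cell_sub <- unlist(lapply(seq_len(config$n_types), function(t) {
      rep(subtypes_of[[t]], length.out = config$n_batches * cpb)
    }))
  }
  libsize <- exp(stats::rnorm(n_cells, 0, config$libsize_log_sd))

  sub_fold <- if (is.null(hier)) 1 else sqrt(config$marker_fold)
  counts <- matrix(0L, n_cells, G)
  bi <- match(cell_batch, batches)
  for (c in seq_len(n_cells)) {
    mu <- libsize[c] * batch_factor[bi[c], ] * base_mean
    mk <- marker_idx[[cell_type[c]]]
    mu[mk] <- mu[mk] * config$marker_fold
    if (!is.null(hier)) {
      sk <- sub_idx[[cell_sub[c]]]
      mu[sk] <- mu[sk] * sub_fold
    }
    counts[c, ] <- stats::rnbinom(G, size = config$dispersion, mu = mu)
  }
  rownames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  colnames(counts) <- genes

  data <- ExpressionMatrix(counts, layer = "counts", batch = cell_batch,
                           label = if (is.null(hier)) cell_type else cell_sub)
  markers <- MarkerTable(lapply(marker_idx, function(ix) genes[ix]))
  out <- list(data = data, markers = markers)
  if (!is.null(hier)) {
    low <- list()
    for (t in types) {
      for (s in subtypes_of[[t]]) {
        low[[s]] <- c(genes[marker_idx[[t]]], genes[sub_idx[[s]]])
      }
    }
    out$markers_low <- MarkerTable(low)
    out$label_high <- cell_type
  }
  out
}

#' Split simulated data into reference and query
#'
#' Cells of \code{holdout_types} go entirely to the query (these types are
#' "unseen" by the reference); remaining cells are split stratified by
#' (label, batch), with \code{fraction} of each stratum in the reference.
#' Both halves keep truth labels and batch.
#'
#' @param data an \code{ExpressionMatrix} with \code{label} (and optionally
#'   \code{batch}).
#' @param holdout_types character vector of labels excluded from the
#'   reference.
#' @param fraction fraction of non-holdout cells assigned to the reference
#'   (0 < fraction < 1, or 1 only when holdout is empty is an error since
#'   the query would be empty).
#' @param seed integer seed for the stratified draw.
#' @return list with \code{reference} and \code{query} ExpressionMatrix.
#' @export
split_reference_query <- function(data, holdout_types = character(),
                                  fraction = 0.5, seed = 0) {
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (is.null(data$label)) stop("data has no labels to stratify on")
  missing <- setdiff(holdout_types, unique(data$label))
  if (length(missing)) {
    stop("holdout type(s) not present in data: ",
         paste(missing, collapse = ", "))
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  n <- nrow(data$values)
  is_holdout <- data$label %in% holdout_types
  stratum <- paste(data$label,
                   if (is.null(data$batch)) "" else data$batch)
  in_ref <- logical(n)
  for (s in unique(stratum[!is_holdout])) {
    idx <- which(stratum == s & !is_holdout)
    n_ref <- round(length(idx) * fraction)
    in_ref[sample(idx, n_ref)] <- TRUE
  }
  if (!any(in_ref)) stop("reference split is empty; increase `fraction`")
  if (!any(!in_ref)) stop("query split is empty; decrease `fraction`")
  list(reference = subset_cells(data, which(in_ref)),
       query = subset_cells(data, which(!in_ref)))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
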