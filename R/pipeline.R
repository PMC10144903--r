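#' Run configuration for the end-to-end workflow
#'
#' Bundles every stage's settings: where inputs come from (on-disk
#' reference/query expression data, or the built-in simulator), the
#' marker-identification settings, the representation pipeline, the
#' consensus annotation grid, and the certainty threshold. Unknown keys
#' in any section are rejected, and every run writes the resolved
#' configuration next to its outputs so results are reproducible.
#'
#' @param seed global integer seed; every random stage derives from it.
#' @param out_dir output directory for artifacts.
#' @param simulate \code{NULL}, or a named list of
#'   \code{\link{SimulationConfig}} arguments; when given, reference and
#'   query are produced by \code{\link{simulate_multibatch}} +
#'   \code{\link{split_reference_query}} and the \code{reference}/
#'   \code{query} sections must be absent.
#' @param split list(fraction, holdout_types) for the simulated split.
#' @param reference,query lists \code{(path, format, metadata)} locating
#'   on-disk count data (see \code{\link{read_expression}},
#'   \code{\link{read_metadata}}).
#' @param markers list: \code{scheme}, \code{n_markers}, \code{methods},
#'   \code{top_k}, \code{alpha} (see \code{\link{identify_markers}}), or
#'   \code{path} to a ready-made marker CSV (skips identification).
#' @param pipeline named list of \code{\link{PipelineConfig}} arguments.
#' @param consensus named list of \code{\link{ConsensusConfig}} arguments
#'   (its seed defaults to the global seed).
#' @param certainty_threshold unassigned cutoff in [0, 1]; \code{NULL}
#'   disables unassigned calling.
#' @return a \code{RunConfig} list.
#' @export
RunConfig <- function(seed = 0, out_dir = ".", simulate = NULL,
                      split = list(fraction = 0.5,
                                   holdout_types = character()),
                      reference = NULL, query = NULL,
                      markers = list(scheme = "rra_top20", n_markers = 20),
                      pipeline = list(), consensus = list(),
                      certainty_threshold = 0.55) {
  .check_keys(split, c("fraction", "holdout_types"), "split")
  .check_keys(markers, c("scheme", "n_markers", "methods", "top_k",
                         "alpha", "path"), "markers")
  .check_keys(pipeline, names(formals(PipelineConfig)), "pipeline")
  .check_keys(consensus, names(formals(ConsensusConfig)), "consensus")
  if (!is.null(simulate)) {
    .check_keys(simulate, names(formals(SimulationConfig)), "simulate")
    if (!is.null(reference) || !is.null(query)) {
      stop("give either `simulate` or `reference`/`query`, not both")
    }
  } else if (is.null(reference) || is.null(query)) {
    stop("without `simulate`, both `reference` and `query` are required")
  }
  for (sec in list(reference, query)) {
    if (!is.null(sec)) .check_keys(sec, c("path", "format", "metadata"),
                                   "reference/query")
  }
  structure(list(seed = seed, out_dir = out_dir, simulate = simulate,
                 split = split, reference = reference, query = query,
                 markers = markers, pipeline = pipeline,
                 consensus = consensus,
                 certainty_threshold = certainty_threshold),
            class = "RunConfig")
}

.check_keys <- function(x, allowed, section) {
  if (is.null(x)) return(invisible(TRUE))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key(s) in `%s`: %s", section,
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys are the arguments of
#'   \code{\link{RunConfig}}.
#' @return a \code{RunConfig}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, names(formals(RunConfig)), "config")
  do.call(RunConfig, raw)
}

#' Run the full workflow
#'
#' Executes the complete marker-based annotation workflow: obtain
#' reference and query counts (from disk or the simulator), log-normalize,
#' identify ranked markers from the reference, build the score-matrix
#' representation for both datasets, consensus-annotate the query, score
#' certainty against the reference centroids, flag unassigned cells, and
#' (when truth labels are available) evaluate. Artifacts written to
#' \code{out_dir}: \code{markers.csv}, \code{scores.csv} (query),
#' \code{annot.tsv}, \code{report.json}, \code{config_resolved.yaml}.
#' Rerunning with identical config and inputs reproduces identical
#' outputs.
#'
#' @param config a \code{RunConfig}.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with \code{markers}, \code{reference_scores},
#'   \code{query_scores}, \code{annotation}, \code{report}.
#' @export
run_end_to_end <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    say("simulating multi-batch counts")
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_multibatch(do.call(SimulationConfig, sim_args))
    holdout <- config$split$holdout_types
    if (is.null(holdout)) holdout <- character()
    sp <- split_reference_query(sim$data, holdout_types = holdout,
                                fraction = config$split$fraction %||% 0.5,
                                seed = config$seed)
    reference <- sp$reference
    query <- sp$query
  } else {
    read_side <- function(sec, what) {
      say("reading ", what, " data from ", sec$path)
      x <- read_expression(sec$path, format = sec$format %||% "mtx_dir")
      if (!is.null(sec$metadata)) {
        x <- attach_metadata(x, read_metadata(sec$metadata))
      }
      x
    }
    reference <- read_side(config$reference, "reference")
    query <- read_side(config$query, "query")
  }
  if (is.null(reference$label)) stop("reference data has no cell-type labels")

  ref_ln <- log_normalize(reference)
  qry_ln <- log_normalize(query)

  mk <- config$markers
  if (!is.null(mk$path)) {
    say("reading marker table from ", mk$path)
    markers <- read_marker_table(mk$path)
  } else {
    say("identifying markers from the reference (",
        mk$scheme %||% "rra_top20", ")")
    markers <- identify_markers(
      ref_ln, scheme = mk$scheme %||% "rra_top20",
      methods = mk$methods %||% c("wilcoxon", "welch_t", "log2fc"),
      n_markers = mk$n_markers %||% 20, top_k = mk$top_k %||% 20,
      alpha = mk$alpha %||% 0.05)
  }
  write_marker_table(markers, file.path(config$out_dir, "markers.csv"))

  pipe <- do.call(PipelineConfig, config$pipeline)
  say("building ", pipe$representation, " representation")
  ref_scores <- build_representation(ref_ln, markers, pipe)
  qry_scores <- build_representation(qry_ln, markers, pipe)
  if (!inherits(qry_scores, "CellTypeScoreMatrix")) {
    stop("end-to-end annotation needs a score representation; set ",
         "pipeline$representation to 'raw_score' or 'pliner_score'")
  }
  write_scores(qry_scores, file.path(config$out_dir, "scores.csv"))

  cons_args <- config$consensus
  if (is.null(cons_args$seed)) cons_args$seed <- config$seed
  cons <- do.call(ConsensusConfig, cons_args)
  say("consensus annotation (", cons$n_chunks, " chunk(s))")
  ann <- annotate_parallel(qry_scores, cons)
  cert <- compute_certainty(qry_scores, ref_scores, reference$label)
  ann$certainty <- cert$certainty
  ann$d_first <- cert$d_first
  ann$d_last <- cert$d_last
  if (!is.null(config$certainty_threshold)) {
    ann <- apply_unassigned(ann, config$certainty_threshold)
  }
  write_annotation(ann, file.path(config$out_dir, "annot.tsv"))

  report <- NULL
  if (!is.null(query$label)) {
    say("evaluating against truth labels")
    report <- MetricsReport(
      acc = overall_accuracy(ann$label, query$label),
      macro_f1 = macro_f1(ann$label, query$label),
      s_celltype = celltype_silhouette(qry_scores$scores, query$label),
      ari = ari(ann$label, query$label),
      nmi = nmi(ann$label, query$label))
    if (!is.null(query$batch) && length(unique(query$batch)) >= 2) {
      report$s_batch <- batch_entropy_mixing(
        qry_scores$scores, query$batch, seed = config$seed)
      report <- aggregate_scores(report)
    }
    rep_out <- unclass(report)
    jsonlite::write_json(rep_out[!vapply(rep_out, is.null, logical(1))],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  resolved <- unclass(config)
  resolved$pipeline <- unclass(pipe)
  resolved$consensus <- unclass(cons)
  yaml::write_yaml(resolved,
                   file.path(config$out_dir, "config_resolved.yaml"))
  invisible(list(markers = markers, reference_scores = ref_scores,
                 query_scores = qry_scores, annotation = ann,
                 report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
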