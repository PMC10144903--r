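# Shared fixtures and independent oracles. The multi-batch benchmark
# fixture is expensive, so it is built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# toy 4-cell x 3-gene log-normalized matrix with two labels
toy_lognorm <- function() {
  m <- rbind(c(5, 1, 0), c(6, 1, 1), c(1, 4, 0), c(2, 5, 2))
  dimnames(m) <- list(paste0("c", 1:4), paste0("g", 1:3))
  ExpressionMatrix(m, layer = "lognorm", label = c("A", "A", "B", "B"))
}

# the standard multi-batch benchmark: 6 types x 3 batches x 100 cells,
# 2000 genes, 15 planted markers per type at fold 4, batch sigma 0.5
bench_fixture <- function() {
  if (!is.null(.fx$bench)) return(.fx$bench)
  sim <- simulate_multibatch(SimulationConfig(seed = 7))
  sp <- split_reference_query(sim$data, fraction = 0.5, seed = 7)
  ref <- log_normalize(sp$reference)
  qry <- log_normalize(sp$query)
  markers <- identify_markers(ref, "rra_top20", n_markers = 15)
  w <- weigh_markers(markers)
  .fx$bench <- list(
    sim = sim, reference = sp$reference, query = sp$query,
    ref_ln = ref, qry_ln = qry, markers = markers,
    ref_scores = score_cells(ref, w, "pliner"),
    qry_scores = score_cells(qry, w, "pliner"))
  .fx$bench
}

# same conditions with one type held out of the reference
holdout_fixture <- function() {
  if (!is.null(.fx$holdout)) return(.fx$holdout)
  sim <- simulate_multibatch(SimulationConfig(seed = 7,
                                              holdout_types = "T3"))
  sp <- split_reference_query(sim$data, holdout_types = "T3",
                              fraction = 0.5, seed = 7)
  ref <- log_normalize(sp$reference)
  qry <- log_normalize(sp$query)
  markers <- identify_markers(ref, "rra_top20", n_markers = 15)
  w <- weigh_markers(markers)
  .fx$holdout <- list(
    reference = sp$reference, query = sp$query,
    ref_scores = score_cells(ref, w, "pliner"),
    qry_scores = score_cells(qry, w, "pliner"))
  .fx$holdout
}

# ---- independent oracles ------------------------------------------------

# order-statistic tail probability by numerical integration of the Beta
# density (never calls pbeta)
beta_tail_numint <- function(r, k, m) {
  if (r <= 0) return(0)
  stats::integrate(function(x) stats::dbeta(x, k, m - k + 1), 0, r,
                   rel.tol = 1e-10)$value
}

# brute-force consensus score: minimum over all m order statistics
rra_oracle <- function(norm_ranks) {
  m <- length(norm_ranks)
  r <- sort(norm_ranks)
  min(vapply(seq_len(m), function(k) beta_tail_numint(r[k], k, m),
             numeric(1)))
}

# Fisher's combination, written out directly
fisher_combined <- function(p) {
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# straightforward NMI from the contingency table, independent of the
# package implementation
nmi_oracle <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  if (h(pa) == 0 || h(pb) == 0) {
    return(if (identical(unname(as.integer(factor(a))),
                         unname(as.integer(factor(b))))) 1 else 0)
  }
  as.numeric(mi / sqrt(h(pa) * h(pb)))
}
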