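mk_scores <- function(m, types = LETTERS[seq_len(ncol(m))]) {
  rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  colnames(m) <- types
  CellTypeScoreMatrix(m)
}

test_that("per-cell labels are the argmax with documented edge rules", {
  sc <- mk_scores(rbind(c(0.2, 0.9, 0.1),
                        c(0.5, 0.5, 0.0),
                        c(0.0, 0.0, 0.0)))
  expect_equal(per_cell_labels(sc, "lexicographic"),
               c("B", "A", "unassigned"))
  # mean-score tie-break: B's column mean (0.467) beats A's (0.233)
  expect_equal(per_cell_labels(sc, "mean_score")[2], "B")
  # adding a constant to one cell's whole row changes nothing
  sc2 <- sc; sc2$scores[1, ] <- sc2$scores[1, ] + 5
  expect_equal(per_cell_labels(sc2, "lexicographic")[1], "B")
})

test_that("over-clustering splits separated blobs into pure clusters", {
  set.seed(2)
  blob <- function(center, n) {
    t(replicate(n, center + stats::rnorm(3, sd = 0.02)))
  }
  m <- rbind(blob(c(1, 0, 0), 60), blob(c(0, 1, 0), 60))
  truth <- rep(c("A", "B"), each = 60)
  sc <- mk_scores(abs(m))
  cl <- overcluster(sc, resolution = 3, k = 5, seed = 7)
  purity <- vapply(split(truth, cl),
                   function(v) max(table(v)) / length(v), numeric(1))
  expect_true(all(purity == 1))
  expect_gt(length(unique(cl)), 1L)

  # determinism
  expect_identical(cl, overcluster(sc, resolution = 3, k = 5, seed = 7))

  # identical rows collapse to one cluster
  same <- mk_scores(matrix(1, 8, 2))
  expect_equal(length(unique(overcluster(same, resolution = 1, k = 5,
                                         seed = 1))), 1L)
  expect_error(overcluster(same, 1, k = 9, seed = 1), "more than k")
})

test_that("cluster-to-type mapping votes by modal label with score tie-break", {
  m <- matrix(0.5, 10, 2)
  m[1:5, 1] <- 0.8    # cluster 1 cells score higher for A
  sc <- mk_scores(m)
  clusters <- rep(c(1L, 2L), each = 5)
  l1 <- c("A", "A", "A", "B", "B", rep("unassigned", 5))
  mapped <- map_clusters_to_types(clusters, l1, sc)
  expect_equal(mapped, c(rep("A", 5), rep("unassigned", 5)))

  # modal tie A/B decided by higher within-cluster mean score
  l2 <- c("A", "A", "B", "B", "unassigned", rep("B", 5))
  mapped2 <- map_clusters_to_types(clusters, l2, sc)
  expect_equal(unique(mapped2[1:5]), "A")

  # unassigned is ignored when any real vote exists
  l3 <- c("B", rep("unassigned", 4), rep("A", 5))
  expect_equal(map_clusters_to_types(clusters, l3, sc)[1], "B")
})

test_that("majority vote across member labelings breaks ties by own score", {
  m <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  sc <- mk_scores(m)
  members <- rbind(c("A", "A", "B"), c("A", "B", "unassigned"))
  out <- markerscore:::.majority_vote(members, sc$scores)
  expect_equal(out[1], "A")         # plain 2-of-3 majority
  expect_equal(out[2], "B")         # 3-way tie: cell 2 scores B highest
})

test_that("consensus annotation recovers truth and beats its members' noise", {
  fx <- bench_fixture()
  ann <- consensus_annotate(fx$qry_scores, ConsensusConfig(seed = 7))
  truth <- fx$query$label
  f1_consensus <- macro_f1(ann$label, truth)
  f1_label1 <- macro_f1(per_cell_labels(fx$qry_scores), truth)
  expect_gte(f1_consensus, f1_label1 - 0.02)
  expect_gte(f1_consensus, 0.95)
  expect_equal(dim(ann$member_labelings), c(nrow(fx$qry_scores$scores), 9L))
  # determinism of the whole grid
  ann2 <- consensus_annotate(fx$qry_scores, ConsensusConfig(seed = 7))
  expect_identical(ann$label, ann2$label)
})

test_that("chunked annotation honors its contract", {
  fx <- bench_fixture()
  cfg <- ConsensusConfig(seed = 7)
  whole <- consensus_annotate(fx$qry_scores, cfg)
  one <- annotate_parallel(fx$qry_scores, cfg, n_chunks = 1)
  expect_identical(one$label, whole$label)
  expect_identical(one$member_labelings, whole$member_labelings)

  four <- annotate_parallel(fx$qry_scores, cfg, n_chunks = 4)
  truth <- fx$query$label
  expect_lt(abs(macro_f1(four$label, truth) - macro_f1(whole$label, truth)),
            0.03)

  tiny <- CellTypeScoreMatrix(fx$qry_scores$scores[1:20, ])
  expect_error(annotate_parallel(tiny, cfg, n_chunks = 4), "too small")
})

test_that("certainty is the rescaled centroid-distance ratio", {
  ref <- mk_scores(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  labs <- c("A", "A", "B", "B")
  # query cell at centroid A: D_1st = 0 -> C = 1
  # query cell equidistant from both centroids -> C = 0
  qry <- mk_scores(rbind(c(1, 0), c(0.5, 0.5)))
  out <- compute_certainty(qry, ref, labs)
  expect_equal(out$certainty, c(1, 0))

  # worked ratio: D_1st = 2, D_Nth = 8 -> C = 0.75
  ref2 <- mk_scores(rbind(c(0, 0), c(10, 0)))
  qry2 <- mk_scores(matrix(c(2, 0), 1))
  out2 <- compute_certainty(qry2, ref2, c("A", "B"))
  expect_equal(out2$certainty, 0.75)
  expect_equal(out2$d_first, 2)
  expect_equal(out2$d_last, 8)

  # degenerate reference: all centroids coincide with the cell -> C = 1
  ref3 <- mk_scores(rbind(c(1, 1), c(1, 1)))
  out3 <- compute_certainty(mk_scores(matrix(c(1, 1), 1)), ref3, c("A", "B"))
  expect_equal(out3$certainty, 1)

  expect_error(compute_certainty(qry, ref, rep("A", 4)), ">= 2 distinct")
})

test_that("unassigned thresholding only relabels low-certainty cells", {
  ann <- AnnotationResult(paste0("c", 1:4), c("A", "B", "A", "B"),
                          certainty = c(0.9, 0.54, 0.56, 0))
  expect_equal(apply_unassigned(ann, 0)$label, ann$label)
  expect_equal(apply_unassigned(ann, 0.55)$label,
               c("A", "unassigned", "A", "unassigned"))
  expect_equal(sum(apply_unassigned(ann, 1)$label == "unassigned"), 4L)
  expect_error(apply_unassigned(ann, 1.2), "\\[0, 1\\]")
  ann$certainty <- NULL
  expect_error(apply_unassigned(ann), "certainty")
})

test_that("high-hierarchy annotation is at least as accurate as low-hierarchy", {
  sim <- simulate_multibatch(SimulationConfig(
    n_types = 3, n_batches = 2, cells_per_type_per_batch = 60,
    n_genes = 800, markers_per_type = 10,
    hierarchy = list(n_subtypes_per_type = 2, sub_markers_per_subtype = 6),
    seed = 7))
  ln <- log_normalize(sim$data)
  cfg <- ConsensusConfig(seed = 7)
  hi <- consensus_annotate(score_cells(ln, weigh_markers(sim$markers),
                                       "pliner"), cfg)
  lo <- consensus_annotate(score_cells(ln, weigh_markers(sim$markers_low),
                                       "pliner"), cfg)
  f1_hi <- macro_f1(hi$label, sim$label_high)
  f1_lo <- macro_f1(lo$label, sim$data$label)
  expect_gte(f1_hi, f1_lo)
  expect_gt(f1_hi, 0.9)
})
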