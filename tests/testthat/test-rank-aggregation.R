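test_that("consensus score matches the closed form for a doubly top-ranked gene", {
  # two lists over a 3-gene universe, gene ranked 1 in both:
  # normalized ranks (1/3, 1/3); rho = min(1 - (2/3)^2, (1/3)^2) = 1/9
  out <- aggregate_topk_rra(list(c("g1", "g2", "g3"),
                                 c("g1", "g3", "g2")),
                            top_k = 3, universe = 3)
  expect_equal(out$rho[out$gene == "g1"], 1 / 9, tolerance = 1e-12)
  expect_equal(out$gene[1], "g1")
})

test_that("single-list aggregation reduces to the normalized rank", {
  out <- aggregate_topk_rra(list(c("a", "b", "c", "d")), top_k = 4,
                            universe = 8)
  expect_equal(out$rho, (1:4) / 8)
  expect_equal(out$gene, c("a", "b", "c", "d"))
})

test_that("genes absent from every truncated list score 1 and rank last", {
  # top_k = 1 keeps only the leaders; trailing genes get r = 1 everywhere
  out <- aggregate_topk_rra(list(c("g1", "g9"), c("g1", "g8")),
                            top_k = 1, universe = 10)
  expect_equal(out$rho[out$gene %in% c("g8", "g9")], c(1, 1))
  expect_equal(out$gene[1], "g1")
  expect_true(all(out$rho > 0 & out$rho <= 1))
})

test_that("aggregation agrees with a numerical-integration order-statistic oracle", {
  set.seed(19)
  for (m in 1:3) {
    for (universe in 2:5) {
      genes <- paste0("g", seq_len(universe))
      for (rep in 1:5) {
        lists <- lapply(seq_len(m), function(i) sample(genes))
        top_k <- sample(universe, 1)
        out <- aggregate_topk_rra(lists, top_k = top_k, universe = universe)
        trunc <- lapply(lists, utils::head, top_k)
        for (g in out$gene) {
          r <- vapply(trunc, function(l) {
            pos <- match(g, l)
            if (is.na(pos)) 1 else pos / universe
          }, numeric(1))
          expect_equal(out$rho[out$gene == g], rra_oracle(r),
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("an extra list ranking a gene first never worsens its score", {
  set.seed(23)
  genes <- paste0("g", 1:10)
  for (rep in 1:20) {
    lists <- lapply(1:2, function(i) sample(genes))
    g <- sample(genes, 1)
    base <- aggregate_topk_rra(lists, top_k = 10, universe = 10)
    extra <- c(g, setdiff(sample(genes), g))
    more <- aggregate_topk_rra(c(lists, list(extra)), top_k = 10,
                               universe = 10)
    expect_lte(more$rho[more$gene == g], base$rho[base$gene == g] + 1e-12)
  }
})

test_that("Lancaster at uniform weight 2 is Fisher's method", {
  mk <- function(p, padj = p) {
    data.frame(gene = paste0("g", seq_along(p)), p_value = p,
               p_adjusted = padj)
  }
  # worked value: p = (0.05, 0.05) -> T = 11.983, combined p ~ 0.0175
  two <- aggregate_significant_lancaster(
    list(mk(c(0.05, 0.9)), mk(c(0.05, 0.9))), alpha = 0.06)
  expect_equal(two$p_combined[two$gene == "g1"],
               fisher_combined(c(0.05, 0.05)), tolerance = 1e-12)
  expect_equal(two$p_combined[two$gene == "g1"], 0.0175, tolerance = 2e-3)

  # single method: the chi-square(2) transform is its own inverse
  one <- aggregate_significant_lancaster(list(mk(c(0.01, 0.2))),
                                         alpha = 0.05)
  expect_equal(one$p_combined, 0.01, tolerance = 1e-12)
  expect_equal(nrow(one), 1L)   # the non-significant gene is excluded

  # p = 1 combines to 1
  p1 <- aggregate_significant_lancaster(list(mk(1, padj = 0.01)),
                                        alpha = 0.05)
  expect_equal(p1$p_combined, 1)

  set.seed(31)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    p <- runif(k)
    res <- lapply(p, function(pi) mk(pi, padj = 0.01))
    comb <- aggregate_significant_lancaster(res, alpha = 0.05)
    expect_equal(comb$p_combined, fisher_combined(p), tolerance = 1e-10)
  }

  expect_error(aggregate_significant_lancaster(list(mk(0.01)),
                                               weights = c(0, -1)),
               "weights")
})

test_that("marker identification recovers planted markers on the benchmark", {
  fx <- bench_fixture()
  recovery <- vapply(names(fx$markers$entries), function(ct) {
    mean(fx$sim$markers$entries[[ct]] %in% fx$markers$entries[[ct]])
  }, numeric(1))
  expect_true(all(recovery >= 0.8))
  expect_true(all(lengths(fx$markers$entries) == 15L))
})

test_that("both aggregation schemes yield overlapping marker calls", {
  fx <- bench_fixture()
  lanc <- identify_markers(fx$ref_ln, "lancaster_significant",
                           n_markers = 15)
  overlap <- vapply(names(lanc$entries), function(ct) {
    length(intersect(lanc$entries[[ct]], fx$markers$entries[[ct]])) / 15
  }, numeric(1))
  expect_gt(mean(overlap), 0.6)
})

test_that("marker identification validates its inputs", {
  x <- toy_lognorm()
  x$label <- rep("A", 4)
  expect_error(identify_markers(x), "2 distinct")
  y <- toy_lognorm()
  w <- capture_warnings(identify_markers(y, "rra_top20", n_markers = 10))
  expect_true(any(grepl("available", w)))   # one warning per short type
})

test_that("rank-discount weights hit both stated endpoints", {
  mt <- MarkerTable(list(A = paste0("g", 1:10)))
  w <- weigh_markers(mt)$entries$A
  expect_identical(w$weight[1], 1)          # rank 1: 100% of expression
  expect_identical(w$weight[10], 0.5)       # rank N: 50%
  w4 <- weigh_markers(MarkerTable(list(A = paste0("g", 1:4))))$entries$A
  expect_equal(w4$weight[2], 0.75)          # 1 - (2/4) * (1/2)

  for (n in 1:100) {
    wn <- weigh_markers(MarkerTable(list(A = paste0("g", seq_len(n)))))
    wt <- wn$entries$A$weight
    expect_equal(wt[1], 1)
    expect_equal(wt[n], if (n == 1) 1 else 0.5)
    expect_true(all(diff(wt) <= 0))
    expect_true(all(wt >= 0.5 & wt <= 1))
  }
})

test_that("alternative weighting schemes keep the same envelope", {
  mt <- MarkerTable(list(A = paste0("g", 1:7)))
  for (s in c("rank_order_centroid", "ratio")) {
    w <- weigh_markers(mt, scheme = s)$entries$A$weight
    expect_equal(w[1], 1)
    expect_equal(w[7], 0.5)
    expect_true(all(diff(w) <= 1e-12))
  }
  w1 <- weigh_markers(MarkerTable(list(A = "g1")), "rank_order_centroid")
  expect_equal(w1$entries$A$weight, 1)
})
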