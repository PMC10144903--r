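test_that("log normalization matches its closed form and identity", {
  m <- matrix(c(2, 19998, 0, 10000), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  x <- ExpressionMatrix(m, layer = "counts")
  ln <- log_normalize(x)
  # count 2 in a cell of total 20000 -> ln(1 + 2/20000 * 10000) = ln 2
  expect_equal(ln$values[1, "g1"], log(2), tolerance = 1e-12)
  expect_equal(ln$values[2, "g1"], 0)   # zero count stays zero
  # per-cell identity: sum(exp(value) - 1) = scale
  expect_equal(unname(Matrix::rowSums(exp(as.matrix(ln$values)) - 1)),
               c(10000, 10000), tolerance = 1e-9)
  expect_equal(ln$layer, "lognorm")

  bad <- ExpressionMatrix(matrix(c(1, 0, 2, 0), 2, 2,
                                 dimnames = list(c("c1", "c2"),
                                                 c("g1", "g2"))),
                          layer = "counts")
  expect_error(log_normalize(bad), "c2")
  expect_error(log_normalize(ln), "counts")
})

test_that("highly variable gene selection favors structured genes", {
  set.seed(4)
  n <- 200
  flat <- matrix(rpois(n * 30, 5), n, 30)
  bimodal <- cbind(matrix(rpois(n * 5, c(1, 9)), n, 5),
                   matrix(5L, n, 5))   # 5 variable + 5 constant genes
  m <- cbind(flat, bimodal)
  dimnames(m) <- list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:40))
  x <- log_normalize(ExpressionMatrix(m, layer = "counts"))
  sel <- highly_variable_genes(x, n_top = 10)
  expect_false(any(c("g36", "g37", "g38", "g39", "g40") %in% sel))

  # single batch: by_batch is the same selection
  x$batch <- rep("B1", n)
  expect_identical(highly_variable_genes(x, 10, by_batch = TRUE), sel)
  x$batch <- NULL
  expect_error(highly_variable_genes(x, 10, by_batch = TRUE), "batch")
  expect_error(highly_variable_genes(x, 0), "positive")
})

test_that("planted markers are enriched among top HVGs on the benchmark", {
  fx <- bench_fixture()
  sel <- highly_variable_genes(fx$qry_ln, n_top = 500)
  planted <- unlist(fx$sim$markers$entries)
  frac_markers <- mean(planted %in% sel)
  frac_background <- 500 / 2000
  expect_gt(frac_markers, 2 * frac_background)
})

test_that("pliner transform applies threshold then TF-IDF", {
  m <- matrix(c(0, 1, 2, 3), 4, 1,
              dimnames = list(paste0("c", 1:4), "g1"))
  x <- ExpressionMatrix(m, layer = "lognorm")
  out <- pliner_transform(x, "g1", percentile = 0.25)
  # threshold = 0.75 (linear interpolation), idf = ln(1 + 4/(1+3)) = ln 2
  expect_equal(out[4, "g1"], 3 * log(2), tolerance = 1e-12)
  expect_equal(out[1, "g1"], 0)
  expect_equal(as.vector(out), c(0, 1, 2, 3) * log(2), tolerance = 1e-12)

  # percentile 0: thresholding inert, pure TF-IDF scaling per gene
  m2 <- matrix(c(1, 2, 0, 4, 5, 6), 3, 2,
               dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  x2 <- ExpressionMatrix(m2, layer = "lognorm")
  out2 <- pliner_transform(x2, c("g1", "g2"), percentile = 0)
  idf <- c(log(1 + 3 / (1 + 2)), log(1 + 3 / (1 + 3)))
  expect_equal(as.matrix(out2), m2 * rep(idf, each = 3), tolerance = 1e-12)

  # all cells equal: every transformed value identical
  m3 <- matrix(2, 5, 1, dimnames = list(paste0("c", 1:5), "g1"))
  out3 <- pliner_transform(ExpressionMatrix(m3, layer = "lognorm"), "g1",
                           percentile = 0.25)
  expect_equal(length(unique(as.vector(out3))), 1L)
  expect_error(pliner_transform(x, "missing_gene", 0.25), "missing_gene")
})

test_that("cell scores are weighted marker sums", {
  m <- matrix(c(1, 2, 0.5,
                0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  x <- ExpressionMatrix(m, layer = "lognorm")
  w <- weigh_markers(MarkerTable(list(A = c("g1", "g2"), B = "g3")))
  sc <- score_cells(x, w, variant = "raw")
  # A: 1 * 1.0 + 2 * 0.5 = 2.0 ; B: 0.5 * 1.0
  expect_equal(sc$scores["c1", "A"], 2)
  expect_equal(sc$scores["c1", "B"], 0.5)
  expect_equal(unname(sc$scores["c2", ]), c(0, 0))   # all-zero cell
  expect_equal(unname(sc$coverage), c(1, 1))
})

test_that("scores are invariant to gene and cell permutations and linear in expression", {
  set.seed(8)
  m <- matrix(round(rexp(20 * 12), 3), 20, 12,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:12)))
  x <- ExpressionMatrix(m, layer = "lognorm")
  w <- weigh_markers(MarkerTable(list(A = c("g01", "g05", "g09"),
                                      B = c("g02", "g03"))))
  base <- score_cells(x, w, "raw")

  gp <- sample(ncol(m)); cp <- sample(nrow(m))
  xp <- ExpressionMatrix(m[cp, gp], layer = "lognorm")
  perm <- score_cells(xp, w, "raw")
  expect_identical(perm$scores[rownames(base$scores), ], base$scores)

  # raw score is linear: scaling one cell's row scales its scores
  m2 <- m; m2["c03", ] <- 2.5 * m2["c03", ]
  sc2 <- score_cells(ExpressionMatrix(m2, layer = "lognorm"), w, "raw")
  expect_equal(sc2$scores["c03", ], 2.5 * base$scores["c03", ],
               tolerance = 1e-12)
  expect_equal(sc2$scores["c04", ], base$scores["c04", ])
})

test_that("absent markers are dropped with coverage reported, never renormalized", {
  m <- matrix(1, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g3")))
  x <- ExpressionMatrix(m, layer = "lognorm")
  w <- weigh_markers(MarkerTable(list(A = c("g1", "g2"), B = "g9")))
  expect_error(score_cells(x, w, "raw"), "B")
  w2 <- weigh_markers(MarkerTable(list(A = c("g1", "g2"), B = "g3")))
  sc <- score_cells(x, w2, "raw")
  # only g1 (weight 1) contributes to A; g2's 0.5 mass is missing
  expect_equal(unname(sc$scores[, "A"]), rep(1, 3))
  expect_equal(unname(sc$coverage["A"]), 1 / 1.5)
})

test_that("representation builder dispatches on the pipeline config", {
  fx <- bench_fixture()
  expect_error(PipelineConfig("hvg_all", "pliner_score"), "markers")

  qry <- fx$qry_ln
  hvg <- build_representation(qry, config = PipelineConfig(
    "hvg_all", "genes", n_hvg = 100))
  expect_s3_class(hvg, "ExpressionMatrix")
  expect_equal(ncol(hvg$values), 100L)

  shared <- build_representation(qry, config = PipelineConfig(
    "hvg_by_batch", "genes", n_hvg = 400))
  expect_s3_class(shared, "ExpressionMatrix")
  expect_lte(ncol(shared$values), 400L)

  mgenes <- build_representation(qry, fx$markers, PipelineConfig(
    "markers", "genes"))
  expect_setequal(gene_ids(mgenes),
                  intersect(gene_ids(qry),
                            unique(unlist(fx$markers$entries))))

  pl <- build_representation(qry, fx$markers, PipelineConfig(
    "markers", "pliner_score"))
  expect_s3_class(pl, "CellTypeScoreMatrix")
  expect_equal(pl$variant, "pliner")
  # definitional equality with the explicit composition
  direct <- score_cells(qry, weigh_markers(fx$markers), "pliner")
  expect_identical(pl$scores, direct$scores)
})
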