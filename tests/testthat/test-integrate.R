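lin_bundle <- function(x, id = "L1") {
  series_bundle(
    series_id = id, expression = x,
    probe_map = data.frame(probe_id = rownames(x), gene_symbol = rownames(x)),
    samples = data.frame(sample_id = colnames(x), series_id = id,
                         class_label = "NSK", country = "X",
                         platform = "P", technology = "A"),
    scale = "linear16")
}

test_that("linear series are homogenized to a 16-bit log2 scale", {
  x <- matrix(c(65535, 100, 3000, 1), 2, 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  out <- ensure_log2_scale(lin_bundle(x))
  expect_identical(out$scale, "log2")
  expect_equal(max(out$expression), 16, tolerance = 1e-12)
  expect_true(all(out$expression >= 0 & out$expression <= 16))

  # 12-bit deposit: rescale by 65535/4095, then log2(v + 1)
  x12 <- matrix(c(4095, 17, 256, 0), 2, 2,
                dimnames = list(c("p1", "p2"), c("a", "b")))
  out12 <- ensure_log2_scale(lin_bundle(x12))
  expect_equal(max(out12$expression), 16, tolerance = 1e-12)
  expect_equal(out12$expression[1, 2],
               log2(256 * 65535 / 4095 + 1), tolerance = 1e-12)
})

test_that("log2-scale input is returned unchanged and the transform is idempotent", {
  sim <- generate_study(small_confounded_config(seed = 3))
  for (b in sim$bundles) {
    once <- ensure_log2_scale(b)
    twice <- ensure_log2_scale(once)
    expect_identical(once$expression, twice$expression)
    if (b$scale == "log2") expect_identical(once$expression, b$expression)
  }
  neg <- matrix(c(-1, 10, 20, 30), 2, 2,
                dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_error(lin_bundle(neg), "\\[0, 65535\\]")
})

test_that("probe summarization follows the chosen union method", {
  x <- matrix(c(2, 4, 6, 2, 4, 10, 5, 5, 5, 1, 7, 9), 4, 3, byrow = TRUE,
              dimnames = list(c("pA1", "pA2", "pA3", "pB1"),
                              c("s1", "s2", "s3")))
  # pA1..pA3 -> gene A (columns hold {2,4,6} style triples), pB1 -> gene B
  x <- rbind(x[1:3, ], x[4, , drop = FALSE])
  b <- series_bundle("S1", x,
                     probe_map = data.frame(
                       probe_id = rownames(x),
                       gene_symbol = c("A", "A", "A", "B")),
                     samples = data.frame(sample_id = colnames(x),
                                          series_id = "S1",
                                          class_label = "NSK", country = "X",
                                          platform = "P", technology = "A"),
                     scale = "log2")
  m <- summarize_probes(b, "mean")$expression
  md <- summarize_probes(b, "median")$expression
  expect_equal(unname(m["A", ]), c(mean(c(2, 2, 5)), mean(c(4, 4, 5)),
                                   mean(c(6, 10, 5))))
  expect_equal(unname(md["A", ]), c(2, 4, 6))
  # single-probe gene identical under both methods
  expect_equal(m["B", ], md["B", ])
  # genes sorted lexicographically
  expect_identical(rownames(m), c("A", "B"))

  b$probe_map <- b$probe_map[-1, ]
  expect_error(summarize_probes(b, "mean"), "pA1")
})

test_that("merging intersects gene panels and conserves samples", {
  g1 <- list(expression = matrix(1:6, 3, 2,
                                 dimnames = list(c("A", "B", "C"),
                                                 c("s1", "s2"))),
             samples = data.frame(sample_id = c("s1", "s2"),
                                  series_id = "S1", class_label = "NSK",
                                  country = "X", platform = "P",
                                  technology = "A"),
             series_id = "S1")
  g2 <- list(expression = matrix(1:6, 3, 2,
                                 dimnames = list(c("B", "C", "D"),
                                                 c("t1", "t2"))),
             samples = data.frame(sample_id = c("t1", "t2"),
                                  series_id = "S2", class_label = "NSK",
                                  country = "X", platform = "P",
                                  technology = "A"),
             series_id = "S2")
  m <- merge_series(list(g1, g2))
  expect_identical(m$gene_symbols, c("B", "C"))
  expect_identical(colnames(m$expression), c("s1", "s2", "t1", "t2"))
  expect_error(merge_series(list(g1)), ">= 2")

  g3 <- g2
  rownames(g3$expression) <- c("X", "Y", "Z")
  expect_error(merge_series(list(g1, g3)), "empty gene-symbol intersection")
})

test_that("merged gene set equals the panel intersection and shrinks monotonically", {
  sim <- generate_study(small_confounded_config(seed = 10))
  gl <- lapply(sim$bundles, function(b)
    summarize_probes(ensure_log2_scale(b), "mean"))
  panels <- lapply(gl, function(g) rownames(g$expression))
  for (k in 2:length(gl)) {
    m <- merge_series(gl[1:k])
    expect_setequal(m$gene_symbols, Reduce(intersect, panels[1:k]))
    expect_true(all(sim$truth$planted_deg_symbols %in% m$gene_symbols))
    expect_equal(ncol(m$expression),
                 sum(vapply(gl[1:k], function(g) ncol(g$expression), 0L)))
    if (k > 2) expect_lte(length(m$gene_symbols), length(prev))
    prev <- m$gene_symbols
  }
  # columns ordered by (series, sample)
  m <- merge_series(gl)
  ord <- order(m$samples$series_id, m$samples$sample_id)
  expect_identical(ord, seq_along(ord))
})

test_that("quantile normalization equalizes within-series sample distributions", {
  set.seed(17)
  x <- matrix(rnorm(200 * 8, 8, 1), 200, 8,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:8)))
  x[, 3] <- x[, 3] * 1.5 + 2
  b <- series_bundle("S1", x,
                     probe_map = data.frame(probe_id = rownames(x),
                                            gene_symbol = rownames(x)),
                     samples = data.frame(sample_id = colnames(x),
                                          series_id = "S1",
                                          class_label = "NSK", country = "X",
                                          platform = "P", technology = "A"),
                     scale = "log2")
  qn <- quantile_normalize(b)
  for (j in 2:8) {
    expect_equal(sort(qn$expression[, j]), sort(qn$expression[, 1]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  ref <- limma::normalizeQuantiles(x)
  expect_equal(unname(qn$expression), unname(ref), tolerance = 1e-8)
})

test_that("mean and median unions differ in the presence of probe offsets", {
  sim <- generate_study(small_confounded_config(seed = 2))
  b <- ensure_log2_scale(sim$bundles[[1]])
  multi <- names(which(table(b$probe_map$gene_symbol) > 2))
  expect_gt(length(multi), 0)
  m1 <- summarize_probes(b, "mean")$expression
  m2 <- summarize_probes(b, "median")$expression
  expect_gt(max(abs(m1[multi, ] - m2[multi, ])), 1e-6)
})
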