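variant <- function(expr, batch, union) {
  list(expression = expr, batch_method = batch, union_method = union)
}

test_that("LS deviation observations follow the definitional arithmetic", {
  x <- matrix(c(1, 3), 1, 2, dimnames = list("gA", c("s1", "s2")))
  ann <- data.frame(sample_id = c("s1", "s2"), class_label = "NSK",
                    country = "X")
  obs <- ls_deviation_table(list(c1 = variant(x, "MC", "mean")), ann)
  expect_equal(obs$value, c(1, 1))        # grand mean 2, deviations +-1

  same <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ann4 <- data.frame(sample_id = paste0("s", 1:4), class_label = "NSK",
                     country = "X")
  obs0 <- ls_deviation_table(list(a = variant(same, "MC", "mean"),
                                  b = variant(same, "MRS", "mean")), ann4)
  expect_true(all(obs0$value == 0))
  expect_equal(nrow(obs0), 4 * 2)         # samples x configurations
})

test_that("LS deviations are invariant to gene and sample ordering", {
  set.seed(5)
  x <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:6)))
  y <- x + rnorm(120, 0, 0.1)
  ann <- data.frame(sample_id = colnames(x),
                    class_label = rep(c("NSK", "BCC"), 3),
                    country = rep(c("U", "V"), each = 3))
  o1 <- ls_deviation_table(list(a = variant(x, "QD", "mean"),
                                b = variant(y, "MRS", "mean")), ann)
  gp <- sample(20); sp <- sample(6)
  o2 <- ls_deviation_table(list(a = variant(x[gp, sp], "QD", "mean"),
                                b = variant(y[gp, sp], "MRS", "mean")), ann)
  k1 <- o1[order(o1$configuration, o1$sample_id), ]
  k2 <- o2[order(o2$configuration, o2$sample_id), ]
  expect_equal(k1$value, k2$value, tolerance = 1e-12)

  y2 <- y[, c(2:6, 1)]
  expect_error(
    ls_deviation_table(list(a = variant(x, "A", "m"),
                            b = variant(y2, "B", "m")), ann),
    "share gene list and samples")
})

test_that("one-factor two-level ANOVA reduces to the pooled t-test", {
  set.seed(9)
  df <- data.frame(value = c(rnorm(12, 0), rnorm(15, 0.8)),
                   TYPE = rep(c("a", "b"), c(12, 15)))
  res <- anova_main_effects(df, factors = "TYPE")
  tt <- t.test(value ~ TYPE, data = df, var.equal = TRUE)
  Frow <- res[res$source == "TYPE", ]
  expect_equal(Frow$F_ratio, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(Frow$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(Frow$df, 1)
})

test_that("Type III sums of squares match a projection oracle and the reference implementation", {
  set.seed(10)
  # unbalanced two-factor layout
  df <- data.frame(
    A = sample(c("a1", "a2", "a3"), 60, TRUE,
               prob = c(0.5, 0.3, 0.2)),
    B = sample(c("b1", "b2"), 60, TRUE, prob = c(0.6, 0.4)))
  df$value <- rnorm(60) + 0.5 * (df$A == "a2") + 1 * (df$B == "b2")
  res <- anova_main_effects(df, factors = c("A", "B"))

  # projection oracle: residual SS of explicitly built design matrices
  old_opt <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opt), add = TRUE)
  df$A <- factor(df$A); df$B <- factor(df$B)
  proj_rss <- function(form) {
    X <- model.matrix(form, data = df)
    sum(qr.resid(qr(X), df$value)^2)
  }
  full <- proj_rss(~ A + B)
  expect_equal(res[res$source == "A", "sum_sq"], proj_rss(~ B) - full,
               tolerance = 1e-10)
  expect_equal(res[res$source == "B", "sum_sq"], proj_rss(~ A) - full,
               tolerance = 1e-10)

  ref <- car::Anova(lm(value ~ A + B, data = df), type = 3)
  expect_equal(res[res$source == "A", "sum_sq"], ref["A", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(res[res$source == "B", "sum_sq"], ref["B", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(res[res$source == "A", "p_value"], ref["A", "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("balanced designs decompose exactly and aliased factors are refused", {
  set.seed(11)
  df <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                    rep = 1:5, stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df)) + (df$A == "a2") * 0.7
  res <- anova_main_effects(df, factors = c("A", "B"))
  ss <- res$sum_sq
  expect_equal(sum(ss[res$source %in% c("A", "B", "RESIDUAL")]),
               ss[res$source == "TOTAL (CORRECTED)"], tolerance = 1e-8)
  expect_equal(res$df[res$source == "RESIDUAL"],
               nrow(df) - 1 - 1 - 2)

  df$C <- ifelse(df$A == "a1", "c1", "c2")   # aliased with A
  expect_error(anova_main_effects(df, factors = c("A", "C")), "aliased")
})

test_that("Ward merge heights match a brute-force Lance-Williams recursion", {
  set.seed(12)
  x <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  hc <- ward_cluster(x, rep(c("NSK", "BCC"), 2),
                     samples_per_class = 2)$hclust

  # brute force: Lance-Williams update on squared distances (Ward)
  n <- 4
  d2 <- as.matrix(dist(t(x)))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  D <- d2
  repeat {
    m <- length(active)
    if (m == 1) break
    best <- c(NA, NA); bv <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < bv) { bv <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bv))
    ni <- sizes[i]; nj <- sizes[j]
    newD <- numeric(m)
    for (k in seq_len(m)) {
      if (k %in% best) next
      nk <- sizes[k]
      newD[k] <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] -
                    nk * D[i, j]) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), best)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], list(unlist(active[best])))
  }
  expect_equal(hc$height, heights, tolerance = 1e-10)
  expect_true(all(diff(hc$height) >= -1e-12))   # monotone linkage
})

test_that("well-separated class blobs form contiguous leaf blocks", {
  set.seed(13)
  g <- 20
  xa <- matrix(rnorm(g * 5, 0, 0.3), g, 5)
  xb <- matrix(rnorm(g * 5, 6, 0.3), g, 5)
  x <- cbind(xa, xb)
  dimnames(x) <- list(sprintf("g%02d", 1:g), sprintf("s%02d", 1:10))
  cl <- rep(c("NSK", "MCC"), each = 5)
  wc <- ward_cluster(x, cl, samples_per_class = 5)
  ord_classes <- cl[match(wc$leaf_order, colnames(x))]
  expect_equal(length(rle(ord_classes)$lengths), 2)  # one block per class
  # top merge joins the two blobs
  expect_equal(max(wc$hclust$height), tail(wc$hclust$height, 1))
})

test_that("representatives are the samples nearest their class centroid", {
  set.seed(14)
  x <- matrix(rnorm(10 * 12, 0, 1), 10, 12,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
  cl <- rep(c("NSK", "BCC"), each = 6)
  expect_warning(wc <- ward_cluster(x[, 1:8], cl[1:8],
                                    samples_per_class = 5), "only 2")
  wc5 <- ward_cluster(x, cl, samples_per_class = 5)
  expect_length(wc5$representatives, 10)
  for (k in unique(cl)) {
    idx <- which(cl == k)
    centroid <- rowMeans(x[, idx])
    d2 <- colSums((x[, idx] - centroid)^2)
    nearest <- colnames(x)[idx[order(d2)][1:5]]
    expect_setequal(intersect(wc5$representatives, colnames(x)[idx]),
                    nearest)
  }
})
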