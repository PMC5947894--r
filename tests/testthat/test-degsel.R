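sim_expr <- function(G, classes, noise = 1, seed = 1, means = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(G * length(classes), 7, 0), G, length(classes))
  if (!is.null(means)) x <- x + means[, match(classes, colnames(means))]
  x <- x + rnorm(length(x), 0, noise)
  dimnames(x) <- list(sprintf("g%04d", seq_len(G)),
                      sprintf("s%03d", seq_along(classes)))
  x
}

test_that("seven observed classes yield exactly 21 pairwise contrasts", {
  classes <- rep(skin_states(), each = 3)
  ct <- fit_moderated_contrasts(sim_expr(40, classes, seed = 2), classes,
                                compute_b = FALSE)
  expect_equal(ncol(ct$lfc), 21)
  expect_equal(nrow(ct$contrasts), choose(7, 2))
  # contrast labels honor the canonical state order
  expect_identical(ct$contrasts$name[1], "BCC_vs_SCC")
})

test_that("identical gene variances collapse moderation to the ordinary t", {
  classes <- rep(c("A", "B"), each = 6)
  set.seed(3)
  G <- 30
  x <- sim_expr(G, classes, noise = 1, seed = 3)
  # rescale every gene's residuals to a common residual variance
  for (g in seq_len(G)) {
    for (k in c("A", "B")) {
      idx <- classes == k
      r <- x[g, idx] - mean(x[g, idx])
      x[g, idx] <- mean(x[g, idx]) + r / sqrt(sum(r^2))
    }
  }
  ct <- fit_moderated_contrasts(x, classes, compute_b = FALSE)
  expect_true(is.infinite(ct$moderation$d0))
  expect_equal(ct$moderation$s_tilde_sq, ct$moderation$s2, tolerance = 1e-12)
  ordinary <- apply(x, 1, function(v)
    stats::t.test(v[classes == "A"], v[classes == "B"],
                  var.equal = TRUE)$statistic)
  expect_equal(unname(ct$t[, 1]), unname(ordinary), tolerance = 1e-9)
})

test_that("moderated statistics match the brute-force empirical-Bayes oracle", {
  for (seed in c(11, 12)) {
    classes <- rep(c("A", "B"), times = c(7, 9))
    set.seed(seed)
    G <- 50
    v <- 2 * 4 / rchisq(G, 4)   # heterogeneous true variances
    x <- matrix(rnorm(G * length(classes), 0, sqrt(v)), G,
                length(classes),
                dimnames = list(sprintf("g%04d", 1:G), NULL))
    x[1:5, classes == "A"] <- x[1:5, classes == "A"] + 3
    ct <- fit_moderated_contrasts(x, classes, compute_b = FALSE)
    orc <- moderated_oracle(x, classes)
    expect_equal(ct$moderation$d0, orc$d0, tolerance = 1e-6)
    expect_equal(ct$moderation$s0_sq, orc$s0, tolerance = 1e-8)
    expect_equal(unname(ct$t[, 1]), unname(orc$t[, 1]), tolerance = 1e-8)
    expect_equal(unname(ct$p[, 1]), unname(orc$p[, 1]), tolerance = 1e-8)
    # and with the reference EB variance-shrinkage implementation
    sv <- limma::squeezeVar(ct$moderation$s2, df = ct$moderation$df_resid)
    expect_equal(sv$df.prior, ct$moderation$d0, tolerance = 1e-6)
    expect_equal(unname(sv$var.post), unname(ct$moderation$s_tilde_sq),
                 tolerance = 1e-8)
  }
})

test_that("prior hyperparameters are recovered from scaled-F variance draws", {
  set.seed(21)
  G <- 5000; d0 <- 4; s02 <- 2
  classes <- rep(c("A", "B", "C"), each = 8)
  v <- s02 * d0 / rchisq(G, d0)
  x <- matrix(rnorm(G * length(classes), 0, sqrt(v)), G, length(classes),
              dimnames = list(sprintf("g%05d", 1:G), NULL))
  ct <- fit_moderated_contrasts(x, classes, compute_b = FALSE)
  expect_lt(abs(ct$moderation$d0 - d0) / d0, 0.15)
  expect_lt(abs(ct$moderation$s0_sq - s02) / s02, 0.10)
  # moderation bracketing
  lo <- pmin(ct$moderation$s2, ct$moderation$s0_sq)
  hi <- pmax(ct$moderation$s2, ct$moderation$s0_sq)
  expect_true(all(ct$moderation$s_tilde_sq >= lo - 1e-12 &
                    ct$moderation$s_tilde_sq <= hi + 1e-12))
})

test_that("contrast statistics are antisymmetric and BH-adjusted within contrast", {
  classes <- rep(c("ALPHA", "BETA", "GAMMA"), each = 5)
  x <- sim_expr(40, classes, seed = 6)
  ct <- fit_moderated_contrasts(x, classes, compute_b = FALSE)
  rev_map <- c(ALPHA = "Q3", BETA = "Q2", GAMMA = "Q1")
  ct_rev <- fit_moderated_contrasts(x, rev_map[classes], compute_b = FALSE)
  # relabeling reverses each pair's orientation
  expect_equal(unname(ct$lfc[, "ALPHA_vs_BETA"]),
               -unname(ct_rev$lfc[, "Q2_vs_Q3"]), tolerance = 1e-12)
  expect_equal(unname(ct$t[, "ALPHA_vs_GAMMA"]),
               -unname(ct_rev$t[, "Q1_vs_Q3"]), tolerance = 1e-12)
  expect_equal(unname(ct$p[, "BETA_vs_GAMMA"]),
               unname(ct_rev$p[, "Q1_vs_Q2"]), tolerance = 1e-12)
  expect_equal(unname(ct$p_adj[, 1]),
               unname(p.adjust(ct$p[, 1], "BH")), tolerance = 1e-12)
  expect_true(all(ct$p_adj >= ct$p - 1e-15))
})

test_that("classes with fewer than two samples are dropped with a warning", {
  classes <- c(rep("A", 4), rep("B", 4), "C")
  x <- sim_expr(20, classes, seed = 7)
  expect_warning(ct <- fit_moderated_contrasts(x, classes,
                                               compute_b = FALSE), "C")
  expect_equal(ncol(ct$lfc), 1)
})

test_that("DEG selection applies both thresholds and counts cases", {
  lfc <- matrix(c(4.5, 3.9, 0.2, 5.0, 1.0, 4.2), 3, 2,
                dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  p <- matrix(c(1e-5, 1e-20, 0.5, 1e-4, 0.2, 0.1), 3, 2,
              dimnames = dimnames(lfc))
  tab <- structure(list(lfc = lfc, t = lfc, p = p, p_adj = p, b = NULL,
                        contrasts = data.frame(a = c("X", "X"),
                                               b = c("Y", "Z"),
                                               name = c("c1", "c2"))),
                   class = "contrast_table")
  sel <- select_degs(tab)
  expect_setequal(sel$degs, c("gA"))
  expect_equal(unname(sel$case_counts), c(2, 0, 0))
  # |LFC| passing but p failing (gC c2) and p passing but LFC failing (gB c1)
  expect_false("gB" %in% sel$degs)
  expect_false("gC" %in% sel$degs)
  expect_error(select_degs(tab, lfc_min = 0), "> 0")
})

test_that("tightening thresholds never enlarges the DEG set", {
  classes <- rep(skin_states(), each = 4)
  means <- matrix(rnorm(30 * 7, 0, 2), 30, 7,
                  dimnames = list(NULL, skin_states()))
  x <- sim_expr(30, classes, seed = 8, means = means)
  ct <- fit_moderated_contrasts(x, classes, compute_b = FALSE)
  loose <- select_degs(ct, lfc_min = 1, p_max = 0.05)
  for (lf in c(1.5, 2, 3)) {
    for (pm in c(0.01, 0.001)) {
      tight <- select_degs(ct, lfc_min = lf, p_max = pm)
      expect_true(all(tight$degs %in% loose$degs))
      expect_true(all(tight$case_counts <= loose$case_counts))
    }
  }
})

test_that("the configuration grid enumerates all cells deterministically", {
  sim <- generate_study(small_confounded_config(seed = 3))
  g1 <- run_configuration_grid(sim$bundles, keep_matrices = FALSE)
  expect_equal(length(g1$counts), 12)
  expect_identical(rownames(g1$counts), batch_methods())
  expect_identical(colnames(g1$counts), c("mean", "median"))
  expect_length(g1$errors, 0)
  expect_true(all(g1$counts["NORDI", ] == 0))
  g2 <- run_configuration_grid(sim$bundles, keep_matrices = FALSE)
  expect_identical(g1$counts, g2$counts)
  expect_identical(lapply(g1$configs, function(cf) cf$selection$degs),
                   lapply(g2$configs, function(cf) cf$selection$degs))
})

test_that("intersection skips empty configurations and reports status", {
  expect_identical(
    intersect_configurations(list(a = c("A", "B"), b = c("B", "C")))$genes,
    "B")
  r <- intersect_configurations(list(a = c("A", "B"), b = character(0),
                                     c = "B"))
  expect_identical(r$genes, "B")
  expect_identical(r$empty, "b")
  expect_setequal(r$contributing, c("a", "c"))
  r0 <- intersect_configurations(list(a = character(0), b = character(0)))
  expect_identical(r0$status, "all_empty")
  expect_length(r0$genes, 0)
  # intersection is contained in every contributing set
  sets <- list(x = c("A", "B", "C"), y = c("B", "C"), z = c("C", "B", "D"))
  ri <- intersect_configurations(sets)
  for (s in sets) expect_true(all(ri$genes %in% s))
})

test_that("DEG summaries aggregate significant contrasts and sort by mean |LFC|", {
  lfc <- matrix(c(4, 6, 5.5, 0.3, 4.4, 0.1), 2, 3, byrow = TRUE,
                dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  p <- matrix(c(1e-6, 1e-8, 1e-7, 0.9, 1e-9, 0.9), 2, 3, byrow = TRUE,
              dimnames = dimnames(lfc))
  tab <- structure(list(lfc = lfc, t = lfc * 2, p = p, p_adj = p, b = NULL),
                   class = "contrast_table")
  sel <- select_degs(tab, lfc_min = 4, p_max = 0.001)
  s <- summarize_degs(sel, tab)
  expect_identical(s$gene, c("gA", "gB"))           # 5.17 > 4.4
  gA <- s[s$gene == "gA", ]
  expect_equal(gA$n_cases, 3)
  expect_equal(gA$mu_lfc, mean(c(4, 6, 5.5)))
  gB <- s[s$gene == "gB", ]
  expect_equal(gB$n_cases, 1)
  expect_equal(gB$sd_lfc, 0)                        # single significant case
  # hand check of the sample-SD convention on a two-case gene
  lfc2 <- matrix(c(4, 6), 1, 2, dimnames = list("gX", c("c1", "c2")))
  p2 <- matrix(c(1e-6, 1e-6), 1, 2, dimnames = dimnames(lfc2))
  tab2 <- structure(list(lfc = lfc2, t = lfc2, p = p2, p_adj = p2, b = NULL),
                    class = "contrast_table")
  s2 <- summarize_degs(select_degs(tab2), tab2)
  expect_equal(s2$mu_lfc, 5)
  expect_equal(s2$sd_lfc, sqrt(2))
  expect_true(all(diff(s$mu_lfc) <= 0))
})
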