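# Shared fixtures: small synthetic studies and hand-rolled oracles.

# balanced (orthogonal) design: all 7 classes in every series, so class and
# series factors are independent and planted effects are recoverable in
# principle by every batch method
balanced_config <- function(seed = 1, n_series = 6, spc = c(5L, 6L),
                            n_genes = 800, n_planted = 20, noise_sd = 0.5,
                            batch_sd_add = 1.0, batch_sd_mult = 0.1, ...) {
  study_config(n_series = n_series, classes_per_series = c(7L, 7L),
               samples_per_class_per_series = spc,
               n_genes_global = n_genes, n_planted_deg = n_planted,
               noise_sd = noise_sd, batch_sd_add = batch_sd_add,
               batch_sd_mult = batch_sd_mult, anchor_class = NULL,
               seed = seed, ...)
}

# small confounded compendium-like design (the generator defaults, scaled)
small_confounded_config <- function(seed = 1, ...) {
  study_config(n_series = 8, classes_per_series = c(1L, 4L),
               samples_per_class_per_series = c(5L, 8L),
               n_genes_global = 400, n_planted_deg = 12, seed = seed, ...)
}

# build a merged_set directly from a matrix and annotations
make_merged <- function(expr, class_label, series_id,
                        country = "X", union_method = "mean") {
  samples <- data.frame(
    sample_id = colnames(expr), series_id = series_id,
    class_label = class_label, country = country,
    platform = "P", technology = "A", stringsAsFactors = FALSE)
  structure(list(expression = expr, gene_symbols = rownames(expr),
                 samples = samples,
                 provenance = list(union_method = union_method,
                                   batch_method = "none",
                                   source_series = unique(series_id))),
            class = "merged_set")
}

# O(n^2) definitional oracle for Hoeffding's D
hoeffding_oracle <- function(x, y) {
  n <- length(x)
  R <- rank(x); S <- rank(y)
  Q <- numeric(n)
  for (i in seq_len(n)) {
    q <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      if (x[j] < x[i] && y[j] < y[i]) q <- q + 1
      else if ((x[j] == x[i] && y[j] < y[i]) ||
               (x[j] < x[i] && y[j] == y[i])) q <- q + 0.5
      else if (x[j] == x[i] && y[j] == y[i]) q <- q + 0.25
    }
    Q[i] <- q
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# brute-force two-sample KS: evaluate the ECDF difference at every data value
ks_oracle <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t)
    abs(mean(a <= t) - mean(b <= t)), 0))
}

# brute-force moderated-t oracle: numerical root-finding on the marginal
# moment equation, then every statistic from first principles
moderated_oracle <- function(x, classes) {
  cls <- sort(unique(classes))
  K <- length(cls); n <- ncol(x); G <- nrow(x)
  n_k <- sapply(cls, function(k) sum(classes == k))
  means <- sapply(cls, function(k) rowMeans(x[, classes == k, drop = FALSE]))
  d <- n - K
  s2 <- pmax(rowSums((x - means[, match(classes, cls)])^2) / d, 1e-12)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  rhs <- mean((e - mean(e))^2 * G / (G - 1)) - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- Inf; s0 <- mean(s2)
  } else {
    d0 <- stats::uniroot(function(v) trigamma(v / 2) - rhs,
                         c(1e-3, 1e6), tol = 1e-12)$root
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  st <- if (is.infinite(d0)) rep(s0, G) else (d0 * s0 + d * s2) / (d0 + d)
  pairs <- utils::combn(cls, 2)
  tt <- pp <- ll <- matrix(NA_real_, G, ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ll[, j] <- means[, a] - means[, b]
    tt[, j] <- ll[, j] / sqrt(st * (1 / n_k[a] + 1 / n_k[b]))
    pp[, j] <- 2 * stats::pt(-abs(tt[, j]), d0 + d)
  }
  list(d0 = d0, s0 = s0, s_tilde = st, t = tt, p = pp, lfc = ll)
}
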