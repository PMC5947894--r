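#' The six batch-effect adjustment methods
#'
#' Names of the batch-adjustment algorithms available in the configuration
#' grid: `MC` (batch mean-centering), `EB` (parametric empirical-Bayes
#' location/scale adjustment), `MRS` (median rank scores), `QD` (per-sample
#' equal-frequency quantile discretization), `GQ` (per-gene cross-batch
#' quantile mapping) and `NORDI` (per-sample normal-model ternary
#' discretization).
#'
#' @return Character vector of the six method names.
#' @export
batch_methods <- function() c("GQ", "EB", "NORDI", "QD", "MRS", "MC")

#' Adjust a merged expression set for series (batch) effects
#'
#' Applies one of six batch-adjustment algorithms to a [merge_series()]
#' result, treating each contributing series as one batch. All methods
#' preserve the matrix shape and the sample annotations; the two
#' discretizing methods (`QD`, `NORDI`) replace intensities by bin indices
#' or ternary codes and therefore bound the attainable between-class
#' log-fold change (at most `Q - 1` and 2 respectively).
#'
#' Algorithms:
#' * `MC`: per gene, subtract the batch mean and add back the grand mean.
#' * `EB`: parametric empirical-Bayes location/scale model. Per gene the
#'   data are standardized with the grand mean and pooled residual SD; per
#'   batch, gene-wise location and scale effects are estimated, shrunk
#'   towards batch-level priors fitted by the method of moments (normal
#'   prior for locations, inverse-gamma for scales), with the
#'   location/scale updates iterated to convergence; the standardization is
#'   then undone. By default no biological covariates are used; with
#'   `protect_classes = TRUE` per-gene class means are removed before and
#'   restored after adjustment so class signal is not absorbed into the
#'   batch estimates under class-batch confounding.
#' * `MRS`: the largest batch (ties broken by lexicographic series id) is
#'   the reference; every other batch maps each gene's value to
#'   `x - median_batch(g) + q_ref(rank_batch(g))` where `q_ref(r)` is the
#'   reference gene median of rank `r`.
#' * `QD`: per sample, equal-frequency discretization into `Q` bins
#'   (default 16); values become bin indices 1..Q.
#' * `GQ`: per gene, each value is carried through its within-batch ECDF
#'   level and re-expressed as the pooled all-batch empirical quantile at
#'   that level.
#' * `NORDI`: per sample, Grubbs outliers are removed iteratively at
#'   `alpha_out`, the retained mean m and SD s are computed, and every
#'   value maps to +1 above `m + z s`, -1 below `m - z s`, else 0, with
#'   `z = qnorm(1 - alpha_disc / 2)`.
#'
#' @param merged A `merged_set`.
#' @param method One of [batch_methods()].
#' @param batches Optional batch label per sample; defaults to the sample
#'   annotation's `series_id`.
#' @param params Method parameters: `Q` (QD bins, default 16), `alpha_out`
#'   and `alpha_disc` (NORDI, default 0.05 each), `tol` and `max_iter`
#'   (EB updates, default 1e-6 / 200), `protect_classes` (EB, default
#'   FALSE).
#' @return A `merged_set` with adjusted expression and updated provenance.
#' @export
apply_batch_adjustment <- function(merged, method, batches = NULL,
                                   params = list()) {
  stopifnot(inherits(merged, "merged_set"))
  method <- match.arg(toupper(method), batch_methods())
  x <- merged$expression
  batches <- batches %||% merged$samples$series_id
  if (length(batches) != ncol(x))
    stopf("need one batch label per sample")
  batches <- as.character(batches)
  sizes <- table(batches)
  if (method %in% c("EB", "MC", "MRS", "GQ") && any(sizes < 2))
    stopf("method %s requires >= 2 samples per batch; singleton batch(es): %s",
          method, paste(names(sizes)[sizes < 2], collapse = ", "))

  adj <- switch(method,
    MC = adjust_mc(x, batches),
    EB = adjust_eb(x, batches,
                   tol = params$tol %||% 1e-6,
                   max_iter = params$max_iter %||% 200,
                   classes = if (isTRUE(params$protect_classes))
                     merged$samples$class_label else NULL),
    MRS = adjust_mrs(x, batches),
    QD = adjust_qd(x, Q = params$Q %||% 16L),
    GQ = adjust_gq(x, batches),
    NORDI = adjust_nordi(x,
                         alpha_out = params$alpha_out %||% 0.05,
                         alpha_disc = params$alpha_disc %||% 0.05,
                         max_iter = params$max_iter %||% 100)
  )
  out <- merged
  out$expression <- adj
  out$provenance$batch_method <- method
  out$provenance$batch_params <- params
  out
}

adjust_mc <- function(x, batches) {
  grand <- rowMeans(x)
  out <- x
  for (b in unique(batches)) {
    idx <- batches == b
    out[, idx] <- x[, idx, drop = FALSE] -
      rowMeans(x[, idx, drop = FALSE]) + grand
  }
  out
}

adjust_eb <- function(x, batches, tol = 1e-6, max_iter = 200, classes = NULL) {
  class_part <- 0
  if (!is.null(classes)) {
    # remove per-gene class means (centered), adjust the remainder, restore
    cm <- vapply(unique(classes), function(k)
      rowMeans(x[, classes == k, drop = FALSE]), numeric(nrow(x)))
    cm <- cm - rowMeans(cm)
    class_part <- cm[, match(classes, unique(classes)), drop = FALSE]
    x <- x - class_part
  }
  ub <- sort(unique(batches))
  n_i <- vapply(ub, function(b) sum(batches == b), 0L)
  alpha <- rowMeans(x)
  # pooled residual SD about batch means
  res2 <- x
  for (b in ub) {
    idx <- batches == b
    res2[, idx] <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
  }
  sigma <- sqrt(rowSums(res2^2) / ncol(x))
  sigma <- pmax(sigma, 1e-8)
  Z <- (x - alpha) / sigma

  out <- Z
  fit_info <- list()
  for (i in seq_along(ub)) {
    idx <- batches == ub[i]
    Zi <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zi)
    d2_hat <- apply(Zi, 1, stats::var)
    g_bar <- mean(g_hat)
    t2 <- max(stats::var(g_hat), 1e-12)
    m <- mean(d2_hat)
    s2 <- stats::var(d2_hat)
    if (!is.finite(s2) || s2 < 1e-12) {
      # near-degenerate scale spread: flat inverse-gamma prior centred at m
      lambda <- 2
      theta <- m
    } else {
      lambda <- (2 * s2 + m^2) / s2
      theta <- (m * s2 + m^3) / s2
    }
    g_star <- g_hat
    d2_star <- d2_hat
    for (it in seq_len(max_iter)) {
      g_new <- (n_i[i] * t2 * g_hat + d2_star * g_bar) /
        (n_i[i] * t2 + d2_star)
      ss <- rowSums((Zi - g_new)^2)
      d2_new <- (theta + 0.5 * ss) / (n_i[i] / 2 + lambda - 1)
      delta <- max(abs(g_new - g_star) / (abs(g_star) + 1e-12),
                   abs(d2_new - d2_star) / (abs(d2_star) + 1e-12))
      g_star <- g_new
      d2_star <- d2_new
      if (delta < tol) break
    }
    out[, idx] <- (Zi - g_star) / sqrt(pmax(d2_star, 1e-12))
    fit_info[[ub[i]]] <- list(gamma_hat = g_hat, gamma_bar = g_bar,
                              tau2 = t2, gamma_star = g_star,
                              delta2_hat = d2_hat, delta2_star = d2_star)
  }
  res <- out * sigma + alpha + class_part
  attr(res, "eb_fit") <- fit_info
  res
}

adjust_mrs <- function(x, batches) {
  ub <- sort(unique(batches))
  sizes <- vapply(ub, function(b) sum(batches == b), 0L)
  ref <- ub[sizes == max(sizes)][1]  # ub sorted, so ties break lexicographically
  med <- vapply(ub, function(b)
    apply(x[, batches == b, drop = FALSE], 1, stats::median),
    numeric(nrow(x)))
  colnames(med) <- ub
  q_ref <- sort(med[, ref])
  out <- x
  for (b in setdiff(ub, ref)) {
    idx <- batches == b
    r <- rank(med[, b], ties.method = "first")
    out[, idx] <- x[, idx, drop = FALSE] - med[, b] + q_ref[r]
  }
  out
}

adjust_qd <- function(x, Q = 16L) {
  if (Q < 2) stopf("QD needs Q >= 2 bins")
  n <- nrow(x)
  apply(x, 2, function(v) ceiling(rank(v, ties.method = "first") * Q / n))
}

adjust_gq <- function(x, batches) {
  ub <- unique(batches)
  N <- ncol(x)
  out <- x
  xs <- t(apply(x, 1, sort))
  for (b in ub) {
    idx <- which(batches == b)
    n_b <- length(idx)
    xb <- x[, idx, drop = FALSE]
    u <- t(apply(xb, 1, rank)) / n_b
    pos <- ceiling(u * N)
    for (j in seq_len(n_b)) {
      out[, idx[j]] <- xs[cbind(seq_len(nrow(x)), pos[, j])]
    }
  }
  out
}

grubbs_retained <- function(v, alpha = 0.05, max_iter = 100) {
  keep <- rep(TRUE, length(v))
  for (it in seq_len(max_iter)) {
    w <- v[keep]
    n <- length(w)
    if (n < 3) break
    s <- stats::sd(w)
    if (s == 0) break
    dev <- abs(w - mean(w))
    Gstat <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * n), n - 2)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (Gstat <= crit) break
    drop_idx <- which(keep)[which.max(dev)]
    keep[drop_idx] <- FALSE
  }
  keep
}

adjust_nordi <- function(x, alpha_out = 0.05, alpha_disc = 0.05,
                         max_iter = 100) {
  z <- stats::qnorm(1 - alpha_disc / 2)
  apply(x, 2, function(v) {
    keep <- grubbs_retained(v, alpha = alpha_out, max_iter = max_iter)
    m <- mean(v[keep])
    s <- stats::sd(v[keep])
    ifelse(v > m + z * s, 1, ifelse(v < m - z * s, -1, 0))
  })
}
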