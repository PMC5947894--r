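with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Taxonomy maps between the 7-, 3- and 2-class skin-state scenarios
#'
#' The seven skin states collapse to three super-states (BCC, SCC, MCC ->
#' carcinoma; PRIMEL, METMEL -> melanoma; NSK, NEV -> healthy) and further
#' to two (carcinoma, melanoma -> tumor; healthy -> healthy). The maps are
#' total and onto, and the 2-class map is the composition of the two.
#'
#' @param n_classes 3 or 2.
#' @return Named character vector mapping each of the 7 states to its
#'   super-state.
#' @export
skin_taxonomy <- function(n_classes = 3) {
  map3 <- c(BCC = "carcinoma", SCC = "carcinoma", MCC = "carcinoma",
            PRIMEL = "melanoma", METMEL = "melanoma",
            NSK = "healthy", NEV = "healthy")
  if (n_classes == 3) return(map3)
  if (n_classes == 2) {
    super2 <- c(carcinoma = "tumor", melanoma = "tumor", healthy = "healthy")
    return(stats::setNames(super2[map3], names(map3)))
  }
  stopf("n_classes must be 3 or 2")
}

#' k-nearest-neighbour mutual information estimator
#'
#' Estimates the mutual information (in nats) between a continuous vector
#' and either a second continuous vector or a discrete class label, using
#' k-nearest-neighbour statistics.
#'
#' For two continuous marginals the estimator is
#' \deqn{I = \psi(k) + \psi(N) - \langle \psi(n_x + 1) + \psi(n_y + 1)
#' \rangle,} where \eqn{n_x(i)}, \eqn{n_y(i)} count points strictly inside
#' the max-norm distance to the k-th joint neighbour. For a discrete
#' target, \deqn{I = \psi(N) - \langle \psi(N_{class}) \rangle + \psi(k) -
#' \langle \psi(m_i) \rangle,} where the k-th neighbour is found within
#' the point's own class and \eqn{m_i} counts points of any class inside
#' that radius. Estimates are clipped at 0. A tiny seeded jitter (1e-10
#' relative scale) breaks distance ties deterministically.
#'
#' @param x Numeric vector.
#' @param y Numeric vector, or a factor/character class label.
#' @param k Number of neighbours (default 3); for a class with at most k
#'   members, k is reduced for that class with a warning.
#' @param jitter_seed Seed for the tie-breaking jitter (default 0).
#' @return Mutual information in nats (non-negative scalar).
#' @export
knn_mutual_information <- function(x, y, k = 3, jitter_seed = 0) {
  n <- length(x)
  if (k < 1) stopf("k must be >= 1")
  if (n < k + 2) stopf("need length >= k + 2")
  discrete <- is.factor(y) || is.character(y) || is.logical(y)
  if (!discrete && length(y) != n) stopf("x and y must have equal length")
  jit <- function(v) {
    s <- max(stats::sd(v), 1e-8)
    v + stats::rnorm(length(v), 0, 1e-10 * s)
  }
  if (discrete) {
    y <- as.character(y)
    if (length(y) != n) stopf("x and y must have equal length")
    xj <- with_preserved_rng(jitter_seed, jit(x))
    tab <- table(y)
    small <- names(tab)[tab <= k]
    if (length(small))
      warnf("class(es) with <= k members, reducing k locally: %s",
            paste(small, collapse = ", "))
    eps <- numeric(n)
    kk <- numeric(n)
    for (cl in names(tab)) {
      idx <- which(y == cl)
      n_c <- length(idx)
      if (n_c < 2) stopf("class %s has a single member", cl)
      k_c <- min(k, n_c - 1)
      for (i in idx) {
        d <- abs(xj[idx] - xj[i])
        eps[i] <- sort(d, partial = k_c + 1)[k_c + 1]
        kk[i] <- k_c
      }
    }
    m_i <- vapply(seq_len(n), function(i)
      sum(abs(xj - xj[i]) <= eps[i]) - 1, 0)
    N_c <- as.vector(tab[y])
    val <- digamma(n) - mean(digamma(N_c)) +
      mean(digamma(kk)) - mean(digamma(m_i))
    return(max(0, val))
  }
  jxy <- with_preserved_rng(jitter_seed, list(jit(x), jit(y)))
  xj <- jxy[[1]]; yj <- jxy[[2]]
  nx <- ny <- numeric(n)
  block <- 512L
  starts <- seq(1L, n, by = block)
  for (s0 in starts) {
    ii <- s0:min(s0 + block - 1L, n)
    dx <- abs(outer(xj[ii], xj, "-"))
    dy <- abs(outer(yj[ii], yj, "-"))
    dz <- pmax(dx, dy)
    eps <- apply(dz, 1, function(v) sort(v, partial = k + 1)[k + 1])
    nx[ii] <- rowSums(dx < eps) - 1
    ny[ii] <- rowSums(dy < eps) - 1
  }
  val <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(0, val)
}

#' Minimum-redundancy maximum-relevance gene ranking
#'
#' Greedy mRMR feature ranking. Relevance of a gene is its k-NN mutual
#' information with the class label (discrete-target estimator);
#' redundancy between genes uses the continuous-continuous estimator. The
#' first gene maximizes relevance; each subsequent step picks, in the
#' difference scheme, \eqn{\arg\max_g [I(g; class) - |S|^{-1} \sum_{s \in
#' S} I(g; s)]} (the quotient scheme divides instead). Score ties break
#' lexicographically by gene symbol.
#'
#' @param expression Gene-by-sample matrix.
#' @param labels Class label per sample.
#' @param k_mi Neighbours for the MI estimators (default 3).
#' @param scheme `"difference"` (default) or `"quotient"`.
#' @param jitter_seed Seed for MI tie-breaking jitter.
#' @return An object of class `mrmr_ranking`: a data frame with columns
#'   `gene`, `relevance`, `redundancy`, `score` in rank order.
#' @export
mrmr_rank <- function(expression, labels, k_mi = 3,
                      scheme = c("difference", "quotient"),
                      jitter_seed = 0) {
  scheme <- match.arg(scheme)
  x <- as.matrix(expression)
  if (nrow(x) < 1) stopf("need >= 1 gene")
  genes <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- genes
  labels <- as.character(labels)
  rel <- vapply(genes, function(g)
    knn_mutual_information(x[g, ], labels, k = k_mi,
                           jitter_seed = jitter_seed), 0)
  red_cache <- matrix(NA_real_, nrow(x), nrow(x), dimnames = list(genes, genes))
  pair_mi <- function(a, b) {
    if (is.na(red_cache[a, b])) {
      v <- knn_mutual_information(x[a, ], x[b, ], k = k_mi,
                                  jitter_seed = jitter_seed)
      red_cache[a, b] <<- v
      red_cache[b, a] <<- v
    }
    red_cache[a, b]
  }
  pick_best <- function(score, cand) {
    best <- max(score)
    cand[score >= best - 1e-12][1]  # candidates sorted: lexicographic ties
  }
  cand <- genes[order(genes)]
  sel <- character(0)
  rows <- list()
  first <- pick_best(rel[cand], cand)
  sel <- first
  cand <- setdiff(cand, first)
  rows[[1]] <- data.frame(gene = first, relevance = rel[first],
                          redundancy = 0, score = rel[first],
                          stringsAsFactors = FALSE)
  while (length(cand)) {
    red <- vapply(cand, function(g)
      mean(vapply(sel, function(s) pair_mi(g, s), 0)), 0)
    score <- if (scheme == "difference") rel[cand] - red else
      rel[cand] / pmax(red, 1e-12)
    g <- pick_best(score, cand)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, relevance = rel[g], redundancy = red[g],
      score = score[cand == g], stringsAsFactors = FALSE)
    sel <- c(sel, g)
    cand <- setdiff(cand, g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

stratified_folds <- function(labels, k, seed) {
  with_preserved_rng(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

#' Cross-validated multiclass SVM on a gene subset
#'
#' Trains soft-margin linear support vector machines (cost 1, one-vs-one
#' voting) under leave-one-out or stratified 10-fold cross-validation.
#' Features are standardized with training-fold statistics only; held-out
#' predictions accumulate into a confusion matrix.
#'
#' @param expression Gene-by-sample matrix.
#' @param labels Class label per sample (every class needs >= 2 samples).
#' @param genes Gene subset to use (default: all rows).
#' @param scheme `"kfold"` (default) or `"loo"`.
#' @param k_folds Number of folds for `"kfold"` (default 10).
#' @param seed Fold-assignment seed (default 20180511).
#' @param kernel SVM kernel (default `"linear"`; `"radial"` available).
#' @param cost Soft-margin regularization constant (default 1).
#' @return An object of class `cv_entry`: `confusion` (true x predicted),
#'   `accuracy`, `per_class` accuracy, `scheme`, `n_genes`,
#'   `degenerate_folds` (folds whose training set missed a class).
#' @export
svm_cross_validate <- function(expression, labels, genes = NULL,
                               scheme = c("kfold", "loo"), k_folds = 10,
                               seed = 20180511, kernel = "linear",
                               cost = 1) {
  scheme <- match.arg(scheme)
  x <- as.matrix(expression)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) stopf("one label per sample required")
  tab <- table(labels)
  if (any(tab < 2)) stopf("every class needs >= 2 samples")
  cls <- order_classes(names(tab))
  n <- ncol(x)
  feat <- t(x)  # samples x genes

  fold <- if (scheme == "loo") seq_len(n) else
    stratified_folds(labels, k_folds, seed)
  pred <- character(n)
  degenerate <- integer(0)
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(labels[tr])) < length(cls))
      degenerate <- c(degenerate, f)
    mu <- colMeans(feat[tr, , drop = FALSE])
    sd_ <- apply(feat[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    ztr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    zte <- sweep(sweep(feat[te, , drop = FALSE], 2, mu), 2, sd_, "/")
    fit <- e1071::svm(x = ztr, y = factor(labels[tr], levels = cls),
                      kernel = kernel, cost = cost, scale = FALSE)
    pred[te] <- as.character(stats::predict(fit, zte))
  }
  confusion <- table(factor(labels, levels = cls),
                     factor(pred, levels = cls))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  structure(
    list(confusion = confusion,
         accuracy = sum(diag(confusion)) / sum(confusion),
         per_class = diag(confusion) / rowSums(confusion),
         scheme = scheme, n_genes = nrow(x),
         degenerate_folds = degenerate),
    class = "cv_entry"
  )
}

#' @export
print.cv_entry <- function(x, ...) {
  cat(sprintf("%s cross-validation, %d gene(s): accuracy %.3f\n",
              toupper(x$scheme), x$n_genes, x$accuracy))
  invisible(x)
}

#' Collapse a confusion matrix to a coarser taxonomy
#'
#' Sums the sub-matrix blocks associated with each super-state: entry
#' (A, B) of the collapsed matrix is the sum of input entries (a, b) over
#' a in A, b in B. Collapsing conserves totals and can only move
#' within-super-state errors onto the diagonal, so accuracy never
#' decreases.
#'
#' @param confusion Square confusion matrix with state labels on both
#'   dimensions.
#' @param map Named map from states to super-states, see
#'   [skin_taxonomy()].
#' @return A list with `confusion` (collapsed matrix), `accuracy` and
#'   `per_class` accuracy.
#' @export
collapse_taxonomy <- function(confusion, map) {
  labs <- rownames(confusion)
  unmapped <- setdiff(labs, names(map))
  if (length(unmapped))
    stopf("unmapped label(s): %s", paste(unmapped, collapse = ", "))
  super <- unique(unname(map[labs]))
  out <- matrix(0, length(super), length(super),
                dimnames = list(true = super, predicted = super))
  for (a in labs) for (b in labs) {
    out[map[[a]], map[[b]]] <- out[map[[a]], map[[b]]] + confusion[a, b]
  }
  list(confusion = out,
       accuracy = sum(diag(out)) / sum(out),
       per_class = diag(out) / rowSums(out))
}

#' Accuracy curves under gradual insertion of ranked genes
#'
#' For each prefix of an mRMR ranking, runs cross-validated SVM
#' classification and records overall, per-class and collapsed-taxonomy
#' accuracies — the data behind incremental accuracy-vs-genes curves.
#'
#' @param expression Gene-by-sample matrix.
#' @param labels Class label per sample.
#' @param ranking An `mrmr_ranking` (or character vector of genes in rank
#'   order).
#' @param schemes Cross-validation schemes to run (default both).
#' @param k_folds,seed,kernel,cost Passed to [svm_cross_validate()].
#' @param max_genes Evaluate prefixes up to this size (default: the whole
#'   ranking).
#' @return An object of class `cv_report`: `curves` (data frame with
#'   columns `k`, `scheme`, `taxonomy`, `accuracy`), `per_class` (data
#'   frame of per-state accuracies by k and scheme, 7-class taxonomy) and
#'   `entries` (the `cv_entry` objects, keyed `scheme.k`).
#' @export
incremental_curves <- function(expression, labels, ranking,
                               schemes = c("loo", "kfold"), k_folds = 10,
                               seed = 20180511, kernel = "linear", cost = 1,
                               max_genes = NULL) {
  genes <- if (inherits(ranking, "data.frame")) ranking$gene else
    as.character(ranking)
  miss <- setdiff(genes, rownames(expression))
  if (length(miss)) stopf("ranking gene(s) absent from expression: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  kmax <- min(max_genes %||% length(genes), length(genes))
  curves <- list()
  pcs <- list()
  entries <- list()
  for (sch in schemes) {
    for (kk in seq_len(kmax)) {
      ent <- svm_cross_validate(expression, labels,
                                genes = genes[seq_len(kk)],
                                scheme = sch, k_folds = k_folds,
                                seed = seed, kernel = kernel, cost = cost)
      entries[[paste(sch, kk, sep = ".")]] <- ent
      c3 <- collapse_taxonomy(ent$confusion, skin_taxonomy(3))
      c2 <- collapse_taxonomy(ent$confusion, skin_taxonomy(2))
      curves[[length(curves) + 1L]] <- data.frame(
        k = kk, scheme = sch,
        taxonomy = c("7-class", "3-class", "2-class"),
        accuracy = c(ent$accuracy, c3$accuracy, c2$accuracy),
        stringsAsFactors = FALSE)
      pcs[[length(pcs) + 1L]] <- data.frame(
        k = kk, scheme = sch, state = names(ent$per_class),
        accuracy = unname(ent$per_class), stringsAsFactors = FALSE)
    }
  }
  structure(
    list(curves = do.call(rbind, curves),
         per_class = do.call(rbind, pcs),
         entries = entries, genes = genes[seq_len(kmax)]),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report over %d gene prefix(es)\n", length(x$genes)))
  best <- x$curves[x$curves$taxonomy == "7-class", ]
  for (sch in unique(best$scheme)) {
    b <- best[best$scheme == sch, ]
    cat(sprintf("  %s: 7-class accuracy %.3f at k = %d (max over k)\n",
                sch, max(b$accuracy), b$k[which.max(b$accuracy)]))
  }
  invisible(x)
}
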