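# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (it in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

order_classes <- function(cls) {
  canon <- skin_states()
  if (all(cls %in% canon)) canon[canon %in% cls] else sort(cls)
}

#' Moderated-t differential expression over all pairwise class contrasts
#'
#' Fits a one-way class-means layout per gene and tests every unordered
#' pair of observed classes with an empirical-Bayes moderated t-statistic:
#' gene-wise residual variances \eqn{s_g^2} (df \eqn{d_g = n - K}) are
#' shrunk towards a prior \eqn{s_0^2} with prior df \eqn{d_0}, both
#' estimated by moment matching on the log variances,
#' \deqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2),}
#' solving \eqn{\psi'(d_0/2) = \mathrm{mean}_g[(e_g-\bar e)^2 G/(G-1) -
#' \psi'(d_g/2)]} by monotone root-finding (a non-positive right-hand side
#' gives \eqn{d_0 = \infty}, i.e. complete pooling, in which case
#' \eqn{s_0^2} is the mean residual variance). The posterior variance is
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, the statistic
#' \eqn{\tilde t = \mathrm{LFC} / (\tilde s_g \sqrt{1/n_a + 1/n_b})} with
#' \eqn{d_0 + d_g} df, and p-values are Benjamini-Hochberg adjusted across
#' genes within each contrast. Seven observed classes give 21 contrasts.
#'
#' A log-posterior-odds B statistic is also reported as a diagnostic, in
#' the standard scaled-t posterior-odds form with prior differential
#' expression proportion 0.01 and the unscaled-variance inflation matched
#' to the upper 1% of the observed |t|.
#'
#' @param expression Gene-by-sample numeric matrix, no missing values.
#' @param classes Class label per sample. Classes with fewer than 2
#'   samples are dropped from contrast enumeration with a warning.
#' @param compute_b Also compute the B statistic (default TRUE).
#' @param b_proportion Prior proportion of differentially expressed genes
#'   used by the B statistic.
#' @return An object of class `contrast_table`: matrices `lfc`, `t`, `p`,
#'   `p_adj` (and `b`) of dimension genes x contrasts, the contrast list,
#'   class means/sizes, and `moderation` (s2, df_resid, d0, s0_sq,
#'   s_tilde_sq).
#' @export
fit_moderated_contrasts <- function(expression, classes, compute_b = TRUE,
                                    b_proportion = 0.01) {
  x <- as.matrix(expression)
  if (anyNA(x)) stopf("expression must not contain missing values")
  classes <- as.character(classes)
  if (length(classes) != ncol(x)) stopf("one class label per sample required")
  tab <- table(classes)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warnf("dropping class(es) with < 2 samples: %s",
          paste(small, collapse = ", "))
    keep <- !(classes %in% small)
    x <- x[, keep, drop = FALSE]
    classes <- classes[keep]
    tab <- table(classes)
  }
  cls <- order_classes(names(tab))
  K <- length(cls)
  if (K < 2) stopf("need >= 2 classes with >= 2 samples each")
  n <- ncol(x)
  G <- nrow(x)
  n_k <- as.integer(tab[cls])
  names(n_k) <- cls

  means <- vapply(cls, function(k) rowMeans(x[, classes == k, drop = FALSE]),
                  numeric(G))
  rss <- rowSums((x - means[, match(classes, cls), drop = FALSE])^2)
  d_g <- n - K
  s2 <- pmax(rss / d_g, 1e-12)

  e <- log(s2) - digamma(d_g / 2) + log(d_g / 2)
  e_bar <- mean(e)
  rhs <- mean((e - e_bar)^2 * G / (G - 1)) - trigamma(d_g / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  }
  s_tilde_sq <- if (is.infinite(d0))
    stats::setNames(rep(s0_sq, G), names(s2)) else
      (d0 * s0_sq + d_g * s2) / (d0 + d_g)

  pairs <- utils::combn(cls, 2)
  C <- ncol(pairs)
  cn <- paste(pairs[1, ], pairs[2, ], sep = "_vs_")
  lfc <- t_stat <- p <- p_adj <- matrix(NA_real_, G, C,
                                        dimnames = list(rownames(x), cn))
  df_total <- d0 + d_g
  for (j in seq_len(C)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    lfc[, j] <- means[, a] - means[, b]
    se <- sqrt(s_tilde_sq * (1 / n_k[a] + 1 / n_k[b]))
    t_stat[, j] <- lfc[, j] / se
    p[, j] <- 2 * stats::pt(-abs(t_stat[, j]), df = df_total)
    p_adj[, j] <- stats::p.adjust(p[, j], method = "BH")
  }

  b_stat <- NULL
  if (compute_b) {
    b_stat <- matrix(NA_real_, G, C, dimnames = dimnames(lfc))
    for (j in seq_len(C)) {
      tj <- t_stat[, j]
      r <- max(1 + 1e-8,
               (stats::quantile(abs(tj), 0.99) /
                  stats::qt(0.995, df = df_total))^2)
      b_stat[, j] <- log(b_proportion / (1 - b_proportion)) -
        0.5 * log(r) +
        stats::dt(tj / sqrt(r), df = df_total, log = TRUE) -
        stats::dt(tj, df = df_total, log = TRUE)
    }
  }

  structure(
    list(lfc = lfc, t = t_stat, p = p, p_adj = p_adj, b = b_stat,
         contrasts = data.frame(a = pairs[1, ], b = pairs[2, ], name = cn,
                                stringsAsFactors = FALSE),
         class_means = means, class_n = n_k,
         moderation = list(s2 = s2, df_resid = d_g, d0 = d0, s0_sq = s0_sq,
                           s_tilde_sq = s_tilde_sq),
         dropped_classes = small),
    class = "contrast_table"
  )
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("Contrast table: %d genes x %d pairwise contrasts (%d classes)\n",
              nrow(x$lfc), ncol(x$lfc), length(x$class_n)))
  cat(sprintf("  moderation: d0 = %s, s0^2 = %.4g, residual df = %d\n",
              format(x$moderation$d0, digits = 4), x$moderation$s0_sq,
              x$moderation$df_resid))
  invisible(x)
}

#' Select differentially expressed genes by LFC and p-value thresholds
#'
#' A gene is a DEG when at least one pairwise contrast has
#' `|LFC| >= lfc_min` and `p <= p_max` (defaults 4 and 0.001); its case
#' count is the number of such contrasts (at most K(K-1)/2).
#'
#' @param table A `contrast_table`.
#' @param lfc_min Minimum absolute log2 fold change.
#' @param p_max Maximum p-value.
#' @param p_type Use raw (default) or BH-adjusted p-values.
#' @return An object of class `deg_selection`: `degs` (character vector),
#'   `case_counts` (per gene), `pass` (logical genes x contrasts matrix)
#'   and the thresholds used.
#' @export
select_degs <- function(table, lfc_min = 4.0, p_max = 0.001,
                        p_type = c("raw", "adjusted")) {
  stopifnot(inherits(table, "contrast_table"))
  p_type <- match.arg(p_type)
  if (lfc_min <= 0 || p_max <= 0) stopf("thresholds must be > 0")
  pm <- if (p_type == "raw") table$p else table$p_adj
  pass <- abs(table$lfc) >= lfc_min & pm <= p_max
  case_counts <- rowSums(pass)
  structure(
    list(degs = rownames(pass)[case_counts > 0],
         case_counts = case_counts, pass = pass,
         lfc_min = lfc_min, p_max = p_max, p_type = p_type),
    class = "deg_selection"
  )
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf("DEG selection: %d gene(s) at |LFC| >= %g and %s p <= %g\n",
              length(x$degs), x$lfc_min, x$p_type, x$p_max))
  invisible(x)
}

#' Run the batch-method x union-method configuration grid
#'
#' Executes the identical merge / batch-adjust / moderated-t / threshold
#' pipeline once per (batch method, union method) configuration — 6 methods
#' times 2 union methods = 12 cells by default — and tabulates the DEG
#' count of every cell. A failing configuration is recorded and the grid
#' continues.
#'
#' @param bundles List of `series_bundle` objects (any scale; they are
#'   homogenized to log2 first).
#' @param methods Batch methods to run (default all six).
#' @param unions Union methods (default mean and median).
#' @param lfc_min,p_max,p_type Selection thresholds, see [select_degs()].
#' @param params Per-method batch parameters, see
#'   [apply_batch_adjustment()].
#' @param keep_matrices Keep each configuration's adjusted matrix (needed
#'   for the downstream robustness ANOVA; default TRUE).
#' @return An object of class `deg_grid`: `counts` (methods x unions
#'   integer matrix), `configs` (named list with each cell's selection,
#'   contrast table and optionally adjusted matrix), `errors`.
#' @export
run_configuration_grid <- function(bundles,
                                   methods = batch_methods(),
                                   unions = c("mean", "median"),
                                   lfc_min = 4.0, p_max = 0.001,
                                   p_type = "raw",
                                   params = list(),
                                   keep_matrices = TRUE) {
  counts <- matrix(NA_integer_, length(methods), length(unions),
                   dimnames = list(methods, unions))
  configs <- list()
  errors <- list()
  for (u in unions) {
    gene_level <- lapply(bundles, function(b)
      summarize_probes(ensure_log2_scale(b), union_method = u))
    merged <- merge_series(gene_level, union_method = u)
    for (m in methods) {
      key <- paste(m, u, sep = ".")
      res <- tryCatch({
        adj <- apply_batch_adjustment(merged, method = m, params = params)
        ct <- fit_moderated_contrasts(adj$expression,
                                      adj$samples$class_label)
        sel <- select_degs(ct, lfc_min = lfc_min, p_max = p_max,
                           p_type = p_type)
        list(selection = sel, contrast_table = ct,
             expression = if (keep_matrices) adj$expression else NULL,
             samples = adj$samples,
             batch_method = m, union_method = u)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        counts[m, u] <- NA_integer_
      } else {
        configs[[key]] <- res
        counts[m, u] <- length(res$selection$degs)
      }
    }
  }
  structure(list(counts = counts, configs = configs, errors = errors,
                 lfc_min = lfc_min, p_max = p_max, p_type = p_type),
            class = "deg_grid")
}

#' @export
print.deg_grid <- function(x, ...) {
  cat("Configuration grid DEG counts:\n")
  print(x$counts)
  if (length(x$errors))
    cat("failed configurations:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Intersect the DEG sets of the configurations that returned candidates
#'
#' Configurations with an empty DEG set are excluded from the intersection
#' (they return no candidates to match against); the final list is the
#' intersection over the remaining sets.
#'
#' @param x A `deg_grid`, or a (named) list of character vectors of DEG
#'   symbols.
#' @return An object of class `deg_intersection`: `genes`, `contributing`
#'   (configuration names intersected), `empty` (configurations skipped)
#'   and a `status` string (`"ok"` or `"all_empty"`).
#' @export
intersect_configurations <- function(x) {
  sets <- if (inherits(x, "deg_grid")) {
    lapply(x$configs, function(cf) cf$selection$degs)
  } else {
    x
  }
  if (!length(sets)) stopf("need at least one configuration")
  nonempty <- sets[lengths(sets) > 0]
  if (!length(nonempty)) {
    return(structure(list(genes = character(0), contributing = character(0),
                          empty = names(sets) %||% seq_along(sets),
                          status = "all_empty"),
                     class = "deg_intersection"))
  }
  structure(
    list(genes = sort(Reduce(intersect, nonempty)),
         contributing = names(nonempty) %||% seq_along(nonempty),
         empty = setdiff(names(sets) %||% seq_along(sets),
                         names(nonempty) %||% seq_along(nonempty)),
         status = "ok"),
    class = "deg_intersection"
  )
}

#' @export
print.deg_intersection <- function(x, ...) {
  cat(sprintf("DEG intersection over %d contributing configuration(s): %d gene(s) [%s]\n",
              length(x$contributing), length(x$genes), x$status))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize selected DEGs over their significant contrasts
#'
#' For each selected gene, summarizes the contrasts in which it passed the
#' thresholds: mean and SD of |LFC|, |t| and |B|, the p-value range, and
#' the case count; rows are ordered by decreasing mean |LFC|.
#'
#' @param selection A `deg_selection`.
#' @param table The matching `contrast_table`.
#' @param genes Genes to summarize (default: the selection's DEG set —
#'   pass the intersection genes to restrict).
#' @param sd_type Sample (default, denominator n-1) or population SD.
#' @return A data frame with one row per gene.
#' @export
summarize_degs <- function(selection, table, genes = NULL,
                           sd_type = c("sample", "population")) {
  stopifnot(inherits(selection, "deg_selection"),
            inherits(table, "contrast_table"))
  sd_type <- match.arg(sd_type)
  genes <- genes %||% selection$degs
  genes <- intersect(genes, rownames(selection$pass))
  if (!length(genes)) stopf("no genes to summarize")
  sdev <- function(v) {
    if (length(v) < 2) return(0)
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  rows <- lapply(genes, function(g) {
    sig <- selection$pass[g, ]
    if (!any(sig)) sig[] <- TRUE  # fall back to all contrasts
    lf <- abs(table$lfc[g, sig])
    tt <- abs(table$t[g, sig])
    pp <- table$p[g, sig]
    bb <- if (!is.null(table$b)) abs(table$b[g, sig]) else NA_real_
    data.frame(
      gene = g, n_cases = sum(selection$pass[g, ]),
      mu_lfc = mean(lf), sd_lfc = sdev(lf),
      mu_t = mean(tt), sd_t = sdev(tt),
      pv_min = min(pp), pv_max = max(pp),
      mu_b = mean(bb), sd_b = if (all(is.na(bb))) NA_real_ else sdev(bb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mu_lfc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
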