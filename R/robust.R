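#' Least-squares deviation observations across preprocessing variants
#'
#' Builds the dependent variable of the robustness ANOVA. Each variant is
#' one configuration's gene-by-sample matrix restricted to the final
#' candidate genes; all variants must share gene list and samples. With
#' \eqn{\bar x_g} the mean of gene \eqn{g} over all samples and all
#' variants, the observation for (sample \eqn{s}, configuration \eqn{c}) is
#' the mean over genes of \eqn{(x_{gsc} - \bar x_g)^2} (log2-squared
#' units), so 678 samples times 4 configurations yield 2712 observations.
#'
#' @param variants Named list of configurations; each element is a list
#'   with `expression` (gene x sample matrix), `batch_method`,
#'   `union_method` (as produced by [run_configuration_grid()] configs).
#' @param annotations Sample annotation data frame (`sample_id`,
#'   `class_label`, `country`) covering all samples.
#' @param genes Optional gene subset (e.g. the final DEG intersection).
#' @return A data frame of class `ls_deviation`: columns `value`,
#'   `sample_id`, `configuration`, `TYPE`, `BATCH`, `METHOD`, `COUNTRY`.
#' @export
ls_deviation_table <- function(variants, annotations, genes = NULL) {
  if (!length(variants)) stopf("need at least one variant")
  if (is.null(names(variants)))
    names(variants) <- paste0("config", seq_along(variants))
  mats <- lapply(variants, function(v) {
    m <- v$expression
    if (!is.null(genes)) {
      miss <- setdiff(genes, rownames(m))
      if (length(miss))
        stopf("variant is missing gene(s): %s",
              paste(utils::head(miss, 5), collapse = ", "))
      m <- m[genes, , drop = FALSE]
    }
    m
  })
  ref <- mats[[1]]
  for (m in mats) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(rownames(m), rownames(ref)) ||
        !identical(colnames(m), colnames(ref)))
      stopf("all variants must share gene list and samples")
  }
  grand <- Reduce(`+`, lapply(mats, rowMeans)) / length(mats)
  ann <- annotations[match(colnames(ref), annotations$sample_id), ]
  if (anyNA(ann$sample_id)) stopf("annotations missing for some samples")
  obs <- do.call(rbind, lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    v <- colMeans((m - grand)^2)
    data.frame(
      value = unname(v),
      sample_id = colnames(m),
      configuration = nm,
      TYPE = ann$class_label,
      BATCH = variants[[nm]]$batch_method %||% nm,
      METHOD = variants[[nm]]$union_method %||% "none",
      COUNTRY = ann$country,
      stringsAsFactors = FALSE
    )
  }))
  rownames(obs) <- NULL
  class(obs) <- c("ls_deviation", "data.frame")
  obs
}

#' Main-effects ANOVA with Type III sums of squares
#'
#' Fits a main-effects linear model with sum-to-zero factor coding and
#' computes partial (Type III) sums of squares by model comparison: each
#' factor's SS is the increase in residual SS when that factor is dropped
#' from the full model. F ratios use the full-model residual mean square.
#'
#' @param observations A data frame (e.g. from [ls_deviation_table()]).
#' @param response Name of the response column (default `"value"`).
#' @param factors Character vector of factor column names; factors with a
#'   single observed level are dropped with a warning.
#' @return An object of class `anova_result`: a data frame with one row
#'   per factor plus `RESIDUAL` and `TOTAL (CORRECTED)` rows, holding sum
#'   of squares, df, mean square, F ratio and p-value.
#' @export
anova_main_effects <- function(observations, response = "value",
                               factors = c("TYPE", "BATCH", "METHOD",
                                           "COUNTRY")) {
  df <- as.data.frame(observations)
  if (!response %in% names(df)) stopf("no response column '%s'", response)
  miss <- setdiff(factors, names(df))
  if (length(miss)) stopf("missing factor column(s): %s",
                          paste(miss, collapse = ", "))
  for (f in factors) df[[f]] <- factor(df[[f]])
  single <- factors[vapply(factors, function(f) nlevels(df[[f]]) < 2, TRUE)]
  if (length(single)) {
    warnf("dropping single-level factor(s): %s", paste(single, collapse = ", "))
    factors <- setdiff(factors, single)
  }
  if (!length(factors)) stopf("no factor with >= 2 levels")

  # aliasing check: a factor nested inside (or identical to) another makes
  # the partial SS undefined
  for (i in seq_along(factors)) {
    for (j in seq_along(factors)) {
      if (i == j) next
      tab <- table(df[[factors[i]]], df[[factors[j]]])
      if (all(rowSums(tab > 0) == 1) && nlevels(df[[factors[i]]]) >=
          nlevels(df[[factors[j]]]))
        stopf("factors '%s' and '%s' are aliased (one is constant within the other's levels)",
              factors[i], factors[j])
    }
  }

  N <- nrow(df)
  p_df <- sum(vapply(factors, function(f) nlevels(df[[f]]) - 1L, 0L))
  if (N <= p_df + 1) stopf("too few observations for the requested factors")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit))))
    stopf("design matrix is rank deficient; factors are aliased")
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- stats::df.residual(fit)
  ms_res <- rss_full / df_res

  rows <- lapply(factors, function(f) {
    sub <- setdiff(factors, f)
    form0 <- stats::as.formula(paste(
      response, "~", if (length(sub)) paste(sub, collapse = " + ") else "1"))
    fit0 <- stats::lm(form0, data = df)
    ss <- sum(stats::residuals(fit0)^2) - rss_full
    dfe <- nlevels(df[[f]]) - 1L
    Fval <- (ss / dfe) / ms_res
    data.frame(source = f, sum_sq = ss, df = dfe, mean_sq = ss / dfe,
               F_ratio = Fval,
               p_value = stats::pf(Fval, dfe, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  total_ss <- sum((df[[response]] - mean(df[[response]]))^2)
  out <- rbind(
    do.call(rbind, rows),
    data.frame(source = "RESIDUAL", sum_sq = rss_full, df = df_res,
               mean_sq = ms_res, F_ratio = NA, p_value = NA,
               stringsAsFactors = FALSE),
    data.frame(source = "TOTAL (CORRECTED)", sum_sq = total_ss, df = N - 1L,
               mean_sq = NA, F_ratio = NA, p_value = NA,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Main-effects ANOVA (Type III partial SS, sum-to-zero coding)\n")
  y <- as.data.frame(x)
  y$sum_sq <- signif(y$sum_sq, 6)
  y$mean_sq <- signif(y$mean_sq, 6)
  y$F_ratio <- signif(y$F_ratio, 6)
  y$p_value <- format.pval(y$p_value, digits = 4)
  print(y, row.names = FALSE)
  invisible(x)
}

# tighter-subtree-first leaf order for an hclust tree: at every internal
# node the child with the smaller merge height is visited first
reorder_tight_first <- function(hc) {
  n <- nrow(hc$merge) + 1L
  height_of <- function(node) if (node < 0) 0 else hc$height[node]
  walk <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    h <- vapply(kids, height_of, 0)
    if (h[2] < h[1]) kids <- kids[2:1]
    c(walk(kids[1]), walk(kids[2]))
  }
  walk(nrow(hc$merge))
}

#' Ward clustering of representative samples per class
#'
#' Picks the `samples_per_class` samples nearest (Euclidean) to each
#' class centroid, then clusters them agglomeratively with Ward's
#' minimum-variance linkage on Euclidean distances (Lance-Williams
#' updates; `stats::hclust(method = "ward.D2")`). Leaves are ordered by a
#' recursive tighter-subtree-first traversal, so cohesive classes form
#' contiguous blocks.
#'
#' @param expression Gene-by-sample matrix (typically restricted to the
#'   final DEG set).
#' @param classes Class label per sample.
#' @param samples_per_class Representatives per class (default 5); a class
#'   with fewer members contributes all of them, with a warning.
#' @return An object of class `ward_clustering`: the `hclust` tree, the
#'   ordered sample ids (`leaf_order`), the representative ids and their
#'   classes, and a Newick-format string of the dendrogram.
#' @export
ward_cluster <- function(expression, classes, samples_per_class = 5) {
  x <- as.matrix(expression)
  classes <- as.character(classes)
  if (length(classes) != ncol(x)) stopf("one class label per sample required")
  if (ncol(x) < 2) stopf("need >= 2 samples")
  reps <- unlist(lapply(unique(classes), function(k) {
    idx <- which(classes == k)
    if (length(idx) < samples_per_class)
      warnf("class %s has only %d sample(s); taking all", k, length(idx))
    centroid <- rowMeans(x[, idx, drop = FALSE])
    d2 <- colSums((x[, idx, drop = FALSE] - centroid)^2)
    idx[order(d2)][seq_len(min(samples_per_class, length(idx)))]
  }))
  xr <- x[, reps, drop = FALSE]
  hc <- stats::hclust(stats::dist(t(xr)), method = "ward.D2")
  ord <- reorder_tight_first(hc)
  leaf_ids <- colnames(xr)[ord]
  structure(
    list(hclust = hc, leaf_order = leaf_ids,
         representatives = colnames(xr),
         representative_classes = stats::setNames(classes[reps], colnames(xr)),
         newick = hclust_to_newick(hc)),
    class = "ward_clustering"
  )
}

hclust_to_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  build <- function(node) {
    if (node < 0) return(lab[-node])
    kids <- hc$merge[node, ]
    sprintf("(%s,%s)", build(kids[1]), build(kids[2]))
  }
  paste0(build(nrow(hc$merge)), ";")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("Ward clustering of %d representative samples\n",
              length(x$representatives)))
  cat("  leaf order:", paste(utils::head(x$leaf_order, 10), collapse = ", "),
      if (length(x$leaf_order) > 10) "..." else "", "\n")
  invisible(x)
}
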