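#' Homogenize a series to the log2 scale
#'
#' Series deposited on a linear intensity scale are first rescaled so their
#' maximum equals 65535 (16-bit depth homogenization) and then transformed
#' with \eqn{v \mapsto \log_2(v + 1)}, so values land in \[0, 16\]. Series
#' already on the log2 scale are returned unchanged (the operation is
#' idempotent).
#'
#' The +1 offset avoids minus infinity at zero intensity. When the stored
#' scale flag is missing or `auto_detect` is on, a maximum above 30 is taken
#' as evidence of a linear scale: log2 microarray intensities never come
#' close to that.
#'
#' @param bundle A `series_bundle`.
#' @param auto_detect Treat a log2-flagged series with max > 30 as linear.
#' @return A `series_bundle` on the log2 scale.
#' @export
ensure_log2_scale <- function(bundle, auto_detect = FALSE) {
  stopifnot(inherits(bundle, "series_bundle"))
  is_linear <- bundle$scale == "linear16" ||
    (auto_detect && max(bundle$expression) > 30)
  if (!is_linear) return(bundle)
  x <- bundle$expression
  if (min(x) < 0)
    stopf("series %s: negative values on a linear-scale series", bundle$series_id)
  x <- x * (65535 / max(x))
  x <- log2(x + 1)
  series_bundle(bundle$series_id, x, bundle$probe_map, bundle$samples,
                scale = "log2")
}

#' Within-series quantile normalization
#'
#' Optional pre-merge step equalizing the intensity distributions of all
#' samples in one series: each column's sorted values are replaced by the
#' row-wise mean of all columns' sorted values (ties receive the mean of
#' their tied positions). Off by default in the pipeline; it stands in for
#' the probe-level normalization layer applied upstream of this package's
#' scope.
#'
#' @param bundle A `series_bundle` on the log2 scale.
#' @return A `series_bundle` with quantile-normalized expression.
#' @export
quantile_normalize <- function(bundle) {
  stopifnot(inherits(bundle, "series_bundle"))
  if (bundle$scale != "log2")
    stopf("series %s: quantile_normalize requires the log2 scale",
          bundle$series_id)
  x <- bundle$expression
  ranks <- apply(x, 2, rank, ties.method = "average")
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(ranks, 2, function(r) {
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(x)
  series_bundle(bundle$series_id, out, bundle$probe_map, bundle$samples,
                scale = "log2")
}

#' Collapse probes to gene symbols
#'
#' Summarizes all probes transcribing the same gene symbol into a single
#' expression value per sample, by mean or median (the two union methods of
#' the configuration grid). Genes are returned in lexicographic order.
#'
#' @param bundle A `series_bundle` on the log2 scale.
#' @param union_method `"mean"` or `"median"`.
#' @return A list with `expression` (gene-by-sample matrix), `samples`
#'   (annotations) and `series_id`.
#' @export
summarize_probes <- function(bundle, union_method = c("mean", "median")) {
  stopifnot(inherits(bundle, "series_bundle"))
  union_method <- match.arg(union_method)
  if (bundle$scale != "log2")
    stopf("series %s: summarize_probes requires the log2 scale; run ensure_log2_scale first",
          bundle$series_id)
  map <- stats::setNames(bundle$probe_map$gene_symbol, bundle$probe_map$probe_id)
  probes <- rownames(bundle$expression)
  unmapped <- probes[!probes %in% names(map)]
  if (length(unmapped))
    stopf("series %s: unmapped probe(s): %s", bundle$series_id,
          paste(utils::head(unmapped, 10), collapse = ", "))
  sym <- map[probes]
  if (union_method == "mean") {
    agg <- rowsum(bundle$expression, group = sym, reorder = TRUE)
    cnt <- as.vector(table(sym)[rownames(agg)])
    gmat <- agg / cnt
  } else {
    idx <- split(seq_along(sym), sym)
    gmat <- t(vapply(idx, function(ii) {
      apply(bundle$expression[ii, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(bundle$expression))))
  }
  gmat <- gmat[order(rownames(gmat)), , drop = FALSE]
  list(expression = gmat, samples = bundle$samples,
       series_id = bundle$series_id)
}

#' Merge gene-level series by gene-symbol intersection
#'
#' Combines two or more gene-level series into a single gene-by-sample
#' matrix over the genes common to every contributing panel; only symbols
#' coded identically on all platforms survive. Samples are concatenated and
#' ordered by (series_id, sample_id).
#'
#' @param gene_level List of gene-level series as returned by
#'   [summarize_probes()].
#' @param union_method Provenance tag for the union method used upstream.
#' @return An object of class `merged_set` with fields `expression`
#'   (gene-by-sample, log2), `gene_symbols`, `samples` and `provenance`.
#' @export
merge_series <- function(gene_level, union_method = "mean") {
  if (length(gene_level) < 2)
    stopf("merge_series requires >= 2 series (got %d)", length(gene_level))
  panels <- lapply(gene_level, function(g) rownames(g$expression))
  common <- Reduce(intersect, panels)
  if (!length(common)) {
    sizes <- paste(sprintf("%s=%d",
                           vapply(gene_level, function(g) g$series_id, ""),
                           lengths(panels)), collapse = ", ")
    stopf("empty gene-symbol intersection across series (panel sizes: %s)", sizes)
  }
  common <- sort(common)
  expr <- do.call(cbind, lapply(gene_level, function(g) {
    g$expression[common, , drop = FALSE]
  }))
  samples <- do.call(rbind, lapply(gene_level, `[[`, "samples"))
  ord <- order(samples$series_id, samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  expr <- expr[, samples$sample_id, drop = FALSE]
  structure(
    list(expression = expr, gene_symbols = common, samples = samples,
         provenance = list(
           union_method = union_method,
           batch_method = "none",
           source_series = vapply(gene_level, function(g) g$series_id, "")
         )),
    class = "merged_set"
  )
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("Merged set: %d genes x %d samples from %d series (union %s, batch %s)\n",
              nrow(x$expression), ncol(x$expression),
              length(x$provenance$source_series),
              x$provenance$union_method, x$provenance$batch_method))
  invisible(x)
}

#' Write a merged set to disk
#'
#' Writes `expression.tsv` (gene-by-sample), `samples.tsv` and
#' `provenance.json` into `directory`.
#'
#' @param merged A `merged_set`.
#' @param directory Target directory.
#' @return The paths written, invisibly.
#' @export
write_merged_set <- function(merged, directory) {
  stopifnot(inherits(merged, "merged_set"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(directory, "expression.tsv")
  sf <- file.path(directory, "samples.tsv")
  jf <- file.path(directory, "provenance.json")
  edf <- data.frame(gene_symbol = rownames(merged$expression),
                    merged$expression, check.names = FALSE)
  utils::write.table(edf, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(merged$samples, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(merged$provenance, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(expression = ef, samples = sf, provenance = jf))
}
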