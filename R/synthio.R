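#' Configuration for a synthetic multi-series expression study
#'
#' Defines the generative conditions for [generate_study()]: a collection of
#' microarray-like series, each measuring only a subset of the seven skin
#' states on a platform-specific gene panel, with series-level batch effects
#' and a set of planted differentially expressed genes of known effect size.
#'
#' The generative model for the log2 intensity of probe \eqn{p} of gene
#' \eqn{g} in sample \eqn{s} of series \eqn{b} is
#' \deqn{x_{gps} = \mu_g + \beta_{g,class(s)} + \gamma_{gb} + o_p +
#'   \delta_{gb}\,\varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),}
#' where \eqn{\mu_g} is a gene baseline, \eqn{\beta} the planted class
#' effects, \eqn{\gamma} additive and \eqn{\delta} multiplicative series
#' (batch) effects, and \eqn{o_p} a fixed per-probe offset. Series flagged as
#' linear-scale are emitted as \eqn{2^x} rescaled to a 16-bit range.
#'
#' @param n_series Number of series (batches) to generate.
#' @param classes Ordered class labels; defaults to [skin_states()].
#' @param classes_per_series Integer range (length 2) of how many classes a
#'   single series measures.
#' @param samples_per_class_per_series Integer range of per-class sample
#'   counts within one series.
#' @param n_genes_global Size of the global gene universe.
#' @param panel_fraction Fraction of global genes present on each platform
#'   panel.
#' @param core_fraction Fraction of global genes guaranteed common to all
#'   panels (the shared core that survives symbol-intersection merging).
#' @param probes_per_gene Integer range of probes interrogating one gene on
#'   one platform.
#' @param n_planted_deg Number of genes given a non-zero class effect.
#' @param planted_effect Minimal class-mean shift of a planted gene, in log2
#'   units (default 5).
#' @param planted_minor_span Half-width (log2 units) of the graded secondary
#'   class profile every planted gene carries: besides its
#'   `planted_effect`-sized shift in one class, the remaining classes take a
#'   random permutation of evenly spaced levels in
#'   `[-planted_minor_span, planted_minor_span]`, emulating the graded
#'   multi-state expression profiles of real marker genes (no two states
#'   are ever exactly equally expressed on a real marker). Set 0 for pure
#'   single-class shifts.
#' @param batch_sd_add SD of additive series effects (log2 units).
#' @param batch_sd_mult SD of log multiplicative series effects.
#' @param noise_sd Residual SD (log2 units).
#' @param linear_scale_fraction Fraction of series emitted on a linear
#'   0..65535 intensity scale instead of log2.
#' @param countries Candidate sample-origin labels; one country is assigned
#'   per series.
#' @param probe_offset_sd SD of the fixed per-probe offsets.
#' @param anchor_class A reference class deposited in most series (the role
#'   normal skin plays in public skin-cancer series); every other class is
#'   guaranteed one series shared with it, so no disease state exists only
#'   in single-class series. Set NULL to disable.
#' @param anchor_fraction Fraction of series containing the anchor class.
#' @param seed Root RNG seed; per-series child seeds are derived from it by
#'   fixed arithmetic.
#' @return An object of class `study_config`.
#' @seealso [generate_study()]
#' @export
study_config <- function(n_series = 12,
                         classes = skin_states(),
                         classes_per_series = c(1L, 4L),
                         samples_per_class_per_series = c(15L, 20L),
                         n_genes_global = 1000,
                         panel_fraction = 0.85,
                         core_fraction = 0.6,
                         probes_per_gene = c(1L, 3L),
                         n_planted_deg = 20,
                         planted_effect = 5.0,
                         planted_minor_span = 1.8,
                         batch_sd_add = 1.0,
                         batch_sd_mult = 0.1,
                         noise_sd = 0.5,
                         linear_scale_fraction = 0.2,
                         countries = c("USA", "Deutschland", "Australia",
                                       "Netherlands", "South Korea",
                                       "United Kingdom", "Finland"),
                         probe_offset_sd = 0.25,
                         anchor_class = "NSK",
                         anchor_fraction = 0.6,
                         seed = 1L) {
  cfg <- list(
    n_series = as.integer(n_series),
    classes = as.character(classes),
    classes_per_series = as.integer(classes_per_series),
    samples_per_class_per_series = as.integer(samples_per_class_per_series),
    n_genes_global = as.integer(n_genes_global),
    panel_fraction = panel_fraction,
    core_fraction = core_fraction,
    probes_per_gene = as.integer(probes_per_gene),
    n_planted_deg = as.integer(n_planted_deg),
    planted_effect = planted_effect,
    planted_minor_span = planted_minor_span,
    batch_sd_add = batch_sd_add,
    batch_sd_mult = batch_sd_mult,
    noise_sd = noise_sd,
    linear_scale_fraction = linear_scale_fraction,
    countries = as.character(countries),
    probe_offset_sd = probe_offset_sd,
    anchor_class = if (is.null(anchor_class)) NULL else as.character(anchor_class),
    anchor_fraction = anchor_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  K <- length(cfg$classes)
  if (K < 2) stopf("at least two classes are required")
  if (anyDuplicated(cfg$classes)) stopf("class labels must be unique")
  rng <- cfg$classes_per_series
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1 || rng[2] > K)
    stopf("classes_per_series must be an increasing range within [1, %d]", K)
  src <- cfg$samples_per_class_per_series
  if (length(src) != 2 || src[1] > src[2] || src[1] < 1)
    stopf("samples_per_class_per_series must be a positive increasing range")
  if (cfg$n_series < 2)
    stopf("need at least 2 series")
  # every class must be placeable in >= 2 distinct series
  if (cfg$n_series * rng[2] < 2 * K)
    stopf("cannot place every class in >= 2 series: %d series with at most %d classes each cover %d class-slots, need %d",
          cfg$n_series, rng[2], cfg$n_series * rng[2], 2 * K)
  if (cfg$core_fraction * cfg$n_genes_global < 1)
    stopf("core_fraction * n_genes_global must be >= 1")
  if (cfg$core_fraction > cfg$panel_fraction || cfg$panel_fraction > 1)
    stopf("need core_fraction <= panel_fraction <= 1")
  if (cfg$batch_sd_add < 0 || cfg$batch_sd_mult < 0 || cfg$noise_sd < 0)
    stopf("all SDs must be >= 0")
  if (cfg$planted_effect <= 0) stopf("planted_effect must be > 0")
  if (cfg$planted_minor_span < 0 ||
      cfg$planted_minor_span >= cfg$planted_effect)
    stopf("planted_minor_span must lie in [0, planted_effect)")
  if (cfg$n_planted_deg > floor(cfg$core_fraction * cfg$n_genes_global))
    stopf("n_planted_deg exceeds the shared core size")
  if (cfg$linear_scale_fraction < 0 || cfg$linear_scale_fraction > 1)
    stopf("linear_scale_fraction must be in [0, 1]")
  if (!is.null(cfg$anchor_class)) {
    if (!cfg$anchor_class %in% cfg$classes)
      stopf("anchor_class '%s' is not among the classes", cfg$anchor_class)
    if (cfg$anchor_fraction <= 0 || cfg$anchor_fraction > 1)
      stopf("anchor_fraction must be in (0, 1]")
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d series, %d classes, %d genes (core %.0f%%), %d planted DEGs (effect %.1f log2)\n",
              x$n_series, length(x$classes), x$n_genes_global,
              100 * x$core_fraction, x$n_planted_deg, x$planted_effect))
  cat(sprintf("  batch SD add/mult: %.2f/%.2f, noise SD %.2f, seed %d\n",
              x$batch_sd_add, x$batch_sd_mult, x$noise_sd, x$seed))
  invisible(x)
}

# draw n integers uniformly from [rng[1], rng[2]] (safe for degenerate ranges)
sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(rng[1], n)
  else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

# Fixed arithmetic for per-series child seeds: independent of how many series
# follow, so extending a study never perturbs earlier series.
series_child_seed <- function(root_seed, idx) {
  as.integer((as.numeric(root_seed) + 104729 * idx) %% 2147483647L)
}

#' Generate a synthetic multi-series study with known ground truth
#'
#' Draws a collection of series bundles under the model documented in
#' [study_config()], together with the generative quantities (planted DEG
#' symbols, class effects, batch effects, baselines) needed to score any
#' downstream recovery experiment.
#'
#' Class-to-series assignment first gives every class two distinct series
#' (so each state is observable across batches), then tops each series up to
#' its drawn class count. Planted genes are drawn from the shared core panel
#' so that they survive symbol-intersection merging; each receives a shift of
#' `planted_effect` (random sign) in one randomly chosen class, giving every
#' planted gene at least one class pair with |effect difference| >=
#' `planted_effect`.
#'
#' @param config A [study_config()].
#' @return A list with elements `bundles` (list of `series_bundle`) and
#'   `truth` (class `study_truth`: `planted_deg_symbols`, `class_effects`,
#'   `batch_add`, `batch_mult`, `baseline_means`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  cfg <- config
  K <- length(cfg$classes)
  G <- cfg$n_genes_global
  genes <- sprintf("G%05d", seq_len(G))

  set.seed(cfg$seed)
  n_core <- max(1L, floor(cfg$core_fraction * G))
  core <- sort(sample(genes, n_core))
  noncore <- setdiff(genes, core)

  mu <- stats::runif(G, 6, 10)
  names(mu) <- genes

  planted <- sort(sample(core, cfg$n_planted_deg))
  beta <- matrix(0, G, K, dimnames = list(genes, cfg$classes))
  # cycle shifted classes so planted signal spreads over all states; shift
  # direction respects the dynamic range (activation on low-baseline genes,
  # repression on high-baseline ones, as on a bounded intensity scale);
  # remaining classes take a graded permutation of well-separated levels
  up_class <- rep_len(sample(cfg$classes), cfg$n_planted_deg)
  sgn <- ifelse(mu[planted] <= stats::median(mu), 1, -1)
  minor_levels <- if (cfg$planted_minor_span > 0 && K > 1)
    seq(-cfg$planted_minor_span, cfg$planted_minor_span, length.out = K)
  else rep(0, K)
  for (i in seq_along(planted)) {
    beta[planted[i], ] <- sample(minor_levels)
    beta[planted[i], up_class[i]] <- sgn[i] * cfg$planted_effect
  }

  # platform panels: shared core plus platform-specific extras
  platforms <- c("PLAT-A1", "PLAT-A2", "PLAT-I1")
  technologies <- c("PLAT-A1" = "A", "PLAT-A2" = "A", "PLAT-I1" = "I")
  panel_n <- max(n_core, floor(cfg$panel_fraction * G))
  panels <- lapply(platforms, function(p) {
    extra <- if (panel_n > n_core) sample(noncore, panel_n - n_core) else character(0)
    sort(c(core, extra))
  })
  names(panels) <- platforms

  # per-platform probe layout with fixed offsets
  probe_tabs <- lapply(platforms, function(p) {
    pg <- panels[[p]]
    np <- sample_range(cfg$probes_per_gene, length(pg))
    probe_id <- unlist(lapply(seq_along(pg), function(i) {
      sprintf("%s_%s_p%d", pg[i], p, seq_len(np[i]))
    }), use.names = FALSE)
    data.frame(
      probe_id = probe_id,
      gene_symbol = rep(pg, np),
      offset = stats::rnorm(sum(np), 0, cfg$probe_offset_sd),
      stringsAsFactors = FALSE
    )
  })
  names(probe_tabs) <- platforms

  # class coverage: each class in >= 2 series; when an anchor class is set,
  # it occupies most series and every other class shares a series with it
  # (mirroring compendia where healthy skin recurs across deposits), then
  # series are topped up to their drawn class counts
  rng <- cfg$classes_per_series
  anchor <- cfg$anchor_class
  ok <- FALSE
  for (attempt in 1:50) {
    series_classes <- replicate(cfg$n_series, character(0), simplify = FALSE)
    fail <- FALSE
    anchor_series <- integer(0)
    if (!is.null(anchor)) {
      n_anchor <- max(2L, round(cfg$anchor_fraction * cfg$n_series))
      anchor_series <- sample(cfg$n_series, min(n_anchor, cfg$n_series))
      for (s in anchor_series)
        series_classes[[s]] <- anchor
    }
    room_for <- function(cl, among) {
      among[vapply(among, function(s)
        length(series_classes[[s]]) < rng[2] &&
          !(cl %in% series_classes[[s]]), TRUE)]
    }
    rest <- setdiff(cfg$classes, anchor)
    for (cl in sample(rest)) {
      first_pool <- if (length(anchor_series))
        room_for(cl, anchor_series) else room_for(cl, seq_len(cfg$n_series))
      if (!length(first_pool)) { fail <- TRUE; break }
      s1 <- if (length(first_pool) == 1) first_pool else sample(first_pool, 1)
      series_classes[[s1]] <- c(series_classes[[s1]], cl)
      second_pool <- room_for(cl, setdiff(seq_len(cfg$n_series), s1))
      if (!length(second_pool)) { fail <- TRUE; break }
      s2 <- if (length(second_pool) == 1) second_pool else sample(second_pool, 1)
      series_classes[[s2]] <- c(series_classes[[s2]], cl)
    }
    if (fail) next
    target <- sample_range(rng, cfg$n_series)
    for (s in seq_len(cfg$n_series)) {
      want <- max(target[s], length(series_classes[[s]]))
      pool <- setdiff(cfg$classes, series_classes[[s]])
      add <- min(want - length(series_classes[[s]]), length(pool))
      if (add > 0)
        series_classes[[s]] <- c(series_classes[[s]], sample(pool, add))
      series_classes[[s]] <- intersect(cfg$classes, series_classes[[s]])
    }
    ok <- TRUE
    break
  }
  if (!ok) stopf("could not place every class in >= 2 series under this configuration")

  n_lin <- round(cfg$linear_scale_fraction * cfg$n_series)
  lin_series <- if (n_lin > 0) sample(cfg$n_series, n_lin) else integer(0)

  batch_add <- matrix(0, G, cfg$n_series,
                      dimnames = list(genes, sprintf("SER%02d", seq_len(cfg$n_series))))
  batch_mult <- matrix(1, G, cfg$n_series, dimnames = dimnames(batch_add))

  bundles <- vector("list", cfg$n_series)
  for (s in seq_len(cfg$n_series)) {
    set.seed(series_child_seed(cfg$seed, s))
    sid <- sprintf("SER%02d", s)
    plat <- sample(platforms, 1)
    country <- sample(cfg$countries, 1)
    gamma <- stats::rnorm(G, 0, cfg$batch_sd_add)
    delta <- exp(stats::rnorm(G, 0, cfg$batch_sd_mult))
    batch_add[, s] <- gamma
    batch_mult[, s] <- delta

    cls <- series_classes[[s]]
    n_per <- sample_range(cfg$samples_per_class_per_series, length(cls))
    class_of <- rep(cls, n_per)
    n_s <- length(class_of)
    sample_ids <- sprintf("%s_%s_%02d", sid, class_of,
                          unlist(lapply(n_per, seq_len)))

    # gene-level signal, then probe expansion
    gmat <- matrix(mu + gamma, G, n_s) +
      beta[, class_of, drop = FALSE] +
      (delta * matrix(stats::rnorm(G * n_s, 0, cfg$noise_sd), G, n_s))
    rownames(gmat) <- genes

    pt <- probe_tabs[[plat]]
    expr <- gmat[pt$gene_symbol, , drop = FALSE] + pt$offset
    dimnames(expr) <- list(pt$probe_id, sample_ids)

    scale <- "log2"
    if (s %in% lin_series) {
      lin <- 2^expr
      expr <- pmin(lin * (65535 / max(lin)), 65535)
      scale <- "linear16"
    }

    bundles[[s]] <- series_bundle(
      series_id = sid,
      expression = expr,
      probe_map = pt[, c("probe_id", "gene_symbol")],
      samples = data.frame(
        sample_id = sample_ids,
        series_id = sid,
        class_label = class_of,
        country = country,
        platform = plat,
        technology = unname(technologies[plat]),
        stringsAsFactors = FALSE
      ),
      scale = scale
    )
  }
  names(bundles) <- vapply(bundles, function(b) b$series_id, "")

  truth <- structure(
    list(planted_deg_symbols = planted,
         class_effects = beta,
         batch_add = batch_add,
         batch_mult = batch_mult,
         baseline_means = mu,
         core_genes = core),
    class = "study_truth"
  )
  list(bundles = bundles, truth = truth)
}

#' Construct a series bundle
#'
#' A series bundle is the unit consumed by the pipeline: one study's
#' probe-level expression matrix, its probe-to-gene-symbol map and its sample
#' annotations, plus the intensity scale the values are on.
#'
#' @param series_id Series identifier.
#' @param expression Numeric probes-by-samples matrix with dimnames.
#' @param probe_map Data frame with columns `probe_id`, `gene_symbol`.
#' @param samples Data frame with columns `sample_id`, `series_id`,
#'   `class_label`, `country`, `platform`, `technology`.
#' @param scale Either `"log2"` or `"linear16"` (linear 0..65535).
#' @return An object of class `series_bundle`.
#' @export
series_bundle <- function(series_id, expression, probe_map, samples,
                          scale = c("log2", "linear16")) {
  scale <- match.arg(scale)
  b <- structure(
    list(series_id = series_id, expression = expression,
         probe_map = probe_map, samples = samples, scale = scale),
    class = "series_bundle"
  )
  validate_series_bundle(b)
  b
}

validate_series_bundle <- function(b) {
  if (!is.matrix(b$expression) || !is.numeric(b$expression))
    stopf("series %s: expression must be a numeric matrix", b$series_id)
  if (any(!is.finite(b$expression)))
    stopf("series %s: expression contains non-finite values", b$series_id)
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(b$probe_map)))
    stopf("series %s: probe_map must have columns probe_id, gene_symbol", b$series_id)
  unmapped <- setdiff(rownames(b$expression), b$probe_map$probe_id)
  if (length(unmapped))
    stopf("series %s: probes missing from probe_map: %s", b$series_id,
          paste(utils::head(unmapped, 5), collapse = ", "))
  need_s <- c("sample_id", "series_id", "class_label", "country",
              "platform", "technology")
  miss <- setdiff(need_s, names(b$samples))
  if (length(miss))
    stopf("series %s: samples annotation missing column(s): %s",
          b$series_id, paste(miss, collapse = ", "))
  if (ncol(b$expression) != nrow(b$samples))
    stopf("series %s: %d expression columns but %d sample annotations",
          b$series_id, ncol(b$expression), nrow(b$samples))
  if (!identical(colnames(b$expression), b$samples$sample_id))
    stopf("series %s: expression column names do not match sample_id order",
          b$series_id)
  if (anyDuplicated(b$samples$sample_id))
    stopf("series %s: duplicated sample ids", b$series_id)
  if (b$scale == "linear16") {
    if (min(b$expression) < 0 || max(b$expression) > 65535 * (1 + 1e-9))
      stopf("series %s: linear16 values must lie in [0, 65535] (observed range [%g, %g])",
            b$series_id, min(b$expression), max(b$expression))
  }
  invisible(b)
}

#' @export
print.series_bundle <- function(x, ...) {
  cat(sprintf("Series bundle %s: %d probes x %d samples (%s scale)\n",
              x$series_id, nrow(x$expression), ncol(x$expression), x$scale))
  cat(sprintf("  classes: %s\n",
              paste(sort(unique(x$samples$class_label)), collapse = ", ")))
  invisible(x)
}

#' Write / read a series bundle as a directory of TSV files
#'
#' The on-disk form is a directory holding three UTF-8 tab-delimited files
#' with header rows: `expression.tsv` (first column `probe_id`, one column
#' per sample), `probes.tsv` (`probe_id`, `gene_symbol`) and `samples.tsv`
#' (`sample_id`, `series_id`, `class_label`, `country`, `platform`,
#' `technology`, `scale`). Values round-trip to at least six decimal places.
#'
#' @param bundle A `series_bundle`.
#' @param directory Target directory (created if needed).
#' @return `write_series_bundle` returns the paths written, invisibly;
#'   `read_series_bundle` returns a `series_bundle`.
#' @export
write_series_bundle <- function(bundle, directory) {
  validate_series_bundle(bundle)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(directory, "expression.tsv")
  pf <- file.path(directory, "probes.tsv")
  sf <- file.path(directory, "samples.tsv")
  edf <- data.frame(probe_id = rownames(bundle$expression),
                    bundle$expression, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(edf, ef, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(bundle$probe_map, pf, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  sdf <- bundle$samples
  sdf$scale <- bundle$scale
  utils::write.table(sdf, sf, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(expression = ef, probes = pf, samples = sf))
}

#' @rdname write_series_bundle
#' @export
read_series_bundle <- function(directory) {
  ef <- file.path(directory, "expression.tsv")
  pf <- file.path(directory, "probes.tsv")
  sf <- file.path(directory, "samples.tsv")
  for (f in c(ef, pf, sf)) {
    if (!file.exists(f)) stopf("missing bundle file: %s", f)
  }
  edf <- utils::read.table(ef, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (names(edf)[1] != "probe_id")
    stopf("%s: first column must be probe_id", ef)
  num <- as.matrix(edf[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(num), nrow(num), ncol(num),
                                     dimnames = list(edf$probe_id, colnames(num))))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1, ]
    stopf("%s: non-numeric cell at row %d (probe %s), column '%s'",
          ef, bad[1], edf$probe_id[bad[1]], colnames(num)[bad[2]])
  }
  pm <- utils::read.table(pf, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "gene_symbol"), names(pm))
  if (length(miss))
    stopf("%s: missing column(s): %s", pf, paste(miss, collapse = ", "))
  sm <- utils::read.table(sf, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need_s <- c("sample_id", "series_id", "class_label", "country",
              "platform", "technology", "scale")
  miss <- setdiff(need_s, names(sm))
  if (length(miss))
    stopf("%s: missing column(s): %s", sf, paste(miss, collapse = ", "))
  scale <- unique(sm$scale)
  if (length(scale) != 1)
    stopf("%s: inconsistent scale column", sf)
  series_bundle(
    series_id = unique(sm$series_id)[1],
    expression = storage,
    probe_map = pm[, c("probe_id", "gene_symbol")],
    samples = sm[, setdiff(need_s, "scale")],
    scale = scale
  )
}
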