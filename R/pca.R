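#' PCA of expressed log expression, samples as observations
#'
#' Principal component analysis of `log2(FPKM + 1)` with samples as
#' observations and transcripts as (centered, unscaled) features. By
#' default transcripts are filtered to those whose mean `log2(FPKM + 1)`
#' over replicates exceeds 1.0 in at least one tissue. Component signs are
#' canonicalized (the largest-magnitude loading of each component is made
#' positive) so repeated runs agree.
#'
#' @param log_expr matrix transcripts x samples of `log2(FPKM + 1)` values.
#' @param metadata sample metadata aligned to columns; needed for the
#'   expressed filter and downstream bootstrap.
#' @param expressed_filter logical per-transcript vector, or `NULL` to
#'   apply the mean-log > `filter_threshold` per-tissue rule, or `FALSE`
#'   to keep all rows.
#' @param filter_threshold threshold on mean `log2(FPKM + 1)` per tissue.
#' @return object of class `pca_axis`: `scores` (samples x components),
#'   `loadings` (transcripts x components), `variance_explained`
#'   (fractions summing to 1 over all components), `center`,
#'   `transcripts`, `metadata`.
#' @export
run_pca <- function(log_expr, metadata = NULL, expressed_filter = NULL,
                    filter_threshold = 1.0) {
  x <- as.matrix(log_expr)
  if (is.null(expressed_filter)) {
    if (is.null(metadata))
      stop("metadata needed to apply the per-tissue expressed filter")
    tm <- tissue_means(x, metadata)
    expressed_filter <- rowSums(tm$mean > filter_threshold) > 0
  } else if (identical(expressed_filter, FALSE)) {
    expressed_filter <- rep(TRUE, nrow(x))
  }
  x <- x[expressed_filter, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 transcripts and >= 2 samples after filtering")
  if (all(apply(x, 1, stats::var) == 0)) stop("degenerate all-constant matrix")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, center = pc$center,
                 transcripts = rownames(x), metadata = metadata),
            class = "pca_axis")
}

#' @export
print.pca_axis <- function(x, ...) {
  k <- min(5, length(x$variance_explained))
  cat(sprintf("pca_axis: %d samples x %d transcripts\n",
              nrow(x$scores), length(x$transcripts)))
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$variance_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap confidence intervals for PCA
#'
#' Stratified bootstrap: replicate samples are resampled with replacement
#' within each tissue, preserving the design; confidence intervals are
#' formed for the component variance fractions and (optionally) the
#' loadings of one component, after sign-aligning every bootstrap
#' replicate to the point estimate. Tissues with a single replicate cannot
#' be stratified and are excluded with a warning.
#'
#' The default interval is the basic (reflected) bootstrap,
#' `[2*point - q_hi, 2*point - q_lo]`: resampling with replacement
#' duplicates samples and systematically inflates the leading eigenvalue
#' fraction, so raw percentile intervals for variance fractions sit above
#' the estimand and badly undercover; reflecting the bootstrap
#' distribution about the point estimate cancels that first-order bias.
#' Raw percentile intervals remain available via `method`.
#'
#' @param log_expr matrix transcripts x samples (already filtered; pass the
#'   rows you analysed, e.g. `pca$transcripts`).
#' @param metadata sample metadata aligned to columns.
#' @param n_boot bootstrap replicates (default 10000).
#' @param ci two-sided confidence level (default 0.99).
#' @param seed mandatory RNG seed.
#' @param components components to summarize variance fractions for.
#' @param loading_component component whose loadings get CIs, or `NULL` to
#'   skip (much faster).
#' @param method `"basic"` (reflected, default) or `"percentile"`.
#' @return list with `var_ci` (components x lo/hi), `var_point`,
#'   `loading_ci` (transcripts x lo/hi or `NULL`), `n_boot`, `ci`, `seed`.
#' @export
bootstrap_pca <- function(log_expr, metadata, n_boot = 10000, ci = 0.99,
                          seed, components = 1:2, loading_component = NULL,
                          method = c("basic", "percentile")) {
  if (missing(seed)) stop("seed is mandatory")
  method <- match.arg(method)
  set.seed(seed)
  x <- as.matrix(log_expr)
  tiss <- metadata$tissue
  tab <- table(tiss)
  singleton <- names(tab)[tab < 2]
  if (length(singleton) > 0) {
    warning("excluding single-replicate tissue(s): ",
            paste(singleton, collapse = ", "))
    keep <- !(tiss %in% singleton)
    x <- x[, keep, drop = FALSE]
    tiss <- tiss[keep]
  }
  idx_by_tissue <- split(seq_along(tiss), tiss)

  point <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve_point <- point$sdev^2 / sum(point$sdev^2)
  components <- components[components <= length(ve_point)]

  ve_boot <- matrix(NA_real_, n_boot, length(components))
  ld_boot <- if (!is.null(loading_component))
    matrix(NA_real_, n_boot, nrow(x)) else NULL
  for (b in seq_len(n_boot)) {
    cols <- unlist(lapply(idx_by_tissue, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    xb <- x[, cols, drop = FALSE]
    if (is.null(loading_component)) {
      xbt <- t(xb)
      xbt <- sweep(xbt, 2, colMeans(xbt))  # center transcripts
      d2 <- svd(xbt, nu = 0, nv = 0)$d^2
      ve_boot[b, ] <- d2[components] / sum(d2)
    } else {
      pb <- stats::prcomp(t(xb), center = TRUE, scale. = FALSE)
      ve_boot[b, ] <- pb$sdev[components]^2 / sum(pb$sdev^2)
      v <- pb$rotation[, loading_component]
      if (sum(v * point$rotation[, loading_component]) < 0) v <- -v
      ld_boot[b, ] <- v
    }
  }
  a <- (1 - ci) / 2
  interval <- function(boot, point, lower = -Inf, upper = Inf) {
    q <- t(apply(boot, 2, stats::quantile, probs = c(a, 1 - a)))
    out <- if (method == "basic")
      cbind(2 * point - q[, 2], 2 * point - q[, 1])
    else q
    out <- pmin(pmax(out, lower), upper)
    colnames(out) <- c("lo", "hi")
    out
  }
  var_ci <- interval(ve_boot, ve_point[components], lower = 0, upper = 1)
  rownames(var_ci) <- paste0("PC", components)
  loading_ci <- NULL
  if (!is.null(ld_boot)) {
    loading_ci <- interval(ld_boot, point$rotation[, loading_component])
    rownames(loading_ci) <- rownames(x)
  }
  list(var_ci = var_ci,
       var_point = stats::setNames(ve_point[components],
                                   paste0("PC", components)),
       loading_ci = loading_ci, n_boot = n_boot, ci = ci, seed = seed)
}

#' Per-transcript correlation with a principal component
#'
#' Pearson correlation between each transcript's sample-wise log
#' expression and the score vector of the chosen component; `R^2 = r^2`.
#' Constant transcripts have undefined correlation and are reported `NA`.
#'
#' @param log_expr matrix transcripts x samples (same samples as the PCA).
#' @param pca a `pca_axis` from [run_pca()].
#' @param component which component (default 1).
#' @return data.frame `transcript_id`, `r`, `r_squared`.
#' @export
correlate_with_pc <- function(log_expr, pca, component = 1) {
  x <- as.matrix(log_expr)
  if (ncol(x) != nrow(pca$scores))
    stop("sample mismatch between log_expr and PCA scores")
  s <- pca$scores[, component]
  r <- suppressWarnings(as.vector(stats::cor(t(x), s)))
  data.frame(transcript_id = rownames(x), r = r, r_squared = r^2,
             stringsAsFactors = FALSE)
}

#' Rank transcripts by squared correlation with a component
#'
#' @param correlations output of [correlate_with_pc()].
#' @param top_n rows to return (fewer if not enough non-missing).
#' @return data.frame sorted by descending `r_squared` (ties broken by
#'   `transcript_id`), with the sign of `r` retained.
#' @export
rank_by_pc_correlation <- function(correlations, top_n = 10) {
  ok <- correlations[!is.na(correlations$r), , drop = FALSE]
  ok <- ok[order(-ok$r_squared, ok$transcript_id), , drop = FALSE]
  utils::head(ok, top_n)
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' Analytic alternative to the bootstrap for marker-gene correlation CIs.
#'
#' @param r observed correlation.
#' @param n number of paired observations.
#' @param level confidence level (default 0.99).
#' @return named vector `lo`, `hi` on the correlation scale.
#' @export
correlation_ci <- function(r, n, level = 0.99) {
  if (n < 4) stop("need n >= 4")
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(lo = tanh(z - q * se), hi = tanh(z + q * se))
}
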