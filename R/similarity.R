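#' Tissue-mean log-expression profiles for clustering
#'
#' Builds the tissues x transcripts profile matrix the dendrograms operate
#' on: per-tissue mean `log2(FPKM + 1)`, restricted by default to
#' expressed transcripts (mean FPKM > `threshold` in at least one tissue).
#'
#' @param fpkm an `fpkm_matrix` or FPKM matrix.
#' @param metadata sample metadata (taken from the `fpkm_matrix` if omitted).
#' @param expressed_only restrict to expressed transcripts (default TRUE).
#' @param threshold FPKM expressed cutoff.
#' @param pseudocount log offset.
#' @return matrix tissues x transcripts.
#' @export
tissue_profiles <- function(fpkm, metadata = NULL, expressed_only = TRUE,
                            threshold = 1.0, pseudocount = 1) {
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  tm <- tissue_means(fpkm, metadata)
  keep <- if (expressed_only) rowSums(tm$mean > threshold) > 0
          else rep(TRUE, nrow(tm$mean))
  t(log2(tm$mean[keep, , drop = FALSE] + pseudocount))
}

#' Pairwise Euclidean distances between tissue profiles
#'
#' @param profiles matrix tissues x features (e.g. from
#'   [tissue_profiles()]).
#' @return a `dist` object with tissue labels.
#' @export
euclidean_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 tissues")
  if (any(!is.finite(profiles))) stop("profiles contain missing values")
  stats::dist(profiles, method = "euclidean")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates a distance matrix with the requested linkage (default
#' complete, which guarantees monotone merge heights). The input is
#' reordered lexicographically by label before clustering so ties are
#' broken deterministically and identical inputs yield identical trees.
#'
#' @param d a `dist` object or symmetric distance matrix with labels.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return an `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  m <- as.matrix(d)
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(m), method = linkage)
}

#' Restrict an expression matrix to a gene family
#'
#' Selects rows whose gene symbol matches a prefix (case-insensitive, e.g.
#' `"MYH"` for the myosin heavy chains, `"HOX"` for the homeobox cluster)
#' or an explicit symbol list; the same clustering machinery then applies
#' to the subset.
#'
#' @param expr matrix with transcripts in rows (tissue means or samples in
#'   columns).
#' @param annotation annotation rows aligned to `expr` rows.
#' @param family a single prefix string, or a character vector / `gene_list`
#'   of exact symbols.
#' @return the matching rows of `expr`.
#' @export
subset_by_family <- function(expr, annotation, family) {
  sym <- toupper(annotation$gene_symbol)
  if (inherits(family, "gene_list")) family <- family$members
  hit <- if (length(family) == 1)
    startsWith(sym, toupper(family))
  else sym %in% toupper(family)
  if (!any(hit)) stop("no gene matches the requested family")
  expr[hit, , drop = FALSE]
}

#' Z-score matrix rows
#'
#' Centers and scales each row to mean 0, sample (n-1) SD 1, the usual
#' heat-map row normalization. Constant rows become all-zero and are
#' flagged in attribute `constant_rows`.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return z-scored matrix.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need >= 2 columns to z-score rows")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  const <- s == 0
  s[const] <- 1
  z <- (m - mu) / s
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}
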