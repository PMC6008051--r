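#' FPKM with mitochondrial reads excluded from the depth denominator
#'
#' Computes `FPKM_ij = 1e9 * c_ij / (l_i * N_j)` where `c_ij` is the unique
#' read count for transcript `i` in sample `j`, `l_i` the transcript length
#' in bp, and `N_j` the per-sample depth summed over *nuclear* transcripts
#' only. Mitochondrial transcripts still receive FPKM values (their
#' numerator is unchanged) but never contribute to any sample's
#' denominator, so tissues with very different mitochondrial loads remain
#' comparable on the nuclear transcriptome.
#'
#' @param dataset an [expression_dataset()].
#' @return object of class `fpkm_matrix`: list with `values` (transcripts x
#'   samples), `denominator_per_sample` (nuclear unique aligned reads
#'   `N_j`) and `annotation`/`metadata` carried through for downstream
#'   stages.
#' @export
compute_fpkm <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  counts <- dataset$counts
  mito <- dataset$annotation$is_mitochondrial
  N <- colSums(counts[!mito, , drop = FALSE])
  if (any(N == 0))
    stop("sample with zero nuclear-aligned reads: ",
         paste(colnames(counts)[N == 0], collapse = ", "))
  l <- dataset$annotation$length_bp
  values <- 1e9 * sweep(counts / l, 2, N, "/")
  structure(list(values = values, denominator_per_sample = N,
                 metadata = dataset$metadata,
                 annotation = dataset$annotation),
            class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat(sprintf("fpkm_matrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  nuclear depth range: %s - %s reads\n",
              format(min(x$denominator_per_sample), big.mark = ","),
              format(max(x$denominator_per_sample), big.mark = ",")))
  invisible(x)
}

fpkm_values <- function(x) {
  if (inherits(x, "fpkm_matrix")) x$values else as.matrix(x)
}

#' Log-transform an FPKM matrix
#'
#' Elementwise `log2(FPKM + pseudocount)`; the pipeline uses
#' `log2(FPKM + 1)` throughout for every log-scale computation (ANOVA,
#' clustering profiles, PCA, correlations).
#'
#' @param fpkm an `fpkm_matrix` or plain non-negative matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return numeric matrix of the same shape.
#' @export
log_transform <- function(fpkm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  v <- fpkm_values(fpkm)
  if (any(v < 0)) stop("fpkm values must be >= 0")
  log2(v + pseudocount)
}

#' Per-tissue means and standard errors
#'
#' Arithmetic mean and SEM of each transcript over a tissue's replicate
#' samples, on whatever scale the input matrix is on (raw FPKM or
#' log2(FPKM+1)). SEM uses the sample SD over replicates; a single-replicate
#' tissue gets `NA` SEM.
#'
#' @param mat matrix transcripts x samples (or an `fpkm_matrix`).
#' @param metadata sample metadata aligned to the columns of `mat`.
#' @param tissues optional subset/order of tissues; default all, in first
#'   appearance order.
#' @return list with `mean` and `sem` (transcripts x tissues matrices) and
#'   `n` (replicates per tissue).
#' @export
tissue_means <- function(mat, metadata, tissues = NULL) {
  v <- fpkm_values(mat)
  stopifnot(ncol(v) == nrow(metadata))
  if (is.null(tissues)) tissues <- unique(metadata$tissue)
  unknown <- setdiff(tissues, metadata$tissue)
  if (length(unknown) > 0)
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "))
  mean_m <- matrix(NA_real_, nrow(v), length(tissues),
                   dimnames = list(rownames(v), tissues))
  sem_m <- mean_m
  n <- integer(length(tissues)); names(n) <- tissues
  for (t in tissues) {
    cols <- which(metadata$tissue == t)
    n[t] <- length(cols)
    sub <- v[, cols, drop = FALSE]
    mean_m[, t] <- rowMeans(sub)
    sem_m[, t] <- if (length(cols) > 1)
      sqrt(rowSums((sub - rowMeans(sub))^2) / (length(cols) - 1)) /
        sqrt(length(cols))
    else NA_real_
  }
  list(mean = mean_m, sem = sem_m, n = n)
}
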