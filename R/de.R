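#' Call transcripts expressed per tissue
#'
#' A transcript is expressed in a tissue when its mean FPKM over that
#' tissue's replicates strictly exceeds `threshold` (default 1.0).
#'
#' @param fpkm an `fpkm_matrix` or FPKM matrix.
#' @param metadata sample metadata aligned to the matrix columns (taken
#'   from the `fpkm_matrix` if omitted).
#' @param threshold strict FPKM cutoff.
#' @return list with `expressed` (logical transcripts x tissues matrix),
#'   `any_tissue`, `all_tissue` (logical vectors) and `threshold`.
#' @export
call_expressed <- function(fpkm, metadata = NULL, threshold = 1.0) {
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  tm <- tissue_means(fpkm, metadata)
  expressed <- tm$mean > threshold
  list(expressed = expressed,
       any_tissue = rowSums(expressed) > 0,
       all_tissue = rowSums(expressed) == ncol(expressed),
       threshold = threshold)
}

#' Core-set Venn regions across muscle classes
#'
#' For each muscle class, the class core is the set of transcripts
#' expressed in *every* tissue of that class; the function returns the
#' sizes of all seven regions of the three-class Venn diagram plus the
#' triple-intersection membership (the "core" transcripts expressed in
#' every tissue of every class).
#'
#' @param calls output of [call_expressed()].
#' @param class_map named character vector mapping tissue -> muscle class.
#' @return list with `region_counts` (named 7-vector), `class_cores`
#'   (per-class transcript ID sets) and `core` (triple intersection IDs).
#' @export
venn_core_sets <- function(calls, class_map) {
  classes <- sort(unique(class_map))
  if (length(classes) != 3)
    stop("venn_core_sets expects exactly three muscle classes")
  ids <- rownames(calls$expressed)
  in_core <- sapply(classes, function(cl) {
    tiss <- names(class_map)[class_map == cl]
    tiss <- intersect(tiss, colnames(calls$expressed))
    if (length(tiss) == 0) stop("empty class: ", cl)
    rowSums(calls$expressed[, tiss, drop = FALSE]) == length(tiss)
  })
  a <- in_core[, 1]; b <- in_core[, 2]; c <- in_core[, 3]
  counts <- c(sum(a & !b & !c), sum(!a & b & !c), sum(!a & !b & c),
              sum(a & b & !c), sum(a & !b & c), sum(!a & b & c),
              sum(a & b & c))
  names(counts) <- c(paste0(classes, "_only"),
                     paste(classes[1], classes[2], sep = "_"),
                     paste(classes[1], classes[3], sep = "_"),
                     paste(classes[2], classes[3], sep = "_"),
                     "all_three")
  list(region_counts = counts,
       class_cores = stats::setNames(
         lapply(classes, function(cl) ids[in_core[, cl]]), classes),
       core = ids[a & b & c])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorized one-way fixed-effects ANOVA over matrix rows.
# Degenerate rules: all groups identical constants -> F = 0, p = 1;
# zero within-group variance with real between-group signal -> p = 1e-300.
row_anova <- function(mat, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- ncol(mat)
  if (k < 2) stop("need at least 2 groups")
  counts <- as.vector(table(groups))
  if (any(counts < 2)) stop("every group needs >= 2 replicates")
  G <- stats::model.matrix(~ 0 + groups)            # n x k indicator
  gsum <- mat %*% G                                  # row sums per group
  gmean <- sweep(gsum, 2, counts, "/")
  grand <- rowMeans(mat)
  ssb <- rowSums(sweep(gmean - grand, 2, counts, function(d, w) d^2 * w))
  sst <- rowSums((mat - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  scale <- pmax(sst, 1e-300)
  F <- (ssb / df1) / pmax(ssw / df2, 1e-300)
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  flat <- sst <= 1e-12 * pmax(rowMeans(mat^2), 1) | sst == 0
  degenerate <- !flat & ssw <= 1e-12 * scale
  F[flat] <- 0; p[flat] <- 1
  p[degenerate] <- 1e-300
  list(F = F, p = p, df1 = df1, df2 = df2)
}

# shared DE engine: expressed filter, row ANOVA, BH within the tested set,
# fold change on raw-FPKM group means with an epsilon pseudocount
group_de <- function(fpkm, metadata, sample_idx, groups,
                     q_thresh, fc_thresh, epsilon, expressed_threshold,
                     pseudocount) {
  v <- fpkm_values(fpkm)[, sample_idx, drop = FALSE]
  md <- metadata[sample_idx, , drop = FALSE]
  groups <- factor(groups)
  gmeans <- vapply(levels(groups), function(g)
    rowMeans(v[, groups == g, drop = FALSE]), numeric(nrow(v)))
  if (is.null(dim(gmeans)))
    gmeans <- matrix(gmeans, nrow = 1,
                     dimnames = list(rownames(v), levels(groups)))
  expressed <- rowSums(gmeans > expressed_threshold) > 0
  tested <- which(expressed)
  if (length(tested) == 0) stop("no transcripts pass the expressed filter")
  logm <- log2(v[tested, , drop = FALSE] + pseudocount)
  an <- row_anova(logm, groups)
  q <- bh_qvalues(an$p)
  gm <- gmeans[tested, , drop = FALSE]
  mx <- apply(gm, 1, max); mn <- apply(gm, 1, min)
  fc <- (mx + epsilon) / (mn + epsilon)
  res <- data.frame(transcript_id = rownames(v)[tested],
                    F = an$F, p = an$p, q = q, fold_change = fc,
                    max_group = colnames(gm)[max.col(gm, "first")],
                    min_group = colnames(gm)[max.col(-gm, "first")],
                    significant = q < q_thresh & fc > fc_thresh,
                    stringsAsFactors = FALSE)
  attr(res, "group_means_fpkm") <- gm
  gml <- vapply(levels(groups), function(g)
    rowMeans(logm[, groups == g, drop = FALSE]), numeric(nrow(logm)))
  if (is.null(dim(gml)))
    gml <- matrix(gml, nrow = 1,
                  dimnames = list(rownames(logm), levels(groups)))
  attr(res, "group_means_log") <- gml
  attr(res, "df") <- c(an$df1, an$df2)
  attr(res, "n_tested") <- length(tested)
  res
}

#' One-way ANOVA differential expression across a tissue set
#'
#' Classical fixed-effects one-way ANOVA of `log2(FPKM + 1)` per
#' transcript over the tissues of `tissue_subset`, BH q-values over the
#' tested set, and a max/min fold change on raw-FPKM tissue means.
#' Transcripts are pre-filtered to those expressed (mean FPKM >
#' `expressed_threshold`) in at least one subset tissue. A transcript is
#' significant when `q < q_thresh`, `fold_change > fc_thresh` and it
#' passed the expressed filter.
#'
#' @param fpkm an `fpkm_matrix` or FPKM matrix.
#' @param metadata sample metadata (taken from the `fpkm_matrix` if
#'   omitted).
#' @param tissue_subset tissues to compare (default: all; needs >= 2, each
#'   with >= 2 replicates).
#' @param q_thresh,fc_thresh significance thresholds (defaults q < 0.01,
#'   fold change > 2.0).
#' @param epsilon pseudocount inside the fold-change ratio (default 0.1).
#' @param expressed_threshold FPKM expressed cutoff (default 1.0).
#' @param pseudocount log-transform offset (default 1).
#' @return data.frame with `transcript_id`, `F`, `p`, `q`, `fold_change`,
#'   `max_group`, `min_group`, `significant`; per-group FPKM and log means
#'   attached as attributes `group_means_fpkm` / `group_means_log`.
#' @export
anova_de <- function(fpkm, metadata = NULL, tissue_subset = NULL,
                     q_thresh = 0.01, fc_thresh = 2.0, epsilon = 0.1,
                     expressed_threshold = 1.0, pseudocount = 1) {
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  if (is.null(tissue_subset)) tissue_subset <- unique(metadata$tissue)
  if (length(tissue_subset) < 2) stop("tissue_subset needs >= 2 tissues")
  idx <- which(metadata$tissue %in% tissue_subset)
  group_de(fpkm, metadata, idx, metadata$tissue[idx],
           q_thresh, fc_thresh, epsilon, expressed_threshold, pseudocount)
}

#' Two-tissue differential expression
#'
#' The two-group case of [anova_de()] (equivalent to a pooled-variance
#' two-sided t-test; `F = t^2`), with a signed log2 fold change
#' `log2((meanA + eps) / (meanB + eps))` recorded alongside the
#' max/min-convention fold change.
#'
#' @inheritParams anova_de
#' @param tissue_a,tissue_b the two tissues compared; `log2_fc > 0` means
#'   higher in `tissue_a`.
#' @return as [anova_de()], plus columns `log2_fc` and `direction`
#'   (`"up_in_a"` / `"up_in_b"` / `"none"`).
#' @export
pairwise_de <- function(fpkm, metadata = NULL, tissue_a, tissue_b,
                        q_thresh = 0.01, fc_thresh = 2.0, epsilon = 0.1,
                        expressed_threshold = 1.0, pseudocount = 1) {
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  res <- anova_de(fpkm, metadata, c(tissue_a, tissue_b), q_thresh, fc_thresh,
                  epsilon, expressed_threshold, pseudocount)
  gm <- attr(res, "group_means_fpkm")
  lfc <- log2((gm[, tissue_a] + epsilon) / (gm[, tissue_b] + epsilon))
  res$log2_fc <- unname(lfc)
  res$direction <- ifelse(lfc > 0, "up_in_a", ifelse(lfc < 0, "up_in_b", "none"))
  attr(res, "tissues") <- c(tissue_a, tissue_b)
  res
}

#' Percent differentially expressed per tissue pair
#'
#' Runs [pairwise_de()] for every tissue pair and reports
#' `100 * n_significant / n_tested` in a symmetric matrix with a zero
#' diagonal. BH adjustment is per comparison, matching per-comparison
#' q-values.
#'
#' @inheritParams anova_de
#' @param tissues tissues to cross (default all).
#' @return symmetric numeric matrix of percentages.
#' @export
de_fraction_matrix <- function(fpkm, metadata = NULL, tissues = NULL,
                               q_thresh = 0.01, fc_thresh = 2.0,
                               epsilon = 0.1, expressed_threshold = 1.0) {
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  if (is.null(tissues)) tissues <- unique(metadata$tissue)
  k <- length(tissues)
  m <- matrix(0, k, k, dimnames = list(tissues, tissues))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    de <- pairwise_de(fpkm, metadata, tissues[i], tissues[j], q_thresh,
                      fc_thresh, epsilon, expressed_threshold)
    m[i, j] <- m[j, i] <- 100 * sum(de$significant) / nrow(de)
  }
  m
}

#' Percent DE at a grid of q-value thresholds
#'
#' One ANOVA per tissue subset, then the %DE (with the fold-change filter
#' applied throughout) at each threshold of `q_grid`. %DE is monotone
#' non-decreasing in q.
#'
#' @inheritParams anova_de
#' @param subsets named list of tissue character vectors.
#' @param q_grid increasing q thresholds in `(0, 1]`.
#' @return data.frame with columns `subset`, `q_thresh`, `percent_de`.
#' @export
de_threshold_sweep <- function(fpkm, metadata = NULL, subsets,
                               q_grid = c(1e-6, 1e-4, 0.01, 0.05),
                               fc_thresh = 2.0) {
  if (any(q_grid <= 0 | q_grid > 1)) stop("q_grid must lie in (0, 1]")
  if (is.null(metadata) && inherits(fpkm, "fpkm_matrix"))
    metadata <- fpkm$metadata
  out <- list()
  for (nm in names(subsets)) {
    de <- anova_de(fpkm, metadata, subsets[[nm]], q_thresh = 1,
                   fc_thresh = fc_thresh)
    pass_fc <- de$fold_change > fc_thresh
    for (q in q_grid)
      out[[length(out) + 1]] <- data.frame(
        subset = nm, q_thresh = q,
        percent_de = 100 * sum(de$q < q & pass_fc) / nrow(de),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
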