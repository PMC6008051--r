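#' Myh fiber-type composition per tissue
#'
#' For each tissue, the percent of Myh-aligning reads (or FPKM) attributed
#' to each myosin heavy chain gene: counts are summed over the tissue's
#' replicates per Myh gene and divided by the total over the whole list.
#' Percentages sum to 100 per tissue; a tissue with no Myh signal at all
#' gets `NA` percentages and is listed in attribute `zero_total_tissues`.
#'
#' @param dataset an `ExpressionDataset`.
#' @param myh_genes character vector of Myh gene symbols (case-insensitive).
#' @param basis `"reads"` (raw unique read counts, the figure-legend
#'   convention) or `"fpkm"` (length-corrected; read-level proportions are
#'   length-biased).
#' @param tissues optional tissue subset.
#' @return data.frame tissues x Myh genes of percentages, with the basis
#'   recorded in attribute `basis`.
#' @export
myh_composition <- function(dataset, myh_genes = c("MYH1", "MYH2", "MYH4", "MYH7"),
                            basis = c("reads", "fpkm"), tissues = NULL) {
  basis <- match.arg(basis)
  if (length(myh_genes) == 0) stop("empty Myh gene list")
  sym <- toupper(dataset$annotation$gene_symbol)
  rows <- which(sym %in% toupper(myh_genes))
  if (length(rows) == 0) stop("no Myh gene present in the annotation")
  vals <- if (basis == "reads") dataset$counts
          else compute_fpkm(dataset)$values
  vals <- vals[rows, , drop = FALSE]
  gene <- dataset$annotation$gene_symbol[rows]
  if (is.null(tissues)) tissues <- unique(dataset$metadata$tissue)
  out <- matrix(NA_real_, length(tissues), length(rows),
                dimnames = list(tissues, gene))
  zero <- character(0)
  for (t in tissues) {
    cols <- dataset$metadata$tissue == t
    tot <- rowSums(vals[, cols, drop = FALSE])  # per-gene sums over reps
    if (sum(tot) == 0) { zero <- c(zero, t); next }
    out[t, ] <- 100 * tot / sum(tot)
  }
  out <- as.data.frame(out)
  attr(out, "basis") <- basis
  attr(out, "zero_total_tissues") <- zero
  out
}

resolve_gene_row <- function(tissue_means, gene, annotation = NULL) {
  ids <- rownames(tissue_means)
  if (!is.null(annotation)) {
    hit <- which(toupper(annotation$gene_symbol) == toupper(gene))
    if (length(hit) >= 1) return(tissue_means[hit[1], ])
  }
  hit <- which(toupper(ids) == toupper(gene))
  if (length(hit) == 0) stop("gene not found: ", gene)
  tissue_means[hit[1], ]
}

#' Correlation of a marker gene with a reference gene across tissues
#'
#' Pearson correlation between two genes' per-tissue mean `log2(FPKM+1)`
#' values, one point per tissue (the fiber-type question: does a
#' fast/slow marker track Myh4 or Myh7 across muscles?).
#'
#' @param tissue_means_log matrix transcripts x tissues of mean
#'   `log2(FPKM + 1)` per tissue.
#' @param marker_gene,reference_gene gene symbols (resolved through
#'   `annotation` if given, else rownames).
#' @param annotation optional annotation aligned to the matrix rows.
#' @return list with `r`, `r_squared`, `n_tissues`.
#' @export
marker_correlation <- function(tissue_means_log, marker_gene, reference_gene,
                               annotation = NULL) {
  if (ncol(tissue_means_log) < 3) stop("need >= 3 tissues")
  x <- resolve_gene_row(tissue_means_log, marker_gene, annotation)
  y <- resolve_gene_row(tissue_means_log, reference_gene, annotation)
  if (stats::sd(y) == 0) stop("reference gene constant across tissues")
  r <- stats::cor(as.numeric(x), as.numeric(y))
  list(r = r, r_squared = r^2, n_tissues = ncol(tissue_means_log))
}

#' R-squared panel of fiber-type markers versus a reference gene
#'
#' Runs [marker_correlation()] for every marker and summarizes: the table
#' sorted by descending R-squared, the median R-squared, and how many
#' markers exceed R-squared 0.5.
#'
#' @inheritParams marker_correlation
#' @param marker_genes character vector of marker symbols.
#' @return list with `table` (gene, r, r_squared), `median_r_squared`,
#'   `n_above_0.5`.
#' @export
marker_panel_summary <- function(tissue_means_log, marker_genes,
                                 reference_gene, annotation = NULL) {
  if (length(marker_genes) == 0) stop("need >= 1 marker gene")
  rows <- lapply(marker_genes, function(g) {
    mc <- marker_correlation(tissue_means_log, g, reference_gene, annotation)
    data.frame(gene = g, r = mc$r, r_squared = mc$r_squared,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r_squared, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       median_r_squared = stats::median(tab$r_squared),
       n_above_0.5 = sum(tab$r_squared > 0.5))
}
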