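#' Tissue-specificity (tau) scores
#'
#' The tau index over per-tissue mean FPKM values `x`:
#' `tau = sum_i (1 - x_i / x_max) / (n - 1)`; 0 for perfectly uniform
#' expression, 1 for expression exclusive to a single tissue. Also reports
#' `max_fraction` (the max tissue mean over the sum of tissue means), the
#' maximizing tissue, and the mean log-scale expression. Transcripts with
#' all-zero means get `NA` scores.
#'
#' @param tissue_means_fpkm matrix transcripts x tissues of mean FPKM.
#' @param tissue_subset optional tissue subset (default all columns).
#' @param pseudocount offset for the reported log-scale mean expression.
#' @return data.frame `transcript_id`, `tau`, `max_tissue`,
#'   `max_fraction`, `mean_fpkm`, `mean_expression` (mean log2(FPKM+1)
#'   over tissues).
#' @export
specificity_scores <- function(tissue_means_fpkm, tissue_subset = NULL,
                               pseudocount = 1) {
  m <- as.matrix(tissue_means_fpkm)
  if (!is.null(tissue_subset)) m <- m[, tissue_subset, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 tissues")
  if (any(m < 0)) stop("tissue means must be >= 0")
  mx <- apply(m, 1, max)
  tot <- rowSums(m)
  n <- ncol(m)
  tau <- rowSums(1 - m / ifelse(mx > 0, mx, 1)) / (n - 1)
  tau[mx == 0] <- NA_real_
  mf <- ifelse(tot > 0, mx / tot, NA_real_)
  data.frame(transcript_id = rownames(m),
             tau = tau,
             max_tissue = colnames(m)[max.col(m, "first")],
             max_fraction = mf,
             mean_fpkm = rowMeans(m),
             mean_expression = rowMeans(log2(m + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Most tissue-specific genes for one tissue
#'
#' Transcripts whose maximizing tissue is `tissue`, ranked by tau then
#' max_fraction (both descending) and filtered to mean FPKM at or above
#' `min_expression`.
#'
#' @param scores output of [specificity_scores()].
#' @param tissue tissue of interest.
#' @param n maximum rows returned (fewer if fewer candidates).
#' @param min_expression minimum mean FPKM across tissues.
#' @return ranked data.frame subset of `scores`.
#' @export
top_specific_genes <- function(scores, tissue, n = 20, min_expression = 0) {
  cand <- scores[!is.na(scores$tau) & scores$max_tissue == tissue &
                   scores$mean_fpkm >= min_expression, , drop = FALSE]
  cand <- cand[order(-cand$tau, -cand$max_fraction, cand$transcript_id), ,
               drop = FALSE]
  utils::head(cand, n)
}

as_symbol_set <- function(x) {
  if (inherits(x, "gene_list")) x$members else unique(toupper(as.character(x)))
}

#' Three-set Venn of DE genes, disease genes and drug targets
#'
#' Region sizes of the three-set Venn over case-normalized gene symbols,
#' plus the "sliver" of druggable DE genes with no known disease link
#' (`drug` intersect `de` minus `disease`).
#'
#' @param de_genes,disease,drug_targets `gene_list`s or character vectors.
#' @return list with `region_counts` (7 named sizes), `sliver` (member
#'   symbols of drug-and-DE-not-disease), `n_union`.
#' @export
gene_set_venn <- function(de_genes, disease, drug_targets) {
  a <- as_symbol_set(de_genes); b <- as_symbol_set(disease)
  c <- as_symbol_set(drug_targets)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  counts <- c(de_only = sum(ina & !inb & !inc),
              disease_only = sum(!ina & inb & !inc),
              drug_only = sum(!ina & !inb & inc),
              de_disease = sum(ina & inb & !inc),
              de_drug = sum(ina & !inb & inc),
              disease_drug = sum(!ina & inb & inc),
              all_three = sum(ina & inb & inc))
  list(region_counts = counts,
       sliver = u[ina & inc & !inb],
       n_union = length(u))
}

#' Candidate myokines: secreted, differentially expressed, well expressed
#'
#' Intersects a secreted-protein gene list with the significant transcripts
#' of a skeletal-muscle DE analysis, keeping genes whose maximum tissue
#' mean FPKM exceeds `min_fpkm`; reports the max/min tissues and their
#' (epsilon-damped) expression ratio.
#'
#' @param de_results output of [anova_de()] over the skeletal subset.
#' @param tissue_means_fpkm matrix transcripts x tissues of mean FPKM.
#' @param secreted `gene_list` or character vector of secreted-protein
#'   gene symbols.
#' @param annotation annotation mapping transcript IDs to gene symbols.
#' @param min_fpkm minimum max-tissue mean FPKM (default 10).
#' @param epsilon pseudocount in the max/min ratio.
#' @return data.frame `transcript_id`, `gene_symbol`, `max_tissue`,
#'   `max_fpkm`, `min_tissue`, `min_fpkm`, `ratio`, sorted by descending
#'   max FPKM.
#' @export
myokine_candidates <- function(de_results, tissue_means_fpkm, secreted,
                               annotation, min_fpkm = 10, epsilon = 0.1) {
  sec <- as_symbol_set(secreted)
  if (length(sec) == 0) stop("empty secreted list")
  sig_ids <- de_results$transcript_id[de_results$significant]
  sym <- toupper(annotation$gene_symbol[match(sig_ids,
                                              annotation$transcript_id)])
  keep <- sym %in% sec
  ids <- sig_ids[keep]; sym <- sym[keep]
  m <- as.matrix(tissue_means_fpkm)[ids, , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(transcript_id = character(0), gene_symbol = character(0),
                      max_tissue = character(0), max_fpkm = numeric(0),
                      min_tissue = character(0), min_fpkm = numeric(0),
                      ratio = numeric(0)))
  mx <- apply(m, 1, max); mn <- apply(m, 1, min)
  out <- data.frame(transcript_id = ids, gene_symbol = sym,
                    max_tissue = colnames(m)[max.col(m, "first")],
                    max_fpkm = mx,
                    min_tissue = colnames(m)[max.col(-m, "first")],
                    min_fpkm = mn,
                    ratio = (mx + epsilon) / (mn + epsilon),
                    stringsAsFactors = FALSE)
  out <- out[out$max_fpkm > min_fpkm, , drop = FALSE]
  out[order(-out$max_fpkm), , drop = FALSE]
}
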