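#' Pair two species' expression matrices through an ortholog table
#'
#' Restricts both matrices to one-to-one ortholog pairs present in both,
#' returning row-aligned matrices. Unpaired rows (either side) are counted
#' in attribute `n_unpaired`.
#'
#' @param expr_a,expr_b matrices with transcript/gene IDs as rownames
#'   (tissue means or samples in columns).
#' @param orthologs one-to-one [ortholog_table()] with `species_a_id`
#'   matching `expr_a` rownames and `species_b_id` matching `expr_b`.
#' @return list with `a`, `b` (row-aligned matrices), `pairs` (the table
#'   rows used).
#' @export
pair_orthologs <- function(expr_a, expr_b, orthologs) {
  keep <- orthologs$species_a_id %in% rownames(expr_a) &
    orthologs$species_b_id %in% rownames(expr_b)
  pairs <- orthologs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no ortholog pair present in both datasets")
  a <- as.matrix(expr_a)[pairs$species_a_id, , drop = FALSE]
  b <- as.matrix(expr_b)[pairs$species_b_id, , drop = FALSE]
  n_unpaired <- (nrow(expr_a) - nrow(pairs)) + (nrow(expr_b) - nrow(pairs)) +
    sum(!keep)
  out <- list(a = a, b = b, pairs = pairs)
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Between-species expression correlation in one tissue
#'
#' Pearson R-squared between the two species' `log2(FPKM + 1)` tissue
#' means over paired orthologs. By default restricted to orthologs
#' expressed (FPKM > `expressed_threshold`) in at least one species.
#'
#' @param paired output of [pair_orthologs()] on FPKM tissue-mean matrices.
#' @param tissue tissue column present in both matrices.
#' @param expressed_only restrict to expressed-in-either orthologs.
#' @param expressed_threshold FPKM cutoff for the filter.
#' @param pseudocount log offset.
#' @return list with `r`, `r_squared`, `n_genes`.
#' @export
species_correlation <- function(paired, tissue, expressed_only = TRUE,
                                expressed_threshold = 1.0, pseudocount = 1) {
  if (!(tissue %in% colnames(paired$a)) || !(tissue %in% colnames(paired$b)))
    stop("tissue absent from one species: ", tissue)
  xa <- paired$a[, tissue]; xb <- paired$b[, tissue]
  if (expressed_only) {
    keep <- xa > expressed_threshold | xb > expressed_threshold
    xa <- xa[keep]; xb <- xb[keep]
  }
  if (length(xa) < 3) stop("fewer than 3 shared genes")
  r <- stats::cor(log2(xa + pseudocount), log2(xb + pseudocount))
  list(r = r, r_squared = r^2, n_genes = length(xa))
}

map_b_to_a <- function(ids_b, orthologs) {
  orthologs$species_a_id[match(ids_b, orthologs$species_b_id)]
}

#' Shared differential expression and direction concordance
#'
#' Given each species' own two-tissue DE table (from [pairwise_de()] on
#' the same tissue contrast), finds the orthologs significant in both and
#' the fraction whose log2 fold changes share sign. A zero fold change
#' counts as discordant unless both are zero.
#'
#' @param de_a,de_b [pairwise_de()] results for species A and B.
#' @param orthologs optional ortholog table (B IDs are mapped onto A's ID
#'   space; omit when the tables already share IDs).
#' @return list of class `concordance_result`: `n_shared_de`,
#'   `n_same_direction`, `percent_same` (`NA` when nothing is shared),
#'   and `per_gene` (id, `log2_fc_a`, `log2_fc_b`, `same`).
#' @export
de_overlap_concordance <- function(de_a, de_b, orthologs = NULL) {
  ta <- attr(de_a, "tissues"); tb <- attr(de_b, "tissues")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb))
    stop("DE tables computed on different tissue contrasts: ",
         paste(ta, collapse = "/"), " vs ", paste(tb, collapse = "/"))
  ids_b <- de_b$transcript_id
  if (!is.null(orthologs)) ids_b <- map_b_to_a(ids_b, orthologs)
  sig_a <- de_a$transcript_id[de_a$significant]
  sig_b <- ids_b[de_b$significant]
  shared <- intersect(sig_a, sig_b[!is.na(sig_b)])
  fa <- de_a$log2_fc[match(shared, de_a$transcript_id)]
  fb <- de_b$log2_fc[match(shared, ids_b)]
  same <- (sign(fa) == sign(fb) & fa != 0) | (fa == 0 & fb == 0)
  structure(list(n_shared_de = length(shared),
                 n_same_direction = sum(same),
                 percent_same = if (length(shared) > 0)
                   100 * sum(same) / length(shared) else NA_real_,
                 per_gene = data.frame(id = shared, log2_fc_a = fa,
                                       log2_fc_b = fb, same = same,
                                       stringsAsFactors = FALSE)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d shared DE orthologs, %d (%.1f%%) same direction\n",
              x$n_shared_de, x$n_same_direction, x$percent_same))
  invisible(x)
}

#' Rank-ordered fold-change profiles across species
#'
#' Shared-DE genes sorted by species A's log2 fold change (descending);
#' species B's fold changes are emitted in that identical order, with the
#' fraction of B entries sharing A's sign as summary.
#'
#' @param concordance a `concordance_result` from
#'   [de_overlap_concordance()].
#' @return list with `profile` (ordered data.frame) and
#'   `shared_sign_fraction`.
#' @export
rank_ordered_fc_profiles <- function(concordance) {
  pg <- concordance$per_gene
  pg <- pg[order(-pg$log2_fc_a, pg$id), , drop = FALSE]
  rownames(pg) <- NULL
  list(profile = pg,
       shared_sign_fraction = if (nrow(pg) > 0) mean(pg$same) else NA_real_)
}

#' Percent of transcripts differentially expressed between sexes
#'
#' Within one tissue, runs the two-group DE test between male and female
#' replicates and reports the percent of tested transcripts significant,
#' with the direction split (percent of the DE genes up in males).
#'
#' @param dataset an `ExpressionDataset` whose metadata carries `sex`.
#' @param tissue tissue to test.
#' @param q_thresh,fc_thresh significance thresholds.
#' @return list with `percent_de`, `n_significant`, `n_tested`,
#'   `percent_up_in_male` (of the significant genes), and `de_table`.
#' @export
sex_de_fraction <- function(dataset, tissue, q_thresh = 0.01, fc_thresh = 2.0) {
  md <- dataset$metadata
  idx <- which(md$tissue == tissue & md$sex %in% c("male", "female"))
  sexes <- table(md$sex[idx])
  if (length(sexes[sexes >= 2]) < 2)
    stop("tissue needs >= 2 replicates of each sex: ", tissue)
  fpkm <- compute_fpkm(dataset)
  res <- group_de(fpkm, md, idx, md$sex[idx], q_thresh, fc_thresh,
                  epsilon = 0.1, expressed_threshold = 1.0, pseudocount = 1)
  gm <- attr(res, "group_means_fpkm")
  lfc <- log2((gm[, "male"] + 0.1) / (gm[, "female"] + 0.1))
  res$log2_fc_male_vs_female <- unname(lfc)
  nsig <- sum(res$significant)
  list(percent_de = 100 * nsig / nrow(res),
       n_significant = nsig, n_tested = nrow(res),
       percent_up_in_male = if (nsig > 0)
         100 * sum(res$significant & lfc > 0) / nsig else NA_real_,
       de_table = res)
}
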