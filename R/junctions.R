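#' Annotated intron set
#'
#' Every gap between consecutive exons of every transcript, as unique
#' `(chrom, start, end, strand)` rows in 0-based half-open coordinates.
#' Isoforms sharing an intron contribute one entry.
#'
#' @param annotation annotation data.frame with `exons` structures.
#' @return data.frame `chrom`, `intron_start`, `intron_end`, `strand`.
#' @export
known_intron_set <- function(annotation) {
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    ex <- parse_exons(annotation$exons[i])
    if (is.null(ex) || nrow(ex) < 2) next
    if (is.unsorted(ex[, 1]))
      stop("unordered exons for ", annotation$transcript_id[i])
    out[[length(out) + 1]] <- data.frame(
      chrom = annotation$chrom[i],
      intron_start = ex[-nrow(ex), 2],
      intron_end = ex[-1, 1],
      strand = annotation$strand[i],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), intron_start = numeric(0),
                      intron_end = numeric(0), strand = character(0)))
  df <- do.call(rbind, out)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

# per-chromosome exon boundary sets (starts = acceptors, ends = donors)
annotation_boundaries <- function(annotation) {
  starts <- list(); ends <- list(); exons <- list()
  for (i in seq_len(nrow(annotation))) {
    ex <- parse_exons(annotation$exons[i])
    if (is.null(ex)) next
    ch <- annotation$chrom[i]
    starts[[ch]] <- c(starts[[ch]], ex[, 1])
    ends[[ch]] <- c(ends[[ch]], ex[, 2])
    exons[[ch]] <- rbind(exons[[ch]], ex)
  }
  list(starts = lapply(starts, unique), ends = lapply(ends, unique),
       exons = exons)
}

#' Find junctions absent from the annotation
#'
#' Aggregates junction records per site across samples (total reads and
#' number of samples detected), removes members of the annotated intron
#' set, filters by total read support, and ranks by descending support
#' (ties by chromosome then start).
#'
#' @param records normalized junction records from [read_junctions()] /
#'   [junction_records()].
#' @param known_set annotated introns from [known_intron_set()].
#' @param min_reads minimum total read support (default 1; >= 5 is a
#'   sensible curation cutoff, mirroring manual-curation practice).
#' @param strand_aware match known introns strand-specifically (default);
#'   set `FALSE` for strand-agnostic junction dialects.
#' @return data.frame of novel-junction calls: site fields plus
#'   `total_reads`, `n_samples_detected`, `classification`
#'   (`"unclassified"` until [classify_events()] is applied).
#' @export
find_novel_junctions <- function(records, known_set, min_reads = 1,
                                 strand_aware = TRUE) {
  key <- if (strand_aware)
    function(d) paste(d$chrom, d$intron_start, d$intron_end, d$strand,
                      sep = ":")
  else
    function(d) paste(d$chrom, d$intron_start, d$intron_end, sep = ":")
  k <- key(records)
  agg_reads <- tapply(records$read_count, k, sum)
  agg_nsamp <- tapply(records$read_count > 0, k, sum)
  first <- !duplicated(k)
  sites <- records[first, c("chrom", "intron_start", "intron_end", "strand"),
                   drop = FALSE]
  ksite <- k[first]
  sites$total_reads <- as.numeric(agg_reads[ksite])
  sites$n_samples_detected <- as.integer(agg_nsamp[ksite])
  novel <- !(ksite %in% key(known_set))
  out <- sites[novel & sites$total_reads >= min_reads, , drop = FALSE]
  out <- out[order(-out$total_reads, out$chrom, out$intron_start), ,
             drop = FALSE]
  out$classification <- rep("unclassified", nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify a novel junction against exon structure
#'
#' Deterministic rule: if both junction ends coincide with annotated exon
#' boundaries (the start with an exon end = donor, the end with an exon
#' start = acceptor) *and* at least one annotated exon lies entirely
#' within the junction's intron, the event is `exon_skipping` (an exon
#' previously thought constitutive is excluded). If one or zero ends sit
#' on an annotated boundary, the event is `novel_exon_or_site` (a novel
#' exon or splice-site use inside an annotated intron). Anything else —
#' including junctions on chromosomes absent from the annotation — is
#' `unresolved`.
#'
#' @param chrom,start,end junction intron coordinates (0-based half-open).
#' @param boundaries output of the internal boundary indexer (built once
#'   by [classify_events()]).
#' @return one of `"exon_skipping"`, `"novel_exon_or_site"`,
#'   `"unresolved"`.
#' @keywords internal
classify_one <- function(chrom, start, end, boundaries) {
  ends <- boundaries$ends[[chrom]]
  starts <- boundaries$starts[[chrom]]
  if (is.null(ends) && is.null(starts)) return("unresolved")
  donor_hit <- start %in% ends
  acceptor_hit <- end %in% starts
  if (donor_hit && acceptor_hit) {
    ex <- boundaries$exons[[chrom]]
    inside <- any(ex[, 1] >= start & ex[, 2] <= end)
    if (inside) return("exon_skipping")
    return("unresolved")
  }
  # one or zero ends on an annotated boundary
  "novel_exon_or_site"
}

#' Classify novel-junction calls
#'
#' Applies the [classify_one()] rule to every call, filling the
#' `classification` column.
#'
#' @param calls output of [find_novel_junctions()].
#' @param annotation annotation with exon structures.
#' @return `calls` with `classification` filled in.
#' @export
classify_events <- function(calls, annotation) {
  b <- annotation_boundaries(annotation)
  calls$classification <- vapply(seq_len(nrow(calls)), function(i)
    classify_one(calls$chrom[i], calls$intron_start[i], calls$intron_end[i],
                 b), character(1))
  calls
}
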