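#' Construct a validated expression dataset
#'
#' Bundles a transcript-by-sample count matrix with per-column sample
#' metadata and per-row transcript annotation. This is the universal input
#' of the pipeline: FPKM normalization, differential expression, clustering
#' and PCA all start from one of these.
#'
#' @param counts non-negative integer matrix, transcripts in rows (rownames =
#'   transcript IDs), samples in columns (colnames = sample IDs). Missing
#'   cells are not allowed; an unobserved transcript has count 0.
#' @param metadata data.frame with columns `sample_id`, `tissue`,
#'   `muscle_class` (one of `"skeletal"`, `"cardiac"`, `"smooth"`),
#'   `species`, `sex` (`"male"`, `"female"` or `"unknown"`), `replicate`
#'   (positive integer). One row per column of `counts`.
#' @param annotation data.frame with columns `transcript_id`, `gene_symbol`,
#'   `chrom`, `is_mitochondrial` (logical or 0/1), `length_bp` (positive
#'   integer), `strand` (`"+"` or `"-"`), and optionally `exons`
#'   (`"start-end,start-end"` strings in 0-based half-open coordinates whose
#'   lengths sum to `length_bp`). One row per row of `counts`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `metadata`, `annotation`.
#' @export
expression_dataset <- function(counts, metadata, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and sample colnames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; offending cell row '%s', column '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"  # keeps integer values, avoids overflow in sums

  metadata <- validate_metadata(metadata)
  annotation <- validate_annotation(annotation)

  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (!identical(colnames(counts), metadata$sample_id))
    stop("counts columns and metadata sample_id must match exactly (same order)")
  if (!identical(rownames(counts), annotation$transcript_id))
    stop("counts rows and annotation transcript_id must match exactly (same order)")

  structure(list(counts = counts, metadata = metadata, annotation = annotation),
            class = "ExpressionDataset")
}

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "muscle_class", "species", "sex", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (!all(metadata$muscle_class %in% c("skeletal", "cardiac", "smooth")))
    stop("muscle_class must be skeletal, cardiac or smooth")
  if (!all(metadata$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  if (any(is.na(metadata$tissue)) || any(metadata$tissue == ""))
    stop("every sample needs a tissue")
  rep_ok <- is.finite(metadata$replicate) & metadata$replicate >= 1 &
    metadata$replicate == round(metadata$replicate)
  if (!all(rep_ok)) stop("replicate must be a positive integer")
  metadata
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "chrom", "is_mitochondrial",
            "length_bp", "strand")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0)
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$transcript_id))
    stop("duplicate transcript_id in annotation")
  annotation$is_mitochondrial <- as.logical(annotation$is_mitochondrial)
  if (any(is.na(annotation$is_mitochondrial)))
    stop("is_mitochondrial must be logical or 0/1")
  if (any(!is.finite(annotation$length_bp) | annotation$length_bp < 1))
    stop("zero-length transcript: length_bp must be >= 1 for ",
         paste(annotation$transcript_id[annotation$length_bp < 1][1]))
  if (!all(annotation$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(annotation$exons)) {
    for (i in seq_len(nrow(annotation))) {
      ex <- parse_exons(annotation$exons[i])
      if (is.null(ex)) next
      if (is.unsorted(ex[, 1]) || any(ex[, 2] <= ex[, 1]))
        stop("exons must be sorted, non-empty intervals: ",
             annotation$transcript_id[i])
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
        stop("exons overlap for ", annotation$transcript_id[i])
      if (sum(ex[, 2] - ex[, 1]) != annotation$length_bp[i])
        stop("exon lengths do not sum to length_bp for ",
             annotation$transcript_id[i])
    }
  }
  annotation
}

# "start-end,start-end" (0-based half-open) -> 2-column matrix, or NULL
parse_exons <- function(s) {
  if (is.na(s) || s == "") return(NULL)
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

format_exons <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  tissues: %d (%s)\n", length(unique(x$metadata$tissue)),
              paste(utils::head(unique(x$metadata$tissue), 5), collapse = ", ")))
  cat(sprintf("  mitochondrial transcripts: %d\n",
              sum(x$annotation$is_mitochondrial)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Read an expression dataset from three TSV files
#'
#' Expects a counts TSV (`transcript_id` column then one column per sample),
#' a metadata TSV (`sample_id`, `tissue`, `muscle_class`, `species`, `sex`,
#' `replicate`) and an annotation TSV (`transcript_id`, `gene_symbol`,
#' `chrom`, `is_mitochondrial`, `length_bp`, `strand`, optional `exons`).
#' Transcripts present in the counts but absent from the annotation are
#' dropped; the number dropped is reported in a warning and attached as
#' attribute `n_dropped`.
#'
#' @param counts_path,metadata_path,annotation_path paths to the three TSVs.
#' @return validated [expression_dataset()].
#' @export
read_expression_dataset <- function(counts_path, metadata_path, annotation_path) {
  for (p in c(counts_path, metadata_path, annotation_path))
    if (!file.exists(p)) stop("missing file: ", p)
  cts <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(cts)[1] != "transcript_id")
    stop("counts TSV must start with a transcript_id column")
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$transcript_id
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  annotation <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!is.null(annotation$exons)) {
    annotation$exons <- as.character(annotation$exons)
    annotation$exons[is.na(annotation$exons)] <- ""
  }

  keep <- rownames(counts) %in% annotation$transcript_id
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " transcript(s) in counts absent from annotation; dropped")
    counts <- counts[keep, , drop = FALSE]
  }
  annotation <- annotation[match(rownames(counts), annotation$transcript_id), ,
                           drop = FALSE]
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (any(is.na(metadata$sample_id)))
    stop("metadata missing entries for some count columns")
  ds <- expression_dataset(counts, metadata, annotation)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Read a splice-junction table and normalize its coordinates
#'
#' Aligner junction outputs come in two common coordinate dialects. All
#' records are converted on read to the package-internal convention:
#' 0-based half-open intron intervals `[start, end)`. The dialect used is
#' recorded on the result (attribute `dialect`, always `"zero_half_open"`
#' after conversion) so a file cannot silently be converted twice.
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `strand`, `reads`,
#'   and optionally `sample_id`.
#' @param coordinate_dialect `"zero_half_open"` (stored as-is) or
#'   `"one_inclusive"` (1-based inclusive `[start, end]`, converted by
#'   `start - 1`).
#' @return data.frame of junction records (`chrom`, `intron_start`,
#'   `intron_end`, `strand`, `read_count`, `sample_id`) in internal
#'   coordinates. Records with zero reads are retained.
#' @export
read_junctions <- function(path, coordinate_dialect = c("zero_half_open",
                                                        "one_inclusive")) {
  coordinate_dialect <- match.arg(coordinate_dialect)
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("junction TSV missing columns: ",
                             paste(miss, collapse = ", "))
  junction_records(df$chrom, df$start, df$end, df$strand, df$reads,
                   sample_id = if (!is.null(df$sample_id)) df$sample_id else "pooled",
                   dialect = coordinate_dialect)
}

#' Build junction records from vectors
#'
#' @inheritParams read_junctions
#' @param chrom,start,end,strand,read_count,sample_id record fields; `start`
#'   and `end` interpreted in `dialect`.
#' @param dialect input coordinate dialect, see [read_junctions()].
#' @return data.frame of normalized junction records.
#' @export
junction_records <- function(chrom, start, end, strand, read_count,
                             sample_id = "pooled",
                             dialect = c("zero_half_open", "one_inclusive")) {
  dialect <- match.arg(dialect)
  if (dialect == "one_inclusive") start <- start - 1L
  if (any(end <= start))
    stop("intron_end must exceed intron_start after coordinate conversion")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  out <- data.frame(chrom = as.character(chrom),
                    intron_start = as.numeric(start),
                    intron_end = as.numeric(end),
                    strand = as.character(strand),
                    read_count = as.numeric(read_count),
                    sample_id = as.character(sample_id),
                    stringsAsFactors = FALSE)
  attr(out, "dialect") <- "zero_half_open"
  out
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by the first column so repeated runs produce identical
#' files; numeric values are written with full precision so that
#' `read_table_result(write_table(x))` round-trips to 1e-12.
#'
#' @param x data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  if (nrow(x) > 1) x <- x[order(x[[1]]), , drop = FALSE]
  utils::write.table(format(x, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_result <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a dendrogram to newick
#'
#' Converts an `hclust` tree to an ultrametric newick string (leaf branch
#' lengths are half the merge heights, the usual midpoint convention) and
#' optionally writes it to a file.
#'
#' @param tree an `hclust` object.
#' @param path optional output path.
#' @return the newick string, invisibly if `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Export junction records or novel-junction calls as BED6
#'
#' @param junctions data.frame with `chrom`, `intron_start`, `intron_end`,
#'   `strand` and either `read_count` or `total_reads`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(junctions, path) {
  reads <- if (!is.null(junctions$total_reads)) junctions$total_reads
           else junctions$read_count
  bed <- data.frame(chrom = junctions$chrom,
                    chromStart = junctions$intron_start,
                    chromEnd = junctions$intron_end,
                    name = paste0(junctions$chrom, ":", junctions$intron_start,
                                  "-", junctions$intron_end),
                    score = pmin(reads, 1000),
                    strand = junctions$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a named gene list with case-normalized symbols
#'
#' @param members character vector of gene symbols (case-folded to upper).
#' @param name list name.
#' @param provenance free-text origin of the list.
#' @return object of class `gene_list`.
#' @export
gene_list <- function(members, name = "gene_list", provenance = "") {
  members <- unique(toupper(as.character(members)))
  if (length(members) == 0) stop("gene list must be non-empty")
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_list")
}

#' Read a one-symbol-per-line gene list file
#' @param path text file, one gene symbol per line.
#' @param name list name (defaults to file name).
#' @return [gene_list()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("missing file: ", path)
  gene_list(readLines(path), name = name, provenance = path)
}

#' Build a one-to-one ortholog table
#'
#' Deduplicates exact pair repeats, then drops any pair whose species-A or
#' species-B identifier still occurs more than once (ambiguous many-to-many
#' orthology). The number of ambiguous pairs dropped is attached as
#' attribute `n_ambiguous_dropped`.
#'
#' @param species_a_id,species_b_id equal-length character vectors.
#' @return data.frame with columns `species_a_id`, `species_b_id`.
#' @export
ortholog_table <- function(species_a_id, species_b_id) {
  df <- unique(data.frame(species_a_id = as.character(species_a_id),
                          species_b_id = as.character(species_b_id),
                          stringsAsFactors = FALSE))
  amb <- duplicated(df$species_a_id) | duplicated(df$species_a_id, fromLast = TRUE) |
    duplicated(df$species_b_id) | duplicated(df$species_b_id, fromLast = TRUE)
  out <- df[!amb, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ambiguous_dropped") <- sum(amb)
  out
}

#' Read an ortholog pairing table from TSV
#' @param path TSV with columns `species_a_id`, `species_b_id`.
#' @return one-to-one [ortholog_table()].
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ortholog_table(df$species_a_id, df$species_b_id)
}

#' Write an expression dataset to the three standard TSVs
#'
#' Inverse of [read_expression_dataset()]; used to materialize simulated
#' datasets on disk.
#'
#' @param dataset an `ExpressionDataset`.
#' @param counts_path,metadata_path,annotation_path output paths.
#' @return invisibly, a character vector of the three paths.
#' @export
write_expression_dataset <- function(dataset, counts_path, metadata_path,
                                     annotation_path) {
  cts <- data.frame(transcript_id = rownames(dataset$counts),
                    dataset$counts, check.names = FALSE)
  utils::write.table(cts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- dataset$annotation
  ann$is_mitochondrial <- as.integer(ann$is_mitochondrial)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path, annotation_path))
}
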