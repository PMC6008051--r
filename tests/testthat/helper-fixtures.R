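# Hand-built fixtures and independent oracles shared across tests.

# tiny dataset: n transcripts x samples from explicit count matrix
tiny_dataset <- function(counts, tissue, lengths = NULL, is_mito = NULL,
                         gene = NULL, sex = NULL, muscle_class = NULL) {
  n <- nrow(counts)
  if (is.null(lengths)) lengths <- rep(1000, n)
  if (is.null(is_mito)) is_mito <- rep(FALSE, n)
  if (is.null(gene)) gene <- paste0("G", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("T", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(sex)) sex <- rep("unknown", ncol(counts))
  if (is.null(muscle_class)) muscle_class <- rep("skeletal", ncol(counts))
  md <- data.frame(sample_id = colnames(counts), tissue = tissue,
                   muscle_class = muscle_class, species = "mouse", sex = sex,
                   replicate = stats::ave(seq_along(tissue), tissue,
                                          FUN = seq_along),
                   stringsAsFactors = FALSE)
  ann <- data.frame(transcript_id = rownames(counts), gene_symbol = gene,
                    chrom = ifelse(is_mito, "chrM", "chr1"),
                    is_mitochondrial = is_mito, length_bp = lengths,
                    strand = "+", stringsAsFactors = FALSE)
  expression_dataset(counts, md, ann)
}

# exhaustive Benjamini-Hochberg definition: on sorted p,
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(p[o][i:m] * m / (i:m))), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# adjusted Rand index between two labelings (closed-form from the
# contingency table); mclust::adjustedRandIndex is the cross-check
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Gaussian rank-one spike design with analytically known PC1 variance
# fraction: x_j = b * s_{tissue(j)} + e_j, e ~ N(0, sd^2 I_p)
gaussian_spike_sim <- function(n_tissues = 8, n_reps = 6, p = 100,
                               b = 0.5, noise_sd = 1, seed) {
  set.seed(seed)
  s_t <- seq(-1.5, 1.5, length.out = n_tissues)
  s <- rep(s_t, each = n_reps)
  n <- length(s)
  x <- outer(rep(b, p), s) + matrix(rnorm(p * n, 0, noise_sd), p, n)
  rownames(x) <- paste0("T", seq_len(p))
  colnames(x) <- paste0("s", seq_len(n))
  md <- data.frame(sample_id = colnames(x),
                   tissue = rep(paste0("tis", seq_len(n_tissues)),
                                each = n_reps),
                   muscle_class = "skeletal", species = "mouse",
                   sex = "unknown", replicate = rep(seq_len(n_reps), n_tissues),
                   stringsAsFactors = FALSE)
  v_s <- sum((s - mean(s))^2) / (n - 1)
  lam1 <- p * b^2 * v_s + noise_sd^2
  true_fraction <- lam1 / (lam1 + (p - 1) * noise_sd^2)
  list(x = x, metadata = md, true_fraction = true_fraction)
}

# a fully null configuration: constant fast fraction and mitochondrial
# load, no class/tissue/driver/DE structure
null_config <- function(seed, n_transcripts = 2000, n_tissues = 11,
                        de_fraction = 0, de_fold_change = 4,
                        nb_dispersion = 0.05, depth_mean = 5e6) {
  cfg <- sim_config(n_transcripts = n_transcripts,
                    tissues_per_class = c(skeletal = n_tissues),
                    n_replicates = 6, depth_mean = depth_mean,
                    nb_dispersion = nb_dispersion,
                    de_fraction = de_fraction,
                    de_fold_change = de_fold_change,
                    mito_fraction_range = c(0.2, 0.2),
                    n_axis_drivers = 0, class_effect_sd = 0,
                    tissue_effect_sd = 0, seed = seed)
  sk <- myoatlas:::sim_tissue_table(cfg)$tissue
  cfg$fast_fraction <- stats::setNames(rep(0.5, length(sk)), sk)
  cfg
}
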