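#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a multi-tissue bulk RNA-seq design (skeletal, cardiac and smooth muscle
#' groups with replicates), negative-binomial counts over log-normal tissue
#' means, a latent fast/slow fiber axis driving Myh-like genes and
#' correlated axis markers, tissue-varying mitochondrial load, and planted
#' differential expression.
#'
#' @param n_transcripts number of transcript models to simulate.
#' @param tissues_per_class named integer vector giving the number of
#'   tissues per muscle class, e.g. `c(skeletal = 11, cardiac = 3, smooth = 3)`.
#' @param n_replicates biological replicates per tissue (default 6).
#' @param depth_mean expected uniquely aligned reads per sample.
#' @param nb_dispersion negative-binomial dispersion phi, so that
#'   `Var = m + phi * m^2`; `phi = 0` gives Poisson counts.
#' @param de_fraction fraction of transcripts receiving a planted
#'   tissue-subset expression shift.
#' @param de_fold_change linear fold change of the planted shifts.
#' @param mito_fraction_range range `(lo, hi)` from which each tissue's
#'   mitochondrial read share is drawn.
#' @param n_mito_transcripts number of mitochondrially encoded transcripts.
#' @param n_axis_drivers number of genes whose log expression follows the
#'   latent fast/slow axis.
#' @param axis_r2_targets target squared correlation(s) between driver log
#'   expression and the latent fast fraction across tissues; recycled over
#'   drivers.
#' @param axis_effect_log2 log2 expression span of the axis effect (slope
#'   magnitude applied to the fast fraction).
#' @param class_effect_sd SD (log2) of per-transcript muscle-class shifts;
#'   0 removes class structure entirely.
#' @param tissue_effect_sd SD (log2) of per-transcript per-tissue shifts
#'   within class; 0 makes tissues of a class identical in expectation.
#' @param sex_de_fraction fraction of transcripts with a planted
#'   male/female expression shift (0 = none).
#' @param sex_de_fold_change linear fold change of the planted sex shifts.
#' @param depth_cv coefficient of variation of per-sample sequencing depth.
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline of
#'   per-transcript tissue means, on the log2 FPKM scale.
#' @param fast_fraction optional named vector overriding the per-tissue
#'   latent fast fraction in `[0, 1]`.
#' @param seed mandatory RNG seed; identical configs with identical seeds
#'   produce byte-identical datasets.
#'
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000,
                       tissues_per_class = c(skeletal = 11, cardiac = 3,
                                             smooth = 3),
                       n_replicates = 6,
                       depth_mean = 5e6,
                       nb_dispersion = 0.05,
                       de_fraction = 0.1,
                       de_fold_change = 4,
                       mito_fraction_range = c(0.05, 0.35),
                       n_mito_transcripts = 13,
                       n_axis_drivers = 50,
                       axis_r2_targets = 0.9,
                       axis_effect_log2 = 3,
                       class_effect_sd = 1,
                       tissue_effect_sd = 0.25,
                       sex_de_fraction = 0,
                       sex_de_fold_change = 2,
                       depth_cv = 0.1,
                       baseline_log2_mean = 4,
                       baseline_log2_sd = 2,
                       fast_fraction = NULL,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_transcripts >= 10,
            all(tissues_per_class >= 0), sum(tissues_per_class) >= 2,
            n_replicates >= 1,
            depth_mean > 0,
            nb_dispersion >= 0,
            de_fraction >= 0, de_fraction <= 1,
            de_fold_change >= 1,
            length(mito_fraction_range) == 2,
            mito_fraction_range[1] >= 0, mito_fraction_range[2] <= 1,
            mito_fraction_range[1] <= mito_fraction_range[2],
            n_mito_transcripts >= 1,
            n_axis_drivers >= 0,
            all(axis_r2_targets > 0), all(axis_r2_targets < 1),
            sex_de_fraction >= 0, sex_de_fraction <= 1,
            depth_cv >= 0)
  if (!all(names(tissues_per_class) %in% c("skeletal", "cardiac", "smooth")))
    stop("tissues_per_class names must be skeletal/cardiac/smooth")
  structure(list(n_transcripts = n_transcripts,
                 tissues_per_class = tissues_per_class,
                 n_replicates = n_replicates,
                 depth_mean = depth_mean,
                 nb_dispersion = nb_dispersion,
                 de_fraction = de_fraction,
                 de_fold_change = de_fold_change,
                 mito_fraction_range = mito_fraction_range,
                 n_mito_transcripts = n_mito_transcripts,
                 n_axis_drivers = n_axis_drivers,
                 axis_r2_targets = axis_r2_targets,
                 axis_effect_log2 = axis_effect_log2,
                 class_effect_sd = class_effect_sd,
                 tissue_effect_sd = tissue_effect_sd,
                 sex_de_fraction = sex_de_fraction,
                 sex_de_fold_change = sex_de_fold_change,
                 depth_cv = depth_cv,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 fast_fraction = fast_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# canonical tissue names, skeletal ordered roughly fast -> slow
.skeletal_names <- c("EDL", "FDB", "tibialis_anterior", "plantaris",
                     "gastrocnemius", "quadriceps", "extraocular",
                     "masseter", "tongue", "diaphragm", "soleus")
.cardiac_names <- c("right_ventricle", "left_ventricle", "right_atrium",
                    "left_atrium")
.smooth_names <- c("aorta", "bladder", "stomach", "esophagus")

sim_tissue_table <- function(config) {
  tpc <- config$tissues_per_class
  pick <- function(pool, k, class) {
    if (k <= length(pool)) pool[seq_len(k)]
    else c(pool, paste0(class, "_", seq_len(k - length(pool)) + length(pool)))
  }
  tissues <- character(0); classes <- character(0)
  for (cl in names(tpc)) {
    if (tpc[[cl]] == 0) next
    pool <- switch(cl, skeletal = .skeletal_names, cardiac = .cardiac_names,
                   smooth = .smooth_names)
    nm <- pick(pool, tpc[[cl]], cl)
    tissues <- c(tissues, nm)
    classes <- c(classes, rep(cl, tpc[[cl]]))
  }
  f <- numeric(length(tissues))
  sk <- classes == "skeletal"
  # latent fast-twitch content: skeletal tissues span the axis, EDL-like
  # fast to soleus-like slow; cardiac is slow-myosin dominated
  if (sum(sk) == 1) f[sk] <- 0.95
  else f[sk] <- seq(0.97, 0.03, length.out = sum(sk))
  f[classes == "cardiac"] <- 0.05
  f[classes == "smooth"] <- 0.5
  names(f) <- tissues
  if (!is.null(config$fast_fraction)) {
    ov <- config$fast_fraction
    f[names(ov)] <- ov
  }
  data.frame(tissue = tissues, muscle_class = classes,
             fast_fraction = unname(f[tissues]), stringsAsFactors = FALSE)
}

#' Simulate a transcript annotation table
#'
#' Transcript models with multi-exon structures on autosomes plus
#' single-exon mitochondrially encoded transcripts on `chrM`. The first
#' three nuclear transcripts are designated Myh-like genes (`MYH4`, `MYH1`
#' fast; `MYH7` slow). Exon coordinates are 0-based half-open and
#' non-overlapping across transcripts.
#'
#' @param n_transcripts total transcripts including mitochondrial ones.
#' @param n_mito_transcripts trailing transcripts placed on `chrM`.
#' @param seed RNG seed.
#' @return annotation data.frame as accepted by [expression_dataset()].
#' @export
simulate_annotation <- function(n_transcripts, n_mito_transcripts = 13, seed) {
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  n <- n_transcripts
  n_mito <- n_mito_transcripts
  n_nuc <- n - n_mito
  id <- sprintf("TX%05d", seq_len(n))
  gene <- sprintf("GN%05d", seq_len(n))
  gene[1:3] <- c("MYH4", "MYH1", "MYH7")
  chrom <- sample(paste0("chr", 1:19), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  length_bp <- pmax(200, round(stats::rlnorm(n, log(2000), 0.5)))
  length_bp[1:3] <- 6000L  # Myh transcripts are ~6 kb and near-equal length
  n_exons <- sample(1:8, n, replace = TRUE)
  is_mito <- rep(FALSE, n)
  if (n_mito > 0) {
    mi <- (n_nuc + 1):n
    is_mito[mi] <- TRUE
    chrom[mi] <- "chrM"
    gene[mi] <- sprintf("MT-GN%02d", seq_len(n_mito))
    n_exons[mi] <- 1
    length_bp[mi] <- pmax(200, round(stats::rlnorm(n_mito, log(1000), 0.3)))
  }
  exons <- character(n)
  for (i in seq_len(n)) {
    k <- n_exons[i]
    # k exon lengths >= 1 summing exactly to length_bp
    el <- as.vector(stats::rmultinom(1, length_bp[i] - k, rep(1, k))) + 1
    il <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else integer(0)
    start0 <- i * 1e5
    starts <- start0 + c(0, cumsum(el[-k] + il))
    ends <- starts + el
    exons[i] <- format_exons(cbind(starts, ends))
  }
  data.frame(transcript_id = id, gene_symbol = gene, chrom = chrom,
             is_mitochondrial = is_mito, length_bp = length_bp,
             strand = strand, exons = exons, stringsAsFactors = FALSE)
}

#' Simulate a multi-tissue expression dataset with planted truth
#'
#' Generates counts `c_ij ~ NegBin(mean = mu_it * length_kb_i * depth_j /
#' 1e6, dispersion phi)` where the per-tissue FPKM-scale mean `mu_it`
#' combines a log-normal baseline, muscle-class and per-tissue shifts,
#' planted differential-expression shifts in random tissue subsets, a
#' latent fast/slow axis for designated driver genes, a
#' fast-fraction-partitioned Myh-like gene trio, and mitochondrial
#' transcripts scaled so each tissue's mitochondrial read share matches a
#' value drawn from the configured range.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (an `ExpressionDataset`) and
#'   `truth` (planted ground truth: DE transcripts with directions, axis
#'   drivers with targets, per-tissue fast fractions and mitochondrial
#'   shares, sex-shifted transcripts, the expected count matrix and the
#'   per-sample depths).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  ann <- simulate_annotation(n, config$n_mito_transcripts, seed = NULL)
  tt <- sim_tissue_table(config)
  Tn <- nrow(tt)
  f <- tt$fast_fraction
  len_kb <- ann$length_bp / 1000
  mito <- ann$is_mitochondrial
  myh_idx <- 1:3

  # baseline + class + tissue shifts on log2 FPKM scale
  log2mu <- matrix(stats::rnorm(n, config$baseline_log2_mean,
                                config$baseline_log2_sd),
                   nrow = n, ncol = Tn)
  if (config$class_effect_sd > 0) {
    for (cl in unique(tt$muscle_class)) {
      d <- stats::rnorm(n, 0, config$class_effect_sd)
      log2mu[, tt$muscle_class == cl] <- log2mu[, tt$muscle_class == cl] + d
    }
  }
  if (config$tissue_effect_sd > 0)
    log2mu <- log2mu + matrix(stats::rnorm(n * Tn, 0, config$tissue_effect_sd),
                              n, Tn)

  eligible <- which(!mito)
  eligible <- setdiff(eligible, myh_idx)
  drivers <- integer(0)
  if (config$n_axis_drivers > 0) {
    if (config$n_axis_drivers > length(eligible))
      stop("n_axis_drivers exceeds available transcripts")
    drivers <- sort(sample(eligible, config$n_axis_drivers))
    eligible <- setdiff(eligible, drivers)
  }
  n_de <- round(config$de_fraction * n)
  if (n_de > length(eligible))
    stop("de_fraction plus driver assignments exceed n_transcripts")
  de_idx <- sort(sample(eligible, n_de))

  de_sign <- integer(0); de_tissues <- list()
  if (n_de > 0) {
    de_sign <- sample(c(-1L, 1L), n_de, replace = TRUE)
    shift <- log2(config$de_fold_change)
    for (k in seq_len(n_de)) {
      sz <- sample(seq_len(Tn - 1), 1)
      ts <- sort(sample(Tn, sz))
      de_tissues[[k]] <- tt$tissue[ts]
      log2mu[de_idx[k], ts] <- log2mu[de_idx[k], ts] + de_sign[k] * shift
    }
  }

  # axis drivers: log2 expression = a + b * fast_fraction + noise, with the
  # noise SD chosen so the expected R^2 against the axis hits the target
  axis_targets <- numeric(0); axis_sign <- integer(0)
  if (length(drivers) > 0) {
    axis_targets <- rep_len(config$axis_r2_targets, length(drivers))
    axis_sign <- sample(c(-1L, 1L), length(drivers), replace = TRUE)
    sd_f <- stats::sd(f)
    for (k in seq_along(drivers)) {
      b <- axis_sign[k] * config$axis_effect_log2
      sigma <- abs(b) * sd_f * sqrt(1 / axis_targets[k] - 1)
      a <- stats::rnorm(1, config$baseline_log2_mean, 1)
      log2mu[drivers[k], ] <- a + b * f + stats::rnorm(Tn, 0, sigma)
    }
  }

  mu <- 2^log2mu

  # Myh-like trio: reads partitioned by latent fast fraction
  myh_pool <- ifelse(tt$muscle_class == "skeletal", 2000,
                     ifelse(tt$muscle_class == "cardiac", 800, 50))
  mu[1, ] <- 0.75 * f * myh_pool   # MYH4 (fast, IIb-like)
  mu[2, ] <- 0.25 * f * myh_pool   # MYH1 (fast, IIx-like)
  mu[3, ] <- (1 - f) * myh_pool    # MYH7 (slow, type I-like)

  # mitochondrial load: scale chrM transcripts so the expected mito read
  # share per tissue equals a draw from mito_fraction_range
  mito_share <- stats::runif(Tn, config$mito_fraction_range[1],
                             config$mito_fraction_range[2])
  names(mito_share) <- tt$tissue
  w <- stats::rlnorm(sum(mito), log(50), 0.5)
  nuc_load <- colSums(mu[!mito, , drop = FALSE] * len_kb[!mito])
  for (t in seq_len(Tn)) {
    target <- mito_share[t] / (1 - mito_share[t]) * nuc_load[t]
    mu[mito, t] <- (w / sum(w)) * target / len_kb[mito]
  }

  # planted sex-biased transcripts (mostly up in males)
  n_sex <- round(config$sex_de_fraction * n)
  sex_idx <- integer(0); sex_sign <- integer(0)
  if (n_sex > 0) {
    pool <- setdiff(eligible, de_idx)
    if (n_sex > length(pool)) stop("sex_de_fraction too large")
    sex_idx <- sort(sample(pool, n_sex))
    sex_sign <- sample(c(1L, -1L), n_sex, replace = TRUE, prob = c(0.85, 0.15))
  }

  # samples: n_replicates per tissue, sexes alternating within tissue
  metadata <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    data.frame(sample_id = paste0(tt$tissue[t], "_", seq_len(config$n_replicates)),
               tissue = tt$tissue[t], muscle_class = tt$muscle_class[t],
               species = "mouse",
               sex = ifelse(seq_len(config$n_replicates) %% 2 == 1,
                            "male", "female"),
               replicate = seq_len(config$n_replicates),
               stringsAsFactors = FALSE)
  }))
  nsamp <- nrow(metadata)
  depth <- config$depth_mean *
    stats::rlnorm(nsamp, -config$depth_cv^2 / 2, config$depth_cv)
  names(depth) <- metadata$sample_id

  expected <- matrix(0, n, nsamp,
                     dimnames = list(ann$transcript_id, metadata$sample_id))
  tidx <- match(metadata$tissue, tt$tissue)
  for (j in seq_len(nsamp)) {
    m <- mu[, tidx[j]] * len_kb * depth[j] / 1e6
    if (n_sex > 0 && metadata$sex[j] == "male")
      m[sex_idx] <- m[sex_idx] * config$sex_de_fold_change^sex_sign
    expected[, j] <- m
  }
  phi <- config$nb_dispersion
  counts <- if (phi > 0)
    matrix(stats::rnbinom(n * nsamp, mu = expected, size = 1 / phi), n, nsamp)
  else
    matrix(stats::rpois(n * nsamp, lambda = expected), n, nsamp)
  dimnames(counts) <- dimnames(expected)

  dataset <- expression_dataset(counts, metadata, ann)
  truth <- structure(list(
    de_transcripts = ann$transcript_id[de_idx],
    de_sign = stats::setNames(de_sign, ann$transcript_id[de_idx]),
    de_tissues = stats::setNames(de_tissues, ann$transcript_id[de_idx]),
    axis_drivers = ann$transcript_id[drivers],
    axis_r2_targets = stats::setNames(axis_targets, ann$transcript_id[drivers]),
    axis_sign = stats::setNames(axis_sign, ann$transcript_id[drivers]),
    latent_fast_fraction = stats::setNames(f, tt$tissue),
    mito_share = mito_share,
    mito_transcripts = ann$transcript_id[mito],
    myh_genes = list(fast = c("MYH4", "MYH1"), slow = "MYH7"),
    sex_de_transcripts = ann$transcript_id[sex_idx],
    sex_de_sign = stats::setNames(sex_sign, ann$transcript_id[sex_idx]),
    mu = mu, depth = depth, expected_counts = expected,
    config = config), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate splice-junction records with planted novel events
#'
#' Emits every annotated intron (the gaps between consecutive exons of each
#' transcript) with random read support, plus `n_novel` junctions absent
#' from the annotated intron set, split between two planted classes:
#' exon-skipping events (both ends on annotated exon boundaries of
#' non-adjacent exons, skipping the one between) and novel-exon/site
#' events (one end moved off every annotated boundary, into an annotated
#' intron).
#'
#' @param annotation annotation data.frame with `exons` structures.
#' @param n_novel number of novel junctions to plant.
#' @param reads_range integer range of per-sample read support.
#' @param seed RNG seed.
#' @param prop_skipping fraction of novel junctions that are exon-skipping
#'   events (the rest are novel-exon/site events).
#' @param sample_ids sample identifiers over which records are emitted.
#' @return list with `junctions` (normalized junction records) and `truth`
#'   (data.frame of planted novel junctions with class labels).
#' @export
simulate_junctions <- function(annotation, n_novel = 50,
                               reads_range = c(5, 500), seed,
                               prop_skipping = 0.5,
                               sample_ids = c("simA", "simB")) {
  set.seed(seed)
  known <- known_intron_set(annotation)
  key <- function(chrom, s, e, st) paste(chrom, s, e, st, sep = ":")
  known_keys <- key(known$chrom, known$intron_start, known$intron_end,
                    known$strand)

  # boundary sets for collision checks
  bounds <- annotation_boundaries(annotation)

  n_skip <- round(n_novel * prop_skipping)
  n_site <- n_novel - n_skip

  # exon-skipping candidates: donor of exon k to acceptor of exon k+2
  skip_cand <- list()
  for (i in seq_len(nrow(annotation))) {
    ex <- parse_exons(annotation$exons[i])
    if (is.null(ex) || nrow(ex) < 3) next
    for (k in seq_len(nrow(ex) - 2)) {
      skip_cand[[length(skip_cand) + 1]] <-
        data.frame(chrom = annotation$chrom[i], intron_start = ex[k, 2],
                   intron_end = ex[k + 2, 1], strand = annotation$strand[i],
                   stringsAsFactors = FALSE)
    }
  }
  skip_cand <- if (length(skip_cand) > 0) do.call(rbind, skip_cand) else
    data.frame()
  if (nrow(skip_cand) > 0) {
    kk <- key(skip_cand$chrom, skip_cand$intron_start, skip_cand$intron_end,
              skip_cand$strand)
    skip_cand <- skip_cand[!duplicated(kk) & !(kk %in% known_keys), ,
                           drop = FALSE]
  }
  if (n_skip > nrow(skip_cand))
    stop("n_novel exceeds constructible exon-skipping sites")
  skip_pick <- skip_cand[sample(nrow(skip_cand), n_skip), , drop = FALSE]

  # novel-exon/site candidates: pull a known intron's acceptor end inward
  if (n_site > nrow(known))
    stop("n_novel exceeds constructible novel-site candidates")
  site_rows <- sample(nrow(known), min(nrow(known), n_site * 3))
  site_pick <- list()
  for (r in site_rows) {
    if (length(site_pick) >= n_site) break
    s <- known$intron_start[r]; e <- known$intron_end[r]
    ch <- known$chrom[r]
    if (e - s < 60) next
    off <- sample(20:min(150, e - s - 20), 1)
    newe <- e - off
    if (newe %in% bounds$starts[[ch]] || newe %in% bounds$ends[[ch]]) next
    cand <- data.frame(chrom = ch, intron_start = s, intron_end = newe,
                       strand = known$strand[r], stringsAsFactors = FALSE)
    kk <- key(ch, s, newe, known$strand[r])
    if (kk %in% known_keys) next
    site_pick[[length(site_pick) + 1]] <- cand
  }
  if (length(site_pick) < n_site)
    stop("n_novel exceeds constructible novel-site candidates")
  site_pick <- do.call(rbind, site_pick)

  novel <- rbind(
    if (n_skip > 0) cbind(skip_pick, class = "exon_skipping"),
    if (n_site > 0) cbind(site_pick, class = "novel_exon_or_site"))
  if (!is.null(novel)) {
    kk <- key(novel$chrom, novel$intron_start, novel$intron_end, novel$strand)
    if (anyDuplicated(kk)) novel <- novel[!duplicated(kk), , drop = FALSE]
  } else novel <- data.frame()

  emit <- rbind(known[, c("chrom", "intron_start", "intron_end", "strand")],
                if (nrow(novel) > 0)
                  novel[, c("chrom", "intron_start", "intron_end", "strand")])
  recs <- do.call(rbind, lapply(sample_ids, function(sid) {
    data.frame(chrom = emit$chrom, intron_start = emit$intron_start,
               intron_end = emit$intron_end, strand = emit$strand,
               read_count = sample(reads_range[1]:reads_range[2], nrow(emit),
                                   replace = TRUE),
               sample_id = sid, stringsAsFactors = FALSE)
  }))
  attr(recs, "dialect") <- "zero_half_open"
  rownames(recs) <- NULL
  rownames(novel) <- NULL
  list(junctions = recs, truth = list(novel_junctions = novel,
                                      n_novel = nrow(novel)))
}

#' Simulate an orthologous two-species, two-tissue pair
#'
#' Two datasets (an EDL-like fast tissue vs a soleus-like slow tissue in
#' each species) sharing orthologous transcripts. A set of `n_co_de`
#' transcripts is planted differentially expressed between the two tissues
#' in both species; a deterministic quota of exactly
#' `round(concordance * n_co_de)` of them shares the sign of its log fold
#' change across species, the rest are flipped. Between-species baseline
#' noise is calibrated so the expected ortholog R^2 within a tissue equals
#' `species_r2_target`.
#'
#' @param config a [sim_config()] (transcript count, replicates, depth,
#'   dispersion and DE fold change are taken from it).
#' @param concordance planted fraction of co-DE orthologs with the same
#'   fold-change direction, in `[0, 1]`.
#' @param seed RNG seed.
#' @param n_co_de number of transcripts planted DE in both species.
#' @param species_r2_target expected squared correlation between species'
#'   log expression across orthologs.
#' @return list with `dataset_a`, `dataset_b` (`ExpressionDataset`s),
#'   `orthologs` (one-to-one table) and `truth`.
#' @export
simulate_species_pair <- function(config, concordance, seed, n_co_de = 200,
                                  species_r2_target = 0.65) {
  stopifnot(inherits(config, "sim_config"),
            concordance >= 0, concordance <= 1)
  set.seed(seed)
  n <- config$n_transcripts
  if (n_co_de > n - 10) stop("n_co_de too large for n_transcripts")
  base_id <- sprintf("OG%05d", seq_len(n))
  len_bp <- pmax(200, round(stats::rlnorm(n, log(2000), 0.5)))
  len_kb <- len_bp / 1000

  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  # cor(A,B) = r => per-species deviation sd from shared-variance split
  r <- sqrt(species_r2_target)
  sigma_sp <- config$baseline_log2_sd * sqrt(1 / r - 1)

  co_idx <- sort(sample(n, n_co_de))
  sign_a <- sample(c(-1L, 1L), n_co_de, replace = TRUE)
  n_same <- round(concordance * n_co_de)
  same <- rep(FALSE, n_co_de)
  if (n_same > 0) same[sample(n_co_de, n_same)] <- TRUE
  sign_b <- ifelse(same, sign_a, -sign_a)
  shift <- log2(config$de_fold_change)

  build_species <- function(prefix, species, signs) {
    log2mu <- matrix(baseline + stats::rnorm(n, 0, sigma_sp), n, 2)
    # column 1 = EDL-like, column 2 = soleus-like
    log2mu[co_idx, 1] <- log2mu[co_idx, 1] + signs * shift / 2
    log2mu[co_idx, 2] <- log2mu[co_idx, 2] - signs * shift / 2
    mu <- 2^log2mu
    tissues <- c("EDL", "soleus")
    metadata <- do.call(rbind, lapply(1:2, function(t) {
      data.frame(sample_id = paste0(prefix, tissues[t], "_",
                                    seq_len(config$n_replicates)),
                 tissue = tissues[t], muscle_class = "skeletal",
                 species = species, sex = "unknown",
                 replicate = seq_len(config$n_replicates),
                 stringsAsFactors = FALSE)
    }))
    nsamp <- nrow(metadata)
    depth <- config$depth_mean *
      stats::rlnorm(nsamp, -config$depth_cv^2 / 2, config$depth_cv)
    tidx <- match(metadata$tissue, tissues)
    expected <- sapply(seq_len(nsamp), function(j)
      mu[, tidx[j]] * len_kb * depth[j] / 1e6)
    phi <- config$nb_dispersion
    counts <- if (phi > 0)
      matrix(stats::rnbinom(n * nsamp, mu = expected, size = 1 / phi), n, nsamp)
    else matrix(stats::rpois(n * nsamp, lambda = expected), n, nsamp)
    ids <- paste0(prefix, base_id)
    dimnames(counts) <- list(ids, metadata$sample_id)
    ann <- data.frame(transcript_id = ids,
                      gene_symbol = paste0(prefix, sprintf("G%05d", seq_len(n))),
                      chrom = "chr1", is_mitochondrial = FALSE,
                      length_bp = len_bp, strand = "+",
                      stringsAsFactors = FALSE)
    expression_dataset(counts, metadata, ann)
  }

  ds_a <- build_species("m_", "mouse", sign_a)
  ds_b <- build_species("r_", "rat", sign_b)
  orth <- ortholog_table(paste0("m_", base_id), paste0("r_", base_id))
  truth <- structure(list(
    co_de = base_id[co_idx],
    co_de_a = paste0("m_", base_id[co_idx]),
    co_de_b = paste0("r_", base_id[co_idx]),
    sign_a = sign_a, sign_b = sign_b,
    concordant = same,
    concordant_direction_fraction = n_same / n_co_de,
    species_r2_target = species_r2_target,
    config = config), class = "sim_truth")
  list(dataset_a = ds_a, dataset_b = ds_b, orthologs = orth, truth = truth)
}
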