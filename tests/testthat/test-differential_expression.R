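# helper: wrap a log2-scale value matrix as FPKM so that anova_de's
# internal log2(FPKM + 1) recovers the values exactly
as_fpkm_scale <- function(log2_values) 2^log2_values - 1

de_metadata <- function(tissue) {
  data.frame(sample_id = paste0("S", seq_along(tissue)), tissue = tissue,
             muscle_class = "skeletal", species = "mouse", sex = "unknown",
             replicate = stats::ave(seq_along(tissue), tissue, FUN = seq_along),
             stringsAsFactors = FALSE)
}

test_that("expressed calls use strict per-tissue mean thresholds", {
  v <- matrix(c(0.5, 0.5, 1.5, 1.5,
                0, 0, 0, 0,
                0.1, 0.1, 0.2, 0.2), nrow = 3, byrow = TRUE,
              dimnames = list(c("T1", "T2", "T3"), paste0("S", 1:4)))
  md <- de_metadata(c("A", "A", "B", "B"))
  calls <- call_expressed(v, md, threshold = 1)
  expect_equal(unname(calls$expressed["T1", ]), c(FALSE, TRUE))
  expect_true(calls$any_tissue[["T1"]])
  expect_false(calls$all_tissue[["T1"]])
  expect_false(calls$any_tissue[["T2"]])
  # strict ">": any positive mean is expressed at threshold 0
  calls0 <- call_expressed(v, md, threshold = 0)
  expect_equal(unname(calls0$expressed["T3", ]), c(TRUE, TRUE))
})

test_that("venn core sets follow every-tissue-in-class logic", {
  # 4 tissues: sk1, sk2 (skeletal), ca1 (cardiac), sm1 (smooth)
  tissue <- c("sk1", "sk2", "ca1", "sm1")
  v <- matrix(c(5, 5, 5, 5,    # everywhere -> triple intersection
                5, 5, 0, 5,    # misses cardiac -> skeletal+smooth region
                5, 0, 5, 5,    # misses one skeletal tissue
                0, 0, 0, 0),   # nowhere
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("T", 1:4), paste0("S", 1:4)))
  md <- de_metadata(tissue)
  calls <- call_expressed(v, md)
  cm <- c(sk1 = "skeletal", sk2 = "skeletal", ca1 = "cardiac", sm1 = "smooth")
  venn <- venn_core_sets(calls, cm)
  expect_equal(venn$core, "T1")
  expect_equal(unname(venn$region_counts["all_three"]), 1)
  expect_equal(unname(venn$region_counts["skeletal_smooth"]), 1)  # T2
  # T3 misses sk2 so it is cardiac+smooth only
  expect_equal(unname(venn$region_counts["cardiac_smooth"]), 1)
  expect_equal(sum(venn$region_counts), 3)  # T4 in no core
})

test_that("ANOVA worked example gives F = 3 with an lm oracle p-value", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  v <- matrix(unlist(g), nrow = 1,
              dimnames = list("T1", paste0("S", 1:9)))
  md <- de_metadata(rep(c("A", "B", "C"), each = 3))
  de <- anova_de(as_fpkm_scale(v), md)
  expect_equal(de$F, 3, tolerance = 1e-9)
  # independent oracle: classical lm/anova on the same numbers
  fit <- stats::anova(stats::lm(unlist(g) ~ rep(c("A", "B", "C"), each = 3)))
  expect_equal(de$p, fit$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(de$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("degenerate variance patterns follow the tie rules", {
  md <- de_metadata(rep(c("A", "B", "C"), each = 2))
  flat <- matrix(rep(4, 6), nrow = 1, dimnames = list("T1", paste0("S", 1:6)))
  de <- anova_de(as_fpkm_scale(flat), md)
  expect_equal(de$F, 0)
  expect_equal(de$p, 1)
  # between-group signal with zero within-group variance
  step <- matrix(c(2, 2, 4, 4, 6, 6), nrow = 1,
                 dimnames = list("T1", paste0("S", 1:6)))
  de2 <- anova_de(as_fpkm_scale(step), md)
  expect_equal(de2$p, 1e-300)
})

test_that("BH q-values match the brute-force tail-min oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(1), 1)
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_qvalues(p), bh_oracle(p))
  }
  # order equivariance
  p <- runif(8)
  perm <- sample(8)
  expect_equal(bh_qvalues(p[perm]), bh_qvalues(p)[perm])
})

test_that("two-group F equals the square of the pooled t statistic", {
  set.seed(7)
  for (i in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- rnorm(na, 5, 1); y <- rnorm(nb, 5, 1)
    v <- matrix(c(x, y), nrow = 1,
                dimnames = list("T1", paste0("S", seq_len(na + nb))))
    md <- de_metadata(rep(c("A", "B"), c(na, nb)))
    de <- pairwise_de(as_fpkm_scale(v), md, "A", "B")
    t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
    expect_equal(de$F, unname(t2), tolerance = 1e-10)
  }
})

test_that("pairwise DE records signed direction and identical tissues yield none", {
  set.seed(8)
  v <- matrix(rep(rnorm(6, 5, 0.2), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("T1", "T2"), paste0("S", 1:6)))
  md <- de_metadata(rep(c("A", "B"), each = 3))
  # tissue B is a replicate-permuted copy of A per transcript: no DE
  de <- pairwise_de(as_fpkm_scale(v), md, "A", "B")
  expect_equal(sum(de$significant), 0)
  # planted strong shift is detected with the right direction
  cfg <- null_config(seed = 12, n_transcripts = 300, n_tissues = 2,
                     de_fraction = 0.1, de_fold_change = 4,
                     nb_dispersion = 0.01)
  sim <- simulate_dataset(cfg)
  fp <- compute_fpkm(sim$dataset)
  tiss <- unique(sim$dataset$metadata$tissue)
  de2 <- pairwise_de(fp, tissue_a = tiss[1], tissue_b = tiss[2])
  hits <- de2$transcript_id[de2$significant]
  planted_here <- names(Filter(function(x) length(x) == 1,
                               sim$truth$de_tissues))
  expect_gt(mean(planted_here %in% hits), 0.9)
})

test_that("the DE fraction matrix is symmetric with a zero diagonal", {
  cfg <- null_config(seed = 13, n_transcripts = 200, n_tissues = 3,
                     de_fraction = 0.2, nb_dispersion = 0.01)
  sim <- simulate_dataset(cfg)
  fp <- compute_fpkm(sim$dataset)
  m <- de_fraction_matrix(fp)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(any(m > 0))
})

test_that("the q-threshold sweep is monotone and plateaus at planted truth", {
  cfg <- null_config(seed = 14, n_transcripts = 400, n_tissues = 4,
                     de_fraction = 0.5, de_fold_change = 16,
                     nb_dispersion = 0.01)
  sim <- simulate_dataset(cfg)
  fp <- compute_fpkm(sim$dataset)
  tiss <- unique(sim$dataset$metadata$tissue)
  sweep <- de_threshold_sweep(fp, subsets = list(all = tiss),
                              q_grid = c(1e-6, 1e-3, 0.01, 0.1, 1))
  expect_true(all(diff(sweep$percent_de) >= 0))
  # huge planted effects: %DE at loose q sits near the planted 50%
  expect_gt(sweep$percent_de[sweep$q_thresh == 0.01], 40)
  expect_lt(sweep$percent_de[sweep$q_thresh == 0.01], 60)
  expect_error(de_threshold_sweep(fp, subsets = list(all = tiss),
                                  q_grid = c(0, 0.5)), "\\(0, 1\\]")
})
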