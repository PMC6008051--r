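pca_metadata <- function(tissue) {
  data.frame(sample_id = paste0("S", seq_along(tissue)), tissue = tissue,
             muscle_class = "skeletal", species = "mouse", sex = "unknown",
             replicate = stats::ave(seq_along(tissue), tissue, FUN = seq_along),
             stringsAsFactors = FALSE)
}

test_that("rank-1 data put all variance on a sign-canonical PC1", {
  s <- c(-2, -1, 0, 1, 2, 3)
  x <- outer(c(1, 2, 3, -1), s)
  dimnames(x) <- list(paste0("T", 1:4), paste0("S", 1:6))
  p <- run_pca(x, expressed_filter = FALSE)
  expect_equal(p$variance_explained[1], 1.0, tolerance = 1e-12)
  # canonical sign: the largest-magnitude loading is positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  p2 <- run_pca(-x, expressed_filter = FALSE)
  expect_gt(p2$loadings[which.max(abs(p2$loadings[, 1])), 1], 0)
})

test_that("two orthogonal equal-variance directions split variance 50/50", {
  # features 1 and 2 vary independently with equal variance over samples
  x <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  dimnames(x) <- list(c("T1", "T2"), paste0("S", 1:4))
  p <- run_pca(x, expressed_filter = FALSE)
  expect_equal(unname(p$variance_explained), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("variance fractions sum to one and match an eigen oracle", {
  set.seed(5)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("T", 1:30), paste0("S", 1:12)))
  p <- run_pca(x, expressed_filter = FALSE)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-10)
  # oracle: eigenvalues of the sample covariance of centered features
  xc <- x - rowMeans(x)
  ev <- eigen(crossprod(xc) / (ncol(x) - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(p$variance_explained[seq_along(ev)] * sum(p$variance_explained),
               ev / sum(ev), tolerance = 1e-8)
})

test_that("per-transcript PC correlations behave as r^2 with invariances", {
  set.seed(6)
  s <- rnorm(20)
  # rank-1 design: every varying feature is proportional to the axis s
  x <- rbind(driver = 3 * s,
             affine = -1.5 * (3 * s) + 7,
             half = 0.5 * s,
             const = rep(2, 20))
  colnames(x) <- paste0("S", 1:20)
  p <- run_pca(x, expressed_filter = FALSE)
  co <- correlate_with_pc(x, p, component = 1)
  expect_equal(co$r_squared[co$transcript_id == "driver"], 1, tolerance = 1e-10)
  expect_equal(co$r_squared[co$transcript_id == "affine"], 1, tolerance = 1e-10)
  expect_true(is.na(co$r[co$transcript_id == "const"]))
  expect_equal(co$r_squared, co$r^2)
})

test_that("null transcripts have mean squared correlation near 1/(n-1)", {
  set.seed(61)
  n <- 66
  x <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(paste0("T", 1:1000), paste0("S", 1:n)))
  # one strong axis so PC1 is well defined, the rest pure noise
  x[1, ] <- 300 * seq_len(n) / n + rnorm(n, 0, 0.01)
  p <- run_pca(x, expressed_filter = FALSE)
  co <- correlate_with_pc(x[-1, ], p, component = 1)
  expect_equal(mean(co$r_squared), 1 / (n - 1), tolerance = 0.25)
})

test_that("ranking is by descending R^2 with stable ties and sign retained", {
  co <- data.frame(transcript_id = c("b", "a", "c", "d"),
                   r = c(0.9, -0.9, 0.5, NA),
                   r_squared = c(0.81, 0.81, 0.25, NA))
  rk <- rank_by_pc_correlation(co, top_n = 10)
  expect_equal(rk$transcript_id, c("a", "b", "c"))
  expect_equal(rk$r[1], -0.9)
  expect_equal(nrow(rank_by_pc_correlation(co, top_n = 2)), 2)
})

test_that("planted axis drivers dominate the top of the PC1 ranking", {
  # one Pecam1-like marker planted at axis R^2 0.56 among strong drivers
  cfg <- sim_config(n_transcripts = 300,
                    tissues_per_class = c(skeletal = 11),
                    n_axis_drivers = 60,
                    axis_r2_targets = c(0.56, rep(0.95, 59)),
                    de_fraction = 0, class_effect_sd = 0,
                    tissue_effect_sd = 0, nb_dispersion = 0.01,
                    mito_fraction_range = c(0.2, 0.2), seed = 71)
  sim <- simulate_dataset(cfg)
  fp <- compute_fpkm(sim$dataset)
  lx <- log_transform(fp)
  p <- run_pca(lx, sim$dataset$metadata)
  co <- correlate_with_pc(lx[p$transcripts, ], p)
  top20 <- rank_by_pc_correlation(co, 20)$transcript_id
  expect_gte(sum(top20 %in% sim$truth$axis_drivers), 18)
  # marker R^2 lookup, averaged over seeds to tame 66-sample r^2 noise
  marker_r2 <- sapply(71:75, function(s) {
    cfg$seed <- s
    sim <- simulate_dataset(cfg)
    lx <- log_transform(compute_fpkm(sim$dataset))
    p <- run_pca(lx, sim$dataset$metadata)
    co <- correlate_with_pc(lx[p$transcripts, ], p)
    marker <- names(sim$truth$axis_r2_targets)[
      sim$truth$axis_r2_targets == 0.56]
    co$r_squared[co$transcript_id == marker]
  })
  expect_lt(abs(mean(marker_r2) - 0.56), 0.1)
})

test_that("bootstrap PCA is seeded, degenerate-tight and warns on singletons", {
  x <- outer(c(1, 2, 3), c(-1, -1, 0, 0, 1, 1))  # zero within-tissue variance
  dimnames(x) <- list(paste0("T", 1:3), paste0("S", 1:6))
  md <- pca_metadata(c("a", "a", "b", "b", "c", "c"))
  bp <- bootstrap_pca(x, md, n_boot = 50, seed = 1, components = 1)
  expect_equal(unname(bp$var_ci["PC1", "hi"] - bp$var_ci["PC1", "lo"]), 0)
  bp2 <- bootstrap_pca(x, md, n_boot = 50, seed = 1, components = 1)
  expect_identical(bp$var_ci, bp2$var_ci)
  md3 <- pca_metadata(c("a", "a", "b", "b", "c", "d"))
  expect_warning(bootstrap_pca(x, md3, n_boot = 10, seed = 1), "single-replicate")
})

test_that("Fisher-z interval contains the point estimate and is ordered", {
  ci <- correlation_ci(0.56, n = 11, level = 0.99)
  expect_lt(ci[["lo"]], 0.56)
  expect_gt(ci[["hi"]], 0.56)
  expect_error(correlation_ci(0.5, n = 3), "n >= 4")
})
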