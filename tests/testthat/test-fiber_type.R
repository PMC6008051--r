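test_that("Myh composition is a percentage of Myh-aligned reads", {
  counts <- matrix(c(800L, 200L, 400L, 600L), nrow = 2,
                   dimnames = list(c("T1", "T2"), c("S1", "S2")))
  ds <- tiny_dataset(counts, tissue = c("EDL", "soleus"),
                     gene = c("Myh4", "Myh7"))
  comp <- myh_composition(ds, c("MYH4", "MYH7"))
  expect_equal(comp["EDL", "Myh4"], 80)
  expect_equal(comp["EDL", "Myh7"], 20)
  expect_equal(unname(rowSums(comp)), c(100, 100))
  # a single Myh gene with any reads owns 100%
  one <- myh_composition(ds, "MYH4")
  expect_equal(one[["Myh4"]], c(100, 100))
  expect_error(myh_composition(ds, character(0)), "empty")
  expect_error(myh_composition(ds, "NOTAGENE"), "no Myh gene")
})

test_that("zero-total tissues are flagged instead of dividing by zero", {
  counts <- matrix(c(10L, 5L, 0L, 0L), nrow = 2,
                   dimnames = list(c("T1", "T2"), c("S1", "S2")))
  ds <- tiny_dataset(counts, tissue = c("EDL", "soleus"),
                     gene = c("Myh4", "Myh7"))
  comp <- myh_composition(ds, c("MYH4", "MYH7"))
  expect_true(all(is.na(comp["soleus", ])))
  expect_identical(attr(comp, "zero_total_tissues"), "soleus")
})

test_that("composition is invariant to uniform depth rescaling of a tissue", {
  set.seed(10)
  counts <- matrix(rpois(8, 300), nrow = 2,
                   dimnames = list(c("T1", "T2"), paste0("S", 1:4)))
  ds1 <- tiny_dataset(counts, tissue = rep(c("EDL", "soleus"), each = 2),
                      gene = c("Myh4", "Myh7"))
  scaled <- counts
  scaled[, 1:2] <- counts[, 1:2] * 7L
  ds2 <- tiny_dataset(scaled, tissue = rep(c("EDL", "soleus"), each = 2),
                      gene = c("Myh4", "Myh7"))
  expect_equal(myh_composition(ds1, c("MYH4", "MYH7")),
               myh_composition(ds2, c("MYH4", "MYH7")))
})

test_that("a slow tissue planted at fast fraction 0.03 is slow-Myh dominated", {
  cfg <- sim_config(n_transcripts = 300, seed = 15)
  sim <- simulate_dataset(cfg)   # default tissue table: soleus at 0.03
  expect_equal(unname(sim$truth$latent_fast_fraction["soleus"]), 0.03)
  comp <- myh_composition(sim$dataset, c("MYH4", "MYH1", "MYH7"))
  expect_gte(comp["soleus", "MYH7"], 95)
  expect_gte(comp["EDL", "MYH4"] + comp["EDL", "MYH1"], 90)
  expect_equal(unname(rowSums(comp)), rep(100, nrow(comp)), tolerance = 1e-9)
})

test_that("marker correlations respect identity, affinity and reference checks", {
  set.seed(11)
  ref <- rnorm(11, 5, 1)
  tm <- rbind(REF = ref, NEG = -ref + 12, NOISE = rnorm(11, 5, 1),
              FLAT = rep(3, 11))
  colnames(tm) <- paste0("tis", 1:11)
  expect_equal(marker_correlation(tm, "REF", "REF")$r_squared, 1)
  mc <- marker_correlation(tm, "NEG", "REF")
  expect_equal(mc$r, -1)
  expect_equal(mc$r_squared, 1)
  expect_error(marker_correlation(tm, "NOISE", "FLAT"), "constant")
  expect_error(marker_correlation(tm[, 1:2], "REF", "NEG"), "3 tissues")
})

test_that("marker panels summarize medians and counts above 0.5", {
  set.seed(12)
  ref <- seq(1, 11)
  mk <- function(r2, sign = 1) {
    # construct a vector with exact sample correlation sqrt(r2) against ref
    e <- residuals(lm(rnorm(11) ~ ref))
    e <- e / sd(e)
    z <- scale(ref)[, 1]
    sign * (sqrt(r2) * z + sqrt(1 - r2) * e)
  }
  tm <- rbind(REF = ref, A = mk(0.1), B = mk(0.2, -1), C = mk(0.9))
  colnames(tm) <- paste0("t", 1:11)
  ps <- marker_panel_summary(tm, c("A", "B", "C"), "REF")
  expect_equal(ps$median_r_squared, 0.2, tolerance = 1e-8)
  expect_equal(ps$n_above_0.5, 1)
  expect_equal(ps$table$gene[1], "C")
  one <- marker_panel_summary(tm, "A", "REF")
  expect_equal(one$median_r_squared, one$table$r_squared)
})

test_that("a planted marker recovers its target axis correlation", {
  # the reference is a near-perfect axis gene (R^2 target 0.99), so the
  # marker's correlation with it estimates the marker's own axis R^2
  cfg <- sim_config(n_transcripts = 400,
                    tissues_per_class = c(skeletal = 11),
                    n_axis_drivers = 10,
                    axis_r2_targets = c(0.99, 0.56, 0.47),
                    nb_dispersion = 0.01, de_fraction = 0,
                    class_effect_sd = 0, tissue_effect_sd = 0, seed = 16)
  r2_47 <- sapply(17:36, function(s) {
    cfg$seed <- s
    sim <- simulate_dataset(cfg)
    fp <- compute_fpkm(sim$dataset)
    tm <- tissue_means(log_transform(fp), sim$dataset$metadata)$mean
    targets <- sim$truth$axis_r2_targets
    marker <- names(targets)[targets == 0.47][1]
    axis_gene <- names(targets)[targets == 0.99][1]
    marker_correlation(tm, marker, axis_gene)$r_squared
  })
  expect_lt(abs(mean(r2_47) - 0.47), 0.15)
})
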