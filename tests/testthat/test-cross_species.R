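pair_fixture <- function(seed = 41, concordance = 0.9, n_co_de = 200,
                         n_transcripts = 1500) {
  cfg <- sim_config(n_transcripts = n_transcripts, n_replicates = 6,
                    depth_mean = 5e6, nb_dispersion = 0.01,
                    de_fold_change = 8, baseline_log2_mean = 5,
                    baseline_log2_sd = 1.2, seed = seed)
  simulate_species_pair(cfg, concordance = concordance, seed = seed,
                        n_co_de = n_co_de)
}

species_de <- function(pr) {
  list(a = pairwise_de(compute_fpkm(pr$dataset_a), tissue_a = "EDL",
                       tissue_b = "soleus", q_thresh = 0.05),
       b = pairwise_de(compute_fpkm(pr$dataset_b), tissue_a = "EDL",
                       tissue_b = "soleus", q_thresh = 0.05))
}

test_that("ortholog pairing drops unmatched and duplicated pairs, idempotently", {
  a <- matrix(1:6, 3, 2, dimnames = list(c("m1", "m2", "m3"), c("EDL", "soleus")))
  b <- matrix(1:6, 3, 2, dimnames = list(c("r1", "r2", "r4"), c("EDL", "soleus")))
  ot <- ortholog_table(c("m1", "m2", "m3", "m2"), c("r1", "r2", "r3", "r2"))
  paired <- pair_orthologs(a, b, ot)
  expect_equal(rownames(paired$a), c("m1", "m2"))  # m3 -> r3 absent from b
  expect_equal(rownames(paired$b), c("r1", "r2"))
  # identity pairing of already-paired matrices is a no-op
  ot2 <- ortholog_table(rownames(paired$a), rownames(paired$b))
  again <- pair_orthologs(paired$a, paired$b, ot2)
  expect_identical(again$a, paired$a)
  expect_identical(again$b, paired$b)
  expect_error(pair_orthologs(a, b, ortholog_table("mX", "rX")), "no ortholog")
})

test_that("species correlation is 1 for identical or affine profiles", {
  m <- matrix(2^(1:8), 8, 1, dimnames = list(paste0("g", 1:8), "EDL"))
  paired <- list(a = m, b = m)
  expect_equal(species_correlation(paired, "EDL")$r_squared, 1)
  paired2 <- list(a = m, b = 2 * m + 1)
  # affine on the FPKM scale is not exactly affine after log, but r stays high;
  # exact affine invariance holds on the log scale itself
  la <- log2(m + 1); lb <- 2 * la + 1
  r <- cor(la, lb)[1]
  expect_equal(r, 1)
  expect_error(species_correlation(paired, "tongue"), "absent")
})

test_that("calibrated species noise yields the target ortholog R^2", {
  r2 <- sapply(101:110, function(s) {
    pr <- pair_fixture(seed = s, n_co_de = 50)
    ta <- tissue_means(compute_fpkm(pr$dataset_a), pr$dataset_a$metadata)$mean
    tb <- tissue_means(compute_fpkm(pr$dataset_b), pr$dataset_b$metadata)$mean
    paired <- pair_orthologs(ta, tb, pr$orthologs)
    species_correlation(paired, "EDL")$r_squared
  })
  expect_lt(abs(mean(r2) - 0.65), 0.1)
})

test_that("direction concordance counts shared signs by hand", {
  de_a <- data.frame(transcript_id = c("g1", "g2", "g3", "g4"),
                     significant = c(TRUE, TRUE, TRUE, FALSE),
                     log2_fc = c(2, 1.5, -3, 5))
  de_b <- data.frame(transcript_id = c("g1", "g2", "g3", "g4"),
                     significant = c(TRUE, TRUE, TRUE, TRUE),
                     log2_fc = c(1, -2, -1, 4))
  cc <- de_overlap_concordance(de_a, de_b)
  expect_equal(cc$n_shared_de, 3)
  expect_equal(cc$n_same_direction, 2)  # g1 (+,+) and g3 (-,-)
  expect_equal(cc$percent_same, 100 * 2 / 3)
  # self-comparison is fully concordant
  self <- de_overlap_concordance(de_a, de_a)
  expect_equal(self$percent_same, 100)
  # symmetry in species order
  cc_rev <- de_overlap_concordance(de_b, de_a)
  expect_equal(cc_rev$percent_same, cc$percent_same)
})

test_that("quota-planted concordance is recovered exactly end-to-end", {
  pr <- pair_fixture(seed = 42, concordance = 0.9, n_co_de = 200)
  de <- species_de(pr)
  cc <- de_overlap_concordance(de$a, de$b, pr$orthologs)
  expect_equal(cc$n_shared_de, 200)
  expect_equal(cc$percent_same, 90.0)
})

test_that("rank-ordered profiles keep A's order and report the sign share", {
  pr <- pair_fixture(seed = 43, concordance = 0.9, n_co_de = 100)
  de <- species_de(pr)
  cc <- de_overlap_concordance(de$a, de$b, pr$orthologs)
  prof <- rank_ordered_fc_profiles(cc)
  expect_true(all(diff(prof$profile$log2_fc_a) <= 0))
  expect_equal(prof$shared_sign_fraction, 0.9, tolerance = 1e-9)
  # a self-comparison emits B sorted descending too
  cc_self <- de_overlap_concordance(de$a, de$a)
  prof_self <- rank_ordered_fc_profiles(cc_self)
  expect_true(all(diff(prof_self$profile$log2_fc_b) <= 0))
  expect_equal(prof_self$shared_sign_fraction, 1)
})

test_that("sex DE fractions recover planted male-biased shifts", {
  # 3 males vs 3 females per tissue leaves 4 within-comparison df, so the
  # planted shifts need low counting noise to clear q < 0.01 reliably
  cfg <- null_config(seed = 44, n_transcripts = 1000, n_tissues = 2,
                     nb_dispersion = 0.001, depth_mean = 1e7)
  cfg$sex_de_fraction <- 0.02
  cfg$sex_de_fold_change <- 6
  sim <- simulate_dataset(cfg)
  sx <- sex_de_fraction(sim$dataset, tissue = "EDL")
  expect_lt(abs(sx$percent_de - 2), 1)
  expect_gt(sx$percent_up_in_male, 50)
  # direction split covers all significant genes
  expect_equal(sx$n_significant,
               round(sx$n_significant * sx$percent_up_in_male / 100) +
                 sum(sx$de_table$significant &
                       sx$de_table$log2_fc_male_vs_female <= 0))
  # a dataset without sexes errors
  cfg2 <- null_config(seed = 45, n_transcripts = 50, n_tissues = 2)
  sim2 <- simulate_dataset(cfg2)
  sim2$dataset$metadata$sex <- "unknown"
  expect_error(sex_de_fraction(sim2$dataset, "EDL"), "sex")
})
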