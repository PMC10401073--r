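toy_lib <- screen_library(data.frame(
  guide_id = c(paste0("GA_g", 1:5), paste0("GB_g", 1:5), paste0("NC", 1:4)),
  gene = c(rep("GA", 5), rep("GB", 5), rep(NA, 4)),
  category = c(rep("gene_of_interest", 10), rep("noncutting_control", 4)),
  stringsAsFactors = FALSE))

test_that("log2 CPM normalization matches the printed formula", {
  m <- matrix(c(100, 1e6 - 100), 2, 1,
              dimnames = list(c("g1", "g2"), "D5"))
  norm <- normalize_counts(m)
  expect_equal(norm["g1", "D5"], log2(101))
  # zero reads map to log2(1) = 0
  m0 <- matrix(c(0, 1000), 2, 1, dimnames = list(c("g1", "g2"), "D5"))
  expect_equal(normalize_counts(m0)["g1", "D5"], 0)
  # CPM scale invariance: doubling the total leaves values unchanged
  m2 <- matrix(c(200, 2e6 - 200), 2, 1,
               dimnames = list(c("g1", "g2"), "D5"))
  expect_equal(normalize_counts(m2)["g1", "D5"], log2(101))
  # per-sample identity: sum(2^value - 1) == 1e6
  set.seed(3)
  mr <- matrix(rpois(300, 800), 100, 3,
               dimnames = list(paste0("g", 1:100), c("D5", "D8", "D16")))
  expect_equal(unname(colSums(2^normalize_counts(mr) - 1)), rep(1e6, 3),
               tolerance = 1e-9)
  mz <- matrix(c(0, 0), 2, 1, dimnames = list(c("g1", "g2"), "D5"))
  expect_error(normalize_counts(mz), "zero total")
})

test_that("log2 fold-change is taken against the day-5 reference", {
  norm <- matrix(c(5, 3, 4, 3), 2, 2,
                 dimnames = list(c("g1", "g2"), c("D5", "D16")))
  lfc <- log2fc_vs_reference(norm, 16)
  expect_equal(unname(lfc), c(-1, 0))
  expect_equal(unname(log2fc_vs_reference(norm, 5)), c(0, 0))
  expect_error(log2fc_vs_reference(norm[, "D16", drop = FALSE], 16),
               "reference")
  # halving a guide's count at constant totals gives lfc ~ -1
  counts <- matrix(c(4000, 96000, 2000, 98000), 2, 2,
                   dimnames = list(c("g1", "g2"), c("D5", "D16")))
  lfc <- log2fc_vs_reference(normalize_counts(counts), 16)
  expect_equal(unname(lfc["g1"]), -1, tolerance = 0.01)
})

test_that("guide Z-scores standardize with the sample sd", {
  z <- zscore_guides(c(a = -1, b = 0, c = 1))
  expect_equal(unname(z), c(-1, 0, 1))  # mean 0, sample sd 1
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # location invariance
  z2 <- zscore_guides(c(a = 9, b = 10, c = 11))
  expect_equal(unname(z2), unname(z))
  expect_error(zscore_guides(c(a = 2, b = 2, c = 2)), "dispersion")
  expect_error(zscore_guides(c(a = 1)), "2 guides")
  # control-based standardization centers on the non-cutting controls
  lfc <- setNames(c(rep(-4, 10), 1, 2, 3, 4), toy_lib$guide_id)
  zc <- zscore_guides(lfc, toy_lib, z_ref = "noncutting")
  nc <- lfc[toy_lib$guide_id[toy_lib$category == "noncutting_control"]]
  expect_equal(unname(zc["NC1"]), unname((1 - mean(nc)) / sd(nc)))
})

test_that("gene Z aggregates guides by mean (or median) per gene", {
  z <- setNames(c(rep(-2, 5), -3, -1, 10, 0, 0, rep(0, 4)), toy_lib$guide_id)
  gz <- gene_zscore(z, toy_lib)
  expect_equal(unname(gz["GA"]), -2)
  expect_equal(unname(gz["GB"]), 1.2)  # mean(-3, -1, 10, 0, 0)
  gzm <- gene_zscore(z, toy_lib, agg = "median")
  expect_equal(unname(gzm["GB"]), 0)
  expect_true("noncutting_control" %in% names(gz))
  expect_error(gene_zscore(z[-1], toy_lib), "without a Z")
})

test_that("delta fitness is half the Z difference and antisymmetric", {
  expect_equal(unname(delta_fitness(c(g = -3), c(g = 1))), -2)
  expect_equal(unname(delta_fitness(c(g = 1.3), c(g = 1.3))), 0)
  set.seed(4)
  za <- setNames(rnorm(50), paste0("g", 1:50))
  zb <- setNames(rnorm(50), paste0("g", 1:50))
  expect_equal(delta_fitness(za, zb), -delta_fitness(zb, za)[names(za)])
  expect_error(delta_fitness(c(a = 1), c(b = 1)), "differ")
})

test_that("hit calling is strictly below the threshold, sorted ascending", {
  fit <- data.frame(gene = c("a", "b", "c", "d"), day = 16,
                    z_a = 0, z_b = 0,
                    delta_z = c(-2.5, -2.0, -1.9, -7), hit = NA)
  hits <- call_hits(fit, 16)
  expect_equal(hits$gene, c("d", "a"))
  expect_false("b" %in% hits$gene)  # -2.0 is not < -2
})

test_that("score_screen composes the chain and is order-invariant", {
  cfg <- screen_sim_config(n_genes_of_interest = 30, n_control_genes = 5,
                           n_essential = 2, n_cutting_controls = 10,
                           n_noncutting_controls = 10, seed = 21,
                           fitness_effects = data.frame(
                             gene = "GOI001", cell_line = "lineA", effect = 2))
  sim <- simulate_screen(cfg)
  fit <- score_screen(sim$counts_a, sim$counts_b)
  d16 <- fit[fit$day == 16, ]
  expect_equal(d16$gene[which.min(d16$delta_z)], "GOI001")
  # identical counts in both lines: delta_z all zero, no hits
  fit0 <- score_screen(sim$counts_a,
                       count_matrix(sim$counts_a$counts,
                                    sim$counts_a$library, "lineB"))
  expect_equal(max(abs(fit0$delta_z)), 0)
  expect_false(any(fit0$hit))
  # permuting guide rows leaves the fitness table unchanged
  perm <- sample(nrow(sim$counts_b$counts))
  cb_perm <- count_matrix(sim$counts_b$counts[perm, ],
                          sim$counts_b$library, "lineB")
  expect_equal(score_screen(sim$counts_a, cb_perm), fit)
  # library mismatch names the offending guides
  lib2 <- sim$counts_a$library
  lib2$guide_id[1] <- "ROGUE_g1"
  cm2 <- sim$counts_a
  rownames(cm2$counts)[1] <- "ROGUE_g1"
  cm2$library <- lib2
  expect_error(score_screen(cm2, sim$counts_b), "ROGUE_g1")
})

test_that("per-sample guide Z has mean 0 and sd 1 under default standardization", {
  sim <- simulate_screen(screen_sim_config(seed = 31))
  norm <- normalize_counts(sim$counts_a)
  for (d in c(8, 16)) {
    z <- zscore_guides(log2fc_vs_reference(norm, d))
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("scaling one sample's counts preserves hit calls", {
  sim <- simulate_screen(screen_sim_config(
    seed = 41, fitness_effects = data.frame(gene = paste0("GOI00", 1:3),
                                            cell_line = "lineA", effect = 2)))
  fit <- score_screen(sim$counts_a, sim$counts_b)
  scaled <- sim$counts_a$counts
  scaled[, "D16"] <- scaled[, "D16"] * 7L
  fit2 <- score_screen(count_matrix(scaled, sim$counts_a$library, "lineA"),
                       sim$counts_b)
  h1 <- call_hits(fit, 16); h2 <- call_hits(fit2, 16)
  expect_setequal(h1$gene, h2$gene)
})
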