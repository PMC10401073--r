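test_that("the simulated library mirrors the configured composition", {
  lib <- sim_library(screen_sim_config())
  expect_equal(nrow(lib), (191 + 50 + 10) * 5 + 75 + 75)  # 1,405 guides
  expect_equal(sum(lib$category == "gene_of_interest"), 191 * 5)
  expect_equal(sum(lib$category == "essential"), 10 * 5)
  expect_equal(sum(lib$category == "noncutting_control"), 75)
  expect_false(anyDuplicated(lib$guide_id) > 0)
})

test_that("screen simulation is a pure function of its config", {
  cfg <- screen_sim_config(seed = 13)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$counts_a$counts, s2$counts_a$counts)
  expect_identical(s1$counts_b$counts, s2$counts_b$counts)
  s3 <- simulate_screen(screen_sim_config(seed = 14))
  expect_false(identical(s1$counts_a$counts, s3$counts_a$counts))
})

test_that("per-sample totals are exact under multinomial sequencing", {
  sim <- simulate_screen(screen_sim_config(seed = 2))
  expect_true(all(colSums(sim$counts_a$counts) == sim$truth$total_reads))
  expect_true(all(colSums(sim$counts_b$counts) == sim$truth$total_reads))
})

test_that("adding a sampling day does not perturb earlier samples", {
  c1 <- simulate_screen(screen_sim_config(seed = 5, days = c(5, 8, 16)))
  c2 <- simulate_screen(screen_sim_config(seed = 5, days = c(5, 8, 11, 16, 20)))
  shared <- c("D5", "D8", "D16")
  expect_identical(c1$counts_a$counts[, shared], c2$counts_a$counts[, shared])
})

test_that("planted effects deplete guides in the configured line only", {
  cfg <- screen_sim_config(seed = 8, fitness_effects = data.frame(
    gene = "GOI005", cell_line = "lineA", effect = 2))
  sim <- simulate_screen(cfg)
  g <- sim$counts_a$library$guide_id[
    !is.na(sim$counts_a$library$gene) & sim$counts_a$library$gene == "GOI005"]
  expect_lt(sum(sim$counts_a$counts[g, "D16"]),
            sum(sim$counts_a$counts[g, "D5"]) / 100)
  expect_gt(sum(sim$counts_b$counts[g, "D16"]),
            sum(sim$counts_b$counts[g, "D5"]) / 4)
  expect_error(simulate_screen(screen_sim_config(fitness_effects = data.frame(
    gene = "NOPE", cell_line = "lineA", effect = 1))), "unknown gene")
})

test_that("binomial pileup simulation recovers the true heteroplasmy", {
  th <- data.frame(position = 3745, ref = "G", alt = "A", fraction = 0.602)
  sim <- simulate_pileups(th, depth = 2000, n_replicates = 100, seed = 17)
  vafs <- vapply(sim$pileups, function(rep)
    vaf_from_pileup(rep[[1]], "A"), numeric(1))
  expect_lt(abs(mean(vafs) - 0.602), 0.01)
  # extremes are exact
  ext <- simulate_pileups(data.frame(position = c(1, 2), ref = "G", alt = "A",
                                     fraction = c(0, 1)),
                          depth = 500, seed = 1)
  expect_equal(vaf_from_pileup(ext$pileups[[1]][[1]], "A"), 0)
  expect_equal(vaf_from_pileup(ext$pileups[[1]][[2]], "A"), 1)
  # determinism
  sim2 <- simulate_pileups(th, depth = 2000, n_replicates = 100, seed = 17)
  expect_identical(sim$pileups[[5]][[1]]$counts, sim2$pileups[[5]][[1]]$counts)
})

test_that("overdispersed sequencing inflates count variance but keeps totals", {
  cfg_od <- screen_sim_config(seed = 3, overdispersion = 50,
                              initial_abundance_dispersion = 0)
  cfg_mn <- screen_sim_config(seed = 3, initial_abundance_dispersion = 0)
  od <- simulate_screen(cfg_od)$counts_a$counts[, "D5"]
  mn <- simulate_screen(cfg_mn)$counts_a$counts[, "D5"]
  expect_equal(sum(od), sum(mn))
  expect_gt(var(od), 2 * var(mn))
})

test_that("truth records round-trip through the JSON sidecar", {
  sim <- simulate_screen(screen_sim_config(seed = 19))
  f <- withr::local_tempfile(fileext = ".json")
  truth <- list(effects = as.data.frame(sim$truth$effects),
                total_reads = sim$truth$total_reads,
                seed = sim$truth$config$seed)
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$total_reads, truth$total_reads)
  expect_equal(back$seed, truth$seed)
  expect_equal(as.matrix(back$effects), sim$truth$effects,
               ignore_attr = TRUE)
})
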