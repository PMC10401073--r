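p <- analysis_params()

rec <- function(tv, nv = NA, td = 20, nd = if (is.na(nv)) NA else 20,
                pos = 3745, ref = "G", alt = "A", id = "T1") {
  mt_variant_record(id, pos, ref, alt, tumor_vaf = tv, tumor_depth = td,
                    normal_vaf = nv, normal_depth = nd)
}

test_that("matched-normal filter applies the printed thresholds", {
  expect_true(filter_matched(rec(0.50, 0.00), p)$passed)
  d <- filter_matched(rec(0.35, 0.00), p)
  expect_false(d$passed)
  expect_equal(d$reasons, "LOW_VAF_DIFF")  # 0.35 - 0 = 0.35 <= 0.4
  # boundary: depths inclusive at 15, diff 0.41 > 0.4
  expect_true(filter_matched(rec(0.45, 0.04, td = 15, nd = 15), p)$passed)
  # every failing clause is enumerated
  d <- filter_matched(rec(0.10, 0.20, td = 10, nd = 5), p)
  expect_setequal(d$reasons, c("LOW_DEPTH_TUMOR", "LOW_DEPTH_NORMAL",
                               "LOW_TUMOR_VAF", "HIGH_NORMAL_VAF",
                               "LOW_VAF_DIFF"))
  expect_false(d$passed)
  expect_error(filter_matched(rec(0.5), p), "filter_unmatched")
})

test_that("matched filter agrees with the brute-force oracle on the boundary grid", {
  grid <- expand.grid(tv = c(0.29, 0.30, 0.31, 0.45, 0.71),
                      nv = c(0.00, 0.04, 0.05, 0.06),
                      td = c(14, 15, 16),
                      nd = c(14, 15, 16))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- filter_matched(rec(g$tv, g$nv, td = g$td, nd = g$nd), p)$passed
    want <- oracle_filter_matched(g$tv, g$nv, g$td, g$nd)
    expect_identical(got, want,
                     label = sprintf("tv=%.2f nv=%.2f td=%d nd=%d",
                                     g$tv, g$nv, g$td, g$nd))
  }
})

test_that("unmatched filter reports LoF and whitelisted variants only", {
  model <- load_gene_model()
  fs <- annotate_variants(rec(0.5, td = 30, pos = 12417, ref = "CA", alt = "C"),
                          model)
  expect_true(filter_unmatched(fs, p = p)$passed)
  melas <- annotate_variants(rec(0.5, td = 30, pos = 3244), model)
  expect_true(filter_unmatched(melas, p = p)$passed)
  mis <- annotate_variants(rec(0.5, td = 30, pos = 3745), model)
  d <- filter_unmatched(mis, p = p)
  expect_false(d$passed)
  expect_equal(d$reasons, "NOT_LOF_UNMATCHED")
  # a study-specific whitelist admits it
  wl <- rbind(default_whitelist(),
              data.frame(position = 3745L, ref = "G", alt = "A"))
  expect_true(filter_unmatched(mis, wl, p)$passed)
  expect_error(filter_unmatched(rec(0.5, td = 30), p = p), "annotate")
  expect_error(filter_unmatched(annotate_variants(rec(0.5, 0.0), model), p = p),
               "filter_matched")
})

test_that("filtering an already-passed set is idempotent", {
  model <- load_gene_model()
  set.seed(11)
  tv <- runif(40, 0, 1); nv <- runif(40, 0, 0.2)
  vars <- do.call(rbind, lapply(seq_along(tv), function(i)
    rec(tv[i], nv[i], td = sample(10:40, 1), nd = sample(10:40, 1),
        pos = 3745 + i, id = paste0("T", i))))
  vars <- annotate_variants(vars, model)
  once <- apply_somatic_filters(vars, p = p)
  passed <- once[once$passed, setdiff(names(once), c("passed", "filter_reasons"))]
  twice <- apply_somatic_filters(passed, p = p)
  expect_true(all(twice$passed))
  expect_identical(passed$position, twice$position)
})

test_that("RNA validation uses a strict 10% boundary and flags zero depth", {
  v <- rec(0.6, td = 1000)
  expect_equal(validate_rna(v, pileup_column(3745, "G", c(G = 88, A = 12)), p),
               "validated")   # 0.12 > 0.10
  expect_equal(validate_rna(v, pileup_column(3745, "G", c(G = 90, A = 10)), p),
               "failed")      # 0.10 is not > 0.10
  expect_equal(validate_rna(v, pileup_column(3745, "G", c(G = 0, A = 0)), p),
               "not_assessable")
  expect_error(validate_rna(v, pileup_column(3746, "G", c(G = 10)), p),
               "position")
})

test_that("cell-line rule keeps nonsynonymous variants above VAF 0.1", {
  model <- load_gene_model()
  vars <- rbind(rec(0.602, pos = 3745),            # missense, kept
                rec(0.9, pos = 16500, ref = "A", alt = "C"),  # noncoding
                rec(0.05, pos = 3745, alt = "T"),  # below threshold
                rec(0.10, pos = 3745, alt = "C"),  # exactly 0.1: strict, dropped
                rec(0.8, pos = 3244))              # tRNA, kept
  vars <- annotate_variants(vars, model)
  kept <- call_cellline(vars, p = p)
  expect_equal(kept$position, c(3745L, 3244L))
  # protein_only drops the tRNA variant
  kept2 <- call_cellline(vars, p = p, protein_only = TRUE)
  expect_equal(kept2$position, 3745L)
  # blacklisted haplogroup marker is removed
  bl <- data.frame(position = 3745L, ref = "G", alt = "A")
  kept3 <- call_cellline(vars, bl, p)
  expect_equal(kept3$position, 3244L)
  expect_error(call_cellline(vars[, setdiff(names(vars), "effect")], p = p),
               "annotate")
})

test_that("VAF from pileup is the alt fraction of total depth", {
  col <- pileup_column(3745, "G", c(G = 398, A = 602))
  expect_equal(vaf_from_pileup(col, "A"), 0.602)
  expect_equal(vaf_from_pileup(pileup_column(1, "G", c(G = 100)), "A"), 0)
  expect_error(vaf_from_pileup(pileup_column(1, "C", c(C = 0)), "A"),
               "zero total depth")
  # indel keys count against total depth at the anchor base
  col <- pileup_column(10, "C", c(C = 60, "del:A" = 40))
  expect_equal(vaf_from_pileup(col, "del:A"), 0.4)
})
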