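model <- load_gene_model()

test_that("documented mitochondrial variants classify as reported", {
  e <- classify_effect(3745, "G", "A", model)
  expect_equal(e$effect, "missense")
  expect_equal(e$gene, "MT-ND1")
  expect_false(e$is_disruptive)
  expect_true(e$is_nonsynonymous)

  e <- classify_effect(3244, "G", "A", model)
  expect_equal(e$effect, "tRNA")
  expect_equal(e$gene, "MT-TL1")

  # single-base deletion inside a protein gene: 1 mod 3 != 0
  e <- classify_effect(12417, "CA", "C", model)
  expect_equal(e$effect, "frameshift")
  expect_equal(e$gene, "MT-ND5")
  expect_true(e$is_disruptive)

  # stop-gain: GGA -> AGA (vertebrate mitochondrial stop)
  e <- classify_effect(3916, "G", "A", model)
  expect_equal(e$effect, "nonsense")
  expect_true(e$is_disruptive)
})

test_that("indel length rule separates frameshift from in-frame", {
  e3 <- classify_effect(13000, "CAAA", "C", model)  # 3-bp deletion in ND5
  expect_equal(e3$effect, "inframe_indel")
  expect_false(e3$is_disruptive)
  e1 <- classify_effect(13000, "C", "CA", model)    # 1-bp insertion
  expect_equal(e1$effect, "frameshift")
  e6 <- classify_effect(13000, "C", "CAAAAAA", model)
  expect_equal(e6$effect, "inframe_indel")
})

test_that("invalid variant input is rejected", {
  expect_error(classify_effect(3745, "G", "G", model), "identical")
  expect_error(classify_effect(16570, "G", "A", model), "position")
  expect_error(classify_effect(3745, "G", "N", model), "A/C/G/T")
  expect_error(classify_effect(3745, "", "A", model), "A/C/G/T")
})

test_that("intergenic and near-origin positions classify without wrap errors", {
  expect_equal(classify_effect(16569, "A", "C", model)$effect, "noncoding")
  expect_equal(classify_effect(1, "A", "C", model)$effect, "noncoding")
  e <- classify_effect(16569, "AC", "A", model)  # deletion spanning origin
  expect_equal(e$effect, "noncoding")
  expect_equal(classify_effect(300, "G", "T", model)$effect, "noncoding")
})

test_that("overlapping genes are each classified and the worst is reported", {
  # MT-ATP8 (8366-8572) overlaps MT-ATP6 (8527-9207)
  e <- classify_effect(8530, "A", "AT", model)
  expect_equal(sort(e$details$gene), c("MT-ATP6", "MT-ATP8"))
  expect_equal(e$effect, "frameshift")
  # tRNA boundary variants spanning into a protein gene report the worst
  e <- classify_effect(3304, "GAAT", "G", model)  # MT-TL1 into MT-ND1 region
  expect_true("tRNA" %in% e$details$effect)
})

test_that("SNV classification matches a brute-force codon oracle", {
  prot <- model$features[model$features$type == "protein", ]
  set.seed(42)
  n_checked <- 0
  for (rep in 1:1200) {
    gi <- sample(nrow(prot), 1)
    feat <- prot[gi, ]
    pos <- sample(feat$start:feat$end, 1)
    others <- genes_at(model, pos)
    if (nrow(others) > 1) next  # overlap handled elsewhere
    ref <- model$sequence[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_effect(pos, ref, alt, model)
    want <- oracle_classify_snv(model$sequence, feat, pos, ref, alt)
    expect_equal(got$effect, want,
                 label = sprintf("m.%d %s>%s (%s)", pos, ref, alt, feat$name))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 1000)
})

test_that("severity ordering drives multi-gene resolution", {
  expect_true(all(diff(effect_severity(
    c("noncoding", "synonymous", "tRNA", "inframe_indel", "missense",
      "nonsense"))) > 0))
  expect_equal(effect_severity("frameshift"), effect_severity("nonsense"))
  expect_equal(effect_severity("rRNA"), effect_severity("tRNA"))
  expect_error(effect_severity("bogus"), "unknown effect")
})

test_that("synthetic protein frames carry no premature stop codons", {
  code <- oracle_mito_code
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  prot <- model$features[model$features$type == "protein", ]
  for (i in seq_len(nrow(prot))) {
    s <- prot$start[i]; e <- prot$end[i]
    n_codon <- (e - s + 1) %/% 3
    codons <- vapply(seq_len(n_codon) - 1, function(k) {
      if (prot$strand[i] == "heavy")
        paste(model$sequence[s + 3 * k + 0:2], collapse = "")
      else paste(comp[model$sequence[e - 3 * k - 0:2]], collapse = "")
    }, character(1))
    expect_false(any(code[codons] == "*"),
                 label = paste("premature stop in", prot$name[i]))
  }
})
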