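# Simulator correctness: ancestor construction, regime-driven
# evolution, truth fidelity, lineage nesting, determinism.

test_that("generated ancestors are ORF-valid, GC-controlled and deterministic", {
  g <- generateAncestor(50000, 0.5, 40, 900, seed = BASE_SEED)
  ft <- cdsFeatures(g)
  expect_length(ft, 40L)
  expect_false(any(S4Vectors::mcols(ft)$pseudo))
  seq <- genomeSeq(g)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(ft)) {
    region <- substr(seq, GenomicRanges::start(ft)[i],
                     GenomicRanges::end(ft)[i])
    cds <- if (as.character(GenomicRanges::strand(ft))[i] == "+") region
           else revCompStr(region)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% stops)
    expect_false(any(codons[-length(codons)] %in% stops))
  }
  # non-overlapping CDS
  o <- order(GenomicRanges::start(ft))
  expect_true(all(GenomicRanges::start(ft)[o][-1] >
                  GenomicRanges::end(ft)[o][-length(ft)]))
  gcFrac <- mean(strsplit(seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcFrac - 0.5), 0.02)
  # determinism
  g2 <- generateAncestor(50000, 0.5, 40, 900, seed = BASE_SEED)
  expect_identical(genomeSeq(g2), seq)
  # degenerate GC target
  expect_error(generateAncestor(50000, 1.0, 40, 900, seed = 1), "degenerate")
  expect_error(generateAncestor(5000, 0.5, 40, 900, seed = 1), "infeasible")
})

test_that("evolveGenome honours n, truth fidelity and determinism", {
  anc <- generateAncestor(30000, 0.5, 20, 900, seed = BASE_SEED)
  # n = 0: identity
  e0 <- evolveGenome(anc, "wildtype", 0, seed = 1)
  expect_identical(genomeSeq(e0$genome), genomeSeq(anc))
  expect_length(e0$truth, 0L)
  # truth applied to the ancestor reproduces the derived genome exactly
  ev <- evolveGenome(anc, "MMR", 150, seed = 2)
  expect_length(ev$truth, 150L)
  expect_identical(applyVariantSet(ev$truth, anc), genomeSeq(ev$genome))
  # determinism: byte-identical outputs
  ev2 <- evolveGenome(anc, "MMR", 150, seed = 2)
  expect_identical(genomeSeq(ev2$genome), genomeSeq(ev$genome))
  expect_identical(variants(ev2$truth), variants(ev$truth))
  # distinct, well-separated sites
  v <- variants(ev$truth)
  expect_true(all(diff(v$pos) > 0))
})

test_that("a fully biased regime only produces its own substitution class", {
  anc <- generateAncestor(30000, 0.5, 20, 900, seed = BASE_SEED)
  w <- c(0, 0, 1, 0, 0, 0)  # all weight on A:T>C:G
  reg <- mutatorRegime(w, indelFraction = 0, name = "forced")
  ev <- evolveGenome(anc, reg, 100, seed = 3)
  v <- variants(ev$truth)
  expect_true(all(v$ref %in% c("A", "T")))
  expect_true(all(classifySubstitution(v$ref, v$alt) == "A:T>C:G"))
})

test_that("per-class truth counts match the multinomial expectation", {
  # chi-square goodness of fit of SNP class counts against the MMR
  # preset weights, across 20 seeds
  anc <- generateAncestor(60000, 0.5, 40, 900, seed = BASE_SEED)
  reg <- regimePreset("MMR")
  w <- classWeights(reg)
  pvals <- vapply(1:20, function(s) {
    ev <- evolveGenome(anc, reg, 600, seed = s)
    cl <- attr(ev$truth, "mutClass")
    cl <- cl[cl != "indel"]
    counts <- table(factor(cl, levels = names(w)))
    suppressWarnings(stats::chisq.test(counts, p = w)$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 0.001)
})

test_that("lineage histories nest variant sets and respect per-edge seeds", {
  anc <- generateAncestor(40000, 0.5, 30, 700, seed = BASE_SEED)
  plan <- data.frame(parent = c("root", "B", "F"),
                     child = c("B", "F", "A"),
                     n = c(10L, 50L, 100L),
                     regime = "wildtype")
  sim <- simulateCollectionHistory(anc, plan, seed = 7)
  kB <- variantKeys(sim$truth$B)
  kF <- variantKeys(sim$truth$F)
  kA <- variantKeys(sim$truth$A)
  expect_length(kB, 10L)
  expect_length(kF, 60L)
  expect_length(kA, 160L)
  expect_true(all(kB %in% kF))
  expect_true(all(kF %in% kA))
  # truth fidelity for every emitted genome
  for (nm in c("B", "F", "A")) {
    expect_identical(applyVariantSet(sim$truth[[nm]], anc),
                     genomeSeq(sim$genomes[[nm]]))
  }
  # identical edges under identical seeds give identical derived genomes
  sim2 <- simulateCollectionHistory(anc, plan, seed = 7)
  expect_identical(genomeSeq(sim2$genomes$A), genomeSeq(sim$genomes$A))
})

test_that("invalid plans are rejected", {
  expect_error(validatePlan(data.frame(parent = "a", child = "a")),
               "columns")
  expect_error(validatePlan(data.frame(parent = c("r", "x"),
                                       child = c("b", "c"),
                                       n = 1L, regime = "MMR")),
               "root|parent")
  expect_error(validatePlan(data.frame(parent = "r", child = "b",
                                       n = -1L, regime = "MMR")))
  expect_error(validatePlan(data.frame(parent = "r", child = "b",
                                       n = 1L, regime = "bogus")),
               "regime")
})

test_that("spectrum of simulated truth converges to the regime weights", {
  anc <- generateAncestor(100000, 0.5, 60, 900, seed = BASE_SEED)
  reg <- regimePreset("MutT")
  ev <- evolveGenome(anc, reg, 1100, seed = 11)
  pr <- computeSpectrum(ev$truth)
  n <- nSnp(pr)
  w <- classWeights(reg)
  for (cl in names(w)) {
    sd <- sqrt(n * w[[cl]] * (1 - w[[cl]]))
    expect_lt(abs(spectrumCounts(pr)[[cl]] - n * w[[cl]]), 3 * sd + 1e-9)
  }
})

test_that("squatter fixtures carry exactly one CDS-altering change in the target", {
  ids <- c("ompR", "envZ", sprintf("g%02d", 1:18))
  parent <- generateAncestor(30000, 0.5, 20, 800, seed = BASE_SEED,
                             geneIds = ids)
  fx <- makeSquatterFixture(parent, "ompR", "missense", seed = 5,
                            nBackground = 6)
  ann <- annotateVariants(fx$truth, parent)
  altering <- ann[!ann$kind %in% c("synonymous", "intergenic"), ]
  expect_equal(nrow(altering), 1L)
  expect_equal(altering$gene_id, "ompR")
  expect_equal(altering$kind, "missense")
  # everything else is background noise: synonymous or intergenic
  expect_equal(nrow(ann), 1L + 6L)
  expect_identical(applyVariantSet(fx$truth, parent), genomeSeq(fx$genome))

  fx2 <- makeSquatterFixture(parent, "envZ", "frameshift", seed = 6,
                             nBackground = 4)
  ann2 <- annotateVariants(fx2$truth, parent)
  hit <- ann2[!ann2$kind %in% c("synonymous", "intergenic"), ]
  expect_equal(hit$gene_id, "envZ")
  expect_equal(hit$kind, "frameshift")
  expect_true(hit$vclass %in% c("INS", "DEL"))
  expect_true((nchar(hit$alt) - nchar(hit$ref)) %% 3 != 0)
})
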