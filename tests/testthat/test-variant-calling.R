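# Collinear calling, the coverage/quality filter and consequence
# annotation.

test_that("identical genomes yield an empty call set", {
  g <- generateAncestor(20000, 0.5, 10, 600, seed = BASE_SEED)
  vs <- callVariantsCollinear(g, g)
  expect_length(vs, 0L)
})

test_that("a single planted substitution is called exactly", {
  g <- generateAncestor(20000, 0.5, 10, 600, seed = BASE_SEED)
  seq <- genomeSeq(g)
  refB <- substr(seq, 1234, 1234)
  altB <- setdiff(c("A", "C", "G", "T"), refB)[1]
  q <- seq
  substr(q, 1234, 1234) <- altB
  vs <- callVariantsCollinear(g, AnnotatedGenome("q", q))
  v <- variants(vs)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 1234L)
  expect_equal(v$ref, refB)
  expect_equal(v$alt, altB)
})

test_that("mixed simulated mutations are recovered with recall and precision 1", {
  anc <- generateAncestor(50000, 0.5, 40, 900, seed = BASE_SEED)
  ev <- evolveGenome(anc, "MMR", 200, seed = 12)
  vs <- callVariantsCollinear(anc, ev$genome)
  expect_setequal(variantKeys(vs), variantKeys(ev$truth))
})

test_that("call-apply round trip holds across seeds and regimes (property)", {
  anc <- generateAncestor(30000, 0.5, 20, 700, seed = BASE_SEED)
  for (s in 1:6) {
    reg <- c("MMR", "MutT", "wildtype")[(s %% 3) + 1]
    ev <- evolveGenome(anc, reg, 120, seed = s)
    vs <- callVariantsCollinear(anc, ev$genome)
    expect_identical(applyVariantSet(vs, anc), genomeSeq(ev$genome))
    expect_setequal(variantKeys(vs), variantKeys(ev$truth))
  }
})

test_that("rearranged genomes raise an explicit non-collinear error", {
  g <- generateAncestor(20000, 0.5, 10, 600, seed = BASE_SEED)
  seq <- genomeSeq(g)
  half <- nchar(seq) %/% 2
  shuffled <- paste0(substr(seq, half + 1, nchar(seq)),
                     substr(seq, 1, half))
  expect_error(callVariantsCollinear(g, AnnotatedGenome("q", shuffled)),
               "non-collinear")
})

test_that("the coverage/quality filter applies strict and inclusive bounds", {
  mk <- function(af, dp, qual) {
    VariantSet("r", "x", pos = 100L, ref = "A", alt = "G",
               qual = qual, dp = dp, af = af)
  }
  th <- filterThresholds()
  expect_length(filterVariants(mk(0.6, 12, 25), th), 1L)   # above all
  expect_length(filterVariants(mk(0.5, 12, 25), th), 0L)   # rel strict >
  expect_length(filterVariants(mk(0.9, 10, 25), th), 0L)   # abs strict >
  expect_length(filterVariants(mk(0.9, 12, 22), th), 0L)   # qual below
  expect_length(filterVariants(mk(0.9, 12, 23), th), 1L)   # qual inclusive >=
  # missing metadata passes with a warning
  noMeta <- VariantSet("r", "x", pos = 100L, ref = "A", alt = "G")
  expect_warning(kept <- filterVariants(noMeta, th), "metadata")
  expect_length(kept, 1L)
})

test_that("raising any threshold never adds variants (monotonicity)", {
  set.seed(BASE_SEED)
  n <- 60L
  vs <- VariantSet("r", "x", pos = seq_len(n) * 10L,
                   ref = rep("A", n), alt = rep("G", n),
                   qual = round(runif(n, 15, 35)),
                   dp = round(runif(n, 5, 25)),
                   af = runif(n))
  base <- variantKeys(filterVariants(vs))
  for (i in 1:10) {
    th <- filterThresholds(minRelCoverage = runif(1, 0.5, 0.9),
                           minAbsCoverage = sample(10:20, 1),
                           minQuality = sample(23:30, 1))
    expect_true(all(variantKeys(filterVariants(vs, th)) %in% base))
  }
})

test_that("SNP consequences are annotated with protein-level names", {
  # gene with Arg (CGT) at codon 190; C>T gives R190C
  cds <- randomCds(250, seed = 101)
  substr(cds, 3 * 189 + 1, 3 * 190) <- "CGT"
  g <- toyGenome(cds)
  gs <- GenomicRanges::start(cdsFeatures(g))[1]
  pos <- gs + 3L * 189L
  vs <- VariantSet("toy", "x", pos = pos, ref = "C", alt = "T")
  ann <- annotateVariants(vs, g)
  expect_equal(ann$kind, "missense")
  expect_equal(ann$hgvs, "R190C")
  expect_equal(ann$codon_index, 190L)
  # mature-protein numbering via a per-gene offset
  ann2 <- annotateVariants(vs, g, proteinOffsets = c(tg01 = 22L))
  expect_equal(ann2$hgvs, "R168C")

  # third-position AAA>AAG stays Lys: synonymous
  cds2 <- randomCds(50, seed = 102)
  substr(cds2, 31, 33) <- "AAA"
  g2 <- toyGenome(cds2)
  gs2 <- GenomicRanges::start(cdsFeatures(g2))[1]
  vs2 <- VariantSet("toy", "x", pos = gs2 + 32L, ref = "A", alt = "G")
  ann <- annotateVariants(vs2, g2)
  expect_equal(ann$kind, "synonymous")

  # premature stop: nonsense
  substr(cds2, 34, 36) <- "TGG"  # Trp; G>A at codon pos 2 gives TAG stop
  g3 <- toyGenome(cds2)
  gs3 <- GenomicRanges::start(cdsFeatures(g3))[1]
  vs3 <- VariantSet("toy", "x", pos = gs3 + 34L, ref = "G", alt = "A")
  ann <- annotateVariants(vs3, g3)
  expect_equal(ann$kind, "nonsense")
})

test_that("in-frame deletions are named over the 3'-shifted residue range", {
  # Leu-Ala repeat at codons 66-69; deleting one LA unit names L68_A69del
  cds <- randomCds(120, seed = 103)
  substr(cds, 3 * 65 + 1, 3 * 69) <- paste0("CTG", "GCG", "CTG", "GCG")
  substr(cds, 3 * 69 + 1, 3 * 71) <- "AAAAAA"  # Lys-Lys ends the repeat
  g <- toyGenome(cds)
  gs <- GenomicRanges::start(cdsFeatures(g))[1]
  # delete 6 bp starting at codon 66 (left placement in the DNA repeat)
  delStart <- gs + 3L * 65L
  ref <- substr(genomeSeq(g), delStart - 1L, delStart + 5L)
  vs <- VariantSet("toy", "x", pos = delStart - 1L, ref = ref,
                   alt = substr(ref, 1, 1))
  vs <- normalizeVariants(vs, g)
  ann <- annotateVariants(vs, g)
  expect_equal(ann$kind, "inframe_del")
  expect_equal(ann$hgvs, "L68_A69del")
})

test_that("+1 insertions inside a CDS C tract are frameshifts", {
  cds <- randomCds(80, seed = 104)
  substr(cds, 40, 45) <- "CCCCCC"
  # keep the frame downstream irrelevant: any +1 is a frameshift
  g <- toyGenome(cds)
  gs <- GenomicRanges::start(cdsFeatures(g))[1]
  p <- gs + 41L
  b <- substr(genomeSeq(g), p, p)
  vs <- normalizeVariants(
    VariantSet("toy", "x", pos = p, ref = b, alt = paste0(b, "C")), g)
  ann <- annotateVariants(vs, g)
  expect_equal(ann$kind, "frameshift")
  expect_equal(ann$hgvs, "fs")
})

test_that("annotation kinds are strand-symmetric", {
  cds <- randomCds(100, seed = 105)
  gPlus <- toyGenome(cds, strands = "+")
  gMinus <- toyGenome(cds, strands = "-")
  gsP <- GenomicRanges::start(cdsFeatures(gPlus))[1]
  gsM <- GenomicRanges::start(cdsFeatures(gMinus))[1]
  geM <- GenomicRanges::end(cdsFeatures(gMinus))[1]
  set.seed(BASE_SEED)
  for (i in 1:15) {
    off <- sample(3:(nchar(cds) - 4), 1)  # 0-based offset in the CDS
    refB <- substr(cds, off + 1, off + 1)
    altB <- sample(setdiff(c("A", "C", "G", "T"), refB), 1)
    vP <- VariantSet("toy", "x", pos = gsP + off, ref = refB, alt = altB)
    vM <- VariantSet("toy", "x", pos = geM - off,
                     ref = chartr("ACGT", "TGCA", refB),
                     alt = chartr("ACGT", "TGCA", altB))
    aP <- annotateVariants(vP, gPlus)
    aM <- annotateVariants(vM, gMinus)
    expect_equal(aM$kind, aP$kind)
    expect_equal(aM$hgvs, aP$hgvs)
  }
})

test_that("a variant overlapping two CDS is annotated once per CDS", {
  cds1 <- "ATGAAACCCTAA"
  cds2 <- "ATGTTTGGGTGA"
  # overlap: place gene 2 starting inside gene 1 by constructing manually
  seq <- paste0("TTTTT", cds1, "TTTTT")
  seq <- paste0(seq, cds2, "TTTTT")
  g <- AnnotatedGenome("toy", seq, features = data.frame(
    gene_id = c("a", "b"),
    start = c(6L, 6L + 12L + 5L), end = c(17L, 6L + 12L + 5L + 11L),
    strand = c("+", "+")))
  # two separate CDS first: sanity
  vs <- VariantSet("toy", "x", pos = 9L, ref = "A", alt = "C")
  expect_equal(nrow(annotateVariants(vs, g)), 1L)
  # overlapping features
  g2 <- AnnotatedGenome("toy", seq, features = data.frame(
    gene_id = c("a", "ov"), start = c(6L, 9L), end = c(17L, 17L),
    strand = c("+", "+")))
  ann <- annotateVariants(vs, g2)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$gene_id, c("a", "ov"))
})
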