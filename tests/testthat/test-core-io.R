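# FASTA/GFF3/VCF round trips and variant normalization.

test_that("FASTA reading and writing preserve sequences and order", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g", "ACGT"), tmp)
  gs <- readGenomeFasta(tmp)
  expect_length(gs, 1L)
  expect_equal(genomeId(gs[[1]]), "g")
  expect_equal(genomeLength(gs[[1]]), 4L)
  expect_equal(genomeSeq(gs[[1]]), "ACGT")

  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtacgt", ">b", "GGGTTTCCC"), tmp2)
  gs2 <- readGenomeFasta(tmp2)
  expect_equal(names(gs2), c("a", "b"))
  expect_equal(genomeSeq(gs2[[1]]), "ACGTACGT")  # uppercased

  tmp3 <- withr::local_tempfile(fileext = ".fasta")
  writeGenomeFasta(gs2, tmp3)
  back <- readGenomeFasta(tmp3)
  expect_equal(lapply(back, genomeSeq), lapply(gs2, genomeSeq))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readGenomeFasta(empty))
})

test_that("GFF3 CDS annotation is read with strand and bounds checks", {
  g <- AnnotatedGenome("chr1", strrep("ACGT", 10))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=geneA",
    "chr1\tsrc\tgene\t1\t9\t.\t+\t.\tID=skipme",
    "chr1\tsrc\tCDS\t11\t19\t.\t-\t0\tID=geneB"
  ), tmp)
  ann <- readCdsAnnotation(tmp, g)
  ft <- cdsFeatures(ann)
  expect_length(ft, 2L)
  expect_equal(S4Vectors::mcols(ft)$gene_id, c("geneA", "geneB"))
  expect_equal(as.character(GenomicRanges::strand(ft)), c("+", "-"))
  # 9 bp => 3 codons, not pseudo
  expect_false(any(S4Vectors::mcols(ft)$pseudo))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t30\t100\t.\t+\t0\tID=tooLong"), bad)
  expect_error(readCdsAnnotation(bad, g), "outside")

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".gff3")
  writeCdsAnnotation(ann, out)
  ann2 <- readCdsAnnotation(out, g)
  expect_equal(GenomicRanges::start(cdsFeatures(ann2)),
               GenomicRanges::start(ft))
})

test_that("VCF reading maps QUAL/DP/AF and anchored indels", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="a">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "ref\t5\t.\tA\tG\t30\tPASS\tDP=15;AF=0.9",
    "ref\t9\t.\tC\tCT\t25\tPASS\tDP=12;AF=0.8"
  ), tmp)
  vs <- readVariantVcf(tmp, isolateId = "iso1")
  v <- variants(vs)
  expect_equal(v$pos, c(5L, 9L))
  expect_equal(v$vclass, c("SNP", "INS"))
  expect_equal(v$qual, c(30, 25))
  expect_equal(v$dp, c(15, 12))
  expect_equal(v$af, c(0.9, 0.8))
})

test_that("VCF write/read round trip is the identity on normalized sets", {
  vs <- VariantSet("ref", "iso", pos = c(3L, 10L, 20L),
                   ref = c("A", "C", "GAT"), alt = c("T", "CTT", "G"),
                   qual = c(40, 35, 33), dp = c(20, 21, 22),
                   af = c(0.95, 0.9, 0.85))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeVariantVcf(vs, tmp, contigLength = 100L)
  back <- readVariantVcf(tmp, isolateId = "iso")
  expect_equal(variants(back), variants(vs))
  expect_equal(referenceId(back), "ref")
})

test_that("indel normalization left-aligns and is idempotent", {
  # run of C at positions 10-13
  g <- AnnotatedGenome("r", paste0("ATGCTAGCT", "CCCC", strrep("GATTAG", 5)))
  # the same +C haplotype written at every offset inside the run
  placements <- lapply(10:13, function(p) {
    b <- substr(genomeSeq(g), p, p)
    VariantSet("r", "x", pos = p, ref = b, alt = paste0(b, "C"))
  })
  norm <- lapply(placements, normalizeVariants, genome = g)
  keys <- vapply(norm, variantKeys, character(1))
  expect_length(unique(keys), 1L)
  expect_equal(variants(norm[[1]])$pos, 9L)  # anchored left of the run
  # idempotent
  expect_equal(variants(normalizeVariants(norm[[1]], g)),
               variants(norm[[1]]))
  # SNPs unchanged
  snp <- VariantSet("r", "x", pos = 5L, ref = "T", alt = "G")
  expect_equal(variants(normalizeVariants(snp, g)), variants(snp))
})

test_that("equivalent deletion placements normalize identically (apply oracle)", {
  # deleting TGC at offset 4 of CTGCTGC equals the left-aligned deletion
  core <- "CTGCTGC"
  g <- AnnotatedGenome("r", paste0("AAAAA", core, "AAAAA"))
  # placement 1: delete the rightmost TGC (genome 10-12, anchor 9)
  v1 <- VariantSet("r", "x", pos = 9L, ref = "CTGC", alt = "C")
  # placement 2: delete the left TGC (genome 7-9, anchor 6)
  v2 <- VariantSet("r", "x", pos = 6L, ref = "CTGC", alt = "C")
  # oracle: both placements produce the same derived string
  expect_equal(applyVariantSet(v1, g), applyVariantSet(v2, g))
  n1 <- normalizeVariants(v1, g)
  n2 <- normalizeVariants(v2, g)
  expect_equal(variants(n1), variants(n2))
  # and applying the normalized record still gives that string
  expect_equal(applyVariantSet(n1, g), applyVariantSet(v1, g))
})

test_that("normalization rejects a mismatching reference allele", {
  g <- AnnotatedGenome("r", "AAAATTTT")
  bad <- VariantSet("r", "x", pos = 2L, ref = "T", alt = "G")
  expect_error(normalizeVariants(bad, g), "does not match")
})

test_that("VariantSet validity enforces sorting and uniqueness", {
  vs <- VariantSet("r", "x", pos = c(9L, 3L, 3L), ref = c("A", "C", "C"),
                   alt = c("G", "T", "T"))
  expect_equal(variants(vs)$pos, c(3L, 9L))  # sorted, deduplicated
  expect_error(VariantSet("r", "x", pos = 0L, ref = "A", alt = "C"))
})
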