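# cgMLST scheme building, allele calling, distances, clustering,
# SNP alignment export and set-specific gene detection.

test_that("scheme construction drops short, ambiguous and paralogous targets", {
  g <- generateAncestor(40000, 0.5, 30, 800, seed = BASE_SEED)
  sch <- buildScheme(g)
  expect_equal(length(sch), 30L)
  expect_setequal(schemeTargets(sch)$gene_id,
                  S4Vectors::mcols(cdsFeatures(g))$gene_id)

  # duplicate one gene elsewhere in the genome: both copies are dropped
  ft <- cdsFeatures(g)
  seq <- genomeSeq(g)
  gs <- GenomicRanges::start(ft)[1]; ge <- GenomicRanges::end(ft)[1]
  dup <- substr(seq, gs, ge)
  # overwrite a long intergenic stretch near the end with the duplicate
  ins <- nchar(seq) - nchar(dup) - 10L
  seq2 <- seq
  substr(seq2, ins, ins + nchar(dup) - 1L) <- dup
  fdf <- data.frame(gene_id = c(S4Vectors::mcols(ft)$gene_id, "dup01"),
                    start = c(GenomicRanges::start(ft), ins),
                    end = c(GenomicRanges::end(ft), ins + nchar(dup) - 1L),
                    strand = c(as.character(GenomicRanges::strand(ft)), "+"))
  g2 <- AnnotatedGenome("dupped", seq2, features = fdf)
  sch2 <- buildScheme(g2)
  expect_false(any(c(S4Vectors::mcols(ft)$gene_id[1], "dup01") %in%
                   schemeTargets(sch2)$gene_id))

  # ambiguity codes exclude a target
  seq3 <- seq
  substr(seq3, gs + 10L, gs + 10L) <- "N"
  g3 <- AnnotatedGenome("withn", seq3, features = as.data.frame(
    cbind(data.frame(gene_id = S4Vectors::mcols(ft)$gene_id,
                     start = GenomicRanges::start(ft),
                     end = GenomicRanges::end(ft),
                     strand = as.character(GenomicRanges::strand(ft))))))
  sch3 <- buildScheme(g3)
  expect_equal(length(sch3), 29L)
})

test_that("allele calling assigns reference and novel alleles and distances", {
  g <- generateAncestor(30000, 0.5, 20, 700, seed = BASE_SEED)
  sch <- buildScheme(g)
  ev <- evolveGenome(g, "wildtype", 25, seed = 9, isolateId = "mut")
  prof <- callAlleleProfiles(sch, list(ref = g, mut = ev$genome))
  # query identical to the reference: every allele is 1
  expect_true(all(prof[, "ref"] == 1L))
  # mutated targets get novel ids, untouched targets stay 1
  ann <- annotateVariants(ev$truth, g)
  mutGenes <- unique(ann$gene_id[!is.na(ann$gene_id)])
  expect_true(all(prof[mutGenes, "mut"] > 1L))
  expect_true(all(prof[setdiff(rownames(prof), mutGenes), "mut"] == 1L))
  d <- allelicDistance(prof)
  expect_equal(unname(d["ref", "mut"]), length(mutGenes))
  expect_equal(diag(d), c(ref = 0, mut = 0))
})

test_that("single-SNP queries differ by one allele at that target", {
  g <- generateAncestor(20000, 0.5, 12, 600, seed = BASE_SEED)
  sch <- buildScheme(g)
  ft <- cdsFeatures(g)
  p <- GenomicRanges::start(ft)[5] + 10L
  seq <- genomeSeq(g)
  q <- seq
  refB <- substr(seq, p, p)
  substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), refB)[1]
  prof <- callAlleleProfiles(sch, list(ref = g,
                                       one = AnnotatedGenome("one", q)))
  hit <- S4Vectors::mcols(ft)$gene_id[5]
  expect_equal(unname(prof[hit, "one"]), 2L)
  expect_true(all(prof[setdiff(rownames(prof), hit), "one"] == 1L))
  expect_equal(unname(allelicDistance(prof)["ref", "one"]), 1)
})

test_that("contig-border-truncated targets are MISSING under pairwise deletion", {
  g <- generateAncestor(20000, 0.5, 12, 600, seed = BASE_SEED)
  sch <- buildScheme(g)
  ft <- cdsFeatures(g)
  seq <- genomeSeq(g)
  # split the query in the middle of target 6: both contigs truncate it
  mid <- (GenomicRanges::start(ft)[6] + GenomicRanges::end(ft)[6]) %/% 2L
  contigs <- list(AnnotatedGenome("c1", substr(seq, 1, mid)),
                  AnnotatedGenome("c2", substr(seq, mid + 1L, nchar(seq))))
  prof <- callAlleleProfiles(sch, list(ref = g, split = contigs))
  broken <- S4Vectors::mcols(ft)$gene_id[6]
  expect_true(is.na(prof[broken, "split"]))
  expect_true(all(prof[setdiff(rownames(prof), broken), "split"] == 1L))
  d <- allelicDistance(prof)
  expect_equal(unname(d["ref", "split"]), 0)
  expect_equal(unname(attr(d, "n_compared")["ref", "split"]),
               nrow(prof) - 1L)
})

test_that("allelic distance uses pairwise deletion on hand-built profiles", {
  prof <- matrix(c(1L, 1L, 1L, 1L, 1L,
                   2L, 2L, NA, 1L, 1L), ncol = 2,
                 dimnames = list(paste0("t", 1:5), c("a", "b")))
  d <- allelicDistance(prof)
  # 3 differing targets, 1 of them MISSING in b: distance 2
  expect_equal(unname(d["a", "b"]), 2)
  expect_equal(unname(attr(d, "n_compared")["a", "b"]), 4L)
  expect_true(isSymmetric(unclass(d)))
})

test_that("UPGMA reproduces hand-computed and brute-force agglomerations", {
  # 2 taxa at distance 2: root at height 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgmaTree(d2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["a", "b"]), 2)
  expect_equal(max(ape::node.depth.edgelength(t2)), 1)
  # 3 taxa: d(A,B)=2, d(A,C)=d(B,C)=6 -> ((A,B) at 1, C) at 3
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgmaTree(d3)
  coph <- ape::cophenetic.phylo(t3)
  expect_equal(unname(coph["A", "B"]), 2)
  expect_equal(unname(coph["A", "C"]), 6)
  expect_true(sameUnrootedTopology(
    t3, ape::read.tree(text = "((A,B),C);")))
  # random matrices up to 6 taxa against the naive oracle
  set.seed(BASE_SEED)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 1, 100)
    m <- m + t(m)
    tr <- upgmaTree(m)
    expect_equal(phyloCophenetic(tr),
                 bruteAverageLinkage(m)[order(letters[1:n]),
                                        order(letters[1:n])],
                 tolerance = 1e-9)
  }
})

test_that("binary variant matrices give Manhattan distances equal to set differences", {
  a <- VariantSet("r", "a", pos = c(1L, 5L, 9L), ref = rep("A", 3),
                  alt = rep("G", 3))
  b <- VariantSet("r", "b", pos = c(21L, 25L, 29L, 33L), ref = rep("C", 4),
                  alt = rep("T", 4))
  m <- binaryVariantMatrix(list(a = a, b = b))
  expect_equal(ncol(m), 7L)
  expect_equal(unname(as.matrix(dist(m, "manhattan"))["a", "b"]), 7)
  # identical sets give identical rows
  m2 <- binaryVariantMatrix(list(x = a, y = a))
  expect_equal(unname(m2["x", ]), unname(m2["y", ]))
  # average-linkage Manhattan: two rows differing in k columns merge at k
  t2 <- averageLinkageManhattan(m)
  expect_equal(unname(ape::cophenetic.phylo(t2)["a", "b"]), 7)
  # brute-force agreement on random binary matrices
  set.seed(BASE_SEED + 1)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    bm <- matrix(rbinom(n * 30, 1, 0.4), nrow = n,
                 dimnames = list(letters[1:n], NULL))
    d <- as.matrix(dist(bm, method = "manhattan"))
    if (any(d[upper.tri(d)] == 0)) next  # degenerate duplicates
    tr <- averageLinkageManhattan(bm)
    expect_equal(phyloCophenetic(tr),
                 bruteAverageLinkage(d)[order(letters[1:n]),
                                        order(letters[1:n])],
                 tolerance = 1e-9)
  }
})

test_that("SNP alignment export concatenates segregating columns in order", {
  g <- AnnotatedGenome("ref", strrep("ACGT", 25))
  s1 <- VariantSet("ref", "i1", pos = c(2L, 30L), ref = c("C", "C"),
                   alt = c("T", "A"))
  s2 <- VariantSet("ref", "i2", pos = c(30L, 50L, 70L),
                   ref = c("C", "C", "C"), alt = c("G", "T", "T"))
  s3 <- VariantSet("ref", "i3", pos = c(2L, 14L),
                   ref = c("C", "C"), alt = c("T", "G"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  phy <- withr::local_tempfile(fileext = ".phy")
  m <- exportSnpAlignment(list(i1 = s1, i2 = s2, i3 = s3), g,
                          fastaPath = fa, phylipPath = phy)
  expect_equal(dim(m), c(4L, 5L))
  expect_equal(colnames(m), as.character(c(2, 14, 30, 50, 70)))
  expect_equal(rownames(m)[1], "ref")
  # isolates without a call carry the reference base
  expect_equal(unname(m["i1", "14"]), "C")
  expect_equal(unname(m["i3", "14"]), "G")
  # files round-trip
  backFa <- readGenomeFasta(fa)
  expect_equal(genomeSeq(backFa[["i2"]]),
               paste(m["i2", ], collapse = ""))
  phyLines <- readLines(phy)
  expect_match(phyLines[1], "^\\s*4\\s+5")
  # no SNPs: explicit error
  expect_error(exportSnpAlignment(
    list(empty = VariantSet("ref", "empty")), g), "no segregating")
})

test_that("set-specific genes recover a planted plasmid block exactly", {
  chrom <- generateAncestor(30000, 0.5, 20, 700, seed = BASE_SEED)
  plasmid <- generateAncestor(8000, 0.5, 10, 600, seed = BASE_SEED + 1,
                              geneIds = sprintf("plas%02d", 1:10))
  evA <- evolveGenome(chrom, "wildtype", 30, seed = 21, isolateId = "A1")
  evB <- evolveGenome(chrom, "wildtype", 30, seed = 22, isolateId = "A2")
  evC <- evolveGenome(chrom, "wildtype", 30, seed = 23, isolateId = "B1")
  evD <- evolveGenome(chrom, "wildtype", 30, seed = 24, isolateId = "B2")
  plasMut <- evolveGenome(plasmid, "wildtype", 5, seed = 25,
                          isolateId = "plasmidA2")
  withPlasmid <- list(A1 = list(evA$genome, plasmid),
                      A2 = list(evB$genome, plasMut$genome))
  without <- list(B1 = list(evC$genome), B2 = list(evD$genome))
  found <- setSpecificGenes(withPlasmid, without)
  expect_setequal(found$gene_id, sprintf("plas%02d", 1:10))
  # A = B: nothing is specific
  expect_equal(nrow(setSpecificGenes(without, without)), 0L)
})

test_that("gene presence respects the 80% identity threshold", {
  set.seed(BASE_SEED)
  gene <- randomCds(160, seed = 301)   # ~480 bp
  host <- paste0(randomCds(200, seed = 302),
                 strrep("T", 30), gene, strrep("T", 30))
  hostG <- AnnotatedGenome("host", host)
  donor <- toyGenome(gene, id = "donor")
  names <- S4Vectors::mcols(cdsFeatures(donor))$gene_id
  # exact copy: present -> not donor-specific against the host
  res <- setSpecificGenes(list(d = donor), list(h = hostG))
  expect_equal(nrow(res), 0L)
  # degrade the host copy to ~78% identity (2 mismatches per 9 bases,
  # evenly spread): below threshold everywhere -> donor-specific
  gv <- strsplit(gene, "")[[1]]
  idx <- sort(c(seq(4, length(gv), by = 9), seq(8, length(gv), by = 9)))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  gv[idx] <- rot[gv[idx]]
  degraded <- paste(gv, collapse = "")
  host2 <- AnnotatedGenome("host2", paste0(
    randomCds(200, seed = 302), strrep("T", 30), degraded, strrep("T", 30)))
  res2 <- setSpecificGenes(list(d = donor), list(h = host2))
  expect_equal(res2$gene_id, names)
})
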