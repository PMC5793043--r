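# Shared fixtures and independent oracles. All expected values used in
# the suite are computed by these oracles (or asserted from construction),
# never by the code paths under test.

BASE_SEED <- 20260923

# --- toy genome construction ---------------------------------------------

# Build a genome from explicit CDS sequences (given on the coding strand)
# separated by fixed intergenic spacers.
toyGenome <- function(cdsSeqs, strands = NULL, spacer = "TTTTTTTTTT",
                      id = "toy", geneIds = NULL) {
  n <- length(cdsSeqs)
  if (is.null(strands)) strands <- rep("+", n)
  pieces <- character(0)
  starts <- integer(n); ends <- integer(n)
  cur <- nchar(spacer)
  for (i in seq_len(n)) {
    placed <- if (strands[i] == "+") cdsSeqs[i] else revCompStr(cdsSeqs[i])
    starts[i] <- cur + 1L
    ends[i] <- cur + nchar(placed)
    pieces <- c(pieces, placed, spacer)
    cur <- ends[i] + nchar(spacer)
  }
  seq <- paste0(spacer, paste(pieces, collapse = ""))
  if (is.null(geneIds)) geneIds <- sprintf("tg%02d", seq_len(n))
  ft <- data.frame(gene_id = geneIds,
                   start = starts, end = ends, strand = strands)
  AnnotatedGenome(id, seq, features = ft)
}

revCompStr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Random codon soup CDS of nCodons (incl. start + stop), oracle-side.
randomCds <- function(nCodons, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  all <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                         c("A","C","G","T"), paste0))
  sense <- setdiff(all, stops)
  paste0("ATG", paste(sample(sense, nCodons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# --- independent oracles --------------------------------------------------

# Naive average-linkage agglomeration from the original distance matrix.
# Returns the cophenetic matrix (merge-level average distance per pair).
bruteAverageLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Cophenetic matrix of an ultrametric phylo tree (pairwise path length =
# twice the merge height under UPGMA's half-distance branch lengths).
phyloCophenetic <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

# Brute-force per-site Ka/Ks enumeration: apply every alternative base at
# every coding position, translate the whole CDS with Biostrings, and
# accumulate ts/tv weights. Independent of codingMap/expectedEffectWeights.
bruteExpectedWeights <- function(genome, tsFraction) {
  ft <- cdsFeatures(genome)
  seq <- genomeSeq(genome)
  gcTable <- Biostrings::GENETIC_CODE
  translate <- function(s) {
    n <- nchar(s) %/% 3L
    paste(gcTable[substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))],
          collapse = "")
  }
  isTs <- function(a, b) {
    (a %in% c("A", "G")) == (b %in% c("A", "G"))
  }
  naExp <- 0; nsExp <- 0; excl <- 0
  for (i in seq_along(ft)) {
    gs <- GenomicRanges::start(ft)[i]; ge <- GenomicRanges::end(ft)[i]
    strand <- as.character(GenomicRanges::strand(ft))[i]
    region <- substr(seq, gs, ge)
    cds <- if (strand == "+") region else revCompStr(region)
    prot <- translate(cds)
    nCod <- nchar(cds) %/% 3L
    for (cpos in seq_len(3L * (nCod - 1L))) {  # terminal stop excluded
      refB <- substr(cds, cpos, cpos)
      for (altB in setdiff(c("A", "C", "G", "T"), refB)) {
        mut <- cds
        substr(mut, cpos, cpos) <- altB
        protM <- translate(mut)
        w <- if (isTs(refB, altB)) tsFraction else (1 - tsFraction) / 2
        ci <- (cpos - 1L) %/% 3L + 1L
        aaR <- substr(prot, ci, ci); aaM <- substr(protM, ci, ci)
        if (aaM == aaR) nsExp <- nsExp + w
        else if (aaM == "*") excl <- excl + w
        else if (aaR == "*") excl <- excl + w
        else naExp <- naExp + w
      }
    }
  }
  list(naExp = naExp, nsExp = nsExp, excluded = excl)
}

# Expected transfer topology of the odyssey-style chain fixtures.
chainTopology <- function() {
  ape::read.tree(text = "(((((Dunne,Meric),NCTC86),CIP),ATCC),DSM);")
}

sameUnrootedTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# The phylogeography study plan used across tests: sibling edges of
# unequal size, then a lengthening transfer chain (>= 20 mutations per
# edge).
chainPlan <- function() {
  data.frame(
    parent = c("Dunne", "Dunne", "NCTC86", "CIP", "ATCC"),
    child = c("Meric", "NCTC86", "CIP", "ATCC", "DSM"),
    n = c(20L, 35L, 60L, 120L, 80L),
    regime = c("MMR", "MMR", "MutT", "MutT", "MutT"),
    stringsAsFactors = FALSE
  )
}

variantKeys <- function(vs) {
  v <- variants(vs)
  paste(v$pos, v$ref, v$alt)
}
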