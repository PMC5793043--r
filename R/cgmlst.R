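# Ad hoc core-genome MLST: scheme construction from a reference
# annotation, gene-by-gene allele calling, allelic and SNP
# presence/absence distances, UPGMA / average-linkage Manhattan
# dendrograms, SNP-concatenation export, and set-specific gene search.

#' Build an ad hoc cgMLST scheme from an annotated reference
#'
#' Retains every CDS of the reference except: targets shorter than
#' `minLen`; targets containing ambiguity codes; and paralogous pairs
#' (two CDS at least `maxParalogIdentity` identical over at least half
#' of the shorter one — both members are dropped).
#'
#' @param reference Annotated [AnnotatedGenome-class].
#' @param minLen Minimum target length in bp.
#' @param maxParalogIdentity Identity above which two targets count as
#'   paralogs.
#' @return A [CgScheme-class].
#' @export
buildScheme <- function(reference, minLen = 120L, maxParalogIdentity = 0.9) {
  ft <- cdsFeatures(reference)
  if (!length(ft)) stop("reference has no CDS annotation")
  mc <- S4Vectors::mcols(ft)
  seq <- genomeSeq(reference)
  starts <- GenomicRanges::start(ft); ends <- GenomicRanges::end(ft)
  strands <- as.character(GenomicRanges::strand(ft))
  seqs <- substring(seq, starts, ends)
  neg <- strands == "-"
  seqs[neg] <- vapply(seqs[neg], revComp, character(1))
  tab <- data.frame(gene_id = mc$gene_id, start = starts, end = ends,
                    strand = strands, sequence = seqs,
                    stringsAsFactors = FALSE)
  keep <- nchar(tab$sequence) >= minLen & grepl("^[ACGT]+$", tab$sequence)
  tab <- tab[keep, , drop = FALSE]
  # paralog screen, strand-agnostic: candidate pairs share a 21-mer in
  # either orientation, then local alignment decides
  drop <- rep(FALSE, nrow(tab))
  if (nrow(tab) > 1L) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
    kmerSets <- lapply(tab$sequence, function(s) unique(.kmerStarts(s, 21L)))
    kmerSetsRc <- lapply(tab$sequence, function(s) {
      unique(.kmerStarts(revComp(s), 21L))
    })
    isParalog <- function(a, b) {
      shorter <- min(nchar(a), nchar(b))
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        type = "local", substitutionMatrix = sm,
        gapOpening = 4, gapExtension = 1)
      alnLen <- Biostrings::nchar(aln)
      alnLen >= 0.5 * shorter &&
        Biostrings::nmatch(aln) / alnLen >= maxParalogIdentity
    }
    for (i in seq_len(nrow(tab) - 1L)) {
      for (j in seq.int(i + 1L, nrow(tab))) {
        fwd <- length(intersect(kmerSets[[i]], kmerSets[[j]])) > 0L
        rev <- length(intersect(kmerSets[[i]], kmerSetsRc[[j]])) > 0L
        if (!fwd && !rev) next
        hit <- (fwd && isParalog(tab$sequence[i], tab$sequence[j])) ||
          (rev && isParalog(tab$sequence[i], revComp(tab$sequence[j])))
        if (hit) { drop[i] <- TRUE; drop[j] <- TRUE }
      }
    }
  }
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  new("CgScheme", referenceId = genomeId(reference),
      referenceSeq = seq, targets = tab)
}

# Extract each target's allele sequence from a single collinear query
# genome via the genome-wide variant call and coordinate mapping.
# Returns character vector (NA = MISSING).
.allelesFromCollinear <- function(scheme, query) {
  ref <- AnnotatedGenome(scheme@referenceId, scheme@referenceSeq)
  vs <- callVariantsCollinear(ref, query)
  qseq <- genomeSeq(query)
  t <- scheme@targets
  qs <- mapRefToDerived(vs, t$start)
  qe <- mapRefToDerived(vs, t$end)
  out <- substring(qseq, qs, qe)
  neg <- t$strand == "-"
  out[neg] <- vapply(out[neg], revComp, character(1))
  out[!grepl("^[ACGT]+$", out)] <- NA_character_
  out
}

# Exact-flank search in a contig set. A target is MISSING when its
# flanks cannot both be located on one contig in consistent orientation
# (the contig-border truncation rule).
.allelesFromContigs <- function(scheme, contigs, flank = 60L) {
  rseq <- scheme@referenceSeq
  t <- scheme@targets
  seqs <- vapply(contigs, genomeSeq, character(1))
  out <- rep(NA_character_, nrow(t))
  for (i in seq_len(nrow(t))) {
    up <- substr(rseq, t$start[i] - flank, t$start[i] - 1L)
    dn <- substr(rseq, t$end[i] + 1L, t$end[i] + flank)
    if (nchar(up) < flank || nchar(dn) < flank) next
    for (cs in seqs) {
      hitU <- .singleFixedMatch(up, cs)
      hitD <- .singleFixedMatch(dn, cs)
      if (!is.na(hitU) && !is.na(hitD) && hitD > hitU + flank) {
        allele <- substr(cs, hitU + flank, hitD - 1L)
        if (grepl("^[ACGT]+$", allele)) {
          out[i] <- if (t$strand[i] == "-") revComp(allele) else allele
        }
        break
      }
      # reverse-complement orientation
      rc <- revComp(cs)
      hitU <- .singleFixedMatch(up, rc)
      hitD <- .singleFixedMatch(dn, rc)
      if (!is.na(hitU) && !is.na(hitD) && hitD > hitU + flank) {
        allele <- substr(rc, hitU + flank, hitD - 1L)
        if (grepl("^[ACGT]+$", allele)) {
          out[i] <- if (t$strand[i] == "-") revComp(allele) else allele
        }
        break
      }
    }
  }
  out
}

.singleFixedMatch <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] > 0L) m[1] else NA_integer_
}

#' Call cgMLST allele profiles for a set of query genomes
#'
#' For every scheme target the orthologous complete CDS is located in
#' each query (via the collinear genome-wide call for single-genome
#' queries, or exact flank matching for contig sets); identical
#' sequences share an allele id, novel sequences get the next id in
#' order of first observation, the reference allele is id 1. Targets
#' that are absent, truncated by a contig border or ambiguous are
#' MISSING (`NA`).
#'
#' @param scheme A [CgScheme-class].
#' @param queries Named list; each element an [AnnotatedGenome-class]
#'   (collinear genome) or a list of them (contig set).
#' @return Integer matrix targets x isolates (rownames = gene ids), NA
#'   for MISSING.
#' @export
callAlleleProfiles <- function(scheme, queries) {
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be a named list")
  }
  t <- scheme@targets
  registry <- lapply(t$sequence, function(s) s)  # per target: allele 1 = ref
  prof <- matrix(NA_integer_, nrow = nrow(t), ncol = length(queries),
                 dimnames = list(t$gene_id, names(queries)))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    alleles <- if (is(q, "AnnotatedGenome")) {
      .allelesFromCollinear(scheme, q)
    } else {
      .allelesFromContigs(scheme, q)
    }
    for (i in seq_len(nrow(t))) {
      a <- alleles[i]
      if (is.na(a)) next
      id <- match(a, registry[[i]])
      if (is.na(id)) {
        registry[[i]] <- c(registry[[i]], a)
        id <- length(registry[[i]])
      }
      prof[i, qi] <- id
    }
  }
  prof
}

#' Pairwise allelic distances between profiles
#'
#' Counts, for each pair of isolates, the targets at which both have an
#' allele call and the calls differ (pairwise deletion of MISSING
#' targets; raw counts, not rescaled).
#'
#' @param profiles Matrix from [callAlleleProfiles()].
#' @return Symmetric numeric matrix of allele differences with attribute
#'   `n_compared` (matrix of mutually typed target counts).
#' @export
allelicDistance <- function(profiles) {
  n <- ncol(profiles)
  if (n < 2L) stop("need at least 2 profiles")
  labs <- colnames(profiles)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  nc <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- !is.na(profiles[, i]) & !is.na(profiles[, j])
      d[i, j] <- d[j, i] <- sum(profiles[both, i] != profiles[both, j])
      nc[i, j] <- nc[j, i] <- sum(both)
    }
  }
  diag(nc) <- nrow(profiles)
  attr(d, "n_compared") <- nc
  d
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean; labels
#' are ordered lexicographically first so that merge ties resolve by
#' label order. Branch heights are ultrametric (root height = distance
#' / 2 for two taxa).
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgmaTree <- function(d) {
  m <- as.matrix(d)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Binary variant presence/absence matrix
#'
#' One column per distinct normalized variant (pos, ref, alt) observed
#' in any of the sets, one row per isolate; entries are 0/1 presence.
#'
#' @param variantSets Named list of [VariantSet-class] versus one
#'   reference.
#' @return Integer 0/1 matrix isolates x variants.
#' @export
binaryVariantMatrix <- function(variantSets) {
  if (is.null(names(variantSets))) {
    names(variantSets) <- vapply(variantSets, isolateId, character(1))
  }
  keys <- lapply(variantSets, function(vs) {
    v <- variants(vs)
    if (!nrow(v)) character(0) else paste(v$pos, v$ref, v$alt, sep = ":")
  })
  all <- unique(unlist(keys))
  allPos <- as.integer(sub(":.*$", "", all))
  all <- all[order(allPos, all)]
  m <- matrix(0L, nrow = length(variantSets), ncol = length(all),
              dimnames = list(names(variantSets), all))
  for (i in seq_along(keys)) m[i, match(keys[[i]], all)] <- 1L
  m
}

#' Average-linkage Manhattan clustering of a binary variant matrix
#'
#' Agglomerative clustering with Manhattan (L1) pairwise distances --
#' for 0/1 rows the distance is the number of discordant variants --
#' and average linkage, ties resolved as in [upgmaTree()].
#'
#' @param m Matrix from [binaryVariantMatrix()].
#' @return A rooted `phylo` dendrogram.
#' @export
averageLinkageManhattan <- function(m) {
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  upgmaTree(d)
}

#' Export the concatenated SNP alignment
#'
#' One column per reference position carrying a SNP in at least one
#' isolate (genomic order); isolates without a call at a column carry
#' the reference base; the reference is included as a row. Written as
#' FASTA and/or relaxed PHYLIP for external maximum-likelihood
#' inference.
#'
#' @param variantSets Named list of normalized [VariantSet-class].
#' @param reference The reference [AnnotatedGenome-class].
#' @param fastaPath,phylipPath Optional output files.
#' @return Character matrix (rows = reference + isolates), invisibly if
#'   files are written.
#' @export
exportSnpAlignment <- function(variantSets, reference,
                               fastaPath = NULL, phylipPath = NULL) {
  if (is.null(names(variantSets))) {
    names(variantSets) <- vapply(variantSets, isolateId, character(1))
  }
  snpTabs <- lapply(variantSets, function(vs) {
    v <- variants(vs)
    v[v$vclass == "SNP", , drop = FALSE]
  })
  pos <- sort(unique(unlist(lapply(snpTabs, function(v) v$pos))))
  if (!length(pos)) stop("no segregating SNP positions to export")
  refBases <- strsplit(genomeSeq(reference), "")[[1]][pos]
  m <- matrix(rep(refBases, length(variantSets) + 1L),
              nrow = length(variantSets) + 1L, byrow = TRUE,
              dimnames = list(c(genomeId(reference), names(variantSets)),
                              pos))
  for (i in seq_along(snpTabs)) {
    v <- snpTabs[[i]]
    m[i + 1L, match(v$pos, pos)] <- v$alt
  }
  if (!is.null(fastaPath)) {
    lines <- as.vector(rbind(paste0(">", rownames(m)),
                             apply(m, 1L, paste, collapse = "")))
    writeLines(lines, fastaPath)
  }
  if (!is.null(phylipPath)) {
    bin <- ape::as.DNAbin(m)
    ape::write.dna(bin, phylipPath, format = "sequential", colsep = "",
                   nbcol = -1)
  }
  m
}

# Is `geneSeq` present in `contigSeq` at >= minIdentity over
# >= minCoverage of the gene? Anchored by a shared unique 21-mer and
# decided by local alignment within a window around the anchor.
.genePresentIn <- function(geneSeq, contigSeq, minIdentity, minCoverage) {
  for (target in c(contigSeq, revComp(contigSeq))) {
    gk <- unique(.kmerStarts(geneSeq, 21L))
    hit <- NA_integer_
    for (kk in gk[seq(1L, length(gk), length.out = min(50L, length(gk)))]) {
      p <- regexpr(kk, target, fixed = TRUE)
      if (p > 0L) { hit <- as.integer(p); break }
    }
    if (is.na(hit)) next
    gl <- nchar(geneSeq)
    ws <- max(1L, hit - gl - 200L)
    we <- min(nchar(target), hit + gl + 200L)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(geneSeq),
      Biostrings::DNAString(substr(target, ws, we)), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    alnLen <- Biostrings::nchar(aln)
    if (alnLen == 0L) next
    identity <- Biostrings::nmatch(aln) / alnLen
    coverage <- alnLen / gl
    if (identity >= minIdentity && coverage >= minCoverage) return(TRUE)
  }
  FALSE
}

.contigList <- function(x) {
  if (is(x, "AnnotatedGenome")) list(x) else x
}

#' Genes present in every isolate of one set and absent from another
#'
#' A gene is "present" in an isolate when an alignment of the gene to
#' any contig reaches at least `minIdentity` identity over at least
#' `minCoverage` of the gene length. Returns the genes (drawn from the
#' annotation of set A's isolates) present in all of A and absent from
#' all of B — the plasmid-contig logic used to pick out
#' collection-specific gene content.
#'
#' @param isolatesA,isolatesB Named lists; each element an
#'   [AnnotatedGenome-class] or list of contigs.
#' @param minIdentity,minCoverage Presence thresholds.
#' @return data.frame with columns `gene_id` and `source` (isolate the
#'   gene sequence was taken from).
#' @export
setSpecificGenes <- function(isolatesA, isolatesB,
                             minIdentity = 0.8, minCoverage = 0.8) {
  # candidate genes: union of A's annotations (first occurrence wins)
  cand <- list()
  for (nm in names(isolatesA)) {
    for (contig in .contigList(isolatesA[[nm]])) {
      ft <- cdsFeatures(contig)
      if (!length(ft)) next
      mc <- S4Vectors::mcols(ft)
      seqs <- substring(genomeSeq(contig), GenomicRanges::start(ft),
                        GenomicRanges::end(ft))
      neg <- as.character(GenomicRanges::strand(ft)) == "-"
      seqs[neg] <- vapply(seqs[neg], revComp, character(1))
      for (i in seq_along(ft)) {
        gid <- mc$gene_id[i]
        if (is.null(cand[[gid]])) {
          cand[[gid]] <- list(seq = seqs[i], source = nm)
        }
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(gene_id = character(), source = character()))
  }
  presentInIsolate <- function(geneSeq, isolate) {
    any(vapply(.contigList(isolate), function(ct) {
      .genePresentIn(geneSeq, genomeSeq(ct), minIdentity, minCoverage)
    }, logical(1)))
  }
  keep <- vapply(names(cand), function(gid) {
    gs <- cand[[gid]]$seq
    inAllA <- all(vapply(isolatesA, function(iso) presentInIsolate(gs, iso),
                         logical(1)))
    if (!inAllA) return(FALSE)
    inAnyB <- any(vapply(isolatesB, function(iso) presentInIsolate(gs, iso),
                         logical(1)))
    !inAnyB
  }, logical(1))
  data.frame(
    gene_id = names(cand)[keep],
    source = vapply(cand[keep], function(x) x$source, character(1)),
    row.names = NULL
  )
}
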