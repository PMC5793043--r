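# Collinear variant calling between near-identical assembled genomes.
#
# Contract: unique shared k-mer anchors (default k = 21, unique in both
# genomes) chained colinearly (leftmost-longest increasing chain);
# inter-anchor gaps resolved by optimal global pairwise alignment
# (match 1, mismatch -2, gap open -4, gap extend -1); output normalized.
# A failed anchor chain (likely rearrangement) raises an explicit
# "non-collinear" error rather than silently truncating the call set.

ALN_MATCH <- 1; ALN_MISMATCH <- -2; ALN_GAP_OPEN <- 4; ALN_GAP_EXT <- 1

.kmerStarts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Longest strictly-increasing subsequence indices (O(n log n)).
.lisIndices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  if (!is.unsorted(x, strictly = TRUE)) return(seq_len(n))
  tailsVal <- numeric(0)
  tailsIdx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tailsVal)  # first tail >= x[i] is j+1
    if (j == length(tailsVal)) {
      tailsVal <- c(tailsVal, x[i]); tailsIdx <- c(tailsIdx, i)
    } else {
      tailsVal[j + 1L] <- x[i]; tailsIdx[j + 1L] <- i
    }
    prev[i] <- if (j > 0L) tailsIdx[j] else 0L
  }
  out <- integer(length(tailsVal))
  cur <- tailsIdx[length(tailsIdx)]
  for (j in rev(seq_along(out))) {
    out[j] <- cur
    cur <- prev[cur]
  }
  out
}

# Align two short segments and emit raw (unnormalized) variant rows with
# reference coordinates offset by refOffset (0-based shift). Segments
# that decompose as prefix + single event + suffix are resolved
# directly; anything more complex goes through optimal affine-gap
# alignment.
.alignSegment <- function(refSeg, qSeg, refOffset, refSeq) {
  if (!nchar(refSeg) && !nchar(qSeg)) return(NULL)
  if (!nchar(qSeg)) {
    # pure deletion; anchor on preceding reference base
    pos <- refOffset
    ref <- substr(refSeq, pos, pos + nchar(refSeg))
    return(data.frame(pos = pos, ref = ref, alt = substr(ref, 1L, 1L)))
  }
  if (!nchar(refSeg)) {
    pos <- refOffset
    if (pos < 1L) {
      # insertion before the first reference base: right-anchored record
      anchor <- substr(refSeq, 1L, 1L)
      return(data.frame(pos = 1L, ref = anchor,
                        alt = paste0(qSeg, anchor)))
    }
    anchor <- substr(refSeq, pos, pos)
    return(data.frame(pos = pos, ref = anchor, alt = paste0(anchor, qSeg)))
  }
  lr <- nchar(refSeg); lq <- nchar(qSeg)
  rv <- strsplit(refSeg, "")[[1]]
  qv <- strsplit(qSeg, "")[[1]]
  if (lr == lq) {
    # gapless alignment is optimal at these scores for equal lengths
    d <- which(rv != qv)
    if (!length(d)) return(NULL)
    return(data.frame(pos = refOffset + d, ref = rv[d], alt = qv[d]))
  }
  # clean single-indel decomposition: common prefix + event + suffix
  nmin <- min(lr, lq)
  pre <- 0L
  while (pre < nmin && rv[pre + 1L] == qv[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre && rv[lr - suf] == qv[lq - suf]) suf <- suf + 1L
  if (pre + suf >= nmin && refOffset + pre >= 1L) {
    pos <- refOffset + pre
    anchor <- substr(refSeq, pos, pos)
    if (lq > lr) {
      insBases <- paste(qv[(pre + 1L):(lq - suf)], collapse = "")
      return(data.frame(pos = pos, ref = anchor,
                        alt = paste0(anchor, insBases)))
    }
    delBases <- paste(rv[(pre + 1L):(lr - suf)], collapse = "")
    return(data.frame(pos = pos, ref = paste0(anchor, delBases),
                      alt = anchor))
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qSeg), Biostrings::DNAString(refSeg),
    type = "global", substitutionMatrix = sm,
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rows <- list()
  rpos <- refOffset  # reference position of last consumed ref base
  i <- 1L
  ncol <- length(qa)
  while (i <= ncol) {
    if (ra[i] != "-" && qa[i] != "-") {
      rpos <- rpos + 1L
      if (ra[i] != qa[i]) {
        rows[[length(rows) + 1L]] <-
          data.frame(pos = rpos, ref = ra[i], alt = qa[i])
      }
      i <- i + 1L
    } else if (ra[i] == "-") {
      j <- i
      while (j <= ncol && ra[j] == "-") j <- j + 1L
      insBases <- paste(qa[i:(j - 1L)], collapse = "")
      anchor <- substr(refSeq, rpos, rpos)
      rows[[length(rows) + 1L]] <-
        data.frame(pos = rpos, ref = anchor, alt = paste0(anchor, insBases))
      i <- j
    } else {
      j <- i
      while (j <= ncol && qa[j] == "-") j <- j + 1L
      delBases <- paste(ra[i:(j - 1L)], collapse = "")
      anchor <- substr(refSeq, rpos, rpos)
      rows[[length(rows) + 1L]] <-
        data.frame(pos = rpos, ref = paste0(anchor, delBases), alt = anchor)
      rpos <- rpos + (j - i)
      i <- j
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Call variants between a reference and a collinear query genome
#'
#' Operates on assembled, near-identical (divergence well below 1%),
#' rearrangement-free genomes: unique shared k-mers anchor an increasing
#' colinear chain; the short segments between anchors are resolved by
#' optimal global alignment and the resulting differences are
#' left-aligned and trimmed. `applyVariantSet(result, reference)`
#' reconstructs the query exactly. Sites whose alleles contain ambiguity
#' codes are masked from the output.
#'
#' @param reference,query [AnnotatedGenome-class] objects.
#' @param k Anchor k-mer size.
#' @return A normalized [VariantSet-class] of the query versus the
#'   reference.
#' @export
callVariantsCollinear <- function(reference, query, k = 21L) {
  rseq <- genomeSeq(reference)
  qseq <- genomeSeq(query)
  if (identical(rseq, qseq)) {
    return(VariantSet(genomeId(reference), genomeId(query)))
  }
  rk <- .kmerStarts(rseq, k)
  qk <- .kmerStarts(qseq, k)
  rUniq <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  qUniq <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
  m <- match(rk, qk)
  keep <- rUniq & !is.na(m)
  keep[keep] <- qUniq[m[keep]]
  rp <- which(keep)
  qp <- m[rp]
  if (length(rp) < 2L) {
    stop("non-collinear: no usable anchor chain between ",
         genomeId(reference), " and ", genomeId(query))
  }
  chain <- .lisIndices(qp)
  # a rearrangement (e.g. a rotation or inversion) leaves at most a
  # large minority of anchors on one colinear chain; true same-strain
  # genomes chain nearly everything
  if (length(chain) < 0.8 * length(rp)) {
    stop("non-collinear: anchor chain covers too little of the genomes ",
         "(likely rearrangement)")
  }
  rp <- rp[chain]; qp <- qp[chain]
  span <- (rp[length(rp)] + k - rp[1]) / nchar(rseq)
  if (span < 0.8) {
    stop("non-collinear: chained anchors span <80% of the reference")
  }

  # collapse same-offset consecutive anchors into exact blocks
  off <- qp - rp
  newBlock <- c(TRUE, diff(off) != 0L)
  blockId <- cumsum(newBlock)
  bFirst <- which(newBlock)
  bLast <- c(bFirst[-1L] - 1L, length(rp))
  nb <- length(bFirst)
  rows <- list()

  # verify each block really is an exact match; residual differences in
  # anchor deserts are handled by aligning the run as one segment
  addGap <- function(rs, re, qs, qe) {
    lenR <- re - rs + 1L; lenQ <- qe - qs + 1L
    pad <- max(0L, -min(lenR, lenQ))
    rs <- rs - pad; qs <- qs - pad
    refSeg <- if (re >= rs) substr(rseq, rs, re) else ""
    qSeg <- if (qe >= qs) substr(qseq, qs, qe) else ""
    if (!nchar(refSeg) && !nchar(qSeg)) return(NULL)
    .alignSegment(refSeg, qSeg, rs - 1L, rseq)
  }

  for (b in seq_len(nb)) {
    i0 <- bFirst[b]; i1 <- bLast[b]
    blockRefStart <- rp[i0]; blockRefEnd <- rp[i1] + k - 1L
    blockQStart <- qp[i0]
    refBlock <- substr(rseq, blockRefStart, blockRefEnd)
    qBlock <- substr(qseq, blockQStart, blockQStart + (blockRefEnd - blockRefStart))
    if (refBlock != qBlock) {
      rows[[length(rows) + 1L]] <-
        addGap(blockRefStart, blockRefEnd, blockQStart,
               blockQStart + (blockRefEnd - blockRefStart))
    }
    if (b < nb) {
      rows[[length(rows) + 1L]] <-
        addGap(blockRefEnd + 1L, rp[bFirst[b + 1L]] - 1L,
               blockQStart + (blockRefEnd - blockRefStart) + 1L,
               qp[bFirst[b + 1L]] - 1L)
    }
  }
  # leading and trailing unanchored ends
  if (rp[1] > 1L || qp[1] > 1L) {
    rows <- c(list(addGap(1L, rp[1] - 1L, 1L, qp[1] - 1L)), rows)
  }
  lastRefEnd <- rp[length(rp)] + k - 1L
  lastQEnd <- qp[length(qp)] + k - 1L
  if (lastRefEnd < nchar(rseq) || lastQEnd < nchar(qseq)) {
    rows[[length(rows) + 1L]] <-
      addGap(lastRefEnd + 1L, nchar(rseq), lastQEnd + 1L, nchar(qseq))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || !nrow(tab)) {
    return(VariantSet(genomeId(reference), genomeId(query)))
  }
  okAcgt <- grepl("^[ACGT]+$", tab$ref) & grepl("^[ACGT]+$", tab$alt)
  tab <- tab[okAcgt, , drop = FALSE]  # ambiguity-containing sites are masked
  vs <- VariantSet(genomeId(reference), genomeId(query),
                   pos = tab$pos, ref = tab$ref, alt = tab$alt)
  normalizeVariants(vs, reference)
}

#' Coverage/quality filter thresholds
#'
#' Defaults mirror the read-level call filter of the source pipeline:
#' relative coverage strictly greater than 0.5, absolute coverage
#' strictly greater than 10 reads, Phred quality at least 23
#' (inclusive).
#'
#' @param minRelCoverage Exclusive lower bound on relative coverage.
#' @param minAbsCoverage Exclusive lower bound on absolute coverage.
#' @param minQuality Inclusive lower bound on Phred quality.
#' @return A named list of thresholds.
#' @export
filterThresholds <- function(minRelCoverage = 0.5, minAbsCoverage = 10,
                             minQuality = 23) {
  stopifnot(minRelCoverage >= 0, minAbsCoverage >= 0, minQuality >= 0)
  list(minRelCoverage = minRelCoverage,
       minAbsCoverage = minAbsCoverage,
       minQuality = minQuality)
}

#' Filter a VariantSet on coverage and quality metadata
#'
#' Keeps a variant iff relative coverage > `minRelCoverage` AND absolute
#' coverage > `minAbsCoverage` (both strict) AND quality >=
#' `minQuality`. Variants with missing metadata pass with a warning:
#' assembly-derived calls carry no read-level metadata, and dropping
#' them would silently empty every simulated call set.
#'
#' @param vs A [VariantSet-class].
#' @param thresholds A [filterThresholds()] list.
#' @return The filtered [VariantSet-class].
#' @export
filterVariants <- function(vs, thresholds = filterThresholds()) {
  v <- variants(vs)
  if (!nrow(v)) return(vs)
  anyMissing <- is.na(v$af) | is.na(v$dp) | is.na(v$qual)
  if (any(anyMissing)) {
    warning(sum(anyMissing), " variant(s) with missing coverage/quality ",
            "metadata pass the corresponding check unexamined")
  }
  keep <- (is.na(v$af) | v$af > thresholds$minRelCoverage) &
    (is.na(v$dp) | v$dp > thresholds$minAbsCoverage) &
    (is.na(v$qual) | v$qual >= thresholds$minQuality)
  .vsFromDf(referenceId(vs), isolateId(vs), v[keep, , drop = FALSE])
}
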