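# Variant normalization (left alignment + parsimony trimming) and
# application of variant sets to sequences. Canonical placement matters
# for set comparison: a 1-bp insertion anywhere inside a homopolymer run
# must collapse to a single record at the run's left edge.

# Normalize one (pos, ref, alt) against a reference sequence string.
# Classic left-align algorithm: trim shared right bases (extending left
# through the reference when an allele empties), then trim shared left
# bases keeping one anchor base for indels.
normalizeOne <- function(pos, ref, alt, seq) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("ref allele does not match genome at position ", pos)
  }
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) {
          # cannot extend left of the sequence: re-anchor on the right
          b <- substr(seq, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        b <- substr(seq, pos - 1L, pos - 1L)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize a VariantSet against its reference genome
#'
#' Indels are left-aligned and parsimony-trimmed (minimal ref/alt,
#' shifted left while the preceding reference base matches); SNPs are
#' unchanged. Normalization is idempotent and gives every haplotype
#' difference a unique representation, which is what makes variant sets
#' comparable across isolates (the mutT-style "+C inside a C tract"
#' insertion is the canonical example).
#'
#' @param vs A [VariantSet-class].
#' @param genome The reference [AnnotatedGenome-class].
#' @return The normalized [VariantSet-class].
#' @export
normalizeVariants <- function(vs, genome) {
  v <- variants(vs)
  if (!nrow(v)) return(vs)
  seq <- genomeSeq(genome)
  for (i in seq_len(nrow(v))) {
    n <- normalizeOne(v$pos[i], v$ref[i], v$alt[i], seq)
    v$pos[i] <- n$pos; v$ref[i] <- n$ref; v$alt[i] <- n$alt
  }
  .vsFromDf(referenceId(vs), isolateId(vs), v)
}

#' Apply a VariantSet to its reference sequence
#'
#' Splices every variant into the reference and returns the derived
#' sequence. Variants must not overlap.
#'
#' @param vs A [VariantSet-class].
#' @param genome The reference [AnnotatedGenome-class] (or a character
#'   sequence).
#' @return The derived sequence as a character string.
#' @export
applyVariantSet <- function(vs, genome) {
  seq <- if (is.character(genome)) genome else genomeSeq(genome)
  v <- variants(vs)
  if (!nrow(v)) return(seq)
  v <- v[order(v$pos), , drop = FALSE]
  ends <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos[-1L] <= ends[-length(ends)])) {
    stop("overlapping variants cannot be applied")
  }
  if (ends[nrow(v)] > nchar(seq)) stop("variant beyond end of sequence")
  n <- nrow(v)
  pieces <- character(2L * n + 1L)
  prevEnd <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(seq, prevEnd + 1L, v$pos[i] - 1L)
    pieces[2L * i] <- v$alt[i]
    prevEnd <- ends[i]
  }
  pieces[2L * n + 1L] <- substr(seq, prevEnd + 1L, nchar(seq))
  paste(pieces, collapse = "")
}

# Map reference coordinates to derived-sequence coordinates through the
# indels of a variant set. Positions inside a deleted span map to the
# deletion anchor. Vectorized over `pos`.
mapRefToDerived <- function(vs, pos) {
  v <- variants(vs)
  v <- v[v$vclass %in% c("INS", "DEL", "MNP") & nchar(v$ref) != nchar(v$alt), ,
         drop = FALSE]
  if (!nrow(v)) return(pos)
  shift <- nchar(v$alt) - nchar(v$ref)
  vEnd <- v$pos + nchar(v$ref) - 1L  # last ref base consumed by the event
  out <- pos
  cum <- cumsum(shift)
  # offset applying to a query position = sum of shifts of events ending
  # strictly before it
  idx <- findInterval(pos - 1L, vEnd)
  off <- ifelse(idx > 0L, cum[pmax(idx, 1L)], 0L)
  out <- pos + off
  # clamp positions falling inside a deleted span onto the anchor base
  for (i in seq_len(nrow(v))) {
    if (shift[i] < 0L) {
      inside <- pos > v$pos[i] & pos <= vEnd[i]
      if (any(inside)) {
        anchorOff <- if (i > 1L) cum[i - 1L] else 0L
        out[inside] <- v$pos[i] + anchorOff
      }
    }
  }
  out
}
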