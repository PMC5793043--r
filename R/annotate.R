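# Coding-consequence annotation with protein-level (HGVS-like) naming.
#
# Conventions: protein numbering over the full precursor, position 1 =
# initiator Met; an optional per-gene offset reproduces mature-protein
# numbering (signal peptide removed). In-frame deletions are named after
# HGVS 3'-shifting within amino-acid repeats (DNA-level records stay
# left-aligned; the conversion happens here, at naming time).

# Per-position coding map of a genome: one row per (position, CDS) pair
# with the codon context on the coding strand. Overlapping CDS
# contribute one row each. Terminal stop codons are excluded when
# `dropTerminalStop` (the Ka/Ks enumeration convention).
codingMap <- function(genome, dropTerminalStop = FALSE) {
  ft <- cdsFeatures(genome)
  seq <- genomeSeq(genome)
  if (!length(ft)) {
    return(data.frame(pos = integer(), gene_id = character(),
                      strand = character(), codonIndex = integer(),
                      posInCodon = integer(), codon = character(),
                      refCoding = character()))
  }
  mc <- S4Vectors::mcols(ft)
  out <- vector("list", length(ft))
  for (i in seq_along(ft)) {
    gs <- GenomicRanges::start(ft)[i]; ge <- GenomicRanges::end(ft)[i]
    strand <- as.character(GenomicRanges::strand(ft))[i]
    ph <- mc$phase[i]
    region <- substr(seq, gs, ge)
    cds <- if (strand == "+") region else revComp(region)
    if (ph > 0L) cds <- substr(cds, ph + 1L, nchar(cds))
    nc <- nchar(cds) %/% 3L
    if (nc == 0L) next
    usable <- if (dropTerminalStop) nc - 1L else nc
    if (usable < 1L) next
    cpos <- seq_len(3L * usable)              # position along coding strand
    codonIndex <- ((cpos - 1L) %/% 3L) + 1L
    posInCodon <- ((cpos - 1L) %% 3L) + 1L
    codons <- substring(cds, 3L * (codonIndex - 1L) + 1L, 3L * codonIndex)
    gpos <- if (strand == "+") gs + ph + cpos - 1L else ge - ph - cpos + 1L
    out[[i]] <- data.frame(
      pos = gpos, gene_id = mc$gene_id[i], strand = strand,
      codonIndex = codonIndex, posInCodon = posInCodon, codon = codons,
      refCoding = substring(cds, cpos, cpos)
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.aaOfCodon <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Vectorized SNP consequence over a coding map. `df` needs pos/ref/alt.
# Returns one row per (SNP, CDS) pair; SNPs outside any CDS are absent.
.snpEffects <- function(df, cmap, proteinOffsets = NULL) {
  hits <- merge(df, cmap, by = "pos")
  if (!nrow(hits)) return(hits)
  altCoding <- ifelse(hits$strand == "+", hits$alt, complementBase(hits$alt))
  altCodon <- hits$codon
  substr(altCodon, hits$posInCodon, hits$posInCodon) <- altCoding
  refAA <- .aaOfCodon(hits$codon)
  altAA <- .aaOfCodon(altCodon)
  kind <- ifelse(refAA == altAA, "synonymous",
          ifelse(altAA == "*", "nonsense",
          ifelse(refAA == "*", "stop_loss", "missense")))
  num <- hits$codonIndex
  if (!is.null(proteinOffsets)) {
    offs <- proteinOffsets[hits$gene_id]
    offs[is.na(offs)] <- 0L
    num <- num - as.integer(offs)
  }
  hits$kind <- kind
  hits$hgvs <- paste0(refAA, num, altAA)
  hits$hgvs[kind == "synonymous"] <- paste0(refAA, num, "=")[kind == "synonymous"]
  hits
}

# Name an in-frame deletion of dAA residues first differing at protein
# index s0, 3'-shifted within repeats per HGVS.
.nameInframeDel <- function(refProt, dAA, s0) {
  n <- nchar(refProt)
  aa <- strsplit(refProt, "")[[1]]
  s <- s0
  while (s + dAA <= n && aa[s] == aa[s + dAA]) s <- s + 1L
  if (dAA == 1L) {
    paste0(aa[s], s, "del")
  } else {
    paste0(aa[s], s, "_", aa[s + dAA - 1L], s + dAA - 1L, "del")
  }
}

#' Annotate variant coding consequences
#'
#' Computes, for every variant and every CDS it touches (one row per
#' variant-CDS pair), the protein-level consequence on the
#' strand-corrected codon: `synonymous`, `missense`, `nonsense`,
#' `stop_loss`, `inframe_del`, `inframe_ins`, `frameshift` or
#' `intergenic`. SNP changes are named `<refAA><pos><altAA>` with
#' full-precursor numbering (position 1 = initiator Met); in-frame
#' deletions are named over the deleted residue range after HGVS-style
#' 3'-shifting within repeats (`L68_A69del`); indels whose length is not
#' a multiple of 3 are frameshifts. MNPs are annotated joined (they are
#' split into SNPs only for spectrum analysis).
#'
#' @param vs A normalized [VariantSet-class].
#' @param genome The annotated reference [AnnotatedGenome-class].
#' @param proteinOffsets Optional named integer vector of per-gene
#'   numbering offsets (e.g. a signal-peptide length, so that `E139G`
#'   reports as `E117G` in mature-protein numbering).
#' @return data.frame with columns pos, ref, alt, vclass, gene_id, kind,
#'   hgvs, codon_index (NA outside CDS). Calls truncated by the genome
#'   end carry `border = TRUE`.
#' @export
annotateVariants <- function(vs, genome, proteinOffsets = NULL) {
  v <- variants(vs)
  empty <- data.frame(pos = integer(), ref = character(), alt = character(),
                      vclass = character(), gene_id = character(),
                      kind = character(), hgvs = character(),
                      codon_index = integer(), border = logical())
  if (!nrow(v)) return(empty)
  ft <- cdsFeatures(genome)
  L <- genomeLength(genome)

  # affected reference span: SNP/MNP cover their ref bases; insertions
  # sit between pos and pos+1; deletions cover the deleted bases
  refLen <- nchar(v$ref)
  spanStart <- ifelse(v$vclass == "INS", v$pos, ifelse(refLen > 1L, v$pos + 1L, v$pos))
  spanEnd <- ifelse(v$vclass == "INS", v$pos + 1L, v$pos + refLen - 1L)
  spanStart <- pmin(spanStart, L); spanEnd <- pmin(spanEnd, L)
  vir <- IRanges::IRanges(spanStart, spanEnd)
  if (length(ft)) {
    fir <- IRanges::IRanges(GenomicRanges::start(ft), GenomicRanges::end(ft))
    ov <- IRanges::findOverlaps(vir, fir)
    hitVar <- S4Vectors::queryHits(ov)
    hitFt <- S4Vectors::subjectHits(ov)
  } else {
    hitVar <- integer(0); hitFt <- integer(0)
  }

  rows <- list()
  # intergenic variants
  inter <- setdiff(seq_len(nrow(v)), unique(hitVar))
  if (length(inter)) {
    rows[[length(rows) + 1L]] <- data.frame(
      pos = v$pos[inter], ref = v$ref[inter], alt = v$alt[inter],
      vclass = v$vclass[inter], gene_id = NA_character_,
      kind = "intergenic", hgvs = NA_character_,
      codon_index = NA_integer_, border = FALSE)
  }

  # SNPs inside CDS: fast vectorized path
  snpIdx <- unique(hitVar[v$vclass[hitVar] == "SNP"])
  if (length(snpIdx)) {
    cmap <- codingMap(genome)
    eff <- .snpEffects(v[snpIdx, c("pos", "ref", "alt")], cmap, proteinOffsets)
    if (nrow(eff)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = eff$pos, ref = eff$ref, alt = eff$alt, vclass = "SNP",
        gene_id = eff$gene_id, kind = eff$kind, hgvs = eff$hgvs,
        codon_index = eff$codonIndex, border = FALSE)
    }
  }

  # indels and MNPs inside CDS: per-pair reconstruction
  otherPairs <- which(v$vclass[hitVar] != "SNP")
  mc <- S4Vectors::mcols(ft)
  seq <- genomeSeq(genome)
  for (pi in otherPairs) {
    vi <- hitVar[pi]; fi <- hitFt[pi]
    gs <- GenomicRanges::start(ft)[fi]; ge <- GenomicRanges::end(ft)[fi]
    strand <- as.character(GenomicRanges::strand(ft))[fi]
    gene <- mc$gene_id[fi]
    dlen <- nchar(v$alt[vi]) - nchar(v$ref[vi])
    border <- (v$pos[vi] + nchar(v$ref[vi]) - 1L) >= L || v$pos[vi] <= 1L
    if (v$vclass[vi] == "MNP") {
      # annotate joined: recompute the protein over the substituted region
      kindName <- .mnpEffect(v[vi, ], gs, ge, strand, seq)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi], vclass = "MNP",
        gene_id = gene, kind = kindName$kind, hgvs = kindName$hgvs,
        codon_index = kindName$codon_index, border = border)
      next
    }
    if (dlen %% 3L != 0L) {
      fsIdx <- .codonIndexAt(v$pos[vi] + 1L, gs, ge, strand)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi],
        vclass = v$vclass[vi], gene_id = gene, kind = "frameshift",
        hgvs = "fs", codon_index = fsIdx, border = border)
      next
    }
    # in-frame indel: compare proteins
    region <- substr(seq, gs, ge)
    relPos <- v$pos[vi] - gs + 1L
    altRegion <- paste0(substr(region, 1L, relPos - 1L), v$alt[vi],
                        substr(region, relPos + nchar(v$ref[vi]), nchar(region)))
    refCds <- if (strand == "+") region else revComp(region)
    altCds <- if (strand == "+") altRegion else revComp(altRegion)
    refProt <- .translateCds(refCds)
    altProt <- .translateCds(altCds)
    if (v$vclass[vi] == "DEL") {
      dAA <- abs(dlen) %/% 3L
      s0 <- .firstDiff(refProt, altProt)
      hg <- .nameInframeDel(refProt, dAA, s0)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi], vclass = "DEL",
        gene_id = gene, kind = "inframe_del", hgvs = hg,
        codon_index = s0, border = border)
    } else {
      s0 <- .firstDiff(refProt, altProt)
      aa <- strsplit(refProt, "")[[1]]
      lhs <- max(1L, s0 - 1L)
      hg <- paste0(aa[lhs], lhs, "_", aa[min(length(aa), lhs + 1L)],
                   min(length(aa), lhs + 1L), "ins")
      rows[[length(rows) + 1L]] <- data.frame(
        pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi], vclass = "INS",
        gene_id = gene, kind = "inframe_ins", hgvs = hg,
        codon_index = s0, border = border)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.translateCds <- function(cds) {
  nc <- (nchar(cds) %/% 3L) * 3L
  if (!nc) return("")
  codons <- substring(cds, seq(1L, nc, 3L), seq(3L, nc, 3L))
  paste(.aaOfCodon(codons), collapse = "")
}

.firstDiff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  for (i in seq_len(n)) if (av[i] != bv[i]) return(i)
  n + 1L
}

.codonIndexAt <- function(pos, gs, ge, strand) {
  cpos <- if (strand == "+") pos - gs + 1L else ge - pos + 1L
  as.integer((cpos - 1L) %/% 3L + 1L)
}

.mnpEffect <- function(vrow, gs, ge, strand, seq) {
  region <- substr(seq, gs, ge)
  relPos <- vrow$pos - gs + 1L
  altRegion <- region
  substr(altRegion, relPos, relPos + nchar(vrow$ref) - 1L) <- vrow$alt
  refProt <- .translateCds(if (strand == "+") region else revComp(region))
  altProt <- .translateCds(if (strand == "+") altRegion else revComp(altRegion))
  if (refProt == altProt) {
    return(list(kind = "synonymous", hgvs = NA_character_,
                codon_index = .codonIndexAt(vrow$pos, gs, ge, strand)))
  }
  s0 <- .firstDiff(refProt, altProt)
  refAA <- substr(refProt, s0, s0); altAA <- substr(altProt, s0, s0)
  kind <- if (altAA == "*") "nonsense" else if (refAA == "*") "stop_loss" else "missense"
  list(kind = kind, hgvs = paste0(refAA, s0, altAA), codon_index = s0)
}
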