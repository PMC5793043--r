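# Forward simulator: annotated ancestor construction and mutator-regime
# evolution along a collection-transfer chain, with exact ground truth.
#
# Design notes (expanded in the methods vignette):
# * The simulator counts mutations, not generations.
# * All mutations of a lineage are drawn in ROOT coordinates and each
#   derived genome is obtained by splicing its accumulated set into the
#   root sequence; variant sets along a root-to-leaf path are therefore
#   nested by construction and no back-mutation can occur.
# * Events on one lineage path are placed with a minimum spacing (and a
#   homopolymer run is blocked as a whole), so every event has a unique
#   normalized representation: the exact-recovery round trip
#   (call(apply(truth)) == truth) is well defined.

MUT_MIN_SPACING <- 25L
MUT_EDGE_MARGIN <- 50L

#' Mutator regime presets
#'
#' `"MMR"` emulates loss of methyl-directed mismatch repair: elevated
#' indel fraction (homopolymer-biased slippage) and transition-dominated
#' substitutions. `"MutT"` emulates loss of oxidized-guanine sanitation:
#' `A:T>C:G` transversions dominate. `"oxidative"` enriches `G:C>T:A`
#' transversions. `"wildtype"` is an unbiased low-indel control.
#'
#' @param name One of `"MMR"`, `"MutT"`, `"oxidative"`, `"wildtype"`.
#' @return A [MutatorRegime-class].
#' @export
regimePreset <- function(name = c("MMR", "MutT", "oxidative", "wildtype")) {
  name <- match.arg(name)
  w <- switch(name,
    MMR = c(0.42, 0.42, 0.04, 0.04, 0.04, 0.04),
    MutT = c(0.15, 0.15, 0.50, 0.05, 0.10, 0.05),
    oxidative = c(0.15, 0.15, 0.10, 0.05, 0.50, 0.05),
    wildtype = rep(1 / 6, 6)
  )
  names(w) <- SUBSTITUTION_CLASSES
  f <- switch(name, MMR = 0.5, MutT = 0.1, oxidative = 0.1, wildtype = 0.1)
  b <- switch(name, MMR = 0.8, 0.5)
  mutatorRegime(w, indelFraction = f, indelHomopolymerBias = b, name = name)
}

SENSE_CODONS <- NULL  # filled at load time
STOP_CODONS <- c("TAA", "TAG", "TGA")

.onLoad <- function(libname, pkgname) {
  cods <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  utils::assignInMyNamespace("SENSE_CODONS", setdiff(cods, STOP_CODONS))
}

#' Generate a random annotated ancestral genome
#'
#' Builds a GC-controlled random chromosome and packs `nGenes`
#' non-overlapping, ORF-valid CDS (ATG start, single terminal stop, no
#' internal stops) on both strands. The realized GC stays within ~2% of
#' the target for genomes of 100 kb and above.
#'
#' @param length Genome length in bp.
#' @param gc Target GC fraction (degenerate values near 0 or 1 are
#'   rejected: no valid start codon can be guaranteed).
#' @param nGenes Number of CDS to pack.
#' @param meanGeneLen Mean CDS length in bp (including the stop codon).
#' @param seed Integer seed; the same inputs and seed give a
#'   byte-identical genome.
#' @param geneIds Optional character vector of gene ids (recycled names
#'   default to `gene001`...).
#' @return An [AnnotatedGenome-class].
#' @export
generateAncestor <- function(length, gc = 0.5, nGenes = 40,
                             meanGeneLen = 900, seed = 1, geneIds = NULL) {
  if (gc >= 0.95 || gc <= 0.05) {
    stop("degenerate GC target: start/stop codons cannot be composed")
  }
  spacer <- 60L
  if (length < nGenes * (meanGeneLen + spacer) + 2L * MUT_EDGE_MARGIN) {
    stop("infeasible packing: genome too short for ", nGenes, " genes")
  }
  if (is.null(geneIds)) geneIds <- sprintf("gene%03d", seq_len(nGenes))
  stopifnot(length(geneIds) == nGenes)
  withSeed(seed, {
    # codon usage weighted by per-base GC so coding regions track the target
    pBase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    codP <- vapply(SENSE_CODONS, function(cd) {
      prod(pBase[strsplit(cd, "")[[1]]])
    }, numeric(1))
    nCodons <- pmax(20L, round((meanGeneLen / 3) * stats::runif(nGenes, 0.8, 1.2)))
    genes <- vapply(seq_len(nGenes), function(i) {
      body <- sample(SENSE_CODONS, nCodons[i] - 2L, replace = TRUE, prob = codP)
      paste0("ATG", paste(body, collapse = ""),
             sample(STOP_CODONS, 1L, prob = c(.6, .2, .2)))
    }, character(1))
    glen <- nchar(genes)
    slack <- length - sum(glen) - 2L * MUT_EDGE_MARGIN
    if (slack < nGenes + 1L) stop("infeasible packing: no room for spacers")
    u <- stats::runif(nGenes + 1L)
    gaps <- floor(slack * u / sum(u))
    starts <- MUT_EDGE_MARGIN + cumsum(gaps[seq_len(nGenes)]) +
      c(0L, cumsum(glen[-nGenes]))
    ends <- starts + glen - 1L
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)
    seq <- randomDna(length, gc)
    for (i in seq_len(nGenes)) {
      ins <- if (strands[i] == "+") genes[i] else revComp(genes[i])
      substr(seq, starts[i], ends[i]) <- ins
    }
    ft <- cdsGRanges(gene_id = geneIds, start = starts, end = ends,
                     strand = strands, product = "hypothetical protein",
                     seqname = "ancestor")
    AnnotatedGenome("ancestor", seq, circular = TRUE, features = ft)
  })
}

# --- internal mutation drawing (root coordinates) -------------------------

# Returns run table of homopolymers >= minRun.
.homopolymerRuns <- function(seq, minRun = 3L) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minRun & r$values %in% DNA_BASES
  data.frame(start = starts[keep], end = ends[keep],
             base = r$values[keep], len = r$lengths[keep])
}

# Canonical alt base for each class given a canonical (A or G) ref.
.CLASS_ALT <- c("A:T>G:C" = "G", "G:C>A:T" = "A", "A:T>C:G" = "C",
                "A:T>T:A" = "T", "G:C>T:A" = "T", "G:C>C:G" = "C")
.CLASS_REF <- c("A:T>G:C" = "A", "G:C>A:T" = "G", "A:T>C:G" = "A",
                "A:T>T:A" = "A", "G:C>T:A" = "G", "G:C>C:G" = "G")

# Draw n mutations on `genome` (root coordinates), avoiding positions
# masked in `blocked` (logical vector over the genome). Returns
# list(tab = data.frame(pos, ref, alt, class), blocked = updated mask).
# RNG state: caller's (wrap in withSeed upstream).
drawMutations <- function(genome, regime, n, blocked = NULL,
                          spacing = MUT_MIN_SPACING) {
  L <- genomeLength(genome)
  seq <- genomeSeq(genome)
  bases <- strsplit(seq, "")[[1]]
  if (is.null(blocked)) blocked <- rep(FALSE, L)
  blocked[seq_len(min(MUT_EDGE_MARGIN, L))] <- TRUE
  blocked[seq.int(max(1L, L - MUT_EDGE_MARGIN + 1L), L)] <- TRUE

  runs <- .homopolymerRuns(seq)
  idxByPair <- list(
    AT = which(bases == "A" | bases == "T"),
    GC = which(bases == "G" | bases == "C")
  )
  w <- classWeights(regime)

  nIndelEv <- stats::rbinom(1L, n, indelFraction(regime))
  nSnpEv <- n - nIndelEv
  block <- function(b, from, to) {
    b[max(1L, from):min(L, to)] <- TRUE
    b
  }
  out <- vector("list", n)
  k <- 0L

  drawSite <- function(pool) {
    for (try in seq_len(5000L)) {
      p <- pool[sample.int(length(pool), 1L)]
      if (!blocked[p]) return(p)
    }
    stop("site exhaustion: could not place mutation")
  }

  if (nSnpEv > 0L) {
    classes <- sample(SUBSTITUTION_CLASSES, nSnpEv, replace = TRUE, prob = w)
    for (cl in classes) {
      pair <- if (.CLASS_REF[[cl]] == "A") "AT" else "GC"
      p <- drawSite(idxByPair[[pair]])
      refb <- bases[p]
      altb <- if (refb == .CLASS_REF[[cl]]) .CLASS_ALT[[cl]] else complementBase(.CLASS_ALT[[cl]])
      k <- k + 1L
      out[[k]] <- data.frame(pos = p, ref = refb, alt = altb, class = cl)
      blocked <- block(blocked, p - spacing, p + spacing)
    }
  }

  if (nIndelEv > 0L) {
    okRuns <- runs[!blocked[runs$start] & runs$start > MUT_EDGE_MARGIN &
                     runs$end < L - MUT_EDGE_MARGIN, , drop = FALSE]
    for (i in seq_len(nIndelEv)) {
      useRun <- nrow(okRuns) > 0L &&
        stats::runif(1L) < regime@indelHomopolymerBias
      if (useRun) {
        repeat {
          ri <- sample.int(nrow(okRuns), 1L)
          run <- okRuns[ri, ]
          if (!any(blocked[run$start:run$end])) break
          okRuns <- okRuns[-ri, , drop = FALSE]
          if (!nrow(okRuns)) { useRun <- FALSE; break }
        }
      }
      if (useRun) {
        # +/-1 bp slippage, anchored left of the run (canonical form)
        anchor <- run$start - 1L
        ref1 <- bases[anchor]
        if (stats::runif(1L) < 0.5) {
          pos <- anchor; ref <- ref1; alt <- paste0(ref1, run$base)
        } else {
          pos <- anchor; ref <- paste0(ref1, run$base); alt <- ref1
        }
        k <- k + 1L
        out[[k]] <- data.frame(pos = pos, ref = ref, alt = alt, class = "indel")
        blocked <- block(blocked, run$start - spacing, run$end + spacing)
      } else {
        len <- sample(1:6, 1L, prob = c(.55, .2, .1, .07, .05, .03))
        for (try in seq_len(1000L)) {
          p <- drawSite(seq_len(L))
          if (any(blocked[max(1L, p - 1L):min(L, p + len + 1L)])) next
          if (stats::runif(1L) < 0.5) {
            ref <- bases[p]
            alt <- paste0(ref, paste(sample(DNA_BASES, len, replace = TRUE),
                                     collapse = ""))
          } else {
            ref <- paste(bases[p:(p + len)], collapse = "")
            alt <- bases[p]
          }
          nn <- normalizeOne(p, ref, alt, seq)
          if (blocked[nn$pos]) next  # canonical position collides; redraw
          k <- k + 1L
          out[[k]] <- data.frame(pos = nn$pos, ref = nn$ref, alt = nn$alt,
                                 class = "indel")
          blocked <- block(blocked, nn$pos - spacing,
                           nn$pos + nchar(nn$ref) + spacing)
          break
        }
      }
    }
  }
  tab <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               class = character())
  if (nrow(tab) < n) stop("site exhaustion: placed ", nrow(tab), " of ", n)
  list(tab = tab, blocked = blocked)
}

# Remap feature coordinates from root to derived coordinates.
.remapFeatures <- function(ft, truthVs, newSeqname) {
  if (!length(ft)) return(ft)
  s <- mapRefToDerived(truthVs, GenomicRanges::start(ft))
  e <- mapRefToDerived(truthVs, GenomicRanges::end(ft))
  mc <- S4Vectors::mcols(ft)
  cdsGRanges(gene_id = mc$gene_id, start = s, end = e,
             strand = as.character(GenomicRanges::strand(ft)),
             phase = mc$phase, product = mc$product, seqname = newSeqname)
}

#' Evolve a genome under a mutator regime
#'
#' Introduces exactly `n` mutations at distinct, well-separated sites.
#' Substitution classes are drawn from the regime's class weights and a
#' matching-base-pair site is then drawn uniformly, so the realized
#' class spectrum is multinomial in the weights. Indels are +/-1 bp
#' homopolymer slippage events with probability
#' `indelHomopolymerBias`, otherwise 1-6 bp events (length 1 dominant)
#' at random sites; all truth records are normalized (left-aligned).
#'
#' @param genome Parent [AnnotatedGenome-class].
#' @param regime A [MutatorRegime-class] (or preset name).
#' @param n Number of mutations.
#' @param seed Integer seed.
#' @param isolateId Label for the derived isolate.
#' @return A list with elements `genome` (derived [AnnotatedGenome-class],
#'   features remapped through the indels) and `truth` (normalized
#'   [VariantSet-class] versus `genome`, with a `class` column retained
#'   as attribute `mutClass`).
#' @export
evolveGenome <- function(genome, regime, n, seed = 1,
                         isolateId = paste0(genomeId(genome), "_derived")) {
  if (is.character(regime)) regime <- regimePreset(regime)
  stopifnot(isWholeNumber(n), n >= 0)
  dm <- withSeed(seed, drawMutations(genome, regime, n))
  .buildDerived(genome, dm$tab, isolateId)
}

.buildDerived <- function(root, tab, isolateId) {
  tab <- tab[order(tab$pos), , drop = FALSE]
  truth <- VariantSet(genomeId(root), isolateId,
                      pos = tab$pos, ref = tab$ref, alt = tab$alt)
  # VariantSet() re-sorts identically (spacing forbids shared positions)
  attr(truth, "mutClass") <- tab$class
  dseq <- applyVariantSet(truth, root)
  ft <- .remapFeatures(cdsFeatures(root), truth, isolateId)
  dg <- AnnotatedGenome(isolateId, dseq, circular = root@circular,
                        features = ft)
  list(genome = dg, truth = truth)
}

#' Simulate a collection-transfer history
#'
#' Evolves derived isolates along a rooted transfer tree (the plan), one
#' mutator regime and mutation count per edge. Mutations on one
#' root-to-leaf path fall on distinct sites, so ancestor-relative
#' variant sets are nested along the path and the number of mutations
#' grows monotonically with transfer depth — the phylogeographic signal
#' the downstream clustering recovers.
#'
#' @param ancestor Root [AnnotatedGenome-class].
#' @param plan data.frame with columns `parent`, `child`, `n`, `regime`
#'   (preset name), edges parent-before-child; see [odysseyPlan()].
#' @param seed Integer seed. Edge `i` uses the derived stream seed
#'   `childSeed(seed, i)`, so a fixed plan and seed reproduce every
#'   genome byte-identically.
#' @return A list with `genomes` (named list of [AnnotatedGenome-class],
#'   root included), `truth` (named list of [VariantSet-class] versus the
#'   root; the root's set is empty) and `plan`.
#' @export
simulateCollectionHistory <- function(ancestor, plan, seed = 1) {
  validatePlan(plan)
  rootLab <- setdiff(plan$parent, plan$child)[1]
  emptyTab <- data.frame(pos = integer(), ref = character(),
                         alt = character(), class = character())
  tabs <- list(); masks <- list()
  tabs[[rootLab]] <- emptyTab
  masks[[rootLab]] <- NULL
  genomes <- list()
  genomes[[rootLab]] <- ancestor
  truth <- list()
  truth[[rootLab]] <- VariantSet(genomeId(ancestor), rootLab)
  for (i in seq_len(nrow(plan))) {
    par <- plan$parent[i]; chd <- plan$child[i]
    regime <- regimePreset(plan$regime[i])
    dm <- withSeed(childSeed(seed, i),
                   drawMutations(ancestor, regime, plan$n[i],
                                 blocked = masks[[par]]))
    tabs[[chd]] <- rbind(tabs[[par]], dm$tab)
    masks[[chd]] <- dm$blocked
    d <- .buildDerived(ancestor, tabs[[chd]], chd)
    genomes[[chd]] <- d$genome
    truth[[chd]] <- d$truth
  }
  list(genomes = genomes, truth = truth, plan = plan)
}

#' Validate a lineage plan
#'
#' Checks the edge table forms a tree: a single root, each child with
#' one parent, parents defined before use, nonnegative mutation counts.
#'
#' @param plan data.frame with columns parent, child, n, regime.
#' @return `TRUE` invisibly; stops on an invalid plan.
#' @export
validatePlan <- function(plan) {
  need <- c("parent", "child", "n", "regime")
  if (!is.data.frame(plan) || !all(need %in% names(plan))) {
    stop("plan must be a data.frame with columns parent, child, n, regime")
  }
  if (anyDuplicated(plan$child)) stop("plan is not a tree: duplicated child")
  roots <- setdiff(plan$parent, plan$child)
  if (length(unique(roots)) != 1L) stop("plan must have exactly one root label")
  seen <- roots[1]
  for (i in seq_len(nrow(plan))) {
    if (!plan$parent[i] %in% seen) {
      stop("plan edge ", i, ": parent '", plan$parent[i],
           "' not defined before use")
    }
    seen <- c(seen, plan$child[i])
  }
  if (any(plan$n < 0)) stop("plan mutation counts must be >= 0")
  ok <- vapply(plan$regime, function(r) {
    r %in% c("MMR", "MutT", "oxidative", "wildtype")
  }, logical(1))
  if (!all(ok)) stop("unknown regime preset in plan")
  invisible(TRUE)
}

#' The collection-odyssey lineage plan
#'
#' Transfer chain of six isolates of one strain across culture
#' collections: the root reference, two sibling isolates of the first
#' collection, then sequential transfers to three further collections.
#' Per-edge mutation counts (4, 11, 94, 341, 126) make the cumulative
#' root-to-leaf totals 4 / 11 / 105 / 446 / 572. Early edges run under
#' the MMR regime (indel- and transition-rich), later edges under the
#' MutT regime (A:T>C:G-enriched), mirroring the sequential inactivation
#' of mismatch repair and oxidized-guanine sanitation.
#'
#' @param scale Multiplier applied to the per-edge mutation counts
#'   (counts are rounded and floored at 2).
#' @return A plan data.frame for [simulateCollectionHistory()].
#' @export
odysseyPlan <- function(scale = 1) {
  plan <- data.frame(
    parent = c("Dunne", "Dunne", "NCTC86", "CIP", "ATCC"),
    child = c("Meric", "NCTC86", "CIP", "ATCC", "DSM"),
    n = c(4L, 11L, 94L, 341L, 126L),
    regime = c("MMR", "MMR", "MutT", "MutT", "MutT"),
    stringsAsFactors = FALSE
  )
  plan$n <- pmax(2L, as.integer(round(plan$n * scale)))
  plan
}

#' Plant a squatter-colony fixture
#'
#' Derives a genome from `parent` carrying exactly one CDS-altering
#' mutation of the requested kind in `targetGene` (a missense SNP or a
#' frameshifting +1 insertion), plus a configurable number of background
#' synonymous and intergenic SNPs that must NOT survive the
#' squatter-variant filter.
#'
#' @param parent Parent [AnnotatedGenome-class] (annotated).
#' @param targetGene gene_id of the regulator gene to hit.
#' @param changeKind `"missense"` or `"frameshift"`.
#' @param seed Integer seed.
#' @param nBackground Number of background (synonymous + intergenic) SNPs.
#' @param isolateId Label of the squatter isolate.
#' @param extraMissenseGene Optional gene_id receiving one additional
#'   missense SNP (noise for convergence tests).
#' @return list(genome, truth) as in [evolveGenome()].
#' @export
makeSquatterFixture <- function(parent, targetGene,
                                changeKind = c("missense", "frameshift"),
                                seed = 1, nBackground = 6,
                                isolateId = "squatter",
                                extraMissenseGene = NULL) {
  changeKind <- match.arg(changeKind)
  ft <- cdsFeatures(parent)
  mc <- S4Vectors::mcols(ft)
  if (!targetGene %in% mc$gene_id) stop("target gene not in annotation: ", targetGene)
  withSeed(seed, {
    blocked <- rep(FALSE, genomeLength(parent))
    rows <- list()
    planted <- .plantCdsChange(parent, targetGene, changeKind, blocked)
    rows[[1]] <- planted$row; blocked <- planted$blocked
    if (!is.null(extraMissenseGene)) {
      p2 <- .plantCdsChange(parent, extraMissenseGene, "missense", blocked)
      rows[[length(rows) + 1L]] <- p2$row; blocked <- p2$blocked
    }
    nSyn <- nBackground %/% 2L
    nInter <- nBackground - nSyn
    for (i in seq_len(nSyn)) {
      s <- .plantSynonymous(parent, blocked)
      rows[[length(rows) + 1L]] <- s$row; blocked <- s$blocked
    }
    for (i in seq_len(nInter)) {
      s <- .plantIntergenic(parent, blocked)
      rows[[length(rows) + 1L]] <- s$row; blocked <- s$blocked
    }
    tab <- do.call(rbind, rows)
    .buildDerived(parent, tab, isolateId)
  })
}

#' Simulate SNPs under a selection regime
#'
#' Draws `n` SNPs at distinct sites uniformly over the genome (coding
#' and intergenic; terminal stop codons excluded, matching the Ka/Ks
#' enumeration convention). At each site the transition partner is
#' chosen with probability `tsFraction`, otherwise one of the two
#' transversions uniformly — i.e. the same per-site allocation the
#' Ka/Ks expectation uses, so with `missenseAcceptance = 1` the process
#' is neutral and the expected Ka/Ks ratio is 1. Missense candidates
#' are retained with probability `missenseAcceptance` (0.5 emulates
#' purifying selection rejecting half of the amino-acid-changing
#' draws).
#'
#' @param genome Annotated [AnnotatedGenome-class].
#' @param n Number of SNPs.
#' @param tsFraction Transition probability per draw.
#' @param missenseAcceptance Acceptance probability for missense draws.
#' @param seed Integer seed.
#' @param isolateId Label for the returned set.
#' @return A [VariantSet-class] of SNPs.
#' @export
simulateSelectionSnps <- function(genome, n, tsFraction = 2 / 3,
                                  missenseAcceptance = 1, seed = 1,
                                  isolateId = "selection_sim") {
  L <- genomeLength(genome)
  seq <- genomeSeq(genome)
  bases <- strsplit(seq, "")[[1]]
  cmap <- codingMap(genome)
  cmapAll <- codingMap(genome, dropTerminalStop = FALSE)
  terminalStops <- setdiff(cmapAll$pos, codingMap(genome, TRUE)$pos)
  tsPartner <- c(A = "G", G = "A", C = "T", T = "C")
  withSeed(seed, {
    chosen <- integer(0)
    alts <- character(0)
    while (length(chosen) < n) {
      m <- 2L * (n - length(chosen)) + 50L
      p <- sample.int(L, m, replace = TRUE)
      p <- p[!(p %in% terminalStops) & !(p %in% chosen)]
      p <- p[!duplicated(p)]
      if (!length(p)) next
      refb <- bases[p]
      isTs <- stats::runif(length(p)) < tsFraction
      alt <- ifelse(isTs, tsPartner[refb], NA)
      tv <- which(!isTs)
      if (length(tv)) {
        alt[tv] <- vapply(tv, function(i) {
          sample(setdiff(DNA_BASES, c(refb[i], tsPartner[[refb[i]]])), 1L)
        }, character(1))
      }
      if (missenseAcceptance < 1) {
        eff <- .snpEffects(data.frame(pos = p, ref = refb, alt = alt), cmap)
        misPos <- unique(eff$pos[eff$kind == "missense"])
        rejected <- misPos[stats::runif(length(misPos)) >= missenseAcceptance]
        keep <- !(p %in% rejected)
      } else {
        keep <- rep(TRUE, length(p))
      }
      chosen <- c(chosen, p[keep])
      alts <- c(alts, alt[keep])
    }
    chosen <- chosen[seq_len(n)]
    alts <- alts[seq_len(n)]
    VariantSet(genomeId(genome), isolateId,
               pos = chosen, ref = bases[chosen], alt = alts)
  })
}

.blockAround <- function(blocked, pos, L, spacing = MUT_MIN_SPACING) {
  blocked[max(1L, pos - spacing):min(L, pos + spacing)] <- TRUE
  blocked
}

# One missense SNP or +1 frameshift insertion inside a gene.
.plantCdsChange <- function(genome, gene, kind, blocked) {
  ft <- cdsFeatures(genome)
  f <- ft[S4Vectors::mcols(ft)$gene_id == gene]
  gs <- GenomicRanges::start(f); ge <- GenomicRanges::end(f)
  seq <- genomeSeq(genome)
  L <- genomeLength(genome)
  strand <- as.character(GenomicRanges::strand(f))
  if (kind == "frameshift") {
    repeat {
      p <- sample(seq.int(gs + 6L, ge - 6L), 1L)
      if (!blocked[p]) break
    }
    b <- substr(seq, p, p)
    nn <- normalizeOne(p, b, paste0(b, b), seq)  # duplicate a base: +1 fs
    row <- data.frame(pos = nn$pos, ref = nn$ref, alt = nn$alt, class = "indel")
    blocked <- .blockAround(blocked, nn$pos, L)
    return(list(row = row, blocked = blocked))
  }
  gc <- Biostrings::GENETIC_CODE
  repeat {
    p <- sample(seq.int(gs + 3L, ge - 3L), 1L)
    if (blocked[p]) next
    cidx0 <- (if (strand == "+") p - gs else ge - p) %/% 3L
    codStart <- if (strand == "+") gs + 3L * cidx0 else ge - 3L * cidx0 - 2L
    cod <- substr(seq, codStart, codStart + 2L)
    codCoding <- if (strand == "+") cod else revComp(cod)
    off <- if (strand == "+") p - codStart else codStart + 2L - p
    refB <- substr(seq, p, p)
    for (altB in sample(setdiff(DNA_BASES, refB))) {
      altCoding <- codCoding
      substr(altCoding, off + 1L, off + 1L) <-
        if (strand == "+") altB else complementBase(altB)
      aaR <- gc[[codCoding]]; aaA <- gc[[altCoding]]
      if (aaA != aaR && aaA != "*" && aaR != "*") {
        row <- data.frame(pos = p, ref = refB, alt = altB, class = "SNP")
        blocked <- .blockAround(blocked, p, L)
        return(list(row = row, blocked = blocked))
      }
    }
  }
}

# A synonymous SNP at a four-fold degenerate third codon position.
.plantSynonymous <- function(genome, blocked) {
  ft <- cdsFeatures(genome)
  seq <- genomeSeq(genome)
  L <- genomeLength(genome)
  gc <- Biostrings::GENETIC_CODE
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  repeat {
    f <- ft[sample.int(length(ft), 1L)]
    gs <- GenomicRanges::start(f); ge <- GenomicRanges::end(f)
    strand <- as.character(GenomicRanges::strand(f))
    nc <- (ge - gs + 1L) %/% 3L
    ci <- sample(seq.int(2L, nc - 1L), 1L)
    codStart <- if (strand == "+") gs + 3L * (ci - 1L) else ge - 3L * ci + 1L
    cod <- substr(seq, codStart, codStart + 2L)
    codCoding <- if (strand == "+") cod else revComp(cod)
    if (!substr(codCoding, 1L, 2L) %in% fourfold) next
    p <- if (strand == "+") codStart + 2L else codStart
    if (blocked[p]) next
    refB <- substr(seq, p, p)
    altB <- sample(setdiff(DNA_BASES, refB), 1L)
    row <- data.frame(pos = p, ref = refB, alt = altB, class = "SNP")
    return(list(row = row, blocked = .blockAround(blocked, p, L)))
  }
}

.plantIntergenic <- function(genome, blocked) {
  ft <- cdsFeatures(genome)
  L <- genomeLength(genome)
  seq <- genomeSeq(genome)
  inCds <- rep(FALSE, L)
  for (i in seq_along(ft)) {
    inCds[GenomicRanges::start(ft)[i]:GenomicRanges::end(ft)[i]] <- TRUE
  }
  pool <- which(!inCds & !blocked)
  pool <- pool[pool > MUT_EDGE_MARGIN & pool < L - MUT_EDGE_MARGIN]
  p <- pool[sample.int(length(pool), 1L)]
  refB <- substr(seq, p, p)
  altB <- sample(setdiff(DNA_BASES, refB), 1L)
  row <- data.frame(pos = p, ref = refB, alt = altB, class = "SNP")
  list(row = row, blocked = .blockAround(blocked, p, L))
}
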