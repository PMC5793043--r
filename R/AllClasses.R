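#' @import methods
NULL

#' AnnotatedGenome: a chromosome (or contig) with its CDS features
#'
#' Container for a single DNA sequence and its coding-sequence annotation.
#' This is the coordinate frame for every downstream analysis: variant
#' calling, effect annotation, spectra, Ka/Ks and cgMLST all use 1-based
#' inclusive coordinates on this sequence.
#'
#' Features are held as a [GenomicRanges::GRanges] with metadata columns
#' `gene_id`, `phase` (0/1/2), `product` and `pseudo` (TRUE when the CDS
#' length after phase adjustment is not a multiple of 3).
#'
#' @slot id Genome identifier.
#' @slot sequence Uppercase DNA string. Ambiguity codes are permitted on
#'   real input; simulated output is strictly ACGT.
#' @slot circular Whether the replicon is circular.
#' @slot features `GRanges` of CDS features.
#'
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(
    id = "character",
    sequence = "character",
    circular = "logical",
    features = "GRanges"
  )
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be length 1")
  if (length(object@sequence) != 1L) msg <- c(msg, "'sequence' must be length 1")
  seq <- object@sequence
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), IUPAC_OK)
  if (length(bad)) {
    msg <- c(msg, paste0("non-IUPAC characters in sequence: ",
                         paste(bad, collapse = ", ")))
  }
  n <- nchar(seq)
  ft <- object@features
  if (length(ft)) {
    if (any(GenomicRanges::start(ft) < 1L) || any(GenomicRanges::end(ft) > n)) {
      msg <- c(msg, "feature intervals must lie within [1, genome length]")
    }
    if (!all(as.character(GenomicRanges::strand(ft)) %in% c("+", "-"))) {
      msg <- c(msg, "feature strand must be '+' or '-'")
    }
    mc <- S4Vectors::mcols(ft)
    for (col in c("gene_id", "phase", "product", "pseudo")) {
      if (!col %in% colnames(mc)) {
        msg <- c(msg, paste0("features need metadata column '", col, "'"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param id Genome identifier.
#' @param sequence DNA string (will be uppercased).
#' @param circular Logical; circular replicon.
#' @param features `GRanges` of CDS features, or a data.frame with columns
#'   `gene_id`, `start`, `end`, `strand` and optionally `phase`, `product`.
#' @return An [AnnotatedGenome-class] object.
#' @examples
#' g <- AnnotatedGenome("toy", "ATGAAATAA")
#' genomeLength(g)
#' @export
AnnotatedGenome <- function(id, sequence, circular = FALSE,
                            features = GenomicRanges::GRanges()) {
  sequence <- toupper(as.character(sequence))
  if (is.data.frame(features)) {
    features <- cdsGRanges(
      gene_id = features$gene_id, start = features$start, end = features$end,
      strand = features$strand,
      phase = if (is.null(features$phase)) 0L else features$phase,
      product = if (is.null(features$product)) "" else features$product,
      seqname = id
    )
  }
  features <- .fillPseudoFlag(features)
  new("AnnotatedGenome", id = id, sequence = sequence,
      circular = circular, features = features)
}

# Build a CDS GRanges with the standard metadata columns.
cdsGRanges <- function(gene_id, start, end, strand, phase = 0L,
                       product = "", seqname = "chr") {
  n <- length(gene_id)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(seqname, n),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$phase <- as.integer(rep(phase, length.out = n))
  S4Vectors::mcols(gr)$product <- as.character(rep(product, length.out = n))
  gr
}

.fillPseudoFlag <- function(ft) {
  if (!length(ft)) {
    if (!"pseudo" %in% colnames(S4Vectors::mcols(ft))) {
      S4Vectors::mcols(ft)$pseudo <- logical(0)
    }
    return(ft)
  }
  ph <- S4Vectors::mcols(ft)$phase
  if (is.null(ph)) ph <- rep(0L, length(ft))
  len <- GenomicRanges::width(ft) - ph
  S4Vectors::mcols(ft)$pseudo <- (len %% 3L) != 0L
  ft
}

#' @describeIn AnnotatedGenome Genome identifier.
#' @param x,object An `AnnotatedGenome`.
#' @export
genomeId <- function(x) x@id

#' @describeIn AnnotatedGenome DNA sequence as a character string.
#' @export
genomeSeq <- function(x) x@sequence

#' @describeIn AnnotatedGenome Sequence length in bp.
#' @export
genomeLength <- function(x) nchar(x@sequence)

#' @describeIn AnnotatedGenome CDS features as a `GRanges`.
#' @export
cdsFeatures <- function(x) x@features

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome", object@id, "\n")
  cat(" ", genomeLength(object), "bp;",
      length(object@features), "CDS features;",
      if (object@circular) "circular" else "linear", "\n")
})

#' VariantSet: normalized differences of one isolate versus a reference
#'
#' A position-sorted set of normalized variants (SNP/INS/DEL/MNP) of one
#' isolate against one reference genome. Indels use the VCF anchor-base
#' convention (`pos` is the base immediately left of the event; for an
#' insertion `alt` extends `ref` on the right, for a deletion `ref`
#' extends `alt`). Optional per-variant call metadata: Phred quality
#' (`qual`), absolute coverage (`dp`), relative coverage (`af`).
#'
#' @slot referenceId Reference genome id.
#' @slot isolateId Query isolate id.
#' @slot variants data.frame with columns pos, ref, alt, vclass, qual, dp, af.
#'
#' @exportClass VariantSet
setClass("VariantSet",
  representation(
    referenceId = "character",
    isolateId = "character",
    variants = "data.frame"
  )
)

setValidity("VariantSet", function(object) {
  v <- object@variants
  msg <- character()
  need <- c("pos", "ref", "alt", "vclass", "qual", "dp", "af")
  if (!all(need %in% colnames(v))) {
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(v)) {
    if (any(v$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (is.unsorted(v$pos)) msg <- c(msg, "variants must be position-sorted")
    key <- paste(v$pos, v$ref, v$alt)
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (pos, ref, alt) entries")
    if (!all(v$vclass %in% c("SNP", "INS", "DEL", "MNP"))) {
      msg <- c(msg, "vclass must be SNP, INS, DEL or MNP")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Classify a ref/alt pair as SNP, INS, DEL or MNP
#'
#' @param ref,alt Reference and alternate allele strings (vectorized).
#' @return Character vector of variant classes.
#' @export
variantClass <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("MNP", length(ref))
  out[nr == 1L & na == 1L & ref != alt] <- "SNP"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  del <- nr > na & substr(ref, 1L, na) == alt
  out[ins] <- "INS"
  out[del] <- "DEL"
  out
}

#' Construct a VariantSet
#'
#' Rows are sorted by position and deduplicated; `vclass` is derived from
#' the alleles.
#'
#' @param referenceId,isolateId Identifiers.
#' @param pos 1-based positions (anchor base for indels).
#' @param ref,alt Allele strings.
#' @param qual Phred-scaled call quality (optional, NA allowed).
#' @param dp Absolute coverage in reads (optional).
#' @param af Relative coverage (fraction of reads supporting the call).
#' @return A [VariantSet-class].
#' @export
VariantSet <- function(referenceId, isolateId, pos = integer(),
                       ref = character(), alt = character(),
                       qual = NA_real_, dp = NA_real_, af = NA_real_) {
  n <- length(pos)
  v <- data.frame(
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    qual = as.numeric(rep_len(qual, n)),
    dp = as.numeric(rep_len(dp, n)),
    af = as.numeric(rep_len(af, n)),
    stringsAsFactors = FALSE
  )
  if (n) {
    v$vclass <- variantClass(v$ref, v$alt)
    v <- v[order(v$pos, v$ref, v$alt), , drop = FALSE]
    v <- v[!duplicated(paste(v$pos, v$ref, v$alt)), , drop = FALSE]
    rownames(v) <- NULL
  } else {
    v$vclass <- character(0)
  }
  v <- v[, c("pos", "ref", "alt", "vclass", "qual", "dp", "af")]
  new("VariantSet", referenceId = referenceId, isolateId = isolateId,
      variants = v)
}

.vsFromDf <- function(referenceId, isolateId, df) {
  VariantSet(referenceId, isolateId,
             pos = df$pos, ref = df$ref, alt = df$alt,
             qual = if ("qual" %in% names(df)) df$qual else NA_real_,
             dp = if ("dp" %in% names(df)) df$dp else NA_real_,
             af = if ("af" %in% names(df)) df$af else NA_real_)
}

#' @describeIn VariantSet Variant table (data.frame).
#' @param x,object A `VariantSet`.
#' @export
variants <- function(x) x@variants

#' @describeIn VariantSet Query isolate id.
#' @export
isolateId <- function(x) x@isolateId

#' @describeIn VariantSet Reference genome id.
#' @export
referenceId <- function(x) x@referenceId

setMethod("length", "VariantSet", function(x) nrow(x@variants))

setMethod("show", "VariantSet", function(object) {
  v <- object@variants
  cat("VariantSet:", object@isolateId, "vs", object@referenceId, "\n")
  cat(" ", nrow(v), "variants (",
      sum(v$vclass == "SNP"), "SNP,",
      sum(v$vclass %in% c("INS", "DEL")), "indel,",
      sum(v$vclass == "MNP"), "MNP )\n")
})

#' MutatorRegime: class-biased mutation process parameters
#'
#' Weights over the six strand-collapsed substitution classes, the
#' fraction of events that are indels, and the probability that an indel
#' is a +/-1 bp slippage event inside a homopolymer run (>= 3 bp).
#'
#' @slot name Regime name.
#' @slot classWeights Named numeric of length 6 over the classes
#'   `A:T>G:C`, `G:C>A:T`, `A:T>C:G`, `A:T>T:A`, `G:C>T:A`, `G:C>C:G`.
#' @slot indelFraction Fraction of mutations that are indels, in [0, 1).
#' @slot indelHomopolymerBias Probability an indel is placed in a
#'   homopolymer run.
#'
#' @exportClass MutatorRegime
setClass("MutatorRegime",
  representation(
    name = "character",
    classWeights = "numeric",
    indelFraction = "numeric",
    indelHomopolymerBias = "numeric"
  )
)

SUBSTITUTION_CLASSES <- c("A:T>G:C", "G:C>A:T", "A:T>C:G",
                          "A:T>T:A", "G:C>T:A", "G:C>C:G")

setValidity("MutatorRegime", function(object) {
  msg <- character()
  w <- object@classWeights
  if (length(w) != 6L || !identical(names(w), SUBSTITUTION_CLASSES)) {
    msg <- c(msg, "classWeights must be named with the 6 substitution classes")
  }
  if (any(w < 0) || sum(w) <= 0) msg <- c(msg, "classWeights must be nonnegative and normalizable")
  f <- object@indelFraction
  if (f < 0 || f >= 1) msg <- c(msg, "indelFraction must be in [0, 1)")
  b <- object@indelHomopolymerBias
  if (b < 0 || b > 1) msg <- c(msg, "indelHomopolymerBias must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a mutator regime
#'
#' @param classWeights Nonnegative weights over the 6 substitution classes
#'   (named; order `A:T>G:C`, `G:C>A:T`, `A:T>C:G`, `A:T>T:A`, `G:C>T:A`,
#'   `G:C>C:G`); they are normalized to sum to 1.
#' @param indelFraction Fraction of mutations that are indels.
#' @param indelHomopolymerBias Probability an indel is a +/-1 bp event in a
#'   homopolymer run of length >= 3.
#' @param name Regime name.
#' @return A [MutatorRegime-class].
#' @seealso [regimePreset()] for the MMR / MutT / oxidative / wildtype presets.
#' @export
mutatorRegime <- function(classWeights, indelFraction = 0.1,
                          indelHomopolymerBias = 0.5, name = "custom") {
  if (is.null(names(classWeights))) names(classWeights) <- SUBSTITUTION_CLASSES
  classWeights <- classWeights[SUBSTITUTION_CLASSES]
  classWeights <- classWeights / sum(classWeights)
  new("MutatorRegime", name = name, classWeights = classWeights,
      indelFraction = indelFraction,
      indelHomopolymerBias = indelHomopolymerBias)
}

#' @describeIn MutatorRegime Normalized class weights.
#' @param x,object A `MutatorRegime`.
#' @export
classWeights <- function(x) x@classWeights

#' @describeIn MutatorRegime Indel fraction.
#' @export
indelFraction <- function(x) x@indelFraction

setMethod("show", "MutatorRegime", function(object) {
  cat("MutatorRegime:", object@name, "\n")
  cat("  indel fraction", object@indelFraction,
      "; homopolymer bias", object@indelHomopolymerBias, "\n")
  print(round(object@classWeights, 3))
})

#' SpectrumProfile: six-class substitution spectrum of one variant set
#'
#' Counts of SNPs per strand-collapsed substitution class, plus the
#' number of indels. The six classes pair each substitution with its
#' reverse complement (T>C counts with A>G as `A:T>G:C`, and so on);
#' `A:T>G:C` and `G:C>A:T` are the transitions, the other four classes
#' the transversions.
#'
#' @slot isolateId Isolate label.
#' @slot counts Named integer vector over the 6 classes.
#' @slot nIndel Number of insertion/deletion events (any length counts once).
#'
#' @exportClass SpectrumProfile
setClass("SpectrumProfile",
  representation(
    isolateId = "character",
    counts = "numeric",
    nIndel = "numeric"
  )
)

setValidity("SpectrumProfile", function(object) {
  if (!identical(names(object@counts), SUBSTITUTION_CLASSES)) {
    return("counts must be named with the 6 substitution classes")
  }
  if (any(object@counts < 0) || object@nIndel < 0) {
    return("counts must be nonnegative")
  }
  TRUE
})

#' @describeIn SpectrumProfile Per-class SNP counts.
#' @param x,object A `SpectrumProfile`.
#' @export
spectrumCounts <- function(x) x@counts

#' @describeIn SpectrumProfile Total SNP count.
#' @export
nSnp <- function(x) sum(x@counts)

#' @describeIn SpectrumProfile Indel count.
#' @export
nIndel <- function(x) x@nIndel

setMethod("show", "SpectrumProfile", function(object) {
  cat("SpectrumProfile:", object@isolateId, "-",
      sum(object@counts), "SNPs,", object@nIndel, "indels\n")
  print(object@counts)
})

#' CgScheme: an ad hoc core-genome MLST scheme
#'
#' The scheme holds one target per retained CDS of the reference genome:
#' its coordinates, strand and coding-strand reference allele sequence
#' (allele id 1). Alleles of query genomes are compared as complete CDS
#' sequences; each distinct sequence per target receives the next
#' integer id in order of first observation.
#'
#' @slot referenceId Reference genome id.
#' @slot referenceSeq Reference genome sequence (needed to anchor queries).
#' @slot targets data.frame with columns gene_id, start, end, strand, sequence.
#'
#' @exportClass CgScheme
setClass("CgScheme",
  representation(
    referenceId = "character",
    referenceSeq = "character",
    targets = "data.frame"
  )
)

setValidity("CgScheme", function(object) {
  t <- object@targets
  need <- c("gene_id", "start", "end", "strand", "sequence")
  if (!all(need %in% colnames(t))) {
    return(paste("targets must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(t$gene_id)) return("target gene_ids must be unique")
  TRUE
})

#' @describeIn CgScheme Target table.
#' @param x,object A `CgScheme`.
#' @export
schemeTargets <- function(x) x@targets

setMethod("length", "CgScheme", function(x) nrow(x@targets))

setMethod("show", "CgScheme", function(object) {
  cat("CgScheme on", object@referenceId, ":",
      nrow(object@targets), "targets\n")
})

#' KaKsResult: observed-versus-expected Ka/Ks of one isolate
#'
#' Observed nonsynonymous and synonymous SNP counts in CDS, expected
#' weights from exhaustive coding-site enumeration under the isolate's
#' transition/transversion composition, and the ratio
#' `(na_obs/ns_obs) / (na_exp/ns_exp)`. Nonsense changes are excluded on
#' both sides. The ratio is `NA` (undefined) when no synonymous change
#' was observed.
#'
#' @slot isolateId Isolate label.
#' @slot naObs,nsObs Observed missense / synonymous counts.
#' @slot naExp,nsExp Expected missense / synonymous weights.
#' @slot ratio The Ka/Ks ratio, or NA when undefined.
#' @slot nExcludedNonsense Observed nonsense SNPs excluded from the counts.
#' @slot tsFraction Transition fraction used for the expectation.
#' @slot note Free-text status ("ok" or reason the ratio is undefined).
#'
#' @exportClass KaKsResult
setClass("KaKsResult",
  representation(
    isolateId = "character",
    naObs = "numeric", nsObs = "numeric",
    naExp = "numeric", nsExp = "numeric",
    ratio = "numeric",
    nExcludedNonsense = "numeric",
    tsFraction = "numeric",
    note = "character"
  )
)

setMethod("show", "KaKsResult", function(object) {
  cat("KaKsResult:", object@isolateId, "\n")
  cat("  observed  Na =", object@naObs, " Ns =", object@nsObs,
      " (", object@nExcludedNonsense, "nonsense excluded )\n")
  cat("  expected  Na =", round(object@naExp, 2),
      " Ns =", round(object@nsExp, 2),
      " at transition fraction", round(object@tsFraction, 3), "\n")
  if (is.na(object@ratio)) {
    cat("  Ka/Ks: undefined (", object@note, ")\n")
  } else {
    cat("  Ka/Ks =", round(object@ratio, 3), "\n")
  }
})

#' @describeIn KaKsResult The Ka/Ks ratio (NA when undefined).
#' @param x,object A `KaKsResult`.
#' @export
kaksRatio <- function(x) x@ratio
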