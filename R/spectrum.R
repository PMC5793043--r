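# Six-class mutational spectra, indel/SNP ratios, mutator-signature
# inference and the spatial-uniformity (hotspot) scan.

#' Classify a substitution into the six strand-collapsed classes
#'
#' Each substitution is collapsed with its reverse complement (T>C
#' counts with A>G as `A:T>G:C`, and so on), giving the classes
#' `A:T>G:C` and `G:C>A:T` (transitions) and `A:T>C:G`, `A:T>T:A`,
#' `G:C>T:A`, `G:C>C:G` (transversions).
#'
#' @param ref,alt Single reference/alternate bases (vectorized), ACGT,
#'   `ref != alt`.
#' @return Character vector of class labels.
#' @export
classifySubstitution <- function(ref, alt) {
  stopifnot(all(ref %in% DNA_BASES), all(alt %in% DNA_BASES), all(ref != alt))
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, complementBase(ref), ref)
  a <- ifelse(flip, complementBase(alt), alt)
  key <- paste0(r, a)
  map <- c(AG = "A:T>G:C", GA = "G:C>A:T", AC = "A:T>C:G",
           AT = "A:T>T:A", GT = "G:C>T:A", GC = "G:C>C:G")
  unname(map[key])
}

# Split MNP rows into per-base SNP rows (differing positions only).
.splitMnps <- function(v) {
  mnp <- which(v$vclass == "MNP" & nchar(v$ref) == nchar(v$alt))
  if (!length(mnp)) return(v[v$vclass == "SNP", , drop = FALSE])
  extra <- lapply(mnp, function(i) {
    rb <- strsplit(v$ref[i], "")[[1]]
    ab <- strsplit(v$alt[i], "")[[1]]
    d <- which(rb != ab)
    data.frame(pos = v$pos[i] + d - 1L, ref = rb[d], alt = ab[d],
               vclass = "SNP", qual = v$qual[i], dp = v$dp[i], af = v$af[i])
  })
  rbind(v[v$vclass == "SNP", , drop = FALSE], do.call(rbind, extra))
}

#' Compute the mutational spectrum of a variant set
#'
#' Tabulates SNPs into the six substitution classes (MNPs are first
#' split into their component SNPs) and counts indels; indels of any
#' length count once.
#'
#' @param vs A normalized [VariantSet-class].
#' @return A [SpectrumProfile-class].
#' @export
computeSpectrum <- function(vs) {
  v <- variants(vs)
  snps <- .splitMnps(v)
  counts <- stats::setNames(numeric(6), SUBSTITUTION_CLASSES)
  if (nrow(snps)) {
    cl <- classifySubstitution(snps$ref, snps$alt)
    tb <- table(factor(cl, levels = SUBSTITUTION_CLASSES))
    counts[] <- as.numeric(tb)
  }
  nInd <- sum(v$vclass %in% c("INS", "DEL"))
  new("SpectrumProfile", isolateId = isolateId(vs), counts = counts,
      nIndel = as.numeric(nInd))
}

#' Indel/SNP ratio of a spectrum
#'
#' @param profile A [SpectrumProfile-class].
#' @return `n_indel / n_snp`, or `NA` (undefined) when the profile has
#'   no SNPs — the "only indels" isolate case.
#' @export
indelSnpRatio <- function(profile) {
  ns <- nSnp(profile)
  if (ns == 0) return(NA_real_)
  nIndel(profile) / ns
}

#' Signature inference configuration
#'
#' @param minEvents Minimum SNPs+indels for a call.
#' @param rMmr Indel/SNP ratio threshold for the MMR flag.
#' @param fTs Transition-fraction threshold for the MMR flag.
#' @param fMutT `A:T>C:G`-fraction threshold for the MutT-like flag.
#' @param fOx `G:C>T:A`-fraction threshold for the oxidative flag.
#' @param alpha One-sided binomial evidence level required against the
#'   null spectrum.
#' @param nullSpectrum Null class probabilities (default uniform over
#'   the 6 classes).
#' @return A named list.
#' @export
signatureConfig <- function(minEvents = 30, rMmr = 0.2, fTs = 0.4,
                            fMutT = 0.15, fOx = 0.15, alpha = 0.001,
                            nullSpectrum = rep(1 / 6, 6)) {
  nullSpectrum <- stats::setNames(nullSpectrum / sum(nullSpectrum),
                                  SUBSTITUTION_CLASSES)
  list(minEvents = minEvents, rMmr = rMmr, fTs = fTs, fMutT = fMutT,
       fOx = fOx, alpha = alpha, nullSpectrum = nullSpectrum)
}

#' Infer mutator signatures from a spectrum
#'
#' Flags the canonical hypermutator signatures: `MMR` (mismatch-repair
#' loss: elevated indel/SNP ratio together with transition dominance),
#' `MutT_like` (oxidized-guanine sanitation loss: `A:T>C:G`
#' transversion excess) and `oxidative_GT` (`G:C>T:A` excess). Each
#' fractional rule is backed by a one-sided binomial test against the
#' configurable null spectrum; a flag requires both the fraction
#' threshold and evidence at `alpha`.
#'
#' @param profile A [SpectrumProfile-class].
#' @param config A [signatureConfig()] list.
#' @return list with `flags` (character subset of the three signatures),
#'   `evidence` (per-signature statistic, threshold and p-value) and
#'   `status` (`"ok"` or `"insufficient data"`).
#' @export
inferMutatorSignatures <- function(profile, config = signatureConfig()) {
  ns <- nSnp(profile); ni <- nIndel(profile)
  evidence <- data.frame(
    signature = c("MMR", "MutT_like", "oxidative_GT"),
    statistic = NA_real_, threshold = NA_real_, p_value = NA_real_,
    flagged = FALSE
  )
  if (ns + ni < config$minEvents) {
    return(list(flags = character(0), evidence = evidence,
                status = "insufficient data"))
  }
  cts <- spectrumCounts(profile)
  null <- config$nullSpectrum
  binP <- function(x, p0) {
    if (ns == 0) return(1)
    stats::binom.test(round(x), ns, p0, alternative = "greater")$p.value
  }
  ratio <- if (ns > 0) ni / ns else Inf
  tsCount <- cts[["A:T>G:C"]] + cts[["G:C>A:T"]]
  tsFrac <- if (ns > 0) tsCount / ns else 0
  pTs <- binP(tsCount, null[["A:T>G:C"]] + null[["G:C>A:T"]])
  mmr <- ratio >= config$rMmr && tsFrac >= config$fTs && pTs < config$alpha

  mtFrac <- if (ns > 0) cts[["A:T>C:G"]] / ns else 0
  pMt <- binP(cts[["A:T>C:G"]], null[["A:T>C:G"]])
  mutt <- mtFrac >= config$fMutT && pMt < config$alpha

  oxFrac <- if (ns > 0) cts[["G:C>T:A"]] / ns else 0
  pOx <- binP(cts[["G:C>T:A"]], null[["G:C>T:A"]])
  ox <- oxFrac >= config$fOx && pOx < config$alpha

  evidence$statistic <- c(tsFrac, mtFrac, oxFrac)
  evidence$threshold <- c(config$fTs, config$fMutT, config$fOx)
  evidence$p_value <- c(pTs, pMt, pOx)
  evidence$flagged <- c(mmr, mutt, ox)
  flags <- evidence$signature[evidence$flagged]
  list(flags = flags, evidence = evidence, status = "ok")
}

#' Scan the physical distribution of variants for hotspots
#'
#' Bins variant positions into fixed windows and tests the counts
#' against the uniform expectation with a chi-square goodness-of-fit
#' test; adjacent windows are pooled until every expectation is at
#' least 1. A spatially random mutation process gives a high p-value;
#' a genuine hotspot drives it to zero.
#'
#' @param vs A [VariantSet-class] with at least one variant.
#' @param genomeLength Reference length in bp.
#' @param windowBp Window size (default 10 kb).
#' @return list with `windows` (data.frame start, end, count, expected,
#'   1-based inclusive; use [writeWindowsBed()] for 0-based half-open
#'   export), `p_value`, `max_window` (row index of the fullest window).
#' @export
hotspotScan <- function(vs, genomeLength, windowBp = 10000L) {
  v <- variants(vs)
  if (!nrow(v)) stop("hotspotScan needs at least one variant")
  starts <- seq.int(1L, genomeLength, by = windowBp)
  ends <- pmin(starts + windowBp - 1L, genomeLength)
  counts <- tabulate(findInterval(v$pos, starts), nbins = length(starts))
  widths <- ends - starts + 1L
  n <- nrow(v)
  expected <- n * widths / genomeLength
  win <- data.frame(start = starts, end = ends, count = counts,
                    expected = expected)
  if (n < 2L) {
    return(list(windows = win, p_value = 1,
                max_window = which.max(counts)[1]))
  }
  # pool adjacent windows until every expected count is >= 1
  pc <- counts; pw <- as.numeric(widths)
  while (length(pc) > 1L && any(n * pw / sum(pw) < 1)) {
    i <- which.min(pw)[1]
    j <- if (i == length(pw)) i - 1L else i + 1L
    pc[j] <- pc[j] + pc[i]; pw[j] <- pw[j] + pw[i]
    pc <- pc[-i]; pw <- pw[-i]
  }
  p <- if (length(pc) < 2L) 1 else {
    suppressWarnings(stats::chisq.test(pc, p = pw / sum(pw))$p.value)
  }
  list(windows = win, p_value = p, max_window = which.max(counts)[1])
}

#' Write per-window counts as BED
#'
#' Exports the [hotspotScan()] window track with BED's 0-based
#' half-open coordinates.
#'
#' @param windows The `windows` data.frame from [hotspotScan()].
#' @param chrom Chromosome name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeWindowsBed <- function(windows, chrom, path) {
  writeLines(paste(chrom, windows$start - 1L, windows$end,
                   windows$count, sep = "\t"), path)
  invisible(path)
}
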