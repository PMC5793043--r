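# Observed-versus-expected Ka/Ks by exhaustive coding-site enumeration.
#
# The expectation enumerates every coding site and each of its three
# alternative bases, weighting the single transition by the isolate's
# transition fraction and the two transversions by (1 - ts)/2 each;
# weights accumulate into missense (Ka) and synonymous (Ks)
# expectations. Nonsense and stop-loss alternatives are excluded from
# both sums, terminal stop codons from the enumeration, and observed
# nonsense SNPs from the observed counts — so a mutation process with
# no selection gives a ratio of 1.

#' Expected missense/synonymous weights by full site enumeration
#'
#' @param genome Annotated [AnnotatedGenome-class] with at least one CDS.
#' @param tsFraction Transition fraction in (0, 1); 1/3 gives uniform
#'   per-alternative weights.
#' @param sixClass If `TRUE`, weight alternatives by a six-class spectrum
#'   instead of the two-class transition/transversion split.
#' @param classWeightsSpectrum Named weights over the six substitution
#'   classes (used when `sixClass`).
#' @return list with `naExp`, `nsExp`, `excluded` (nonsense/stop-loss
#'   weight) and `nSites`.
#' @export
expectedEffectWeights <- function(genome, tsFraction, sixClass = FALSE,
                                  classWeightsSpectrum = NULL) {
  cmap <- codingMap(genome, dropTerminalStop = TRUE)
  if (!nrow(cmap)) stop("genome has no CDS to enumerate")
  n <- nrow(cmap)
  refC <- cmap$refCoding
  aaRef <- .aaOfCodon(cmap$codon)
  naExp <- 0; nsExp <- 0; excl <- 0
  for (altBase in DNA_BASES) {
    sel <- refC != altBase
    if (!any(sel)) next
    altCodon <- cmap$codon[sel]
    substr(altCodon, cmap$posInCodon[sel], cmap$posInCodon[sel]) <- altBase
    aaAlt <- .aaOfCodon(altCodon)
    if (sixClass) {
      if (is.null(classWeightsSpectrum)) {
        stop("sixClass mode needs classWeightsSpectrum")
      }
      wSpec <- classWeightsSpectrum[SUBSTITUTION_CLASSES]
      wSpec <- wSpec / sum(wSpec)
      cl <- classifySubstitution(refC[sel], rep(altBase, sum(sel)))
      # per site, normalize over the 3 alternatives of that reference base
      pairTotal <- ifelse(refC[sel] %in% c("A", "T"),
                          sum(wSpec[c("A:T>G:C", "A:T>C:G", "A:T>T:A")]),
                          sum(wSpec[c("G:C>A:T", "G:C>T:A", "G:C>C:G")]))
      w <- as.numeric(wSpec[cl]) / pairTotal
    } else {
      ts <- isTransitionVec(refC[sel], rep(altBase, sum(sel)))
      w <- ifelse(ts, tsFraction, (1 - tsFraction) / 2)
    }
    syn <- aaAlt == aaRef[sel]
    non <- aaAlt == "*" & aaRef[sel] != "*"
    sloss <- aaRef[sel] == "*" & aaAlt != "*"
    mis <- !syn & !non & !sloss
    naExp <- naExp + sum(w[mis])
    nsExp <- nsExp + sum(w[syn])
    excl <- excl + sum(w[non | sloss])
  }
  list(naExp = naExp, nsExp = nsExp, excluded = excl, nSites = n)
}

#' Observed missense/synonymous counts from annotated SNPs
#'
#' Counts coding SNP consequences: missense and synonymous tallied,
#' nonsense tallied separately and excluded, everything else (indels,
#' intergenic) ignored.
#'
#' @param annotation data.frame from [annotateVariants()].
#' @return list with `naObs`, `nsObs`, `nNonsense`.
#' @export
observedEffectCounts <- function(annotation) {
  snp <- annotation[annotation$vclass == "SNP", , drop = FALSE]
  list(naObs = sum(snp$kind == "missense"),
       nsObs = sum(snp$kind == "synonymous"),
       nNonsense = sum(snp$kind == "nonsense"))
}

#' Ka/Ks of an isolate's variant set
#'
#' Estimates the transition fraction from all of the isolate's SNPs
#' (coding and intergenic), computes the expected missense/synonymous
#' weights by full site enumeration at that fraction, counts the
#' observed coding consequences, and returns
#' `(na_obs/ns_obs) / (na_exp/ns_exp)`. A ratio near 1 indicates
#' neutral evolution. Isolates without synonymous SNPs (e.g. an
#' indel-only call set) give an undefined ratio.
#'
#' @param genome Annotated reference [AnnotatedGenome-class].
#' @param vs The isolate's normalized [VariantSet-class].
#' @param sixClass Use the six-class spectrum weighting (sensitivity
#'   analysis mode) instead of the transition/transversion split.
#' @return A [KaKsResult-class].
#' @export
kaks <- function(genome, vs, sixClass = FALSE) {
  v <- .splitMnps(variants(vs))
  iso <- isolateId(vs)
  if (!nrow(v)) {
    return(new("KaKsResult", isolateId = iso, naObs = 0, nsObs = 0,
               naExp = NA_real_, nsExp = NA_real_, ratio = NA_real_,
               nExcludedNonsense = 0, tsFraction = NA_real_,
               note = "no SNPs observed"))
  }
  tsFrac <- mean(isTransitionVec(v$ref, v$alt))
  ann <- annotateVariants(vs, genome)
  obs <- observedEffectCounts(ann)
  spec <- NULL
  if (sixClass) {
    pr <- computeSpectrum(vs)
    spec <- spectrumCounts(pr)
    if (sum(spec) == 0) spec <- rep(1, 6)
  }
  expw <- expectedEffectWeights(genome, tsFrac, sixClass = sixClass,
                                classWeightsSpectrum = spec)
  if (obs$nsObs == 0 || expw$nsExp == 0) {
    return(new("KaKsResult", isolateId = iso,
               naObs = obs$naObs, nsObs = obs$nsObs,
               naExp = expw$naExp, nsExp = expw$nsExp, ratio = NA_real_,
               nExcludedNonsense = obs$nNonsense, tsFraction = tsFrac,
               note = "undefined (no synonymous)"))
  }
  ratio <- (obs$naObs / obs$nsObs) / (expw$naExp / expw$nsExp)
  new("KaKsResult", isolateId = iso,
      naObs = obs$naObs, nsObs = obs$nsObs,
      naExp = expw$naExp, nsExp = expw$nsExp, ratio = ratio,
      nExcludedNonsense = obs$nNonsense, tsFraction = tsFrac, note = "ok")
}

#' One-row TSV summary of a KaKsResult
#'
#' @param res A [KaKsResult-class].
#' @return data.frame with one row.
#' @export
kaksRow <- function(res) {
  data.frame(isolate = res@isolateId, na_obs = res@naObs, ns_obs = res@nsObs,
             na_exp = res@naExp, ns_exp = res@nsExp, ratio = res@ratio,
             n_excluded_nonsense = res@nExcludedNonsense,
             ts_fraction = res@tsFraction, note = res@note)
}
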