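# Antimutator gene-panel screening and the squatter-colony
# convergence filter.

#' Default antimutator / resistance gene panel
#'
#' Role-tagged panel covering methyl-directed mismatch repair,
#' oxidized-guanine sanitation, the SPANC-balance loci, efflux systems
#' and the porin regulators.
#'
#' @return data.frame with columns `gene_id` and `role`.
#' @export
defaultGenePanel <- function() {
  data.frame(
    gene_id = c("mutL", "mutS", "mutH", "dam", "uvrD",
                "mutT", "mutY", "mutM",
                "miaA",
                "rpoS", "ompF",
                "acrB", "acrE", "acrS", "rob",
                "ompR", "envZ", "ompC", "ompA"),
    role = c(rep("MMR", 5), rep("oxidized_guanine", 3), "other",
             rep("SPANC", 2), rep("efflux", 4), rep("regulator", 4)),
    stringsAsFactors = FALSE
  )
}

#' Screen a gene panel for allele differences
#'
#' Calls the query against the reference and reports every change --
#' CDS-altering and synonymous -- falling in a panel gene, with
#' protein-level naming from [annotateVariants()]. Panel genes are
#' matched by `gene_id` in the reference annotation; ids absent from
#' the annotation are ignored.
#'
#' @param reference Annotated [AnnotatedGenome-class].
#' @param query Query [AnnotatedGenome-class], or a precomputed
#'   [VariantSet-class] versus the reference.
#' @param panel data.frame with columns gene_id, role (see
#'   [defaultGenePanel()]).
#' @param proteinOffsets Passed to [annotateVariants()].
#' @return data.frame of per-gene changes (columns of
#'   [annotateVariants()] plus `role`).
#' @export
screenGenePanel <- function(reference, query, panel = defaultGenePanel(),
                            proteinOffsets = NULL) {
  vs <- if (is(query, "VariantSet")) query else {
    callVariantsCollinear(reference, query)
  }
  ann <- annotateVariants(vs, reference, proteinOffsets = proteinOffsets)
  hit <- ann[!is.na(ann$gene_id) & ann$gene_id %in% panel$gene_id, ,
             drop = FALSE]
  hit$role <- panel$role[match(hit$gene_id, panel$gene_id)]
  rownames(hit) <- NULL
  hit
}

#' Squatter-specific candidate resistance variants
#'
#' The squatter filter: variants present in the squatter but absent
#' from its parental isolate (set difference on normalized
#' (pos, ref, alt) keys — left-aligned indels in repeats compare
#' equal), retaining only indels overlapping a CDS and SNPs annotated
#' missense or nonsense. Synonymous and intergenic changes never pass.
#'
#' @param parent Parental [VariantSet-class] versus the reference, or an
#'   [AnnotatedGenome-class] to be called against it.
#' @param squatter Squatter [VariantSet-class] or [AnnotatedGenome-class].
#' @param reference Annotated reference [AnnotatedGenome-class].
#' @return The filtered [VariantSet-class], with the annotation table in
#'   attribute `annotation`.
#' @export
squatterSpecificVariants <- function(parent, squatter, reference) {
  toSet <- function(x) {
    if (is(x, "VariantSet")) normalizeVariants(x, reference)
    else callVariantsCollinear(reference, x)
  }
  pv <- toSet(parent)
  sv <- toSet(squatter)
  vp <- variants(pv); vsq <- variants(sv)
  keyP <- paste(vp$pos, vp$ref, vp$alt)
  keyS <- paste(vsq$pos, vsq$ref, vsq$alt)
  only <- vsq[!(keyS %in% keyP), , drop = FALSE]
  cand <- .vsFromDf(referenceId(sv), isolateId(sv), only)
  ann <- annotateVariants(cand, reference)
  keep <- (ann$vclass %in% c("INS", "DEL") & ann$kind != "intergenic") |
    (ann$vclass %in% c("SNP", "MNP") & ann$kind %in% c("missense", "nonsense"))
  annKeep <- ann[keep, , drop = FALSE]
  keyA <- unique(paste(annKeep$pos, annKeep$ref, annKeep$alt))
  outDf <- only[paste(only$pos, only$ref, only$alt) %in% keyA, , drop = FALSE]
  out <- .vsFromDf(referenceId(sv), isolateId(sv), outDf)
  attr(out, "annotation") <- annKeep
  out
}

#' Convergently mutated genes across squatter isolates
#'
#' Counts, per gene, how many squatter isolates carry at least one
#' qualifying (filtered) change, and reports the genes hit in at least
#' `minHits` isolates. The default threshold of n-1 generalizes an
#' "all or nearly all" convergence rule.
#'
#' @param filteredSets Named list of [squatterSpecificVariants()] outputs
#'   (>= 2 sets).
#' @param minHits Minimum number of isolates hit (default
#'   `length(filteredSets) - 1`).
#' @return list with `report` (data.frame gene_id, hits, n_total for
#'   genes reaching the threshold, sorted by hits) and `evidence`
#'   (per-gene, per-isolate change tables for all genes hit at least
#'   once).
#' @export
convergenceGenes <- function(filteredSets, minHits = NULL) {
  n <- length(filteredSets)
  if (n < 2L) stop("need at least two squatter sets")
  if (is.null(minHits)) minHits <- n - 1L
  if (is.null(names(filteredSets))) {
    names(filteredSets) <- vapply(filteredSets, isolateId, character(1))
  }
  perIso <- lapply(names(filteredSets), function(nm) {
    ann <- attr(filteredSets[[nm]], "annotation")
    if (is.null(ann) || !nrow(ann)) return(NULL)
    ann$isolate <- nm
    ann
  })
  allAnn <- do.call(rbind, perIso[!vapply(perIso, is.null, logical(1))])
  if (is.null(allAnn) || !nrow(allAnn)) {
    return(list(report = data.frame(gene_id = character(), hits = integer(),
                                    n_total = integer()),
                evidence = list()))
  }
  hitTab <- unique(allAnn[, c("gene_id", "isolate")])
  hits <- table(hitTab$gene_id)
  rep <- data.frame(gene_id = names(hits), hits = as.integer(hits),
                    n_total = n, row.names = NULL)
  rep <- rep[order(-rep$hits, rep$gene_id), , drop = FALSE]
  evidence <- split(allAnn, allAnn$gene_id)
  list(report = rep[rep$hits >= minHits, , drop = FALSE],
       evidence = evidence)
}
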