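# End-to-end orchestration: configuration, the simulate / analyze /
# squatter commands, and plain-text report generation. Logs go to
# stderr; data go to files only.

#' Build a validated run configuration
#'
#' Every default equals the corresponding module-level default. All
#' randomness flows from the single top-level `seed` via per-stage
#' derived streams.
#'
#' @param outDir Output directory.
#' @param seed Top-level integer seed.
#' @param genomeLength,gc,nGenes,meanGeneLen Ancestor parameters.
#' @param planScale Multiplier on the odyssey plan mutation counts.
#' @param thresholds [filterThresholds()] list.
#' @param signature [signatureConfig()] list.
#' @param schemeMinLen,schemeMaxParalogIdentity [buildScheme()] parameters.
#' @param convergenceMinHits Convergence threshold (NULL = n - 1).
#' @param hotspotWindowBp Window for [hotspotScan()].
#' @return A validated config list (class `mutatorscanConfig`).
#' @export
runConfig <- function(outDir = "mutatorscan-out", seed = 1,
                      genomeLength = 120000L, gc = 0.5, nGenes = 100L,
                      meanGeneLen = 900L, planScale = 1,
                      thresholds = filterThresholds(),
                      signature = signatureConfig(),
                      schemeMinLen = 120L, schemeMaxParalogIdentity = 0.9,
                      convergenceMinHits = NULL,
                      hotspotWindowBp = 10000L) {
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              genomeLength = as.integer(genomeLength), gc = gc,
              nGenes = as.integer(nGenes),
              meanGeneLen = as.integer(meanGeneLen), planScale = planScale,
              thresholds = thresholds, signature = signature,
              schemeMinLen = as.integer(schemeMinLen),
              schemeMaxParalogIdentity = schemeMaxParalogIdentity,
              convergenceMinHits = convergenceMinHits,
              hotspotWindowBp = as.integer(hotspotWindowBp))
  validateConfig(cfg)
  class(cfg) <- "mutatorscanConfig"
  cfg
}

#' Validate a run configuration
#'
#' @param cfg A config list.
#' @return `TRUE` invisibly; stops with a message on invalid values.
#' @export
validateConfig <- function(cfg) {
  stopifnot(is.character(cfg$outDir), length(cfg$outDir) == 1L)
  if (!isWholeNumber(cfg$seed)) stop("seed must be a whole number")
  if (!isWholeNumber(cfg$genomeLength) || cfg$genomeLength < 10000) {
    stop("genomeLength must be an integer >= 10000")
  }
  if (cfg$gc <= 0.05 || cfg$gc >= 0.95) stop("gc must be in (0.05, 0.95)")
  if (!isWholeNumber(cfg$nGenes) || cfg$nGenes < 1) stop("nGenes must be >= 1")
  if (cfg$planScale <= 0) stop("planScale must be positive")
  th <- cfg$thresholds
  if (!all(c("minRelCoverage", "minAbsCoverage", "minQuality") %in% names(th)) ||
      any(unlist(th[1:3]) < 0)) {
    stop("invalid filter thresholds")
  }
  sg <- cfg$signature
  if (sg$alpha <= 0 || sg$alpha >= 1) stop("signature alpha must be in (0,1)")
  if (!is.null(cfg$convergenceMinHits) &&
      !isWholeNumber(cfg$convergenceMinHits)) {
    stop("convergenceMinHits must be a whole number or NULL")
  }
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented
#' defaults.
#'
#' @param path YAML file.
#' @return A validated config (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$thresholds)) y$thresholds <- do.call(filterThresholds, y$thresholds)
  if (!is.null(y$signature)) y$signature <- do.call(signatureConfig, y$signature)
  do.call(runConfig, y)
}

.log <- function(...) message("[mutatorscan] ", ...)

.writeHeaderTsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# mutatorscan ",
                      as.character(utils::packageVersion("mutatorscan"))),
               paste0("# seed=", cfg$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate the collection odyssey
#'
#' Generates the ancestral genome, evolves the odyssey-plan isolates,
#' and writes the ancestor FASTA + GFF3, per-isolate FASTA, truth VCFs
#' and the plan as a tab-separated file. Identical configs produce
#' byte-identical outputs.
#'
#' @param cfg A [runConfig()] configuration.
#' @return Invisibly, the [simulateCollectionHistory()] result.
#' @export
cmdSimulate <- function(cfg) {
  validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .log("generating ancestor (", cfg$genomeLength, " bp, ", cfg$nGenes,
       " genes)")
  anc <- generateAncestor(cfg$genomeLength, cfg$gc, cfg$nGenes,
                          cfg$meanGeneLen, seed = childSeed(cfg$seed, 0L))
  plan <- odysseyPlan(scale = cfg$planScale)
  .log("evolving ", nrow(plan), " edges")
  sim <- simulateCollectionHistory(anc, plan, seed = cfg$seed)
  writeGenomeFasta(anc, file.path(cfg$outDir, "ancestor.fasta"))
  writeCdsAnnotation(anc, file.path(cfg$outDir, "ancestor.gff3"))
  for (nm in names(sim$genomes)) {
    if (nm == plan$parent[1]) next
    writeGenomeFasta(sim$genomes[[nm]],
                     file.path(cfg$outDir, paste0(nm, ".fasta")))
    writeVariantVcf(sim$truth[[nm]],
                    file.path(cfg$outDir, paste0(nm, ".truth.vcf")),
                    contigLength = cfg$genomeLength)
  }
  utils::write.table(plan, file.path(cfg$outDir, "plan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .log("simulation written to ", cfg$outDir)
  invisible(sim)
}

#' Run the full comparative analysis
#'
#' Re-simulates (or reuses) the odyssey isolates and emits the complete
#' report bundle: per-isolate call VCFs, the six-class spectrum table
#' with indel/SNP ratios and signature flags, the Ka/Ks table, allelic
#' and SNP presence/absence distance matrices with their UPGMA /
#' average-linkage Manhattan trees (Newick), the concatenated SNP
#' alignment (FASTA + PHYLIP), per-window hotspot tracks, and the
#' antimutator panel screen.
#'
#' @param cfg A [runConfig()] configuration.
#' @param sim Optional result of [cmdSimulate()] to reuse.
#' @return Invisibly, a list of the in-memory results.
#' @export
cmdAnalyze <- function(cfg, sim = NULL) {
  validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sim)) sim <- cmdSimulate(cfg)
  anc <- sim$genomes[[sim$plan$parent[1]]]
  isolates <- setdiff(names(sim$genomes), genomeId(anc))
  rootLab <- sim$plan$parent[1]
  isolates <- setdiff(names(sim$genomes), rootLab)

  .log("calling variants for ", length(isolates), " isolates")
  calls <- lapply(isolates, function(nm) {
    vs <- callVariantsCollinear(anc, sim$genomes[[nm]])
    vs <- suppressWarnings(filterVariants(vs, cfg$thresholds))
    writeVariantVcf(vs, file.path(cfg$outDir, paste0(nm, ".calls.vcf")),
                    annotation = annotateVariants(vs, anc),
                    contigLength = genomeLength(anc))
    vs
  })
  names(calls) <- isolates

  .log("spectra and signatures")
  spectra <- lapply(calls, computeSpectrum)
  specTab <- do.call(rbind, lapply(isolates, function(nm) {
    pr <- spectra[[nm]]
    sig <- inferMutatorSignatures(pr, cfg$signature)
    cbind(data.frame(isolate = nm, n_snp = nSnp(pr), n_indel = nIndel(pr),
                     indel_snp_ratio = indelSnpRatio(pr)),
          as.data.frame(t(spectrumCounts(pr))),
          data.frame(signatures = paste(sig$flags, collapse = ",")))
  }))
  .writeHeaderTsv(specTab, file.path(cfg$outDir, "spectrum.tsv"), cfg)

  .log("Ka/Ks")
  kkTab <- do.call(rbind, lapply(isolates, function(nm) {
    kaksRow(kaks(anc, calls[[nm]]))
  }))
  .writeHeaderTsv(kkTab, file.path(cfg$outDir, "kaks.tsv"), cfg)

  .log("cgMLST")
  scheme <- buildScheme(anc, cfg$schemeMinLen, cfg$schemeMaxParalogIdentity)
  queries <- c(stats::setNames(list(anc), rootLab), sim$genomes[isolates])
  prof <- callAlleleProfiles(scheme, queries)
  d <- allelicDistance(prof)
  utils::write.table(d, file.path(cfg$outDir, "allelic_distance.tsv"),
                     sep = "\t", quote = FALSE)
  treeA <- upgmaTree(d)
  ape::write.tree(treeA, file.path(cfg$outDir, "cgmlst_upgma.nwk"))

  bm <- binaryVariantMatrix(c(stats::setNames(
    list(VariantSet(genomeId(anc), rootLab)), rootLab), calls))
  dB <- as.matrix(stats::dist(bm, method = "manhattan"))
  utils::write.table(dB, file.path(cfg$outDir, "snp_indel_distance.tsv"),
                     sep = "\t", quote = FALSE)
  treeB <- averageLinkageManhattan(bm)
  ape::write.tree(treeB, file.path(cfg$outDir, "presence_absence_tree.nwk"))

  exportSnpAlignment(calls, anc,
                     fastaPath = file.path(cfg$outDir, "snp_alignment.fasta"),
                     phylipPath = file.path(cfg$outDir, "snp_alignment.phy"))

  .log("hotspot scan")
  hsTab <- do.call(rbind, lapply(isolates, function(nm) {
    if (!length(calls[[nm]])) return(NULL)
    hs <- hotspotScan(calls[[nm]], genomeLength(anc), cfg$hotspotWindowBp)
    writeWindowsBed(hs$windows, genomeId(anc),
                    file.path(cfg$outDir, paste0(nm, ".windows.bed")))
    data.frame(isolate = nm, p_value = hs$p_value,
               max_window_start = hs$windows$start[hs$max_window])
  }))
  .writeHeaderTsv(hsTab, file.path(cfg$outDir, "hotspots.tsv"), cfg)

  .log("gene panel screen")
  panel <- defaultGenePanel()
  scrTab <- do.call(rbind, lapply(isolates, function(nm) {
    hits <- screenGenePanel(anc, calls[[nm]], panel)
    if (!nrow(hits)) return(NULL)
    cbind(isolate = nm, hits)
  }))
  if (is.null(scrTab)) {
    scrTab <- data.frame(isolate = character(), gene_id = character(),
                         kind = character(), hgvs = character())
  }
  .writeHeaderTsv(scrTab, file.path(cfg$outDir, "panel_screen.tsv"), cfg)

  .log("analysis written to ", cfg$outDir)
  invisible(list(sim = sim, calls = calls, spectra = spectra,
                 spectrum_table = specTab, kaks_table = kkTab,
                 scheme = scheme, profiles = prof,
                 allelic_distance = d, upgma = treeA,
                 binary_matrix = bm, manhattan_tree = treeB,
                 hotspots = hsTab, screen = scrTab))
}

#' Run the squatter-colony convergence analysis
#'
#' Builds six squatter fixtures from one parental isolate (five hit in
#' the same regulator gene, one in its partner sensor gene, each with
#' background synonymous/intergenic noise), applies the
#' squatter-specific variant filter and writes the convergence report.
#'
#' @param cfg A [runConfig()] configuration.
#' @param parent Optional parental [AnnotatedGenome-class]; by default a
#'   fresh ancestor is generated from the config.
#' @return Invisibly, the [convergenceGenes()] result.
#' @export
cmdSquatter <- function(cfg, parent = NULL) {
  validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(parent)) {
    ids <- c("ompR", "envZ", sprintf("gene%03d", seq_len(cfg$nGenes - 2L)))
    parent <- generateAncestor(cfg$genomeLength, cfg$gc, cfg$nGenes,
                               cfg$meanGeneLen,
                               seed = childSeed(cfg$seed, 0L),
                               geneIds = ids)
  }
  targets <- c(rep("ompR", 5), "envZ")
  kinds <- c("missense", "missense", "frameshift", "missense", "missense",
             "missense")
  sets <- lapply(seq_along(targets), function(i) {
    fx <- makeSquatterFixture(parent, targets[i], kinds[i],
                              seed = childSeed(cfg$seed, 100L + i),
                              isolateId = paste0("squatter", i))
    squatterSpecificVariants(VariantSet(genomeId(parent), "parent"),
                             fx$truth, parent)
  })
  names(sets) <- paste0("squatter", seq_along(targets))
  conv <- convergenceGenes(sets, minHits = cfg$convergenceMinHits)
  .writeHeaderTsv(conv$report, file.path(cfg$outDir, "convergence.tsv"), cfg)
  ev <- do.call(rbind, lapply(names(conv$evidence), function(g) {
    conv$evidence[[g]]
  }))
  .writeHeaderTsv(ev, file.path(cfg$outDir, "squatter_variants.tsv"), cfg)
  .log("squatter analysis written to ", cfg$outDir)
  invisible(conv)
}
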