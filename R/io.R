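# Readers and writers for the standard formats (FASTA, GFF3, VCF 4.x).
# All coordinates are 1-based inclusive; files are UTF-8 with LF newlines.

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @return A list of [AnnotatedGenome-class] (features empty), in file order.
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) {
    AnnotatedGenome(ids[i], toupper(as.character(ss[[i]])))
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A single [AnnotatedGenome-class] or a list of them.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path, width = 70L) {
  if (is(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, genomeSeq, character(1)))
  names(ss) <- vapply(genomes, genomeId, character(1))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read CDS annotation (GFF3) onto a genome
#'
#' Only rows of type `CDS` are retained. The gene identifier is taken
#' from the `ID` attribute, falling back to `locus_tag`.
#'
#' @param path GFF3 file.
#' @param genome The [AnnotatedGenome-class] the annotation belongs to.
#' @return The genome with its `features` slot filled.
#' @export
readCdsAnnotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (!length(gr)) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% colnames(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  if ("locus_tag" %in% colnames(mc)) {
    lt <- as.character(mc$locus_tag)
    ids[is.na(ids) | ids == ""] <- lt[is.na(ids) | ids == ""]
  }
  if (anyNA(ids) || any(ids == "")) stop("CDS feature without ID/locus_tag in ", path)
  if (any(GenomicRanges::end(gr) > genomeLength(genome)) ||
      any(GenomicRanges::start(gr) < 1L)) {
    stop("CDS interval outside genome ", genomeId(genome))
  }
  ph <- if ("phase" %in% colnames(mc)) {
    p <- suppressWarnings(as.integer(as.character(mc$phase)))
    ifelse(is.na(p), 0L, p)
  } else rep(0L, length(gr))
  prod <- if ("product" %in% colnames(mc)) as.character(mc$product) else rep("", length(gr))
  prod[is.na(prod)] <- ""
  ft <- cdsGRanges(
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = ph, product = prod, seqname = genomeId(genome)
  )
  AnnotatedGenome(genomeId(genome), genomeSeq(genome),
                  circular = genome@circular, features = ft)
}

#' Write CDS annotation to GFF3
#'
#' @param genome An [AnnotatedGenome-class] with features.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
writeCdsAnnotation <- function(genome, path) {
  ft <- cdsFeatures(genome)
  lines <- c("##gff-version 3",
             paste("##sequence-region", genomeId(genome), 1, genomeLength(genome)))
  if (length(ft)) {
    mc <- S4Vectors::mcols(ft)
    attr <- paste0("ID=", mc$gene_id,
                   ifelse(nzchar(mc$product), paste0(";product=", mc$product), ""))
    rows <- paste(genomeId(genome), "mutatorscan", "CDS",
                  GenomicRanges::start(ft), GenomicRanges::end(ft), ".",
                  as.character(GenomicRanges::strand(ft)), mc$phase, attr,
                  sep = "\t")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF file into a VariantSet
#'
#' Quality is taken from `QUAL`; absolute coverage from INFO key `DP`;
#' relative coverage (fraction of reads supporting the allele) from INFO
#' key `AF`. Multi-allelic rows are split into one variant per ALT.
#'
#' @param path VCF 4.x file (plain text).
#' @param isolateId Isolate label (defaults to the file base name).
#' @param referenceId Reference label (defaults to the CHROM of the first row).
#' @return A [VariantSet-class].
#' @export
readVariantVcf <- function(path, isolateId = NULL, referenceId = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(isolateId)) {
    isolateId <- sub("\\.vcf$", "", basename(path))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    return(VariantSet(referenceId %||% "unknown", isolateId))
  }
  if (is.null(referenceId)) referenceId <- unname(fix[1L, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  altRaw <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
  if (anyNA(pos) || anyNA(ref) || any(ref == "") || anyNA(altRaw)) {
    stop("malformed VCF row in ", path)
  }
  alts <- strsplit(toupper(altRaw), ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_along(pos), nalt)
  VariantSet(referenceId, isolateId,
             pos = pos[idx], ref = ref[idx], alt = unlist(alts),
             qual = qual[idx], dp = dp[idx], af = af[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a VariantSet as VCF 4.2
#'
#' Emits plain-text VCF with INFO keys `DP` (absolute coverage) and `AF`
#' (relative coverage) when present, and optional annotation keys `EFF`
#' (consequence kind), `GENE` and `AACHG` (protein-level change) taken
#' from an [annotateVariants()] table.
#'
#' @param vs A [VariantSet-class].
#' @param path Output file.
#' @param annotation Optional data.frame from [annotateVariants()].
#' @param contigLength Optional reference length for the `##contig` header.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(vs, path, annotation = NULL, contigLength = NULL) {
  v <- variants(vs)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=mutatorscan"),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Absolute coverage">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Relative coverage (supporting-read fraction)">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding consequence kind">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=AACHG,Number=1,Type=String,Description="Protein-level change">'
  )
  if (!is.null(contigLength)) {
    hdr <- c(hdr, paste0("##contig=<ID=", referenceId(vs),
                         ",length=", contigLength, ">"))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- rep("", nrow(v))
  addKV <- function(info, key, val, fmt = "%s") {
    has <- !is.na(val)
    piece <- ifelse(has, paste0(key, "=", sprintf(fmt, val)), "")
    ifelse(has, ifelse(nzchar(info), paste0(info, ";", piece), piece), info)
  }
  if (nrow(v)) {
    info <- addKV(info, "DP", v$dp, "%g")
    info <- addKV(info, "AF", v$af, "%g")
    if (!is.null(annotation) && nrow(annotation)) {
      key <- paste(v$pos, v$ref, v$alt)
      akey <- paste(annotation$pos, annotation$ref, annotation$alt)
      m <- match(key, akey)
      info <- addKV(info, "EFF", annotation$kind[m])
      info <- addKV(info, "GENE", annotation$gene_id[m])
      info <- addKV(info, "AACHG", annotation$hgvs[m])
    }
    info[!nzchar(info)] <- "."
  }
  rows <- if (nrow(v)) {
    paste(referenceId(vs), v$pos, ".", v$ref, v$alt,
          ifelse(is.na(v$qual), ".", sprintf("%g", v$qual)), "PASS", info,
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
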