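#' Transcript start site of annotated genes
#'
#' The TSS anchors the cis/distal windows. For "+" or unknown strand the
#' TSS is the interval's first base; for "-" strand it is the last base of
#' the half-open BED interval. Positions are reported 0-based, matching the
#' BED input coordinates.
#'
#' @param gr a named [GenomicRanges::GRanges] from [readBedAnnotation()].
#' @return data.frame with columns `chrom` and `pos` (0-based), rownames =
#'   locus names.
#' @export
tssOf <- function(gr) {
  str <- as.character(GenomicRanges::strand(gr))
  pos <- ifelse(str == "-",
                GenomicRanges::end(gr) - 1L,    # last base, 0-based
                GenomicRanges::start(gr) - 1L)  # first base, 0-based
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = as.numeric(pos), row.names = names(gr),
             stringsAsFactors = FALSE)
}

#' Genomic position of CpG loci
#'
#' CpG probes are single-base BED intervals by convention; the position is
#' the interval start (0-based). Wider intervals also use the start, with a
#' one-time width warning. Chromosome names pass through unchanged — there
#' is no whitelist and no "chr1"/"1" harmonization.
#'
#' @inheritParams tssOf
#' @return data.frame with columns `chrom` and `pos` (0-based).
#' @export
cpgPosition <- function(gr) {
  if (any(GenomicRanges::width(gr) > 1L))
    eqtmLog(sum(GenomicRanges::width(gr) > 1L),
            " CpG annotation interval(s) wider than one base; using the start coordinate")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = as.numeric(GenomicRanges::start(gr) - 1L),
             row.names = names(gr), stringsAsFactors = FALSE)
}

#' Does one (gene, CpG) pair belong to a mapping modality?
#'
#' cis: same chromosome and `|cpg - tss| <= window` (boundary belongs to
#' the window). distal: same chromosome and `|cpg - tss| > window`.
#' trans: different chromosomes. all: every pair. With the default windows
#' (cis 1 Mb, distal 50 kb) cis and distal overlap for same-chromosome
#' distances in (50 kb, 1 Mb]; that overlap is deliberate, following the
#' modality definitions literally.
#'
#' @param gene single-record named GRanges for the gene.
#' @param cpg single-record named GRanges for the CpG.
#' @param mode a [MappingMode-class].
#' @return logical scalar.
#' @export
pairInMode <- function(gene, cpg, mode) {
  if (mode@mode == "all") return(TRUE)
  g <- tssOf(gene)
  c0 <- cpgPosition(cpg)
  sameChrom <- g$chrom[1L] == c0$chrom[1L]
  switch(mode@mode,
    trans = !sameChrom,
    cis = sameChrom && abs(c0$pos[1L] - g$pos[1L]) <= mode@window,
    distal = sameChrom && abs(c0$pos[1L] - g$pos[1L]) > mode@window)
}

#' Enumerate the (gene, CpG) pairs a modality selects
#'
#' Vectorized realization of [pairInMode()] over the full gene x CpG grid.
#' Genes or CpGs absent from their annotation are excluded in cis, distal
#' and trans modes (each missing id logged once); in all mode no annotation
#' is consulted and every pair is selected. Ordering is deterministic:
#' gene-major in `geneIds` order, CpGs in `cpgIds` order within each gene.
#'
#' @param geneAnnot,cpgAnnot named GRanges annotations (may be NULL in all
#'   mode).
#' @param geneIds,cpgIds ordered locus ids from the data matrices.
#' @param mode a [MappingMode-class].
#' @return a `PairSelection` list: `geneIds`, `cpgIds`, `all` (logical,
#'   TRUE when every pair is selected without materializing indices), and
#'   otherwise `sel`, a per-gene list of selected CpG index vectors.
#'   Use [pairCount()] for the total.
#' @export
enumeratePairs <- function(geneAnnot, cpgAnnot, geneIds, cpgIds, mode) {
  stopifnot(length(geneIds) > 0L, length(cpgIds) > 0L)
  out <- list(geneIds = geneIds, cpgIds = cpgIds, all = FALSE, sel = NULL)
  if (mode@mode == "all") {
    out$all <- TRUE
    class(out) <- "PairSelection"
    return(out)
  }
  if (is.null(geneAnnot) || is.null(cpgAnnot))
    stopf("%s mode requires gene and CpG annotations", mode@mode)
  gTss <- tssOf(geneAnnot)
  cPos <- cpgPosition(cpgAnnot)
  if (length(intersect(unique(gTss$chrom), unique(cPos$chrom))) == 0L)
    warning("gene and CpG annotations share no chromosome names; check naming conventions (e.g. 'chr1' vs '1')",
            call. = FALSE)
  missG <- setdiff(geneIds, rownames(gTss))
  missC <- setdiff(cpgIds, rownames(cPos))
  for (id in missG) eqtmLog("gene absent from annotation, excluded: ", id)
  for (id in missC) eqtmLog("CpG absent from annotation, excluded: ", id)
  cKnown <- which(cpgIds %in% rownames(cPos))
  cChrom <- cPos[cpgIds[cKnown], "chrom"]
  cPos0 <- cPos[cpgIds[cKnown], "pos"]
  sel <- vector("list", length(geneIds))
  for (gi in seq_along(geneIds)) {
    if (!geneIds[gi] %in% rownames(gTss)) {
      sel[[gi]] <- integer(0)
      next
    }
    gc <- gTss[geneIds[gi], "chrom"]
    gp <- gTss[geneIds[gi], "pos"]
    same <- cChrom == gc
    hit <- switch(mode@mode,
      trans = !same,
      cis = same & abs(cPos0 - gp) <= mode@window,
      distal = same & abs(cPos0 - gp) > mode@window)
    sel[[gi]] <- cKnown[hit]
  }
  out$sel <- sel
  class(out) <- "PairSelection"
  out
}

#' Total number of pairs in a selection
#'
#' Available without materializing the pairs in all mode.
#'
#' @param selection a `PairSelection` from [enumeratePairs()].
#' @return numeric pair count.
#' @export
pairCount <- function(selection) {
  if (selection$all)
    return(as.numeric(length(selection$geneIds)) * length(selection$cpgIds))
  sum(vapply(selection$sel, length, integer(1L)))
}
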