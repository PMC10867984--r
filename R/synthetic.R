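#' Generate unstructured random ("dummy") inputs
#'
#' Produces a complete, seed-reproducible input set for a mapping run:
#' expression (independent standard Gaussian per cell, emulating log
#' expression levels), methylation (independent uniform on \[0,1\],
#' emulating Beta scores), covariates (standard Gaussian), and BED
#' annotations with loci placed uniformly at random over a configurable
#' chromosome layout. Genes get 1 kb intervals with random strand; CpGs get
#' single-base intervals. The same seed yields byte-identical files.
#'
#' @param nSamples,nGenes,nCpgs,nCovariates dimensions (all >= 1 except
#'   `nCovariates >= 0`).
#' @param seed integer RNG seed, or `NA` to draw from the current RNG
#'   stream (useful inside Monte-Carlo replicate loops, where one stream
#'   seeded once guarantees independent replicates).
#' @param outDir optional directory; when given, writes expression.csv,
#'   methylation.csv, covariates.csv, genes.bed, cpgs.bed there.
#' @param nChromosomes,chromLength chromosome layout (default: 2
#'   chromosomes of 200 Mb).
#' @return (invisibly) list with matrices `expression`, `methylation`,
#'   `covariates`, GRanges `geneAnnot`, `cpgAnnot`, and `paths` (NULL when
#'   `outDir` is missing).
#' @export
generateDummy <- function(nSamples, nGenes, nCpgs, nCovariates = 0L,
                          seed = 1L, outDir = NULL,
                          nChromosomes = 2L, chromLength = 2e8) {
  stopifnot(nSamples >= 1, nGenes >= 1, nCpgs >= 1, nCovariates >= 0,
            nChromosomes >= 1, chromLength > 1e3)
  if (!is.na(seed)) set.seed(seed)
  samples <- sprintf("sample%04d", seq_len(nSamples))
  genes <- sprintf("gene%05d", seq_len(nGenes))
  cpgs <- sprintf("cpg%06d", seq_len(nCpgs))
  expression <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                       dimnames = list(genes, samples))
  methylation <- matrix(runif(nCpgs * nSamples), nCpgs, nSamples,
                        dimnames = list(cpgs, samples))
  covariates <- matrix(rnorm(nSamples * nCovariates), nSamples, nCovariates,
                       dimnames = list(samples,
                                       if (nCovariates) sprintf("cov%d", seq_len(nCovariates))))
  geneAnnot <- .placeLoci(genes, nChromosomes, chromLength, width = 1000L,
                          randomStrand = TRUE)
  cpgAnnot <- .placeLoci(cpgs, nChromosomes, chromLength, width = 1L,
                         randomStrand = FALSE)
  paths <- if (!is.null(outDir))
    .writeDatasetFiles(expression, methylation, covariates,
                       geneAnnot, cpgAnnot, outDir)
  invisible(list(expression = expression, methylation = methylation,
                 covariates = covariates, geneAnnot = geneAnnot,
                 cpgAnnot = cpgAnnot, paths = paths))
}

.placeLoci <- function(ids, nChromosomes, chromLength, width,
                       randomStrand) {
  chrom <- paste0("chr", sample.int(nChromosomes, length(ids), replace = TRUE))
  start0 <- floor(runif(length(ids), 0, chromLength - width))
  strand <- if (randomStrand) sample(c("+", "-"), length(ids), replace = TRUE)
            else rep("*", length(ids))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                width = width),
                               strand = strand)
  names(gr) <- ids
  gr
}

.writeDatasetFiles <- function(expression, methylation, covariates,
                               geneAnnot, cpgAnnot, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(outDir, "expression.csv"),
    methylation = file.path(outDir, "methylation.csv"),
    covariates = file.path(outDir, "covariates.csv"),
    geneBed = file.path(outDir, "genes.bed"),
    cpgBed = file.path(outDir, "cpgs.bed"))
  .writeMatrixCsv(expression, "id", paths$expression)
  .writeMatrixCsv(methylation, "id", paths$methylation)
  .writeMatrixCsv(covariates, "sample_id", paths$covariates)
  .writeBed(geneAnnot, paths$geneBed)
  .writeBed(cpgAnnot, paths$cpgBed)
  paths
}

.writeMatrixCsv <- function(m, idCol, path) {
  fm <- matrix(sprintf("%.15g", m), nrow(m), ncol(m),
               dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colnames(m))
  write.table(df, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
}

.writeBed <- function(gr, path) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   format(GenomicRanges::start(gr) - 1L, scientific = FALSE, trim = TRUE),
                   format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
                   names(gr), 0L, strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Specification of an effect-planted synthetic dataset
#'
#' @param nSamples,nGenes,nCpgs,nCovariates dimensions.
#' @param effects data.frame with columns `gene_id`, `cpg_id`, `effect`
#'   (expression units per Beta unit); may be empty for a pure null.
#' @param covariateEffects numeric vector of length `nCovariates`, the
#'   common covariate coefficients applied to every gene.
#' @param noiseSd Gaussian noise standard deviation (> 0), expression
#'   units.
#' @param seed integer RNG seed, or `NA` to draw from the current RNG
#'   stream.
#' @param nChromosomes,chromLength chromosome layout.
#' @return list of class `EffectSpec`.
#' @export
effectSpec <- function(nSamples, nGenes, nCpgs, nCovariates = 0L,
                       effects = data.frame(gene_id = character(0),
                                            cpg_id = character(0),
                                            effect = numeric(0)),
                       covariateEffects = rep(0, nCovariates),
                       noiseSd = 1, seed = 1L,
                       nChromosomes = 2L, chromLength = 2e8) {
  stopifnot(noiseSd > 0, length(covariateEffects) == nCovariates,
            all(c("gene_id", "cpg_id", "effect") %in% colnames(effects)))
  spec <- list(nSamples = nSamples, nGenes = nGenes, nCpgs = nCpgs,
               nCovariates = nCovariates, effects = effects,
               covariateEffects = covariateEffects, noiseSd = noiseSd,
               seed = seed, nChromosomes = nChromosomes,
               chromLength = chromLength)
  class(spec) <- "EffectSpec"
  spec
}

#' Generate an effect-planted synthetic dataset
#'
#' Builds methylation (uniform Beta-like values on \[0,1\]) and covariates
#' as in [generateDummy()], then constructs every expression row from the
#' generative model behind the mapper:
#' `y_k = sum_j a_jk * M_j + X b + Gaussian noise(sd)`,
#' where the planted `a_jk` come from the spec's effect table and `b` is
#' the common covariate-effect vector. The planted pairs with their effect
#' sizes are returned (and written) as a truth table for scoring recovery
#' and power.
#'
#' @param spec an [effectSpec()].
#' @param outDir optional directory; when given, also writes the dataset
#'   files plus `truth.csv` (gene_id, cpg_id, effect).
#' @return (invisibly) list as in [generateDummy()] plus `truth`
#'   data.frame.
#' @export
generateWithEffects <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "EffectSpec"))
  if (!is.na(spec$seed)) set.seed(spec$seed)
  samples <- sprintf("sample%04d", seq_len(spec$nSamples))
  genes <- sprintf("gene%05d", seq_len(spec$nGenes))
  cpgs <- sprintf("cpg%06d", seq_len(spec$nCpgs))
  badG <- setdiff(spec$effects$gene_id, genes)
  badC <- setdiff(spec$effects$cpg_id, cpgs)
  if (length(badG) || length(badC))
    stopf("planted pair references nonexistent locus: %s",
          paste(c(badG, badC), collapse = ", "))
  methylation <- matrix(runif(spec$nCpgs * spec$nSamples),
                        spec$nCpgs, spec$nSamples,
                        dimnames = list(cpgs, samples))
  covariates <- matrix(rnorm(spec$nSamples * spec$nCovariates),
                       spec$nSamples, spec$nCovariates,
                       dimnames = list(samples,
                                       if (spec$nCovariates) sprintf("cov%d", seq_len(spec$nCovariates))))
  signal <- matrix(0, spec$nGenes, spec$nSamples,
                   dimnames = list(genes, samples))
  if (nrow(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      g <- spec$effects$gene_id[i]
      signal[g, ] <- signal[g, ] +
        spec$effects$effect[i] * methylation[spec$effects$cpg_id[i], ]
    }
  }
  if (spec$nCovariates)
    signal <- signal + matrix(rep(as.numeric(covariates %*% spec$covariateEffects),
                                  each = spec$nGenes),
                              spec$nGenes, spec$nSamples)
  expression <- signal + matrix(rnorm(spec$nGenes * spec$nSamples,
                                      sd = spec$noiseSd),
                                spec$nGenes, spec$nSamples)
  dimnames(expression) <- list(genes, samples)
  geneAnnot <- .placeLoci(genes, spec$nChromosomes, spec$chromLength,
                          width = 1000L, randomStrand = TRUE)
  cpgAnnot <- .placeLoci(cpgs, spec$nChromosomes, spec$chromLength,
                         width = 1L, randomStrand = FALSE)
  truth <- spec$effects[, c("gene_id", "cpg_id", "effect"), drop = FALSE]
  paths <- NULL
  if (!is.null(outDir)) {
    paths <- .writeDatasetFiles(expression, methylation, covariates,
                                geneAnnot, cpgAnnot, outDir)
    paths$truth <- file.path(outDir, "truth.csv")
    write.table(truth, paths$truth, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(list(expression = expression, methylation = methylation,
                 covariates = covariates, geneAnnot = geneAnnot,
                 cpgAnnot = cpgAnnot, truth = truth, paths = paths))
}
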