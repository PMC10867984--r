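#' Select the compute device for a run
#'
#' `"auto"` probes for a usable accelerator and falls back to the CPU;
#' `"cpu"` forces the CPU; `"accelerator"` errors when none is present.
#' This build computes through CPU BLAS in double precision, so the probe
#' reports no accelerator; the descriptor keeps the execution contract
#' (device class + thread count) explicit and testable.
#'
#' @param request one of "auto", "cpu", "accelerator".
#' @param cpuThreads positive integer, recorded in the CPU descriptor.
#'   Results are deterministic and identical for any thread count.
#' @return list of class `eqtmDevice` with elements `type` and `threads`.
#' @export
selectDevice <- function(request = c("auto", "cpu", "accelerator"),
                         cpuThreads = 1L) {
  request <- match.arg(request)
  cpuThreads <- as.integer(cpuThreads)
  if (is.na(cpuThreads) || cpuThreads < 1L)
    stopf("cpuThreads must be a positive integer")
  if (request == "accelerator" && !.acceleratorAvailable())
    stopf("accelerator requested but none is available on this system")
  dev <- list(type = "cpu", threads = cpuThreads)
  class(dev) <- "eqtmDevice"
  dev
}

.acceleratorAvailable <- function() FALSE  # CPU BLAS backend only

# Working-set cost model behind the genes-per-chunk estimator, in bytes:
#   bytes * overhead * (2*n*G + 2*n*C + 4*G*C + n*(m+2))
# i.e. input blocks for G genes and C CpGs (n values each), their
# residualized copies, the four G x C result matrices (est/se/t/p), and the
# design plus its orthonormal basis; overhead 1.25 covers temporaries.
.CHUNK_OVERHEAD <- 1.25

.workingSetBytes <- function(nGenes, nCpgs, nSamples, mCovariates,
                             bytesPerValue) {
  bytesPerValue * .CHUNK_OVERHEAD *
    (2 * nSamples * nGenes + 2 * nSamples * nCpgs +
     4 * nGenes * nCpgs + nSamples * (mCovariates + 2))
}

#' Estimate how many genes fit in one chunk
#'
#' Inverts the documented working-set cost model (see
#' [planChunks()]) for the largest gene count whose block — inputs,
#' residualized copies, and the four result matrices — fits the memory
#' budget. The formula is closed-form, so the estimate is exactly
#' reproducible:
#' `G = floor((budget/(bytes*1.25) - 2nC - n(m+2)) / (2n + 4C))`.
#'
#' @param nSamples,nCpgsPerBlock,mCovariates problem dimensions.
#' @param bytesPerValue bytes per stored value (8 for double precision).
#' @param memoryBudget available bytes for one block.
#' @return integer gene count >= 1.
#' @export
estimateGenesPerChunk <- function(nSamples, nCpgsPerBlock, mCovariates,
                                  bytesPerValue, memoryBudget) {
  stopifnot(nSamples > 0, nCpgsPerBlock > 0, mCovariates >= 0,
            bytesPerValue > 0, memoryBudget > 0)
  minBudget <- .workingSetBytes(1, nCpgsPerBlock, nSamples, mCovariates,
                                bytesPerValue)
  if (minBudget > memoryBudget)
    stopf("memory budget %.0f bytes is below the single-gene working set; need at least %.0f bytes for %d CpGs per block",
          memoryBudget, minBudget, nCpgsPerBlock)
  g <- floor((memoryBudget / (bytesPerValue * .CHUNK_OVERHEAD) -
              2 * nSamples * nCpgsPerBlock - nSamples * (mCovariates + 2)) /
             (2 * nSamples + 4 * nCpgsPerBlock))
  max(1L, as.integer(g))
}

#' Plan the chunk decomposition of the gene x CpG grid
#'
#' Tiles the grid into contiguous blocks. Explicit chunk sizes are honored
#' verbatim; `"auto"` CpG chunks default to `min(nCpgs, 1e5)` and `"auto"`
#' gene chunks come from [estimateGenesPerChunk()]. Results are invariant
#' to the decomposition; chunking only bounds the working set.
#'
#' @param nGenes,nCpgs grid dimensions.
#' @param geneChunk,cpgChunk positive integers or "auto".
#' @param nSamples,mCovariates,bytesPerValue,memoryBudget cost-model inputs
#'   (see [estimateGenesPerChunk()]); only consulted for "auto" sizes and
#'   the per-block estimates.
#' @return list of class `ChunkPlan`: `geneStarts`/`geneEnds`,
#'   `cpgStarts`/`cpgEnds`, `blockBytes` (largest block's working-set
#'   estimate), `nBlocks`.
#' @export
planChunks <- function(nGenes, nCpgs, geneChunk = "auto", cpgChunk = "auto",
                       nSamples = NULL, mCovariates = 0L,
                       bytesPerValue = 8, memoryBudget = 2^31) {
  stopifnot(nGenes >= 1, nCpgs >= 1)
  if (identical(cpgChunk, "auto")) cpgChunk <- min(nCpgs, 1e5)
  cpgChunk <- max(1L, as.integer(cpgChunk))
  if (identical(geneChunk, "auto")) {
    if (is.null(nSamples)) stopf("auto gene chunking needs nSamples for the cost model")
    geneChunk <- min(nGenes,
                     estimateGenesPerChunk(nSamples, min(cpgChunk, nCpgs),
                                           mCovariates, bytesPerValue,
                                           memoryBudget))
  }
  geneChunk <- max(1L, as.integer(geneChunk))
  gs <- seq.int(1L, nGenes, by = geneChunk)
  cs <- seq.int(1L, nCpgs, by = cpgChunk)
  plan <- list(
    geneStarts = gs, geneEnds = pmin(gs + geneChunk - 1L, nGenes),
    cpgStarts = cs, cpgEnds = pmin(cs + cpgChunk - 1L, nCpgs),
    blockBytes = if (is.null(nSamples)) NA_real_ else
      .workingSetBytes(min(geneChunk, nGenes), min(cpgChunk, nCpgs),
                       nSamples, mCovariates, bytesPerValue),
    nBlocks = length(gs) * length(cs))
  if (!is.na(plan$blockBytes) && plan$blockBytes > memoryBudget)
    warning(sprintf("explicit chunk sizes give an estimated block working set of %.0f bytes, above the %.0f-byte budget",
                    plan$blockBytes, memoryBudget), call. = FALSE)
  class(plan) <- "ChunkPlan"
  plan
}

#' Run an end-to-end eQTM mapping analysis
#'
#' Orchestrates a full run: device selection, pair enumeration for the
#' requested modality, chunked block dispatch to the batched regression (or
#' Pearson) core, p-value filtering, and column-selected CSV output. The
#' covariate design is validated and residualization applied once per
#' block, never per pair. Output rows are deterministic: gene-major in
#' expression-matrix order, CpGs in methylation-matrix order within each
#' gene. Results are identical across chunk decompositions and thread
#' settings. A failing block aborts the run (with its coordinates) and no
#' output file is left behind.
#'
#' @param dataset an [EqtmDataset-class] from [alignSamples()].
#' @param geneAnnot,cpgAnnot named GRanges annotations (required for cis,
#'   distal and trans modes).
#' @param mode a [MappingMode-class]; default all-by-all.
#' @param method "mlr" (covariate-adjusted linear model) or "pearson".
#' @param device,cpuThreads see [selectDevice()].
#' @param geneChunk,cpgChunk,memoryBudget see [planChunks()].
#' @param pMax strict p-value ceiling for written rows; defaults to the
#'   mode's own default (1e-5 for trans/all, none for cis/distal). Pass
#'   `NA` to disable.
#' @param columns statistic columns to write; `cov_<name>_<stat>` terms
#'   (mlr only) trigger per-covariate estimation.
#' @param outputPath output CSV path.
#' @return list of class `eqtmRunSummary`: `pairsTested`, `rowsWritten`,
#'   `degenerateLoci`, `nBlocks`, `device`, `outputPath`.
#' @export
runMapping <- function(dataset, geneAnnot = NULL, cpgAnnot = NULL,
                       mode = mappingMode("all"),
                       method = c("mlr", "pearson"),
                       device = "auto", cpuThreads = 1L,
                       geneChunk = "auto", cpgChunk = "auto",
                       memoryBudget = 2^31,
                       pMax = NULL,
                       columns = c("est", "se", "t", "p"),
                       outputPath) {
  stopifnot(is(dataset, "EqtmDataset"), is(mode, "MappingMode"))
  method <- match.arg(method)
  dev <- selectDevice(device, cpuThreads)
  if (is.null(pMax)) pMax <- mode@pMax
  expr <- exprValues(dataset)
  meth <- methValues(dataset)
  covs <- covValues(dataset)
  withCov <- any(grepl("^cov_", columns))
  if (withCov && method == "pearson")
    stopf("per-covariate columns are only available with method = 'mlr'")
  design <- if (method == "mlr") validateDesign(covs) else NULL
  selection <- enumeratePairs(geneAnnot, cpgAnnot,
                              rownames(expr), rownames(meth), mode)
  plan <- planChunks(nrow(expr), nrow(meth), geneChunk, cpgChunk,
                     nSamples = nSamples(dataset), mCovariates = ncol(covs),
                     memoryBudget = memoryBudget)
  eqtmLog(sprintf("device: %s (%d thread%s); %d block(s); %s mode, %s method; %.0f pair(s) selected",
                  dev$type, dev$threads, if (dev$threads > 1) "s" else "",
                  plan$nBlocks, mode@mode, method, pairCount(selection)),
          level = 2L)
  statCols <- unique(c("est", "se", "t", "p", columns))
  pieces <- list()
  degenerate <- character(0)
  pairsTested <- 0
  for (bi in seq_along(plan$geneStarts)) {
    g0 <- plan$geneStarts[bi]; g1 <- plan$geneEnds[bi]
    blockPieces <- list()
    for (ci in seq_along(plan$cpgStarts)) {
      c0 <- plan$cpgStarts[ci]; c1 <- plan$cpgEnds[ci]
      piece <- tryCatch({
        res <- if (method == "mlr")
          batchedMlr(expr[g0:g1, , drop = FALSE],
                     meth[c0:c1, , drop = FALSE], design,
                     withCovariates = withCov)
        else
          pearsonBlock(expr[g0:g1, , drop = FALSE],
                       meth[c0:c1, , drop = FALSE])
        degenerate <- union(degenerate, res$degenerate_cpgs)
        .extractBlockRows(res, selection, g0, g1, c0, c1, statCols)
      }, error = function(e) {
        stopf("block genes[%d..%d] x cpgs[%d..%d] failed: %s",
              g0, g1, c0, c1, conditionMessage(e))
      })
      blockPieces[[ci]] <- piece
      eqtmLog(sprintf("block %d/%d done (%d row(s))",
                      (bi - 1L) * length(plan$cpgStarts) + ci,
                      plan$nBlocks, nrow(piece)), level = 2L)
    }
    merged <- do.call(rbind, blockPieces)
    if (nrow(merged))
      merged <- merged[order(merged$.g, merged$.c), , drop = FALSE]
    pairsTested <- pairsTested + nrow(merged)
    pieces[[bi]] <- merged
  }
  results <- do.call(rbind, pieces)
  results$.g <- NULL
  results$.c <- NULL
  rownames(results) <- NULL
  written <- tryCatch(
    writeResults(results, outputPath, columns = columns, pMax = pMax),
    error = function(e) {
      if (file.exists(outputPath)) unlink(outputPath)
      stop(e)
    })
  summary <- list(pairsTested = pairsTested, rowsWritten = written,
                  degenerateLoci = length(degenerate),
                  nBlocks = plan$nBlocks, device = dev,
                  outputPath = outputPath)
  class(summary) <- "eqtmRunSummary"
  summary
}

# Pull the selected (gene, CpG) rows of one block into a data.frame with
# global grid coordinates (.g, .c) used for deterministic ordering.
.extractBlockRows <- function(res, selection, g0, g1, c0, c1, statCols) {
  gIdx <- g0:g1
  if (selection$all) {
    perGene <- rep(list(c0:c1), length(gIdx))
  } else {
    perGene <- lapply(selection$sel[gIdx], function(s) s[s >= c0 & s <= c1])
  }
  counts <- lengths(perGene)
  gGlob <- rep(gIdx, counts)
  cGlob <- unlist(perGene, use.names = FALSE)
  if (length(gGlob) == 0L) {
    out <- data.frame(gene_id = character(0), cpg_id = character(0),
                      .g = integer(0), .c = integer(0))
    for (sc in statCols) out[[sc]] <- numeric(0)
    return(out)
  }
  ij <- cbind(gGlob - g0 + 1L, cGlob - c0 + 1L)
  out <- data.frame(gene_id = res$gene_ids[ij[, 1L]],
                    cpg_id = res$cpg_ids[ij[, 2L]],
                    .g = gGlob, .c = cGlob,
                    stringsAsFactors = FALSE)
  for (sc in statCols) out[[sc]] <- res[[sc]][ij]
  out
}

#' @export
print.eqtmRunSummary <- function(x, ...) {
  cat("eQTM mapping run\n",
      "  pairs tested:     ", format(x$pairsTested, big.mark = ","), "\n",
      "  rows written:     ", format(x$rowsWritten, big.mark = ","), "\n",
      "  degenerate loci:  ", x$degenerateLoci, "\n",
      "  blocks:           ", x$nBlocks, "\n",
      "  device:           ", x$device$type,
      " (", x$device$threads, " thread(s))\n",
      "  output:           ", x$outputPath, "\n", sep = "")
  invisible(x)
}
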