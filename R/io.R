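#' Read a locus-by-sample matrix from CSV
#'
#' Expression and methylation inputs share one layout: samples in columns,
#' loci in rows, a header row of sample ids and a first column of locus ids.
#' File order of both axes is preserved.
#'
#' @param path path to a CSV file.
#' @param missing policy for empty/NA cells: `"error"` (default) rejects the
#'   file; `"drop-loci"` drops every locus (row) containing a missing value
#'   and logs each dropped locus id.
#' @return numeric matrix (loci x samples) with locus ids as rownames and
#'   sample ids as colnames.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,s1,s2", "g1,1.5,2", "g2,0,1"), f)
#' readLocusMatrix(f)
#' @export
readLocusMatrix <- function(path, missing = c("error", "drop-loci")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stopf("empty matrix in %s: need at least one locus row and one sample column", path)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stopf("duplicate locus id '%s' in %s", ids[duplicated(ids)][1L], path)
  if (anyDuplicated(samples))
    stopf("duplicate sample id '%s' in %s", samples[duplicated(samples)][1L], path)
  vals <- .parseNumericCells(df[-1L], path, rowIds = ids)
  dimnames(vals) <- list(ids, samples)
  if (anyNA(vals)) {
    if (missing == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stopf("missing value at locus '%s', sample '%s' in %s (use missing = 'drop-loci' to drop such rows)",
            ids[bad[1L]], samples[bad[2L]], path)
    }
    drop <- !complete.cases(vals)
    for (id in ids[drop])
      eqtmLog("dropping locus with missing values: ", id)
    vals <- vals[!drop, , drop = FALSE]
    if (nrow(vals) == 0L) stopf("all loci dropped from %s", path)
  }
  vals
}

# Parse a data.frame of character cells into a numeric matrix, reporting
# the coordinates of the first non-numeric cell. Empty strings -> NA.
.parseNumericCells <- function(df, path, rowIds) {
  out <- matrix(NA_real_, nrow(df), ncol(df))
  for (jj in seq_along(df)) {
    raw <- trimws(df[[jj]])
    raw[raw == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(v))
    if (length(bad))
      stopf("non-numeric cell '%s' at row '%s', column '%s' in %s",
            raw[bad[1L]], rowIds[bad[1L]], colnames(df)[jj], path)
    out[, jj] <- v
  }
  out
}

#' Read a covariate table from CSV
#'
#' Covariates in columns, samples in rows; the header holds covariate names
#' and the first column holds sample ids. All cells must be numeric:
#' categorical covariates must be encoded (e.g. as indicator columns) before
#' input. A file with zero covariate columns is valid and yields an
#' intercept-only model downstream.
#'
#' @param path path to a CSV file.
#' @return numeric matrix (samples x covariates) with dimnames; zero columns
#'   allowed.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 1L)
    stopf("empty covariate table in %s", path)
  ids <- df[[1L]]
  covs <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stopf("duplicate sample id '%s' in %s", ids[duplicated(ids)][1L], path)
  if (anyDuplicated(covs))
    stopf("duplicate covariate name '%s' in %s", covs[duplicated(covs)][1L], path)
  if (length(covs) == 0L) {
    vals <- matrix(numeric(0), nrow = length(ids), ncol = 0L)
  } else {
    vals <- .parseNumericCells(df[-1L], path, rowIds = ids)
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stopf("missing value at sample '%s', covariate '%s' in %s",
            ids[bad[1L]], covs[bad[2L]], path)
    }
  }
  dimnames(vals) <- list(ids, covs)
  vals
}

#' Read locus annotations from a BED file
#'
#' Accepts tab- or space-delimited BED with at least four columns (chrom,
#' start, end, name) and an optional sixth strand column. Coordinates are
#' interpreted 0-based half-open per the BED standard and stored as a
#' `GRanges` (1-based closed, the usual conversion); a missing or "."
#' strand becomes "*". Record order is preserved.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges] named by the BED name column.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t999\t1000\tcg0001\t.\t+", f)
#' readBedAnnotation(f)
#' @export
readBedAnnotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
               comment.char = "#", quote = "", fill = TRUE),
    error = function(e) stopf("cannot parse BED file %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 4L)
    stopf("BED file %s has %d column(s); need at least chrom, start, end, name",
          path, ncol(df))
  chrom <- as.character(df[[1L]])
  start0 <- suppressWarnings(as.numeric(df[[2L]]))
  end0 <- suppressWarnings(as.numeric(df[[3L]]))
  name <- as.character(df[[4L]])
  if (anyNA(name) || any(name == ""))
    stopf("BED record with fewer than 4 columns (chrom, start, end, name) in %s", path)
  if (anyNA(start0) || anyNA(end0))
    stopf("non-numeric start/end in BED file %s", path)
  if (any(start0 < 0))
    stopf("negative start coordinate in BED file %s", path)
  if (any(end0 <= start0)) {
    i <- which(end0 <= start0)[1L]
    stopf("empty or inverted interval for '%s' (start %g, end %g) in %s",
          name[i], start0[i], end0[i], path)
  }
  if (anyDuplicated(name))
    stopf("duplicate locus name '%s' in BED file %s",
          name[duplicated(name)][1L], path)
  if (any(chrom == ""))
    stopf("empty chromosome name in BED file %s", path)
  strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else rep("*", nrow(df))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand)
  names(gr) <- name
  gr
}

#' Align expression, methylation and covariates on shared samples
#'
#' Restricts all three inputs to the intersection of their sample-id sets,
#' ordered as in the expression matrix, and returns a validated
#' [EqtmDataset-class]. The number of samples dropped from each input is
#' logged. Alignment is idempotent.
#'
#' @param expression genes x samples matrix (see [readLocusMatrix()]).
#' @param methylation CpG loci x samples matrix.
#' @param covariates samples x covariates matrix (see [readCovariates()]).
#' @return an [EqtmDataset-class]
#' @export
alignSamples <- function(expression, methylation, covariates) {
  for (nm in c("expression", "methylation"))
    if (nrow(get(nm)) == 0L || ncol(get(nm)) == 0L) stopf("empty %s matrix", nm)
  if (nrow(covariates) == 0L) stopf("empty covariate table")
  shared <- intersect(intersect(colnames(expression), colnames(methylation)),
                      rownames(covariates))
  if (length(shared) == 0L)
    stopf("sample alignment failed: no sample id shared by expression, methylation and covariates")
  keep <- colnames(expression)[colnames(expression) %in% shared]
  if (length(keep) < 3L)
    stopf("only %d shared sample(s); need at least 3", length(keep))
  dropE <- ncol(expression) - length(keep)
  dropM <- ncol(methylation) - length(keep)
  dropX <- nrow(covariates) - length(keep)
  if (dropE + dropM + dropX > 0L)
    eqtmLog(sprintf("sample alignment dropped %d expression / %d methylation / %d covariate sample(s); n = %d",
                    dropE, dropM, dropX, length(keep)))
  ds <- new("EqtmDataset",
            expression  = expression[, keep, drop = FALSE],
            methylation = methylation[, keep, drop = FALSE],
            covariates  = covariates[keep, , drop = FALSE])
  validObject(ds)
  ds
}

#' Write filtered, column-selected association results to CSV
#'
#' Writes a header `gene_id,cpg_id,<columns>` and one row per result pair,
#' preserving input row order. When `pMax` is given, only rows with
#' `p < pMax` (strict) are written; pairs whose p-value is a degenerate-
#' locus sentinel (NaN) are then excluded. Numeric values are serialized
#' with 15 significant digits so that re-read values round-trip and chunk
#' invariance is checkable on files.
#'
#' @param results data.frame with columns `gene_id`, `cpg_id` and the
#'   statistic columns produced by the engine (`est`, `se`, `t`, `p`, and
#'   optionally `cov_<name>_<stat>` terms).
#' @param path output CSV path.
#' @param columns statistic columns to write, a subset of those available.
#' @param pMax optional strict p-value ceiling in (0, 1]; `NA`/`NULL` writes
#'   every row.
#' @return (invisibly) the number of rows written.
#' @export
writeResults <- function(results, path, columns = c("est", "se", "t", "p"),
                         pMax = NULL) {
  if (is.null(pMax) || length(pMax) == 0L) pMax <- NA_real_
  if (!is.na(pMax) && (pMax <= 0 || pMax > 1))
    stopf("pMax must lie in (0, 1], got %g", pMax)
  avail <- setdiff(colnames(results), c("gene_id", "cpg_id"))
  unknown <- setdiff(columns, avail)
  if (length(unknown))
    stopf("unknown result column(s): %s (available: %s)",
          paste(unknown, collapse = ", "), paste(avail, collapse = ", "))
  keep <- if (is.na(pMax)) rep(TRUE, nrow(results))
          else !is.na(results$p) & results$p < pMax
  out <- results[keep, c("gene_id", "cpg_id", columns), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  write.table(out, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(sum(keep))
}
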