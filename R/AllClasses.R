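#' EqtmDataset: a sample-aligned expression/methylation/covariate trio
#'
#' Container for the three inputs of an eQTM mapping run after sample
#' alignment. Expression and methylation are stored loci-by-samples (log
#' expression levels and Beta scores, respectively); covariates are stored
#' samples-by-covariates. Validity requires the three components to share an
#' identical, identically ordered sample set of at least 3 samples, unique
#' ids on every axis, finite values, and no constant covariate column (a
#' constant column would collide with the intercept the model always adds).
#'
#' @slot expression numeric matrix, genes x samples, with dimnames.
#' @slot methylation numeric matrix, CpG loci x samples, with dimnames.
#' @slot covariates numeric matrix, samples x covariates, with dimnames
#'   (zero columns permitted: intercept-only model).
#'
#' @seealso [alignSamples()] which constructs validated instances.
#' @export
setClass("EqtmDataset",
  representation(
    expression  = "matrix",
    methylation = "matrix",
    covariates  = "matrix"
  )
)

.checkIds <- function(ids, what) {
  if (is.null(ids) || length(ids) == 0L)
    return(sprintf("missing %s ids", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1L]))
  NULL
}

setValidity("EqtmDataset", function(object) {
  e <- object@expression; m <- object@methylation; x <- object@covariates
  msgs <- c(
    .checkIds(rownames(e), "gene"),
    .checkIds(rownames(m), "CpG"),
    .checkIds(colnames(e), "sample")
  )
  if (length(msgs)) return(msgs)
  if (!identical(colnames(e), colnames(m)) ||
      !identical(colnames(e), rownames(x)))
    return("expression, methylation and covariates must share identical, identically ordered sample ids")
  if (ncol(e) < 3L)
    return("fewer than 3 shared samples: model unidentifiable")
  if (!all(is.finite(e))) return("non-finite values in expression matrix")
  if (!all(is.finite(m))) return("non-finite values in methylation matrix")
  if (ncol(x) > 0L) {
    if (!all(is.finite(x))) return("non-finite values in covariate table")
    if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
      return("covariate names missing or duplicated")
    const <- apply(x, 2L, function(v) max(v) - min(v) == 0)
    if (any(const))
      return(sprintf("constant covariate column after sample alignment: '%s'",
                     colnames(x)[const][1L]))
  }
  TRUE
})

#' @describeIn EqtmDataset number of shared samples
#' @param object,x an `EqtmDataset`
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "EqtmDataset", function(x) ncol(x@expression))

#' @describeIn EqtmDataset sample ids, in aligned order
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "EqtmDataset", function(x) colnames(x@expression))

#' @describeIn EqtmDataset genes x samples expression matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setMethod("exprValues", "EqtmDataset", function(x) x@expression)

#' @describeIn EqtmDataset CpG loci x samples methylation matrix
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))

#' @export
setMethod("methValues", "EqtmDataset", function(x) x@methylation)

#' @describeIn EqtmDataset samples x covariates matrix
#' @export
setGeneric("covValues", function(x) standardGeneric("covValues"))

#' @export
setMethod("covValues", "EqtmDataset", function(x) x@covariates)

setMethod("show", "EqtmDataset", function(object) {
  cat("EqtmDataset\n",
      "  genes:      ", nrow(object@expression), "\n",
      "  CpG loci:   ", nrow(object@methylation), "\n",
      "  samples:    ", ncol(object@expression), "\n",
      "  covariates: ", ncol(object@covariates),
      if (ncol(object@covariates))
        paste0(" (", paste(colnames(object@covariates), collapse = ", "), ")")
      else " (intercept-only)",
      "\n", sep = "")
})

#' MappingMode: one of the four genomic pairing modalities
#'
#' Describes which (gene, CpG) pairs an analysis evaluates. `cis` keeps
#' pairs on the same chromosome within `window` base pairs of the gene's
#' transcript start site (TSS), symmetric on both sides, boundary inclusive.
#' `distal` keeps same-chromosome pairs strictly farther than `window` from
#' the TSS. `trans` keeps pairs on different chromosomes. `all` keeps every
#' pair. Default windows: cis 1 Mb, distal 50 kb; default p-value ceiling
#' for output filtering: 1e-5 for trans and all, none for cis/distal.
#'
#' @slot mode one of "cis", "distal", "trans", "all"
#' @slot window window size in base pairs (NA for trans/all)
#' @slot pMax p-value filter threshold in (0, 1], or NA for no filtering
#' @export
setClass("MappingMode",
  representation(mode = "character", window = "numeric", pMax = "numeric")
)

setValidity("MappingMode", function(object) {
  if (!object@mode %in% c("cis", "distal", "trans", "all"))
    return("mode must be one of cis, distal, trans, all")
  if (object@mode %in% c("cis", "distal") &&
      (!is.finite(object@window) || object@window <= 0))
    return("window must be a positive number of base pairs")
  if (!is.na(object@pMax) && (object@pMax <= 0 || object@pMax > 1))
    return("pMax must lie in (0, 1]")
  TRUE
})

#' Construct a MappingMode
#'
#' @param mode "cis", "distal", "trans" or "all".
#' @param window half-width of the TSS window in base pairs; defaults to
#'   1e6 for cis and 5e4 for distal; ignored for trans/all.
#' @param pMax p-value threshold for output filtering (strict `p < pMax`);
#'   defaults to 1e-5 for trans/all and to no filtering for cis/distal.
#'   Pass `NA` explicitly to disable filtering in any mode.
#' @return a [MappingMode-class] object
#' @examples
#' mappingMode("cis")               # 1 Mb window, no p filter
#' mappingMode("trans")             # p < 1e-5 filter
#' mappingMode("distal", window = 2e4)
#' @export
mappingMode <- function(mode = c("cis", "distal", "trans", "all"),
                        window = NULL, pMax = NULL) {
  mode <- match.arg(mode)
  if (is.null(window))
    window <- switch(mode, cis = 1e6, distal = 5e4, NA_real_)
  if (is.null(pMax))
    pMax <- switch(mode, trans = 1e-5, all = 1e-5, NA_real_)
  new("MappingMode", mode = mode, window = as.numeric(window),
      pMax = as.numeric(pMax))
}

setMethod("show", "MappingMode", function(object) {
  cat("MappingMode: ", object@mode,
      if (!is.na(object@window)) sprintf(" (window %g bp)", object@window),
      if (!is.na(object@pMax)) sprintf(" [p < %g]", object@pMax),
      "\n", sep = "")
})

#' DesignBlock: validated regression design shared across all pairs
#'
#' The n x (m+1) design `[intercept | covariates]`, checked to have full
#' column rank, together with a thin orthonormal basis `Q` of its column
#' space used for one-shot covariate residualization.
#'
#' @slot base n x (m+1) design matrix, first column all ones
#' @slot rank column rank (== m+1 after validation)
#' @slot Q n x (m+1) orthonormal basis of the design column space
#' @seealso [validateDesign()]
#' @export
setClass("DesignBlock",
  representation(base = "matrix", rank = "integer", Q = "matrix")
)

setValidity("DesignBlock", function(object) {
  if (!all(object@base[, 1L] == 1)) return("first design column must be the intercept")
  if (object@rank != ncol(object@base)) return("design must have full column rank")
  TRUE
})
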