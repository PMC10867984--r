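# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately avoid the package's batched code paths:
# per-pair stats come from stats::lm / stats::cor on one pair at a time.

# Full-design per-pair OLS oracle: regress y on [1, X, M] with lm() and
# return the methylation term's estimate, standard error and t statistic.
lmPairOracle <- function(y, M, X = NULL) {
  dat <- data.frame(y = y, M = M)
  if (!is.null(X) && ncol(X) > 0) {
    X <- as.matrix(X)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    dat <- cbind(dat, X)
  }
  fit <- stats::lm(y ~ ., data = dat)
  co <- summary(fit)$coefficients["M", ]
  list(est = unname(co[1L]), se = unname(co[2L]), t = unname(co[3L]))
}

# Pearson oracle via the direct covariance formula.
corPairOracle <- function(y, M) {
  sum((y - mean(y)) * (M - mean(M))) /
    sqrt(sum((y - mean(y))^2) * sum((M - mean(M))^2))
}

# Quiet dataset builder around the dummy generator.
makeDummyDataset <- function(nSamples, nGenes, nCpgs, nCovariates = 0L,
                             seed = 1L, ...) {
  d <- generateDummy(nSamples, nGenes, nCpgs, nCovariates, seed = seed, ...)
  list(ds = alignSamples(d$expression, d$methylation, d$covariates),
       raw = d)
}

# Temp-file CSV writers for authored fixtures.
writeCsvLines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

withQuietLogs <- function(expr) {
  withr::with_options(list(eqtmMapper.verbose = 0L), expr)
}

# Scalar double-loop enumeration oracle over pairInMode().
enumOracle <- function(geneAnnot, cpgAnnot, geneIds, cpgIds, mode) {
  hits <- list()
  for (g in geneIds) for (c in cpgIds) {
    ok <- if (mode@mode == "all") TRUE
    else if (!g %in% names(geneAnnot) || !c %in% names(cpgAnnot)) FALSE
    else pairInMode(geneAnnot[g], cpgAnnot[c], mode)
    if (ok) hits[[length(hits) + 1L]] <- c(g, c)
  }
  if (length(hits)) do.call(rbind, hits) else matrix(character(0), 0, 2)
}

# Flatten a PairSelection into a (gene, cpg) id matrix in engine order.
selectionPairs <- function(sel) {
  if (sel$all) {
    as.matrix(expand.grid(cpg = sel$cpgIds, gene = sel$geneIds,
                          stringsAsFactors = FALSE))[, c("gene", "cpg")]
  } else {
    counts <- lengths(sel$sel)
    cbind(rep(sel$geneIds, counts),
          sel$cpgIds[unlist(sel$sel, use.names = FALSE)])
  }
}
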