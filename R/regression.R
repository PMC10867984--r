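#' Validate the shared regression design
#'
#' Builds the n x (m+1) design `[intercept | covariates]` used for every
#' (gene, CpG) pair, prepends the intercept column (the model always has
#' one; users must not supply their own), and verifies full column rank.
#' Residual degrees of freedom of the per-pair model are n - m - 2
#' (intercept + m covariates + the methylation term), so n > m + 2 is
#' required.
#'
#' @param covariates samples x covariates numeric matrix (possibly zero
#'   columns), already sample-aligned.
#' @return a [DesignBlock-class] carrying the design and a thin orthonormal
#'   basis of its column space.
#' @export
validateDesign <- function(covariates) {
  n <- nrow(covariates)
  m <- ncol(covariates)
  if (n <= m + 2L)
    stopf("n = %d samples with m = %d covariates leaves non-positive residual degrees of freedom (df = n - m - 2 = %d)",
          n, m, n - m - 2L)
  base <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrd <- qr(base)
  if (qrd$rank < ncol(base)) {
    # name an offending column: the first pivoted-out column
    dropped <- qrd$pivot[seq.int(qrd$rank + 1L, ncol(base))]
    stopf("rank-deficient design: covariate '%s' is constant or collinear with other columns",
          colnames(base)[dropped[1L]])
  }
  Q <- qr.Q(qrd)
  new("DesignBlock", base = base, rank = ncol(base), Q = Q)
}

#' Residualize locus rows against the design
#'
#' Removes from every row of `Y` (loci x samples) its least-squares
#' projection onto the design columns, leaving residuals orthogonal to the
#' intercept and every covariate. Computing this once per block — rather
#' than refitting the covariates for every pair — is the
#' Frisch-Waugh-Lovell shortcut that makes batched mass regression cheap.
#'
#' @param Y loci x samples numeric matrix.
#' @param design a [DesignBlock-class] whose rows match `Y`'s columns.
#' @return matrix of the same shape as `Y`.
#' @export
residualize <- function(Y, design) {
  stopifnot(is(design, "DesignBlock"))
  if (ncol(Y) != nrow(design@base))
    stopf("Y has %d samples but design has %d rows", ncol(Y), nrow(design@base))
  # Projection accumulated one orthonormal basis column at a time, via
  # elementwise products and rowSums. Each row's result then depends only
  # on that row and Q — bitwise, not just mathematically — so residuals are
  # identical whatever block of rows they are computed in. (BLAS gemm picks
  # shape-dependent kernels whose roundings differ between, say, a 1-row
  # and a 50-row block; that would break exact chunk invariance.)
  proj <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(ncol(design@Q))) {
    coefs <- rowSums(Y * rep(design@Q[, i], each = nrow(Y)))
    proj <- proj + outer(coefs, design@Q[, i])
  }
  Y - proj
}

# Pairwise cross-product matrix <Y[k,], M[j,]> computed row-by-row with a
# fixed reduction order, so every entry is bitwise independent of the
# block shape (see residualize()).
.rowwiseCross <- function(Yb, Mb) {
  out <- matrix(0, nrow(Yb), nrow(Mb),
                dimnames = list(rownames(Yb), rownames(Mb)))
  for (k in seq_len(nrow(Yb)))
    out[k, ] <- rowSums(Mb * rep(Yb[k, ], each = nrow(Mb)))
  out
}

#' Two-sided p-value from the standard normal tail
#'
#' Returns `2 * (1 - pnorm(|t|))` computed via the complementary tail
#' (`lower.tail = FALSE`), which stays accurate for large |t| where the
#' naive form would cancel catastrophically. This Gaussian approximation
#' stands in for the Student-t distribution; the two agree closely once the
#' residual degrees of freedom are large (roughly n >= 20) and the
#' approximation is anti-conservative below that.
#'
#' @param t numeric vector/matrix of statistics; non-finite entries yield
#'   NaN.
#' @return values in `[0, 1]`, same shape as `t`.
#' @examples
#' gaussianTwoSidedP(c(0, 1.96, 40))
#' @export
gaussianTwoSidedP <- function(t) {
  p <- 2 * pnorm(abs(t), lower.tail = FALSE)
  # undefined statistics (NA/NaN) propagate as NaN sentinels; +/-Inf is a
  # meaningful limit and maps to p = 0
  p[is.na(t)] <- NaN
  p
}

# Shared degenerate-row detector: residual (or centered) sum of squares
# negligibly small relative to the raw row scale. A constant row after
# intercept removal lands at ~1e-30 relative; any informative locus is far
# above 1e-20.
.degenerateRows <- function(ss, rawSS) {
  ss <= rawSS * 1e-20 | ss == 0
}

#' Batched covariate-adjusted linear regression over a gene x CpG block
#'
#' For every (gene k, CpG j) pair, fits expression on
#' `[intercept, covariates, methylation]` and reports the methylation
#' coefficient. All pairs in the block are fitted at once: expression and
#' methylation rows are residualized against the design, after which the
#' coefficient is a ratio of cross-products —
#' `est = <y_res, M_res> / ||M_res||^2`,
#' `se = sqrt(RSS / df) / ||M_res||` with `df = n - m - 2`,
#' `t = est / se`, and `p` from [gaussianTwoSidedP()]. This is numerically
#' equivalent to fitting each full model separately (Frisch-Waugh-Lovell).
#'
#' CpG rows with zero residual variance (e.g. constant methylation) produce
#' NaN sentinels for every gene and are logged, never an error.
#'
#' @param exprBlock genes x samples matrix (rows of the expression matrix).
#' @param methBlock CpG loci x samples matrix.
#' @param design a [DesignBlock-class] from [validateDesign()].
#' @param withCovariates also compute per-covariate-term estimates,
#'   standard errors, t and p (including the intercept), recovered from the
#'   partitioned full-model fit.
#' @return a list of class `eqtmResultBlock`: `gene_ids`, `cpg_ids`, `df`,
#'   and genes x CpGs matrices `est`, `se`, `t`, `p` (plus
#'   `cov_<name>_<stat>` matrices when `withCovariates = TRUE`).
#' @export
batchedMlr <- function(exprBlock, methBlock, design, withCovariates = FALSE) {
  stopifnot(is(design, "DesignBlock"))
  n <- nrow(design@base)
  m <- ncol(design@base) - 1L
  df <- n - m - 2L
  Yr <- residualize(exprBlock, design)
  Mr <- residualize(methBlock, design)
  sy2 <- rowSums(Yr * Yr)
  sm2 <- rowSums(Mr * Mr)
  degen <- .degenerateRows(sm2, rowSums(methBlock * methBlock))
  if (any(degen))
    for (id in rownames(methBlock)[degen])
      eqtmLog("degenerate methylation locus (zero residual variance): ", id)
  sm2[degen] <- NaN
  cross <- .rowwiseCross(Yr, Mr)                    # genes x cpgs
  est <- sweep(cross, 2L, sm2, "/")
  rss <- pmax(sy2 - sweep(cross^2, 2L, sm2, "/"), 0)
  se <- sqrt(sweep(rss / df, 2L, sm2, "/"))
  tst <- est / se
  res <- list(gene_ids = rownames(exprBlock), cpg_ids = rownames(methBlock),
              est = est, se = se, t = tst, p = gaussianTwoSidedP(tst),
              df = df, degenerate_cpgs = rownames(methBlock)[degen])
  if (withCovariates) {
    A <- chol2inv(chol(crossprod(design@base)))     # (m+1) x (m+1)
    By <- A %*% crossprod(design@base, t(exprBlock))  # (m+1) x genes
    Bm <- A %*% crossprod(design@base, t(methBlock))  # (m+1) x cpgs
    sigma2 <- rss / df                              # genes x cpgs
    nms <- c("intercept", colnames(design@base)[-1L])
    for (i in seq_len(m + 1L)) {
      cEst <- outer(By[i, ], rep(1, ncol(est))) - sweep(est, 2L, Bm[i, ], "*")
      varFac <- A[i, i] + sweep(matrix(1, nrow(est), ncol(est)), 2L,
                                Bm[i, ]^2 / sm2, "*")
      cSe <- sqrt(sigma2 * varFac)
      cT <- cEst / cSe
      dimnames(cEst) <- dimnames(cSe) <- dimnames(cT) <- dimnames(est)
      res[[paste0("cov_", nms[i], "_est")]] <- cEst
      res[[paste0("cov_", nms[i], "_se")]] <- cSe
      res[[paste0("cov_", nms[i], "_t")]] <- cT
      res[[paste0("cov_", nms[i], "_p")]] <- gaussianTwoSidedP(cT)
    }
  }
  class(res) <- "eqtmResultBlock"
  res
}

#' Pearson correlation over a gene x CpG block
#'
#' Computes the Pearson correlation between every expression row and
#' methylation row, with `t = r * sqrt((n-2) / (1-r^2))`, a two-sided
#' Gaussian p-value, and `se = sqrt((1-r^2) / (n-2))` kept for column
#' compatibility with the regression output. No covariate adjustment is
#' performed in this mode. `|r| = 1` saturates `t` at a fixed 1e8 sentinel
#' with `p = 0`; zero-variance rows on either side yield NaN sentinels and
#' are logged.
#'
#' @inheritParams batchedMlr
#' @return an `eqtmResultBlock` list; `est` holds r and `df = n - 2`.
#' @export
pearsonBlock <- function(exprBlock, methBlock) {
  n <- ncol(exprBlock)
  if (n < 3L) stopf("need at least 3 samples for a correlation p-value, got %d", n)
  if (ncol(methBlock) != n) stopf("sample dimension mismatch between blocks")
  Yc <- exprBlock - rowMeans(exprBlock)
  Mc <- methBlock - rowMeans(methBlock)
  sy2 <- rowSums(Yc * Yc)
  sm2 <- rowSums(Mc * Mc)
  degenY <- .degenerateRows(sy2, rowSums(exprBlock^2))
  degenM <- .degenerateRows(sm2, rowSums(methBlock^2))
  for (id in rownames(exprBlock)[degenY])
    eqtmLog("degenerate expression locus (zero variance): ", id)
  for (id in rownames(methBlock)[degenM])
    eqtmLog("degenerate methylation locus (zero variance): ", id)
  sy2[degenY] <- NaN
  sm2[degenM] <- NaN
  r <- .rowwiseCross(Yc, Mc) / sqrt(outer(sy2, sm2))
  r <- pmin(pmax(r, -1), 1)
  sat <- abs(r) == 1
  tst <- r * sqrt((n - 2) / (1 - r^2))
  tst[sat & !is.na(r)] <- sign(r[sat & !is.na(r)]) * PEARSON_T_SATURATION
  p <- gaussianTwoSidedP(tst)
  p[sat & !is.na(r)] <- 0
  se <- sqrt((1 - r^2) / (n - 2))
  res <- list(gene_ids = rownames(exprBlock), cpg_ids = rownames(methBlock),
              est = r, se = se, t = tst, p = p, df = n - 2L,
              degenerate_cpgs = rownames(methBlock)[degenM])
  class(res) <- "eqtmResultBlock"
  res
}
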