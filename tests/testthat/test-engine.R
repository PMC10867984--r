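test_that("device selection honors requests and reports CPU threads", {
  dev <- selectDevice("cpu", cpuThreads = 4)
  expect_identical(dev$type, "cpu")
  expect_identical(dev$threads, 4L)
  expect_identical(selectDevice("auto")$type, "cpu")
  expect_error(selectDevice("accelerator"), "accelerator requested but none")
  expect_error(selectDevice("cpu", cpuThreads = 0), "positive integer")
})

test_that("genes-per-chunk estimate reproduces its closed-form cost model", {
  n <- 1000; C <- 100000; m <- 3; b <- 4; budget <- 6.2e9
  got <- estimateGenesPerChunk(n, C, m, b, budget)
  # independent evaluation of the documented formula
  overhead <- 1.25
  expected <- floor((budget / (b * overhead) - 2 * n * C - n * (m + 2)) /
                    (2 * n + 4 * C))
  expect_equal(got, as.integer(expected))
  expect_gte(got, 1)
  # the returned count's working set actually fits the budget
  ws <- b * overhead * (2 * n * got + 2 * n * C + 4 * got * C + n * (m + 2))
  expect_lte(ws, budget)
})

test_that("genes-per-chunk is monotone in the budget and errors when nothing fits", {
  est1 <- estimateGenesPerChunk(500, 1000, 2, 8, 1e8)
  est2 <- estimateGenesPerChunk(500, 1000, 2, 8, 2e8)
  expect_gte(est2, est1)
  expect_error(estimateGenesPerChunk(500, 1000, 2, 8, 1e4),
               "below the single-gene working set; need at least")
})

test_that("chunk plans tile the grid exactly once", {
  plan <- planChunks(250, 90, geneChunk = 100, cpgChunk = 40)
  expect_equal(plan$geneStarts, c(1L, 101L, 201L))
  expect_equal(plan$geneEnds, c(100L, 200L, 250L))
  expect_equal(plan$cpgStarts, c(1L, 41L, 81L))
  expect_equal(plan$nBlocks, 9L)
  # tiling identity: block areas sum to the grid size, no overlap
  areas <- outer(plan$geneEnds - plan$geneStarts + 1L,
                 plan$cpgEnds - plan$cpgStarts + 1L)
  expect_equal(sum(areas), 250 * 90)

  one <- planChunks(10, 20, geneChunk = 100, cpgChunk = 100)
  expect_equal(one$nBlocks, 1L)

  auto <- planChunks(50, 200, nSamples = 30, mCovariates = 2)
  expect_equal(sum(outer(auto$geneEnds - auto$geneStarts + 1L,
                         auto$cpgEnds - auto$cpgStarts + 1L)), 50 * 200)
})

test_that("a full run accounts for every pair and honors the p filter", {
  fx <- makeDummyDataset(30, 10, 20, nCovariates = 2, seed = 31)
  out <- tempfile(fileext = ".csv")
  s <- runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
                  mode = mappingMode("all", pMax = NA), outputPath = out)
  expect_equal(s$pairsTested, 200)
  expect_equal(s$rowsWritten, 200L)
  expect_equal(s$degenerateLoci, 0L)
  r <- read.csv(out)
  expect_equal(nrow(r), 200L)
  # oracle: per-pair filter count at a lenient threshold
  thr <- 0.05
  oracleCount <- 0L
  for (k in rownames(exprValues(fx$ds))) for (j in rownames(methValues(fx$ds))) {
    o <- lmPairOracle(exprValues(fx$ds)[k, ], methValues(fx$ds)[j, ],
                      covValues(fx$ds))
    if (gaussianTwoSidedP(o$t) < thr) oracleCount <- oracleCount + 1L
  }
  s2 <- runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
                   mode = mappingMode("all", pMax = NA), pMax = thr,
                   outputPath = out)
  expect_equal(as.integer(s2$rowsWritten), oracleCount)
  expect_lte(s2$rowsWritten, s2$pairsTested)
})

test_that("results are invariant to the chunk decomposition and thread count", {
  fx <- makeDummyDataset(40, 15, 33, nCovariates = 1, seed = 32)
  readSorted <- function(f) {
    r <- read.csv(f, colClasses = "character")
    r[order(r$gene_id, r$cpg_id), ]
  }
  files <- character(0)
  for (cfg in list(c(1, 1), c(7, 13), c(1000, 1000))) {
    f <- tempfile(fileext = ".csv")
    runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
               mode = mappingMode("all", pMax = NA),
               geneChunk = cfg[1], cpgChunk = cfg[2], outputPath = f)
    files <- c(files, f)
  }
  f4 <- tempfile(fileext = ".csv")
  runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
             mode = mappingMode("all", pMax = NA), cpuThreads = 4,
             outputPath = f4)
  ref <- readSorted(files[1])
  for (f in c(files[-1], f4))
    expect_identical(readSorted(f), ref)
  # and byte-identical files for identical settings
  expect_identical(readLines(files[3]), readLines(f4))
})

test_that("modal runs only evaluate and write the selected pairs", {
  fx <- makeDummyDataset(25, 8, 40, seed = 33)
  sel <- enumeratePairs(fx$raw$geneAnnot, fx$raw$cpgAnnot,
                        rownames(exprValues(fx$ds)),
                        rownames(methValues(fx$ds)), mappingMode("trans"))
  out <- tempfile(fileext = ".csv")
  s <- runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
                  mode = mappingMode("trans", pMax = NA),
                  geneChunk = 3, cpgChunk = 11, outputPath = out)
  expect_equal(s$pairsTested, pairCount(sel))
  got <- read.csv(out)
  want <- selectionPairs(sel)
  expect_identical(got$gene_id, unname(want[, 1]))
  expect_identical(got$cpg_id, unname(want[, 2]))
})

test_that("per-covariate columns round-trip through the writer", {
  fx <- makeDummyDataset(30, 4, 6, nCovariates = 2, seed = 34)
  out <- tempfile(fileext = ".csv")
  runMapping(fx$ds, fx$raw$geneAnnot, fx$raw$cpgAnnot,
             mode = mappingMode("all", pMax = NA),
             columns = c("est", "p", "cov_cov1_est", "cov_cov1_p"),
             outputPath = out)
  r <- read.csv(out)
  expect_identical(colnames(r),
                   c("gene_id", "cpg_id", "est", "p", "cov_cov1_est", "cov_cov1_p"))
  # spot-check one pair against lm()
  X <- covValues(fx$ds)
  fit <- summary(stats::lm(exprValues(fx$ds)[2, ] ~ X + methValues(fx$ds)[3, ]))
  row <- r[r$gene_id == "gene00002" & r$cpg_id == "cpg000003", ]
  expect_equal(row$cov_cov1_est, fit$coefficients["Xcov1", 1], tolerance = 1e-6)
})
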