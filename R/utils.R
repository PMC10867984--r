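#' @importFrom methods new validObject is
#' @importFrom stats pnorm rnorm runif complete.cases
#' @importFrom utils read.csv read.table write.table
NULL

# Internal logging. Levels: 0 silent, 1 info (default), 2 debug.
# Controlled by options(eqtmMapper.verbose = <level>).
eqtmLog <- function(..., level = 1L) {
  opt <- getOption("eqtmMapper.verbose", 1L)
  if (opt >= level) message("[eqtmMapper] ", ...)
  invisible(NULL)
}

# Saturation value for the Pearson t statistic at |r| = 1. Fixed so that
# outputs are deterministic; the associated p-value is exactly 0.
PEARSON_T_SATURATION <- 1e8

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
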