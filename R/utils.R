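#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
"_PACKAGE"

#' Deterministically derive child seeds from a master seed
#'
#' Simulation batches, calibration and dose sweeps all draw their per-run
#' seeds through this helper so that a single master seed pins down every
#' stream in a pipeline. Child seeds are sampled without replacement from
#' the positive 32-bit integers.
#'
#' @param master_seed single integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1L)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise maximum of a numeric matrix without extra dependencies.
row_max <- function(m) do.call(pmax, as.data.frame(m))

# Row-wise cumulative sums for a small number of columns (alternatives).
row_cumsum <- function(m) {
  k <- ncol(m)
  u <- matrix(0, k, k)
  u[upper.tri(u, diag = TRUE)] <- 1
  m %*% u
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cashdose_config_error", "error")))
}
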