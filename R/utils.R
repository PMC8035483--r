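#' @useDynLib connsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov lm pchisq pf pt qnorm rbinom rnorm runif
#'   anova coef pnorm sd setNames vcov complete.cases
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; edge counts at a sparsity
#' threshold use the half-up convention so that e.g. 400.5 candidate edges
#' become 401.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' A fixed polynomial hash of the key string, initialised with the master
#' seed, reduced modulo 2^31 - 1. Per-subject (and per grid point) seeds are
#' derived this way so results do not depend on cohort ordering or on how
#' work is split across processes.
#'
#' @param master_seed integer master seed.
#' @param key character scalar identifying the consumer (e.g. a subject id).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, length(key) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h + 1)
}

#' Trapezoidal integral of a metric curve over a sparsity grid
#'
#' @param curve numeric vector of metric values, one per grid point.
#' @param grid a sparsity grid from [sparsity_grid()], or a numeric vector of
#'   abscissae.
#' @return scalar area under the curve.
#' @examples
#' g <- sparsity_grid(0.1, 0.34, 0.01)
#' curve_auc(rep(2, length(g$points)), g)  # 0.48 = 2 * 0.24
#' @export
curve_auc <- function(curve, grid) {
  x <- if (is.list(grid)) grid$points else grid
  if (length(x) < 2L) stop("AUC needs a grid with at least 2 points")
  if (length(curve) != length(x)) stop("curve length must equal grid size")
  sum(diff(x) * (curve[-length(curve)] + curve[-1]) / 2)
}

assert_square_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > tol) stop(what, " must be symmetric")
  invisible(TRUE)
}
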