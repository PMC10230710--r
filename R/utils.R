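## Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Stop with a consistent error class so callers/tests can target it.
qtlmed_stop <- function(msg, class = "qtlmed_error") {
  stop(structured_condition(msg, c(class, "qtlmed_error")))
}

structured_condition <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-2)))
}

## Residualize columns of `m` (vector or matrix) against design W via QR.
## W must include the intercept explicitly if wanted.
project_out <- function(m, W) {
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    qtlmed_stop("rank-deficient covariate design", "qtlmed_rank_error")
  }
  as.matrix(qr.resid(qrW, as.matrix(m)))
}

## Build [intercept | covariates] design, validating dimensions.
covariate_design <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) {
    qtlmed_stop("covariates and phenotype have different sample counts")
  }
  if (anyNA(covariates)) qtlmed_stop("covariates contain missing values")
  cbind(1, covariates)
}

## Standardize to mean 0, sd 1; constant vectors become all zeros.
standardize <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

#' Derive deterministic child seeds from one master seed
#'
#' Used by every staged computation so that a single master seed fixes all
#' sources of randomness; child seeds stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x > 0
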