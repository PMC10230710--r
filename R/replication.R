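## Cross-dataset replication statistics: Storey's pi1 with a bootstrap CI,
## allelic sign-concordance, and donor down-sampling.

#' Storey's pi1 replication statistic
#'
#' Estimates the fraction of non-null associations among a vector of
#' replication p-values. `pi0(lambda) = #\{p > lambda\} / (n (1 - lambda))`
#' on the grid; the final pi0 is a natural cubic spline (3 df) through
#' `pi0(lambda)` evaluated at the maximum lambda, clamped to [0, 1]
#' (`smoother = FALSE` uses the grid mean instead); `pi1 = 1 - pi0`. A
#' percentile bootstrap over the p-values gives the 95% CI.
#'
#' @param p Replication p-values (n >= 20 recommended for a stable
#'   smoother).
#' @param storey_lambda Lambda grid, default `seq(0.2, 0.8, 0.1)` (the
#'   trans-replication convention is `seq(0.1, max(p), 0.05)`).
#' @param n_boot Bootstrap resamples (default 1000; 0 disables the CI).
#' @param smoother Use the spline smoother (default) or the grid mean.
#' @param seed Optional seed for the bootstrap.
#' @return One-row data.frame of class `pi1_result`: `pi1`, `pi0`,
#'   `ci_lower`, `ci_upper`, `n_pairs`.
#' @export
storey_pi1 <- function(p, storey_lambda = seq(0.2, 0.8, 0.1),
                       n_boot = 1000, smoother = TRUE, seed = NULL) {
  if (any(p < 0 | p > 1)) qtlmed_stop("p-values outside [0, 1]")
  if (any(storey_lambda <= 0 | storey_lambda >= 1)) {
    qtlmed_stop("storey_lambda grid must lie strictly inside (0, 1)")
  }
  storey_lambda <- sort(unique(storey_lambda))
  point <- function(pv) {
    pi0_l <- vapply(storey_lambda,
                    function(l) mean(pv > l) / (1 - l), numeric(1))
    pi0 <- if (smoother && length(storey_lambda) >= 4) {
      sp <- stats::smooth.spline(storey_lambda, pi0_l, df = 3)
      stats::predict(sp, x = max(storey_lambda))$y
    } else {
      mean(pi0_l)
    }
    min(max(pi0, 0), 1)
  }
  pi0 <- point(p)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot),
                    function(b) 1 - point(sample(p, replace = TRUE)),
                    numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  out <- data.frame(pi1 = 1 - pi0, pi0 = pi0,
                    ci_lower = ci[1], ci_upper = ci[2],
                    n_pairs = length(p))
  class(out) <- c("pi1_result", class(out))
  out
}

#' Allelic sign concordance across a triplet table
#'
#' Fraction of triplets whose X->M and X->Y effect estimates share a sign.
#' Zero or non-finite betas are excluded and counted.
#'
#' @param triplets data.frame with `beta_xm` and `beta_xy`.
#' @return List: `fraction`, `n_used`, `n_excluded`.
#' @export
sign_concordance <- function(triplets) {
  ok <- is.finite(triplets$beta_xm) & is.finite(triplets$beta_xy) &
    triplets$beta_xm != 0 & triplets$beta_xy != 0
  frac <- if (any(ok)) {
    mean(sign(triplets$beta_xm[ok]) == sign(triplets$beta_xy[ok]))
  } else NA_real_
  list(fraction = frac, n_used = sum(ok), n_excluded = sum(!ok))
}

#' Down-sample donors consistently across a dataset
#'
#' Draws a uniform donor subset without replacement and subsets every
#' matrix/vector in the dataset by the same rows, e.g. to equalize sample
#' sizes between two cell types before comparing discovery power.
#'
#' @param dataset Named list of vectors/matrices/data.frames whose first
#'   dimension is donors.
#' @param n_target Target donor count (<= available).
#' @param seed Integer seed.
#' @return The subset dataset with attribute `"donors"` (the rows kept).
#' @export
downsample_donors <- function(dataset, n_target, seed = 1L) {
  n <- NROW(dataset[[1]])
  if (n_target > n) qtlmed_stop("n_target exceeds available donors")
  set.seed(seed)
  keep <- sort(sample.int(n, n_target))
  out <- lapply(dataset, function(el) {
    if (is.null(dim(el))) el[keep] else el[keep, , drop = FALSE]
  })
  attr(out, "donors") <- keep
  out
}
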