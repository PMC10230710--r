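## Regression-based mediation comparator: conditional association of the
## variant with the outcome given the (residualized) mediator, calibrated
## against a permutation null of decoy mediators summarized by a
## generalized extreme value (GEV) fit.

#' Least-squares residualization against covariates
#'
#' @param values Vector (or matrix of columns) to residualize.
#' @param covariates Covariate matrix (an intercept is added).
#' @return Residual vector/matrix, orthogonal to the covariates.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  W <- covariate_design(nrow(v), covariates)
  res <- project_out(v, W)
  if (is.vector(values)) drop(res) else res
}

#' Conditional p-value of the variant given the mediator
#'
#' Two-sided p-value of the X coefficient in
#' `Y ~ X + Z_Y + M_residualized`. A large conditional p indicates that the
#' mediator absorbs the variant's effect on the outcome — the signature of
#' mediation.
#'
#' @param y Outcome vector.
#' @param x Variant dosage.
#' @param covariates_y Covariates of the outcome model (`Z_Y`).
#' @param m_residualized Mediator already residualized against its own
#'   covariates (`Z_M`), see [residualize()].
#' @return Scalar p-value (1 when the design is degenerate, e.g. the
#'   mediator collinear with the variant beyond tolerance).
#' @export
conditional_pvalue <- function(y, x, covariates_y = NULL, m_residualized) {
  fit_qtl(y, x, covariates = covariates_y,
          extra_conditioning = m_residualized)$p_nominal
}

## ---- generalized extreme value distribution ------------------------------

#' GEV cumulative distribution function
#' @param q Quantiles.
#' @param loc,scale,shape Location, scale (> 0) and shape parameters
#'   (shape = 0 is the Gumbel limit).
#' @return CDF values.
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-9) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- ifelse(t > 0, exp(-t^(-1 / shape)),
                ifelse(shape > 0, 0, 1))
  out
}

#' GEV density
#' @inheritParams pgev
#' @param x Evaluation points.
#' @return Density values (0 outside the support).
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) {
    return(exp(-z - exp(-z)) / scale)
  }
  t <- 1 + shape * z
  ifelse(t > 0, t^(-1 / shape - 1) * exp(-t^(-1 / shape)) / scale, 0)
}

#' Maximum-likelihood GEV fit
#'
#' Nelder-Mead over (location, log scale, shape), started from Gumbel
#' moment estimates. Used to summarize permutation maxima.
#'
#' @param x Sample (e.g. per-permutation maximum conditional p-values).
#' @return List of class `gev_fit`: `loc`, `scale`, `shape`, `converged`,
#'   `n`, `loglik`.
#' @export
fit_gev <- function(x) {
  stopifnot(length(x) >= 20)
  s0 <- stats::sd(x) * sqrt(6) / pi
  if (!is.finite(s0) || s0 <= 0) s0 <- 1e-6
  start <- c(mean(x) - 0.5772 * s0, log(s0), 0.1)
  nll <- function(par) {
    d <- dgev(x, par[1], exp(par[2]), par[3])
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  opt <- tryCatch(stats::optim(start, nll, method = "Nelder-Mead",
                               control = list(maxit = 2000)),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
    return(structure(list(loc = NA_real_, scale = NA_real_,
                          shape = NA_real_, converged = FALSE,
                          n = length(x), loglik = NA_real_),
                     class = "gev_fit"))
  }
  structure(list(loc = opt$par[1], scale = exp(opt$par[2]),
                 shape = opt$par[3],
                 converged = opt$convergence == 0,
                 n = length(x), loglik = -opt$value),
            class = "gev_fit")
}

#' Permutation-GEV family-wise mediation test for one triplet
#'
#' The observed statistic is the conditional p-value of X given the true
#' mediator. The null is built by conditioning on decoy mediators (e.g.
#' chromatin peaks from another chromosome): per permutation the decoy set
#' is sample-index-permuted, the conditional p-value is computed for every
#' decoy, and the maximum (least significant) is recorded. A GEV is fitted
#' to the permutation maxima and the FWER-controlled mediation p-value is
#' the upper-tail probability `1 - GEV_CDF(observed)`.
#'
#' @param y Outcome vector.
#' @param x Variant dosage.
#' @param m_residualized True-mediator values residualized by `Z_M`.
#' @param decoys Samples x decoys matrix of decoy mediators (already
#'   residualized by `Z_M`); 10 decoy regions by default upstream.
#' @param covariates_y Covariates of the outcome model.
#' @param n_perm Number of permutations (default 1000, >= 100 required).
#' @param seed Integer seed for the permutation draws.
#' @param alpha Significance level (default 0.05).
#' @param triplet_id Optional label.
#' @return One-row data.frame: `triplet_id`, `p_conditional_observed`,
#'   `fwer_p`, `significant`, `gev_converged`.
#' @export
permutation_gev_fwer <- function(y, x, m_residualized, decoys,
                                 covariates_y = NULL, n_perm = 1000,
                                 seed = 1L, alpha = 0.05,
                                 triplet_id = NA_character_) {
  if (n_perm < 100) qtlmed_stop("n_perm must be >= 100")
  decoys <- as.matrix(decoys)
  if (ncol(decoys) < 1) qtlmed_stop("at least one decoy mediator required")
  n <- length(y)
  W0 <- covariate_design(n, covariates_y)
  qrW <- qr(W0)
  yr <- qr.resid(qrW, y)
  xr <- qr.resid(qrW, x)
  dr <- qr.resid(qrW, decoys)
  df <- n - ncol(W0) - 2  # + mediator + x
  cond_p <- function(yv, xv, mv) {
    smm <- sum(mv^2)
    if (smm < 1e-12) return(1)
    xv2 <- xv - mv * (sum(mv * xv) / smm)
    yv2 <- yv - mv * (sum(mv * yv) / smm)
    sxx <- sum(xv2^2)
    if (sxx < 1e-10 * max(1, sum(xv^2))) return(1)
    beta <- sum(xv2 * yv2) / sxx
    resid <- yv2 - beta * xv2
    se <- sqrt(sum(resid^2) / df / sxx)
    2 * stats::pt(-abs(beta / se), df)
  }
  p_obs <- conditional_pvalue(y, x, covariates_y, m_residualized)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    max(vapply(seq_len(ncol(dr)), function(k) {
      mv <- qr.resid(qrW, dr[idx, k])
      cond_p(yr, xr, mv)
    }, numeric(1)))
  }, numeric(1))
  gev <- fit_gev(maxima)
  if (is.na(gev$loc)) {
    message("GEV fit failed; falling back to the empirical tail proportion")
    fwer_p <- mean(maxima >= p_obs)
  } else {
    fwer_p <- 1 - pgev(p_obs, gev$loc, gev$scale, gev$shape)
  }
  data.frame(triplet_id = triplet_id, p_conditional_observed = p_obs,
             fwer_p = fwer_p, significant = fwer_p < alpha,
             gev_converged = isTRUE(gev$converged),
             stringsAsFactors = FALSE)
}
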