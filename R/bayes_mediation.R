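## Bayesian model selection over causal DAG configurations for X-M-Y triplets.
##
## A triplet consists of a genetic variant X (dosage, analysed on the -1/0/1
## scale), a candidate mediator phenotype M (e.g. chromatin accessibility of a
## peak) and an outcome phenotype Y (e.g. gene expression). Twelve causal
## configurations are scored, each a pair of conjugate Bayesian linear
## regressions whose marginal likelihoods are available in closed form.

#' Prior hyperparameters for Bayesian mediation model selection
#'
#' @param phi2 Numeric length-3 vector of prior effect sizes on the
#'   odds-of-PVE scale (`odds = pve / (1 - pve)`, so `phi2 = 1` corresponds to
#'   a prior guess of 50% variance explained) for, in order, the X->M edge,
#'   the M-Y mediation edge (either direction), and the X->Y edge.
#' @param kappa,lambda_scale Degrees of freedom and scale of the scaled
#'   inverse-chi-square prior on the residual variance of each regression.
#'   The defaults `(0.001, 0.001)` are non-informative.
#' @param tau Numeric length-2 vector: prior variance multipliers (times the
#'   residual variance) for the intercept and for covariate coefficients.
#'   The large defaults `(1000, 1000)` are effectively flat.
#' @param model_prior_mode `"complete"` restricts the model set to the eight
#'   non-reactive configurations (reactive causality deemed implausible a
#'   priori, e.g. when the variant sits inside the mediator peak);
#'   `"reactive"` allows all twelve.
#' @param reactive_rule How the reactive classification sum is formed:
#'   `"partial_reactive"` (default) sums complete-reactive + partial-reactive;
#'   `"literal"` sums complete-reactive + partial-mediation.
#' @return An object of class `mediation_priors`.
#' @export
mediation_priors <- function(phi2 = c(1, 1, 1),
                             kappa = 0.001,
                             lambda_scale = 0.001,
                             tau = c(1000, 1000),
                             model_prior_mode = c("complete", "reactive"),
                             reactive_rule = c("partial_reactive", "literal")) {
  model_prior_mode <- match.arg(model_prior_mode)
  reactive_rule <- match.arg(reactive_rule)
  stopifnot(length(phi2) == 3, all(phi2 > 0),
            kappa > 0, lambda_scale > 0,
            length(tau) == 2, all(tau > 0))
  structure(list(phi2 = as.numeric(phi2), kappa = kappa,
                 lambda_scale = lambda_scale, tau = as.numeric(tau),
                 model_prior_mode = model_prior_mode,
                 reactive_rule = reactive_rule),
            class = "mediation_priors")
}

#' The twelve causal DAG configurations
#'
#' Each configuration is described by three switches: whether X enters the
#' M-equation, the state of the mediation edge between M and Y (absent,
#' M->Y, or Y->M), and whether X enters the Y-equation.
#'
#' @return A data.frame with columns `label`, `x_to_m`, `med`, `x_to_y` and
#'   `reactive` (whether the mediation edge points Y->M).
#' @export
causal_models <- function() {
  m <- expand.grid(x_to_m = c(FALSE, TRUE),
                   x_to_y = c(FALSE, TRUE),
                   med = c("none", "m_to_y", "y_to_m"),
                   stringsAsFactors = FALSE)
  key <- paste(m$x_to_m, m$med, m$x_to_y)
  labels <- c(
    "FALSE none FALSE"   = "no-effects",
    "TRUE none FALSE"    = "x->m only",
    "FALSE m_to_y FALSE" = "m->y only",
    "FALSE none TRUE"    = "x->y only",
    "TRUE m_to_y FALSE"  = "complete mediation",
    "TRUE none TRUE"     = "co-local",
    "FALSE m_to_y TRUE"  = "x->y + m->y",
    "TRUE m_to_y TRUE"   = "partial mediation",
    "FALSE y_to_m FALSE" = "y->m only",
    "FALSE y_to_m TRUE"  = "complete reactive",
    "TRUE y_to_m FALSE"  = "x->m + y->m",
    "TRUE y_to_m TRUE"   = "partial reactive")
  m$label <- unname(labels[key])
  m$reactive <- m$med == "y_to_m"
  m[, c("label", "x_to_m", "med", "x_to_y", "reactive")]
}

#' Closed-form log marginal likelihood of one conjugate Bayesian regression
#'
#' The model is `w = X b + e`, `e ~ N(0, sigma2 I)`, `b_j ~ N(0, sigma2 d_j)`
#' independently, and `sigma2` scaled-inverse-chi-square(`kappa`, `lambda`).
#' Both the coefficients and the residual variance are integrated out
#' analytically, yielding a multivariate-t marginal.
#'
#' @param w Response vector.
#' @param design Design matrix (including any intercept column).
#' @param prior_var Per-column prior variance multipliers `d_j` (length
#'   `ncol(design)`).
#' @param kappa,lambda_scale Residual-variance prior hyperparameters.
#' @return The log marginal likelihood (a scalar).
#' @export
marginal_log_likelihood <- function(w, design, prior_var,
                                    kappa = 0.001, lambda_scale = 0.001) {
  design <- as.matrix(design)
  n <- length(w)
  stopifnot(nrow(design) == n, length(prior_var) == ncol(design),
            all(prior_var > 0), kappa > 0, lambda_scale > 0)
  a0 <- kappa / 2
  b0 <- kappa * lambda_scale / 2
  G <- crossprod(design) + diag(1 / prior_var, ncol(design))
  cG <- tryCatch(chol(G), error = function(e)
    qtlmed_stop("singular penalized Gram matrix", "qtlmed_singular_error"))
  Xty <- crossprod(design, w)
  bhat <- backsolve(cG, forwardsolve(t(cG), Xty))
  ssr <- sum(w^2) - sum(Xty * bhat)
  ## Guard tiny negative from rounding.
  ssr <- max(ssr, 0)
  an <- a0 + n / 2
  bn <- b0 + ssr / 2
  -0.5 * n * log(2 * pi) -
    0.5 * (sum(log(prior_var)) + 2 * sum(log(diag(cG)))) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
}

## Log marginal likelihood of one structural equation of a DAG model.
## response: already standardized; effects: list of named effect columns with
## their phi2 entries; W: centered covariate matrix (may be NULL).
equation_logml <- function(response, effect_cols, effect_phi2, covariates,
                           priors) {
  n <- length(response)
  design <- matrix(1, n, 1)
  prior_var <- priors$tau[1]
  if (!is.null(covariates) && ncol(covariates) > 0) {
    design <- cbind(design, covariates)
    prior_var <- c(prior_var, rep(priors$tau[2], ncol(covariates)))
  }
  if (length(effect_cols) > 0) {
    for (i in seq_along(effect_cols)) {
      col <- effect_cols[[i]]
      v <- stats::var(col)
      if (!is.finite(v) || v <= 0) {
        ## Monomorphic effect column: contributes prior-only normalization
        ## through a negligible-variance column guard.
        v <- .Machine$double.eps
      }
      design <- cbind(design, col)
      ## phi2 is on the odds-of-PVE scale for a unit-variance response:
      ## prior E[b^2] * Var(col) / sigma2 = phi2.
      prior_var <- c(prior_var, effect_phi2[i] / v)
    }
  }
  marginal_log_likelihood(response, design, prior_var,
                          kappa = priors$kappa,
                          lambda_scale = priors$lambda_scale)
}

#' Posterior over the twelve causal models for one X-M-Y triplet
#'
#' Factorizes the joint likelihood of (M, Y) according to each DAG: for
#' forward-type models `p(m | parents) * p(y | parents)`, for reactive-type
#' models `p(y | parents) * p(m | parents, y)`. Each factor is a conjugate
#' Bayesian regression scored in closed form; the posterior over models is
#' the prior-weighted softmax of the joint log marginal likelihoods.
#'
#' @param x Genotype dosage vector coded 0/1/2 or -1/0/1 (re-encoded to
#'   -1/0/1 internally).
#' @param m,y Mediator and outcome phenotype vectors (standardized
#'   internally).
#' @param covariates_m,covariates_y Optional covariate matrices for the M-
#'   and Y-equations (the caQTL and eQTL covariates respectively).
#' @param priors A [mediation_priors()] object.
#' @return An object of class `model_posterior`: a list with `posterior`
#'   (named probabilities over the allowed models; excluded models are
#'   exactly 0), `log_marginal` (per-model joint log marginal likelihoods),
#'   `classification` (one of `"forward"`, `"reactive"`, `"independence"`,
#'   `"other"`), `posterior_forward_sum` and `posterior_reactive_sum`.
#' @export
posterior_over_models <- function(x, m, y,
                                  covariates_m = NULL, covariates_y = NULL,
                                  priors = mediation_priors()) {
  stopifnot(inherits(priors, "mediation_priors"))
  n <- length(x)
  if (length(m) != n || length(y) != n) {
    qtlmed_stop("x, m, y must share sample order and length")
  }
  if (anyNA(x) || anyNA(m) || anyNA(y)) {
    qtlmed_stop("complete cases required (missing values found)")
  }
  x <- encode_dosage(x)
  n_cov <- max(if (is.null(covariates_m)) 0 else ncol(as.matrix(covariates_m)),
               if (is.null(covariates_y)) 0 else ncol(as.matrix(covariates_y)))
  if (n < n_cov + 3 + 1) {
    qtlmed_stop(sprintf(
      "n = %d samples too few for %d covariates plus triplet effects",
      n, n_cov))
  }
  ms <- standardize(m)
  ys <- standardize(y)
  Zm <- prep_covariates(covariates_m, n)
  Zy <- prep_covariates(covariates_y, n)

  models <- causal_models()
  allowed <- if (priors$model_prior_mode == "complete") !models$reactive
             else rep(TRUE, nrow(models))
  phi2 <- priors$phi2
  logml <- rep(NA_real_, nrow(models))
  for (i in seq_len(nrow(models))) {
    if (!allowed[i]) next
    mod <- models[i, ]
    if (mod$med == "y_to_m") {
      ## reactive factorization p(y | X) p(m | X, Y)
      ll_y <- equation_logml(ys,
                             if (mod$x_to_y) list(x) else list(),
                             phi2[3], Zy, priors)
      eff <- list(); ph <- numeric(0)
      if (mod$x_to_m) { eff <- c(eff, list(x)); ph <- c(ph, phi2[1]) }
      eff <- c(eff, list(ys)); ph <- c(ph, phi2[2])
      ll_m <- equation_logml(ms, eff, ph, Zm, priors)
    } else {
      ## forward factorization p(m | X) p(y | X, M)
      ll_m <- equation_logml(ms,
                             if (mod$x_to_m) list(x) else list(),
                             phi2[1], Zm, priors)
      eff <- list(); ph <- numeric(0)
      if (mod$x_to_y) { eff <- c(eff, list(x)); ph <- c(ph, phi2[3]) }
      if (mod$med == "m_to_y") { eff <- c(eff, list(ms)); ph <- c(ph, phi2[2]) }
      ll_y <- equation_logml(ys, eff, ph, Zy, priors)
    }
    logml[i] <- ll_m + ll_y
  }

  ## Uniform prior over the allowed set.
  lp <- logml[allowed]
  w <- exp(lp - max(lp))
  post <- rep(0, nrow(models))
  post[allowed] <- w / sum(w)
  names(post) <- models$label
  names(logml) <- models$label

  p_fwd <- post[["complete mediation"]] + post[["partial mediation"]]
  p_rxn <- if (priors$reactive_rule == "literal") {
    post[["complete reactive"]] + post[["partial mediation"]]
  } else {
    post[["complete reactive"]] + post[["partial reactive"]]
  }
  classification <- if (p_fwd > 0.5) "forward"
    else if (p_rxn > 0.5) "reactive"
    else if (names(post)[which.max(post)] == "co-local") "independence"
    else "other"

  structure(list(posterior = post, log_marginal = logml,
                 classification = classification,
                 posterior_forward_sum = unname(p_fwd),
                 posterior_reactive_sum = unname(p_rxn),
                 n = n, priors = priors),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Bayesian mediation model posterior (n =", x$n, ")\n")
  print(round(x$posterior, 4))
  cat("classification:", x$classification,
      sprintf("(forward sum %.3f, reactive sum %.3f)\n",
              x$posterior_forward_sum, x$posterior_reactive_sum))
  invisible(x)
}

## Re-encode dosage to -1/0/1 (accepts 0/1/2 or already-centered input).
encode_dosage <- function(x) {
  x <- as.numeric(x)
  if (all(x >= 0) && max(x) > 1) x - 1 else x
}

prep_covariates <- function(z, n) {
  if (is.null(z)) return(NULL)
  z <- as.matrix(z)
  if (nrow(z) != n) qtlmed_stop("covariate rows do not match sample count")
  ## Center and unit-scale so tau stays interpretable across covariates.
  apply(z, 2, standardize)
}

#' Positional mediation scan
#'
#' Substitutes each candidate mediator (e.g. every chromatin peak within
#' +/- 1 Mb of the outcome gene's TSS) into the triplet and recomputes the
#' model posterior, to test the specificity of a mediation call.
#'
#' @param x,y Variant dosage and outcome phenotype.
#' @param mediators Matrix (samples x candidates) of candidate mediator
#'   phenotypes, with column names.
#' @param positions Optional numeric vector of candidate genomic positions
#'   used to sort the output for plotting.
#' @param covariates_m,covariates_y,priors Passed to
#'   [posterior_over_models()].
#' @return A data.frame with one row per candidate: `candidate`, `position`,
#'   the forward/reactive posterior sums, and the classification.
#' @export
mediation_scan <- function(x, y, mediators, positions = NULL,
                           covariates_m = NULL, covariates_y = NULL,
                           priors = mediation_priors()) {
  mediators <- as.matrix(mediators)
  if (ncol(mediators) < 1) qtlmed_stop("at least one candidate mediator required")
  ids <- colnames(mediators) %||% paste0("cand_", seq_len(ncol(mediators)))
  res <- lapply(seq_len(ncol(mediators)), function(j) {
    po <- posterior_over_models(x, mediators[, j], y,
                                covariates_m = covariates_m,
                                covariates_y = covariates_y, priors = priors)
    data.frame(candidate = ids[j],
               position = if (is.null(positions)) NA_real_ else positions[j],
               posterior_forward_sum = po$posterior_forward_sum,
               posterior_reactive_sum = po$posterior_reactive_sum,
               classification = po$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(positions)) out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical-Bayes grid selection of the phi2 hyperparameters
#'
#' For each phi2 grid point, sums over a collection of triplets the log of
#' the prior-weighted total evidence (the model-averaged marginal
#' likelihood), and reports the maximizing grid point(s).
#'
#' @param triplet_data List of triplets, each a list with elements `x`, `m`,
#'   `y` and optional `covariates_m`, `covariates_y`.
#' @param phi2_grid Matrix or data.frame with three columns (one phi2 vector
#'   per row, odds scale).
#' @param priors Baseline priors; phi2 is overridden per grid point.
#' @return A list with `grid` (data.frame of phi2 values and the summed log
#'   evidence) and `argmax` (row indices attaining the maximum).
#' @export
select_phi2 <- function(triplet_data, phi2_grid,
                        priors = mediation_priors(model_prior_mode = "reactive")) {
  phi2_grid <- as.matrix(phi2_grid)
  stopifnot(length(triplet_data) > 0, nrow(phi2_grid) > 0,
            ncol(phi2_grid) == 3)
  total <- numeric(nrow(phi2_grid))
  for (g in seq_len(nrow(phi2_grid))) {
    pg <- priors
    pg$phi2 <- as.numeric(phi2_grid[g, ])
    total[g] <- sum(vapply(triplet_data, function(tr) {
      po <- posterior_over_models(tr$x, tr$m, tr$y,
                                  covariates_m = tr$covariates_m,
                                  covariates_y = tr$covariates_y,
                                  priors = pg)
      lm <- po$log_marginal[is.finite(po$log_marginal)]
      ## log of model-averaged evidence under the uniform model prior
      mx <- max(lm)
      mx + log(mean(exp(lm - mx)))
    }, numeric(1)))
  }
  grid <- data.frame(phi2_xm = phi2_grid[, 1], phi2_my = phi2_grid[, 2],
                     phi2_xy = phi2_grid[, 3], sum_log_evidence = total)
  list(grid = grid, argmax = which(total == max(total)))
}
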