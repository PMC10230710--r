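## Measurement-error model: ICC estimation from technical replicates and
## the flip-threshold simulation that identifies causal calls vulnerable to
## direction flipping when the mediator-side phenotype is noisy.

#' Intraclass correlation from technical replicates
#'
#' One-way random-effects ICC(1) from the one-way ANOVA decomposition:
#' `(MSB - MSW) / (MSB + (k0 - 1) MSW)` where `k0` is the
#' harmonic-adjusted mean replicate count
#' `(N - sum(k_i^2)/N) / (n_donors - 1)`. May be negative when
#' within-donor variability exceeds between-donor variability.
#'
#' @param replicates data.frame with columns `donor`, `value` (and
#'   optionally `replicate`); donors with a single measurement contribute
#'   to the grand mean only through their one value.
#' @param feature_id Optional label carried into the result.
#' @return A one-row data.frame: `feature_id`, `icc`,
#'   `n_donors_with_replicates`, `mean_replicates`.
#' @export
estimate_icc <- function(replicates, feature_id = NA_character_) {
  stopifnot(all(c("donor", "value") %in% names(replicates)))
  counts <- table(replicates$donor)
  if (length(counts) < 2) qtlmed_stop("ICC undefined with a single donor")
  if (sum(counts >= 2) < 2) {
    qtlmed_stop("ICC requires >= 2 donors with >= 2 replicates")
  }
  N <- nrow(replicates)
  k <- as.numeric(counts)
  n_donors <- length(k)
  grand <- mean(replicates$value)
  donor_means <- tapply(replicates$value, replicates$donor, mean)
  ssb <- sum(k * (donor_means - grand)^2)
  ssw <- sum((replicates$value - donor_means[as.character(replicates$donor)])^2)
  msb <- ssb / (n_donors - 1)
  msw <- ssw / (N - n_donors)
  k0 <- (N - sum(k^2) / N) / (n_donors - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  data.frame(feature_id = feature_id, icc = icc,
             n_donors_with_replicates = sum(k >= 2),
             mean_replicates = mean(k[k >= 2]),
             stringsAsFactors = FALSE)
}

#' Simulate the ICC threshold at which a causal model flips direction
#'
#' Generates a triplet with the stated true causal direction and edge PVEs,
#' injects Gaussian measurement error on the chromatin-side phenotype M
#' (the mediator under forward truth; the chain endpoint under reactive
#' truth) across an ICC grid, runs the twelve-model Bayesian selection
#' (reactive priors) at every grid point, fits local-linear
#' (tricube-weighted) regressions of the forward-sum and reactive-sum
#' posteriors against realized ICC, and reports the ICC at which the two
#' fitted curves cross. A crossing is accepted only when the two fitted
#' curves exchange dominance cleanly — above the candidate one curve rises
#' while the other falls — so noise-level wiggles between two negligible
#' posteriors are not called flips. Under forward truth this is the ICC
#' below which the (wrong) reactive model dominates; under reactive truth
#' an accepted crossing marks a reactive-to-forward flip. The whole
#' procedure is repeated `n_reps` times and accepted thresholds are
#' averaged.
#'
#' @param pve_a PVE of the X -> proximal-node edge (X->M under forward
#'   truth; X->Y under reactive truth).
#' @param pve_b PVE of the mediation edge (M->Y under forward truth; Y->M
#'   under reactive truth). Under complete mediation the total variance of
#'   the distal node explained by X is `pve_a * pve_b`.
#' @param direction `"forward"` or `"reactive"` truth.
#' @param n_samples Donors per replicate (default 75).
#' @param icc_grid ICC grid; default 20 evenly spaced points in (0.05, 1].
#' @param n_reps Number of simulation repetitions averaged (default 10).
#' @param priors Priors for the model selection; reactive mode is required
#'   so both directions compete.
#' @param maf Variant minor allele frequency (default 0.5).
#' @param span Local regression span (default 0.75).
#' @param seed Integer seed; fixes all repetitions.
#' @param slope_rule `"diverge"` (default) accepts a crossing when the two
#'   fitted curves part monotonically above it in either orientation;
#'   `"recover"` additionally requires the correct model to be the rising
#'   one; `"literal"` requires the wrong model to be the rising one.
#' @param error_on Which phenotype receives the measurement error: `"m"`
#'   (default, the chromatin phenotype in both directions) or the
#'   symmetric `"y"` pathway.
#' @return A list of class `flip_threshold`: `icc_threshold` (averaged, or
#'   NA when no repetition produced an accepted crossing), `per_rep`
#'   thresholds, `direction`, `pve_a`, `pve_b`, `n_reps`, and the last
#'   repetition's fitted curves for plotting.
#' @export
simulate_flip_threshold <- function(pve_a, pve_b,
                                    direction = c("forward", "reactive"),
                                    n_samples = 75,
                                    icc_grid = seq(0.05, 1, length.out = 20),
                                    n_reps = 10,
                                    priors = mediation_priors(model_prior_mode = "reactive"),
                                    maf = 0.5, span = 0.75, seed = 1L,
                                    slope_rule = c("diverge", "recover", "literal"),
                                    error_on = c("m", "y")) {
  direction <- match.arg(direction)
  slope_rule <- match.arg(slope_rule)
  error_on <- match.arg(error_on)
  stopifnot(pve_a > 0, pve_a < 1, pve_b > 0, pve_b < 1,
            all(icc_grid > 0), all(icc_grid <= 1))
  if (priors$model_prior_mode != "reactive") {
    qtlmed_stop("flip simulation needs reactive-mode priors (all 12 models)")
  }
  seeds <- derive_seeds(seed, n_reps)
  thresholds <- rep(NA_real_, n_reps)
  curves <- NULL
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    n <- n_samples
    x <- stats::rbinom(n, 2L, maf)
    xc <- x - 1
    var_x <- 2 * maf * (1 - maf)
    a <- sqrt(pve_a / var_x)
    b <- sqrt(pve_b)
    ## causal chain X -> proximal -> distal; under forward truth the
    ## proximal node is M and the distal is Y, under reactive truth the
    ## proximal node is Y and the distal is M
    proximal <- a * xc + stats::rnorm(n, 0, sqrt(1 - pve_a))
    distal <- b * proximal + stats::rnorm(n, 0, sqrt(1 - pve_b))
    m_true <- if (direction == "forward") proximal else distal
    y_true <- if (direction == "forward") distal else proximal
    noisy <- if (error_on == "m") m_true else y_true
    v_true <- stats::var(noisy)
    rec <- data.frame(icc = numeric(0), p_fwd = numeric(0), p_rxn = numeric(0))
    for (icc in icc_grid) {
      obs <- if (icc >= 1) noisy else {
        noisy + stats::rnorm(n, 0, sqrt(v_true * (1 - icc) / icc))
      }
      realized <- v_true / stats::var(obs)
      po <- if (error_on == "m") {
        posterior_over_models(x, obs, y_true, priors = priors)
      } else {
        posterior_over_models(x, m_true, obs, priors = priors)
      }
      rec <- rbind(rec, data.frame(icc = min(realized, 1),
                                   p_fwd = po$posterior_forward_sum,
                                   p_rxn = po$posterior_reactive_sum))
    }
    fit <- fit_flip_curves(rec, span)
    thresholds[r] <- find_crossing(fit, direction, slope_rule)
    curves <- fit
  }
  found <- thresholds[!is.na(thresholds)]
  structure(list(icc_threshold = if (length(found)) mean(found) else NA_real_,
                 per_rep = thresholds, direction = direction,
                 pve_a = pve_a, pve_b = pve_b, n_reps = n_reps,
                 icc_grid = icc_grid, curves = curves),
            class = "flip_threshold")
}

## Local-linear tricube-weighted fits of both posterior sums vs ICC,
## evaluated on a fine prediction grid to avoid discretization bias at the
## crossing.
fit_flip_curves <- function(rec, span, n_fine = 200L) {
  grid <- seq(min(rec$icc), max(rec$icc), length.out = n_fine)
  safe_loess <- function(y) {
    fit <- tryCatch(
      stats::loess(y ~ icc, data = cbind(rec, y = y), span = span,
                   degree = 1, family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) return(rep(NA_real_, length(grid)))
    pmin(pmax(stats::predict(fit, data.frame(icc = grid)), 0), 1)
  }
  data.frame(icc = grid,
             fwd = safe_loess(rec$p_fwd),
             rxn = safe_loess(rec$p_rxn))
}

## Crossing of the fitted curves with the slope acceptance rule: the
## candidate is the interpolated root of (correct - wrong); it is accepted
## when, over the ICC range above it (trend assessed by a least-squares
## slope of the fitted curve), the correct-direction curve rises and the
## wrong-direction curve falls. The smallest accepted crossing is the flip
## threshold (the ICC below which the wrong model dominates).
find_crossing <- function(fit, direction, slope_rule, window = Inf,
                          dominance_margin = 0.1) {
  if (anyNA(fit$fwd) || anyNA(fit$rxn)) return(NA_real_)
  correct <- if (direction == "forward") fit$fwd else fit$rxn
  wrong <- if (direction == "forward") fit$rxn else fit$fwd
  if (max(correct) - min(correct) < 1e-6 && max(wrong) - min(wrong) < 1e-6) {
    message("flip simulation: degenerate (constant) posterior curves")
    return(NA_real_)
  }
  d <- correct - wrong
  k <- length(d)
  flips <- which(d[-k] * d[-1] < 0 | d[-k] == 0)
  if (length(flips) == 0) return(NA_real_)
  region_slope <- function(v, idx) {
    hi <- which(fit$icc <= fit$icc[idx] + window & fit$icc >= fit$icc[idx])
    if (length(hi) < 3) hi <- idx:min(idx + 2L, k)
    unname(stats::coef(stats::lm(v[hi] ~ fit$icc[hi]))[2])
  }
  for (i in flips) {
    cand <- fit$icc[i] +
      (fit$icc[i + 1] - fit$icc[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
    s_correct <- region_slope(correct, i)
    s_wrong <- region_slope(wrong, i)
    ok <- switch(slope_rule,
      diverge = (s_correct > 0 && s_wrong < 0) ||
                (s_wrong > 0 && s_correct < 0),
      recover = s_correct > 0 && s_wrong < 0,
      literal = s_wrong > 0 && s_correct < 0)
    if (!ok) next
    ## materiality on the high-ICC side only: there posteriors are well
    ## resolved, so a real flip shows material dominance; on the low-ICC
    ## side measurement noise suppresses every mediator-bearing model and
    ## dominance is inherently relative
    if (s_correct < 0 &&
        max(wrong[i:k] - correct[i:k]) < dominance_margin) next
    return(cand)
  }
  NA_real_
}

#' @export
print.flip_threshold <- function(x, ...) {
  cat(sprintf("ICC flip threshold (%s truth, PVE_A = %.2f, PVE_B = %.2f):\n",
              x$direction, x$pve_a, x$pve_b))
  if (is.na(x$icc_threshold)) cat("  no accepted crossing found\n")
  else cat(sprintf("  %.3f (averaged over %d/%d repetitions)\n",
                   x$icc_threshold, sum(!is.na(x$per_rep)), x$n_reps))
  invisible(x)
}

#' Filter classified triplets by measurement reliability
#'
#' Excludes (1) any triplet with non-positive (or missing) ICC on either
#' phenotype, and (2) reactive-classified triplets whose chromatin
#' (mediator-side) ICC falls below the triplet's flip threshold. Forward
#' calls are not threshold-filtered: forward-to-reactive flipping removes
#' forward calls, so surviving forward calls at positive ICC are not the
#' artifact this filter targets.
#'
#' @param triplets data.frame with `classification` and id columns.
#' @param icc_m,icc_y Named numeric vectors of ICC per mediator / outcome
#'   feature (names matched against `m_feature_id` / `y_feature_id`).
#' @param thresholds Optional named numeric vector of per-triplet flip
#'   thresholds (names matched against
#'   `paste(x_variant_id, m_feature_id, y_feature_id)`).
#' @return A list with `retained` (triplet subset) and `excluded`
#'   (data.frame of dropped triplets with a `reason` column).
#' @export
filter_triplets <- function(triplets, icc_m, icc_y, thresholds = NULL) {
  reasons <- rep(NA_character_, nrow(triplets))
  key <- paste(triplets$x_variant_id, triplets$m_feature_id,
               triplets$y_feature_id)
  for (i in seq_len(nrow(triplets))) {
    im <- icc_m[triplets$m_feature_id[i]]
    iy <- icc_y[triplets$y_feature_id[i]]
    if (is.na(im) || is.na(iy)) {
      reasons[i] <- "no replicate data"
    } else if (im <= 0 || iy <= 0) {
      reasons[i] <- "non-positive ICC"
    } else if (identical(triplets$classification[i], "reactive") &&
               !is.null(thresholds) && !is.na(thresholds[key[i]]) &&
               im < thresholds[key[i]]) {
      reasons[i] <- "chromatin ICC below flip threshold"
    }
  }
  drop <- !is.na(reasons)
  excluded <- triplets[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reasons[drop]
  for (r in which(drop)) {
    message("filter_triplets: dropped ", key[r], " (", reasons[r], ")")
  }
  list(retained = triplets[!drop, , drop = FALSE], excluded = excluded)
}

#' Sweep the PVE grid for reactive-to-forward flipping
#'
#' Runs [simulate_flip_threshold()] under reactive truth at every
#' combination of the PVE grid and reports, per grid point, how many
#' repetitions produced an accepted reactive-to-forward crossing. A grid
#' point counts as flipping when a majority of its repetitions do — a
#' reproducible phenomenon rather than a single-draw accident. The summary
#' value is the smallest PVE (the binding min of the pair) at any flipping
#' grid point, or the grid maximum when no point flips (the flip boundary
#' then lies above the sweep).
#'
#' @param pve_grid PVE values swept for both edges (default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.95)`).
#' @param n_samples,n_reps,priors,maf,span,seed As in
#'   [simulate_flip_threshold()]; `n_reps` defaults to 5 per grid point.
#' @return List: `flips` (matrix of per-point flip counts), `n_reps`,
#'   `min_flip_pve` (the reported boundary value).
#' @export
flip_boundary_sweep <- function(pve_grid = c(0.1, 0.3, 0.5, 0.7, 0.95),
                                n_samples = 75, n_reps = 5,
                                priors = mediation_priors(model_prior_mode = "reactive"),
                                maf = 0.5, span = 0.75, seed = 1L) {
  k <- length(pve_grid)
  seeds <- derive_seeds(seed, k * k)
  flips <- matrix(0L, k, k,
                  dimnames = list(pve_a = pve_grid, pve_b = pve_grid))
  idx <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      idx <- idx + 1L
      ft <- simulate_flip_threshold(pve_grid[i], pve_grid[j],
                                    direction = "reactive",
                                    n_samples = n_samples, n_reps = n_reps,
                                    priors = priors, maf = maf, span = span,
                                    seed = seeds[idx])
      flips[i, j] <- sum(!is.na(ft$per_rep))
    }
  }
  detected <- which(flips > n_reps / 2, arr.ind = TRUE)
  min_flip_pve <- if (nrow(detected) > 0) {
    min(pmin(pve_grid[detected[, 1]], pve_grid[detected[, 2]]))
  } else {
    max(pve_grid)
  }
  list(flips = flips, n_reps = n_reps, min_flip_pve = min_flip_pve)
}
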