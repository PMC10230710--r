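## Synthetic genotype/phenotype generator with planted causal architectures.
##
## Every downstream stage of the package is exercised against data produced
## here, where the true causal structure (forward, reactive, independence,
## or any of the twelve DAG configurations) is known, effect sizes are set
## by proportion-of-variance-explained (PVE) targets, and measurement noise
## is controlled through target intraclass correlations (ICC).

#' Describe a synthetic genome layout
#'
#' Coordinates are 0-based half-open internally (BED convention).
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param peaks data.frame with columns `peak_id`, `chrom`, `start`, `end`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `is_tf`, `is_pseudogene`.
#' @return A validated object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, peaks, genes) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("peak_id", "chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (is.null(genes$is_tf)) genes$is_tf <- FALSE
  if (is.null(genes$is_pseudogene)) genes$is_pseudogene <- FALSE
  if (anyDuplicated(peaks$peak_id)) qtlmed_stop("duplicate peak_ids")
  if (anyDuplicated(genes$gene_id)) qtlmed_stop("duplicate gene_ids")
  if (any(peaks$start >= peaks$end)) qtlmed_stop("peak start must be < end")
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(peaks$end > len[peaks$chrom]) || any(peaks$start < 0)) {
    qtlmed_stop("peaks outside chromosome bounds")
  }
  if (any(genes$tss >= len[genes$chrom]) || any(genes$tss < 0)) {
    qtlmed_stop("gene TSS outside chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, peaks = peaks, genes = genes),
            class = "genome_layout")
}

#' Specify one planted triplet architecture
#'
#' @param true_model One of the twelve labels from [causal_models()], or the
#'   aliases `"forward"` (= complete mediation), `"reactive"` (= complete
#'   reactive) and `"independence"` (= co-local).
#' @param pve_a Fraction of mediator variance explained by X (X->M edge for
#'   forward-type models; X->Y edge for reactive-type models).
#' @param pve_b Fraction of outcome variance explained by the mediator along
#'   the M-Y edge (M->Y for forward, Y->M for reactive).
#' @param pve_c Fraction of outcome variance explained directly by X.
#' @param maf Minor allele frequency of X in (0, 0.5]. Default 0.5, the
#'   most-informative balanced case.
#' @param n_samples Number of donors.
#' @param icc_m,icc_y Target intraclass correlations of the observed
#'   mediator/outcome (1 = no measurement error).
#' @param n_replicate_donors Donors receiving technical replicates.
#' @param n_replicates Replicate draws per replicated donor (>= 2).
#' @param fix_sign If TRUE all planted effects are positive; by default each
#'   edge's sign is drawn at random.
#' @return An object of class `synthetic_architecture`.
#' @export
synthetic_architecture <- function(true_model = "complete mediation",
                                   pve_a = 0.3, pve_b = 0.3, pve_c = 0,
                                   maf = 0.5, n_samples = 75,
                                   icc_m = 1, icc_y = 1,
                                   n_replicate_donors = 0, n_replicates = 3,
                                   fix_sign = FALSE) {
  aliases <- c(forward = "complete mediation",
               reactive = "complete reactive",
               independence = "co-local")
  if (true_model %in% names(aliases)) true_model <- aliases[[true_model]]
  if (!true_model %in% causal_models()$label) {
    qtlmed_stop(paste("unknown true_model:", true_model))
  }
  pves <- c(pve_a, pve_b, pve_c)
  if (any(pves < 0) || any(pves >= 1)) qtlmed_stop("PVE values must lie in [0, 1)")
  if (pve_b + pve_c >= 1) qtlmed_stop("pve_b + pve_c must be < 1")
  if (maf <= 0 || maf > 0.5) qtlmed_stop("maf must lie in (0, 0.5]")
  if (icc_m <= 0 || icc_m > 1 || icc_y <= 0 || icc_y > 1) {
    qtlmed_stop("ICC targets must lie in (0, 1]")
  }
  if (!is_count(n_samples) || n_samples < 2) qtlmed_stop("n_samples must be >= 2")
  structure(list(true_model = true_model, pve_a = pve_a, pve_b = pve_b,
                 pve_c = pve_c, maf = maf, n_samples = n_samples,
                 icc_m = icc_m, icc_y = icc_y,
                 n_replicate_donors = n_replicate_donors,
                 n_replicates = n_replicates, fix_sign = fix_sign),
            class = "synthetic_architecture")
}

#' Simulate biallelic genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn binomial(2, maf) per sample. When `ld_block_r2` is
#' given, variants within a block are generated by correlated copying at the
#' haplotype level: each haplotype allele is copied from the previous
#' variant with probability `sqrt(ld_block_r2)` and redrawn otherwise, so
#' adjacent variants have expected r^2 near the target.
#'
#' @param n_samples Number of samples (>= 2).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `maf`.
#' @param ld_block_r2 Optional target squared correlation between adjacent
#'   variants within a block.
#' @param block_size Number of consecutive variants per LD block.
#' @param seed Integer seed; fixed seed fixes the output exactly.
#' @return Integer matrix samples x variants of 0/1/2 dosages with variant
#'   ids as column names; `variants` attached as attribute `"variants"`.
#' @export
generate_genotypes <- function(n_samples, variants, ld_block_r2 = NULL,
                               block_size = nrow(variants), seed = 1L) {
  if (!is_count(n_samples) || n_samples < 2) {
    qtlmed_stop("n_samples must be a positive integer >= 2")
  }
  stopifnot(all(c("id", "chrom", "pos", "maf") %in% names(variants)))
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    qtlmed_stop("maf must lie in (0, 0.5]")
  }
  set.seed(seed)
  v <- nrow(variants)
  h1 <- matrix(0L, n_samples, v)
  h2 <- matrix(0L, n_samples, v)
  copy_p <- if (is.null(ld_block_r2)) 0 else sqrt(ld_block_r2)
  for (j in seq_len(v)) {
    p <- variants$maf[j]
    fresh1 <- stats::rbinom(n_samples, 1L, p)
    fresh2 <- stats::rbinom(n_samples, 1L, p)
    new_block <- is.null(ld_block_r2) || (j - 1) %% block_size == 0
    if (new_block || j == 1) {
      h1[, j] <- fresh1; h2[, j] <- fresh2
    } else {
      keep1 <- stats::rbinom(n_samples, 1L, copy_p) == 1L
      keep2 <- stats::rbinom(n_samples, 1L, copy_p) == 1L
      h1[, j] <- ifelse(keep1, h1[, j - 1], fresh1)
      h2[, j] <- ifelse(keep2, h2[, j - 1], fresh2)
    }
  }
  g <- h1 + h2
  colnames(g) <- variants$id
  attr(g, "variants") <- variants
  g
}

## Solve an effect size from a PVE target: beta^2 * var_x / var_total = pve,
## with var_total the intended unit variance of the response.
pve_beta <- function(pve, var_x) if (pve == 0) 0 else sqrt(pve / var_x)

#' Generate one X-M-Y triplet with a planted causal structure
#'
#' Phenotypes are built from unit-variance structural components: each edge
#' coefficient is solved from its PVE target, residual noise absorbs the
#' remaining variance. Measurement error is added so that
#' `Var(true) / Var(observed)` equals the target ICC, and technical
#' replicate tables re-draw the same error model per replicate.
#'
#' @param arch A [synthetic_architecture()].
#' @param covariates Optional sample x covariate matrix whose columns are
#'   added (unit coefficient) to both phenotypes.
#' @param seed Integer seed.
#' @return A list with `x` (dosage 0/1/2), `m_true`, `y_true`, `m_obs`,
#'   `y_obs`, `replicates_m`, `replicates_y` (long data.frames with columns
#'   donor, replicate, value), the drawn effect signs, and `arch`.
#' @export
generate_triplet_data <- function(arch, covariates = NULL, seed = 1L) {
  stopifnot(inherits(arch, "synthetic_architecture"))
  if (arch$icc_m <= 0 || arch$icc_y <= 0) qtlmed_stop("ICC of 0 is not allowed")
  set.seed(seed)
  n <- arch$n_samples
  mod <- causal_models()
  mod <- mod[mod$label == arch$true_model, ]
  x <- stats::rbinom(n, 2L, arch$maf)
  xc <- x - 1  # -1/0/1 encoding used in the structural equations
  var_x <- 2 * arch$maf * (1 - arch$maf)
  sgn <- if (arch$fix_sign) c(1, 1, 1) else sample(c(-1, 1), 3, replace = TRUE)
  a <- sgn[1] * pve_beta(arch$pve_a, var_x)    # X -> mediator-proximal node
  b <- sgn[2] * pve_beta(arch$pve_b, 1)        # mediation edge
  cc <- sgn[3] * pve_beta(arch$pve_c, var_x)   # direct X -> outcome

  if (!mod$reactive) {
    ## forward-type: M = aX + e ; Y = bM + cX + e
    a_eff <- if (mod$x_to_m) a else 0
    b_eff <- if (mod$med == "m_to_y") b else 0
    c_eff <- if (mod$x_to_y) cc else 0
    m_true <- a_eff * xc + stats::rnorm(n, 0, sqrt(1 - ifelse(mod$x_to_m, arch$pve_a, 0)))
    resid_y <- 1 - ifelse(mod$med == "m_to_y", arch$pve_b, 0) -
      ifelse(mod$x_to_y, arch$pve_c, 0)
    y_true <- b_eff * m_true + c_eff * xc + stats::rnorm(n, 0, sqrt(resid_y))
  } else {
    ## reactive-type: Y = aX + e ; M = bY + cX + e  (Y mediates X -> M)
    a_eff <- if (mod$x_to_y) a else 0
    b_eff <- b
    c_eff <- if (mod$x_to_m) cc else 0
    y_true <- a_eff * xc + stats::rnorm(n, 0, sqrt(1 - ifelse(mod$x_to_y, arch$pve_a, 0)))
    resid_m <- 1 - arch$pve_b - ifelse(mod$x_to_m, arch$pve_c, 0)
    m_true <- b_eff * y_true + c_eff * xc + stats::rnorm(n, 0, sqrt(resid_m))
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    m_true <- m_true + rowSums(covariates)
    y_true <- y_true + rowSums(covariates)
  }
  m_obs <- add_measurement_error(m_true, arch$icc_m)
  y_obs <- add_measurement_error(y_true, arch$icc_y)
  reps <- make_replicates(m_true, y_true, arch)
  list(x = x, m_true = m_true, y_true = y_true,
       m_obs = m_obs, y_obs = y_obs,
       replicates_m = reps$m, replicates_y = reps$y,
       signs = sgn, arch = arch)
}

## Gaussian measurement error with analytically-set variance:
## err_var = Var(true) * (1 - icc) / icc  =>  Var(true)/Var(obs) ~ icc.
add_measurement_error <- function(true_values, icc) {
  if (icc >= 1) return(true_values)
  ev <- stats::var(true_values) * (1 - icc) / icc
  true_values + stats::rnorm(length(true_values), 0, sqrt(ev))
}

make_replicates <- function(m_true, y_true, arch) {
  if (arch$n_replicate_donors < 2) return(list(m = NULL, y = NULL))
  donors <- sort(sample.int(arch$n_samples, arch$n_replicate_donors))
  draw <- function(true_values, icc) {
    ev <- if (icc >= 1) 0 else stats::var(true_values) * (1 - icc) / icc
    do.call(rbind, lapply(donors, function(d) {
      data.frame(donor = d,
                 replicate = seq_len(arch$n_replicates),
                 value = true_values[d] +
                   stats::rnorm(arch$n_replicates, 0, sqrt(ev)))
    }))
  }
  list(m = draw(m_true, arch$icc_m), y = draw(y_true, arch$icc_y))
}

#' Plant motif consensus sequences into random peak sequences
#'
#' Peak sequences are i.i.d. uniform over A/C/G/T; the PWM consensus (the
#' per-position maximum-weight base) is inserted at a random offset in
#' exactly `round(planted_fraction * n_peaks)` peaks.
#'
#' @param pwm A PWM as returned by [read_jaspar()] or any 4 x width numeric
#'   matrix with rownames A, C, G, T.
#' @param peaks data.frame with `peak_id`, `start`, `end` (half-open).
#' @param planted_fraction Fraction of peaks receiving a consensus planting.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame peak_id, offset (0-based), strand).
#' @export
generate_motif_instances <- function(pwm, peaks, planted_fraction, seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1)
  width <- ncol(pwm)
  lens <- peaks$end - peaks$start
  if (width > min(lens)) qtlmed_stop("PWM wider than the shortest peak")
  set.seed(seed)
  consensus <- pwm_consensus(pwm)
  n_plant <- round(planted_fraction * nrow(peaks))
  planted <- if (n_plant > 0) sort(sample.int(nrow(peaks), n_plant)) else integer(0)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- sample(bases, lens[i], replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- peaks$peak_id
  truth <- data.frame(peak_id = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  for (i in planted) {
    off <- sample.int(lens[i] - width + 1L, 1L) - 1L
    substr(seqs[i], off + 1L, off + width) <- consensus
    truth <- rbind(truth, data.frame(peak_id = peaks$peak_id[i],
                                     offset = off, strand = "+",
                                     stringsAsFactors = FALSE))
  }
  list(sequences = seqs, truth = truth)
}

#' Simulate GWAS summary statistics with a planted causal variant
#'
#' A GWAS cohort of `n_gwas` samples is formed by resampling rows of the
#' supplied genotype panel with replacement (preserving allele frequencies
#' and LD), a quantitative trait is generated so the causal variant explains
#' `trait_pve` of its variance, and marginal per-variant OLS summary
#' statistics are returned.
#'
#' @param genotypes Samples x variants dosage matrix with column names.
#' @param causal_variant Column name of the causal variant ("" for a pure
#'   null trait).
#' @param trait_pve Fraction of trait variance explained by the causal
#'   variant (0 gives a null GWAS).
#' @param n_gwas GWAS cohort size.
#' @param seed Integer seed.
#' @return data.frame with columns `variant`, `beta`, `se`, `p`.
#' @export
generate_gwas_stats <- function(genotypes, causal_variant, trait_pve,
                                n_gwas, seed = 1L) {
  genotypes <- as.matrix(genotypes)
  if (trait_pve > 0 && !causal_variant %in% colnames(genotypes)) {
    qtlmed_stop(paste("unknown causal variant:", causal_variant))
  }
  set.seed(seed)
  rows <- sample.int(nrow(genotypes), n_gwas, replace = TRUE)
  G <- genotypes[rows, , drop = FALSE]
  if (trait_pve > 0) {
    g <- G[, causal_variant]
    vg <- stats::var(g)
    beta <- if (vg > 0) sqrt(trait_pve / ((1 - trait_pve) * vg)) else 0
    trait <- beta * g + stats::rnorm(n_gwas)
  } else {
    trait <- stats::rnorm(n_gwas)
  }
  out <- lapply(colnames(G), function(v) {
    r <- fit_qtl(trait, G[, v])
    data.frame(variant = v, beta = r$beta, se = r$se, p = r$p_nominal,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
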