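## LD-threshold conditional colocalization of QTL signals with GWAS loci.

#' Squared LD correlation between two dosage vectors
#'
#' @param a,b Genotype dosage vectors on the same samples.
#' @return Squared Pearson correlation.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) qtlmed_stop("dosage vectors differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    qtlmed_stop("LD r2 undefined for a monomorphic variant")
  }
  stats::cor(a, b)^2
}

#' Define LD-independent GWAS index variants
#'
#' Greedy selection by ascending p-value among genome-wide-significant
#' variants (p < `p_threshold`), discarding candidates with r^2 at or above
#' `r2_max` to any already-accepted index.
#'
#' @param gwas data.frame with `variant`, `p` (and optionally `position`).
#' @param genotypes Samples x variants dosage panel for LD (columns named).
#' @param p_threshold Genome-wide significance (default 5e-8).
#' @param r2_max Maximum pairwise LD among indices (default 0.2).
#' @return data.frame of index variants (possibly empty), ordered by p.
#' @export
define_gwas_index <- function(gwas, genotypes, p_threshold = 5e-8,
                              r2_max = 0.2) {
  cand <- gwas[gwas$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  keep <- character(0)
  for (v in cand$variant) {
    if (!v %in% colnames(genotypes)) next
    indep <- all(vapply(keep, function(k)
      ld_r2(genotypes[, v], genotypes[, k]) < r2_max, logical(1)))
    if (indep) keep <- c(keep, v)
  }
  out <- cand[match(keep, cand$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional colocalization test of a QTL signal with a GWAS index
#'
#' Computes LD between the QTL and GWAS index variants and refits the QTL
#' model with the GWAS index dosage as an additional covariate. The pair is
#' called colocalized when r^2 > `r2_min` and the conditional p-value of
#' the QTL variant rises above the discovery significance threshold
#' (attenuation rule). Identical variants (r^2 = 1 collinear) are
#' colocalized by definition and the conditional fit is skipped.
#'
#' @param phenotype Molecular phenotype vector.
#' @param qtl_variant,gwas_variant Column names in `genotypes`.
#' @param genotypes Samples x variants dosage panel.
#' @param covariates QTL model covariates.
#' @param p_discovery Significance threshold the QTL had to beat at
#'   discovery; the conditional p must exceed it for attenuation.
#' @param r2_min LD threshold (default 0.8).
#' @return One-row data.frame: `qtl_variant`, `gwas_variant`, `ld_r2`,
#'   `p_marginal`, `p_conditional`, `fold_attenuation`
#'   (log10 p ratio), `colocalized`.
#' @export
test_coloc <- function(phenotype, qtl_variant, gwas_variant, genotypes,
                       covariates = NULL, p_discovery = 1e-5,
                       r2_min = 0.8) {
  for (v in c(qtl_variant, gwas_variant)) {
    if (!v %in% colnames(genotypes)) qtlmed_stop(paste("variant not in panel:", v))
  }
  gq <- genotypes[, qtl_variant]
  gg <- genotypes[, gwas_variant]
  r2 <- ld_r2(gq, gg)
  marg <- fit_qtl(phenotype, gq, covariates = covariates)
  if (r2 > 1 - 1e-12) {
    message("GWAS index collinear with QTL variant; conditional fit skipped")
    return(data.frame(qtl_variant = qtl_variant, gwas_variant = gwas_variant,
                      ld_r2 = r2, p_marginal = marg$p_nominal,
                      p_conditional = NA_real_, fold_attenuation = NA_real_,
                      colocalized = TRUE, stringsAsFactors = FALSE))
  }
  cond <- fit_qtl(phenotype, gq, covariates = covariates,
                  extra_conditioning = gg)
  attenuated <- cond$degenerate || cond$p_nominal > p_discovery
  data.frame(qtl_variant = qtl_variant, gwas_variant = gwas_variant,
             ld_r2 = r2, p_marginal = marg$p_nominal,
             p_conditional = cond$p_nominal,
             fold_attenuation = log10(cond$p_nominal) - log10(marg$p_nominal),
             colocalized = r2 > r2_min && attenuated,
             stringsAsFactors = FALSE)
}
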