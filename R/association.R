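## Fixed-effect linear-model QTL engine.
##
## Cis caQTL/eQTL and trans scans are covariate-adjusted least squares on
## unrelated samples; the variant effect is tested with the usual t
## statistic (computed through Frisch-Waugh-Lovell projection, numerically
## identical to the full-design fit but fast enough for permutation loops).

#' Test one variant-phenotype association
#'
#' Fits `y ~ x + covariates (+ extra_conditioning)` by least squares and
#' returns the effect, standard error and two-sided p-value of `x`.
#'
#' @param y Phenotype vector.
#' @param x Genotype dosage vector (0/1/2).
#' @param covariates Optional sample x covariate matrix.
#' @param extra_conditioning Optional additional conditioning vectors
#'   (vector or matrix), e.g. a GWAS index variant or a mediator.
#' @param variant_id,feature_id Optional labels carried into the result.
#' @return A one-row data.frame (`qtl_result`): `variant_id`, `feature_id`,
#'   `beta`, `se`, `p_nominal`, `n_samples`, `degenerate`. Rank-deficient or
#'   monomorphic designs are flagged degenerate with the `p = 1` convention.
#' @export
fit_qtl <- function(y, x, covariates = NULL, extra_conditioning = NULL,
                    variant_id = NA_character_, feature_id = NA_character_) {
  n <- length(y)
  if (length(x) != n) qtlmed_stop("y and x must share sample order and length")
  W <- covariate_design(n, covariates)
  if (!is.null(extra_conditioning)) W <- cbind(W, as.matrix(extra_conditioning))
  if (n <= ncol(W) + 1) qtlmed_stop("too few samples for the design")
  qrW <- qr(W)
  degenerate <- FALSE
  beta <- se <- NA_real_
  p <- 1
  if (qrW$rank < ncol(W)) {
    degenerate <- TRUE
  } else {
    xr <- qr.resid(qrW, x)
    sxx <- sum(xr^2)
    ## monomorphic x, or x inside the conditioning span
    if (sxx < 1e-10 * max(1, sum(x^2))) {
      degenerate <- TRUE
    } else {
      yr <- qr.resid(qrW, y)
      beta <- sum(xr * yr) / sxx
      resid <- yr - beta * xr
      df <- n - ncol(W) - 1
      sigma2 <- sum(resid^2) / df
      se <- sqrt(sigma2 / sxx)
      tval <- beta / se
      p <- 2 * stats::pt(-abs(tval), df)
    }
  }
  data.frame(variant_id = variant_id, feature_id = feature_id,
             beta = beta, se = se, p_nominal = p, n_samples = n,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Effective number of independent tests in a cis window
#'
#' Counts the smallest number of leading eigenvalues of the variant
#' correlation matrix needed to explain at least `var_explained` of the
#' total variance — an eigenvalue-based surrogate for per-gene local
#' multiple-testing correction.
#'
#' @param genotypes Samples x variants dosage matrix for one feature's cis
#'   window.
#' @param var_explained Variance-explained level (default 0.99).
#' @return Integer `M_eff` in `[1, n_variants]`.
#' @export
effective_tests <- function(genotypes, var_explained = 0.99) {
  genotypes <- as.matrix(genotypes)
  v <- ncol(genotypes)
  if (v == 0) qtlmed_stop("at least one variant required")
  if (v == 1) return(1L)
  sds <- apply(genotypes, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) <= 1) return(1L)
  cc <- stats::cor(genotypes[, keep, drop = FALSE])
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= var_explained - 1e-12)[1])
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' @param p Vector of p-values.
#' @param level FDR level for the significance flags (5% for caQTL, 10% for
#'   the trans scan).
#' @return data.frame with `p`, `q` and `significant`.
#' @export
bh_fdr <- function(p, level = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) qtlmed_stop("p-values outside [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = q < level)
}

#' Hierarchical eGene multiple-testing correction
#'
#' Per gene, nominal p-values are locally adjusted by the effective-test
#' count (`p_local = min(1, p * m_eff)`); the top variant's locally adjusted
#' p per gene enters a Benjamini-Hochberg correction across genes; genes
#' with global q < `level` are flagged eGenes.
#'
#' @param results data.frame of per-variant results with columns
#'   `feature_id`, `variant_id`, `p_nominal`.
#' @param m_eff Named vector of effective test counts per feature (default
#'   1 for all).
#' @param level eGene FDR level (default 0.05).
#' @return data.frame, one row per gene: top variant, `p_local`, `q_global`,
#'   `egene` flag.
#' @export
hierarchical_egene_fdr <- function(results, m_eff = NULL, level = 0.05) {
  stopifnot(all(c("feature_id", "variant_id", "p_nominal") %in% names(results)))
  groups <- split(results, results$feature_id)
  rows <- lapply(names(groups), function(g) {
    gr <- groups[[g]]
    gr <- gr[is.finite(gr$p_nominal), , drop = FALSE]
    if (nrow(gr) == 0) {
      message("hierarchical_egene_fdr: empty group skipped: ", g)
      return(NULL)
    }
    me <- if (is.null(m_eff)) 1 else m_eff[[g]] %||% 1
    p_local <- pmin(1, gr$p_nominal * me)
    top <- which.min(p_local)
    data.frame(feature_id = g, variant_id = gr$variant_id[top],
               p_nominal = gr$p_nominal[top], m_eff = me,
               p_local = p_local[top], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q_global <- stats::p.adjust(out$p_local, method = "BH")
  out$egene <- out$q_global < level
  rownames(out) <- NULL
  out
}

#' Greedy windowed LD pruning
#'
#' Within each window of `window` consecutive variants (ordered by
#' position), one of any pair with r^2 greater than `r2` is removed — the
#' earlier-position variant is kept — then the window slides by `step`.
#' Mirrors the common 50/5/0.5 pairwise pruning parameters.
#'
#' @param genotypes Samples x variants dosage matrix, columns ordered by
#'   position, with column names.
#' @param window,step,r2 Pruning parameters.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window = 50L, step = 5L, r2 = 0.5) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  v <- ncol(genotypes)
  keep <- rep(TRUE, v)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, v)
    idx <- start:end
    for (i in idx) {
      if (!keep[i]) next
      for (j in idx[idx > i]) {
        if (!keep[j]) next
        r <- suppressWarnings(stats::cor(genotypes[, i], genotypes[, j]))
        if (is.finite(r) && r^2 > r2) keep[j] <- FALSE
      }
    }
    if (end == v) break
    start <- start + step
  }
  ids[keep]
}

#' Trans-eQTL scan with distance, MAF, pseudogene and cross-mappability
#' filters
#'
#' Tests cis-eSNPs against distal genes: only pairs with the variant more
#' than `distance` bp from the gene TSS (or on another chromosome) are
#' tested; variants must exceed the MAF threshold (strict); pseudogenes are
#' excluded; gene pairs whose symmetric log2 cross-mappability exceeds 5 are
#' excluded. Results receive a Benjamini-Hochberg correction at 10% FDR.
#'
#' @param genotypes Samples x variants dosage matrix (cis-eSNPs, columns
#'   named).
#' @param expression Samples x genes expression matrix (columns named).
#' @param variant_info data.frame `id`, `chrom`, `pos` for the variants.
#' @param gene_info data.frame `gene_id`, `chrom`, `tss`, `is_pseudogene`.
#' @param covariates Optional covariate matrix.
#' @param maf_min Strict MAF threshold (default 0.025).
#' @param distance Minimum |variant - TSS| on the same chromosome (default
#'   1e6).
#' @param crossmap Optional data.frame `gene_a`, `gene_b`, `crossmap`
#'   (log2) used with [symmetric_crossmap()]; the upstream gene of each
#'   variant can be supplied via `upstream_gene` (named vector variant ->
#'   gene) so variant-gene pairs with symmetric log2 cross-mappability > 5
#'   are dropped. Missing entries are treated as 0 and retained.
#' @param upstream_gene Optional named character vector mapping variant id
#'   to its cis gene.
#' @param prune Logical; LD-prune the variants first (50/5/0.5).
#' @param fdr_level FDR level for flags (default 0.10).
#' @return data.frame of `qtl_result` rows with `q` and `significant`.
#' @export
trans_scan <- function(genotypes, expression, variant_info, gene_info,
                       covariates = NULL, maf_min = 0.025, distance = 1e6,
                       crossmap = NULL, upstream_gene = NULL,
                       prune = TRUE, fdr_level = 0.10) {
  genotypes <- as.matrix(genotypes)
  expression <- as.matrix(expression)
  maf <- apply(genotypes, 2, function(g) {
    f <- mean(g) / 2
    min(f, 1 - f)
  })
  keep_v <- maf > maf_min
  if (prune && sum(keep_v) > 1) {
    ord <- order(variant_info$chrom[match(colnames(genotypes), variant_info$id)],
                 variant_info$pos[match(colnames(genotypes), variant_info$id)])
    pruned <- ld_prune(genotypes[, ord, drop = FALSE][, keep_v[ord], drop = FALSE])
    keep_v <- keep_v & colnames(genotypes) %in% pruned
  }
  genes <- gene_info[!gene_info$is_pseudogene, , drop = FALSE]
  rows <- list()
  for (v in colnames(genotypes)[keep_v]) {
    vi <- variant_info[variant_info$id == v, ]
    for (g in intersect(genes$gene_id, colnames(expression))) {
      gi <- genes[genes$gene_id == g, ]
      same_chr <- gi$chrom == vi$chrom
      if (same_chr && abs(vi$pos - gi$tss) <= distance) next
      if (!is.null(crossmap) && !is.null(upstream_gene) &&
          !is.na(upstream_gene[v])) {
        cm <- symmetric_crossmap(crossmap, upstream_gene[[v]], g)
        if (cm > 5) next
      }
      r <- fit_qtl(expression[, g], genotypes[, v], covariates = covariates,
                   variant_id = v, feature_id = g)
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p_nominal, level = fdr_level)
  out$q <- adj$q
  out$significant <- adj$significant
  rownames(out) <- NULL
  out
}

#' Symmetric log2 cross-mappability of a gene pair
#'
#' `(crossmap(A,B) + crossmap(B,A)) / 2`; a missing entry is treated as 0
#' (the pair is retained) with a message.
#'
#' @param crossmap data.frame with columns `gene_a`, `gene_b`, `crossmap`.
#' @param gene_a,gene_b Gene ids.
#' @return Scalar symmetric cross-mappability.
#' @export
symmetric_crossmap <- function(crossmap, gene_a, gene_b) {
  get1 <- function(a, b) {
    hit <- crossmap$crossmap[crossmap$gene_a == a & crossmap$gene_b == b]
    if (length(hit) == 0) {
      message("crossmap entry missing for ", a, "->", b, "; treated as 0")
      0
    } else hit[1]
  }
  (get1(gene_a, gene_b) + get1(gene_b, gene_a)) / 2
}
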