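## Construction, validation and annotation of candidate X-M-Y triplets
## under the three eligibility rules:
##   forward  — the ca/eQTL variant lies inside the chromatin peak and the
##              peak is within +/- 1 Mb of the gene TSS;
##   reactive — the variant cis-regulates a TF whose motif the peak carries,
##              the variant is a significant trans-caQTL for that peak, and
##              the variant lies outside the peak;
##   trans    — the variant is a cis-eSNP of an upstream gene and a
##              significant trans-eQTL of a distal downstream gene.

CIS_WINDOW <- 1e6       # |variant - TSS| window, inclusive
PROMOTER_WINDOW <- 2000 # promoter = +/- 2 kb of TSS

## half-open interval membership: start <= pos < end
pos_in_peak <- function(pos, start, end) pos >= start & pos < end

#' Build forward-eligible triplets from significant ca/eQTL results
#'
#' One triplet per (variant, peak, gene) where the variant is significant
#' for both the peak (caQTL, 5% FDR) and the gene (eGene), lies inside the
#' peak interval (half-open), and the variant is within +/- 1 Mb of the
#' gene TSS (inclusive).
#'
#' @param caqtl data.frame of significant caQTL: `variant_id`, `feature_id`
#'   (peak), `beta`.
#' @param eqtl data.frame of significant eQTL: `variant_id`, `feature_id`
#'   (gene), `beta`.
#' @param layout A [genome_layout()] providing peak intervals, gene TSS and
#'   variant positions via `variant_info`.
#' @param variant_info data.frame `id`, `chrom`, `pos` (0-based positions).
#' @return data.frame of triplets with eligibility `"forward"` and
#'   `direction_shared` (sign concordance of the two betas).
#' @export
build_forward_triplets <- function(caqtl, eqtl, layout, variant_info) {
  stopifnot(inherits(layout, "genome_layout"))
  shared <- intersect(caqtl$variant_id, eqtl$variant_id)
  rows <- list()
  for (v in shared) {
    vi <- variant_info[variant_info$id == v, ]
    if (nrow(vi) != 1) qtlmed_stop(paste("variant not in panel:", v))
    ca <- caqtl[caqtl$variant_id == v, , drop = FALSE]
    eq <- eqtl[eqtl$variant_id == v, , drop = FALSE]
    for (pi in seq_len(nrow(ca))) {
      pk <- layout$peaks[layout$peaks$peak_id == ca$feature_id[pi], ]
      if (nrow(pk) != 1) next
      if (pk$chrom != vi$chrom) next
      if (!pos_in_peak(vi$pos, pk$start, pk$end)) next
      for (gi in seq_len(nrow(eq))) {
        gn <- layout$genes[layout$genes$gene_id == eq$feature_id[gi], ]
        if (nrow(gn) != 1) next
        if (gn$chrom != vi$chrom) next
        if (abs(vi$pos - gn$tss) > CIS_WINDOW) next
        rows[[length(rows) + 1L]] <- data.frame(
          x_variant_id = v, m_feature_id = pk$peak_id,
          y_feature_id = gn$gene_id, eligibility = "forward",
          beta_xm = ca$beta[pi], beta_xy = eq$beta[gi],
          direction_shared = sign(ca$beta[pi]) == sign(eq$beta[gi]),
          stringsAsFactors = FALSE)
      }
    }
  }
  triplet_table(rows)
}

#' Build reactive-eligible triplets
#'
#' X must cis-regulate a transcription-factor gene (significance assessed by
#' rerunning the hierarchical eGene procedure on the TF-gene subset
#' upstream of this call); the candidate peak must carry a motif hit for
#' that TF (>= 80% relative score); X must be a significant trans-caQTL for
#' the peak; and variants lying inside the peak are excluded — within-peak
#' variants indicate cis (forward) action.
#'
#' @param tf_eqtl data.frame of significant TF cis-eQTL pairs:
#'   `variant_id`, `feature_id` (TF gene), `beta`.
#' @param pwms Named list of PWMs keyed by TF gene id.
#' @param peak_sequences Named character vector of peak sequences.
#' @param trans_caqtl data.frame of significant trans-caQTL: `variant_id`,
#'   `feature_id` (peak), `beta`.
#' @param layout,variant_info As in [build_forward_triplets()].
#' @param min_relative_score Motif-match threshold (default 0.8).
#' @return data.frame of triplets with eligibility `"reactive"`; M is the
#'   peak, Y the TF gene.
#' @export
build_reactive_triplets <- function(tf_eqtl, pwms, peak_sequences,
                                    trans_caqtl, layout, variant_info,
                                    min_relative_score = 0.8) {
  rows <- list()
  for (i in seq_len(nrow(tf_eqtl))) {
    v <- tf_eqtl$variant_id[i]
    tf <- tf_eqtl$feature_id[i]
    pwm <- pwms[[tf]]
    if (is.null(pwm)) {
      message("TF without PWM skipped: ", tf)
      next
    }
    vi <- variant_info[variant_info$id == v, ]
    tc <- trans_caqtl[trans_caqtl$variant_id == v, , drop = FALSE]
    for (j in seq_len(nrow(tc))) {
      pk_id <- tc$feature_id[j]
      pk <- layout$peaks[layout$peaks$peak_id == pk_id, ]
      if (nrow(pk) == 1 && pk$chrom == vi$chrom &&
          pos_in_peak(vi$pos, pk$start, pk$end)) next  # cis action, excluded
      seqs <- peak_sequences[[pk_id]]
      if (is.null(seqs)) next
      hits <- scan_pwm(seqs, pwm, min_relative_score)
      if (nrow(hits) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        x_variant_id = v, m_feature_id = pk_id, y_feature_id = tf,
        eligibility = "reactive",
        beta_xm = tc$beta[j], beta_xy = tf_eqtl$beta[i],
        direction_shared = sign(tc$beta[j]) == sign(tf_eqtl$beta[i]),
        stringsAsFactors = FALSE)
    }
  }
  triplet_table(rows)
}

#' Build trans-eligible triplets
#'
#' X is a cis-eSNP of an upstream gene (M); downstream genes (Y) come from
#' the trans scan at 10% FDR. Self-pairs and pairs with symmetric log2
#' cross-mappability above 5 are dropped.
#'
#' @param cis_pairs data.frame `variant_id`, `feature_id` (upstream gene),
#'   `beta`.
#' @param trans_results Significant trans-eQTL rows (`variant_id`,
#'   `feature_id` downstream gene, `beta`).
#' @param crossmap Optional cross-mappability table (`gene_a`, `gene_b`,
#'   `crossmap`, log2 scale).
#' @return data.frame of triplets with eligibility `"trans"`.
#' @export
build_trans_triplets <- function(cis_pairs, trans_results, crossmap = NULL) {
  rows <- list()
  for (i in seq_len(nrow(cis_pairs))) {
    v <- cis_pairs$variant_id[i]
    up <- cis_pairs$feature_id[i]
    tr <- trans_results[trans_results$variant_id == v, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      down <- tr$feature_id[j]
      if (down == up) next
      if (!is.null(crossmap)) {
        cm <- symmetric_crossmap(crossmap, up, down)
        if (cm > 5) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        x_variant_id = v, m_feature_id = up, y_feature_id = down,
        eligibility = "trans",
        beta_xm = cis_pairs$beta[i], beta_xy = tr$beta[j],
        direction_shared = sign(cis_pairs$beta[i]) == sign(tr$beta[j]),
        stringsAsFactors = FALSE)
    }
  }
  triplet_table(rows)
}

triplet_table <- function(rows) {
  if (length(rows) == 0) {
    return(data.frame(x_variant_id = character(0),
                      m_feature_id = character(0),
                      y_feature_id = character(0),
                      eligibility = character(0),
                      beta_xm = numeric(0), beta_xy = numeric(0),
                      direction_shared = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1:3]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-validate triplet eligibility invariants
#'
#' Checks every row of a triplet table against its eligibility rule
#' (forward: variant inside peak and within 1 Mb of the TSS; reactive:
#' variant outside the peak; trans: upstream != downstream) and errors on
#' the first violation.
#'
#' @param triplets Triplet data.frame.
#' @param layout,variant_info Genomic context.
#' @return TRUE invisibly when all invariants hold.
#' @export
validate_triplets <- function(triplets, layout, variant_info) {
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    vi <- variant_info[variant_info$id == tr$x_variant_id, ]
    if (tr$eligibility == "forward") {
      pk <- layout$peaks[layout$peaks$peak_id == tr$m_feature_id, ]
      gn <- layout$genes[layout$genes$gene_id == tr$y_feature_id, ]
      ok <- nrow(pk) == 1 && nrow(gn) == 1 && pk$chrom == vi$chrom &&
        pos_in_peak(vi$pos, pk$start, pk$end) &&
        abs(vi$pos - gn$tss) <= CIS_WINDOW
    } else if (tr$eligibility == "reactive") {
      pk <- layout$peaks[layout$peaks$peak_id == tr$m_feature_id, ]
      ok <- !(nrow(pk) == 1 && pk$chrom == vi$chrom &&
                pos_in_peak(vi$pos, pk$start, pk$end))
    } else if (tr$eligibility == "trans") {
      ok <- tr$m_feature_id != tr$y_feature_id
    } else ok <- FALSE
    if (!ok) qtlmed_stop(sprintf("triplet %d violates its %s invariant",
                                 i, tr$eligibility))
  }
  invisible(TRUE)
}

#' Annotate triplets and compare predictive features between classes
#'
#' Given classified triplets (forward vs independence), compares continuous
#' features (r^2 of residualized M and Y; absolute variant-TSS distance)
#' with unpaired two-sided t-tests and binary features (promoter
#' membership, optional motif-disruption and allele-specific accessibility
#' flags) with chi-square tests.
#'
#' @param triplets Triplet data.frame with a `classification` column and
#'   annotation columns `r2_ym`, `tss_distance`, `in_promoter` and
#'   optionally `motif_disruption`, `asca`.
#' @param classes Length-2 character vector of class labels to compare.
#' @return data.frame with one row per feature: `feature`, `test`,
#'   `statistic`, `p`.
#' @export
annotate_and_compare <- function(triplets,
                                 classes = c("forward", "independence")) {
  sub <- triplets[triplets$classification %in% classes, , drop = FALSE]
  tab <- table(factor(sub$classification, levels = classes))
  out <- list()
  add <- function(feature, test, statistic, p) {
    out[[length(out) + 1L]] <<- data.frame(feature = feature, test = test,
                                           statistic = statistic, p = p,
                                           stringsAsFactors = FALSE)
  }
  if (any(tab < 2)) {
    message("annotate_and_compare: a class has < 2 members; skipped")
    return(do.call(rbind, out))
  }
  grp <- factor(sub$classification, levels = classes)
  for (feat in intersect(c("r2_ym", "tss_distance"), names(sub))) {
    v <- if (feat == "tss_distance") abs(sub[[feat]]) else sub[[feat]]
    tt <- stats::t.test(v ~ grp, var.equal = FALSE)
    add(feat, "t", unname(tt$statistic), tt$p.value)
  }
  for (feat in intersect(c("in_promoter", "motif_disruption", "asca"),
                         names(sub))) {
    f <- sub[[feat]]
    if (length(unique(f)) < 2) next
    ct <- suppressWarnings(stats::chisq.test(table(grp, f)))
    add(feat, "chi-square", unname(ct$statistic), ct$p.value)
  }
  do.call(rbind, out)
}

#' Annotate triplets with r2(Y,M), TSS distance and promoter membership
#'
#' @param triplets Triplet table.
#' @param m_matrix,y_matrix Samples x features phenotype matrices.
#' @param covariates_m,covariates_y Optional covariates used to residualize
#'   M and Y before computing their squared correlation.
#' @param layout,variant_info Genomic context.
#' @return The triplet table with `r2_ym`, `tss_distance`, `in_promoter`
#'   columns appended.
#' @export
annotate_triplets <- function(triplets, m_matrix, y_matrix,
                              covariates_m = NULL, covariates_y = NULL,
                              layout = NULL, variant_info = NULL) {
  n <- nrow(as.matrix(m_matrix))
  Wm <- covariate_design(n, covariates_m)
  Wy <- covariate_design(n, covariates_y)
  r2 <- td <- rep(NA_real_, nrow(triplets))
  prom <- rep(NA, nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    m <- project_out(as.matrix(m_matrix)[, triplets$m_feature_id[i]], Wm)
    y <- project_out(as.matrix(y_matrix)[, triplets$y_feature_id[i]], Wy)
    r2[i] <- stats::cor(m, y)^2
    if (!is.null(layout) && !is.null(variant_info)) {
      vi <- variant_info[variant_info$id == triplets$x_variant_id[i], ]
      gn <- layout$genes[layout$genes$gene_id == triplets$y_feature_id[i], ]
      if (nrow(gn) == 1 && gn$chrom == vi$chrom) {
        td[i] <- vi$pos - gn$tss
        prom[i] <- abs(td[i]) <= PROMOTER_WINDOW
      }
    }
  }
  triplets$r2_ym <- r2
  triplets$tss_distance <- td
  triplets$in_promoter <- prom
  triplets
}
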