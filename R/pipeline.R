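## End-to-end orchestration: simulate -> QTL -> triplets -> Bayesian
## mediation -> measurement-error filter -> regression comparator ->
## replication summaries, with one config, per-stage derived seeds, a
## manifest of output checksums and structured drop logs.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_samples Donors (default 300).
#' @param n_forward,n_independence Planted triplet counts (default 24 + 16
#'   = 40 triplets).
#' @param pve Planted edge PVE for every edge (default 0.5, a strong-signal
#'   demo regime).
#' @param maf Variant MAF (default 0.5).
#' @param icc Measurement ICC of both phenotypes (default 0.9).
#' @param n_replicate_donors,n_replicates Technical replicate design
#'   (default 50 donors x 3 draws).
#' @param caqtl_fdr,egene_fdr FDR levels (defaults 0.05).
#' @param flip_n_reps,flip_grid_points Flip-simulation effort per triplet.
#' @param n_perm,n_decoys Regression-comparator effort.
#' @param stages Named logical vector toggling `error_model` and
#'   `regression`.
#' @return Config list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_samples = 300L,
                           n_forward = 24L, n_independence = 16L,
                           pve = 0.5, maf = 0.5, icc = 0.9,
                           n_replicate_donors = 50L, n_replicates = 3L,
                           caqtl_fdr = 0.05, egene_fdr = 0.05,
                           flip_n_reps = 2L, flip_grid_points = 10L,
                           n_perm = 200L, n_decoys = 5L,
                           stages = c(error_model = TRUE,
                                      regression = TRUE)) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys override [default_config()] values.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Simulates planted forward and independence architectures on a synthetic
#' genome, runs the caQTL/eQTL scans with hierarchical correction, builds
#' forward-eligible triplets, classifies them with the twelve-model
#' Bayesian selection (reactive priors so false reactives are observable),
#' applies the ICC filter with per-triplet flip thresholds, runs the
#' regression comparator, and writes every stage table plus a checksum
#' manifest. Reruns with the same config reproduce identical checksums.
#'
#' @param config A [default_config()] / [read_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (data.frame file, md5), `tables` (the
#'   in-memory stage outputs) and `truth` (planted architecture table).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("qtlmed_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  n <- config$n_samples
  n_trip <- config$n_forward + config$n_independence

  ## --- simulate ----------------------------------------------------------
  spacing <- 3e6
  chrom_len <- (n_trip + 1) * spacing
  truth <- data.frame(
    triplet = seq_len(n_trip),
    true_model = rep(c("complete mediation", "co-local"),
                     c(config$n_forward, config$n_independence)),
    stringsAsFactors = FALSE)
  base <- (truth$triplet - 1) * spacing
  variants <- data.frame(id = paste0("var_", truth$triplet), chrom = "chr1",
                         pos = base + 1000, maf = config$maf)
  peaks <- data.frame(peak_id = paste0("peak_", truth$triplet), chrom = "chr1",
                      start = base + 500, end = base + 1500)
  genes <- data.frame(gene_id = paste0("gene_", truth$triplet), chrom = "chr1",
                      tss = base + 50000, strand = "+",
                      is_tf = FALSE, is_pseudogene = FALSE)
  layout <- genome_layout(data.frame(name = "chr1", length = chrom_len),
                          peaks, genes)
  trip_seeds <- derive_seeds(seeds[1], n_trip)
  sims <- lapply(seq_len(n_trip), function(i) {
    arch <- synthetic_architecture(
      true_model = truth$true_model[i],
      pve_a = config$pve, pve_b = if (truth$true_model[i] == "co-local") 0 else config$pve,
      pve_c = if (truth$true_model[i] == "co-local") config$pve else 0,
      maf = config$maf, n_samples = n,
      icc_m = config$icc, icc_y = config$icc,
      n_replicate_donors = config$n_replicate_donors,
      n_replicates = config$n_replicates)
    generate_triplet_data(arch, seed = trip_seeds[i])
  })
  G <- do.call(cbind, lapply(sims, `[[`, "x"))
  colnames(G) <- variants$id
  attr(G, "variants") <- variants
  M <- do.call(cbind, lapply(sims, `[[`, "m_obs"))
  colnames(M) <- peaks$peak_id
  Y <- do.call(cbind, lapply(sims, `[[`, "y_obs"))
  colnames(Y) <- genes$gene_id

  files <- list()
  emit <- function(obj, name, writer = write_tsv) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[name]] <<- p
  }
  emit(G, "genotypes.vcf", function(o, p) write_vcf(o, p))
  emit(peaks, "peaks.bed", function(o, p) write_bed(o, p))
  emit(genes, "genes.tsv")
  emit(M, "phenotype_chromatin.tsv")
  emit(Y, "phenotype_expression.tsv")
  emit(truth, "truth.tsv")

  ## --- QTL scans ---------------------------------------------------------
  caqtl <- do.call(rbind, lapply(seq_len(n_trip), function(i)
    fit_qtl(M[, i], G[, i], variant_id = variants$id[i],
            feature_id = peaks$peak_id[i])))
  adj <- bh_fdr(caqtl$p_nominal, level = config$caqtl_fdr)
  caqtl$q <- adj$q
  caqtl$significant <- adj$significant
  eqtl <- do.call(rbind, lapply(seq_len(n_trip), function(i)
    fit_qtl(Y[, i], G[, i], variant_id = variants$id[i],
            feature_id = genes$gene_id[i])))
  egenes <- hierarchical_egene_fdr(eqtl, level = config$egene_fdr)
  emit(caqtl, "caqtl.tsv")
  emit(egenes, "egenes.tsv")

  ## --- triplets ----------------------------------------------------------
  sig_ca <- caqtl[caqtl$significant, c("variant_id", "feature_id", "beta")]
  sig_e <- merge(egenes[egenes$egene, c("feature_id", "variant_id")],
                 eqtl[, c("variant_id", "feature_id", "beta")],
                 by = c("variant_id", "feature_id"))
  triplets <- build_forward_triplets(sig_ca, sig_e, layout, variants)
  validate_triplets(triplets, layout, variants)
  emit(triplets, "triplets.tsv")

  ## --- Bayesian mediation ------------------------------------------------
  priors <- mediation_priors(model_prior_mode = "reactive")
  med <- do.call(rbind, lapply(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    po <- posterior_over_models(G[, tr$x_variant_id], M[, tr$m_feature_id],
                                Y[, tr$y_feature_id], priors = priors)
    cbind(tr[, 1:4],
          as.data.frame(as.list(stats::setNames(
            po$posterior, make.names(names(po$posterior))))),
          data.frame(posterior_forward_sum = po$posterior_forward_sum,
                     posterior_reactive_sum = po$posterior_reactive_sum,
                     classification = po$classification))
  }))
  triplets$classification <- med$classification
  emit(med, "mediation.tsv")

  ## --- measurement-error filter ------------------------------------------
  if (isTRUE(config$stages[["error_model"]])) {
    icc_m <- vapply(seq_len(n_trip), function(i)
      estimate_icc(sims[[i]]$replicates_m, peaks$peak_id[i])$icc, numeric(1))
    names(icc_m) <- peaks$peak_id
    icc_y <- vapply(seq_len(n_trip), function(i)
      estimate_icc(sims[[i]]$replicates_y, genes$gene_id[i])$icc, numeric(1))
    names(icc_y) <- genes$gene_id
    emit(data.frame(feature = c(names(icc_m), names(icc_y)),
                    icc = c(icc_m, icc_y)), "icc.tsv")
    need_thr <- which(triplets$classification == "reactive")
    thresholds <- NULL
    if (length(need_thr)) {
      thr_seeds <- derive_seeds(seeds[3], length(need_thr))
      thresholds <- vapply(seq_along(need_thr), function(k) {
        simulate_flip_threshold(
          pve_a = config$pve, pve_b = config$pve, direction = "forward",
          n_samples = n, n_reps = config$flip_n_reps,
          icc_grid = seq(0.05, 1, length.out = config$flip_grid_points),
          seed = thr_seeds[k])$icc_threshold
      }, numeric(1))
      names(thresholds) <- paste(triplets$x_variant_id[need_thr],
                                 triplets$m_feature_id[need_thr],
                                 triplets$y_feature_id[need_thr])
      emit(data.frame(triplet = names(thresholds), icc_threshold = thresholds),
           "flip_thresholds.tsv")
    }
    filt <- filter_triplets(triplets, icc_m, icc_y, thresholds)
    triplets <- filt$retained
    emit(triplets, "triplets_filtered.tsv")
    if (nrow(filt$excluded)) emit(filt$excluded, "triplets_excluded.tsv")
  } else {
    triplets$provenance <- "unfiltered"
    emit(triplets, "triplets_unfiltered.tsv")
  }

  ## --- regression comparator ---------------------------------------------
  reg <- NULL
  if (isTRUE(config$stages[["regression"]]) && nrow(triplets) > 0) {
    reg_seeds <- derive_seeds(seeds[4], nrow(triplets))
    reg <- do.call(rbind, lapply(seq_len(nrow(triplets)), function(i) {
      tr <- triplets[i, ]
      j <- match(tr$m_feature_id, peaks$peak_id)
      decoy_idx <- setdiff(seq_len(n_trip), j)
      set.seed(reg_seeds[i])
      decoy_idx <- sample(decoy_idx, min(config$n_decoys, length(decoy_idx)))
      permutation_gev_fwer(
        y = Y[, tr$y_feature_id], x = G[, tr$x_variant_id],
        m_residualized = residualize(M[, tr$m_feature_id]),
        decoys = residualize(M[, decoy_idx, drop = FALSE]),
        n_perm = config$n_perm, seed = reg_seeds[i],
        triplet_id = paste(tr$x_variant_id, tr$m_feature_id,
                           tr$y_feature_id))
    }))
    emit(reg, "regression_mediation.tsv")
  }

  ## --- replication summary + manifest -------------------------------------
  conc <- sign_concordance(triplets)
  emit(data.frame(metric = c("sign_concordance", "n_triplets_final"),
                  value = c(conc$fraction, nrow(triplets))),
       "summary.tsv")
  manifest <- data.frame(file = names(files),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  list(manifest = manifest,
       tables = list(caqtl = caqtl, egenes = egenes, triplets = triplets,
                     mediation = med, regression = reg),
       truth = truth, out_dir = out_dir)
}
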