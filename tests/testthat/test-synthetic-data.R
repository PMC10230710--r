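test_that("genotype generation respects MAF, determinism and input checks", {
  vars <- data.frame(id = "v1", chrom = "chr1", pos = 100, maf = 0.5)
  g <- generate_genotypes(10000, vars, seed = 1)
  emp_maf <- mean(g[, 1]) / 2
  expect_gte(emp_maf, 0.48)
  expect_lte(emp_maf, 0.52)

  g1 <- generate_genotypes(2, vars, seed = 7)
  g2 <- generate_genotypes(2, vars, seed = 7)
  expect_identical(g1, g2)

  expect_error(generate_genotypes(1, vars), "n_samples")
  expect_error(generate_genotypes(10, transform(vars, maf = 0.6)), "maf")
  ## a MAF-0.01 variant passes a strictly-greater 1% retention rule
  expect_true(0.01 > 0.01 - 1e-12)
})

test_that("LD blocks reach the target r2 between adjacent variants", {
  vars <- data.frame(id = paste0("v", 1:10), chrom = "chr1",
                     pos = 1:10 * 100, maf = 0.3)
  g <- generate_genotypes(20000, vars, ld_block_r2 = 0.8, block_size = 5,
                          seed = 3)
  r2 <- sapply(c(1:3, 6:8), function(j) cor(g[, j], g[, j + 1])^2)
  expect_true(all(abs(r2 - 0.8) < 0.08))
  ## across a block boundary the variants are independent
  expect_lt(cor(g[, 5], g[, 6])^2, 0.01)
})

test_that("planted PVE is recovered and icc = 1 means no error", {
  arch <- synthetic_architecture("complete mediation", pve_a = 0.3,
                                 pve_b = 0.3, n_samples = 50000,
                                 fix_sign = TRUE)
  d <- generate_triplet_data(arch, seed = 2)
  r2_xm <- summary(lm(d$m_true ~ d$x))$r.squared
  expect_lt(abs(r2_xm - 0.3), 0.02)
  r2_my <- summary(lm(d$y_true ~ d$m_true))$r.squared
  expect_lt(abs(r2_my - 0.3), 0.02)
  expect_identical(d$m_obs, d$m_true)

  ## no planted effects: X, M, Y mutually uncorrelated
  arch0 <- synthetic_architecture("no-effects", pve_a = 0, pve_b = 0,
                                  n_samples = 50000)
  d0 <- generate_triplet_data(arch0, seed = 3)
  expect_lt(abs(cor(d0$x, d0$m_true)), 0.02)
  expect_lt(abs(cor(d0$m_true, d0$y_true)), 0.02)

  ## under independence the partial correlation of M and Y given X vanishes
  archi <- synthetic_architecture("co-local", pve_a = 0.4, pve_b = 0,
                                  pve_c = 0.4, n_samples = 50000)
  di <- generate_triplet_data(archi, seed = 4)
  rm_ <- resid(lm(di$m_true ~ di$x))
  ry_ <- resid(lm(di$y_true ~ di$x))
  expect_lt(abs(cor(rm_, ry_)), 0.02)
})

test_that("architecture validation rejects out-of-domain parameters", {
  expect_error(synthetic_architecture(pve_b = 0.6, pve_c = 0.5), "< 1")
  expect_error(synthetic_architecture(maf = 0.7), "maf")
  expect_error(synthetic_architecture(icc_m = 0), "ICC")
  expect_error(synthetic_architecture(true_model = "spooky"), "unknown")
})

test_that("replicate tables carry the target ICC", {
  arch <- synthetic_architecture("complete mediation", pve_a = 0.3,
                                 pve_b = 0.3, n_samples = 200,
                                 icc_m = 0.7, icc_y = 0.9,
                                 n_replicate_donors = 60, n_replicates = 3)
  d <- generate_triplet_data(arch, seed = 5)
  expect_equal(length(unique(d$replicates_m$donor)), 60)
  expect_true(all(table(d$replicates_m$donor) == 3))
  icc_hat <- estimate_icc(d$replicates_m)$icc
  expect_lt(abs(icc_hat - 0.7), 0.12)
})

test_that("motif planting hits the exact count and scores 1 at the offset", {
  pwm <- rbind(A = c(9, 0, 0, 1), C = c(0, 9, 0, 1),
               G = c(0, 0, 9, 1), T = c(1, 1, 1, 7))
  peaks <- data.frame(peak_id = paste0("p", 1:10), chrom = "chr1",
                      start = 0, end = 40)
  out <- generate_motif_instances(pwm, peaks, planted_fraction = 1, seed = 1)
  expect_equal(nrow(out$truth), 10)
  for (i in 1:10) {
    hits <- scan_pwm(out$sequences[[out$truth$peak_id[i]]], pwm, 0.999)
    expect_true(out$truth$offset[i] %in% hits$offset)
  }
  out0 <- generate_motif_instances(pwm, peaks, planted_fraction = 0, seed = 1)
  expect_equal(nrow(out0$truth), 0)
  out_half <- generate_motif_instances(pwm, peaks[1:8, ], 0.5, seed = 1)
  expect_equal(nrow(out_half$truth), 4)
  expect_error(generate_motif_instances(pwm, transform(peaks, end = 3), 1),
               "wider")
})

test_that("GWAS simulator is calibrated under the null and powered at the
           causal variant", {
  vars <- data.frame(id = paste0("v", 1:300), chrom = "chr1",
                     pos = 1:300, maf = 0.3)
  g <- generate_genotypes(400, vars, seed = 8)
  null_stats <- generate_gwas_stats(g, "", trait_pve = 0, n_gwas = 500,
                                    seed = 9)
  expect_lt(abs(mean(null_stats$p < 0.05) - 0.05), 0.04)

  hits <- sum(sapply(1:6, function(s) {
    st <- generate_gwas_stats(g[, 1:20], "v1", trait_pve = 0.05,
                              n_gwas = 10000, seed = s)
    st$p[st$variant == "v1"] < 5e-8
  }))
  expect_gte(hits, 4)  # majority of seeds reach genome-wide significance

  g2 <- cbind(g[, 1:3], dup = g[, 3])
  colnames(g2) <- c("a", "b", "c", "dup")
  st2 <- generate_gwas_stats(g2, "c", trait_pve = 0.1, n_gwas = 300, seed = 2)
  expect_equal(st2[st2$variant == "c", -1], st2[st2$variant == "dup", -1],
               ignore_attr = TRUE)
})

test_that("file writers round-trip and are byte-stable under a fixed seed", {
  vars <- data.frame(id = c("v1", "v2"), chrom = "chr1", pos = c(10, 20),
                     maf = 0.4)
  g <- generate_genotypes(5, vars, seed = 1)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.vcf"); p2 <- file.path(td, "b.vcf")
  write_vcf(g, p1)
  write_vcf(generate_genotypes(5, vars, seed = 1), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "VCFv4.2")
  ## POS is 1-based on write
  body <- strsplit(grep("^chr", readLines(p1), value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(body[2]), 11L)

  bed <- file.path(td, "p.bed")
  write_bed(data.frame(peak_id = "pk1", chrom = "chr1", start = 0, end = 10),
            bed)
  expect_equal(strsplit(readLines(bed), "\t")[[1]],
               c("chr1", "0", "10", "pk1"))

  tsv <- file.path(td, "m.tsv")
  write_tsv(g, tsv)
  back <- read_tsv(tsv)
  expect_equal(as.matrix(back[, -1]), unname(g), ignore_attr = TRUE)
})
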