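make_layout <- function() {
  genome_layout(
    chromosomes = data.frame(name = c("chr1", "chr2"), length = 5e6),
    peaks = data.frame(peak_id = c("pkA", "pkB", "pkC"),
                       chrom = c("chr1", "chr1", "chr2"),
                       start = c(1000, 200000, 1000),
                       end = c(2000, 201000, 2000)),
    genes = data.frame(gene_id = c("g1", "g2", "tf1"),
                       chrom = c("chr1", "chr1", "chr2"),
                       tss = c(50000, 3.5e6, 10000), strand = "+",
                       is_tf = c(FALSE, FALSE, TRUE),
                       is_pseudogene = FALSE))
}

test_that("genome layout validation enforces coordinates and uniqueness", {
  expect_s3_class(make_layout(), "genome_layout")
  bad <- data.frame(peak_id = "p", chrom = "chr1", start = 10, end = 10)
  expect_error(genome_layout(data.frame(name = "chr1", length = 100),
                             bad,
                             data.frame(gene_id = "g", chrom = "chr1",
                                        tss = 5, strand = "+")),
               "start")
})

test_that("forward triplets require the variant inside the peak (half-open)
           and within 1 Mb of the TSS", {
  layout <- make_layout()
  vi <- data.frame(id = c("v_in", "v_out", "v_start", "v_far"),
                   chrom = "chr1", pos = c(1500, 999, 1000, 200500))
  ca <- data.frame(variant_id = c("v_in", "v_out", "v_start", "v_far"),
                   feature_id = c("pkA", "pkA", "pkA", "pkB"),
                   beta = c(1, 1, 1, -1))
  eq <- data.frame(variant_id = c("v_in", "v_out", "v_start", "v_far"),
                   feature_id = c("g1", "g1", "g1", "g2"),
                   beta = c(-0.5, 1, 1, 1))
  tr <- build_forward_triplets(ca, eq, layout, vi)
  ## v_out is 1 bp upstream of the peak: excluded; v_start sits exactly on
  ## the half-open start: included; v_far is > 1 Mb from g2's TSS: excluded
  expect_setequal(tr$x_variant_id, c("v_in", "v_start"))
  expect_false(tr$direction_shared[tr$x_variant_id == "v_in"])
  expect_true(tr$direction_shared[tr$x_variant_id == "v_start"])
  expect_silent(validate_triplets(tr, layout, vi))
})

test_that("a synthetic mix of qualifying and disqualifying pairs yields
           exactly the qualifying triplets", {
  layout <- make_layout()
  vi <- data.frame(id = paste0("w", 1:5), chrom = "chr1",
                   pos = c(1100, 1200, 1300, 500, 2500))
  ca <- data.frame(variant_id = paste0("w", 1:5), feature_id = "pkA",
                   beta = 1)
  eq <- data.frame(variant_id = paste0("w", 1:5), feature_id = "g1",
                   beta = 1)
  tr <- build_forward_triplets(ca, eq, layout, vi)
  expect_equal(nrow(tr), 3)  # w4 before the peak, w5 after it
})

test_that("PWM scanning matches the exhaustive per-offset oracle on both
           strands and scores the consensus at 1", {
  pwm <- rbind(A = c(5, 1, 0, 2), C = c(1, 6, 1, 1),
               G = c(2, 0, 7, 1), T = c(0, 1, 0, 4))
  cons <- pwm_consensus(pwm)
  expect_equal(cons, "ACGT")
  ## ACGT is its own reverse complement, so both strands score 1
  hit <- scan_pwm(cons, pwm, 0.99)
  expect_equal(hit$relative_score[hit$strand == "+"], 1)

  set.seed(1)
  seqs <- replicate(10, paste(sample(c("A", "C", "G", "T"), 12,
                                     replace = TRUE), collapse = ""))
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  for (s in seqs) {
    hits <- scan_pwm(s, pwm, 0)
    ch <- strsplit(s, "")[[1]]
    for (o in 0:(nchar(s) - 4)) {
      raw <- sum(sapply(1:4, function(k) pwm[ch[o + k], k]))
      rel <- (raw - smin) / (smax - smin)
      got <- hits$relative_score[hits$offset == o & hits$strand == "+"]
      expect_equal(got, rel, tolerance = 1e-12)
      ## reverse strand: score the reverse complement window
      win <- substr(s, o + 1, o + 4)
      rc <- strsplit(revcomp(win), "")[[1]]
      raw_r <- sum(sapply(1:4, function(k) pwm[rc[k], k]))
      rel_r <- (raw_r - smin) / (smax - smin)
      got_r <- hits$relative_score[hits$offset == o & hits$strand == "-"]
      expect_equal(got_r, rel_r, tolerance = 1e-12)
    }
  }
})

test_that("PWM scanning agrees with Biostrings scoring", {
  skip_if_not_installed("Biostrings")
  pwm <- rbind(A = c(5, 1, 0, 2), C = c(1, 6, 1, 1),
               G = c(2, 0, 7, 1), T = c(0, 1, 0, 4))
  prob <- sweep(pwm, 2, colSums(pwm), "/")
  seq <- "ACGTTGCAAC"
  hits <- scan_pwm(seq, pwm, 0)
  fwd <- hits[hits$strand == "+", ]
  for (i in seq_len(nrow(fwd))) {
    bs <- Biostrings::PWMscoreStartingAt(prob, seq,
                                         starting.at = fwd$offset[i] + 1)
    smin <- sum(apply(prob, 2, min)); smax <- sum(apply(prob, 2, max))
    expect_equal(fwd$relative_score[i], (bs - smin) / (smax - smin),
                 tolerance = 1e-6)
  }
})

test_that("JASPAR reader parses count blocks", {
  td <- withr::local_tempdir()
  f <- file.path(td, "m.jaspar")
  writeLines(c(">MA0001.1 TFX",
               "A [ 4 19  0  0 ]",
               "C [16  0 20  0 ]",
               "G [ 0  1  0 20 ]",
               "T [ 0  0  0  0 ]"), f)
  pwms <- read_jaspar(f)
  expect_named(pwms, "TFX")
  expect_equal(dim(pwms$TFX), c(4, 4))
  expect_equal(pwm_consensus(pwms$TFX), "CACG")
})

test_that("reactive triplets require a motif-bearing peak and exclude
           within-peak variants", {
  layout <- make_layout()
  pwm <- rbind(A = c(9, 0), C = c(0, 9), G = c(0, 0), T = c(0, 0))
  vi <- data.frame(id = c("r1", "r2"), chrom = c("chr2", "chr1"),
                   pos = c(1500, 999))
  tf_eq <- data.frame(variant_id = c("r1", "r2"), feature_id = "tf1",
                      beta = 1)
  tc <- data.frame(variant_id = c("r1", "r2"),
                   feature_id = c("pkC", "pkA"), beta = 1)
  seqs <- c(pkC = "GGACGG", pkA = "GGACGG")
  tr <- build_reactive_triplets(tf_eq, list(tf1 = pwm), seqs, tc, layout, vi)
  ## r1 lies inside pkC -> excluded (cis action); r2 is outside pkA
  expect_equal(tr$x_variant_id, "r2")
  expect_equal(tr$eligibility, "reactive")
  expect_silent(validate_triplets(tr, layout, vi))

  ## no motif hit -> no triplet; missing PWM -> logged skip
  tr2 <- build_reactive_triplets(tf_eq, list(tf1 = pwm),
                                 c(pkC = "GGGGGG", pkA = "GGGGGG"),
                                 tc, layout, vi)
  expect_equal(nrow(tr2), 0)
  expect_message(
    build_reactive_triplets(tf_eq, list(), seqs, tc, layout, vi),
    "without PWM")
})

test_that("trans triplets drop self-pairs and high cross-mappability", {
  cis <- data.frame(variant_id = c("v1", "v2"),
                    feature_id = c("up1", "up2"), beta = 1)
  trres <- data.frame(variant_id = c("v1", "v1", "v2"),
                      feature_id = c("down1", "up1", "down2"), beta = -1)
  xm <- data.frame(gene_a = c("up2", "down2"), gene_b = c("down2", "up2"),
                   crossmap = c(6, 6))
  tr <- build_trans_triplets(cis, trres, xm)
  expect_equal(tr$x_variant_id, "v1")
  expect_equal(tr$y_feature_id, "down1")
})

test_that("feature comparison runs t and chi-square tests and skips tiny
           classes", {
  set.seed(1)
  n <- 40
  trips <- data.frame(
    classification = rep(c("forward", "independence"), each = n),
    r2_ym = c(rnorm(n, 0.5, 0.05), rnorm(n, 0.2, 0.05)),
    tss_distance = c(rnorm(n, 1e4, 1e3), rnorm(n, 1e5, 1e4)),
    in_promoter = rep(c(TRUE, FALSE), each = n))
  cmp <- annotate_and_compare(trips)
  expect_setequal(cmp$feature, c("r2_ym", "tss_distance", "in_promoter"))
  expect_lt(cmp$p[cmp$feature == "r2_ym"], 1e-6)
  expect_lt(cmp$p[cmp$feature == "in_promoter"], 0.01)

  tiny <- trips[c(1, n + 1), ]
  expect_message(annotate_and_compare(tiny), "< 2")
})

test_that("null feature distributions are rarely rejected", {
  set.seed(2)
  rejected <- replicate(100, {
    n <- 30
    trips <- data.frame(
      classification = rep(c("forward", "independence"), each = n),
      r2_ym = rnorm(2 * n, 0.3, 0.1))
    annotate_and_compare(trips)$p < 0.05
  })
  expect_gte(mean(!rejected), 0.88)
})
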