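test_that("RPKM and RPM follow their definitions", {
  ## 100 tags in a 2 kb region, 10,000 total:
  ## RPKM = 100 / (2 kb * 0.01 M) = 5000; RPM = 100 / 0.01 M = 10000
  set.seed(2)
  inside <- sample(5000:6999, 100, replace = TRUE)
  outside <- sample(20000:90000, 9900, replace = TRUE)
  trk <- make_track(c(inside, outside), rep("+", 10000), len = 1e5)
  reg <- data.frame(region_id = "r", chrom = "chr1", start = 5000L,
                    end = 7000L, strand = "+", stringsAsFactors = FALSE)
  q <- quantify(trk, reg)
  expect_equal(q$sense_count, 100)
  expect_equal(q$sense_rpkm, 5000)
  expect_equal(q$sense_rpm, 10000)
  expect_equal(q$antisense_count, 0)

  ## empty region
  q0 <- quantify(trk, transform(reg, start = 0L, end = 10L))
  expect_equal(q0$sense_count, 0)
  expect_equal(q0$sense_rpkm, 0)

  ## doubling every tag leaves RPKM unchanged
  dbl <- make_track(rep(c(inside, outside), 2), rep("+", 20000), len = 1e5)
  expect_equal(quantify(dbl, reg)$sense_rpkm, q$sense_rpkm)

  ## a length override (longest isoform) changes the RPKM denominator
  qlen <- quantify(trk, transform(reg, length = 4000L))
  expect_equal(qlen$sense_rpkm, 2500)
})

test_that("counts are additive over partitions and exclusive across strands", {
  set.seed(3)
  trk <- make_track(sample.int(1e4, 2000, replace = TRUE) - 1L,
                    sample(c("+", "-"), 2000, replace = TRUE), len = 1e4)
  parts <- data.frame(region_id = c("a", "b", "c", "whole"),
                      chrom = "chr1", start = c(0L, 3000L, 7000L, 0L),
                      end = c(3000L, 7000L, 10000L, 10000L), strand = "+",
                      stringsAsFactors = FALSE)
  q <- quantify(trk, parts)
  expect_equal(sum(q$sense_count[1:3]), q$sense_count[4])
  expect_equal(sum(q$antisense_count[1:3]), q$antisense_count[4])
  ## sense + antisense equals the pooled count
  pooled <- quantify(trk, transform(parts[4, ], strand = "."))
  expect_equal(q$sense_count[4] + q$antisense_count[4],
               pooled$sense_count)
})

test_that("expected RPKM is invariant under uniform subsampling", {
  set.seed(5)
  n <- 40000
  trk <- make_track(sample.int(1e5, n, replace = TRUE) - 1L,
                    rep("+", n), len = 1e5)
  reg <- data.frame(region_id = "r", chrom = "chr1", start = 10000L,
                    end = 30000L, strand = "+", stringsAsFactors = FALSE)
  full <- quantify(trk, reg)
  keep <- runif(n) < 0.5
  sub <- tag_track(trk$tags[keep, ], trk$chrom_lengths, "sub")
  half <- quantify(sub, reg)
  ## binomial CI on the count ratio propagated to the RPKM ratio
  expect_lt(abs(half$sense_rpkm / full$sense_rpkm - 1),
            4 / sqrt(full$sense_count * 0.5))
})

test_that("quantification contracts are enforced", {
  trk <- make_track(1:10, rep("+", 10), len = 100L)
  reg <- data.frame(region_id = "r", chrom = "chr1", start = 0L,
                    end = 500L, strand = "+", stringsAsFactors = FALSE)
  expect_error(quantify(trk, reg), "bounds")
  empty <- tag_track(data.frame(chrom = character(), pos = integer(),
                                strand = character()), c(chr1 = 100L))
  expect_error(quantify(empty, transform(reg, end = 50L)), "zero total")
})

test_that("TSS windows are oriented: sense downstream, antisense upstream", {
  ## + gene at 10000 with sense tags only downstream of the TSS
  ann <- gene_annotation(
    data.frame(gene_id = "g", chrom = "chr1", start = 10000L, end = 16000L,
               strand = "+", stringsAsFactors = FALSE),
    chrom_lengths = c(chr1 = 50000L))
  trk <- make_track(seq(10100L, 11000L, by = 10L), "+", len = 50000L)
  v <- tss_sense_antisense(trk, ann)
  expect_gt(v$sense_rpm, 0)
  expect_equal(v$antisense_rpm, 0)

  ## mirrored - strand gene with mirrored tags gives identical values
  annm <- gene_annotation(
    data.frame(gene_id = "g", chrom = "chr1", start = 34000L, end = 40000L,
               strand = "-", stringsAsFactors = FALSE),
    chrom_lengths = c(chr1 = 50000L))
  trkm <- make_track(50000L - 1L - seq(10100L, 11000L, by = 10L), "-",
                     len = 50000L)
  vm <- tss_sense_antisense(trkm, annm)
  expect_equal(vm$sense_count, v$sense_count)
  expect_equal(vm$antisense_count, v$antisense_count)
})

test_that("the recovered AS/S ratio matches the generator's analytic expectation", {
  cfg <- sim_config(seed = 2)
  gen <- generate_annotation(cfg)
  trk <- simulate_tags(gen$annotation, gen$truth, "chrrna", "control", cfg)
  v <- tss_sense_antisense(trk, gen$annotation)
  g <- gen$truth$genes
  as <- gen$truth$as_transcripts
  lam_s <- cfg$depth / (cfg$n_chromosomes * cfg$genome_length) / 2
  w <- 3000
  ## expected sense counts: gene coverage clipped to the window + background
  exp_s <- g$rate * pmin(w, g$end - g$start) + lam_s * w
  ## expected antisense counts: overlap of each AS transcript with the
  ## upstream window (5'AS transcripts only) + background
  exp_a <- rep(lam_s * w, nrow(g))
  for (i in seq_len(nrow(as))) {
    gi <- match(as$gene_id[i], g$gene_id)
    win <- if (g$strand[gi] == "+") c(g$tss[gi] - w, g$tss[gi])
           else c(g$tss[gi] + 1, g$tss[gi] + 1 + w)
    ov <- max(0, min(as$end[i], win[2]) - max(as$start[i], win[1]))
    exp_a[gi] <- exp_a[gi] + as$rate_control[i] * ov
  }
  expect_lt(abs(sum(v$sense_count) - sum(exp_s)) / sum(exp_s), 0.02)
  expect_lt(abs(sum(v$antisense_count) - sum(exp_a)) / sum(exp_a), 0.05)
  ## the planted antisense/sense rate ratio is recovered in aggregate
  sig_a <- sum(v$antisense_count) - lam_s * w * nrow(g)
  sig_s <- sum(v$sense_count) - lam_s * w * nrow(g)
  expected_ratio <- sum(exp_a - lam_s * w) / sum(exp_s - lam_s * w)
  expect_lt(abs(sig_a / sig_s - expected_ratio), 0.02)
})
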