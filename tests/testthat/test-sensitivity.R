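test_that("the 1.5-fold rule calls sensitivity with pseudocount stabilisation", {
  mk <- function(v) data.frame(region_id = c("r1"), antisense_rpkm = v,
                               stringsAsFactors = FALSE)
  s <- sensitivity_call(mk(3.0), mk(1.0), pseudocount = 0)
  expect_equal(s$fold_change, 3.0)
  expect_true(s$sensitive)
  expect_equal(s$direction, "down")

  s2 <- sensitivity_call(mk(1.0), mk(1.0), pseudocount = 0)
  expect_equal(s2$fold_change, 1.0)
  expect_false(s2$sensitive)

  ## both zero with a pseudocount: fold exactly 1, never sensitive
  s3 <- sensitivity_call(mk(0), mk(0), pseudocount = 0.1)
  expect_equal(s3$fold_change, 1.0)
  expect_false(s3$sensitive)

  ## 1.5-fold increases are reported as "up", not sensitive
  s4 <- sensitivity_call(mk(1.0), mk(2.0), pseudocount = 0)
  expect_false(s4$sensitive)
  expect_equal(s4$direction, "up")

  ## exact threshold: >= 1.5 is sensitive
  s5 <- sensitivity_call(mk(1.5), mk(1.0), pseudocount = 0)
  expect_true(s5$sensitive)

  ## region mismatch is an error
  b <- data.frame(region_id = "other", antisense_rpkm = 1)
  expect_error(sensitivity_call(mk(1), b), "identical region_ids")

  ## a minimum-control floor suppresses low-expression calls
  s6 <- sensitivity_call(mk(0.2), mk(0.05), pseudocount = 0,
                         min_control = 1)
  expect_false(s6$sensitive)
})

test_that("association windows include and exclude at their documented boundaries", {
  pk <- data.frame(chrom = "chr1", start = 9900L, end = 10100L,
                   peak_id = "p1", summit = 10000L, strand = "+",
                   stringsAsFactors = FALSE)
  ## AS mode, +/-250 bp of the summit
  for (case in list(c(249, TRUE), c(250, TRUE), c(251, FALSE))) {
    tr <- data.frame(as_id = "t", chrom = "chr1",
                     anchor = 10000L + case[1], stringsAsFactors = FALSE)
    expect_equal(nrow(associate(tr, pk, "as")) == 1, case[2] == 1,
                 info = paste("as", case[1]))
  }
  ## eRNA mode, +/-500 bp between intervals
  for (case in list(c(499, TRUE), c(500, TRUE), c(501, FALSE))) {
    er <- data.frame(region_id = "e", chrom = "chr1",
                     start = 10100L + case[1], end = 10100L + case[1] + 4000L,
                     stringsAsFactors = FALSE)
    expect_equal(nrow(associate(er, pk, "erna")) == 1, case[2] == 1,
                 info = paste("erna", case[1]))
  }
  ## TES mode, +/-2 kb of the annotated TES
  for (case in list(c(1999, TRUE), c(2000, TRUE), c(2001, FALSE))) {
    tr <- data.frame(transcript_id = "t", chrom = "chr1",
                     anchor = 10000L + case[1], stringsAsFactors = FALSE)
    expect_equal(nrow(associate(tr, pk, "tes")) == 1, case[2] == 1,
                 info = paste("tes", case[1]))
  }
})

test_that("the nearest peak is reported on multiple hits", {
  pk <- data.frame(chrom = "chr1", start = c(0L, 0L), end = c(50L, 50L),
                   peak_id = c("far", "near"),
                   summit = c(10200L, 10100L), strand = "+",
                   stringsAsFactors = FALSE)
  tr <- data.frame(as_id = "t", chrom = "chr1", anchor = 10000L,
                   stringsAsFactors = FALSE)
  out <- associate(tr, pk, "as", window = 250)
  expect_equal(out$peak_id, "near")
  expect_equal(out$distance, 100)
})

test_that("association is invariant under genome translation", {
  set.seed(8)
  pk <- data.frame(chrom = "chr1", start = 0L, end = 1L,
                   peak_id = sprintf("p%d", 1:20),
                   summit = sort(sample.int(1e5, 20)), strand = "+",
                   stringsAsFactors = FALSE)
  tr <- data.frame(as_id = sprintf("t%d", 1:30), chrom = "chr1",
                   anchor = sort(sample.int(1e5, 30)),
                   stringsAsFactors = FALSE)
  a0 <- associate(tr, pk, "as")
  shift <- 12345L
  pk2 <- transform(pk, summit = summit + shift, start = start + shift,
                   end = end + shift)
  tr2 <- transform(tr, anchor = anchor + shift)
  a1 <- associate(tr2, pk2, "as")
  expect_identical(a0, a1)
})

test_that("summaries count association and sensitivity jointly and safely", {
  calls <- data.frame(region_id = c("a", "b", "c"),
                      sensitive = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  assoc <- data.frame(transcript_id = c("a", "c"), peak_id = "p",
                      stringsAsFactors = FALSE)
  s <- summarize_sensitivity(calls, assoc)
  expect_equal(s$n, 3)
  expect_equal(s$n_associated, 2)
  expect_equal(s$n_sensitive, 2)
  expect_equal(s$n_both, 1)
  expect_equal(s$frac_both, 1 / 3)

  ## empty universe: all-zero summary, no division by zero
  s0 <- summarize_sensitivity(calls[0, ], assoc[0, ], character(0))
  expect_equal(s0$n, 0)
  expect_equal(s0$frac_sensitive, 0)

  ## fully sensitive, fully associated
  s1 <- summarize_sensitivity(
    data.frame(region_id = "a", sensitive = TRUE),
    data.frame(transcript_id = "a", peak_id = "p"))
  expect_equal(s1$frac_both, 1)
})

test_that("the recovered sensitive fraction matches the planted fraction", {
  sim <- default_sim()
  as <- sim$truth$as_transcripts
  reg <- data.frame(region_id = as$as_id, chrom = as$chrom,
                    start = as$start, end = as$end, strand = as$strand,
                    stringsAsFactors = FALSE)
  qc <- quantify(sim$tracks$chrrna_control, reg)
  qo <- quantify(sim$tracks$chrrna_oe, reg)
  calls <- sensitivity_call(qc, qo, value = "sense_rpkm")
  phat <- mean(calls$sensitive)
  p0 <- sim$config$frac_as_sensitive
  ## 95% binomial CI around the planted fraction
  expect_lt(abs(phat - p0), 1.96 * sqrt(p0 * (1 - p0) / nrow(as)) + 0.02)
})
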