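test_that("annotation generation is deterministic and respects packing constraints", {
  cfg <- sim_config(n_genes = 20, n_chromosomes = 1, genome_length = 2e6,
                    depth = 2e4, seed = 1)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  g <- a1$annotation$genes
  expect_equal(nrow(g), 20)
  expect_true(all(g$end - g$start >= 2000))
  o <- order(g$start)
  gaps <- g$start[o][-1] - g$end[o][-20]
  expect_true(all(gaps > 2000))
  expect_true(all(g$tss == ifelse(g$strand == "+", g$start, g$end - 1)))
  expect_true(all(g$tes == ifelse(g$strand == "+", g$end - 1, g$start)))

  ## byte-identical serialized annotation under one seed
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation(a1$annotation, f1, "gtf")
  write_annotation(a2$annotation, f2, "gtf")
  expect_identical(readLines(f1), readLines(f2))

  ## enhancer centres keep their clearance from genes
  e <- a1$truth$enhancers
  for (i in seq_len(nrow(e))) {
    d <- pmax(g$start - e$center[i], e$center[i] - g$end)
    expect_gt(min(d[g$chrom == e$chrom[i]]), 2000)
  }
})

test_that("invalid configurations are rejected with the violated constraint", {
  expect_error(sim_config(min_gene_length = 1000), "min_gene_length")
  expect_error(sim_config(min_intergenic_gap = 1500), "min_intergenic_gap")
  expect_error(sim_config(oe_reduction_factor = 0.5), "oe_reduction_factor")
  expect_error(sim_config(as_rate_ratio = 1.2), "as_rate_ratio")
  expect_error(
    generate_annotation(sim_config(n_genes = 200, n_chromosomes = 1,
                                   genome_length = 1e5)),
    "infeasible packing")
})

test_that("tag simulation is deterministic, conserves counts, and rejects unknown pairs", {
  cfg <- small_config()
  gen <- generate_annotation(cfg)
  for (ac in list(c("chrrna", "control"), c("chrrna", "oe"),
                  c("rloop", "d210n"), c("rloop", "wkkd"),
                  c("cap", "control"), c("cap", "oe"))) {
    t1 <- simulate_tags(gen$annotation, gen$truth, ac[1], ac[2], cfg)
    t2 <- simulate_tags(gen$annotation, gen$truth, ac[1], ac[2], cfg)
    expect_identical(t1, t2)
    expect_identical(t1$total_tags, nrow(t1$tags))
    expect_identical(t1$label, paste(ac[1], ac[2], sep = ":"))
  }
  expect_error(simulate_tags(gen$annotation, gen$truth, "rloop", "control",
                             cfg), "unknown assay/condition")
})

test_that("the WKKD track is background-only: planted peaks are not enriched", {
  cfg <- small_config()
  gen <- generate_annotation(cfg)
  trk <- simulate_tags(gen$annotation, gen$truth, "rloop", "wkkd", cfg)
  ## total within Poisson range of the configured background depth
  expect_lt(abs(trk$total_tags - cfg$depth), 5 * sqrt(cfg$depth))
  ## pooled count over all planted peak intervals consistent with lambda_bg
  pk <- gen$truth$peaks
  pos <- trk$tags$pos[trk$tags$chrom == "chr1"]
  obs <- sum(vapply(seq_len(nrow(pk)),
                    function(i) sum(pos >= pk$start[i] & pos < pk$end[i]),
                    numeric(1)))
  expected <- sum(pk$end - pk$start) * cfg$depth / cfg$genome_length
  expect_lt(abs(obs - expected), 5 * sqrt(expected))
})

test_that("overexpression halves sensitive antisense output across replicate simulations", {
  cfg <- sim_config(n_genes = 6, n_chromosomes = 1, genome_length = 2e5,
                    depth = 400, frac_as_sensitive = 1,
                    oe_reduction_factor = 2, n_enhancers = 0, seed = 11)
  gen <- generate_annotation(cfg)
  as <- gen$truth$as_transcripts
  count_as <- function(trk) {
    sum(vapply(seq_len(nrow(as)), function(i) {
      sum(trk$tags$pos >= as$start[i] & trk$tags$pos < as$end[i] &
            trk$tags$strand == as$strand[i])
    }, numeric(1)))
  }
  tot_c <- tot_o <- 0
  for (r in seq_len(200)) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    tot_c <- tot_c + count_as(simulate_tags(gen$annotation, gen$truth,
                                            "chrrna", "control", cfg_r))
    tot_o <- tot_o + count_as(simulate_tags(gen$annotation, gen$truth,
                                            "chrrna", "oe", cfg_r))
  }
  ## analytic expectation includes the uniform background inside AS spans
  lam_s <- cfg$depth / cfg$genome_length / 2
  exp_c <- sum((as$rate_control + lam_s) * (as$end - as$start))
  exp_o <- sum((as$rate_oe + lam_s) * (as$end - as$start))
  expect_lt(abs(tot_o / tot_c - exp_o / exp_c), 0.02)
  expect_lt(abs(exp_o / exp_c - 0.5), 0.03)
})

test_that("sense gene-body coverage follows the planted Poisson rates", {
  cfg <- sim_config(seed = 3)
  gen <- generate_annotation(cfg)
  trk <- simulate_tags(gen$annotation, gen$truth, "chrrna", "control", cfg)
  g <- gen$truth$genes
  lam_s <- cfg$depth / (cfg$n_chromosomes * cfg$genome_length) / 2
  obs <- vapply(seq_len(nrow(g)), function(i) {
    sum(trk$tags$pos >= g$start[i] & trk$tags$pos < g$end[i] &
          trk$tags$chrom == g$chrom[i] & trk$tags$strand == g$strand[i])
  }, numeric(1))
  expected <- (g$rate + lam_s) * (g$end - g$start)
  ## chi-square goodness of fit against the analytic Poisson means
  x2 <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(x2, df = nrow(g), lower.tail = FALSE)
  expect_gt(p, 1e-3)
})

test_that("promoter-coupled antisense transcripts sit within 250 bp of a planted summit", {
  gen <- generate_annotation(sim_config(seed = 5))
  as <- gen$truth$as_transcripts
  pk <- gen$truth$peaks
  for (i in seq_len(nrow(as))) {
    d <- abs(pk$summit[pk$chrom == as$chrom[i]] - as$a5[i])
    expect_lte(min(d), 250)
  }
  expect_true(all(as$sensitive %in% c(TRUE, FALSE)))
  expect_true(all(as$as_id[as$sensitive] %in% as$as_id))
})

test_that("bisulfite clones convert deterministically at the planted rates", {
  ## extremes: everything inside converted, nothing outside
  sim <- simulate_bisulfite_clones(400, c(100, 300), n_clones = 5,
                                   p_in = 1, p_out = 0, seed = 1)
  refv <- strsplit(sim$reference, "")[[1]]
  cpos <- which(refv == "C") - 1L
  inside <- cpos >= 100 & cpos < 300
  for (cl in sim$clones_ct) {
    clv <- strsplit(cl, "")[[1]]
    expect_true(all(clv[cpos[inside] + 1L] == "T"))
    expect_true(all(clv[cpos[!inside] + 1L] == "C"))
  }

  ## per-position conversion frequencies match the binomial expectation
  n <- 60
  sim2 <- simulate_bisulfite_clones(600, c(200, 450), n_clones = n,
                                    p_in = 0.9, p_out = 0.01, seed = 2)
  prof <- conversion_profile(sim2$reference, sim2$clones_ct, "CT")
  inside2 <- prof$pos >= 200 & prof$pos < 450
  ## pooled counts against exact binomial quantiles
  kin <- sum(prof$conversions[inside2]); nin <- sum(prof$coverage[inside2])
  kout <- sum(prof$conversions[!inside2]); nout <- sum(prof$coverage[!inside2])
  expect_gt(kin, qbinom(1e-5, nin, 0.9))
  expect_lt(kin, qbinom(1 - 1e-5, nin, 0.9))
  expect_lt(kout, qbinom(1 - 1e-5, nout, 0.01))

  ## degenerate reference: no informative positions inside the footprint
  ref <- paste(rep(c("A", "T"), 100), collapse = "")
  sim3 <- simulate_bisulfite_clones(footprint = c(50, 150), n_clones = 3,
                                    p_in = 0.9, p_out = 0, seed = 3,
                                    reference = ref)
  prof3 <- conversion_profile(sim3$reference, sim3$clones_ct, "CT")
  expect_equal(nrow(prof3), 0)

  ## validation
  expect_error(simulate_bisulfite_clones(p_in = 0.5, p_out = 0.9),
               "p_out")
  expect_error(simulate_bisulfite_clones(400, c(100, 600)),
               "footprint outside reference")
})
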