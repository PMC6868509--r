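mk_ann <- function(genes, len = 1e6) {
  gene_annotation(genes, chrom_lengths = c(chr1 = as.integer(len)))
}

test_that("the non-overlapping gene filter applies the 2 kb rules", {
  ## two genes with a 1.9 kb gap: both removed
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  start = c(10000L, 16900L), end = c(15000L, 22000L),
                  strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_nonoverlapping_genes(mk_ann(g))$genes), 0)

  ## same genes with a 2.5 kb gap: both kept
  g2 <- g; g2$start[2] <- 17500L; g2$end[2] <- 22500L
  expect_equal(nrow(filter_nonoverlapping_genes(mk_ann(g2))$genes), 2)

  ## isolated 5 kb gene kept; isolated 1.5 kb and exactly-2 kb genes removed
  iso <- data.frame(gene_id = c("big", "small", "edge"), chrom = "chr1",
                    start = c(10000L, 100000L, 200000L),
                    end = c(15000L, 101500L, 202000L), strand = "+",
                    stringsAsFactors = FALSE)
  kept <- filter_nonoverlapping_genes(mk_ann(iso))$genes$gene_id
  expect_identical(kept, "big")

  ## overlapping genes are removed even when a third gene is clean
  ov <- data.frame(gene_id = c("x", "y", "z"), chrom = "chr1",
                   start = c(10000L, 12000L, 50000L),
                   end = c(16000L, 18000L, 55000L), strand = "+",
                   stringsAsFactors = FALSE)
  expect_identical(filter_nonoverlapping_genes(mk_ann(ov))$genes$gene_id,
                   "z")
})

test_that("peaks are classified into the oriented category windows", {
  ## + strand gene with TSS at 10000, TES at 14999
  ann <- mk_ann(data.frame(gene_id = "g", chrom = "chr1", start = 10000L,
                           end = 15000L, strand = "+",
                           stringsAsFactors = FALSE))
  mk_pk <- function(summit, strand) {
    data.frame(chrom = "chr1", start = summit - 50L, end = summit + 50L,
               peak_id = "p", summit = as.integer(summit), strand = strand,
               stringsAsFactors = FALSE)
  }
  cls <- function(summit, strand)
    classify_peaks(mk_pk(summit, strand), ann)$category

  expect_equal(cls(9200, "+"), "TSS")      # 800 bp upstream
  expect_equal(cls(8000, "+"), "TSS")      # window edge, included
  expect_equal(cls(7999, "+"), "intergenic")
  expect_equal(cls(10999, "+"), "TSS")     # 1 kb downstream edge - 1
  expect_equal(cls(12000, "+"), "genebody")
  expect_equal(cls(14500, "+"), "TES")
  expect_equal(cls(16998, "+"), "TES")     # 2 kb downstream of TES edge
  expect_equal(cls(12000, "-"), "AS")      # mid-gene, reverse direction
  expect_equal(cls(16999, "-"), "AS")      # within the 2 kb pad
  expect_equal(cls(60000, "+"), "intergenic")

  ## ambiguous strand is rejected
  expect_error(classify_peaks(mk_pk(12000, "."), ann), "ambiguous")
})

test_that("category conflicts resolve by TSS > TES priority and nearest gene", {
  ## gene A's TES window overlaps gene B's TSS window; peak lands in both
  ann <- mk_ann(data.frame(gene_id = c("A", "B"), chrom = "chr1",
                           start = c(10000L, 20000L),
                           end = c(17000L, 26000L), strand = "+",
                           stringsAsFactors = FALSE))
  pk <- data.frame(chrom = "chr1", start = 18200L, end = 18400L,
                   peak_id = "p", summit = 18300L, strand = "+",
                   stringsAsFactors = FALSE)
  call <- classify_peaks(pk, ann)
  expect_equal(call$category, "TSS")
  expect_equal(call$host_gene_id, "B")
})

test_that("classification is exactly symmetric under genome mirroring", {
  sim <- default_sim()
  ann <- filter_nonoverlapping_genes(sim$annotation)
  pk <- sim$peaks[sim$peaks$strand %in% c("+", "-"), ]
  calls <- classify_peaks(pk, ann)

  m_ann <- mirror_annotation(ann)
  m_pk <- mirror_peaks(pk, sim$annotation$chrom_lengths)
  m_calls <- classify_peaks(m_pk, m_ann)
  expect_identical(m_calls$category, calls$category)
  expect_identical(m_calls$host_gene_id, calls$host_gene_id)
})

test_that("every strand-assigned peak receives exactly one category", {
  sim <- default_sim()
  ann <- filter_nonoverlapping_genes(sim$annotation)
  pk <- sim$peaks[sim$peaks$strand %in% c("+", "-"), ]
  calls <- classify_peaks(pk, ann)
  expect_equal(nrow(calls), nrow(pk))
  expect_true(all(calls$category %in%
                    c("TSS", "TES", "genebody", "AS", "intergenic")))
  expect_true(all(is.na(calls$host_gene_id) ==
                    (calls$category == "intergenic")))
  cs <- category_summary(calls)
  expect_equal(sum(cs$count), nrow(pk))
  expect_equal(sum(cs$fraction), 1)
})

test_that("quantification regions follow the PROMPT/eRNA geometry and clip at edges", {
  ann <- mk_ann(data.frame(gene_id = c("gp", "gm", "edge"), chrom = "chr1",
                           start = c(10000L, 40000L, 1000L),
                           end = c(15000L, 45000L, 4000L),
                           strand = c("+", "-", "+"),
                           stringsAsFactors = FALSE))
  enh <- data.frame(enh_id = "e1", chrom = "chr1", center = 50000L,
                    stringsAsFactors = FALSE)
  expect_message(reg <- build_regions(ann, enh), "clipped")

  pr <- reg[reg$region_id == "gp:PROMPT", ]
  expect_equal(c(pr$start, pr$end), c(7000, 10000))
  expect_equal(pr$strand, "-")

  ## - strand gene: PROMPT is upstream in its direction, i.e. to the right
  pm <- reg[reg$region_id == "gm:PROMPT", ]
  expect_equal(c(pm$start, pm$end), c(45000, 48000))
  expect_equal(pm$strand, "+")

  er <- reg[reg$type == "eRNA", ]
  expect_equal(c(er$start, er$end), c(48000, 52000))

  ## TSS at 1000: PROMPT clipped to [0, 1000)
  pe <- reg[reg$region_id == "edge:PROMPT", ]
  expect_equal(c(pe$start, pe$end), c(0, 1000))

  expect_true(all(reg$start < reg$end))
  expect_equal(reg[reg$type == "premRNA", "start"],
               c(10000, 40000, 1000))
})
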