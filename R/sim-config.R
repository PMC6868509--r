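#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults encode
#' the study conditions the rest of the package is exercised under: genes of
#' 2-5 kb separated by more than 2 kb (so all survive the non-overlapping gene
#' filter), TSS/TES/enhancer-anchored R-loop peaks at 10-fold enrichment over
#' a flat background, lower-level antisense transcripts at one tenth of the
#' host gene's rate, and a designated sensitive subset whose antisense output
#' drops `oe_reduction_factor`-fold upon RNase H1 overexpression.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param n_genes number of genes across the genome.
#' @param min_gene_length,max_gene_length gene length range, bp. Must be
#'   >= 2000 so every simulated gene passes the length filter applied by
#'   [filter_nonoverlapping_genes()].
#' @param min_intergenic_gap minimum bp between neighbouring features; must
#'   exceed 2000 so simulated genes survive the 2 kb proximity filter.
#' @param n_enhancers number of intergenic enhancer centres.
#' @param frac_as_sensitive fraction of antisense transcripts planted as
#'   RNase-H1 sensitive (Bernoulli per transcript).
#' @param as_rate_ratio antisense/sense expression ratio in (0, 1).
#' @param oe_reduction_factor fold reduction of sensitive antisense loci in
#'   the overexpression condition; >= 1 (1 = exact null).
#' @param peak_fold pooled tag-rate enrichment of planted R-loop peaks over
#'   background in the D210N track; 1 = exact null (no enrichment).
#' @param peak_width width of planted peaks, bp.
#' @param depth expected number of background tags per track; the uniform
#'   background rate is `lambda_bg = depth / (n_chromosomes * genome_length)`
#'   pooled over both strands.
#' @param sense_rate expected sense tag rate per bp of gene body in the
#'   chromatin RNA tracks (modulated per gene by a lognormal factor,
#'   `rate_sdlog`).
#' @param rate_sdlog sdlog of the per-gene lognormal expression multiplier.
#' @param as_length_range antisense transcript length range, bp.
#' @param as_class_probs probabilities of the three antisense classes
#'   (5'AS upstream-antisense of the TSS, gene AS internal, 3'AS at the TES).
#' @param cap_tss_count expected capped 5'-end tags per gene TSS.
#' @param cap_as_count expected capped 5'-end tags per antisense transcript
#'   5' end.
#' @param cap_jitter_sd positional jitter (sd, bp) of capped 5'-end tags.
#' @param cap_background expected stray background tags per cap track.
#' @param promoter_coupled if `TRUE`, every antisense 5' end is planted
#'   within 250 bp of a planted peak summit (positive control for the
#'   association analysis).
#' @param seed integer seed; identical configs give byte-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 20, genome_length = 1e6, n_chromosomes = 1,
#'                   depth = 2e4, seed = 1)
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chromosomes = 2,
                       n_genes = 200,
                       min_gene_length = 2000,
                       max_gene_length = 5000,
                       min_intergenic_gap = 2500,
                       n_enhancers = 20,
                       frac_as_sensitive = 0.5,
                       as_rate_ratio = 0.1,
                       oe_reduction_factor = 2,
                       peak_fold = 10,
                       peak_width = 400,
                       depth = 4e4,
                       sense_rate = 0.8,
                       rate_sdlog = 0.2,
                       as_length_range = c(1200, 1800),
                       as_class_probs = c(five_prime = 0.5, gene = 0.25,
                                          three_prime = 0.25),
                       cap_tss_count = 400,
                       cap_as_count = 120,
                       cap_jitter_sd = 10,
                       cap_background = 1000,
                       promoter_coupled = TRUE,
                       seed = 1) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              n_genes = n_genes, min_gene_length = min_gene_length,
              max_gene_length = max_gene_length,
              min_intergenic_gap = min_intergenic_gap,
              n_enhancers = n_enhancers,
              frac_as_sensitive = frac_as_sensitive,
              as_rate_ratio = as_rate_ratio,
              oe_reduction_factor = oe_reduction_factor,
              peak_fold = peak_fold, peak_width = peak_width, depth = depth,
              sense_rate = sense_rate, rate_sdlog = rate_sdlog,
              as_length_range = as_length_range,
              as_class_probs = as_class_probs,
              cap_tss_count = cap_tss_count, cap_as_count = cap_as_count,
              cap_jitter_sd = cap_jitter_sd, cap_background = cap_background,
              promoter_coupled = isTRUE(promoter_coupled),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  .assert(cfg$min_gene_length >= 2000,
          "min_gene_length must be >= 2000 (genes below 2 kb are discarded by the gene filter)")
  .assert(cfg$min_intergenic_gap > 2000,
          "min_intergenic_gap must be > 2000 (the 2 kb proximity filter would drop every gene)")
  .assert(cfg$max_gene_length >= cfg$min_gene_length,
          "max_gene_length must be >= min_gene_length")
  .assert(cfg$oe_reduction_factor >= 1, "oe_reduction_factor must be >= 1")
  .assert(cfg$frac_as_sensitive >= 0 && cfg$frac_as_sensitive <= 1,
          "frac_as_sensitive must be in [0, 1]")
  .assert(cfg$as_rate_ratio > 0 && cfg$as_rate_ratio < 1,
          "as_rate_ratio must be in (0, 1)")
  .assert(cfg$peak_fold >= 1, "peak_fold must be >= 1")
  .assert(cfg$depth > 0 && cfg$sense_rate > 0 && cfg$cap_tss_count > 0 &&
            cfg$cap_as_count > 0, "all rates must be > 0")
  .assert(.is_count(cfg$n_genes) && cfg$n_genes >= 1, "n_genes must be a positive count")
  .assert(.is_count(cfg$n_chromosomes) && cfg$n_chromosomes >= 1,
          "n_chromosomes must be a positive count")
  .assert(.is_count(cfg$n_enhancers), "n_enhancers must be a count")
  .assert(length(cfg$as_class_probs) == 3 && all(cfg$as_class_probs >= 0) &&
            sum(cfg$as_class_probs) > 0, "as_class_probs must be 3 non-negative weights")
  .assert(length(cfg$as_length_range) == 2 &&
            cfg$as_length_range[1] >= 500 &&
            cfg$as_length_range[2] >= cfg$as_length_range[1],
          "as_length_range must be an increasing pair >= 500 bp")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp\n", x$n_chromosomes,
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  genes: %d (%d-%d bp), gap > %d bp, enhancers: %d\n",
              x$n_genes, x$min_gene_length, x$max_gene_length,
              x$min_intergenic_gap, x$n_enhancers))
  cat(sprintf("  background depth: %s tags/track; peak fold %g (width %d bp)\n",
              format(x$depth, big.mark = ","), x$peak_fold, x$peak_width))
  cat(sprintf("  AS/sense ratio %.2f; sensitive fraction %.2f; OE reduction %gx\n",
              x$as_rate_ratio, x$frac_as_sensitive, x$oe_reduction_factor))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## pooled (both-strand) background tag rate per bp
.lambda_bg <- function(cfg) cfg$depth / (cfg$n_chromosomes * cfg$genome_length)
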