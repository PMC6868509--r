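#' Simulate a stranded 5'-tag track for one assay/condition
#'
#' Draws independent Poisson tag counts per position class and places tags
#' uniformly within each class interval:
#'
#' * all assays: uniform background at pooled rate `lambda_bg =
#'   depth / genome_bp`, split equally between strands;
#' * `chrrna`: sense gene-body tags at the per-gene planted rate, antisense
#'   tags within each antisense transcript at `as_rate_ratio` times the host
#'   rate; under `condition = "oe"` the sensitive antisense loci are reduced
#'   `oe_reduction_factor`-fold, every other class unchanged;
#' * `rloop`: `condition = "d210n"` adds `(peak_fold - 1) * lambda_bg` on the
#'   peak's strand inside every planted peak, so the pooled in-peak rate is
#'   exactly `peak_fold * lambda_bg` (and `peak_fold = 1` is an exact null);
#'   `condition = "wkkd"` is background only;
#' * `cap`: tags concentrated at gene TSSs and antisense 5' ends with
#'   Gaussian positional jitter; sensitive antisense cap counts are reduced
#'   under `"oe"`.
#'
#' Identical `(annotation, truth, assay, condition, config)` input gives a
#' byte-identical track; each assay/condition pair uses its own RNG stream
#' derived from `config$seed`.
#'
#' @param annotation,truth output of [generate_annotation()].
#' @param assay `"chrrna"`, `"rloop"` or `"cap"`.
#' @param condition `"control"`/`"oe"` for chrrna and cap;
#'   `"d210n"`/`"wkkd"` for rloop.
#' @param config the [sim_config()] used to generate the annotation.
#' @return A [tag_track()] labelled `"assay:condition"`.
#' @examples
#' sim <- generate_annotation(sim_config(n_genes = 10, n_chromosomes = 1,
#'                                       genome_length = 5e5, depth = 1e4))
#' trk <- simulate_tags(sim$annotation, sim$truth, "rloop", "wkkd",
#'                      sim$truth$config)
#' trk$total_tags
#' @export
simulate_tags <- function(annotation, truth, assay, condition, config) {
  .assert(inherits(annotation, "gene_annotation"), "not a gene_annotation")
  .assert(inherits(truth, "synthetic_truth"), "not a synthetic_truth")
  set.seed(.track_seed(config$seed, assay, condition))
  lam <- .lambda_bg(config)
  cl <- annotation$chrom_lengths

  if (assay == "cap") {
    tags <- .simulate_cap(truth, condition, config, cl)
    return(tag_track(tags, cl, paste(assay, condition, sep = ":")))
  }

  ## interval classes: chrom, start, end, strand, expected count
  classes <- data.frame(chrom = rep(names(cl), each = 2L),
                        start = 0L, end = rep(unname(cl), each = 2L),
                        strand = rep(c("+", "-"), length(cl)),
                        expected = rep(unname(cl), each = 2L) * lam / 2,
                        shape = "uniform")

  if (assay == "chrrna") {
    g <- truth$genes
    classes <- rbind(classes, data.frame(
      chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
      expected = g$rate * (g$end - g$start), shape = "uniform"))
    as <- truth$as_transcripts
    as_rate <- if (condition == "oe") as$rate_oe else as$rate_control
    classes <- rbind(classes, data.frame(
      chrom = as$chrom, start = as$start, end = as$end, strand = as$strand,
      expected = as_rate * (as$end - as$start), shape = "uniform"))
  } else if (assay == "rloop" && condition == "d210n") {
    pk <- truth$peaks
    ## planted R-loop signal is peaked (triangular density centred on the
    ## summit), not a flat plateau; total mass = (peak_fold - 1) * lam * width
    classes <- rbind(classes, data.frame(
      chrom = pk$chrom, start = pk$start, end = pk$end, strand = pk$strand,
      expected = (config$peak_fold - 1) * lam * (pk$end - pk$start),
      shape = "triangular"))
  }
  ## rloop/wkkd: background only

  tags <- .draw_class_tags(classes)
  tag_track(tags, cl, paste(assay, condition, sep = ":"))
}

.draw_class_tags <- function(classes) {
  if (is.null(classes$shape)) classes$shape <- "uniform"
  n <- stats::rpois(nrow(classes), classes$expected)
  keep <- which(n > 0L)
  if (length(keep) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  chrom <- rep(classes$chrom[keep], n[keep])
  strand <- rep(classes$strand[keep], n[keep])
  width <- rep(classes$end[keep] - classes$start[keep], n[keep])
  tri <- rep(classes$shape[keep] == "triangular", n[keep])
  ntot <- sum(n[keep])
  u <- stats::runif(ntot)
  ## triangular classes use the mean of two uniforms: density peaks at the
  ## interval centre
  u[tri] <- (u[tri] + stats::runif(sum(tri))) / 2
  pos <- rep(classes$start[keep], n[keep]) + floor(u * width)
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

.simulate_cap <- function(truth, condition, config, chrom_lengths) {
  g <- truth$genes
  as <- truth$as_transcripts
  as_cap <- rep(config$cap_as_count, nrow(as))
  if (condition == "oe")
    as_cap[as$sensitive] <- as_cap[as$sensitive] / config$oe_reduction_factor

  src <- data.frame(chrom = c(g$chrom, as$chrom),
                    pos = c(g$tss, as$a5),
                    strand = c(g$strand, as$strand),
                    expected = c(rep(config$cap_tss_count, nrow(g)), as_cap))
  n <- stats::rpois(nrow(src), src$expected)
  keep <- which(n > 0L)
  pos <- rep(src$pos[keep], n[keep]) +
    as.integer(round(stats::rnorm(sum(n[keep]), 0, config$cap_jitter_sd)))
  tags <- data.frame(chrom = rep(src$chrom[keep], n[keep]),
                     pos = pos,
                     strand = rep(src$strand[keep], n[keep]),
                     stringsAsFactors = FALSE)
  ## sparse stray background
  bg <- data.frame(chrom = rep(names(chrom_lengths), each = 2L),
                   start = 0L, end = rep(unname(chrom_lengths), each = 2L),
                   strand = rep(c("+", "-"), length(chrom_lengths)),
                   expected = config$cap_background /
                     (2 * length(chrom_lengths)))
  tags <- rbind(tags, .draw_class_tags(bg))
  tags$pos <- pmin(pmax(tags$pos, 0L),
                   unname(chrom_lengths[tags$chrom]) - 1L)
  tags
}
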