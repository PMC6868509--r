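#' Generate a synthetic gene annotation with ground truth
#'
#' Packs non-overlapping genes and intergenic enhancer centres onto the
#' simulated chromosomes, assigns strands, and plants the ground-truth
#' features the downstream analysis is meant to recover: an R-loop peak at
#' every gene TSS and TES and at every enhancer centre, plus one antisense
#' transcript per gene (5'AS, gene AS or 3'AS) whose 5' end is, in
#' promoter-coupled mode, within 250 bp of a planted peak summit. A random
#' subset of antisense transcripts is labelled RNase-H1 sensitive.
#'
#' All coordinates are 0-based half-open; strands are `+`/`-`; the TSS is the
#' 5' end of the gene in its direction of transcription and the TES the 3'
#' end (poly(A) position).
#'
#' @param config a [sim_config()] object.
#' @return A list with components `annotation` (a `gene_annotation`) and
#'   `truth` (a `synthetic_truth` holding planted peaks, antisense
#'   transcripts with sensitivity labels, enhancers, and per-locus expected
#'   tag rates).
#' @examples
#' sim <- generate_annotation(sim_config(n_genes = 20, n_chromosomes = 1,
#'                                       genome_length = 1e6, depth = 2e4,
#'                                       seed = 1))
#' nrow(sim$annotation$genes)
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_feat <- config$n_genes + config$n_enhancers
  ## features (genes + zero-width enhancer centres) distributed round-robin
  chrom_of <- rep_len(seq_len(config$n_chromosomes), n_feat)
  is_gene <- sample(rep(c(TRUE, FALSE), c(config$n_genes, config$n_enhancers)))

  widths <- integer(n_feat)
  widths[is_gene] <- floor(stats::runif(config$n_genes,
                                        config$min_gene_length,
                                        config$max_gene_length + 1))
  g <- config$min_intergenic_gap + 1L

  starts <- integer(n_feat)
  for (ch in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ch)
    k <- length(idx)
    if (k == 0L) next
    need <- sum(widths[idx]) + (k + 1L) * g
    if (need > config$genome_length)
      stop(sprintf(paste0("infeasible packing: chromosome %d needs %d bp for %d ",
                          "features with min_intergenic_gap %d but genome_length is %d"),
                   ch, need, k, config$min_intergenic_gap, config$genome_length),
           call. = FALSE)
    slack <- config$genome_length - need
    u <- stats::runif(k + 1L)
    extra <- floor(u / sum(u) * slack)
    gaps <- g + extra
    starts[idx] <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, widths[idx][-k]))
  }
  ends <- starts + widths

  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(config$genome_length,
                                       config$n_chromosomes), chrom_names)

  gi <- which(is_gene)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = chrom_names[chrom_of[gi]],
    start = starts[gi], end = ends[gi], strand = strand,
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$rate <- config$sense_rate * stats::rlnorm(config$n_genes, 0,
                                                  config$rate_sdlog)

  ei <- which(!is_gene)
  enhancers <- data.frame(
    enh_id = sprintf("enh%03d", seq_along(ei)),
    chrom = chrom_names[chrom_of[ei]],
    center = starts[ei],
    strand = sample(c("+", "-"), length(ei), replace = TRUE),
    stringsAsFactors = FALSE)

  ## planted R-loop peaks: one at every TSS and TES (on the gene strand) and
  ## one at every enhancer centre
  half <- config$peak_width %/% 2L
  mk_peak <- function(anchor_pos, strand, chrom, anchor, anchor_id) {
    data.frame(chrom = chrom, start = anchor_pos - half,
               end = anchor_pos - half + config$peak_width,
               summit = anchor_pos, strand = strand, anchor = anchor,
               anchor_id = anchor_id, stringsAsFactors = FALSE)
  }
  peaks <- rbind(
    mk_peak(genes$tss, genes$strand, genes$chrom, "TSS", genes$gene_id),
    mk_peak(genes$tes, genes$strand, genes$chrom, "TES", genes$gene_id),
    if (nrow(enhancers))
      mk_peak(enhancers$center, enhancers$strand, enhancers$chrom,
              "enhancer", enhancers$enh_id))
  peaks$peak_id <- sprintf("planted%03d", seq_len(nrow(peaks)))
  peaks$start <- pmax(peaks$start, 0L)

  truth_as <- .plant_as_transcripts(genes, config)

  annotation <- gene_annotation(genes[, c("gene_id", "chrom", "start", "end",
                                          "strand", "tss", "tes")],
                                chrom_lengths = chrom_lengths)

  truth <- structure(list(
    genes = genes,
    as_transcripts = truth_as,
    peaks = peaks,
    enhancers = enhancers,
    lambda_bg = .lambda_bg(config),
    config = config), class = "synthetic_truth")

  list(annotation = annotation, truth = truth)
}

## one antisense transcript per gene; intervals are half-open, strand is the
## opposite of the host; a5 is the transcript 5' end (a single position)
.plant_as_transcripts <- function(genes, config) {
  n <- nrow(genes)
  cls <- sample(c("five_prime", "gene", "three_prime"), n, replace = TRUE,
                prob = config$as_class_probs / sum(config$as_class_probs))
  len <- floor(stats::runif(n, config$as_length_range[1],
                            config$as_length_range[2] + 1))
  ## promoter-coupled mode keeps the AS 5' end well within 250 bp of the
  ## planted TSS (5'AS) or TES (gene AS / 3'AS) peak summit
  umax <- if (config$promoter_coupled) 150 else 800
  u <- floor(stats::runif(n, 30, umax + 1))
  dir <- ifelse(genes$strand == "+", 1L, -1L)
  a5 <- ifelse(cls == "five_prime", genes$tss - dir * u,
        ifelse(cls == "gene",       genes$tes - dir * u,
                                    genes$tes + dir * u))
  as_strand <- .strand_flip(genes$strand)
  start <- ifelse(as_strand == "+", a5, a5 - len + 1L)
  end <- start + len
  sensitive <- stats::runif(n) < config$frac_as_sensitive
  rate_control <- config$as_rate_ratio * genes$rate
  rate_oe <- ifelse(sensitive, rate_control / config$oe_reduction_factor,
                    rate_control)
  data.frame(as_id = sprintf("as%03d", seq_len(n)),
             gene_id = genes$gene_id, class = cls, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = as_strand, a5 = as.integer(a5),
             sensitive = sensitive, rate_control = rate_control,
             rate_oe = rate_oe, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d genes, %d AS transcripts (%d sensitive), %d planted peaks, %d enhancers\n",
              nrow(x$genes), nrow(x$as_transcripts),
              sum(x$as_transcripts$sensitive), nrow(x$peaks),
              nrow(x$enhancers)))
  invisible(x)
}
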