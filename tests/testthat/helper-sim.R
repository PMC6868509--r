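## Shared fixtures, built in code.

## small single-chromosome configuration for fast tests
small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 10, n_chromosomes = 1, genome_length = 4e5,
             n_enhancers = 2, depth = 4000, seed = seed, ...)
}

## the default study conditions, simulated once and cached across test files
.default_sim_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.default_sim_env$sim)) {
    cfg <- sim_config(seed = 1)
    gen <- generate_annotation(cfg)
    tracks <- list(
      chrrna_control = simulate_tags(gen$annotation, gen$truth, "chrrna",
                                     "control", cfg),
      chrrna_oe = simulate_tags(gen$annotation, gen$truth, "chrrna", "oe",
                                cfg),
      rloop_d210n = simulate_tags(gen$annotation, gen$truth, "rloop",
                                  "d210n", cfg),
      rloop_wkkd = simulate_tags(gen$annotation, gen$truth, "rloop", "wkkd",
                                 cfg))
    peaks <- assign_strand(call_peaks(tracks$rloop_d210n,
                                      tracks$rloop_wkkd),
                           tracks$rloop_d210n)
    .default_sim_env$sim <- list(config = cfg, annotation = gen$annotation,
                                 truth = gen$truth, tracks = tracks,
                                 peaks = peaks)
  }
  .default_sim_env$sim
}

## mirror a genome: position x -> L - 1 - x, strands flipped
mirror_peaks <- function(peaks, chrom_lengths) {
  L <- chrom_lengths[peaks$chrom]
  out <- peaks
  out$start <- as.integer(L - peaks$end)
  out$end <- as.integer(L - peaks$start)
  out$summit <- as.integer(L - 1L - peaks$summit)
  out$strand <- ifelse(peaks$strand == "+", "-",
                       ifelse(peaks$strand == "-", "+", peaks$strand))
  out
}

mirror_annotation <- function(annotation) {
  g <- annotation$genes
  L <- annotation$chrom_lengths[g$chrom]
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = as.integer(L - g$end),
                    end = as.integer(L - g$start),
                    strand = ifelse(g$strand == "+", "-", "+"),
                    stringsAsFactors = FALSE)
  gene_annotation(out, chrom_lengths = annotation$chrom_lengths)
}

## simple stranded track constructor for hand-built fixtures
make_track <- function(pos, strand, chrom = "chr1", len = NULL,
                       label = "test") {
  len <- len %||% (max(pos) + 1000L)
  tag_track(data.frame(chrom = chrom, pos = as.integer(pos),
                       strand = strand, stringsAsFactors = FALSE),
            stats::setNames(as.integer(len), chrom[1]), label)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
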