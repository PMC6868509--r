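#' Filter to the non-overlapping gene set
#'
#' Retains genes longer than `min_length` bp that have no other gene
#' (coding or non-coding) within `flank` bp of their span — the gene set
#' every strand-specific downstream analysis is restricted to. Two genes
#' separated by a gap smaller than `flank` are both removed.
#'
#' @param annotation a [gene_annotation()].
#' @param min_length minimum gene length, bp (strictly greater-than).
#' @param flank exclusion distance to any other gene, bp.
#' @return A filtered [gene_annotation()] (possibly empty).
#' @export
filter_nonoverlapping_genes <- function(annotation, min_length = 2000,
                                        flank = 2000) {
  g <- annotation$genes
  keep <- (g$end - g$start) > min_length
  for (chrom in unique(g$chrom)) {
    i <- which(g$chrom == chrom)
    if (length(i) < 2L) next
    o <- i[order(g$start[i])]
    ## running-max end of all earlier genes vs each gene's padded start,
    ## and next start vs padded running end: exact for arbitrary overlaps
    prev_max_end <- cummax(g$end[o])
    clash_left <- c(FALSE, prev_max_end[-length(o)] > g$start[o][-1] - flank)
    clash_right <- c(rev(cummin(rev(g$start[o])))[-1] <
                       g$end[o][-length(o)] + flank, FALSE)
    keep[o] <- keep[o] & !clash_left & !clash_right
  }
  out <- annotation
  out$genes <- g[keep, , drop = FALSE]
  rownames(out$genes) <- NULL
  if (!is.null(out$transcripts))
    out$transcripts <- out$transcripts[
      out$transcripts$gene_id %in% out$genes$gene_id, , drop = FALSE]
  out
}

#' Classify peaks into genomic categories
#'
#' Assigns every strand-bearing peak exactly one category, with all windows
#' oriented in the host gene's transcription direction:
#'
#' * `TSS`: summit within 2 kb upstream to 1 kb downstream of a TSS, on the
#'   gene's strand;
#' * `TES`: within 1 kb upstream to 2 kb downstream of the poly(A) site, on
#'   the gene's strand;
#' * `genebody`: the remaining genic region, on the gene's strand;
#' * `AS`: within the gene span padded by 2 kb on both sides, but on the
#'   reverse strand;
#' * `intergenic`: no overlap with any of the above.
#'
#' Multi-category conflicts are resolved by the fixed priority
#' TSS > TES > genebody > AS; among several genes offering the same
#' category, the nearest anchoring feature wins. By default a peak is "in"
#' a window if its summit is (`mode = "summit"`); `mode = "overlap"` instead
#' requires any overlap of the peak interval with the window.
#'
#' @param peaks a strand-assigned `peak_set`; peaks with strand `"."` are
#'   rejected.
#' @param annotation the filtered [gene_annotation()].
#' @param mode `"summit"` (default) or `"overlap"`.
#' @param tss_up,tss_down,tes_up,tes_down,as_flank window sizes, bp.
#' @return A data.frame (`category_calls`): `peak_id, category,
#'   host_gene_id, distance` (signed bp from summit to the anchoring
#'   feature, in the gene's direction; `NA` for intergenic).
#' @export
classify_peaks <- function(peaks, annotation, mode = c("summit", "overlap"),
                           tss_up = 2000, tss_down = 1000, tes_up = 1000,
                           tes_down = 2000, as_flank = 2000) {
  mode <- match.arg(mode)
  .assert(!any(peaks$strand == "."),
          "peak(s) with ambiguous strand '.': exclude them before classification")
  .assert(all(peaks$strand %in% c("+", "-")), "peaks must carry +/- strands")
  g <- annotation$genes
  n <- nrow(peaks)
  category <- rep("intergenic", n)
  host <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  prio <- c(TSS = 1, TES = 2, genebody = 3, AS = 4, intergenic = 5)

  for (i in seq_len(n)) {
    gs <- g[g$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(gs) == 0L) next
    x <- peaks$summit[i]
    dir <- ifelse(gs$strand == "+", 1L, -1L)
    d_tss <- dir * (x - gs$tss)
    d_tes <- dir * (x - gs$tes)
    same <- gs$strand == peaks$strand[i]
    if (mode == "summit") {
      in_tss <- same & d_tss >= -tss_up & d_tss < tss_down
      in_tes <- same & d_tes >= -tes_up & d_tes < tes_down
      in_body <- same & x >= gs$start & x < gs$end
      in_as <- !same & x >= gs$start - as_flank & x < gs$end + as_flank
    } else {
      ps <- peaks$start[i]; pe <- peaks$end[i]
      ov <- function(ws, we) pmax(ws, ps) < pmin(we, pe)
      w_tss_lo <- ifelse(gs$strand == "+", gs$tss - tss_up,
                         gs$tss - tss_down + 1L)
      w_tss_hi <- w_tss_lo + tss_up + tss_down
      w_tes_lo <- ifelse(gs$strand == "+", gs$tes - tes_up,
                         gs$tes - tes_down + 1L)
      w_tes_hi <- w_tes_lo + tes_up + tes_down
      in_tss <- same & ov(w_tss_lo, w_tss_hi)
      in_tes <- same & ov(w_tes_lo, w_tes_hi)
      in_body <- same & ov(gs$start, gs$end)
      in_as <- !same & ov(gs$start - as_flank, gs$end + as_flank)
    }
    cand_cat <- ifelse(in_tss, "TSS",
                ifelse(in_tes, "TES",
                ifelse(in_body, "genebody",
                ifelse(in_as, "AS", "intergenic"))))
    anchor_dist <- ifelse(cand_cat == "TSS", d_tss,
                   ifelse(cand_cat == "TES", d_tes,
                          ifelse(abs(d_tss) <= abs(d_tes), d_tss, d_tes)))
    hit <- which(cand_cat != "intergenic")
    if (length(hit) == 0L) next
    best <- hit[order(prio[cand_cat[hit]], abs(anchor_dist[hit]))][1]
    category[i] <- cand_cat[best]
    host[i] <- gs$gene_id[best]
    dist[i] <- anchor_dist[best]
  }
  out <- data.frame(peak_id = peaks$peak_id, category = category,
                    host_gene_id = host, distance = dist,
                    stringsAsFactors = FALSE)
  class(out) <- c("category_calls", "data.frame")
  out
}

#' Summarise category calls
#'
#' @param calls output of [classify_peaks()].
#' @return A data.frame of counts and fractions per category.
#' @export
category_summary <- function(calls) {
  lev <- c("TSS", "TES", "genebody", "AS", "intergenic")
  n <- table(factor(calls$category, levels = lev))
  data.frame(category = lev, count = as.integer(n),
             fraction = as.numeric(n) / max(1L, nrow(calls)),
             stringsAsFactors = FALSE)
}

#' Build the standard quantification regions
#'
#' Constructs the region table used for expression boxplots:
#' * `PROMPT`: 3 kb upstream of each TSS, on the antisense strand;
#' * `premRNA`: the whole annotated gene span, sense strand;
#' * `lincRNA`: the annotated span (TSS to TES) of supplied lincRNAs;
#' * `eRNA`: enhancer centre +/- 2 kb, both strands (strand `"."`).
#'
#' Regions extending past a chromosome edge are clipped (with a message).
#'
#' @param annotation the filtered [gene_annotation()].
#' @param enhancers optional data.frame with `enh_id, chrom, center`.
#' @param lincRNAs optional data.frame with `gene_id, chrom, start, end,
#'   strand`.
#' @param prompt_len PROMPT length upstream of the TSS, bp.
#' @param erna_flank eRNA half-window around the enhancer centre, bp.
#' @return A region data.frame: `region_id, type, chrom, start, end,
#'   strand`.
#' @export
build_regions <- function(annotation, enhancers = NULL, lincRNAs = NULL,
                          prompt_len = 3000, erna_flank = 2000) {
  g <- annotation$genes
  cl <- annotation$chrom_lengths
  prompt_start <- ifelse(g$strand == "+", g$tss - prompt_len, g$tss + 1L)
  prompt_end <- prompt_start + prompt_len
  regions <- rbind(
    data.frame(region_id = paste0(g$gene_id, ":PROMPT"), type = "PROMPT",
               chrom = g$chrom, start = prompt_start, end = prompt_end,
               strand = .strand_flip(g$strand), stringsAsFactors = FALSE),
    data.frame(region_id = paste0(g$gene_id, ":premRNA"), type = "premRNA",
               chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE))
  if (!is.null(lincRNAs) && nrow(lincRNAs))
    regions <- rbind(regions, data.frame(
      region_id = paste0(lincRNAs$gene_id, ":lincRNA"), type = "lincRNA",
      chrom = lincRNAs$chrom, start = lincRNAs$start, end = lincRNAs$end,
      strand = lincRNAs$strand, stringsAsFactors = FALSE))
  if (!is.null(enhancers) && nrow(enhancers))
    regions <- rbind(regions, data.frame(
      region_id = paste0(enhancers$enh_id, ":eRNA"), type = "eRNA",
      chrom = enhancers$chrom, start = enhancers$center - erna_flank,
      end = enhancers$center + erna_flank, strand = ".",
      stringsAsFactors = FALSE))
  clipped_lo <- regions$start < 0
  clipped_hi <- regions$end > cl[regions$chrom]
  if (any(clipped_lo | clipped_hi))
    message(sum(clipped_lo | clipped_hi),
            " region(s) clipped at chromosome edges")
  regions$start <- as.integer(pmax(regions$start, 0L))
  regions$end <- as.integer(pmin(regions$end, cl[regions$chrom]))
  rownames(regions) <- NULL
  regions
}
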