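#' Stranded expression over regions
#'
#' Counts 5'-end tags by their single stored position within each region and
#' normalises to RPKM (per kb of region per million mapped tags) and RPM
#' (per million mapped tags) using the track's total tag count. `sense`
#' tags lie on the region's strand, `antisense` tags on the opposite
#' strand; regions with strand `"."` (e.g. eRNA windows) pool both strands
#' into the sense slot. A `length` column, when present, overrides the
#' interval width in the RPKM denominator (for genes quantified by the
#' length of the longest isoform).
#'
#' @param track a [tag_track()] with at least one tag.
#' @param regions data.frame with `region_id, chrom, start, end, strand`
#'   (and optionally `length`).
#' @param strand_mode `"both"` (default), `"sense"` or `"antisense"`;
#'   restricts which columns are populated.
#' @return A data.frame (`expression_table`): `region_id, condition,
#'   sense_count, antisense_count, sense_rpkm, antisense_rpkm, sense_rpm,
#'   antisense_rpm`.
#' @examples
#' trk <- tag_track(data.frame(chrom = "chr1", pos = c(10, 20, 30),
#'                             strand = c("+", "+", "-")),
#'                  c(chr1 = 1000L), "demo")
#' quantify(trk, data.frame(region_id = "r1", chrom = "chr1", start = 0,
#'                          end = 100, strand = "+"))
#' @export
quantify <- function(track, regions, strand_mode = c("both", "sense",
                                                     "antisense")) {
  strand_mode <- match.arg(strand_mode)
  .assert(inherits(track, "tag_track"), "not a tag_track")
  .assert(track$total_tags > 0, "track has zero total tags")
  cl <- track$chrom_lengths
  .assert(all(regions$chrom %in% names(cl)),
          "region chromosome absent from track")
  .assert(all(regions$start >= 0 & regions$end <= cl[regions$chrom]),
          "region outside chromosome bounds")
  n <- nrow(regions)
  sense <- antisense <- integer(n)
  for (chrom in unique(regions$chrom)) {
    i <- which(regions$chrom == chrom)
    plus <- .count_in(.track_pos(track, chrom, "+"), regions$start[i],
                      regions$end[i])
    minus <- .count_in(.track_pos(track, chrom, "-"), regions$start[i],
                       regions$end[i])
    st <- regions$strand[i]
    sense[i] <- ifelse(st == "+", plus, ifelse(st == "-", minus,
                                               plus + minus))
    antisense[i] <- ifelse(st == "+", minus, ifelse(st == "-", plus, 0L))
  }
  if (strand_mode == "sense") antisense[] <- 0L
  if (strand_mode == "antisense") sense[] <- 0L
  len_kb <- (regions$length %||% (regions$end - regions$start)) / 1000
  mil <- track$total_tags / 1e6
  out <- data.frame(region_id = regions$region_id, condition = track$label,
                    sense_count = sense, antisense_count = antisense,
                    sense_rpkm = sense / (len_kb * mil),
                    antisense_rpkm = antisense / (len_kb * mil),
                    sense_rpm = sense / mil, antisense_rpm = antisense / mil,
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Sense/antisense expression around gene TSSs
#'
#' The promoter-window comparison of sense and antisense transcription:
#' for each gene the sense value counts tags on the gene's strand in the
#' `window` bp downstream of the TSS (direction of transcription) and the
#' antisense value counts opposite-strand tags in the `window` bp upstream
#' of the TSS (the PROMPT geometry). Values are reported as RPM and RPKM
#' (per kb of the possibly edge-clipped window).
#'
#' @param track a [tag_track()].
#' @param annotation a [gene_annotation()] (normally the filtered set).
#' @param window window size, bp (default 3000).
#' @return A data.frame: `gene_id, sense_count, antisense_count, sense_rpm,
#'   antisense_rpm, sense_rpkm, antisense_rpkm`.
#' @export
tss_sense_antisense <- function(track, annotation, window = 3000) {
  g <- annotation$genes
  .assert(track$total_tags > 0, "track has zero total tags")
  cl <- track$chrom_lengths
  ## oriented half-open windows: downstream-sense [tss, tss+w) for '+',
  ## mirrored for '-'; upstream-antisense [tss-w, tss) for '+'
  s_start <- ifelse(g$strand == "+", g$tss, g$tss - window + 1L)
  s_end <- s_start + window
  a_start <- ifelse(g$strand == "+", g$tss - window, g$tss + 1L)
  a_end <- a_start + window
  s_start <- pmax(s_start, 0L); a_start <- pmax(a_start, 0L)
  s_end <- pmin(s_end, cl[g$chrom]); a_end <- pmin(a_end, cl[g$chrom])

  sc <- ac <- integer(nrow(g))
  for (chrom in unique(g$chrom)) {
    i <- which(g$chrom == chrom)
    pp <- .track_pos(track, chrom, "+"); pm <- .track_pos(track, chrom, "-")
    splus <- .count_in(pp, s_start[i], s_end[i])
    sminus <- .count_in(pm, s_start[i], s_end[i])
    aplus <- .count_in(pp, a_start[i], a_end[i])
    aminus <- .count_in(pm, a_start[i], a_end[i])
    sc[i] <- ifelse(g$strand[i] == "+", splus, sminus)
    ac[i] <- ifelse(g$strand[i] == "+", aminus, aplus)
  }
  mil <- track$total_tags / 1e6
  data.frame(gene_id = g$gene_id, sense_count = sc, antisense_count = ac,
             sense_rpm = sc / mil, antisense_rpm = ac / mil,
             sense_rpkm = sc / ((s_end - s_start) / 1000 * mil),
             antisense_rpkm = ac / ((a_end - a_start) / 1000 * mil),
             stringsAsFactors = FALSE)
}
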