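#' Call capped 5'-end clusters
#'
#' Positional single-linkage clustering of capped 5'-end tags: same-strand
#' positions at most `merge_distance` bp apart are merged into one cluster;
#' clusters with fewer than `min_count` tags are dropped. Each cluster
#' records its interval, total tag count and mode position (the most
#' frequent 5' end, leftmost on ties). Output clusters on one strand are
#' disjoint and separated by more than `merge_distance` bp, so clustering
#' the mode positions reproduces the clustering (idempotence).
#'
#' @param cap_track a [tag_track()] of capped 5'-end positions.
#' @param merge_distance single-linkage merge distance, bp (> 0).
#' @param min_count minimum tags per reported cluster.
#' @return A data.frame (`cap_clusters`): `cluster_id, chrom, start, end,
#'   strand, count, mode_pos`.
#' @examples
#' trk <- tag_track(data.frame(chrom = "chr1", pos = c(100, 101, 103),
#'                             strand = "+"), c(chr1 = 1000L), "cap")
#' call_cap_clusters(trk, merge_distance = 25, min_count = 3)
#' @export
call_cap_clusters <- function(cap_track, merge_distance = 150,
                              min_count = 5) {
  .assert(merge_distance > 0, "merge_distance must be > 0")
  out <- list()
  for (key in names(cap_track$index)) {
    pos <- cap_track$index[[key]]
    if (length(pos) == 0L) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    grp <- cumsum(c(1L, diff(pos) > merge_distance))
    for (g in split(pos, grp)) {
      if (length(g) < min_count) next
      tab <- table(g)
      out[[length(out) + 1L]] <- data.frame(
        chrom = parts[1], start = min(g), end = max(g) + 1L,
        strand = parts[2], count = length(g),
        mode_pos = as.integer(names(tab)[which.max(tab)]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), count = integer(),
                      mode_pos = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res <- cbind(cluster_id = sprintf("cap%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res
}

#' Overlap between cap clusters and peaks
#'
#' For a peak set and a cluster set, the fraction of peaks with at least
#' one cluster within `window` bp (any strand) and the converse fraction of
#' clusters near a peak; distances are gaps between the half-open
#' intervals (0 for overlap).
#'
#' @param clusters output of [call_cap_clusters()].
#' @param peaks a `peak_set`.
#' @param window distance threshold, bp.
#' @return A one-row data.frame: `n_peaks, n_clusters,
#'   frac_peaks_with_cluster, frac_clusters_with_peak`.
#' @export
cluster_peak_overlap <- function(clusters, peaks, window = 0) {
  near <- function(a, b) {
    hits <- logical(nrow(a))
    for (chrom in unique(a$chrom)) {
      i <- which(a$chrom == chrom)
      bb <- b[b$chrom == chrom, , drop = FALSE]
      if (nrow(bb) == 0L) next
      for (j in i) {
        hits[j] <- any(.interval_gap(a$start[j], a$end[j], bb$start,
                                     bb$end) <= window)
      }
    }
    hits
  }
  frac <- function(x) if (length(x) == 0L) 0 else mean(x)
  data.frame(n_peaks = nrow(peaks), n_clusters = nrow(clusters),
             frac_peaks_with_cluster = frac(near(peaks, clusters)),
             frac_clusters_with_peak = frac(near(clusters, peaks)))
}

#' RNase-H1 sensitivity of cap clusters
#'
#' Counts capped tags over each cluster interval (on the cluster's strand)
#' in the control and overexpression tracks, normalises per million mapped
#' tags, and applies the 1.5-fold sensitivity rule of
#' [sensitivity_call()].
#'
#' @param clusters output of [call_cap_clusters()].
#' @param control_track,oe_track cap [tag_track()]s for the two conditions.
#' @param threshold,pseudocount passed to [sensitivity_call()]
#'   (pseudocount on the RPM scale).
#' @return A `sensitivity_calls` data.frame keyed by `cluster_id`.
#' @export
cluster_sensitivity <- function(clusters, control_track, oe_track,
                                threshold = 1.5, pseudocount = 0.1) {
  regions <- data.frame(region_id = clusters$cluster_id,
                        chrom = clusters$chrom, start = clusters$start,
                        end = clusters$end, strand = clusters$strand,
                        stringsAsFactors = FALSE)
  qc <- quantify(control_track, regions)
  qo <- quantify(oe_track, regions)
  sensitivity_call(qc, qo, value = "sense_rpm", threshold = threshold,
                   pseudocount = pseudocount)
}
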