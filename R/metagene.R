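#' Peak-density metagene profile
#'
#' Histogram of signed summit-to-anchor distances (each peak is attributed
#' to its nearest anchor, orientation-corrected so that positive offsets
#' point in the direction of transcription). Bins are centred on offsets
#' `-window, ..., -binsize, 0, binsize, ..., window` (the two edge bins are
#' half-width), so the zero-offset bin straddles the anchor symmetrically
#' and the bins tile `[-window, window]` exactly. The density is
#' normalised to the total number of peaks, so `sum(density * binsize)`
#' equals the fraction of peaks falling within the window.
#'
#' @param peaks a `peak_set` (needs `chrom` and `summit`).
#' @param anchors data.frame with `chrom, pos, strand` (e.g. TSSs of the
#'   filtered gene set).
#' @param window half-window, bp.
#' @param binsize bin width, bp; must divide `2 * window`.
#' @return An object of class `meta_profile` with `offset` (bin starts),
#'   `density`, `count`, `n_anchors`, `n_total`.
#' @export
peak_density_profile <- function(peaks, anchors, window = 2000,
                                 binsize = 50) {
  .assert((2 * window) %% binsize == 0,
          "binsize must divide 2 * window (%d)", 2 * window)
  .assert(nrow(anchors) > 0, "no anchors")
  nb <- as.integer(2 * window / binsize) + 1L
  counts <- integer(nb)
  for (i in seq_len(nrow(peaks))) {
    a <- anchors[anchors$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    j <- which.min(abs(peaks$summit[i] - a$pos))
    off <- (peaks$summit[i] - a$pos[j]) * ifelse(a$strand[j] == "+", 1L, -1L)
    b <- .offset_bin(off, window, binsize)
    if (!is.na(b)) counts[b] <- counts[b] + 1L
  }
  structure(list(anchor = "custom",
                 offset = seq(-window, window, by = binsize),
                 count = counts,
                 density = counts / (max(1L, nrow(peaks)) * binsize),
                 n_anchors = nrow(anchors), n_total = nrow(peaks),
                 window = window, binsize = binsize),
            class = "meta_profile")
}

## zero-centred bin index for offsets in [-window, window]; NA outside
.offset_bin <- function(off, window, binsize) {
  b <- floor((off + window + binsize / 2) / binsize) + 1L
  nb <- as.integer(2 * window / binsize) + 1L
  b <- pmin(b, nb)  # off == +window falls in the last (half) bin
  ifelse(off >= -window & off <= window, b, NA_integer_)
}

#' Coverage metagene around anchors
#'
#' Per-bin tag counts averaged over anchors and scaled per million mapped
#' tags, reported separately for the sense and antisense strand relative to
#' each anchor's direction of transcription (bins and strands are mirrored
#' for `-` anchors). Bins are centred on offsets `-window, ..., 0, ...,
#' window` as in [peak_density_profile()]; the two edge bins cover half a
#' `binsize` each.
#'
#' @param track a nonempty [tag_track()].
#' @param anchors data.frame with `chrom, pos, strand`.
#' @param window half-window, bp.
#' @param binsize bin width, bp; must divide `2 * window`.
#' @return A `meta_profile` with `sense` and `antisense` per-bin values
#'   (mean tags per anchor per bin, per million mapped tags).
#' @export
coverage_metagene <- function(track, anchors, window = 2000, binsize = 50) {
  .assert((2 * window) %% binsize == 0,
          "binsize must divide 2 * window (%d)", 2 * window)
  .assert(nrow(anchors) > 0, "no anchors")
  .assert(track$total_tags > 0, "track is empty")
  nb <- as.integer(2 * window / binsize) + 1L
  sense <- antisense <- numeric(nb)
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]; pos <- anchors$pos[i]
    dir <- ifelse(anchors$strand[i] == "+", 1L, -1L)
    for (st in c("+", "-")) {
      p <- .pos_in(.track_pos(track, chrom, st), pos - window - 1L,
                   pos + window + 2L)
      if (length(p) == 0L) next
      b <- .offset_bin(dir * (p - pos), window, binsize)
      b <- b[!is.na(b)]
      if (length(b) == 0L) next
      bins <- tabulate(b, nb)
      if (st == anchors$strand[i]) sense <- sense + bins
      else antisense <- antisense + bins
    }
  }
  scale <- 1e6 / (track$total_tags * nrow(anchors))
  structure(list(anchor = "custom", offset = seq(-window, window,
                                                 by = binsize),
                 sense = sense * scale, antisense = antisense * scale,
                 n_anchors = nrow(anchors), window = window,
                 binsize = binsize, label = track$label),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("Metagene profile: +/-%d bp in %d bp bins over %d anchor(s)\n",
              x$window, x$binsize, x$n_anchors))
  invisible(x)
}

#' Plot a metagene profile
#'
#' @param x a `meta_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meta_profile <- function(x, ...) {
  mid <- x$offset + x$binsize / 2
  if (!is.null(x$density)) {
    graphics::plot(mid, x$density, type = "h", xlab = "offset (bp)",
                   ylab = "peak density", ...)
  } else {
    graphics::plot(mid, x$sense, type = "l", xlab = "offset (bp)",
                   ylab = "RPM per anchor", ...)
    graphics::lines(mid, x$antisense, lty = 2)
    graphics::legend("topright", c("sense", "antisense"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}

#' Rank-based distribution comparison
#'
#' Standard rank tests for figure-legend style group comparisons: the
#' two-group Wilcoxon rank-sum test (exact for small samples without ties)
#' or the Kruskal-Wallis test for two or more groups.
#'
#' @param groups list of numeric vectors, each with at least one value.
#' @param method `"kruskal"` or `"wilcoxon"`.
#' @param exact for Wilcoxon: force the exact null distribution
#'   (default lets [stats::wilcox.test()] decide).
#' @return A list: `statistic`, `p_value`, `method`.
#' @examples
#' compare_distributions(list(1:3, 4:6), method = "wilcoxon")
#' @export
compare_distributions <- function(groups, method = c("kruskal", "wilcoxon"),
                                  exact = NULL) {
  method <- match.arg(method)
  .assert(is.list(groups) && all(vapply(groups, length, 1L) >= 1L),
          "each group needs at least one value")
  if (method == "wilcoxon") {
    .assert(length(groups) == 2L, "wilcoxon compares exactly 2 groups")
    ht <- stats::wilcox.test(groups[[1]], groups[[2]], exact = exact)
  } else {
    .assert(length(groups) >= 2L, "kruskal needs >= 2 groups")
    ht <- stats::kruskal.test(groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
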