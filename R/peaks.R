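#' Call strand-aware R-loop peaks against a background track
#'
#' A simplified MACS-style local-Poisson caller for 5'-tag tracks. Sliding
#' windows (pooled over strands) are scored with the Poisson upper-tail
#' p-value of the IP count given `lambda = max(genome-wide background rate,
#' local background rate in 1 kb and 10 kb flanks)`, the background scaled
#' to the IP depth. Windows significant after Benjamini-Hochberg adjustment
#' across all tested windows are merged when at most `merge_gap` bp apart.
#' Each merged peak reports its summit (position of maximum IP coverage),
#' a fold enrichment (the maximum windowed IP/expected ratio across its
#' member windows, i.e. the summit-region fold, which is what the retention
#' rule filters), and the minimum member p/q-value. Retained peaks satisfy
#' `fold_enrichment > min_fold` and `q_value < max_q` (defaults 5 and 0.05).
#' Strands are assigned afterwards with [assign_strand()] by majority vote
#' of overlapping stranded IP tags.
#'
#' @param ip,background [tag_track()] objects; `background` must be
#'   nonempty (the Poisson rate is undefined otherwise).
#' @param window,step sliding-window width and step, bp; `window >= step > 0`.
#' @param merge_gap maximum gap between significant windows merged into one
#'   peak, bp.
#' @param min_fold,max_q retention thresholds.
#' @param keep_all if `TRUE` also return sub-threshold merged peaks
#'   (flagged by `retained`).
#' @return A data.frame of class `peak_set`: `chrom, start, end, peak_id,
#'   summit, strand, ip_count, expected, fold_enrichment, p_value, q_value,
#'   retained` (strand is `"*"` until [assign_strand()] is applied). The
#'   window-level scan is attached as attribute `"windows"`.
#' @examples
#' sim <- generate_annotation(sim_config(n_genes = 10, n_chromosomes = 1,
#'                                       genome_length = 5e5, depth = 2e4))
#' ip <- simulate_tags(sim$annotation, sim$truth, "rloop", "d210n",
#'                     sim$truth$config)
#' bg <- simulate_tags(sim$annotation, sim$truth, "rloop", "wkkd",
#'                     sim$truth$config)
#' pk <- call_peaks(ip, bg)
#' nrow(pk)
#' @export
call_peaks <- function(ip, background, window = 200, step = 50,
                       merge_gap = 100, min_fold = 5, max_q = 0.05,
                       keep_all = FALSE) {
  .assert(inherits(ip, "tag_track") && inherits(background, "tag_track"),
          "ip and background must be tag_track objects")
  .assert(ip$total_tags > 0, "IP track is empty")
  .assert(background$total_tags > 0,
          "background track has zero tags: Poisson rate undefined")
  .assert(window >= step && step > 0, "need window >= step > 0")
  cl <- ip$chrom_lengths
  .assert(window <= min(cl), "window (%d) larger than smallest chromosome",
          window)

  scale <- ip$total_tags / background$total_tags
  genome_rate <- background$total_tags / sum(cl)  # pooled, per bp

  win <- lapply(names(cl), function(chrom) {
    L <- cl[[chrom]]
    starts <- seq.int(0L, L - window, by = step)
    ipp <- .track_pos(ip, chrom)
    bgp <- .track_pos(background, chrom)
    k <- .count_in(ipp, starts, starts + window)
    ctr <- starts + window / 2
    lam <- .window_lambda(bgp, ctr, window, L, genome_rate) * scale
    data.frame(chrom = chrom, start = starts, end = starts + window,
               ip_count = k, lambda = lam,
               p_value = poisson_tail(k, lam), stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, win)
  win$q_value <- benjamini_hochberg(win$p_value)

  sig <- win[win$q_value < max_q, , drop = FALSE]
  peaks <- .merge_windows(sig, merge_gap, ip, background, scale, genome_rate)
  if (nrow(peaks)) {
    peaks$retained <- peaks$fold_enrichment > min_fold & peaks$q_value < max_q
    if (!keep_all) peaks <- peaks[peaks$retained, , drop = FALSE]
    rownames(peaks) <- NULL
    if (nrow(peaks)) peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  class(peaks) <- c("peak_set", "data.frame")
  attr(peaks, "windows") <- win
  attr(peaks, "chrom_lengths") <- cl
  peaks
}

## local lambda: max of genome rate and the background rate in the 1 kb and
## 10 kb windows centred on `center`, clipped at chromosome edges, expressed
## as expected counts per `window` bp (unscaled)
.window_lambda <- function(bgp, center, window, chrom_len, genome_rate) {
  local_rate <- function(flank) {
    lo <- pmax(center - flank / 2, 0)
    hi <- pmin(center + flank / 2, chrom_len)
    .count_in(bgp, lo, hi) / (hi - lo)
  }
  pmax(genome_rate, local_rate(1000), local_rate(10000)) * window
}

.merge_windows <- function(sig, merge_gap, ip, background, scale,
                           genome_rate) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      summit = integer(), strand = character(),
                      ip_count = integer(), expected = numeric(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (chrom in unique(sig$chrom)) {
    s <- sig[sig$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1L, s$start[-1] - cummax(s$end[-nrow(s)]) > merge_gap))
    ipp <- .track_pos(ip, chrom)
    bgp <- .track_pos(background, chrom)
    L <- ip$chrom_lengths[[chrom]]
    for (gidx in split(seq_len(nrow(s)), grp)) {
      S <- min(s$start[gidx]); E <- max(s$end[gidx])
      pos <- .pos_in(ipp, S, E)
      cnt <- length(pos)
      ## summit: position of maximum smoothed IP coverage (tags within
      ## +/-50 bp), leftmost on ties
      summit <- if (cnt) {
        dens <- .count_in(pos, pos - 50L, pos + 51L)
        pos[which.max(dens)]
      } else as.integer((S + E) / 2)
      len <- E - S
      local <- function(flank) {
        lo <- max(S - flank / 2, 0); hi <- min(E + flank / 2, L)
        .count_in(bgp, lo, hi) / (hi - lo)
      }
      expected <- max(genome_rate, local(1000), local(10000)) * len * scale
      ## summit-region fold: the best member window's IP/expected ratio
      fold <- max(s$ip_count[gidx] / s$lambda[gidx])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = S, end = E, peak_id = NA_character_,
        summit = summit, strand = "*", ip_count = cnt, expected = expected,
        fold_enrichment = fold, p_value = min(s$p_value[gidx]),
        q_value = min(s$q_value[gidx]), retained = NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`; the window score of the peak
#' caller. `k = 0` gives 1 for any rate.
#'
#' @param k observed count(s).
#' @param lambda expected count(s).
#' @return p-value vector.
#' @export
poisson_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up FDR adjustment of p-values (delegates to
#' [stats::p.adjust()] after validation); realises the `q-value < 0.05`
#' retention rule of the peak caller.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values, elementwise `>= p` after monotonicity enforcement.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
#' @export
benjamini_hochberg <- function(p_values) {
  .assert(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Assign strands to pooled peaks by majority vote
#'
#' Implements post-hoc strand assignment by intersecting called peaks with
#' the strand-specific IP tags: each peak takes the majority strand of the
#' IP tags it overlaps; exact ties give strand `"."` and the peak is flagged
#' `ambiguous` (such peaks are excluded from strand-specific downstream
#' steps).
#'
#' @param peaks a `peak_set` from [call_peaks()].
#' @param ip the stranded IP [tag_track()].
#' @return `peaks` with `strand`, `plus_tags`, `minus_tags` and `ambiguous`
#'   filled in.
#' @export
assign_strand <- function(peaks, ip) {
  if (nrow(peaks) == 0L) {
    peaks$plus_tags <- integer(0); peaks$minus_tags <- integer(0)
    peaks$ambiguous <- logical(0)
    return(peaks)
  }
  plus <- minus <- integer(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    i <- which(peaks$chrom == chrom)
    plus[i] <- .count_in(.track_pos(ip, chrom, "+"), peaks$start[i],
                         peaks$end[i])
    minus[i] <- .count_in(.track_pos(ip, chrom, "-"), peaks$start[i],
                          peaks$end[i])
  }
  .assert(all(plus + minus > 0),
          "peak with zero overlapping IP tags: cannot assign strand")
  peaks$strand <- ifelse(plus > minus, "+", ifelse(minus > plus, "-", "."))
  peaks$plus_tags <- plus
  peaks$minus_tags <- minus
  peaks$ambiguous <- peaks$strand == "."
  peaks
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s)", nrow(x)))
  if (nrow(x) && !is.null(x$strand))
    cat(sprintf(" (%d +, %d -, %d ambiguous)", sum(x$strand == "+"),
                sum(x$strand == "-"), sum(x$strand == ".")))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
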