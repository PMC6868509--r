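#' Score RNase-H1 sensitivity by RPKM fold change
#'
#' A region is sensitive when its expression drops at least
#' `threshold`-fold upon RNase H1 overexpression:
#' `fold_change = (control + pseudocount) / (oe + pseudocount) >= threshold`
#' (default 1.5). Increases of at least `threshold`-fold are reported
#' separately as direction `"up"`.
#'
#' @param control,oe `expression_table`s from [quantify()] over the same
#'   regions (matched by `region_id`; mismatches are an error).
#' @param value which column to compare (default `"antisense_rpkm"`; use
#'   `"sense_rpkm"` for sense regions).
#' @param threshold sensitivity fold threshold (>= 1).
#' @param pseudocount RPKM pseudocount stabilising low-count ratios.
#' @param min_control optional minimum control value; regions below it are
#'   never called sensitive.
#' @return A data.frame (`sensitivity_calls`): `region_id, control_value,
#'   oe_value, fold_change, sensitive, direction`.
#' @examples
#' a <- data.frame(region_id = "r1", antisense_rpkm = 3.0)
#' b <- data.frame(region_id = "r1", antisense_rpkm = 1.0)
#' sensitivity_call(a, b, pseudocount = 0)
#' @export
sensitivity_call <- function(control, oe, value = "antisense_rpkm",
                             threshold = 1.5, pseudocount = 0.1,
                             min_control = 0) {
  .assert(threshold >= 1, "threshold must be >= 1")
  .assert(pseudocount >= 0, "pseudocount must be >= 0")
  .assert(identical(as.character(control$region_id),
                    as.character(oe$region_id)),
          "control and oe must cover identical region_ids in the same order")
  cv <- control[[value]]
  ov <- oe[[value]]
  .assert(!is.null(cv) && !is.null(ov), "value column '%s' missing", value)
  fold <- (cv + pseudocount) / (ov + pseudocount)
  out <- data.frame(region_id = control$region_id, control_value = cv,
                    oe_value = ov, fold_change = fold,
                    sensitive = fold >= threshold & cv >= min_control,
                    direction = ifelse(fold >= threshold, "down",
                                       ifelse(1 / fold >= threshold, "up",
                                              "stable")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sensitivity_calls", "data.frame")
  out
}

#' Associate transcripts or regions with nearby peaks
#'
#' Implements the analysis' standard association windows:
#' * `mode = "as"`: an antisense transcript is associated when its 5'-end
#'   anchor lies within `window` bp (default 250) of a peak summit;
#' * `mode = "erna"`: an eRNA region is associated when any peak interval
#'   lies within `window` bp (default 500) of the region interval;
#' * `mode = "tes"`: a transcript is associated when a peak summit lies
#'   within `window` bp (default 2000) of its annotated TES anchor.
#'
#' The nearest peak is reported; on distance ties the first peak in input
#' order wins.
#'
#' @param transcripts data.frame with `chrom` plus an `anchor` position
#'   column (modes `as`/`tes`) or `start`/`end` interval columns (mode
#'   `erna`), and an id in the first matching of `as_id`/`region_id`/
#'   `transcript_id`.
#' @param peaks a `peak_set` (needs `chrom`, `summit`, `start`, `end`,
#'   `peak_id`).
#' @param mode `"as"`, `"erna"` or `"tes"`.
#' @param window association window, bp; mode-specific default when `NULL`.
#' @return A data.frame (one row per associated transcript):
#'   `transcript_id, peak_id, distance, window, mode`.
#' @export
associate <- function(transcripts, peaks, mode = c("as", "erna", "tes"),
                      window = NULL) {
  mode <- match.arg(mode)
  window <- window %||% c(as = 250, erna = 500, tes = 2000)[[mode]]
  idcol <- intersect(c("as_id", "region_id", "transcript_id", "gene_id"),
                     names(transcripts))[1]
  .assert(!is.na(idcol), "transcripts need an id column")
  ids <- as.character(transcripts[[idcol]])
  n <- nrow(transcripts)
  hit_peak <- rep(NA_character_, n)
  hit_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- peaks[peaks$chrom == transcripts$chrom[i], , drop = FALSE]
    if (nrow(p) == 0L) next
    d <- if (mode == "erna") {
      .interval_gap(transcripts$start[i], transcripts$end[i], p$start, p$end)
    } else {
      .assert(!is.null(transcripts$anchor), "mode '%s' needs an anchor column",
              mode)
      abs(transcripts$anchor[i] - p$summit)
    }
    j <- which.min(d)
    if (d[j] <= window) {
      hit_peak[i] <- p$peak_id[j]
      hit_dist[i] <- d[j]
    }
  }
  ok <- which(!is.na(hit_peak))
  data.frame(transcript_id = ids[ok], peak_id = hit_peak[ok],
             distance = hit_dist[ok], window = rep(window, length(ok)),
             mode = rep(mode, length(ok)), stringsAsFactors = FALSE)
}

#' Summarise sensitivity and peak association
#'
#' Joint summary over a transcript universe: how many transcripts are
#' peak-associated, how many are RNase-H1 sensitive, and how many are both
#' (the stacked-pie numbers). Safe on empty inputs.
#'
#' @param calls `sensitivity_calls` from [sensitivity_call()].
#' @param associations output of [associate()].
#' @param universe character vector of transcript ids defining the
#'   denominator; defaults to the ids in `calls`.
#' @return A one-row data.frame: `n, n_associated, n_sensitive, n_both` and
#'   the corresponding fractions (0 when `n = 0`).
#' @export
summarize_sensitivity <- function(calls, associations, universe = NULL) {
  universe <- universe %||% as.character(calls$region_id)
  n <- length(universe)
  assoc <- universe %in% associations$transcript_id
  sens <- universe %in% calls$region_id[calls$sensitive]
  frac <- function(k) if (n == 0L) 0 else k / n
  data.frame(n = n, n_associated = sum(assoc), n_sensitive = sum(sens),
             n_both = sum(assoc & sens), frac_associated = frac(sum(assoc)),
             frac_sensitive = frac(sum(sens)),
             frac_both = frac(sum(assoc & sens)))
}
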