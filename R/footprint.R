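#' Call bisulfite conversions in one clone
#'
#' Compares a clone against the reference (same length, no indels): in
#' `CT` mode, reference cytosines are the informative positions and a
#' clone `T` at such a position is a conversion (a clone `C` is
#' unconverted); `GA` mode is the symmetric complementary-strand reading
#' (reference `G`, clone `A`). Any other mismatch is a sequencing error,
#' excluded from the informative set; clones with more than
#' `max_error_rate` non-bisulfite mismatches are flagged `excluded`.
#'
#' @param reference,clone character strings of equal length (ACGT/N).
#' @param mode `"CT"` or `"GA"`.
#' @param max_error_rate maximum tolerated fraction of non-bisulfite
#'   mismatches before the clone is excluded (default 0.05).
#' @return A list: `informative` (0-based reference positions), `converted`
#'   (logical per informative position), `errors` (0-based positions of
#'   non-bisulfite mismatches), `error_rate`, `excluded`.
#' @examples
#' call_conversions("ACGC", "ATGT", mode = "CT")$converted
#' @export
call_conversions <- function(reference, clone, mode = c("CT", "GA"),
                             max_error_rate = 0.05) {
  mode <- match.arg(mode)
  .assert(nchar(reference) == nchar(clone),
          "clone length (%d) differs from reference length (%d)",
          nchar(clone), nchar(reference))
  refv <- strsplit(toupper(reference), "")[[1]]
  clov <- strsplit(toupper(clone), "")[[1]]
  from <- if (mode == "CT") "C" else "G"
  to <- if (mode == "CT") "T" else "A"
  informative <- which(refv == from)
  converted <- clov[informative] == to
  unconverted <- clov[informative] == from
  ## mismatches that are not the bisulfite change (at informative or other
  ## positions) are sequencing errors
  mism <- clov != refv & clov != "N" & refv != "N"
  mism[informative] <- mism[informative] & !converted
  err <- which(mism)
  bad_informative <- informative %in% err
  keep <- !bad_informative
  rate <- length(err) / length(refv)
  list(informative = informative[keep] - 1L, converted = converted[keep],
       errors = err - 1L, error_rate = rate,
       excluded = rate > max_error_rate)
}

#' Per-position conversion profile over clones
#'
#' Aggregates [call_conversions()] across clones: for each informative
#' reference position (C in `CT` mode, G in `GA` mode) the number of
#' covering clones, the number of conversions, and their ratio. Clones
#' exceeding the error threshold are dropped (with a message).
#'
#' @param reference reference sequence.
#' @param clones character vector of clone sequences.
#' @param mode `"CT"` or `"GA"`.
#' @param max_error_rate passed to [call_conversions()].
#' @return A data.frame of class `conversion_profile`: `pos` (0-based
#'   reference coordinate), `conversions`, `coverage`, `frequency`; the
#'   number of used clones is attached as attribute `n_clones`.
#' @export
conversion_profile <- function(reference, clones, mode = c("CT", "GA"),
                               max_error_rate = 0.05) {
  mode <- match.arg(mode)
  from <- if (mode == "CT") "C" else "G"
  refv <- strsplit(toupper(reference), "")[[1]]
  informative <- which(refv == from) - 1L
  conv <- cov <- integer(length(informative))
  used <- 0L
  for (cl in clones) {
    cc <- call_conversions(reference, cl, mode, max_error_rate)
    if (cc$excluded) next
    used <- used + 1L
    idx <- match(cc$informative, informative)
    cov[idx] <- cov[idx] + 1L
    conv[idx] <- conv[idx] + as.integer(cc$converted)
  }
  if (used < length(clones))
    message(length(clones) - used, " clone(s) excluded (error rate > ",
            max_error_rate, ")")
  out <- data.frame(pos = informative, conversions = conv, coverage = cov,
                    frequency = ifelse(cov > 0, conv / cov, NA_real_))
  class(out) <- c("conversion_profile", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "n_clones") <- used
  out
}

#' Estimate the single-stranded DNA footprint interval
#'
#' Smooths the per-position conversion frequency with a centred running
#' mean over `smooth_window` informative positions (shrinking at the
#' edges) and reports the longest contiguous run of informative positions
#' with smoothed frequency at or above `freq_threshold`, in reference
#' coordinates. An empty result (no position passes) is returned as a
#' zero-length interval, not an error.
#'
#' @param profile a `conversion_profile`.
#' @param freq_threshold smoothed-frequency threshold in `[0, 1]`.
#' @param smooth_window running-mean width in informative positions (odd
#'   values centre exactly).
#' @return A list: `interval` (half-open `c(start, end)` in reference
#'   coordinates, or `integer(0)` when empty), `n_positions` (informative
#'   positions in the run), and `smoothed` (the smoothed frequency track).
#' @export
footprint_interval <- function(profile, freq_threshold = 0.5,
                               smooth_window = 5) {
  .assert(nrow(profile) >= 1, "no informative positions in profile")
  .assert(freq_threshold >= 0 && freq_threshold <= 1,
          "freq_threshold must be in [0, 1]")
  f <- profile$frequency
  ok <- !is.na(f)
  sm <- rep(NA_real_, length(f))
  half <- max(0L, (as.integer(smooth_window) - 1L) %/% 2L)
  fi <- f[ok]
  smi <- vapply(seq_along(fi), function(i) {
    lo <- max(1L, i - half); hi <- min(length(fi), i + half)
    mean(fi[lo:hi])
  }, numeric(1))
  sm[ok] <- smi

  pass <- !is.na(sm) & sm >= freq_threshold
  if (!any(pass))
    return(list(interval = integer(0), n_positions = 0L,
                smoothed = transform(profile, smoothed = sm)))
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- starts[best]; i2 <- ends[best]
  list(interval = c(profile$pos[i1], profile$pos[i2] + 1L),
       n_positions = i2 - i1 + 1L,
       smoothed = transform(profile, smoothed = sm))
}
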