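## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

.strand_flip <- function(s) {
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

## number of sorted integer positions falling in [start, end), vectorised over
## intervals; `pos` must be sorted ascending
.count_in <- function(pos, start, end) {
  if (length(pos) == 0L) return(integer(length(start)))
  findInterval(end - 0.5, pos) - findInterval(start - 0.5, pos)
}

## sorted positions of `pos` within [start, end) (scalar interval)
.pos_in <- function(pos, start, end) {
  if (length(pos) == 0L) return(integer(0))
  i <- findInterval(c(start - 0.5, end - 0.5), pos)
  if (i[2] <= i[1]) return(integer(0))
  pos[(i[1] + 1L):i[2]]
}

## gap in bp between half-open intervals [a1,a2) and [b1,b2); 0 when they touch
## or overlap
.interval_gap <- function(a1, a2, b1, b2) {
  pmax(0L, pmax(a1, b1) - pmin(a2, b2))
}

## deterministic per-track RNG stream offsets; keeps derived seeds < 2^31 for
## small user seeds
.track_seed <- function(seed, assay, condition) {
  key <- paste(assay, condition, sep = ":")
  offsets <- c("chrrna:control" = 1L, "chrrna:oe" = 2L,
               "rloop:d210n" = 3L, "rloop:wkkd" = 4L,
               "cap:control" = 5L, "cap:oe" = 6L)
  .assert(key %in% names(offsets), "unknown assay/condition pair '%s'", key)
  as.integer(seed) + 1000003L * offsets[[key]]
}
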