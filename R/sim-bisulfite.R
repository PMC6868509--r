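#' Simulate bisulfite-converted plasmid clones
#'
#' Emulates bisulfite mapping of the single-stranded DNA exposed by a
#' plasmid R-loop: bisulfite converts unmethylated dC to dU (read as T)
#' only in single-stranded conformation, so cytosines inside the planted
#' footprint convert with high probability `p_in` and those outside with
#' the low background probability `p_out`. Clones are generated for both
#' strand readings: C-to-T on the top strand and, symmetrically, G-to-A for
#' the complementary strand.
#'
#' @param ref_length reference length in bp (ignored when `reference` is
#'   given).
#' @param footprint half-open interval `c(start, end)` of the planted
#'   single-stranded region, 0-based, within the reference.
#' @param n_clones number of sequenced clones per strand reading.
#' @param p_in,p_out per-cytosine conversion probabilities inside/outside
#'   the footprint; `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @param reference optional explicit reference sequence (character string,
#'   alphabet ACGT); by default a uniform-random sequence is drawn.
#' @return A list with `reference` (character string), `clones_ct` and
#'   `clones_ga` (named character vectors of clone sequences), and `truth`
#'   (`footprint`, `p_in`, `p_out`).
#' @examples
#' sim <- simulate_bisulfite_clones(600, c(200, 450), n_clones = 10,
#'                                  p_in = 0.9, p_out = 0.01, seed = 1)
#' substr(sim$clones_ct[[1]], 1, 40)
#' @export
simulate_bisulfite_clones <- function(ref_length = 600,
                                      footprint = c(200, 450),
                                      n_clones = 10, p_in = 0.9,
                                      p_out = 0.01, seed = 1,
                                      reference = NULL) {
  .assert(p_out >= 0 && p_out < p_in && p_in <= 1,
          "need 0 <= p_out < p_in <= 1")
  set.seed(as.integer(seed))
  if (is.null(reference)) {
    reference <- paste(sample(c("A", "C", "G", "T"), ref_length,
                              replace = TRUE), collapse = "")
  } else {
    .assert(grepl("^[ACGTN]*$", reference), "reference alphabet must be ACGTN")
    ref_length <- nchar(reference)
  }
  .assert(length(footprint) == 2 && footprint[1] < footprint[2],
          "footprint must be an increasing pair")
  .assert(footprint[1] >= 0 && footprint[2] <= ref_length,
          "footprint outside reference [0, %d)", ref_length)

  refv <- strsplit(reference, "")[[1]]
  inside <- seq_len(ref_length) - 1L >= footprint[1] &
    seq_len(ref_length) - 1L < footprint[2]

  convert <- function(target, to) {
    at <- which(refv == target)
    p <- ifelse(inside[at], p_in, p_out)
    vapply(seq_len(n_clones), function(i) {
      clone <- refv
      hit <- stats::runif(length(at)) < p
      clone[at[hit]] <- to
      paste(clone, collapse = "")
    }, character(1))
  }
  clones_ct <- stats::setNames(convert("C", "T"),
                               sprintf("clone_ct_%02d", seq_len(n_clones)))
  clones_ga <- stats::setNames(convert("G", "A"),
                               sprintf("clone_ga_%02d", seq_len(n_clones)))
  list(reference = reference, clones_ct = clones_ct, clones_ga = clones_ga,
       truth = list(footprint = as.integer(footprint), p_in = p_in,
                    p_out = p_out))
}
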