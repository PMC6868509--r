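#' Gene annotation container
#'
#' Holds genes (and optionally transcripts) with 0-based half-open
#' coordinates. The TSS is the 5' end in the direction of transcription
#' (`start` for `+` genes, `end - 1` for `-` genes) and the TES the 3' end
#' (poly(A) position).
#'
#' @param genes data.frame with columns `gene_id, chrom, start, end, strand`
#'   (and optionally `tss`, `tes`, `length` for the longest isoform).
#' @param transcripts optional data.frame with `transcript_id, gene_id,
#'   chrom, start, end, strand`; gene spans are taken from the most 5' TSS to
#'   the most 3' TES, i.e. the union of each gene's transcripts.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, transcripts = NULL, chrom_lengths = NULL) {
  .assert(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                names(genes)), "genes needs gene_id/chrom/start/end/strand")
  .assert(all(genes$start < genes$end), "gene start must be < end")
  .assert(all(genes$start >= 0), "negative gene coordinates")
  .assert(all(genes$strand %in% c("+", "-")),
          "unknown strand symbol in annotation (expected +/-)")
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (is.null(genes$tes))
    genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  if (is.null(genes$length)) genes$length <- genes$end - genes$start
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  structure(list(genes = genes, transcripts = transcripts,
                 chrom_lengths = chrom_lengths),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Gene annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_lengths)))
  invisible(x)
}

#' Stranded 5'-tag track
#'
#' A track stores single-position 5'-end tags per chromosome and strand,
#' sorted; every downstream statistic consumes these position counts.
#'
#' @param tags data.frame with columns `chrom, pos, strand` (0-based
#'   positions).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param label free-text label, conventionally `"assay:condition"`.
#' @return An object of class `tag_track` with fields `tags` (sorted),
#'   `chrom_lengths`, `total_tags`, `label` and a per-(chromosome, strand)
#'   position index.
#' @export
tag_track <- function(tags, chrom_lengths, label = "") {
  .assert(all(c("chrom", "pos", "strand") %in% names(tags)),
          "tags needs chrom/pos/strand")
  .assert(all(tags$strand %in% c("+", "-")), "tag strand must be + or -")
  .assert(all(tags$pos >= 0), "negative tag position")
  .assert(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  bad <- tags$pos >= chrom_lengths[tags$chrom]
  .assert(!any(bad), "tag position beyond chromosome end")
  o <- order(tags$chrom, tags$strand, tags$pos)
  tags <- tags[o, , drop = FALSE]
  rownames(tags) <- NULL
  idx <- split(as.integer(tags$pos), paste(tags$chrom, tags$strand, sep = "|"))
  structure(list(tags = tags, chrom_lengths = chrom_lengths,
                 total_tags = nrow(tags), label = label, index = idx),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("Tag track '%s': %s tags on %d chromosome(s) (%d +, %d -)\n",
              x$label, format(x$total_tags, big.mark = ","),
              length(x$chrom_lengths), sum(x$tags$strand == "+"),
              sum(x$tags$strand == "-")))
  invisible(x)
}

## sorted positions for one chromosome/strand ("both" pools strands)
.track_pos <- function(track, chrom, strand = "both") {
  if (strand == "both") {
    p <- sort(c(track$index[[paste(chrom, "+", sep = "|")]],
                track$index[[paste(chrom, "-", sep = "|")]]))
    return(p %||% integer(0))
  }
  track$index[[paste(chrom, strand, sep = "|")]] %||% integer(0)
}

#' Read and write tag tracks as BED6
#'
#' Tags are exchanged as BED6 with one line per tag (`score = 1`,
#' `end = start + 1`), preceded by a `track name=` header line carrying the
#' label. `read_tags(write_tags(x))` restores the identical multiset of
#' positions and strands.
#'
#' @param track a [tag_track()].
#' @param path file path.
#' @param chrom_lengths optional named lengths for the reconstructed track
#'   (BED does not carry them); inferred from the data when omitted.
#' @param label optional label override; defaults to the file's `track name`.
#' @return `read_tags` returns a [tag_track()]; `write_tags` returns `path`
#'   invisibly.
#' @export
write_tags <- function(track, path) {
  .assert(inherits(track, "tag_track"), "not a tag_track")
  con <- file(path, "w")
  writeLines(sprintf('track name="%s" type=bed', track$label), con)
  close(con)
  if (nrow(track$tags)) {
    dt <- data.table::data.table(chrom = track$tags$chrom,
                                 start = as.integer(track$tags$pos),
                                 end = as.integer(track$tags$pos) + 1L,
                                 name = ".", score = 1L,
                                 strand = track$tags$strand)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path, chrom_lengths = NULL, label = NULL) {
  first <- readLines(path, n = 2L)
  has_header <- length(first) >= 1L && grepl("^(track|browser|#)", first[1])
  if (is.null(label) && has_header && grepl('name="', first[1]))
    label <- sub('.*name="([^"]*)".*', "\\1", first[1])
  empty <- length(first) < (1L + has_header)
  dt <- if (empty) data.table::data.table() else tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE,
                      skip = if (has_header) 1L else 0L, fill = TRUE),
    error = function(e) stop("malformed BED file: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(dt) == 0L) {
    tags <- data.frame(chrom = character(), pos = integer(),
                       strand = character(), stringsAsFactors = FALSE)
    return(tag_track(tags, chrom_lengths %||% stats::setNames(integer(0),
                                                              character(0)),
                     label %||% ""))
  }
  .assert(ncol(dt) >= 6, "BED6 required: found %d columns", ncol(dt))
  start <- dt[[2]]; end <- dt[[3]]; strand <- dt[[6]]
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("malformed BED line %d: start=%s end=%s",
                 bad[1] + has_header, start[bad[1]], end[bad[1]]),
         call. = FALSE)
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads))
    stop(sprintf("unknown strand symbol '%s' at line %d", strand[bads[1]],
                 bads[1] + has_header), call. = FALSE)
  tags <- data.frame(chrom = as.character(dt[[1]]), pos = as.integer(start),
                     strand = as.character(strand), stringsAsFactors = FALSE)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(tags$pos, tags$chrom, max) + 1L
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  tag_track(tags, chrom_lengths, label %||% "")
}

#' Write a per-strand coverage bedGraph
#'
#' Derived, lossy view of a track: adjacent positions with equal tag counts
#' are merged into one interval. A track with a single tag at position p
#' yields one line covering `[p, p + 1)` with value 1.
#'
#' @param track a [tag_track()].
#' @param path output path.
#' @param strand which strand to export, `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  con <- file(path, "w")
  writeLines(sprintf('track type=bedGraph name="%s (%s)"', track$label,
                     strand), con)
  close(con)
  keep <- track$tags$strand == strand
  if (any(keep)) {
    tg <- track$tags[keep, c("chrom", "pos")]
    rows <- lapply(split(tg$pos, tg$chrom), function(pos) {
      r <- rle(sort(pos))       # coverage per occupied position
      u <- r$values; n <- r$lengths
      ## merge consecutive positions with identical coverage
      grp <- cumsum(c(1L, diff(u) != 1L | n[-1] != n[-length(n)]))
      data.frame(start = u[!duplicated(grp)],
                 end = u[rev(!duplicated(rev(grp)))] + 1L,
                 value = n[!duplicated(grp)])
    })
    out <- do.call(rbind, Map(cbind, chrom = names(rows), rows))
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}

#' Read a gene annotation from GTF or BED
#'
#' GTF (Ensembl dialect, 1-based closed on disk) is parsed with
#' `rtracklayer`; a gene's span is the union of its transcripts ("from the
#' most 5' TSS to the most 3' TES") and its quantification `length` is the
#' longest isoform. BED6 input is taken as one gene per line. All
#' coordinates are normalised to 0-based half-open internally.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed"`.
#' @param chrom_lengths optional named chromosome lengths.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = c("gtf", "bed"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("failed to parse GTF '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    df <- as.data.frame(gr)
    .assert(all(as.character(df$strand) %in% c("+", "-")),
            "unknown strand symbol in GTF")
    tx <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
    if (nrow(tx) == 0L) tx <- df[df$type == "gene", , drop = FALSE]
    if (is.null(tx$transcript_id)) tx$transcript_id <- tx$gene_id
    transcripts <- data.frame(transcript_id = tx$transcript_id,
                              gene_id = tx$gene_id,
                              chrom = as.character(tx$seqnames),
                              start = tx$start - 1L, end = tx$end,
                              strand = as.character(tx$strand),
                              stringsAsFactors = FALSE)
    agg_min <- tapply(transcripts$start, transcripts$gene_id, min)
    agg_max <- tapply(transcripts$end, transcripts$gene_id, max)
    agg_len <- tapply(transcripts$end - transcripts$start,
                      transcripts$gene_id, max)
    first <- !duplicated(transcripts$gene_id)
    ids <- transcripts$gene_id[first]
    genes <- data.frame(gene_id = ids,
                        chrom = transcripts$chrom[first],
                        start = as.integer(agg_min[ids]),
                        end = as.integer(agg_max[ids]),
                        strand = transcripts$strand[first],
                        length = as.integer(agg_len[ids]),
                        stringsAsFactors = FALSE)
    return(gene_annotation(genes, transcripts, chrom_lengths))
  }
  dt <- tryCatch(data.table::fread(path, sep = "\t", header = FALSE),
                 error = function(e) stop("malformed BED file: ",
                                          conditionMessage(e), call. = FALSE))
  .assert(ncol(dt) >= 6, "BED6 required: found %d columns", ncol(dt))
  bad <- which(dt[[2]] < 0 | dt[[3]] <= dt[[2]])
  if (length(bad))
    stop(sprintf("malformed BED line %d: start=%s end=%s", bad[1],
                 dt[[2]][bad[1]], dt[[3]][bad[1]]), call. = FALSE)
  genes <- data.frame(gene_id = as.character(dt[[4]]),
                      chrom = as.character(dt[[1]]),
                      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
                      strand = as.character(dt[[6]]), stringsAsFactors = FALSE)
  gene_annotation(genes, NULL, chrom_lengths)
}

#' Write a gene annotation as GTF or BED6
#'
#' @param annotation a [gene_annotation()].
#' @param path output path.
#' @param format `"gtf"` (1-based closed, `gene_id`/`transcript_id`
#'   attributes) or `"bed"` (0-based half-open BED6).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  g <- annotation$genes
  if (format == "bed") {
    dt <- data.table::data.table(g$chrom, as.integer(g$start),
                                 as.integer(g$end), g$gene_id, 0L, g$strand)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    return(invisible(path))
  }
  tx <- annotation$transcripts
  if (is.null(tx))
    tx <- data.frame(transcript_id = paste0(g$gene_id, ".t1"),
                     gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                     end = g$end, strand = g$strand, stringsAsFactors = FALSE)
  attr_gene <- sprintf('gene_id "%s";', g$gene_id)
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id,
                     tx$transcript_id)
  lines <- c(
    sprintf("%s\trloopas\tgene\t%d\t%d\t.\t%s\t.\t%s", g$chrom,
            g$start + 1L, g$end, g$strand, attr_gene),
    sprintf("%s\trloopas\ttranscript\t%d\t%d\t.\t%s\t.\t%s", tx$chrom,
            tx$start + 1L, tx$end, tx$strand, attr_tx),
    sprintf("%s\trloopas\texon\t%d\t%d\t.\t%s\t.\t%s", tx$chrom,
            tx$start + 1L, tx$end, tx$strand, attr_tx))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write called peaks (extended BED6)
#'
#' Peaks travel as BED6 plus extra columns, a narrowPeak-like dialect:
#' `chrom start end peak_id score strand summit_offset fold p q [category]`.
#' `score` is `round(min(1000, -10 * log10(q)))`. Round-trip stable for all
#' stored fields.
#'
#' @param peaks a peak data.frame as returned by [call_peaks()].
#' @param path file path.
#' @return `read_peaks` returns the peak data.frame; `write_peaks` returns
#'   `path` invisibly.
#' @export
write_peaks <- function(peaks, path) {
  q <- pmax(peaks$q_value, 1e-300)
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = as.integer(peaks$start),
    end = as.integer(peaks$end), name = peaks$peak_id,
    score = as.integer(round(pmin(1000, -10 * log10(q)))),
    strand = peaks$strand,
    summit_offset = as.integer(peaks$summit - peaks$start),
    fold = peaks$fold_enrichment, p = peaks$p_value, q = peaks$q_value)
  if (!is.null(peaks$category)) dt$category <- peaks$category
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  bad <- which(dt$start < 0 | dt$end <= dt$start)
  if (length(bad))
    stop(sprintf("malformed peak line %d: start=%s end=%s", bad[1] + 1L,
                 dt$start[bad[1]], dt$end[bad[1]]), call. = FALSE)
  out <- data.frame(chrom = dt$chrom, start = as.integer(dt$start),
                    end = as.integer(dt$end), peak_id = dt$name,
                    summit = as.integer(dt$start + dt$summit_offset),
                    strand = dt$strand, fold_enrichment = dt$fold,
                    p_value = dt$p, q_value = dt$q, stringsAsFactors = FALSE)
  if (!is.null(dt$category)) out$category <- dt$category
  out
}

#' Write synthetic truth tables
#'
#' Serialises a `synthetic_truth` as tab-delimited tables plus a JSON config
#' echo, the machine-readable acceptance oracle for a simulated run.
#'
#' @param truth a `synthetic_truth` from [generate_annotation()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$as_transcripts,
                     file.path(dir, "truth_as_transcripts.tsv"), sep = "\t")
  data.table::fwrite(truth$peaks, file.path(dir, "truth_peaks.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$enhancers, file.path(dir, "truth_enhancers.tsv"),
                     sep = "\t")
  cfg <- truth$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "truth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and write FASTA sequences
#'
#' Thin wrappers over `Biostrings` returning plain named character vectors,
#' the representation the bisulfite footprint module works with.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
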