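#' Pipeline run configuration
#'
#' One auditable place for every stage parameter: the synthetic-data
#' configuration plus all analysis windows and thresholds (peak calling
#' 200/50/100 bp windows with fold > 5 and q < 0.05 retention; category
#' windows 2000/1000 bp at the TSS and 1000/2000 bp at the TES; association
#' windows 250/500/2000 bp; 1.5-fold sensitivity with 0.1 pseudocount;
#' metagene +/-2 kb in 50 bp bins; cap clustering 150 bp / 5 tags).
#'
#' @param sim a [sim_config()]; its seed drives the whole run.
#' @param ... overrides for any analysis parameter (see defaults in the
#'   returned object).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), ...) {
  p <- list(window = 200, step = 50, merge_gap = 100, min_fold = 5,
            max_q = 0.05, tss_up = 2000, tss_down = 1000, tes_up = 1000,
            tes_down = 2000, as_flank = 2000, as_window = 250,
            erna_window = 500, tes_window = 2000, sens_threshold = 1.5,
            pseudocount = 0.1, min_control_rpkm = 0, tss_sas_window = 3000,
            prompt_len = 3000, erna_flank = 2000, meta_window = 2000,
            binsize = 50, cap_merge = 150, cap_min_count = 5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  .assert(length(unknown) == 0, "unknown run_config parameter(s): %s",
          paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  .assert(p$min_fold > 0 && p$max_q > 0 && p$max_q <= 1 &&
            p$sens_threshold >= 1 && p$pseudocount >= 0,
          "run_config parameter out of range")
  structure(c(list(sim = sim), p), class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: simulation of annotation, truth and all
#' six tag tracks; strand-aware peak calling (D210N IP vs WKKD background)
#' with post-hoc strand assignment; non-overlapping gene filtering and peak
#' classification; region building; sense/antisense TSS quantification;
#' antisense sensitivity calling (chromatin RNA control vs RNase H1
#' overexpression) against the planted labels; peak-transcript and
#' eRNA-peak association; metagene profiling; cap-cluster calling, overlap
#' and sensitivity; and truth-comparison metrics (precision/recall per
#' stage). With a fixed seed the returned report is fully deterministic.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, every stage's output is
#'   written in formats readable by the stage's standalone function (BED6
#'   tracks, extended-BED peaks, TSV tables, JSON report).
#' @param write_tracks write the (large) tag tracks too, default `FALSE`.
#' @return A list of class `pipeline_report`; see the `metrics` element
#'   for the truth-recovery summary.
#' @examples
#' \donttest{
#' cfg <- run_config(sim_config(n_genes = 30, n_chromosomes = 1,
#'                              genome_length = 1e6, depth = 2e4,
#'                              n_enhancers = 4, seed = 1))
#' rep <- run_all(cfg)
#' rep$metrics$peak_recall
#' }
#' @export
run_all <- function(config, outdir = NULL, write_tracks = FALSE) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  sim <- config$sim

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  gen <- stage("simulate", generate_annotation(sim))
  annotation <- gen$annotation; truth <- gen$truth
  tracks <- stage("simulate", list(
    chrrna_control = simulate_tags(annotation, truth, "chrrna", "control", sim),
    chrrna_oe = simulate_tags(annotation, truth, "chrrna", "oe", sim),
    rloop_d210n = simulate_tags(annotation, truth, "rloop", "d210n", sim),
    rloop_wkkd = simulate_tags(annotation, truth, "rloop", "wkkd", sim),
    cap_control = simulate_tags(annotation, truth, "cap", "control", sim),
    cap_oe = simulate_tags(annotation, truth, "cap", "oe", sim)))

  peaks <- stage("callpeaks", {
    pk <- call_peaks(tracks$rloop_d210n, tracks$rloop_wkkd,
                     window = config$window, step = config$step,
                     merge_gap = config$merge_gap,
                     min_fold = config$min_fold, max_q = config$max_q)
    assign_strand(pk, tracks$rloop_d210n)
  })
  stranded <- peaks[peaks$strand %in% c("+", "-"), , drop = FALSE]

  filtered <- stage("classify", {
    fg <- filter_nonoverlapping_genes(annotation)
    .assert(nrow(fg$genes) > 0, "empty gene annotation after filtering")
    fg
  })
  categories <- stage("classify",
    classify_peaks(stranded, filtered, tss_up = config$tss_up,
                   tss_down = config$tss_down, tes_up = config$tes_up,
                   tes_down = config$tes_down, as_flank = config$as_flank))

  regions <- stage("classify",
    build_regions(filtered, truth$enhancers, prompt_len = config$prompt_len,
                  erna_flank = config$erna_flank))

  tss_sas <- stage("quantify", list(
    control = tss_sense_antisense(tracks$chrrna_control, filtered,
                                  config$tss_sas_window),
    oe = tss_sense_antisense(tracks$chrrna_oe, filtered,
                             config$tss_sas_window)))

  as_regions <- data.frame(region_id = truth$as_transcripts$as_id,
                           chrom = truth$as_transcripts$chrom,
                           start = truth$as_transcripts$start,
                           end = truth$as_transcripts$end,
                           strand = truth$as_transcripts$strand,
                           stringsAsFactors = FALSE)
  as_quant <- stage("quantify", list(
    control = quantify(tracks$chrrna_control, as_regions),
    oe = quantify(tracks$chrrna_oe, as_regions)))

  sens <- stage("sensitivity",
    sensitivity_call(as_quant$control, as_quant$oe, value = "sense_rpkm",
                     threshold = config$sens_threshold,
                     pseudocount = config$pseudocount,
                     min_control = config$min_control_rpkm))

  as_anchors <- data.frame(as_id = truth$as_transcripts$as_id,
                           chrom = truth$as_transcripts$chrom,
                           anchor = truth$as_transcripts$a5,
                           stringsAsFactors = FALSE)
  assoc_as <- stage("associate",
    associate(as_anchors, stranded, mode = "as", window = config$as_window))
  erna_regions <- regions[regions$type == "eRNA", , drop = FALSE]
  assoc_erna <- stage("associate",
    associate(erna_regions, stranded, mode = "erna",
              window = config$erna_window))
  sens_summary <- summarize_sensitivity(sens, assoc_as,
                                        truth$as_transcripts$as_id)

  tss_anchors <- data.frame(chrom = filtered$genes$chrom,
                            pos = filtered$genes$tss,
                            strand = filtered$genes$strand,
                            stringsAsFactors = FALSE)
  meta <- stage("metagene", list(
    peak_density = peak_density_profile(stranded, tss_anchors,
                                        config$meta_window, config$binsize),
    coverage_d210n = coverage_metagene(tracks$rloop_d210n, tss_anchors,
                                       config$meta_window, config$binsize),
    coverage_wkkd = coverage_metagene(tracks$rloop_wkkd, tss_anchors,
                                      config$meta_window, config$binsize)))

  caps <- stage("caps", {
    cl <- call_cap_clusters(tracks$cap_control,
                            merge_distance = config$cap_merge,
                            min_count = config$cap_min_count)
    list(clusters = cl,
         overlap = cluster_peak_overlap(cl, stranded,
                                        window = config$as_window),
         sensitivity = cluster_sensitivity(cl, tracks$cap_control,
                                           tracks$cap_oe,
                                           threshold = config$sens_threshold,
                                           pseudocount = config$pseudocount))
  })

  metrics <- .truth_metrics(truth, peaks, stranded, categories, sens,
                            assoc_as, caps)

  report <- structure(list(
    config = config,
    n_genes = nrow(annotation$genes),
    n_genes_filtered = nrow(filtered$genes),
    track_totals = vapply(tracks, function(t) t$total_tags, numeric(1)),
    peaks = peaks, categories = categories,
    category_summary = category_summary(categories),
    tss_sense_antisense = tss_sas, as_sensitivity = sens,
    associations_as = assoc_as, associations_erna = assoc_erna,
    sensitivity_summary = sens_summary, metagene = meta, caps = caps,
    metrics = metrics), class = "pipeline_report")

  if (!is.null(outdir))
    .write_report(report, annotation, truth, tracks, outdir, write_tracks)
  report
}

## truth-recovery metrics: precision/recall of peaks, strand accuracy,
## TSS classification accuracy, sensitivity precision/recall, association
## and cap recovery fractions
.truth_metrics <- function(truth, peaks, stranded, categories, sens,
                           assoc_as, caps) {
  tp <- truth$peaks
  overlaps_planted <- function(i) {
    j <- tp$chrom == peaks$chrom[i]
    any(pmax(tp$start[j], peaks$start[i]) < pmin(tp$end[j], peaks$end[i]))
  }
  called_hit <- if (nrow(peaks)) vapply(seq_len(nrow(peaks)),
                                        overlaps_planted, logical(1))
                else logical(0)
  planted_hit <- vapply(seq_len(nrow(tp)), function(i) {
    j <- peaks$chrom == tp$chrom[i]
    any(pmax(peaks$start[j], tp$start[i]) < pmin(peaks$end[j], tp$end[i]))
  }, logical(1))

  ## strand accuracy over called peaks matched to a unique planted peak
  strand_ok <- n_matched <- 0L
  if (nrow(stranded)) {
    for (i in seq_len(nrow(stranded))) {
      j <- which(tp$chrom == stranded$chrom[i] &
                   pmax(tp$start, stranded$start[i]) <
                   pmin(tp$end, stranded$end[i]))
      if (length(j) == 1L) {
        n_matched <- n_matched + 1L
        strand_ok <- strand_ok + (tp$strand[j] == stranded$strand[i])
      }
    }
  }

  ## classification accuracy of planted TSS peaks: the called peak whose
  ## summit is nearest a planted TSS summit must be classified TSS
  tss_truth <- tp[tp$anchor == "TSS", , drop = FALSE]
  tss_acc <- NA_real_
  if (nrow(stranded) && nrow(tss_truth)) {
    ok <- total <- 0L
    for (i in seq_len(nrow(tss_truth))) {
      j <- which(stranded$chrom == tss_truth$chrom[i] &
                   abs(stranded$summit - tss_truth$summit[i]) <= 200)
      if (length(j) == 0L) next
      j <- j[which.min(abs(stranded$summit[j] - tss_truth$summit[i]))]
      total <- total + 1L
      ok <- ok + (categories$category[match(stranded$peak_id[j],
                                            categories$peak_id)] == "TSS")
    }
    if (total > 0L) tss_acc <- ok / total
  }

  truth_sens <- truth$as_transcripts$sensitive
  called_sens <- sens$sensitive[match(truth$as_transcripts$as_id,
                                      sens$region_id)]
  sens_prec <- if (sum(called_sens) > 0)
    sum(called_sens & truth_sens) / sum(called_sens) else NA_real_
  sens_rec <- if (sum(truth_sens) > 0)
    sum(called_sens & truth_sens) / sum(truth_sens) else NA_real_

  ## cap clusters recovered at planted 5' ends (TSS or AS 5' end)
  anchors <- c(truth$genes$tss, truth$as_transcripts$a5)
  anchor_chrom <- c(truth$genes$chrom, truth$as_transcripts$chrom)
  cl <- caps$clusters
  cap_rec <- if (length(anchors)) mean(vapply(seq_along(anchors),
    function(i) {
      j <- cl$chrom == anchor_chrom[i]
      any(abs(cl$mode_pos[j] - anchors[i]) <= 50)
    }, logical(1))) else NA_real_

  list(
    n_peaks_called = nrow(peaks),
    n_peaks_planted = nrow(tp),
    peak_precision = if (nrow(peaks)) mean(called_hit) else NA_real_,
    peak_recall = mean(planted_hit),
    strand_accuracy = if (n_matched) strand_ok / n_matched else NA_real_,
    tss_classification_accuracy = tss_acc,
    sensitivity_precision = sens_prec,
    sensitivity_recall = sens_rec,
    sensitive_fraction_called = mean(called_sens),
    as_association_fraction = nrow(assoc_as) /
      max(1L, nrow(truth$as_transcripts)),
    cap_cluster_recovery = cap_rec)
}

.write_report <- function(report, annotation, truth, tracks, outdir,
                          write_tracks) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_annotation(annotation, file.path(outdir, "annotation.gtf"), "gtf")
  write_annotation(annotation, file.path(outdir, "annotation.bed"), "bed")
  write_truth(truth, file.path(outdir, "truth"))
  if (write_tracks)
    for (nm in names(tracks))
      write_tags(tracks[[nm]], file.path(outdir, paste0(nm, ".bed")))
  write_peaks(report$peaks, file.path(outdir, "peaks.tsv"))
  data.table::fwrite(report$categories, file.path(outdir, "categories.tsv"),
                     sep = "\t")
  data.table::fwrite(report$as_sensitivity,
                     file.path(outdir, "as_sensitivity.tsv"), sep = "\t")
  data.table::fwrite(report$associations_as,
                     file.path(outdir, "associations_as.tsv"), sep = "\t")
  data.table::fwrite(report$caps$clusters,
                     file.path(outdir, "cap_clusters.tsv"), sep = "\t")
  jsonlite::write_json(report_json(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Pipeline report", "",
          sprintf("- genes simulated: %d (filtered: %d)", report$n_genes,
                  report$n_genes_filtered),
          sprintf("- peaks called: %d (planted: %d)",
                  report$metrics$n_peaks_called,
                  report$metrics$n_peaks_planted),
          sprintf("- peak precision/recall: %.3f / %.3f",
                  report$metrics$peak_precision, report$metrics$peak_recall),
          sprintf("- sensitivity precision/recall: %.3f / %.3f",
                  report$metrics$sensitivity_precision,
                  report$metrics$sensitivity_recall),
          sprintf("- AS transcripts peak-associated: %.3f",
                  report$metrics$as_association_fraction))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}

#' Serialisable summary of a pipeline report
#'
#' Flattens the deterministic parts of a [run_all()] report (config echo,
#' stage counts, category summary, sensitivity summary, truth metrics)
#' for JSON output; two runs with the same seed give identical structures.
#'
#' @param report a `pipeline_report`.
#' @return A plain nested list.
#' @export
report_json <- function(report) {
  cfg <- report$config
  sim <- cfg$sim
  class(sim) <- NULL
  params <- cfg[setdiff(names(cfg), "sim")]
  list(config = c(list(sim = sim), params),
       n_genes = report$n_genes,
       n_genes_filtered = report$n_genes_filtered,
       track_totals = as.list(report$track_totals),
       n_peaks = nrow(report$peaks),
       category_summary = report$category_summary,
       sensitivity_summary = report$sensitivity_summary,
       cap_overlap = report$caps$overlap,
       metrics = report$metrics)
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$metrics
  cat("R-loop antisense pipeline report\n")
  cat(sprintf("  genes: %d (filtered %d); peaks called: %d (planted %d)\n",
              x$n_genes, x$n_genes_filtered, m$n_peaks_called,
              m$n_peaks_planted))
  cat(sprintf("  peak precision %.3f, recall %.3f, strand accuracy %.3f\n",
              m$peak_precision, m$peak_recall, m$strand_accuracy))
  cat(sprintf("  TSS classification accuracy: %.3f\n",
              m$tss_classification_accuracy))
  cat(sprintf("  sensitivity precision %.3f, recall %.3f (called fraction %.3f)\n",
              m$sensitivity_precision, m$sensitivity_recall,
              m$sensitive_fraction_called))
  cat(sprintf("  AS transcripts associated with peaks: %.3f\n",
              m$as_association_fraction))
  invisible(x)
}
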