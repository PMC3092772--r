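#' Run the full targeted assembly pipeline
#'
#' Loads targets, builds the word index, streams and recruits reads,
#' assembles every target independently, and writes the four output files.
#' Run statistics (reads seen/retained, per-target contig lengths and
#' extensions) are logged to stderr in `key=value` form. A target that
#' yields no contig is a result, not an error.
#'
#' @param fof Path to the file of filenames listing FASTA/FASTQ read files.
#' @param targets_path Path to the multi-FASTA of target sequences.
#' @param out_prefix Output path prefix.
#' @param k Word size (default 15).
#' @param m Minimum in-target overlap (default 15; must be >= `k`).
#' @param o Minimum flank extension coverage (default 2).
#' @param r Minimum top-base ratio for extension (default 0.7).
#' @param c Minimum depth for an in-target position to be reported
#'   (default 1).
#' @param chunk_size Read-stream chunk size.
#' @param write_recruited Also write `{prefix}.recruited.fa` with the
#'   retained reads (off by default).
#' @param quiet Suppress the run log.
#' @return Invisibly, a list with `contigs`, `stats`, `report` (variant
#'   support table) and `paths`.
#' @export
run_assemble <- function(fof, targets_path, out_prefix, k = 15L, m = 15L,
                         o = 2L, r = 0.7, c = 1L, chunk_size = 5000L,
                         write_recruited = FALSE, quiet = FALSE) {
  validate_params(k, m, o, r, c)
  log_kv <- function(...) if (!quiet) message(sprintf(...))
  config <- list(k = k, m = m, o = o, r = r, c = c)

  targets <- load_targets(targets_path, k = k)
  log_kv("stage=load targets=%d", nrow(targets))
  index <- build_index(targets, k = k)
  log_kv("stage=index words=%d hits=%d", length(ls(index$table)), index$n_hits)

  recruited <- recruit(stream_reads(fof, chunk_size), index)
  log_kv("stage=recruit reads_total=%d reads_retained=%d",
         recruited$stats$total, recruited$stats$retained)
  if (write_recruited)
    write_recruited_fasta(recruited, paste0(out_prefix, ".recruited.fa"))

  contigs <- assemble_all(targets, recruited, m = m, o = o, r = r, c = c, k = k)
  for (tid in names(contigs)) {
    ct <- contigs[[tid]]
    if (is.null(ct))
      log_kv("stage=assemble target=%s contig=none", tid)
    else
      log_kv("stage=assemble target=%s contig_length=%d left_ext=%d right_ext=%d reads=%d",
             tid, nchar(ct$sequence), ct$left_ext, ct$right_ext, ct$n_reads)
  }

  paths <- write_outputs(contigs, out_prefix, config = config)
  report <- variant_report(targets, contigs)
  rpath <- paste0(out_prefix, ".variants.tsv")
  write_variant_report(report, rpath, config = config)
  log_kv("stage=write prefix=%s", out_prefix)

  invisible(list(contigs = contigs, recruited_stats = recruited$stats,
                 report = report, paths = c(paths, variants = rpath)))
}
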