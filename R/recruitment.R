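#' Recruit reads whose first k bases match a target word
#'
#' Streams the input reads once and retains exactly those whose first
#' `k` bases exactly match some indexed word. Anchoring is strictly to the
#' read's first `k` bases, not to any internal word: opposite-strand reads
#' are captured through the index's minus-strand words, and the analytic
#' flank-extension bound (read length minus the minimum overlap) holds only
#' under this prefix anchoring. Reads shorter than `k`, or carrying an `N`
#' among their first `k` bases, are never retained. Exact duplicate reads are
#' all retained and all counted.
#'
#' @param reads A `read_stream` from [stream_reads()], or an in-memory data
#'   frame with columns `read_id` and `sequence` (and optionally
#'   `source_file`).
#' @param index A `word_index` from [build_index()].
#' @return Object of class `recruitment`: a list with `reads` (data frame of
#'   retained reads), `hits` (parallel list of candidate word-hit data
#'   frames), `k`, and `stats` (`total`, `retained`, and `per_target`
#'   candidate read counts).
#' @export
recruit <- function(reads, index) {
  stream <- as_read_stream(reads)
  k <- index$k
  kept_chunks <- list()
  hit_chunks <- list()
  total <- 0L
  per_target <- stats::setNames(integer(length(index$target_ids)),
                                index$target_ids)
  repeat {
    chunk <- next_chunk(stream)
    if (is.null(chunk)) break
    total <- total + nrow(chunk)
    if (nrow(chunk) == 0L) next
    prefix <- substr(chunk$sequence, 1L, k)
    eligible <- nchar(chunk$sequence) >= k & !grepl("N", prefix, fixed = TRUE)
    if (!any(eligible)) next
    upfx <- unique(prefix[eligible])
    found <- mget(upfx, envir = index$table, ifnotfound = list(NULL))
    has_hit <- !vapply(found, is.null, logical(1))
    if (!any(has_hit)) next
    keep <- eligible & prefix %in% upfx[has_hit]
    hits <- found[prefix[keep]]
    kept_chunks[[length(kept_chunks) + 1L]] <- chunk[keep, , drop = FALSE]
    hit_chunks[[length(hit_chunks) + 1L]] <- hits
    for (h in hits) {
      tids <- unique(h$target_id)
      per_target[tids] <- per_target[tids] + 1L
    }
  }
  if (length(kept_chunks)) {
    kept <- do.call(rbind, kept_chunks)
    rownames(kept) <- NULL
    hits <- do.call(c, hit_chunks)
  } else {
    kept <- data.frame(read_id = character(0), sequence = character(0),
                       source_file = character(0), stringsAsFactors = FALSE)
    hits <- list()
  }
  structure(list(reads = kept, hits = unname(hits), k = k,
                 stats = list(total = total, retained = nrow(kept),
                              per_target = per_target)),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("<recruitment> k=%d | reads seen=%d retained=%d\n",
              x$k, x$stats$total, x$stats$retained))
  for (t in names(x$stats$per_target))
    cat(sprintf("  %s: %d candidate reads\n", t, x$stats$per_target[[t]]))
  invisible(x)
}

#' Write recruited reads to a FASTA sidecar
#'
#' Debugging aid: dumps the retained reads of a recruitment.
#'
#' @param recruited A `recruitment` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_recruited_fasta <- function(recruited, path) {
  set <- Biostrings::DNAStringSet(recruited$reads$sequence)
  names(set) <- sprintf("%s %s", recruited$reads$read_id,
                        recruited$reads$source_file)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
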