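#' Extract every k-length word from both strands of a target
#'
#' A target of length `L` yields exactly `2 * (L - k + 1)` words: for each
#' 0-based offset `i`, the plus-strand substring `target[i, i+k)` and the
#' reverse complement of that same substring for the minus strand. All
#' occurrences are retained, including duplicate words from internal repeats
#' and palindromes (one entry per strand/offset pair).
#'
#' @param target One-row target record (see [target_record()]).
#' @param k Word size (default 15).
#' @return Data frame with columns `word`, `target_id`, `strand` (`"+"` or
#'   `"-"`) and `offset` (0-based start of the word on the target's plus
#'   strand).
#' @export
extract_words <- function(target, k = 15L) {
  L <- target$length
  if (L < k) stop(sprintf("target '%s' shorter than word size", target$target_id))
  n <- L - k + 1L
  starts <- seq_len(n)
  plus <- substring(target$sequence, starts, starts + k - 1L)
  data.frame(word = c(plus, revcomp(plus)),
             target_id = target$target_id,
             strand = rep(c("+", "-"), each = n),
             offset = rep(starts - 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Build the word index over a set of targets
#'
#' Every word from every target (both strands) is stored in a hash table
#' mapping word to its list of hits `(target_id, strand, offset)`. A word
#' shared by several targets, strands or offsets maps to all of its hits;
#' disambiguation happens at placement time, not here. Index size depends on
#' total target length only, never on the read set.
#'
#' @param targets Data frame of target records.
#' @param k Word size (default 15). Values below 11 trigger a warning, since
#'   short words lose specificity and recruit unrelated reads.
#' @return Object of class `word_index` with elements `k`, `table`
#'   (environment keyed by word), `n_hits` and `target_ids`.
#' @export
build_index <- function(targets, k = 15L) {
  k <- as.integer(k)
  if (k < 1L) stop("word size k must be >= 1")
  if (k < 11L)
    warning(sprintf(
      "word size k=%d is low-specificity: short words recruit unrelated reads", k))
  tab <- new.env(hash = TRUE, parent = emptyenv())
  n_hits <- 0L
  if (nrow(targets) > 0L) {
    all <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i)
      extract_words(targets[i, ], k)))
    n_hits <- nrow(all)
    for (grp in split(seq_len(nrow(all)), all$word)) {
      hits <- all[grp, c("target_id", "strand", "offset")]
      rownames(hits) <- NULL
      assign(all$word[grp[1L]], hits, envir = tab)
    }
  }
  structure(list(k = k, table = tab, n_hits = n_hits,
                 target_ids = targets$target_id),
            class = "word_index")
}

#' Look up a word in the index
#'
#' Exact-match semantics only; words containing `N` are never indexed and
#' never match.
#'
#' @param index A `word_index`.
#' @param word DNA string of length exactly `index$k`.
#' @return Data frame of hits (`target_id`, `strand`, `offset`); zero rows on
#'   a miss.
#' @export
lookup_word <- function(index, word) {
  if (nchar(word) != index$k)
    stop(sprintf("query length %d != word size %d", nchar(word), index$k))
  hits <- get0(word, envir = index$table, inherits = FALSE)
  if (is.null(hits))
    hits <- data.frame(target_id = character(0), strand = character(0),
                       offset = integer(0), stringsAsFactors = FALSE)
  hits
}

#' @export
print.word_index <- function(x, ...) {
  cat(sprintf("<word_index> k=%d | %d targets | %d distinct words | %d hits\n",
              x$k, length(x$target_ids), length(ls(x$table)), x$n_hits))
  invisible(x)
}
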