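# Independent brute-force oracles. These deliberately avoid the package's
# index/placement code paths: everything is naive scanning.

# All k-words of a target and its reverse complement, by direct substring
# enumeration.
oracle_words <- function(target_seq, k) {
  n <- nchar(target_seq) - k + 1
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(target_seq)))
  c(substring(target_seq, 1:n, k:(k + n - 1)),
    substring(rc, 1:n, k:(k + n - 1)))
}

# Which reads would be recruited: naive loop comparing each read's prefix
# against every word of every target.
oracle_recruit <- function(read_seqs, target_seqs, k) {
  words <- unlist(lapply(target_seqs, oracle_words, k = k))
  vapply(read_seqs, function(s) {
    if (nchar(s) < k) return(FALSE)
    p <- substr(s, 1, k)
    if (grepl("N", p, fixed = TRUE)) return(FALSE)
    any(p == words)
  }, logical(1), USE.NAMES = FALSE)
}

# All word hits for one query word on one target, by scanning all substrings
# of both strands.
oracle_word_hits <- function(target_seq, k, word) {
  n <- nchar(target_seq) - k + 1
  plus <- substring(target_seq, 1:n, k:(k + n - 1))
  minus <- vapply(1:n, function(i) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(target_seq, i, i + k - 1)))), character(1))
  po <- which(plus == word) - 1L
  mo <- which(minus == word) - 1L
  data.frame(strand = c(rep("+", length(po)), rep("-", length(mo))),
             offset = c(po, mo), stringsAsFactors = FALSE)
}

# Exhaustive gapless alignment of an oriented read against a target: every
# start where the in-target overlap agrees perfectly and spans >= m bases.
oracle_placements <- function(read_seq, target_seq, m) {
  L <- nchar(target_seq)
  len <- nchar(read_seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read_seq)))
  hits <- list()
  for (strand in c("+", "-")) {
    oseq <- if (strand == "+") read_seq else rc
    for (s in (-len + 1):(L - 1)) {
      lo <- max(s, 0); hi <- min(s + len, L)
      ov <- hi - lo
      if (ov < m) next
      if (substr(oseq, lo - s + 1, hi - s) == substr(target_seq, lo + 1, hi))
        hits[[length(hits) + 1]] <- data.frame(strand = strand, start = s,
                                               overlap = ov)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(strand = character(0), start = integer(0),
                  overlap = integer(0))
}

# Base counts of a coverage table at one axis position.
cov_col_test <- function(cov, pos) targetasm:::cov_col(cov, pos)

# Per-position depth recount over placed reads, counting only A/C/G/T bases.
oracle_recount <- function(placed) {
  tab <- list()
  for (i in seq_len(nrow(placed))) {
    bases <- strsplit(placed$oriented_sequence[i], "")[[1]]
    for (j in seq_along(bases)) {
      if (!bases[j] %in% c("A", "C", "G", "T")) next
      key <- as.character(placed$start[i] + j - 1)
      if (is.null(tab[[key]])) tab[[key]] <- integer(0)
      tab[[key]][bases[j]] <- sum(tab[[key]][bases[j]], 1L, na.rm = TRUE)
    }
  }
  tab
}
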