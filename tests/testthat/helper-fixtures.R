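# Fixture builders shared across tests. All randomness is seeded at the call
# site; helpers themselves are deterministic given the RNG state.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Flip one base to a different one.
flip_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

reads_df <- function(seqs, prefix = "r") {
  data.frame(read_id = sprintf("%s%04d", prefix, seq_along(seqs)),
             sequence = seqs, source_file = "test", stringsAsFactors = FALSE)
}

# A reference with an embedded target and dense error-free tiling reads.
tiling_fixture <- function(ref_len = 300, target_len = 70, read_len = 33,
                           copies = 2) {
  ref <- rand_dna(ref_len)
  at <- sample.int(ref_len - target_len - 40, 1) + 20
  target <- target_record("t", substr(ref, at, at + target_len - 1))
  list(ref = ref, target = target, target_start = at,
       reads = tile_reads(ref, read_len, copies = copies))
}

write_fasta_file <- function(seqs, path, ids = NULL, width = 60) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(seqs))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

write_fastq_file <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("q%d", seq_along(seqs))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  invisible(path)
}
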