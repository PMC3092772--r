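#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  out <- character(length(x))
  nz <- !is.na(x) & nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out[!nz] <- x[!nz]
  out
}

# Uppercase and collapse every symbol outside {A,C,G,T,N} to N.
sanitize_read_seq <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  x
}

# Usage errors (bad flags/parameters) are a distinct condition class so the
# command-line wrapper can map them to exit status 2.
usage_error <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("usage_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# Validate the assembly parameter set shared by run_assemble() and the CLI.
validate_params <- function(k, m, o, r, c) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    usage_error("word size k must be a positive integer")
  if (!is.numeric(m) || length(m) != 1L || m != round(m))
    usage_error("minimum overlap m must be an integer")
  if (m < k)
    usage_error(sprintf("minimum overlap m (%d) must be >= word size k (%d)", m, k))
  if (!is.numeric(o) || length(o) != 1L || o < 1)
    usage_error("minimum extension coverage o must be >= 1")
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    usage_error("base ratio r must satisfy 0 < r <= 1")
  if (!is.numeric(c) || length(c) != 1L || c < 1)
    usage_error("minimum report coverage c must be >= 1")
  invisible(TRUE)
}

# rbind a list of data frames, dropping NULLs; NULL when nothing remains.
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

config_string <- function(config) {
  if (is.null(config) || length(config) == 0L) return("")
  paste(sprintf("%s=%s", names(config), vapply(config, format, character(1))),
        collapse = " ")
}
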