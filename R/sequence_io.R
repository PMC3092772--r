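#' Construct a target record
#'
#' A target is a named DNA sequence defining the sequence space to be
#' interrogated. Optional metadata columns (variant kind, focal offset,
#' allele label, junction coordinate) travel with the record and are encoded
#' into / parsed from FASTA description lines as `key=value` tokens.
#'
#' @param target_id Target name (first whitespace-delimited token of a FASTA
#'   header).
#' @param sequence DNA string; must contain only `A`, `C`, `G`, `T` after
#'   uppercasing (words must be exact-matchable, so ambiguity codes are
#'   rejected).
#' @param kind,focal,allele,variant_id,junction Optional metadata: variant
#'   class, 0-based focal offset on the target, allele label (`"ref"`/`"alt"`),
#'   variant identifier, and 0-based junction coordinate for breakpoint
#'   targets.
#' @return A one-row data frame with columns `target_id`, `sequence`,
#'   `length` plus the metadata columns.
#' @export
target_record <- function(target_id, sequence, kind = NA_character_,
                          focal = NA_integer_, allele = NA_character_,
                          variant_id = NA_character_, junction = NA_integer_) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence))
    stop(sprintf("target '%s' contains characters outside {A,C,G,T}", target_id))
  data.frame(target_id = as.character(target_id), sequence = sequence,
             length = nchar(sequence), kind = kind,
             focal = as.integer(focal), allele = allele,
             variant_id = variant_id, junction = as.integer(junction),
             stringsAsFactors = FALSE)
}

empty_targets <- function() {
  target_record("x", "ACGT")[0L, ]
}

parse_target_meta <- function(desc) {
  get1 <- function(key, pat) {
    m <- regmatches(desc, regexec(paste0("\\b", key, "=(", pat, ")"), desc))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  list(kind = get1("kind", "\\S+"),
       focal = suppressWarnings(as.integer(get1("focal", "-?\\d+"))),
       allele = get1("allele", "\\S+"),
       variant_id = get1("variant", "\\S+"),
       junction = suppressWarnings(as.integer(get1("junction", "\\d+"))))
}

#' Load target sequences from a multi-FASTA file
#'
#' One record per FASTA entry, order preserved. Targets shorter than the word
#' size or containing non-ACGT characters are rejected; duplicated IDs are
#' disambiguated with an ordinal suffix and a warning.
#'
#' @param path Path to a multi-FASTA file (plain or gzip-compressed).
#' @param k Word size the targets must support (default 15).
#' @return Data frame of target records (see [target_record()]).
#' @export
load_targets <- function(path, k = 15L) {
  if (!file.exists(path)) stop(sprintf("target file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop(sprintf("failed to parse targets from %s: %s",
                                 path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("no targets found in %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("duplicate target IDs disambiguated: %s",
                    paste(unique(ids[dup]), collapse = ", ")))
    ids <- make.unique(ids, sep = ".")
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop(sprintf("target(s) contain non-ACGT characters: %s",
                 paste(ids[bad], collapse = ", ")))
  short <- nchar(seqs) < k
  if (any(short))
    stop(sprintf("target shorter than word size (k=%d): %s",
                 k, paste(ids[short], collapse = ", ")))
  meta <- lapply(headers, parse_target_meta)
  out <- data.frame(target_id = ids, sequence = unname(seqs),
                    length = nchar(seqs),
                    kind = vapply(meta, `[[`, character(1), "kind"),
                    focal = vapply(meta, `[[`, integer(1), "focal"),
                    allele = vapply(meta, `[[`, character(1), "allele"),
                    variant_id = vapply(meta, `[[`, character(1), "variant_id"),
                    junction = vapply(meta, `[[`, integer(1), "junction"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write target records to FASTA
#'
#' Metadata columns that are set are encoded in the description as
#' `key=value` tokens, so that [load_targets()] round-trips them.
#'
#' @param targets Data frame of target records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_fasta <- function(targets, path) {
  desc <- vapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    tok <- character(0)
    if (!is.na(t$kind)) tok <- c(tok, sprintf("kind=%s", t$kind))
    if (!is.na(t$focal)) tok <- c(tok, sprintf("focal=%d", t$focal))
    if (!is.na(t$allele)) tok <- c(tok, sprintf("allele=%s", t$allele))
    if (!is.na(t$variant_id)) tok <- c(tok, sprintf("variant=%s", t$variant_id))
    if (!is.na(t$junction)) tok <- c(tok, sprintf("junction=%d", t$junction))
    if (length(tok)) paste(t$target_id, paste(tok, collapse = " ")) else t$target_id
  }, character(1))
  set <- Biostrings::DNAStringSet(targets$sequence)
  names(set) <- desc
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- read streaming -----------------------------------------------------------

detect_read_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- ""
  while (TRUE) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1, 1); break }
  }
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop(sprintf("cannot detect FASTA/FASTQ format of %s (first character '%s')",
               path, first))
}

read_fof <- function(fof_path) {
  if (!file.exists(fof_path))
    stop(sprintf("file of filenames not found: %s", fof_path))
  lines <- trimws(readLines(fof_path))
  files <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(files) == 0L) stop("no input read files listed in file of filenames")
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop(sprintf("read file(s) listed but not found: %s",
                 paste(missing, collapse = ", ")))
  files
}

#' Open a lazy read stream over a file of filenames
#'
#' Reads are yielded in file order, in chunks, so that memory use is a
#' function of the chunk size only and never of the total read count. Each
#' listed file may be FASTA or FASTQ (auto-detected per file from its first
#' record character), plain or gzip-compressed. FASTQ qualities are parsed
#' and discarded: the assembly algorithm never uses them. Read sequences are
#' uppercased and any symbol outside `{A,C,G,T,N}` is mapped to `N`.
#'
#' @param fof_path File of filenames: one path per line; blank lines and
#'   lines starting with `#` are skipped.
#' @param chunk_size Number of reads fetched per chunk (default 5000).
#' @return An object of class `read_stream`. Call [next_chunk()] to obtain
#'   the next data frame of reads (`read_id`, `sequence`, `source_file`) or
#'   `NULL` at end of stream.
#' @export
stream_reads <- function(fof_path, chunk_size = 5000L) {
  files <- read_fof(fof_path)
  state <- new.env(parent = emptyenv())
  state$files <- files
  state$formats <- vapply(files, detect_read_format, character(1))
  state$file_i <- 1L
  state$skip <- 0L
  state$chunk_size <- as.integer(chunk_size)
  structure(list(state = state), class = "read_stream")
}

#' Fetch the next chunk from a read stream
#'
#' @param stream A `read_stream` from [stream_reads()].
#' @return Data frame with columns `read_id`, `sequence`, `source_file`, or
#'   `NULL` when the stream is exhausted.
#' @export
next_chunk <- function(stream) UseMethod("next_chunk")

#' @export
next_chunk.read_stream <- function(stream) {
  st <- stream$state
  while (st$file_i <= length(st$files)) {
    path <- st$files[st$file_i]
    fmt <- st$formats[st$file_i]
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = fmt, nrec = st$chunk_size,
                                 skip = st$skip),
      error = function(e)
        stop(sprintf("malformed %s record in %s near record %d: %s",
                     fmt, path, st$skip + 1L, conditionMessage(e))))
    if (length(set) == 0L) {
      st$file_i <- st$file_i + 1L
      st$skip <- 0L
      next
    }
    st$skip <- st$skip + length(set)
    ids <- sub("\\s.*$", "", names(set))
    return(data.frame(read_id = ids,
                      sequence = sanitize_read_seq(as.character(set)),
                      source_file = path, stringsAsFactors = FALSE,
                      row.names = NULL))
  }
  NULL
}

#' Materialise all reads from a stream or file of filenames
#'
#' Convenience for small inputs and tests; production runs should pass the
#' stream straight to [recruit()].
#'
#' @param x A `read_stream` or a file-of-filenames path.
#' @param chunk_size Chunk size when `x` is a path.
#' @return Data frame of reads.
#' @export
collect_reads <- function(x, chunk_size = 5000L) {
  if (!inherits(x, "read_stream")) x <- stream_reads(x, chunk_size)
  chunks <- list()
  repeat {
    ch <- next_chunk(x)
    if (is.null(ch)) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  if (length(chunks) == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      source_file = character(0), stringsAsFactors = FALSE))
  do.call(rbind, chunks)
}

# Wrap an in-memory data frame of reads as a single-pass stream.
as_read_stream <- function(reads) {
  if (inherits(reads, "read_stream")) return(reads)
  if (!is.data.frame(reads)) stop("reads must be a data frame or read_stream")
  if (is.null(reads$source_file)) reads$source_file <- "<memory>"
  reads$sequence <- sanitize_read_seq(reads$sequence)
  state <- new.env(parent = emptyenv())
  state$done <- FALSE
  state$reads <- reads
  structure(list(state = state), class = c("df_stream", "read_stream"))
}

#' @export
next_chunk.df_stream <- function(stream) {
  st <- stream$state
  if (st$done || nrow(st$reads) == 0L) return(NULL)
  st$done <- TRUE
  st$reads
}

# -- writers ------------------------------------------------------------------

#' Write reads to FASTQ
#'
#' Writes 4-line FASTQ records with a constant placeholder quality (`I`),
#' since downstream assembly ignores qualities.
#'
#' @param reads Data frame with `read_id` and `sequence` columns.
#' @param path Output path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                         function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a file of filenames
#'
#' @param files Character vector of read-file paths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fof <- function(files, path) {
  writeLines(files, path)
  invisible(path)
}

#' Write assembler outputs
#'
#' Writes the four standard output files for a set of contigs:
#' `{prefix}.contigs.fa` (consensus sequences; headers carry contig length,
#' number of contributing reads and the 1-based inclusive target span on the
#' contig), `{prefix}.readpos.tsv` (placed reads with 0-based contig start
#' and strand), `{prefix}.coverage.tsv` (per-position depth, 1-based), and
#' `{prefix}.pileup.tsv` (per-position base tallies relative to the target
#' frame). The TSV files start with a `#`-prefixed header naming the columns;
#' when a `config` is supplied it is embedded as a comment (and as key=value
#' tokens on FASTA headers) so every output records the run parameters.
#'
#' @param contigs List of `contig` objects (see [assemble_target()]).
#' @param out_prefix Output path prefix.
#' @param config Optional named list of run parameters.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_outputs <- function(contigs, out_prefix, config = NULL) {
  contigs <- Filter(Negate(is.null), contigs)
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))
  cfg <- config_string(config)
  paths <- c(contigs = paste0(out_prefix, ".contigs.fa"),
             readpos = paste0(out_prefix, ".readpos.tsv"),
             coverage = paste0(out_prefix, ".coverage.tsv"),
             pileup = paste0(out_prefix, ".pileup.tsv"))

  headers <- vapply(contigs, function(ct)
    paste0(ct$contig_id,
           sprintf(" length=%d reads=%d target=%s target_span=%d-%d",
                   nchar(ct$sequence), ct$n_reads, ct$target_id,
                   ct$target_span[1], ct$target_span[2]),
           if (nzchar(cfg)) paste0(" ", cfg) else ""), character(1))
  set <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, paths[["contigs"]])

  write_tsv <- function(path, cols, df) {
    con <- file(path, "wt")
    on.exit(close(con))
    if (nzchar(cfg)) writeLines(paste0("# config: ", cfg), con)
    writeLines(paste0("#", paste(cols, collapse = "\t")), con)
    if (nrow(df) > 0L)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }

  readpos <- rbind_all(lapply(contigs, function(ct) {
    if (ct$n_reads == 0L) return(NULL)
    data.frame(read_id = ct$reads$read_id, source_file = ct$reads$source_file,
               contig_id = ct$contig_id, start = ct$reads$contig_start,
               strand = ct$reads$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(readpos))
    readpos <- data.frame(read_id = character(0), source_file = character(0),
                          contig_id = character(0), start = integer(0),
                          strand = character(0))
  write_tsv(paths[["readpos"]],
            c("read_id", "source_file", "contig_id", "start", "strand"), readpos)

  covdf <- rbind_all(lapply(contigs, function(ct)
    data.frame(contig_id = ct$contig_id, position = seq_along(ct$depth),
               depth = ct$depth, stringsAsFactors = FALSE)))
  if (is.null(covdf))
    covdf <- data.frame(contig_id = character(0), position = integer(0),
                        depth = integer(0))
  write_tsv(paths[["coverage"]], c("contig_id", "position", "depth"), covdf)

  piledf <- rbind_all(lapply(contigs, pileup_frame))
  if (is.null(piledf))
    piledf <- data.frame(contig_id = character(0), position = integer(0),
                         target_rel = integer(0), target_base = character(0),
                         consensus_base = character(0), depth = integer(0),
                         counts = character(0))
  write_tsv(paths[["pileup"]],
            c("contig_id", "position", "target_rel", "target_base",
              "consensus_base", "depth", "counts"), piledf)

  invisible(paths)
}

# Per-position rows of the modified pileup for one contig. target_rel is the
# position on the target axis (0 = target start); the target base is '-'
# outside the original target bounds.
pileup_frame <- function(ct) {
  n <- nchar(ct$sequence)
  if (n == 0L) return(NULL)
  axis <- ct$axis_origin + seq_len(n) - 1L
  in_target <- axis >= 0L & axis < ct$target_length
  tbase <- rep("-", n)
  tbase[in_target] <- strsplit(ct$target_sequence, "")[[1]][axis[in_target] + 1L]
  counts <- vapply(seq_len(n), function(i) {
    cts <- ct$counts[, i]
    nz <- cts > 0L
    if (!any(nz)) return(".")
    paste(sprintf("%s:%d", DNA_BASES[nz], cts[nz]), collapse = ",")
  }, character(1))
  data.frame(contig_id = ct$contig_id, position = seq_len(n),
             target_rel = axis, target_base = tbase,
             consensus_base = strsplit(ct$sequence, "")[[1]],
             depth = ct$depth, counts = counts, stringsAsFactors = FALSE)
}
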