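#' Simulate a uniform-random reference sequence
#'
#' @param length Reference length in nt (> 0).
#' @param seed Optional integer seed; the seed fully determines the output.
#' @return DNA string.
#' @export
simulate_reference <- function(length, seed = NULL) {
  if (length < 1L) stop("reference length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

#' Implant a variant into a reference with recorded ground truth
#'
#' Supported kinds: `snv` (substitute one base at `pos`), `deletion` (remove
#' `len` bases starting at `pos`, recording the resulting junction), and
#' `fusion` (concatenate `reference[1..pos]` with `partner[partner_pos..]`,
#' recording the junction). Positions are 1-based.
#'
#' @param reference DNA string.
#' @param kind One of `"snv"`, `"deletion"`, `"fusion"`.
#' @param pos 1-based position: the substituted base (snv), first deleted
#'   base (deletion), or last retained reference base (fusion).
#' @param alt Alternate base for `snv`; sampled from the other three bases
#'   when omitted (set a seed upstream for reproducibility).
#' @param len Deletion length in nt.
#' @param partner Partner DNA string for `fusion`.
#' @param partner_pos 1-based first partner base retained (default 1).
#' @return List with `sequence` (the edited molecule) and `truth` (one-row
#'   data frame: kind, pos, ref, alt, junction).
#' @export
implant_variant <- function(reference, kind = c("snv", "deletion", "fusion"),
                            pos, alt = NULL, len = NULL, partner = NULL,
                            partner_pos = 1L) {
  kind <- match.arg(kind)
  n <- nchar(reference)
  if (pos < 1L || pos > n) stop(sprintf("position %d out of range [1,%d]", pos, n))
  if (kind == "snv") {
    ref_base <- substr(reference, pos, pos)
    if (is.null(alt)) alt <- sample(setdiff(DNA_BASES, ref_base), 1L)
    if (alt == ref_base) stop("alt base equals the reference base")
    mut <- reference
    substr(mut, pos, pos) <- alt
    truth <- data.frame(kind = "snv", pos = pos, ref = ref_base, alt = alt,
                        junction = NA_integer_, stringsAsFactors = FALSE)
    return(list(sequence = mut, truth = truth))
  }
  if (kind == "deletion") {
    if (is.null(len) || len < 1L) stop("deletion length must be >= 1")
    if (pos + len - 1L > n) stop("deletion extends past the reference end")
    mut <- paste0(substr(reference, 1L, pos - 1L),
                  substr(reference, pos + len, n))
    truth <- data.frame(kind = "deletion", pos = pos, ref = substr(
                          reference, pos, pos + len - 1L), alt = "-",
                        junction = pos - 1L, stringsAsFactors = FALSE)
    return(list(sequence = mut, truth = truth))
  }
  if (is.null(partner)) stop("fusion requires a partner sequence")
  if (partner_pos < 1L || partner_pos > nchar(partner))
    stop("partner_pos out of range")
  mut <- paste0(substr(reference, 1L, pos),
                substr(partner, partner_pos, nchar(partner)))
  truth <- data.frame(kind = "fusion", pos = pos, ref = NA_character_,
                      alt = NA_character_, junction = pos,
                      stringsAsFactors = FALSE)
  list(sequence = mut, truth = truth)
}

#' Simulate stranded shotgun reads from one or more alleles
#'
#' Read start positions are uniform over valid positions of the sampled
#' allele; each read is drawn from the plus or minus strand according to the
#' strand balance (minus-strand reads are reverse-complemented before being
#' reported, as a sequencer would emit them); substitution errors are applied
#' per base at the configured rate. The substitution-only error model matches
#' a gapless assembler: indel errors would only reduce recruitment, which is
#' exercised instead by elevating the substitution rate.
#'
#' @param alleles Character vector of allele sequences (e.g. the two
#'   haplotypes of a heterozygote).
#' @param depth Mean total coverage across alleles.
#' @param read_length Read length in nt (must not exceed the shortest
#'   allele).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param fractions Allele sampling fractions (default equal).
#' @param strand_balance Probability a read comes from the plus strand
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @param id_prefix Read-name prefix.
#' @return Data frame of reads (`read_id`, `sequence`, `source_file`) with
#'   ground-truth columns `allele`, `start` (1-based on the allele) and
#'   `strand`.
#' @export
simulate_reads <- function(alleles, depth, read_length, error_rate = 0,
                           fractions = NULL, strand_balance = 0.5,
                           seed = NULL, id_prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error rate must be in [0, 1)")
  lens <- nchar(alleles)
  if (read_length > min(lens))
    stop("read length exceeds the shortest allele length")
  if (is.null(fractions)) fractions <- rep(1 / length(alleles), length(alleles))
  n_reads <- round(depth * max(lens) / read_length)
  which_allele <- sample.int(length(alleles), n_reads, replace = TRUE,
                             prob = fractions)
  starts <- vapply(which_allele, function(a)
    sample.int(lens[a] - read_length + 1L, 1L), integer(1))
  seqs <- substring(alleles[which_allele], starts, starts + read_length - 1L)
  plus <- stats::runif(n_reads) < strand_balance
  if (any(!plus)) seqs[!plus] <- revcomp(seqs[!plus])
  if (error_rate > 0 && n_reads > 0L) {
    seqs <- vapply(seqs, function(s) {
      hit <- which(stats::runif(read_length) < error_rate)
      for (p in hit) {
        substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1L)
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(read_id = sprintf("%s_%05d", id_prefix, seq_len(n_reads)),
             sequence = seqs, source_file = "simulated",
             allele = which_allele, start = starts,
             strand = ifelse(plus, "+", "-"), stringsAsFactors = FALSE)
}

#' Deterministic dense tiling reads
#'
#' Emits error-free reads starting at every position of the reference, on
#' the requested strands, `copies` identical reads per (start, strand). Two
#' copies per placement are the default so that the extreme flank positions
#' of an assembly -- covered by exactly one distinct placement -- still meet
#' the default extension depth threshold (`o = 2`), which is the condition
#' under which the analytic per-side extension bound `read_length - m` is
#' realised.
#'
#' @param reference DNA string.
#' @param read_length Read length in nt.
#' @param copies Identical reads per (start, strand) (default 2).
#' @param strands Strands to emit (default both).
#' @param id_prefix Read-name prefix.
#' @return Data frame of reads (`read_id`, `sequence`, `source_file`).
#' @export
tile_reads <- function(reference, read_length, copies = 2L,
                       strands = c("+", "-"), id_prefix = "tile") {
  n <- nchar(reference)
  if (read_length > n) stop("read length exceeds reference length")
  starts <- seq_len(n - read_length + 1L)
  plus <- substring(reference, starts, starts + read_length - 1L)
  seqs <- character(0)
  labs <- character(0)
  if ("+" %in% strands) {
    seqs <- c(seqs, plus)
    labs <- c(labs, sprintf("p%05d", starts))
  }
  if ("-" %in% strands) {
    seqs <- c(seqs, revcomp(plus))
    labs <- c(labs, sprintf("m%05d", starts))
  }
  seqs <- rep(seqs, each = copies)
  labs <- paste0(rep(labs, each = copies), "_c", seq_len(copies))
  data.frame(read_id = paste0(id_prefix, "_", labs), sequence = seqs,
             source_file = "tiling", stringsAsFactors = FALSE)
}

#' Write simulation ground truth as TSV
#'
#' The header comment records the full simulation config for provenance.
#'
#' @param truth Data frame of truth records.
#' @param path Output path.
#' @param config Optional named list describing the simulation.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, config = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  cfg <- config_string(config)
  if (nzchar(cfg)) writeLines(paste0("# config: ", cfg), con)
  writeLines(paste0("#", paste(colnames(truth), collapse = "\t")), con)
  if (nrow(truth) > 0L)
    utils::write.table(truth, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
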