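#' Design a reference/variant target pair for an SNV
#'
#' Builds two targets differing only at the centre base of an odd-length
#' context: one carrying the reference base, one the variant. Centring the
#' base under scrutiny maximises the number of recruiting words that overlap
#' it. Contexts shorter than `2k + 1` still work but fewer than `k` words
#' overlap the focal base, so recruitment is less sensitive; a warning is
#' emitted.
#'
#' @param context Odd-length DNA string whose centre base is the reference
#'   allele. The conventional length is 51.
#' @param ref_base,alt_base Single reference and variant bases;
#'   `alt_base` must differ from `ref_base`.
#' @param id Variant identifier used to name the pair.
#' @param k Word size used downstream (for the sensitivity warning).
#' @return Two-row target data frame (alleles `ref` and `alt`) with `focal`
#'   set to the 0-based centre offset.
#' @export
snv_target_pair <- function(context, ref_base, alt_base, id = "snv", k = 15L) {
  context <- toupper(context)
  n <- nchar(context)
  if (n %% 2L == 0L) stop("context length must be odd so the focal base is centred")
  centre <- (n + 1L) %/% 2L
  if (substr(context, centre, centre) != toupper(ref_base))
    stop(sprintf("centre base '%s' does not match ref_base '%s'",
                 substr(context, centre, centre), ref_base))
  if (toupper(alt_base) == toupper(ref_base))
    stop("alt_base must differ from ref_base")
  if (n < 2L * k + 1L)
    warning(sprintf(
      "context length %d < %d: fewer than k words overlap the focal base", n,
      2L * k + 1L))
  alt_seq <- context
  substr(alt_seq, centre, centre) <- toupper(alt_base)
  rbind(
    target_record(paste0(id, "_ref"), context, kind = "snv",
                  focal = centre - 1L, allele = "ref", variant_id = id),
    target_record(paste0(id, "_alt"), alt_seq, kind = "snv",
                  focal = centre - 1L, allele = "alt", variant_id = id))
}

#' Design a four-probe set with an ambiguous last base
#'
#' For discovering unknown sequence 3' of a known prefix (e.g. a viral
#' integration or fusion partner): four targets share the same known prefix
#' and differ only in their final base, one per nucleotide. Exactly the probe
#' whose last base matches the unknown neighbouring sequence can recruit
#' reads spanning into it and extend past its end.
#'
#' @param known_prefix DNA string of length at least `k`; conventionally 37
#'   bases, giving 38-base probes.
#' @param id Probe-set identifier.
#' @param k Word size (minimum viable prefix length).
#' @return Four-row target data frame, ids suffixed `_A`, `_C`, `_G`, `_T`,
#'   with `focal` set to the 0-based offset of the ambiguous base.
#' @export
fusion_probe_set <- function(known_prefix, id = "probe", k = 15L) {
  known_prefix <- toupper(known_prefix)
  if (nchar(known_prefix) < k)
    stop(sprintf("known prefix must be at least k=%d bases", k))
  if (grepl("[^ACGT]", known_prefix))
    stop("known prefix contains non-ACGT characters")
  do.call(rbind, lapply(DNA_BASES, function(b)
    target_record(paste0(id, "_", b), paste0(known_prefix, b), kind = "fusion",
                  focal = nchar(known_prefix), allele = b, variant_id = id)))
}

#' Design a breakpoint junction target
#'
#' Concatenates two arms flanking a putative junction (fusion, deletion
#' breakpoint, integration). The junction coordinate (= left-arm length) is
#' recorded in the target metadata for downstream chimaeric-read counting.
#' When the arms come from different molecules, any recruited read spanning
#' the junction is chimaera evidence by construction.
#'
#' @param left_arm,right_arm Non-empty DNA strings.
#' @param id Target identifier.
#' @param k Word size (the combined target must be at least `k` long).
#' @return One-row target data frame with `junction` set.
#' @export
junction_target <- function(left_arm, right_arm, id = "junction", k = 15L) {
  left_arm <- toupper(left_arm)
  right_arm <- toupper(right_arm)
  if (!nzchar(left_arm) || !nzchar(right_arm))
    stop("both junction arms must be non-empty")
  if (nchar(left_arm) + nchar(right_arm) < k)
    stop(sprintf("combined arm length must be at least k=%d", k))
  target_record(id, paste0(left_arm, right_arm), kind = "junction",
                focal = nchar(left_arm), variant_id = id,
                junction = nchar(left_arm))
}

#' Batch-design SNV/indel target pairs from a reference and VCF
#'
#' For each VCF row, a symmetric context is extracted around `POS` from the
#' reference and a ref/alt target pair is built. SNVs centre the substituted
#' base; for indels the first altered base is placed at the centre and the
#' alt target carries the edited sequence trimmed/padded to the same length.
#'
#' @param ref_fasta Path to the reference FASTA.
#' @param vcf_path Path to a VCF file (only CHROM, POS, REF, ALT are used).
#' @param target_length Odd target length (default 51).
#' @return Target data frame with two rows per variant.
#' @export
targets_from_vcf <- function(ref_fasta, vcf_path, target_length = 51L) {
  if (target_length %% 2L == 0L) stop("target_length must be odd")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("targets_from_vcf requires the vcfR package")
  ref <- Biostrings::readDNAStringSet(ref_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  fix <- as.data.frame(vcfR::getFIX(
    vcfR::read.vcfR(vcf_path, verbose = FALSE)), stringsAsFactors = FALSE)
  flank <- (target_length - 1L) %/% 2L
  out <- lapply(seq_len(nrow(fix)), function(i) {
    chrom <- fix$CHROM[i]
    pos <- as.integer(fix$POS[i])
    refa <- toupper(fix$REF[i])
    alta <- toupper(strsplit(fix$ALT[i], ",")[[1]][1])
    if (!chrom %in% names(ref))
      stop(sprintf("VCF CHROM '%s' not in reference", chrom))
    chrseq <- as.character(ref[[chrom]])
    if (pos < 1L || pos + nchar(refa) - 1L > nchar(chrseq))
      stop(sprintf("VCF POS %d out of range for %s", pos, chrom))
    if (substr(chrseq, pos, pos + nchar(refa) - 1L) != refa)
      stop(sprintf("VCF REF mismatch at %s:%d", chrom, pos))
    id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i]
          else sprintf("%s_%d", chrom, pos)
    if (nchar(refa) == 1L && nchar(alta) == 1L) {
      ctx <- substr(chrseq, pos - flank, pos + flank)
      if (nchar(ctx) < target_length)
        stop(sprintf("variant %s too close to reference edge", id))
      return(snv_target_pair(ctx, refa, alta, id = id))
    }
    # indel: centre the first altered base; both alleles reported at
    # target_length by taking a window of the edited sequence
    edited <- paste0(substr(chrseq, 1L, pos - 1L), alta,
                     substr(chrseq, pos + nchar(refa), nchar(chrseq)))
    ref_t <- substr(chrseq, pos - flank, pos - flank + target_length - 1L)
    alt_t <- substr(edited, pos - flank, pos - flank + target_length - 1L)
    if (nchar(ref_t) < target_length || nchar(alt_t) < target_length)
      stop(sprintf("variant %s too close to reference edge", id))
    rbind(
      target_record(paste0(id, "_ref"), ref_t, kind = "indel", focal = flank,
                    allele = "ref", variant_id = id),
      target_record(paste0(id, "_alt"), alt_t, kind = "indel", focal = flank,
                    allele = "alt", variant_id = id))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
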