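#' Count reads spanning a focal target position
#'
#' A spanning read covers the focal position; an interior spanning read
#' additionally has the focal base at least `margin` bases away from both of
#' its ends (default 5), discounting edge-unreliable support.
#'
#' @param contig A `contig` object (or `NULL`, giving zero counts).
#' @param focal 0-based focal offset on the target axis; must lie within the
#'   original target bounds.
#' @param margin Interior edge margin in bases (default 5).
#' @return List with `n_spanning` and `n_interior`.
#' @export
count_spanning <- function(contig, focal, margin = 5L) {
  if (is.null(contig)) return(list(n_spanning = 0L, n_interior = 0L))
  if (focal < 0L || focal >= contig$target_length)
    stop(sprintf("focal position %d outside target bounds [0,%d)",
                 focal, contig$target_length))
  rd <- contig$reads
  if (nrow(rd) == 0L) return(list(n_spanning = 0L, n_interior = 0L))
  pos_in_read <- focal - rd$start
  spanning <- pos_in_read >= 0L & pos_in_read < rd$length
  interior <- spanning & pos_in_read >= margin &
    (rd$length - 1L - pos_in_read) >= margin
  list(n_spanning = sum(spanning), n_interior = sum(interior))
}

#' Per-allele support and a genotype-style call for an SNV target pair
#'
#' Evaluates the reference and variant targets of one locus and summarises
#' them as `both` (heterozygous-consistent), `ref-only`, `alt-only`, or
#' `no-call`. An allele is detected when its interior spanning-read count
#' reaches `threshold` (default 1: presence/absence).
#'
#' @param ref_contig,alt_contig `contig` objects for the two alleles (either
#'   may be `NULL` when that target assembled nothing).
#' @param focal 0-based focal offset on the target axis.
#' @param margin Interior edge margin (default 5).
#' @param threshold Interior spanning reads required for detection
#'   (default 1).
#' @return List with `per_allele` (data frame: allele, n_spanning,
#'   n_interior, detected) and `call`.
#' @export
allele_report <- function(ref_contig, alt_contig, focal, margin = 5L,
                          threshold = 1L) {
  cr <- count_spanning(ref_contig, focal, margin)
  ca <- count_spanning(alt_contig, focal, margin)
  det_r <- cr$n_interior >= threshold
  det_a <- ca$n_interior >= threshold
  call <- if (det_r && det_a) "both"
          else if (det_r) "ref-only"
          else if (det_a) "alt-only"
          else "no-call"
  list(per_allele = data.frame(
         allele = c("ref", "alt"),
         n_spanning = c(cr$n_spanning, ca$n_spanning),
         n_interior = c(cr$n_interior, ca$n_interior),
         detected = c(det_r, det_a), stringsAsFactors = FALSE),
       call = call)
}

#' Chimaeric-read evidence at a junction
#'
#' Counts placed reads with at least one base strictly on each side of a
#' junction coordinate (direct evidence for a fusion, integration or
#' deletion breakpoint) and reports how many consensus bases extend beyond
#' the target on each side (novel sequence length).
#'
#' @param contig A `contig` object.
#' @param junction 0-based target-axis coordinate of the junction (bases at
#'   positions `< junction` are left-side). Must lie within the assembled
#'   contig.
#' @return List with `n_chimaeric`, `n_left_only`, `n_right_only`,
#'   `novel_left` and `novel_right`.
#' @export
chimaera_report <- function(contig, junction) {
  if (is.null(contig)) stop("no contig assembled")
  lo <- contig$axis_origin
  hi <- contig$axis_origin + nchar(contig$sequence)
  if (junction <= lo || junction >= hi)
    stop(sprintf("junction %d outside contig span [%d,%d)", junction, lo, hi))
  rd <- contig$reads
  left_bases <- pmin(rd$start + rd$length, junction) - rd$start
  right_bases <- rd$start + rd$length - pmax(rd$start, junction)
  chim <- left_bases >= 1L & right_bases >= 1L
  list(n_chimaeric = sum(chim),
       n_left_only = sum(left_bases >= 1L & right_bases < 1L),
       n_right_only = sum(right_bases >= 1L & left_bases < 1L),
       novel_left = contig$left_ext,
       novel_right = contig$right_ext)
}

#' Build and write a variant support report
#'
#' Turns assembled contigs plus target metadata into a one-row-per-(variant,
#' allele) table: spanning and interior spanning read counts and a
#' presence/absence call per allele, with the pair-level call repeated on
#' both rows. Targets without variant metadata are reported with their focal
#' position taken as the target midpoint.
#'
#' @param targets Target data frame (with `variant_id`/`allele`/`focal`
#'   metadata where available).
#' @param contigs Named list of contigs from [assemble_all()].
#' @param margin Interior edge margin (default 5).
#' @param threshold Detection threshold (default 1).
#' @return Data frame with columns `variant_id`, `target_id`, `allele`,
#'   `n_spanning`, `n_interior`, `detected`, `call`.
#' @export
variant_report <- function(targets, contigs, margin = 5L, threshold = 1L) {
  rows <- list()
  vids <- ifelse(is.na(targets$variant_id), targets$target_id,
                 targets$variant_id)
  for (vid in unique(vids)) {
    grp <- targets[vids == vid, , drop = FALSE]
    alleles <- ifelse(is.na(grp$allele), "ref", grp$allele)
    counts <- lapply(seq_len(nrow(grp)), function(i) {
      focal <- grp$focal[i]
      if (is.na(focal)) focal <- grp$length[i] %/% 2L
      ct <- contigs[[grp$target_id[i]]]
      if (!is.null(ct) && focal >= ct$target_length) focal <- ct$target_length - 1L
      count_spanning(ct, focal, margin)
    })
    det <- vapply(counts, function(x) x$n_interior >= threshold, logical(1))
    call <- if (all(c("ref", "alt") %in% alleles)) {
      dr <- any(det[alleles == "ref"]); da <- any(det[alleles == "alt"])
      if (dr && da) "both" else if (dr) "ref-only"
      else if (da) "alt-only" else "no-call"
    } else if (any(det)) "detected" else "no-call"
    rows[[vid]] <- data.frame(
      variant_id = vid, target_id = grp$target_id, allele = alleles,
      n_spanning = vapply(counts, `[[`, integer(1), "n_spanning"),
      n_interior = vapply(counts, `[[`, integer(1), "n_interior"),
      detected = det, call = call, stringsAsFactors = FALSE)
  }
  out <- rbind_all(rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(0), target_id = character(0),
                      allele = character(0), n_spanning = integer(0),
                      n_interior = integer(0), detected = logical(0),
                      call = character(0), stringsAsFactors = FALSE)
  out
}

#' Write a variant support report as TSV
#'
#' @param report Data frame from [variant_report()].
#' @param path Output path.
#' @param config Optional named list of run parameters embedded as a header
#'   comment.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(report, path, config = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  cfg <- config_string(config)
  if (nzchar(cfg)) writeLines(paste0("# config: ", cfg), con)
  writeLines(paste0("#", paste(colnames(report), collapse = "\t")), con)
  if (nrow(report) > 0L)
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
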