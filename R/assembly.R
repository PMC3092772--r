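#' Place recruited reads on a target's coordinate axis
#'
#' Each candidate word hit proposes a placement: a plus-strand hit at offset
#' `i` places the read at start `i`; a minus-strand hit at offset `i` places
#' the reverse-complemented read at start `i + k - read_length`, so that the
#' oriented read's last `k` bases sit over `[i, i + k)`. Starts may be
#' negative (read begins left of the target). A candidate is accepted iff its
#' overlap with the target interval `[0, L)` is at least `m` bases and the
#' oriented read agrees with the target at every in-target position it covers
#' (the perfect-agreement rule; an `N` counts as a mismatch). Among multiple
#' accepted candidates for one read, the largest in-target overlap wins, ties
#' broken by smallest start, then by plus strand. Rejection is a normal
#' outcome, tallied in the returned stats.
#'
#' @param recruited A `recruitment` object.
#' @param target One-row target record.
#' @param m Minimum in-target overlap in bases (default 15).
#' @param k Word size used at recruitment; defaults to `recruited$k`.
#' @return List with `placed` (data frame: `read_id`, `source_file`,
#'   `strand`, `start`, `oriented_sequence`, `length`, `overlap`) and `stats`
#'   (`n_candidate_reads`, `n_placed`, `n_rejected`).
#' @export
place_reads <- function(recruited, target, m = 15L, k = recruited$k) {
  tid <- target$target_id
  tseq <- target$sequence
  L <- target$length
  idx <- which(vapply(recruited$hits, function(h) tid %in% h$target_id,
                      logical(1)))
  n_cand <- length(idx)
  if (n_cand == 0L)
    return(list(placed = empty_placements(),
                stats = list(n_candidate_reads = 0L, n_placed = 0L,
                             n_rejected = 0L)))
  seqs <- recruited$reads$sequence[idx]
  rcs <- revcomp(seqs)
  rows <- vector("list", n_cand)
  for (j in seq_len(n_cand)) {
    i <- idx[j]
    h <- recruited$hits[[i]]
    h <- h[h$target_id == tid, , drop = FALSE]
    len <- nchar(seqs[j])
    start <- ifelse(h$strand == "+", h$offset, h$offset + k - len)
    cand <- data.frame(strand = h$strand, start = start,
                       stringsAsFactors = FALSE)
    cand <- unique(cand)
    best <- NULL
    for (ci in seq_len(nrow(cand))) {
      s <- cand$start[ci]
      lo <- max(s, 0L)
      hi <- min(s + len, L)
      ov <- hi - lo
      if (ov < m) next
      oseq <- if (cand$strand[ci] == "+") seqs[j] else rcs[j]
      if (substr(oseq, lo - s + 1L, hi - s) != substr(tseq, lo + 1L, hi)) next
      if (is.null(best) || ov > best$overlap ||
          (ov == best$overlap &&
           (s < best$start || (s == best$start && cand$strand[ci] == "+")))) {
        best <- list(strand = cand$strand[ci], start = s, overlap = ov,
                     oseq = oseq)
      }
    }
    if (!is.null(best)) {
      rows[[j]] <- data.frame(read_id = recruited$reads$read_id[i],
                              source_file = recruited$reads$source_file[i],
                              strand = best$strand, start = best$start,
                              oriented_sequence = best$oseq, length = len,
                              overlap = best$overlap, stringsAsFactors = FALSE)
    }
  }
  placed <- rbind_all(rows)
  if (is.null(placed)) placed <- empty_placements()
  list(placed = placed,
       stats = list(n_candidate_reads = n_cand, n_placed = nrow(placed),
                    n_rejected = n_cand - nrow(placed)))
}

empty_placements <- function() {
  data.frame(read_id = character(0), source_file = character(0),
             strand = character(0), start = integer(0),
             oriented_sequence = character(0), length = integer(0),
             overlap = integer(0), stringsAsFactors = FALSE)
}

#' Construct a coverage table
#'
#' Low-level constructor, mainly for tests and the extension-threshold
#' examples: a 4-row counts matrix (rows `A`, `C`, `G`, `T`) over a window of
#' consecutive target-axis positions.
#'
#' @param counts 4-row integer matrix with rownames `A,C,G,T`.
#' @param origin Target-axis position of the first column (may be negative;
#'   0 is the first target base).
#' @return Object of class `coverage_table`.
#' @export
coverage_table <- function(counts, origin = 0L) {
  if (!is.matrix(counts) || nrow(counts) != 4L ||
      !identical(rownames(counts), DNA_BASES))
    stop("counts must be a 4-row matrix with rownames A,C,G,T")
  structure(list(counts = counts, origin = as.integer(origin)),
            class = "coverage_table")
}

#' Tally per-position base counts over placed reads
#'
#' Accumulates every oriented `A/C/G/T` base of every placed read at its
#' target-axis position, including flank positions left of 0 and right of the
#' target end. `N` bases are excluded from the counts but still occupy the
#' read's span.
#'
#' @param placed Data frame of placements from [place_reads()].
#' @return A `coverage_table`.
#' @export
build_coverage <- function(placed) {
  if (nrow(placed) == 0L)
    return(coverage_table(matrix(0L, 4L, 0L, dimnames = list(DNA_BASES, NULL)),
                          origin = 0L))
  origin <- min(placed$start)
  width <- max(placed$start + placed$length) - origin
  counts <- matrix(0L, 4L, width, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(nrow(placed))) {
    bases <- strsplit(placed$oriented_sequence[i], "")[[1]]
    ridx <- match(bases, DNA_BASES)
    keep <- !is.na(ridx)
    if (!any(keep)) next
    cidx <- placed$start[i] - origin + which(keep)
    ij <- cbind(ridx[keep], cidx)
    counts[ij] <- counts[ij] + 1L
  }
  coverage_table(counts, origin)
}

# Base counts at one target-axis position (zeros outside the table).
cov_col <- function(cov, pos) {
  j <- pos - cov$origin + 1L
  if (j < 1L || j > ncol(cov$counts))
    return(stats::setNames(integer(4L), DNA_BASES))
  cov$counts[, j]
}

# Decide one flank position: accepted iff depth >= o and top/depth >= r.
# On acceptance the most represented base is returned (alphabetical first on
# a tie, reachable only when r <= 0.5 since a depth->2 tie has ratio 0.5).
flank_call <- function(cts, o, r) {
  depth <- sum(cts)
  if (depth < o) return(NULL)
  top <- max(cts)
  if (top / depth < r) return(NULL)
  DNA_BASES[which.max(cts)]
}

#' Extend the in-target consensus bidirectionally
#'
#' Within the target bounds the consensus equals the target verbatim (the
#' perfect-agreement rule guarantees every contributing read matches there).
#' Walking outward one position at a time -- left from position -1 and right
#' from the target end -- a flank position is appended iff its total depth is
#' at least `o` and the most represented base accounts for at least fraction
#' `r` of that depth. The first failing position terminates that direction
#' permanently; a failed position is never revisited.
#'
#' @param cov A `coverage_table` on the target axis.
#' @param target One-row target record.
#' @param o Minimum flank coverage (default 2).
#' @param r Minimum top-base ratio, `count(top)/depth` (default 0.7).
#' @param placed Optional placements data frame carried onto the contig.
#' @return A `contig` object (untrimmed; see [assemble_target()] for the
#'   report-coverage trim).
#' @export
extend_consensus <- function(cov, target, o = 2L, r = 0.7,
                             placed = empty_placements()) {
  L <- target$length
  left <- character(0)
  p <- -1L
  repeat {
    b <- flank_call(cov_col(cov, p), o, r)
    if (is.null(b)) break
    left <- c(b, left)
    p <- p - 1L
  }
  right <- character(0)
  p <- L
  repeat {
    b <- flank_call(cov_col(cov, p), o, r)
    if (is.null(b)) break
    right <- c(right, b)
    p <- p + 1L
  }
  new_contig(target, cov, paste(left, collapse = ""),
             paste(right, collapse = ""), 0L, L - 1L, placed)
}

# Assemble a contig object from its parts. i0/j0 are the first/last reported
# in-target axis positions (0-based, inclusive); flanks are only reported on
# a side whose in-target edge was not trimmed.
new_contig <- function(target, cov, left_flank, right_flank, i0, j0, placed) {
  left_ext <- if (i0 == 0L) nchar(left_flank) else 0L
  right_ext <- if (j0 == target$length - 1L) nchar(right_flank) else 0L
  core <- substr(target$sequence, i0 + 1L, j0 + 1L)
  seqn <- paste0(if (left_ext) left_flank else "", core,
                 if (right_ext) right_flank else "")
  axis_origin <- i0 - left_ext
  n <- nchar(seqn)
  counts <- matrix(0L, 4L, n, dimnames = list(DNA_BASES, NULL))
  src <- (axis_origin - cov$origin + 1L):(axis_origin - cov$origin + n)
  ok <- src >= 1L & src <= ncol(cov$counts)
  if (any(ok)) counts[, which(ok)] <- cov$counts[, src[ok], drop = FALSE]
  target_len_rep <- j0 - i0 + 1L
  if (nrow(placed) > 0L) placed$contig_start <- placed$start - axis_origin
  else placed$contig_start <- integer(0)
  structure(list(
    contig_id = paste0(target$target_id, ".contig"),
    target_id = target$target_id,
    sequence = seqn,
    left_ext = left_ext,
    right_ext = right_ext,
    axis_origin = axis_origin,
    target_length = target$length,
    target_sequence = target$sequence,
    target_span = c(start = left_ext + 1L, end = left_ext + target_len_rep),
    depth = unname(colSums(counts)),
    counts = counts,
    reads = placed,
    n_reads = nrow(placed)
  ), class = "contig")
}

#' Assemble one target from its recruited reads
#'
#' Composes [place_reads()], [build_coverage()] and [extend_consensus()],
#' then trims the reported contig inward from each end until every reported
#' in-target position has depth at least `c` (flank extension on a side is
#' dropped if that side's in-target edge is trimmed). Returns `NULL` when no
#' read places on the target -- absence is a result, not an error.
#'
#' @param target One-row target record.
#' @param recruited A `recruitment` object.
#' @param m Minimum in-target overlap (default 15).
#' @param o Minimum flank extension coverage (default 2).
#' @param r Minimum top-base ratio for extension (default 0.7).
#' @param c Minimum depth for an in-target position to be reported
#'   (default 1).
#' @param k Word size; defaults to `recruited$k`.
#' @return A `contig` object or `NULL`.
#' @export
assemble_target <- function(target, recruited, m = 15L, o = 2L, r = 0.7,
                            c = 1L, k = recruited$k) {
  pl <- place_reads(recruited, target, m = m, k = k)
  if (nrow(pl$placed) == 0L) return(NULL)
  cov <- build_coverage(pl$placed)
  L <- target$length
  depth_in <- vapply(0:(L - 1L), function(p) sum(cov_col(cov, p)), numeric(1))
  i0 <- 0L
  while (i0 < L && depth_in[i0 + 1L] < c) i0 <- i0 + 1L
  j0 <- L - 1L
  while (j0 >= i0 && depth_in[j0 + 1L] < c) j0 <- j0 - 1L
  if (i0 > j0) return(NULL)
  full <- extend_consensus(cov, target, o = o, r = r, placed = pl$placed)
  if (i0 == 0L && j0 == L - 1L) return(full)
  lf <- if (i0 == 0L) substr(full$sequence, 1L, full$left_ext) else ""
  rf <- if (j0 == L - 1L)
    substr(full$sequence, nchar(full$sequence) - full$right_ext + 1L,
           nchar(full$sequence)) else ""
  new_contig(target, cov, lf, rf, i0, j0, pl$placed)
}

#' Assemble every target against one recruitment
#'
#' @param targets Data frame of target records.
#' @param recruited A `recruitment` object.
#' @inheritParams assemble_target
#' @return Named list of `contig` objects (targets yielding no contig are
#'   `NULL` entries).
#' @export
assemble_all <- function(targets, recruited, m = 15L, o = 2L, r = 0.7,
                         c = 1L, k = recruited$k) {
  out <- lapply(seq_len(nrow(targets)), function(i)
    assemble_target(targets[i, ], recruited, m = m, o = o, r = r, c = c,
                    k = k))
  stats::setNames(out, targets$target_id)
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf(
    "<contig> %s | %d bp | target %s span %d-%d | left_ext=%d right_ext=%d | %d reads\n",
    x$contig_id, nchar(x$sequence), x$target_id, x$target_span[1],
    x$target_span[2], x$left_ext, x$right_ext, x$n_reads))
  invisible(x)
}
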