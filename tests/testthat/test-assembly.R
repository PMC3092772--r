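recruit_one <- function(seqs, target) recruit(reads_df(seqs), build_index(target))

test_that("placement coordinates and the perfect-agreement rule", {
  set.seed(401)
  tseq <- rand_dna(51)
  tg <- target_record("t", tseq)

  # exact interior subsequence places at its true offset on the plus strand
  rec <- recruit_one(substr(tseq, 11, 46), tg)
  pl <- place_reads(rec, tg)$placed
  expect_equal(pl$start, 10L)
  expect_equal(pl$strand, "+")

  # reverse-complement of the target prefix places at start 0, minus strand:
  # the '-' hit at offset 21 gives start = 21 + 15 - 36 = 0
  rec <- recruit_one(revcomp(substr(tseq, 1, 36)), tg)
  pl <- place_reads(rec, tg)$placed
  expect_equal(pl$start, 0L)
  expect_equal(pl$strand, "-")
  expect_equal(pl$oriented_sequence, substr(tseq, 1, 36))

  # one downstream in-target mismatch rejects the read outright
  bad <- substr(tseq, 1, 36)
  substr(bad, 30, 30) <- flip_base(substr(bad, 30, 30))
  rec <- recruit_one(bad, tg)
  expect_equal(rec$stats$retained, 1L)  # recruited on its clean prefix ...
  res <- place_reads(rec, tg)
  expect_equal(nrow(res$placed), 0L)   # ... but never placed
  expect_equal(res$stats$n_rejected, 1L)

  # an N over the target counts as a mismatch
  nread <- substr(tseq, 1, 36)
  substr(nread, 20, 20) <- "N"
  expect_equal(nrow(place_reads(recruit_one(nread, tg), tg)$placed), 0L)

  # overlap below m is rejected even though the prefix matched
  tail_read <- paste0(substr(tseq, 38, 51), rand_dna(22))  # 14 in-target bases
  rec <- recruit_one(tail_read, tg)
  expect_equal(nrow(place_reads(rec, tg, m = 15)$placed), 0L)
})

test_that("placements match exhaustive gapless alignment on random fixtures", {
  set.seed(402)
  for (rep in 1:15) {
    tg <- target_record("t", rand_dna(sample(40:90, 1)))
    # reads sampled from a mutated/unmutated copy, both strands
    base <- tg$sequence
    reads <- vapply(1:10, function(i) {
      s <- sample(nchar(base) - 25, 1)
      r <- substr(base, s, min(nchar(base), s + sample(24:35, 1)))
      if (runif(1) < 0.3) substr(r, 12, 12) <- flip_base(substr(r, 12, 12))
      if (runif(1) < 0.5) revcomp(r) else r
    }, character(1))
    rec <- recruit_one(reads, tg)
    pl <- place_reads(rec, tg, m = 15)$placed
    for (i in seq_len(nrow(rec$reads))) {
      want <- oracle_placements(rec$reads$sequence[i], tg$sequence, m = 15)
      got <- pl[pl$read_id == rec$reads$read_id[i], ]
      if (nrow(want) == 0) {
        expect_equal(nrow(got), 0L)
      } else {
        # the accepted placement is the max-overlap (then leftmost) candidate
        best <- want[order(-want$overlap, want$start), ][1, ]
        expect_equal(got$start, best$start)
        expect_equal(got$overlap, best$overlap)
      }
    }
  }
})

test_that("coverage tallies are additive, flank-aware and recount exactly", {
  set.seed(403)
  tg <- target_record("t", rand_dna(150))
  reads <- rep(substr(tg$sequence, 21, 56), 2)  # identical duplicates
  pl <- place_reads(recruit_one(reads, tg), tg)$placed
  cov <- build_coverage(pl)
  expect_equal(cov$origin, 20L)
  expect_true(all(cov$counts[cbind(
    match(strsplit(substr(tg$sequence, 21, 56), "")[[1]], c("A","C","G","T")),
    1:36)] == 2L))

  expect_equal(ncol(build_coverage(place_reads(
    recruit_one("ACGT", tg), tg)$placed)$counts), 0L)

  # randomized tiling recount oracle, including flank positions
  fx <- tiling_fixture(ref_len = 250, target_len = 80, read_len = 33)
  pl <- place_reads(recruit(fx$reads, build_index(fx$target)), fx$target)$placed
  cov <- build_coverage(pl)
  want <- oracle_recount(pl)
  for (key in names(want)) {
    pos <- as.integer(key)
    cts <- cov_col_test(cov, pos)
    for (b in names(want[[key]]))
      expect_equal(unname(cts[b]), unname(want[[key]][b]))
    expect_equal(sum(cts), sum(want[[key]]))
  }

  # N in a flank position is excluded from counts but occupies the span
  tg2 <- target_record("t2", rand_dna(60))
  ctx <- paste0(rand_dna(10), tg2$sequence, rand_dna(10))
  rds <- c(substr(ctx, 36, 71), substr(ctx, 36, 71))
  nread <- rds[1]
  substr(nread, 36, 36) <- "N"   # last base lies in the right flank
  pl2 <- place_reads(recruit_one(c(rds, nread), tg2), tg2)$placed
  cov2 <- build_coverage(pl2)
  flank_pos <- 60L  # first right-flank position
  expect_equal(sum(cov_col_test(cov2, flank_pos)), 2L)  # N read not counted
})

test_that("extension thresholds follow the coverage and ratio rules exactly", {
  tg <- target_record("t", strrep("ACGT", 5))
  mk <- function(...) {
    cols <- list(...)
    m <- matrix(0L, 4, length(cols), dimnames = list(c("A","C","G","T"), NULL))
    for (i in seq_along(cols)) m[names(cols[[i]]), i] <- cols[[i]]
    m
  }
  # right flank at position L: {A:3, C:1} depth 4 ratio 0.75 -> accepted A
  cov <- coverage_table(mk(c(A = 3L, C = 1L)), origin = 20L)
  ct <- extend_consensus(cov, tg, o = 2, r = 0.7)
  expect_equal(ct$right_ext, 1L)
  expect_equal(substr(ct$sequence, nchar(ct$sequence), nchar(ct$sequence)), "A")

  # depth o-1 terminates
  ct <- extend_consensus(coverage_table(mk(c(A = 1L)), 20L), tg, o = 2, r = 0.7)
  expect_equal(ct$right_ext, 0L)

  # ratio just below r terminates: 2/3 < 0.7
  ct <- extend_consensus(coverage_table(mk(c(A = 2L, C = 1L)), 20L), tg,
                         o = 2, r = 0.7)
  expect_equal(ct$right_ext, 0L)

  # ratio exactly r accepted: 7/10 = 0.7
  ct <- extend_consensus(coverage_table(mk(c(A = 7L, C = 3L)), 20L), tg,
                         o = 2, r = 0.7)
  expect_equal(ct$right_ext, 1L)

  # a tie cannot pass r > 0.5, so extension terminates on ties
  ct <- extend_consensus(coverage_table(mk(c(A = 2L, C = 2L)), 20L), tg,
                         o = 2, r = 0.7)
  expect_equal(ct$right_ext, 0L)
  # with r <= 0.5 the alphabetically first base is chosen (documented)
  ct <- extend_consensus(coverage_table(mk(c(C = 2L, G = 2L)), 20L), tg,
                         o = 2, r = 0.5)
  expect_equal(ct$right_ext, 1L)
  expect_equal(substr(ct$sequence, 21, 21), "C")

  # the first failing position stops the walk even if later positions pass
  cov <- coverage_table(mk(c(A = 3L), c(A = 1L), c(A = 5L)), origin = 20L)
  ct <- extend_consensus(cov, tg, o = 2, r = 0.7)
  expect_equal(ct$right_ext, 1L)

  # left flank walks outward from -1 symmetrically
  cov <- coverage_table(mk(c(G = 4L), c(T = 3L, A = 1L)), origin = -2L)
  ct <- extend_consensus(cov, tg, o = 2, r = 0.7)
  expect_equal(ct$left_ext, 2L)
  expect_equal(substr(ct$sequence, 1, 2), "GT")
})

test_that("dense tiling realizes the analytic extension bounds", {
  set.seed(405)
  ref <- rand_dna(500)
  tg <- target_record("t70", substr(ref, 216, 285))
  rec <- recruit(tile_reads(ref, 33), build_index(tg))
  ct <- assemble_target(tg, rec, m = 15)
  expect_equal(ct$left_ext, 18L)   # 33 - 15
  expect_equal(ct$right_ext, 18L)
  expect_equal(substr(ct$sequence, 19, 88), tg$sequence)
  expect_equal(ct$sequence, substr(ref, 198, 303))  # flanks match the genome

  # no recruited reads -> no contig
  expect_null(assemble_target(tg, recruit(reads_df(rand_dna(36)),
                                          build_index(tg))))
})

test_that("extension never exceeds read length minus the minimum overlap", {
  set.seed(406)
  for (rep in 1:10) {
    fx <- tiling_fixture(ref_len = sample(150:300, 1),
                         target_len = sample(40:80, 1),
                         read_len = sample(c(25, 33, 36, 50), 1))
    m <- 15
    rec <- recruit(fx$reads, build_index(fx$target))
    ct <- assemble_target(fx$target, rec, m = m)
    maxlen <- max(nchar(fx$reads$sequence))
    expect_lte(ct$left_ext, maxlen - m)
    expect_lte(ct$right_ext, maxlen - m)
    # target fidelity: the in-target slice equals the target verbatim
    expect_equal(substr(ct$sequence, ct$target_span[1], ct$target_span[2]),
                 fx$target$sequence)
  }
})

test_that("assembly is deterministic under read-order permutation", {
  set.seed(407)
  fx <- tiling_fixture(ref_len = 250, target_len = 60, read_len = 33)
  reads2 <- fx$reads[sample(nrow(fx$reads)), ]
  idx <- build_index(fx$target)
  c1 <- assemble_target(fx$target, recruit(fx$reads, idx))
  c2 <- assemble_target(fx$target, recruit(reads2, idx))
  expect_equal(c1$sequence, c2$sequence)
  expect_equal(c1$depth, c2$depth)
  expect_equal(c1$left_ext, c2$left_ext)
})

test_that("reverse-complementing the target mirrors the contig", {
  set.seed(408)
  fx <- tiling_fixture(ref_len = 220, target_len = 66, read_len = 33)
  rc <- target_record("t", revcomp(fx$target$sequence))
  c1 <- assemble_target(fx$target, recruit(fx$reads, build_index(fx$target)))
  c2 <- assemble_target(rc, recruit(fx$reads, build_index(rc)))
  expect_equal(c2$sequence, revcomp(c1$sequence))
  expect_equal(c2$left_ext, c1$right_ext)
  expect_equal(c2$right_ext, c1$left_ext)
})

test_that("report-coverage trimming narrows the reported target window", {
  set.seed(409)
  tg <- target_record("t", rand_dna(60))
  # reads cover only positions 10..49 of the target (at depth 2)
  rds <- rep(substr(tg$sequence, 11, 50), 2)
  rec <- recruit_one(rds, tg)
  ct <- assemble_target(tg, rec, m = 15, c = 1)
  expect_equal(ct$target_span, c(start = 1L, end = 40L), ignore_attr = TRUE)
  expect_equal(ct$sequence, substr(tg$sequence, 11, 50))
  expect_equal(ct$left_ext, 0L)  # trimmed side reports no flank
  expect_equal(ct$right_ext, 0L)
  # c above the available depth removes the contig entirely
  expect_null(assemble_target(tg, rec, m = 15, c = 3))
})
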