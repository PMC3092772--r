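test_that("load_targets parses multi-FASTA and enforces target contracts", {
  set.seed(101)
  d <- withr::local_tempdir()
  fa <- file.path(d, "targets.fa")
  s51 <- rand_dna(51); s38 <- rand_dna(38)
  write_fasta_file(c(s51, s38), fa, ids = c("snv1", "probe1"), width = 20)

  tg <- load_targets(fa)
  expect_equal(tg$target_id, c("snv1", "probe1"))
  expect_equal(tg$length, c(51L, 38L))
  expect_equal(tg$sequence, c(s51, s38))  # multi-line FASTA reassembled

  # boundary: length == k is accepted, k - 1 rejected
  write_fasta_file(rand_dna(15), fa, ids = "edge")
  expect_equal(load_targets(fa, k = 15)$length, 15L)
  write_fasta_file(rand_dna(14), fa, ids = "short")
  expect_error(load_targets(fa, k = 15), "shorter than word size")

  # non-ACGT targets rejected; lowercase accepted and uppercased
  write_fasta_file("ACGTNACGTNACGTNN", fa, ids = "hasN")
  expect_error(load_targets(fa), "non-ACGT")
  write_fasta_file(tolower(s51), fa, ids = "lower")
  expect_equal(load_targets(fa)$sequence, s51)

  # duplicate IDs disambiguated with a warning, order preserved
  writeLines(c(">dup", s51, ">dup", s38), fa)
  expect_warning(tg <- load_targets(fa), "duplicate")
  expect_equal(tg$target_id, c("dup", "dup.1"))

  expect_error(load_targets(file.path(d, "absent.fa")), "not found")
  writeLines(character(0), fa)
  expect_error(load_targets(fa), "no targets")
})

test_that("target metadata round-trips through FASTA headers", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "designed.fa")
  set.seed(102)
  ctx <- rand_dna(51)
  tg <- snv_target_pair(ctx, substr(ctx, 26, 26), flip_base(substr(ctx, 26, 26)),
                        id = "rs1")
  tg <- rbind(tg, junction_target(rand_dna(36), rand_dna(14), id = "fus1"))
  write_targets_fasta(tg, fa)
  back <- load_targets(fa)
  expect_equal(back$sequence, tg$sequence)
  expect_equal(back$focal, tg$focal)
  expect_equal(back$allele, tg$allele)
  expect_equal(back$variant_id, tg$variant_id)
  expect_equal(back$junction, tg$junction)
})

test_that("stream_reads concatenates files lazily and sanitizes sequences", {
  set.seed(103)
  d <- withr::local_tempdir()
  fq1 <- file.path(d, "lane1.fq"); fq2 <- file.path(d, "lane2.fq")
  fa <- file.path(d, "reads.fa")
  s1 <- replicate(100, rand_dna(36)); s2 <- replicate(100, rand_dna(36))
  write_fastq_file(s1, fq1); write_fastq_file(s2, fq2)
  fof <- file.path(d, "reads.fof")
  writeLines(c("# comment line", fq1, "", fq2), fof)

  all <- collect_reads(fof)
  expect_equal(nrow(all), 200L)
  expect_equal(all$sequence, c(s1, s2))
  expect_equal(unique(all$source_file), c(fq1, fq2))

  # chunking smaller than the file preserves order and count
  chunked <- collect_reads(stream_reads(fof, chunk_size = 7))
  expect_equal(chunked, all)

  # FASTA input auto-detected
  write_fasta_file(s1[1:5], fa)
  writeLines(fa, fof)
  expect_equal(collect_reads(fof)$sequence, s1[1:5])

  # gzip-compressed input accepted
  gz <- file.path(d, "lane1.fq.gz")
  con <- gzfile(gz, "wt"); writeLines(readLines(fq1), con); close(con)
  writeLines(gz, fof)
  expect_equal(collect_reads(fof)$sequence, s1)

  # non-ACGTN symbols map to N, lowercase uppercased, count conserved
  write_fastq_file(c("acgtRYacgt", "ACGT-ACGT."), file.path(d, "odd.fq"))
  writeLines(file.path(d, "odd.fq"), fof)
  odd <- collect_reads(fof)
  expect_equal(odd$sequence, c("ACGTNNACGT", "ACGTNACGTN"))

  # errors: empty fof, missing listed file
  writeLines(c("", "# nothing"), fof)
  expect_error(collect_reads(fof), "no input read files")
  writeLines(file.path(d, "ghost.fq"), fof)
  expect_error(collect_reads(fof), "ghost")
})

test_that("write_outputs emits the four dialects and round-trips contigs", {
  set.seed(104)
  d <- withr::local_tempdir()
  fx <- tiling_fixture(ref_len = 200, target_len = 60, read_len = 33)
  rec <- recruit(fx$reads, build_index(fx$target))
  ct <- assemble_target(fx$target, rec)
  cfg <- list(k = 15, m = 15, o = 2, r = 0.7, c = 1)
  paths <- write_outputs(list(ct), file.path(d, "run"), config = cfg)

  # FASTA round-trip and header fields
  back <- Biostrings::readDNAStringSet(paths[["contigs"]])
  expect_equal(as.character(back[[1]]), ct$sequence)
  expect_match(names(back), sprintf("target_span=%d-%d", ct$left_ext + 1,
                                    ct$left_ext + 60))
  expect_match(names(back), "k=15")

  # TSVs: header comments, column counts, coverage/pileup agreement
  rp <- readLines(paths[["readpos"]])
  expect_match(rp[1], "^# config")
  expect_match(rp[2], "^#read_id\tsource_file\tcontig_id\tstart\tstrand")
  expect_equal(length(rp) - 2L, ct$n_reads)

  cov <- read.delim(paths[["coverage"]], header = FALSE, comment.char = "#")
  expect_equal(nrow(cov), nchar(ct$sequence))
  expect_equal(cov$V3, ct$depth)

  pile <- read.delim(paths[["pileup"]], header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
  names(pile) <- c("contig_id", "position", "target_rel", "target_base",
                   "consensus_base", "depth", "counts")
  expect_equal(paste(pile$consensus_base, collapse = ""), ct$sequence)
  # flank rows flagged with '-' target base and out-of-target target_rel
  expect_true(all(pile$target_base[pile$target_rel < 0] == "-"))
  expect_true(all(pile$target_base[pile$target_rel >= 60] == "-"))
  in_t <- pile$target_rel >= 0 & pile$target_rel < 60
  expect_equal(paste(pile$target_base[in_t], collapse = ""),
               fx$target$sequence)
  # counts column sums to the depth column at every position
  count_sum <- vapply(pile$counts, function(s) {
    if (s == ".") return(0L)
    sum(as.integer(sub("^[ACGT]:", "", strsplit(s, ",")[[1]])))
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(count_sum, pile$depth)

  # zero contigs: four files written, headers only
  paths0 <- write_outputs(list(), file.path(d, "empty"), config = cfg)
  expect_true(all(file.exists(paths0)))
  expect_equal(length(Biostrings::readDNAStringSet(paths0[["contigs"]])), 0L)
  expect_equal(sum(!startsWith(readLines(paths0[["pileup"]]), "#")), 0L)
})
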