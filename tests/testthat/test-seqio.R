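test_that("FASTQ and FASTA round-trip identically on canonical files", {
  reads <- tibble::tibble(
    id = c("r1", "r2 desc"),
    sequence = c("ACGTACGT", "TTTTNGGG"),
    quality = c("FFFFFFFF", "IIIIIIII"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_identical(read_fastq(fq), reads)
  before <- readLines(fq)
  write_fastq(read_fastq(fq), fq)
  expect_identical(readLines(fq), before)

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reads[, c("id", "sequence")], fa)
  expect_identical(read_fasta(fa), reads[, c("id", "sequence")])

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_identical(nrow(read_fastq(empty)), 0L)
})

test_that("malformed FASTQ is rejected with the offending record named", {
  f <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "+", "FFFF", "@r2", "ACGT"), f)
  expect_error(read_fastq(f), "record 2")
  writeLines(c("@r1", "ACGT", "+", "FFF"), f)
  expect_error(read_fastq(f), "lengths differ")
})

test_that("anchored_locate agrees with an exhaustive all-offset scan", {
  set.seed(401)
  for (i in 1:300) {
    read <- random_seq(sample(30:60, 1))
    if (i %% 3 == 0) {
      anchor <- random_seq(sample(8:12, 1))       # usually absent
    } else {
      off <- sample(0:(nchar(read) - 12), 1)      # planted, maybe mutated
      anchor <- substr(read, off + 1, off + 12)
      k <- sample(0:2, 1)
      if (k > 0) {
        pos <- sample(12, k)
        for (p in pos) substr(anchor, p, p) <- sample(DNA, 1)
      }
    }
    max_mm <- sample(0:2, 1)
    got <- anchored_locate(read, anchor, max_mm)
    want <- brute_locate(read, anchor, max_mm)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$offset, want$offset)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("equal-quality repeated anchors resolve to the smallest offset", {
  anchor <- "ACGTACGTAC"
  read <- paste0("TTTT", anchor, "GGGGGG", anchor, "CCCC")
  hit <- anchored_locate(read, anchor, 0)
  expect_equal(hit$offset, 4)
  expect_equal(hit$mismatches, 0)
  # brute force confirms the tie
  cand <- brute_locate(read, anchor, 0)
  expect_equal(cand$offset, 4)
})

test_that("anchored_locate handles strands, absence and bad anchors", {
  read <- paste0("AAAA", "ACGGATCGTT", "TTTT")
  expect_null(anchored_locate("AAAAAAAAAACCCC", "GGGGGGGG", 0))
  rc <- reverse_complement(read)
  hit <- anchored_locate(rc, "ACGGATCGTT", 0, search_both_strands = TRUE)
  expect_equal(hit$strand, "-")
  expect_equal(hit$offset, 4)
  expect_error(anchored_locate(read, "ACGTXCGT", 1), "A,C,G,T,N")
})

test_that("reverse_complement and hamming behave and invert", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AACGTN"), "NACGTT")
  expect_equal(hamming("AAAA", "AAAT"), 1)
  expect_error(hamming("AA", "AAA"), "equal-length")
  set.seed(402)
  seqs <- vapply(1:20, function(i) random_seq(1000), character(1))
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
  expect_identical(reverse_complement(seqs[1]), revcomp_oracle(seqs[1]))
})

test_that("read pairs merge through containment, overlap and quality", {
  set.seed(403)
  frag <- random_seq(40)
  # full read-through, post-trimming: both mates are the whole fragment
  r1 <- list(sequence = frag, quality = strrep("F", 40))
  r2 <- list(sequence = revcomp_oracle(frag), quality = strrep("F", 40))
  m <- merge_read_pair(r1, r2)
  expect_identical(m$sequence, frag)

  # non-overlapping mates fail
  expect_null(merge_read_pair(list(sequence = random_seq(30)),
                              list(sequence = random_seq(30))))

  # disagreement in a 12-nt overlap resolves to the higher-quality base
  left <- random_seq(28); ovl <- random_seq(12); right <- random_seq(28)
  s1 <- paste0(left, ovl)
  ovl_bad <- ovl
  substr(ovl_bad, 6, 6) <- setdiff(DNA, substr(ovl, 6, 6))[1]
  s2 <- revcomp_oracle(paste0(ovl_bad, right))
  cand <- brute_overlaps(s1, s2)
  expect_equal(sum(cand$mm == min(cand$mm)), 1)   # unique best overlap
  m <- merge_read_pair(
    list(sequence = s1, quality = strrep(rawToChar(as.raw(40 + 33)), 40)),
    list(sequence = s2, quality = strrep(rawToChar(as.raw(10 + 33)), 40)))
  expect_identical(m$sequence, paste0(left, ovl, right))
})

test_that("merging is symmetric up to reverse complement", {
  set.seed(404)
  for (i in 1:10) {
    frag <- random_seq(60)
    s1 <- substr(frag, 1, 45)
    s2 <- revcomp_oracle(substr(frag, 16, 60))
    a <- merge_read_pair(list(sequence = s1), list(sequence = s2))
    b <- merge_read_pair(list(sequence = s2), list(sequence = s1))
    expect_identical(a$sequence, frag)
    expect_identical(reverse_complement(b$sequence), a$sequence)
  }
})
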