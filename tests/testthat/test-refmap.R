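# Reference packing, the probed group index, both-strand alignment and
# alignment-record coding.

test_that("reference packing deletes N and restores it on unpack", {
  ref <- "ACGTNNNACGTACGTNGGG"
  pk <- pack_reference(ref)
  expect_identical(pk$length, 15)
  expect_identical(unpack_reference(pk), ref)
  # pure-ACGT reference packs 4 bases per byte
  pk2 <- pack_reference(strrep("ACGT", 25))
  expect_identical(length(pk2$data), 25L)
})

test_that("index construction discards almost nothing at low occupancy", {
  f <- fix_sim()
  prof <- sim_profile(genome_length = 1e5)
  g <- sim_genome(prof, seed = 182)
  idx <- build_ref_index(g, table_bits = 18)
  expect_identical(idx$n_groups, floor(1e5 / 32))
  expect_lt(idx$discard_fraction, 0.01)
})

test_that("an empty or short reference yields an empty index and no matches", {
  idx <- build_ref_index("ACGTACGT", 12)
  expect_identical(idx$n_groups, 0)
  a <- align_read(idx, strrep("ACGT", 20))
  expect_false(a$matched)
})

test_that("alignment finds verbatim, reverse-complement and rejects noise", {
  f <- fix_sim()
  g <- f$genome
  idx <- build_ref_index(g, 18)
  L <- 100L
  # verbatim copy: matched forward with all mismatch slots at L+1
  r <- substr(g, 501, 500 + L)
  a <- align_read(idx, r)
  expect_true(a$matched)
  expect_identical(a$dir, 0L)
  expect_identical(a$ptr, 500)
  expect_identical(c(a$m1, a$m2, a$m3, a$m4), rep(L + 1L, 4))
  # reverse complement with one substitution
  w <- substr(g, 2001, 2000 + L)
  pos <- 37L
  rcpos <- L - pos + 1L  # position in the reverse-complemented read
  rr <- revcomp(w)
  old <- substr(rr, rcpos, rcpos)
  substr(rr, rcpos, rcpos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  a <- align_read(idx, rr)
  expect_true(a$matched)
  expect_identical(a$dir, 1L)
  expect_identical(a$ptr, 2000)
  expect_identical(a$m1, rcpos)
  expect_identical(c(a$m2, a$m3, a$m4), rep(L + 1L, 3))
  # five substitutions inside the first half: every window has m4 < L/2
  r5 <- substr(g, 3001, 3000 + L)
  for (p in c(5L, 15L, 25L, 35L, 45L))
    substr(r5, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r5, p, p))[1]
  a <- align_read(idx, r5)
  expect_false(a$matched)
  # reads shorter than one group are never matched
  expect_false(align_read(idx, substr(g, 1, 31))$matched)
})

test_that("candidate ranking maximises the fourth mismatch position", {
  # brute-force oracle over all reference windows on a small genome
  prof <- sim_profile(genome_length = 3000)
  g <- sim_genome(prof, seed = 192)
  idx <- build_ref_index(g, 14)
  set.seed(192)
  for (i in 1:10) {
    # start on a group boundary so the seed window is indexed; mutations sit
    # beyond the first group
    s <- 32L * sample.int((nchar(g) - 80) %/% 32L, 1) + 1L
    r <- substr(g, s, s + 63)
    nmut <- sample(0:3, 1)
    for (p in sample(33:64, nmut))
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    a <- align_read(idx, r)
    expect_true(a$matched)
    # oracle: the best achievable m4 over every forward window
    m4s <- vapply(seq_len(nchar(g) - 63), function(w) {
      mm <- which(strsplit(substr(g, w, w + 63), "")[[1]] != strsplit(r, "")[[1]])
      if (length(mm) >= 4) mm[4] else 65L
    }, integer(1))
    expect_identical(a$m4, as.integer(max(m4s)))
  }
})

test_that("alignment records serialize as specified and round-trip", {
  aln <- data.frame(matched = c(FALSE, TRUE, FALSE),
                    dir = c(0L, 1L, 0L), ptr = c(0, 123456789, 0),
                    m1 = c(0L, 7L, 0L), m2 = c(0L, 13L, 0L),
                    m3 = c(0L, 101L, 0L), m4 = c(0L, 101L, 0L))
  raw_fast <- code_alignments(aln, slow = FALSE)
  # one 0 byte per unmatched read, 9 bytes for the matched one
  expect_identical(length(raw_fast), 2L + 9L)
  expect_identical(as.integer(raw_fast[1]), 0L)
  dec <- decode_alignments(raw_fast, 3)
  expect_identical(dec$matched, aln$matched)
  expect_identical(dec$ptr[2], aln$ptr[2])
  expect_identical(dec$m1[2], 7L)

  # all-unmatched file of n reads is exactly n bytes in fast mode
  n <- 57L
  aln0 <- data.frame(matched = rep(FALSE, n), dir = 0L, ptr = 0,
                     m1 = 0L, m2 = 0L, m3 = 0L, m4 = 0L)
  expect_identical(length(code_alignments(aln0, FALSE)), n)
})

test_that("context-modelled alignment coding beats raw bytes on sorted data", {
  f <- fix_sim()
  idx <- build_ref_index(f$genome, 18)
  aln <- align_reads(idx, f$sim$sam$records$seq)  # position-sorted reads
  fast <- code_alignments(aln, FALSE)
  slow <- code_alignments(aln, TRUE)
  expect_lt(length(slow), 0.7 * length(fast))
  dec <- decode_alignments(slow, nrow(aln), TRUE)
  expect_identical(dec$matched, aln$matched)
  expect_identical(dec$ptr[dec$matched], aln$ptr[aln$matched])
  expect_identical(dec$m4[dec$matched], aln$m4[aln$matched])
})

test_that("alignment record fuzz round-trips in both coders", {
  set.seed(202)
  for (rep in 1:6) {
    n <- sample(c(1, 20, 200), 1)
    matched <- runif(n) < 0.7
    L <- 100L
    m <- t(vapply(seq_len(n), function(i) {
      k <- sample(0:4, 1)
      sort(c(sample(1:L, k), rep(L + 1L, 4 - k)))
    }, integer(4)))
    aln <- data.frame(matched = matched, dir = sample(0:1, n, TRUE),
                      ptr = floor(runif(n, 0, 2^27)),
                      m1 = as.integer(m[, 1]), m2 = as.integer(m[, 2]),
                      m3 = as.integer(m[, 3]), m4 = as.integer(m[, 4]))
    aln[!matched, c("dir", "m1", "m2", "m3", "m4")] <- 0L
    aln$ptr[!matched] <- 0
    for (slow in c(FALSE, TRUE)) {
      dec <- decode_alignments(code_alignments(aln, slow), n, slow)
      expect_identical(dec$matched, aln$matched)
      expect_identical(dec$ptr[matched], aln$ptr[matched])
      expect_identical(dec$m1[matched], aln$m1[matched])
      expect_identical(dec$m4[matched], aln$m4[matched])
    }
  }
})

test_that("matched bases are deleted from the residual sequence stream", {
  f <- fix_sim()
  idx <- build_ref_index(f$genome, 18)
  reads <- f$sim$fastq$seq
  aln <- align_reads(idx, reads)
  res <- .c_refmap_residual(reads, aln, idx)
  L <- nchar(reads)
  expected <- sum(L[!aln$matched]) +
    sum(pmax(L[aln$matched] - aln$m4[aln$matched] + 1L, 0L))
  expect_identical(nchar(res$residual), expected)
  rec <- .c_refmap_reconstruct(aln, res$residual, res$mis, idx, L)
  expect_identical(chartr("N", "A", rec), chartr("N", "A", reads))
})

test_that("reference-based coding reduces bits per base end to end", {
  fq <- fix_fastq_path()
  fa <- fix_ref_path()
  td <- tempdir()
  noref <- compress_fastq(fq, file.path(td, "nr.fqz"), mode = "fastqz",
                          level = "slow")
  wref <- compress_fastq(fq, file.path(td, "wr.fqz"), mode = "fastqz",
                         level = "slow", ref = fa, table_bits = 18)
  expect_lt(wref$bits_per_base, noref$bits_per_base)
  # and the reference-coded container still round-trips byte-exactly
  out <- file.path(td, "wr.out")
  decompress(file.path(td, "wr.fqz"), out, ref = fa)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(fq, "raw", file.size(fq)))
  # decoding without the reference is refused
  expect_error(decompress(file.path(td, "wr.fqz"), out), "reference")
})

test_that("probed insertion discards more as occupancy grows", {
  d1 <- index_discard_sim(16, 0.2, seed = 1)
  d2 <- index_discard_sim(16, 0.9, seed = 1)
  expect_lt(d1, d2)
  expect_lt(d1, 0.01)
})
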