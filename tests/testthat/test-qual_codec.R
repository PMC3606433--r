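# Quality canonicalisation, context keys, adaptive coding, byte-code packing
# and the two lossy modes.

test_that("canonical symbols implement the 0/62/63 conventions", {
  expect_identical(canonicalize_quals("IIII", "ACGT"), rep(40L, 4))
  # terminal run of score 2 collapses to the sentinel 63
  expect_identical(canonicalize_quals("GG####", "ACGTAC"), c(38L, 38L, 63L))
  # N forces symbol 0
  expect_identical(canonicalize_quals("I!I", "ANA"), c(40L, 0L, 40L))
  # a single terminal '#' is NOT collapsed
  expect_identical(canonicalize_quals("II#", "ACG"), c(40L, 40L, 2L))
  # scores above 62 clamp
  expect_identical(canonicalize_quals("~", "A"), 62L)
  expect_error(canonicalize_quals("II", "A"), "length")
})

test_that("decanonicalisation inverts the sentinel and N conventions", {
  for (case in list(c("GG####", "ACGTAC"), c("I!I", "ANA"), c("#", "A"),
                    c("IIII", "ACGT"), c("##", "AC"))) {
    sym <- canonicalize_quals(case[1], case[2])
    out <- decanonicalize_quals(sym, nchar(case[1]))
    # N positions come back as '!' (their symbol is 0 by construction)
    expected <- case[1]
    expect_identical(out, expected)
  }
})

test_that("context keys are pure functions of history with the stated layout", {
  expect_identical(qual_context(integer(), 1), 0)
  expect_identical(qual_context(integer(), 3), 0)
  # level 2: (q1, q2 %/% 4) -> 38*16 + 40%/%4
  expect_identical(qual_context(c(40, 38), 2), 38 * 16 + 10)
  # level 1 is just the previous score
  expect_identical(qual_context(c(17, 33), 1), 33)
  # purity
  h <- c(30, 35, 12, 38)
  expect_identical(qual_context(h, 3), qual_context(h, 3))
})

test_that("quality streams round-trip losslessly at all levels", {
  f <- fix_sim()
  quals <- f$sim$fastq$qual[1:300]
  seqs <- f$sim$fastq$seq[1:300]
  lens <- nchar(quals)
  for (lev in 1:3) {
    e <- encode_fqz_quals(quals, seqs, lev)
    dec <- decode_fqz_quals(e$data, lens, lev)
    # decoding restores everything except N positions, which carry '!' by the
    # quality-0 convention (the container reinstates exceptions)
    canon <- vapply(seq_along(quals), function(i)
      decanonicalize_quals(canonicalize_quals(quals[i], seqs[i]), lens[i]),
      character(1))
    expect_identical(dec, canon)
  }
})

test_that("quality fuzz round-trips: '#' tails, N bases, length-1 reads", {
  set.seed(81)
  seqs <- rand_reads(120, 1:40, seed = 81, n_prob = 0.05)
  quals <- vapply(seq_along(seqs), function(i)
    rand_qual_for(seqs[i], tail2 = i %% 3 == 0), character(1))
  for (lev in c(1, 3)) {
    e <- encode_fqz_quals(quals, seqs, lev)
    dec <- decode_fqz_quals(e$data, nchar(quals), lev)
    canon <- vapply(seq_along(quals), function(i)
      decanonicalize_quals(canonicalize_quals(quals[i], seqs[i]), nchar(quals[i])),
      character(1))
    expect_identical(dec, canon)
  }
})

test_that("richer contexts do not hurt on synthetic qualities", {
  # level 3 has half a million contexts, so it needs enough data to pay off
  # its startup cost; a few hundred thousand scores suffice
  prof <- sim_profile(genome_length = 1e5, coverage = 8)
  g <- sim_genome(prof, seed = 11)
  sim <- sim_reads(g, prof, seed = 11)
  b1 <- bytes(encode_fqz_quals(sim$fastq$qual, sim$fastq$seq, 1)$data)
  b3 <- bytes(encode_fqz_quals(sim$fastq$qual, sim$fastq$seq, 3)$data)
  expect_lte(b3, b1 * 1.02)
})

test_that("lossy 'within' stays within Q and keeps low values exact", {
  # the printed example: value 37 with Q = 2 maps into {35..39}
  seqs <- rep(paste(rep("A", 50), collapse = ""), 40)
  quals <- vapply(1:40, function(i)
    intToUtf8(33 + sample(2:45, 50, replace = TRUE)), character(1))
  set.seed(91)
  for (Q in 1:8) {
    e <- encode_fqz_quals(quals, seqs, 2, Q = Q, lossy = "within")
    dec <- decode_fqz_quals(e$data, nchar(quals), 2)
    vo <- lapply(strsplit(quals, ""), function(x) utf8ToInt(paste(x, collapse = "")) - 33)
    vd <- lapply(strsplit(dec, ""), function(x) utf8ToInt(paste(x, collapse = "")) - 33)
    for (i in seq_along(vo)) {
      hi <- vo[[i]] > Q
      expect_true(all(abs(vo[[i]][hi] - pmin(vd[[i]][hi], 62)) <= Q))
      expect_identical(vo[[i]][!hi], vd[[i]][!hi])
      if (Q == 1) expect_identical(vo[[i]], vd[[i]])
    }
    if (Q == 2) {
      # every stored replacement of an original 37 lies in 35..39
      for (i in seq_along(vo)) {
        at37 <- vo[[i]] == 37
        expect_true(all(vd[[i]][at37] >= 35 & vd[[i]][at37] <= 39))
      }
    }
  }
})

test_that("lossy rounding maps to multiples of Q with fixed points", {
  expect_identical(lossy_round(36, 4), 36L)
  expect_identical(lossy_round(c(0, 1), 4), c(0L, 1L))  # values <= 1 untouched
  v <- 2:62
  r <- lossy_round(v, 4)
  # multiples of Q, except at the symbol-range boundary where values clamp
  expect_true(all(r %% 4 == 0 | r == 1 | r == 62))
  expect_true(all(abs(r - v) <= 2))
})

test_that("compressed size shrinks as Q grows", {
  f <- fix_sim()
  quals <- f$sim$fastq$qual
  seqs <- f$sim$fastq$seq
  sz <- vapply(c(1, 2, 4), function(Q)
    bytes(encode_fqz_quals(quals, seqs, 2, Q = Q, lossy = "within")$data),
    numeric(1))
  expect_true(all(diff(sz) <= 0))
})

test_that("byte-code packing uses run, triple, pair, single and end marker", {
  # a run of 38s packs to one code
  expect_identical(length(fastqz_pack_quals(rep(38, 10))), 1L)
  # a triple in 35..38 packs to one code
  expect_identical(length(fastqz_pack_quals(c(36, 37, 38))), 1L)
  # run then end-of-2s marker, nothing after
  codes <- fastqz_pack_quals(c(rep(38, 12), 2, 2, 2))
  expect_identical(length(codes), 2L)
  expect_identical(as.integer(codes[2]), 0L)
  # pair in 31..38
  expect_identical(length(fastqz_pack_quals(c(31, 34))), 1L)
  # singles for everything else
  expect_identical(length(fastqz_pack_quals(c(10, 20))), 2L)
})

test_that("byte-code packing inverts exactly for fuzzed symbol vectors", {
  set.seed(101)
  for (i in 1:80) {
    L <- sample(1:80, 1)
    sym <- sample(0:62, L, replace = TRUE)
    if (i %% 2 == 0 && L > 4) sym[(L - sample(2:4, 1)):L] <- 2L
    if (i %% 5 == 0) sym[] <- 38L
    codes <- fastqz_pack_quals(sym)
    expect_identical(fastqz_unpack_quals(codes, L), as.integer(sym))
  }
})
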