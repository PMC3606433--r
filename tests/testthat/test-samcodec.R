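# CIGAR anchoring, per-position coding (samcomp1) and reference-diff coding
# (samcomp2), with the SAM container round trips.

sam_paths <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- fix_sim()
      td <- tempdir()
      sam <- file.path(td, "fixture.sam")
      write_sam(f$sim$sam, sam)
      cache <<- list(sam = sam, fa = fix_ref_path(), sim = f$sim, genome = f$genome)
    }
    cache
  }
})

test_that("CIGAR walking anchors bases to reference coordinates", {
  a <- anchor_bases(10, "4M", "ACGT")
  expect_identical(a$ref_coord, c(9, 10, 11, 12))
  expect_true(all(a$channel == "MATCHED"))

  a <- anchor_bases(10, "2M1I2M", "ACGTA")
  expect_identical(a$ref_coord, c(9, 10, NA, 11, 12))
  expect_identical(a$channel[3], "INSERTION")

  a <- anchor_bases(10, "3S5M", "ACGTACGT")
  expect_identical(a$channel[1:3], rep("SOFTCLIP", 3))
  expect_identical(a$ref_coord[4:8], c(9, 10, 11, 12, 13))

  # deletions advance the reference without consuming read bases
  a <- anchor_bases(1, "2M2D2M", "ACGT")
  expect_identical(a$ref_coord, c(0, 1, 4, 5))

  expect_error(anchor_bases(1, "4M", "ACGTACGT"), "match")
  expect_error(anchor_bases(1, "xM", "ACGT"), "CIGAR")
})

test_that("SAM containers round-trip all retained columns", {
  p <- sam_paths()
  td <- tempdir()
  cz <- file.path(td, "rt.fqz")
  out <- file.path(td, "rt.sam")
  for (mode in c("samcomp1", "samcomp2")) {
    for (use_ref in c(FALSE, TRUE)) {
      rf <- if (use_ref) p$fa else NULL
      suppressWarnings(compress_sam(p$sam, cz, mode = mode, ref = rf))
      decompress(cz, out, ref = rf)
      expect_identical(readLines(out), readLines(p$sam),
                       info = paste(mode, use_ref))
    }
  }
})

test_that("records with CIGAR features and missing qualities round-trip", {
  td <- tempdir()
  sam <- file.path(td, "feat.sam")
  lines <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:600",
    paste("r1", 0, "chr1", 5, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r2", 0, "chr1", 5, 60, "3S4M2I1M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("r3", 16, "chr1", 8, 37, "2M3D6M2H", "*", 0, 0,
          "ACGTACGT", "*", sep = "\t"),
    paste("r4", 0, "chr1", 100, 60, "5M1N5M", "*", 0, 0,
          "ACGTANCGTA", "IIIII!IIII", sep = "\t"),
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0,
          "NNACGTACGT", "!!IIIIIIII", sep = "\t"))
  writeLines(lines, sam)
  ref <- c(chr1 = paste(rep("ACGT", 150), collapse = ""))
  fa <- file.path(td, "feat.fa")
  write_fasta(ref, fa)
  cz <- file.path(td, "feat.fqz"); out <- file.path(td, "feat.out")
  for (mode in c("samcomp1", "samcomp2")) {
    compress_sam(sam, cz, mode = mode, ref = fa)
    decompress(cz, out, ref = fa)
    expect_identical(readLines(out), lines, info = mode)
  }
})

test_that("samcomp1 rejects unsorted input; samcomp2 accepts it", {
  p <- sam_paths()
  td <- tempdir()
  sam2 <- file.path(td, "shuffled.sam")
  s <- read_sam(p$sam)
  set.seed(212)
  s$records <- s$records[sample(nrow(s$records)), ]
  write_sam(s, sam2)
  cz <- file.path(td, "u.fqz")
  expect_error(compress_sam(sam2, cz, mode = "samcomp1"), "sorted")
  expect_silent(compress_sam(sam2, cz, mode = "samcomp2", ref = p$fa))
  out <- file.path(td, "u.sam")
  decompress(cz, out, ref = p$fa)
  expect_identical(readLines(out), readLines(sam2))
})

test_that("samcomp2 warns without a reference", {
  p <- sam_paths()
  expect_warning(compress_sam(p$sam, file.path(tempdir(), "w.fqz"),
                              mode = "samcomp2"), "reference")
})

test_that("per-position coding improves with coverage depth", {
  prof <- sim_profile(genome_length = 2e4, substitution_rate = 0.003)
  g <- sim_genome(prof, seed = 222)
  bpb <- vapply(c(1, 5, 30), function(cov) {
    prof$coverage <- cov
    sim <- sim_reads(g, prof, seed = 222)
    r <- sim$sam$records
    enc <- .c_samcomp_encode(r$flag, r$pos, match(r$rname, unique(r$rname)) - 1L,
                             r$mapq, r$cigar, r$seq, 1L, NA_character_)
    length(enc$bases) * 8 / sum(nchar(r$seq))
  }, numeric(1))
  expect_true(all(diff(bpb) < 0.05))  # non-increasing within sampling noise
  expect_lt(bpb[3], bpb[1])
})

test_that("no-reference coding costs about 2 extra bits per consensus base", {
  prof <- sim_profile(genome_length = 5e4, coverage = 30,
                      substitution_rate = 0, n_rate = 0,
                      terminal_run2_probability = 0)
  g <- sim_genome(prof, seed = 232)
  r <- sim_reads(g, prof, seed = 232)$sam$records
  rn <- match(r$rname, unique(r$rname)) - 1L
  with_ref <- .c_samcomp_encode(r$flag, r$pos, rn, r$mapq, r$cigar, r$seq, 1L, g)
  no_ref <- .c_samcomp_encode(r$flag, r$pos, rn, r$mapq, r$cigar, r$seq, 1L,
                              NA_character_)
  extra <- (length(no_ref$bases) - length(with_ref$bases)) * 8 / no_ref$n_covered
  expect_lte(extra, 2.2)
  # equivalently: no-ref total is at most ref total + 2.2 bits per covered base
  expect_lte(length(no_ref$bases) * 8,
             length(with_ref$bases) * 8 + 2.2 * no_ref$n_covered)
})

test_that("a slightly diverged reference codes nearly as well as the truth", {
  prof <- sim_profile(genome_length = 5e4, coverage = 30)
  g <- sim_genome(prof, seed = 242)
  # mutate 1% of reference positions
  set.seed(242)
  gm <- strsplit(g, "")[[1]]
  mut <- sample(length(gm), round(0.01 * length(gm)))
  gm[mut] <- vapply(gm[mut], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  gm <- paste(gm, collapse = "")
  r <- sim_reads(g, prof, seed = 242)$sam$records
  rn <- match(r$rname, unique(r$rname)) - 1L
  truth <- length(.c_samcomp_encode(r$flag, r$pos, rn, r$mapq, r$cigar, r$seq, 1L, g)$bases)
  diverged <- length(.c_samcomp_encode(r$flag, r$pos, rn, r$mapq, r$cigar, r$seq, 1L, gm)$bases)
  expect_lt(diverged, truth * 1.10)
})

test_that("name order shrinks the identifier stream under samcomp2", {
  p <- sam_paths()
  td <- tempdir()
  s <- read_sam(p$sam)
  byname <- s
  byname$records <- s$records[order(s$records$qname), ]
  name_sam <- file.path(td, "byname.sam")
  write_sam(byname, name_sam)
  bd_name <- compress_sam(name_sam, file.path(td, "n.fqz"), mode = "samcomp2",
                          ref = p$fa)
  bd_pos <- compress_sam(p$sam, file.path(td, "p.fqz"), mode = "samcomp2",
                         ref = p$fa)
  expect_lt(bd_name$sizes[["QNAM"]], bd_pos$sizes[["QNAM"]])
})
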