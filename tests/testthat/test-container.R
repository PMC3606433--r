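# Container format, FASTQ round trips across codec families, stream
# accounting and the command-line interface.

test_that("every codec family round-trips the FASTQ byte-exactly", {
  fq <- fix_fastq_path()
  orig <- readBin(fq, "raw", file.size(fq))
  td <- tempdir()
  cz <- file.path(td, "c.fqz"); out <- file.path(td, "c.out")
  for (cfg in list(c("store", "fast"), c("fqz", "fast"), c("fqz", "slow"),
                   c("fastqz", "fast"), c("fastqz", "slow"))) {
    compress_fastq(fq, cz, mode = cfg[1], level = cfg[2])
    decompress(cz, out)
    expect_identical(readBin(out, "raw", file.size(out)), orig,
                     info = paste(cfg, collapse = "/"))
  }
})

test_that("medium level (order-14, dual model) round-trips end to end", {
  fq <- fix_fastq_path()
  td <- tempdir()
  cz <- file.path(td, "med.fqz"); out <- file.path(td, "med.out")
  compress_fastq(fq, cz, mode = "fqz", level = "medium")
  decompress(cz, out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(fq, "raw", file.size(fq)))
})

test_that("empty FASTQ files make valid zero-record containers", {
  td <- tempdir()
  ef <- file.path(td, "empty.fastq")
  writeBin(raw(0), ef)
  cz <- file.path(td, "empty.fqz"); out <- file.path(td, "empty.out")
  for (mode in c("store", "fqz", "fastqz")) {
    bd <- compress_fastq(ef, cz, mode = mode, level = "fast")
    expect_identical(bd$n_records, 0L)
    decompress(cz, out)
    expect_identical(file.size(out), 0)
  }
})

test_that("the printed two-record example round-trips byte-exactly", {
  td <- tempdir()
  fq <- file.path(td, "two.fastq")
  writeLines(c(
    "@SRR062634.2724179 HWI-EAS110_103327062:6:13:11133:13696/1",
    "TGGAATCAGATGGAATCATCGAATGGACTGGAATGGAATCATTGAATGGACTCGAAAGG",
    "+",
    "GGGFGGFDGGGGGGFGFGGGGGGGGGGGGGGEFGGGGFGEDGGGFGGGFEDFGCDFDG?",
    "@SRR062634.2724180 HWI-EAS110_103327062:6:13:11133:11572/1",
    "ATATAGTCCATTGTACTCCCTTGCTTAAATCTGGATCCCTGCAAATAAAAACATCTTCC",
    "+",
    "GGGGGGGGFGGGGEGGFGGGEGGFDGEAEGGEEEEBEEEEEEEEEEEEEEEEEEECCCC"), fq)
  orig <- readBin(fq, "raw", file.size(fq))
  cz <- file.path(td, "two.fqz"); out <- file.path(td, "two.out")
  for (mode in c("fqz", "fastqz")) {
    compress_fastq(fq, cz, mode = mode, level = "fast")
    decompress(cz, out)
    expect_identical(readBin(out, "raw", file.size(out)), orig)
  }
})

test_that("'+'-line dialects and missing final newline are preserved", {
  td <- tempdir()
  fq <- file.path(td, "plus.fastq")
  txt <- paste(c("@r1 one", "ACGT", "+r1 one", "IIII",
                 "@r2 two", "GGCC", "+", "IIHH"), collapse = "\n")
  writeBin(charToRaw(txt), fq)  # no trailing newline
  orig <- readBin(fq, "raw", file.size(fq))
  cz <- file.path(td, "plus.fqz"); out <- file.path(td, "plus.out")
  for (mode in c("fqz", "fastqz")) {
    compress_fastq(fq, cz, mode = mode, level = "fast")
    decompress(cz, out)
    expect_identical(readBin(out, "raw", file.size(out)), orig)
  }
})

test_that("malformed FASTQ is rejected with a record index", {
  td <- tempdir()
  bad <- file.path(td, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)       # length mismatch
  expect_error(read_fastq(bad), "record 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2"), bad)
  expect_error(read_fastq(bad), "multiple of 4")
  writeLines(c("@r1", "ACXT", "+", "IIII"), bad)
  expect_error(read_fastq(bad), "ACGTN")
})

test_that("store-mode accounting reports the 8-bit baselines exactly", {
  fq <- fix_fastq_path()
  cz <- file.path(tempdir(), "st.fqz")
  compress_fastq(fq, cz, mode = "store")
  st <- container_stats(cz)
  expect_identical(st$bits_per_base, 8)
  expect_identical(st$bits_per_quality, 8)
})

test_that("block sizes plus container overhead account for the file exactly", {
  fq <- fix_fastq_path()
  cz <- file.path(tempdir(), "acc.fqz")
  compress_fastq(fq, cz, mode = "fqz", level = "fast")
  st <- container_stats(cz)
  # header: 4 magic + 3 bytes; per block: 4 tag + 8 length + 4 crc
  overhead <- 7 + length(st$sizes) * 16
  expect_identical(sum(st$sizes) + overhead, st$file_size)
})

test_that("a flipped payload bit is reported as corruption, not garbage", {
  fq <- fix_fastq_path()
  td <- tempdir()
  cz <- file.path(td, "ok.fqz")
  compress_fastq(fq, cz, mode = "fqz", level = "fast")
  r <- readBin(cz, "raw", file.size(cz))
  set.seed(252)
  for (i in 1:5) {
    rr <- r
    at <- sample(30:length(r), 1)
    rr[at] <- xor(rr[at], as.raw(2^sample(0:7, 1)))
    bad <- file.path(td, "bad.fqz")
    writeBin(rr, bad)
    expect_error(decompress(bad, file.path(td, "bad.out")),
                 "checksum|corrupt|truncated")
  }
})

test_that("identical inputs and options produce byte-identical containers", {
  fq <- fix_fastq_path()
  td <- tempdir()
  a <- file.path(td, "d1.fqz"); b <- file.path(td, "d2.fqz")
  compress_fastq(fq, a, mode = "fqz", level = "fast")
  compress_fastq(fq, b, mode = "fqz", level = "fast")
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
})

test_that("lossy containers differ from the input only in bounded quality", {
  fq <- fix_fastq_path()
  orig <- read_fastq(fq)
  td <- tempdir()
  cz <- file.path(td, "q2.fqz"); out <- file.path(td, "q2.out")
  compress_fastq(fq, cz, mode = "fqz", level = "fast", Q = 2)
  decompress(cz, out)
  dec <- read_fastq(out)
  expect_identical(dec$id, orig$id)
  expect_identical(dec$seq, orig$seq)
  qo <- utf8ToInt(paste(orig$qual, collapse = "")) - 33L
  qd <- utf8ToInt(paste(dec$qual, collapse = "")) - 33L
  sel <- qo > 2L
  expect_true(all(abs(qo[sel] - qd[sel]) <= 2L))
  expect_identical(qo[!sel], qd[!sel])
})

test_that("variable-length reads are supported end to end", {
  prof <- sim_profile(genome_length = 1e4, coverage = 4,
                      read_length = c(40L, 120L))
  g <- sim_genome(prof, seed = 262)
  sim <- sim_reads(g, prof, seed = 262)
  td <- tempdir()
  fq <- file.path(td, "var.fastq")
  write_fastq(sim$fastq, fq)
  cz <- file.path(td, "var.fqz"); out <- file.path(td, "var.out")
  for (mode in c("fqz", "fastqz")) {
    compress_fastq(fq, cz, mode = mode, level = "fast")
    decompress(cz, out)
    expect_identical(readBin(out, "raw", file.size(out)),
                     readBin(fq, "raw", file.size(fq)))
  }
})

test_that("the CLI drives compress, decompress, stats and simulate", {
  td <- file.path(tempdir(), "clitest")
  dir.create(td, showWarnings = FALSE)
  pre <- file.path(td, "sim")
  expect_identical(suppressMessages(fqzlite_cli(
    c("simulate", pre, "--genome-length", "5000", "--coverage", "3",
      "--seed", "5"))), 0L)
  expect_true(file.exists(paste0(pre, ".fastq")))
  cz <- file.path(td, "cli.fqz")
  out <- capture.output(st <- fqzlite_cli(c("compress", paste0(pre, ".fastq"),
                                            cz, "--mode", "fqz", "--level", "fast")))
  expect_identical(st, 0L)
  expect_true(any(grepl("bits/base", out)))
  dec <- file.path(td, "cli.out")
  expect_identical(fqzlite_cli(c("decompress", cz, dec)), 0L)
  expect_identical(readBin(dec, "raw", file.size(dec)),
                   readBin(paste0(pre, ".fastq"), "raw",
                           file.size(paste0(pre, ".fastq"))))
  out <- capture.output(st <- fqzlite_cli(c("stats", cz)))
  expect_identical(st, 0L)
  expect_identical(suppressMessages(fqzlite_cli(c("nonsense"))), 1L)
})
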