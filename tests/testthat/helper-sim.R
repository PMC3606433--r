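# Shared synthetic fixtures, built once per test run.
.fix <- new.env()

fix_sim <- function() {
  if (is.null(.fix$sim)) {
    prof <- sim_profile(genome_length = 3e4, coverage = 6)
    .fix$genome <- sim_genome(prof, seed = 101)
    .fix$sim <- sim_reads(.fix$genome, prof, seed = 101)
    .fix$profile <- prof
  }
  list(genome = .fix$genome, sim = .fix$sim, profile = .fix$profile)
}

fix_fastq_path <- function() {
  if (is.null(.fix$fq_path)) {
    f <- fix_sim()
    .fix$fq_path <- file.path(tempdir(), "fixture.fastq")
    write_fastq(f$sim$fastq, .fix$fq_path)
  }
  .fix$fq_path
}

fix_ref_path <- function() {
  if (is.null(.fix$fa_path)) {
    f <- fix_sim()
    .fix$fa_path <- file.path(tempdir(), "fixture.fa")
    write_fasta(c(sim1 = f$genome), .fix$fa_path)
  }
  .fix$fa_path
}

# random printable identifier-ish strings (ASCII 33..126 plus space)
rand_ids <- function(n, maxlen = 60, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    l <- sample.int(maxlen, 1)
    intToUtf8(sample(c(32:126), l, replace = TRUE))
  }, character(1))
}

rand_reads <- function(n, lens, seed = 1, n_prob = 0) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    l <- if (length(lens) > 1) sample(lens, 1) else lens
    ab <- c("A", "C", "G", "T")
    if (n_prob > 0) {
      paste(sample(c(ab, "N"), l, replace = TRUE,
                   prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
    } else paste(sample(ab, l, replace = TRUE), collapse = "")
  }, character(1))
}

# a quality string matched to a read: N positions get '!', optionally a '#' tail
rand_qual_for <- function(seq, tail2 = FALSE) {
  l <- nchar(seq)
  q <- sample(2:40, l, replace = TRUE)
  if (tail2 && l >= 3) q[(l - sample(2:min(l - 1, 6), 1) + 1):l] <- 2L
  q[strsplit(seq, "")[[1]] == "N"] <- 0L
  intToUtf8(q + 33L)
}

# code length in bytes of a raw stream
bytes <- function(x) length(x)
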