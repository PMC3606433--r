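#' Simulation profile for synthetic sequencing data
#'
#' Defaults emulate a deep Illumina run on a small genome: qualities start
#' near the common maximum of 38, decline along the read with per-read level
#' shifts (good and bad sequences), a fraction of reads end in a run of
#' score 2 (`'#'`), `N` bases always carry quality 0, and identifiers follow
#' an instrument_run:lane:tile:x:y template with an incrementing record
#' counter.
#'
#' @param genome_length genome size in bases.
#' @param markov_order order of the Markov chain generating the genome.
#' @param coverage mean sequencing depth.
#' @param read_length read length (a single value, or a range `c(min, max)`
#'   for variable-length reads).
#' @param substitution_rate per-base substitution error probability.
#' @param n_rate per-base probability of an `N` call (quality 0).
#' @param quality_start_level modal starting quality score.
#' @param quality_decline_rate mean quality decline per base along the read.
#' @param quality_shift_sd standard deviation of the per-read quality shift.
#' @param quality_noise_sd per-base quality noise standard deviation.
#' @param terminal_run2_probability probability that a read ends in a run of
#'   score 2.
#' @param name_prefix,instrument,run,lane identifier template fields.
#' @param repeat_fraction fraction of the genome covered by duplicated
#'   segments (exercises match models).
#' @param repeat_length length of each duplicated segment.
#' @return a profile list.
#' @export
sim_profile <- function(genome_length = 1e5, markov_order = 0L, coverage = 30,
                        read_length = 100L, substitution_rate = 0.005,
                        n_rate = 0.002, quality_start_level = 38L,
                        quality_decline_rate = 0.08, quality_shift_sd = 3,
                        quality_noise_sd = 2, terminal_run2_probability = 0.1,
                        name_prefix = "SRR000001", instrument = "HWI-EAS110",
                        run = "103327062", lane = 6L,
                        repeat_fraction = 0, repeat_length = 300L) {
  as.list(environment())
}

#' Generate a synthetic genome
#'
#' Draws a sequence from an order-`m` Markov chain over ACGT (order 0 is
#' i.i.d. uniform), optionally overwriting a fraction of the genome with
#' copies of earlier segments to create repeats.
#'
#' @param profile profile from [sim_profile()] (fields `genome_length`,
#'   `markov_order`, `repeat_fraction`, `repeat_length`).
#' @param seed integer seed; the same seed always yields the same genome.
#' @return a single genome string.
#' @export
sim_genome <- function(profile = sim_profile(), seed = 1L) {
  G <- as.integer(profile$genome_length)
  if (is.na(G) || G < 1L) stop("genome_length must be >= 1")
  set.seed(seed, kind = "Mersenne-Twister")
  m <- as.integer(profile$markov_order)
  bases <- c("A", "C", "G", "T")
  if (m == 0L) {
    g <- sample(bases, G, replace = TRUE)
  } else {
    # random sparse transition table: each context prefers one base
    nctx <- 4L^m
    pref <- sample(1:4, nctx, replace = TRUE)
    g <- character(G)
    ctx <- 0L
    for (i in seq_len(G)) {
      p <- rep(0.1, 4)
      p[pref[ctx + 1L]] <- 0.7
      b <- sample.int(4L, 1L, prob = p)
      g[i] <- bases[b]
      ctx <- (ctx * 4L + b - 1L) %% nctx
    }
  }
  g <- paste(g, collapse = "")
  if (profile$repeat_fraction > 0 && G > 2L * profile$repeat_length) {
    ncopy <- ceiling(profile$repeat_fraction * G / profile$repeat_length)
    for (i in seq_len(ncopy)) {
      src <- sample.int(G - profile$repeat_length, 1L)
      dst <- sample.int(G - profile$repeat_length, 1L)
      substr(g, dst, dst + profile$repeat_length - 1L) <-
        substr(g, src, src + profile$repeat_length - 1L)
    }
  }
  g
}

#' Simulate reads from a genome
#'
#' Samples reads uniformly from both strands, applies substitution and `N`
#' errors, generates declining qualities with per-read shifts and optional
#' terminal `'#'` runs, and builds Illumina-style identifiers with an
#' incrementing counter. Also returns the coordinate-sorted truth alignment
#' (SAM fields) for the reference-based codecs.
#'
#' Each component (positions, errors, qualities, names) draws from its own
#' sub-generator derived from `seed`, so changing one setting does not
#' perturb the others.
#'
#' @param genome genome string from [sim_genome()].
#' @param profile profile from [sim_profile()].
#' @param seed integer seed.
#' @param rname reference name used in the truth alignment.
#' @return list with `fastq` (fields as in [read_fastq()]) and `sam` (fields
#'   as in [read_sam()], records sorted by position).
#' @export
sim_reads <- function(genome, profile = sim_profile(), seed = 1L,
                      rname = "sim1") {
  G <- nchar(genome)
  rl <- as.integer(profile$read_length)
  Lmax <- max(rl)
  if (Lmax > G) stop("read_length must not exceed genome_length")
  nreads <- max(1L, round(profile$coverage * G / mean(rl)))
  sub_seed <- function(k) as.integer((seed * 7L + k) %% .Machine$integer.max)

  set.seed(sub_seed(1L))
  L <- if (length(rl) > 1L) sample(rl[1]:rl[2], nreads, replace = TRUE)
       else rep(rl, nreads)
  pos <- vapply(L, function(l) sample.int(G - l + 1L, 1L), integer(1))
  strand <- sample(c(0L, 1L), nreads, replace = TRUE)

  o <- order(pos)  # truth SAM is coordinate sorted; FASTQ keeps name order
  frag <- substring(genome, pos, pos + L - 1L)

  set.seed(sub_seed(2L))
  bases <- c("A", "C", "G", "T")
  reads_ref <- frag  # in reference orientation, with errors
  for (i in seq_len(nreads)) {
    s <- strsplit(frag[i], "")[[1]]
    err <- runif(L[i]) < profile$substitution_rate
    if (any(err)) {
      for (j in which(err)) {
        s[j] <- sample(setdiff(bases, s[j]), 1L)
      }
    }
    reads_ref[i] <- paste(s, collapse = "")
  }

  set.seed(sub_seed(3L))
  nmask <- lapply(L, function(l) runif(l) < profile$n_rate)

  set.seed(sub_seed(4L))
  shift <- rnorm(nreads, 0, profile$quality_shift_sd)
  run2 <- runif(nreads) < profile$terminal_run2_probability
  run2_len <- pmin(pmax(rgeom(nreads, 0.3) + 2L, 2L), L - 1L)
  quals <- character(nreads)
  for (i in seq_len(nreads)) {
    q <- profile$quality_start_level - profile$quality_decline_rate * (seq_len(L[i]) - 1L) +
      shift[i] + rnorm(L[i], 0, profile$quality_noise_sd)
    q <- pmin(pmax(round(q), 3L), 40L)
    if (run2[i]) q[(L[i] - run2_len[i] + 1L):L[i]] <- 2L
    # qualities are reported in machine (read) orientation: mirror the N mask
    # for reverse-strand reads so N always carries quality 0
    mq <- if (strand[i] == 1L) rev(nmask[[i]]) else nmask[[i]]
    q[mq] <- 0L
    quals[i] <- intToUtf8(q + 33L)
  }

  # read orientation: sequence as the machine would report it
  seqs <- reads_ref
  for (i in seq_len(nreads)) {
    s <- strsplit(reads_ref[i], "")[[1]]
    s[nmask[[i]]] <- "N"
    seqs[i] <- paste(s, collapse = "")
  }
  seqs_fastq <- ifelse(strand == 1L, revcomp(seqs), seqs)

  set.seed(sub_seed(5L))
  tile <- cumsum(c(1L, runif(nreads - 1L) < 0.001))
  x <- sample.int(20000L, nreads, replace = TRUE)
  y <- sample.int(20000L, nreads, replace = TRUE)
  qname <- sprintf("%s.%d %s_%s:%d:%d:%d:%d/1", profile$name_prefix,
                   seq_len(nreads), profile$instrument, profile$run,
                   profile$lane, tile, x, y)

  fastq <- list(id = paste0("@", qname), seq = seqs_fastq, qual = quals,
                plus_repeat = rep(FALSE, nreads), final_newline = TRUE)
  sam <- list(
    header = c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", rname, G)),
    records = data.frame(
      qname = qname[o], flag = ifelse(strand[o] == 1L, 16L, 0L),
      rname = rname, pos = pos[o], mapq = 60L,
      cigar = sprintf("%dM", L[o]), rnext = "*", pnext = 0L, tlen = 0L,
      seq = seqs[o],
      qual = ifelse(strand[o] == 1L, revstr(quals[o]), quals[o]),
      stringsAsFactors = FALSE))
  list(fastq = fastq, sam = sam)
}

#' Reverse complement
#'
#' @param s character vector of base strings.
#' @export
revcomp <- function(s) {
  revstr(chartr("ACGTacgt", "TGCAtgca", s))
}

revstr <- function(s) {
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
         USE.NAMES = FALSE)
}

#' 454-style mixed alphanumeric identifiers
#'
#' Generates identifiers whose accession part mixes letters and digits in a
#' base-64 style encoding, producing unstable token structure (the case where
#' simple string-delta identifier coding beats tokenised coding).
#'
#' @param n number of identifiers.
#' @param seed integer seed.
#' @export
sim_names_454 <- function(n, seed = 1L) {
  set.seed(seed)
  alpha <- c(LETTERS, letters, 0:9, "_", "-")
  key <- vapply(seq_len(n), function(i)
    paste(sample(alpha, 14, replace = TRUE), collapse = ""), character(1))
  paste0("@GKCN2LV01", key)
}
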