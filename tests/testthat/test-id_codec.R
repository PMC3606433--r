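# Identifier tokenisation, token diffing, stream coding and line deltas.

EX_PREV <- "@SRR062634.2724180 HWI-EAS110_103327062:6:13:11133:11572/1"
EX_CUR  <- "@SRR062634.2724181 HWI-EAS110_103327062:6:13:11133:5630/1"

test_that("tokenisation splits types by maximal munch", {
  tk <- tokenize_id("@SRR062634.3364 HWI-EAS110_103327062:6:1:1944:962/2")
  expect_identical(tk$type[1:6],
                   c("PUNCT", "ALPHA", "LEADING_ZERO_NUMERIC", "NUMERIC",
                     "PUNCT", "NUMERIC"))
  expect_identical(tk$value[1:6], c("@", "SRR", "0", "62634", ".", "3364"))
  expect_identical(tk$slot, seq_len(nrow(tk)))

  expect_identical(tokenize_id("abc007xyz")$value, c("abc", "00", "7", "xyz"))
  expect_identical(nrow(tokenize_id("")), 0L)
})

test_that("detokenisation inverts tokenisation for arbitrary printable ids", {
  ids <- rand_ids(200, seed = 21)
  for (id in ids) expect_identical(detokenize_id(tokenize_id(id)), id)
  # long digit runs and leading zeros survive chunking
  for (id in c("0", "00", "a000b", strrep("9", 40), paste0("x", strrep("0", 300))))
    expect_identical(detokenize_id(tokenize_id(id)), id)
})

test_that("token diffing applies the match and bounded-delta rules", {
  d <- diff_tokens(EX_PREV, EX_PREV)
  expect_true(all(d$type == "MATCH"))

  prev <- "@SRR1.100:962/2"
  d <- diff_tokens(prev, "@SRR1.100:963/2")
  expect_identical(d$type[d$type != "MATCH"], "DELTA")
  expect_identical(d$value[d$type == "DELTA"], "1")

  # a numeric decrease is not a delta: the rule requires 0..255 higher
  d <- diff_tokens("@x100", "@x90")
  expect_identical(d$type[3], "NUMERIC")
  expect_identical(d$value[3], "90")
  # an increase above 255 is a literal too
  d <- diff_tokens("@x100", "@x400")
  expect_identical(d$type[3], "NUMERIC")
})

test_that("identifier streams round-trip in both modes", {
  f <- fix_sim()
  ids <- f$sim$fastq$id
  for (mode in c("tokenized", "string_delta")) {
    e <- encode_id_stream(ids, mode)
    expect_identical(decode_id_stream(e, length(ids), mode), ids)
  }
  # single identifier and arbitrary ASCII fuzz
  e <- encode_id_stream("only-one/1")
  expect_identical(decode_id_stream(e, 1), "only-one/1")
  fuzz <- rand_ids(150, seed = 31)
  for (mode in c("tokenized", "string_delta")) {
    e <- encode_id_stream(fuzz, mode)
    expect_identical(decode_id_stream(e, length(fuzz), mode), fuzz)
  }
})

test_that("structured identifiers compress below 4 bytes each", {
  set.seed(41)
  ids <- sprintf("@SRR062634.%d HWI-EAS110_103327062:6:1:1944:%d/1",
                 1:1000, sample.int(20000, 1000, replace = TRUE))
  e <- encode_id_stream(ids, "tokenized")
  expect_lt(length(e) / 1000, 4)
})

test_that("454-style base-64 names favour string-delta coding", {
  ids <- sim_names_454(500, seed = 51)
  et <- encode_id_stream(ids, "tokenized")
  es <- encode_id_stream(ids, "string_delta")
  expect_lt(length(es), length(et))
  expect_identical(decode_id_stream(es, 500, "string_delta"), ids)
})

test_that("line delta reproduces the printed example: (18)(1)(51) '5630/1' (0)", {
  d <- fastqz_delta(EX_PREV, EX_CUR)
  expect_identical(d$column, 18L)
  expect_identical(d$increment, 1L)
  expect_identical(d$match_len, 51L)
  expect_identical(d$literal, "5630/1")
  expect_identical(d$terminator, 0L)
  expect_identical(fastqz_delta_apply(EX_PREV, d), EX_CUR)
})

# brute-force oracle: search all (column, increment) pairs with an
# independent pure-R implementation of the adjustment
delta_oracle <- function(prev, cur) {
  lcp <- function(a, b) {
    av <- utf8ToInt(a); bv <- utf8ToInt(b)
    n <- min(length(av), length(bv))
    if (n == 0) return(0L)
    d <- which(av[1:n] != bv[1:n])
    if (length(d)) d[1] - 1L else n
  }
  adjust <- function(s, col, inc) {
    ch <- strsplit(s, "")[[1]]
    if (col > length(ch) || !grepl("[0-9]", ch[col])) return(s)
    e <- col
    while (e < length(ch) && grepl("[0-9]", ch[e + 1]) && e - col < 17) e <- e + 1
    run <- paste(ch[col:e], collapse = "")
    num <- as.numeric(run) + inc
    rendered <- formatC(num, width = nchar(run), flag = "0", format = "d")
    paste0(substr(s, 1, col - 1), rendered,
           substr(s, e + 1, nchar(s)))
  }
  best <- lcp(prev, cur)
  for (col in seq_len(nchar(prev))) {
    if (!grepl("[0-9]", substr(prev, col, col))) next
    for (inc in 1:255) {
      m <- lcp(adjust(prev, col, inc), cur)
      if (m > best) best <- m
    }
  }
  best
}

test_that("line delta degenerate cases", {
  d <- fastqz_delta("same line", "same line")
  expect_identical(unlist(d[c("column", "increment", "match_len")]),
                   c(column = 0L, increment = 0L, match_len = 9L))
  expect_identical(d$literal, "")
  # the numeric field grew by 299, beyond the 255 increment cap, so no
  # adjustment can reproduce the whole number; the best admissible pair
  # increments "1" to "3" (matching the digits' common prefix) and the rest
  # is literal -- and the inverse still reconstructs the line
  d <- fastqz_delta("r1", "r300")
  expect_identical(d$column, 2L)
  expect_identical(d$increment, 29L)   # "1" + 29 = "30", two matching digits
  expect_identical(d$match_len, 3L)
  expect_identical(d$literal, "0")
  expect_identical(fastqz_delta_apply("r1", d), "r300")
  expect_identical(d$match_len, delta_oracle("r1", "r300"))
  # a truly inadmissible case: nothing numeric to adjust
  d <- fastqz_delta("abc", "xyz")
  expect_identical(d$column, 0L)
  expect_identical(d$match_len, 0L)
  expect_identical(d$literal, "xyz")
})

test_that("chosen match length is maximal (brute-force oracle)", {
  set.seed(61)
  cases <- list(
    c("@r9.17 x:100:5", "@r9.18 x:100:5"),
    c("@a007:199 t", "@a007:200 t"),
    c("@q33z", "@q34z9"),
    c("run42base", "run43base"))
  for (i in 1:10) {
    a <- sprintf("@id%d f:%d:%d", sample(99, 1), sample(999, 1), sample(99, 1))
    b <- sprintf("@id%d f:%d:%d", sample(99, 1), sample(999, 1), sample(99, 1))
    cases <- c(cases, list(c(a, b)))
  }
  for (cs in cases) {
    d <- fastqz_delta(cs[1], cs[2])
    expect_identical(d$match_len, delta_oracle(cs[1], cs[2]),
                     info = paste(cs, collapse = " -> "))
    expect_identical(fastqz_delta_apply(cs[1], d), cs[2])
  }
})

test_that("line-delta identifier streams round-trip, fast and slow", {
  f <- fix_sim()
  ids <- f$sim$fastq$id[1:400]
  for (slow in c(FALSE, TRUE)) {
    e <- encode_fastqz_ids(ids, slow)
    expect_identical(decode_fastqz_ids(e, length(ids), slow), ids)
  }
  fuzz <- rand_ids(100, seed = 71)
  for (slow in c(FALSE, TRUE)) {
    e <- encode_fastqz_ids(fuzz, slow)
    expect_identical(decode_fastqz_ids(e, length(fuzz), slow), fuzz)
  }
})

test_that("a change in one numeric field is coded as a single-slot delta", {
  # the per-slot model structure: all other slots stay MATCH
  prev <- "@SRR062634.3364 HWI-EAS110_103327062:6:1:1944:962/2"
  cur <- sub(":962/", ":963/", prev)
  d <- diff_tokens(prev, cur)
  changed <- which(d$type != "MATCH")
  expect_identical(length(changed), 1L)
  expect_identical(d$type[changed], "DELTA")
})
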