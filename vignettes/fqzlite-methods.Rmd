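---
title: "Stream-split compression of sequencing data: models and design"
author: "fqzlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stream-split compression of sequencing data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqzlite)
```

## The model

A FASTQ record interleaves three statistically unrelated texts: a
machine-generated identifier, base calls from a four-letter alphabet with
genomic structure, and Phred-scaled quality scores with smooth positional
trends. fqzlite compresses each as an independent stream. Every stream is
driven by the same engine: adaptive context models feed probabilities to a
32-bit byte-wise arithmetic (range) coder, so a symbol predicted with
probability $p$ costs about $-\log_2 p$ bits. Compression quality is then
entirely a question of how well the contexts predict, and each stream gets
contexts shaped to its structure.

The predictor vocabulary is shared across codecs:

* **Direct frequency models** — 8-bit counters per symbol, addressed by a
  context key. Counters increment by 4 and all counters in a context halve
  (rounding up, so support is never lost) when one would pass 255. The
  coding probability of symbol $i$ is $(2c_i+1)/(2\sum_j c_j + A)$.
* **Adaptive bit models** — a probability nudged toward each observed bit by
  a step shrinking with the context count.
* **Indirect (bit-history) models** — a hashed context maps to an 8-bit
  state recording the last bit and a saturating run length (capped at 40);
  the state maps to an adaptively adjusted probability.
* **A logistic mixer** — component predictions are combined by weighted
  averaging in the logistic domain, $\mathrm{squash}(\sum_i w_i\,
  \mathrm{stretch}(p_i))$ with $\mathrm{stretch}(p) = \ln p/(1-p)$; weights
  are selected per context and trained by gradient steps on the coding loss.
* **Secondary estimation (SSE/APM)** — the mixed prediction is refined by an
  interpolated table keyed by a bit history.
* **A match model** — the last occurrence of the current context in history
  predicts the next bit with confidence $1 - 1/\ell$ for a live match of
  $\ell$ bits; one wrong bit cancels the match.

All model arithmetic is integer (probabilities on a 12-bit grid, clamped to
$[1/4096,\,4095/4096]$; stretch/squash via fixed lookup tables), so encoder
and decoder are bit-identical across platforms and containers are fully
deterministic.

### Why the counter increment is 4

The increment sets the effective memory of a frequency model: larger steps
adapt faster but estimate noisier probabilities. We require the coder to sit
within 1% + 128 bits of the Shannon bound on $10^4$-symbol streams from
known distributions. With increment 8 the estimation noise on a 90/10
binary source averages ≈ 197 bits of excess — outside that contract — while
increment 4 (an effective window of ~128 counts) stays near 60–120 bits with
margin, at a negligible cost in adaptation speed for the stream sizes the
codecs see. Per-reference-position models (below) are the exception: one
visit at a site is one read's worth of evidence, so they use increment 16.

## Identifier coding

Two schemes are implemented. The *tokenised* codec splits an identifier into
typed tokens (letter runs, leading-zero runs, other digit runs, punctuation
runs) by maximal munch, then codes each token slot against the same slot of
the previous identifier: identical tokens become a MATCH flag, numeric
values 0–255 higher become a one-byte DELTA, anything else is coded
literally with per-slot models (numeric values little-endian across four
byte models, split into 32-bit quantities above $2^{32}$). Identifiers with
unstable token structure (base-64 style names) overflow the 32-slot budget
and fall back, per record, to a prefix-length + suffix *string-delta* coder,
which is also available as a mode of its own.

The *line-delta* codec encodes each line against its predecessor as "go to
column $c$, add $i \le 255$ to the decimal string there, copy the first $m$
bytes of the adjusted line, append the literal remainder, terminate with 0".
The $(c, i)$ pair maximising $m$ is chosen by exhaustive search over all
increments at every digit column up to the first mismatch — partial matches
of the rendered digits count, which a brute-force oracle in the test suite
confirms is necessary for optimality. Ties prefer the smaller increment and
then the larger (most local) column, which is also what reproduces the
worked example coded as column 18, increment 1, copy 51. In slow mode the
delta bytes are further coded by two direct and two indirect byte-context
models mixed with weights selected by the column.

## Quality coding

Scores are mapped to canonical symbols 0–63: ASCII−33 clamped to 62, symbol
0 reserved for `N` bases, and a terminal run (length ≥ 2) of score 2 —
the classic low-quality read tail — collapsed to a single sentinel 63.
Collapsing a lone terminal 2 would make decoding ambiguous, so it is coded
plainly. Three context levels trade memory for accuracy:

| level | context | size |
|---|---|---|
| 1 | previous score $q_{i-1}$ | 64 |
| 2 | $q_{i-1}$, $\lfloor q_{i-2}/4\rfloor$ | 1k |
| 3 | level 2 + position bucket ($\min(i,127)/8$), max of last 6 scores ($/4$), flag any score < 20 | 512k |

Level 3 realises the three empirical correlations quality streams show —
neighbour correlation, positional decline, and good/bad whole reads. Its
half-million contexts need a few hundred thousand scores before they pay for
their startup cost, which the tests size for explicitly.

Two lossy modes exist. *Rounding* replaces every value above 1 by the
nearest multiple of $Q$ (ties upward, clamped to 1..62, so the deviation is
at most $\lceil Q/2\rceil$ — at the top of the range a clamped value may not
be a multiple). *Within-Q* instead lets the encoder replace each value above
$Q$ by whichever value within $\pm Q$ the current context model predicts
most strongly; the model and the context history are updated with the stored
value so the decoder stays in lockstep. $Q = 1$ is exactly lossless in both
modes.

## Base-call coding

The order-$k$ codec codes each base (2 bits; `N` is coded as `A` and
restored from its quality-0 convention) under the previous $k$ bases. The
context register resets at read boundaries so records stay independently
decodable in order. With deep coverage of a small genome the table converges
to the genome itself and the cost per base falls well below 1 bit. Options
mirror the fast/medium/slow presets: $k = 12$ flat, $k = 14$ flat, $k = 16$
with $2^{24}$ hashed contexts (collisions cost ratio, never correctness).
Optional extras are reverse-complement training (each coded base also trains
the opposite-strand context, helping when per-strand coverage is thin) and a
second fixed order-7 model; each base is then coded by whichever model holds
the strongest single-symbol bias — to any base, not just the one being coded,
so the decoder can repeat the choice — with ties to the order-$k$ model and
no mixing.

The packing codec assigns A=1, T=2, C=3, G=4 and greedily packs 3 or 4 bases
per byte: after three bases with value $v$, a fourth base $c$ joins iff
$4v + c \le 255$. Three-base bytes occupy 63–84 and four-base bytes 85–255,
so group size is recoverable from the byte alone; a 1–2 base remainder at
stream end uses escape bytes below 21. The non-zero codes make the parse
self-synchronising: shifted copies of the same sequence tend to converge to
identical group boundaries (G-, CG- and CCG-initial groups are always
3-base, which is what creates the anchor points). One caveat is documented
in the tests: a 4-base group can never start with G (its value would exceed
255), so not every shifted parse of every read resynchronises within a short
window. In slow mode the packed bytes are coded bit-wise by a mix of direct
order-0..2 models, an indirect order-3 model and an order-5 match model,
refined by a secondary estimator keyed by the bit history of a hashed
order-4 context — the match model is what exploits read overlap at depth.

## Reference-based coding

Given a reference FASTA, reads are aligned with a hashed index: the
N-stripped reference is cut into non-overlapping 32-base groups, each
hashed into a table slot holding a 27-bit group pointer and a 5-bit checksum
(cheap early rejection of collisions). Insertion probes 8 consecutive slots
and discards the pointer if all are full — lost coverage, never an error.
Alignment rolls a polynomial hash over every 32-base window of the read and
of its reverse complement, turns index hits into implied start positions
(capped at 16 candidates per strand), and ranks candidates by the position
of the fourth mismatch, breaking ties with the third, second and first. A
best fourth mismatch before half the read length, or a read shorter than one
group, leaves the read unmatched.

A matched read is stored as up to four 1-based mismatch positions (read
length + 1 fills unused slots), a direction bit and a 4-byte pointer; an
unmatched read is a single 0 byte. Matched bases are deleted from the
sequence stream; mismatch literals are coded under the expected reference
base, and everything from the fourth mismatch onward stays in the ordinary
sequence stream. In slow mode the record bytes are coded under a context of
the parse state, the previous bits of the current byte, and the high 6 bits
of the previous byte — except for the two low pointer bytes, which are close
to uniform. The same reference (verified by checksum) must be present to
decompress.

## SAM coding

Both SAM codecs retain qname, flag, rname, pos, mapq, CIGAR, sequence and
quality; template columns 7–9 and auxiliary tags are documented losses
(stored only if non-default), and the header passes through verbatim.
Identifiers and qualities reuse the codecs above; flags, mapq, position
deltas, rname indices and CIGAR text go to a side stream of order-0/1 byte
models.

*Per-position coding* (position-sorted input required, violations are
errors) anchors every M/=/X base to a reference coordinate via the CIGAR
walk and codes it with that coordinate's own adaptive 4-symbol model —
as coverage accumulates the model sharpens, so deep data approaches the
cost of reference-based coding without any reference. When a reference is
supplied, a fresh coordinate's model is seeded with its reference base
worth one observation (increment 16). Without one, the coordinate is
seeded from a low-order consensus context: an order-2 model over the
consensus calls at the two preceding coordinates, with wide (+1, cap
$2^{20}$) counters, granting its modal base only the mass by which it
exceeds a uniform share — so a flat consensus (a random genome) seeds
nothing and a skewed one seeds its MAP base. Insertions, soft-clips and
unmapped reads use their own channel models. The measured no-reference
penalty on 30× error-free coverage is ≈ 2.0 bits per covered position —
essentially the one-time cost of learning each site's base, equivalent to
shipping a compressed copy of the consensus.

*Reference-difference coding* keeps no per-coordinate state (memory
independent of genome length) and accepts records in any order, which keeps
name-sorted identifiers highly compressible. Each anchored base codes a
match/mismatch bit against the reference under the last 16 match bits as
context; mismatched bases are then coded under the reference base. Without
a reference it degrades to a low-order context model, with a warning.

## Container format

One container serves all codec families: magic `FQZ1`, a version byte, a
mode byte and tagged blocks (`META`, `ID`/`QNAM`, `SEQ`, `QUAL`, `ALN`,
`MIS`, `SIDE`), each carrying an 8-byte length and a CRC-32 verified before
any decoding — a flipped bit is reported as corruption, never decoded into
silent garbage. `META` (a serialized R list) holds record counts, read
lengths, the `+`-line repetition flags, the final-newline flag, the
reference checksum, and the exception table for positions violating the
`N` ⇔ quality-0 convention, which is what makes lossless round trips
byte-exact rather than merely semantically equal. Store mode keeps raw
streams and anchors the accounting at exactly 8 bits per base and per
quality.

## The simulator

`sim_genome()` and `sim_reads()` generate the structure the codecs exploit:
an order-$m$ Markov genome (order 0 by default, optional duplicated
segments for match models), uniform both-strand sampling, per-base
substitution and `N` errors (`N` always carries quality 0 in machine
orientation), qualities that start near 38 and decline with per-read level
shifts (lag-1 autocorrelation > 0.3), a configurable fraction of terminal
`'#'` runs, Illumina-style names with an incrementing counter and random
coordinates, and a coordinate-sorted truth SAM with correct CIGARs. One
seed drives independent sub-generators per component, so changing the name
template does not perturb base calls. Default sizes (100 kb genome, 30×,
100 bp) put the medium-mode overall ratio in the 0.15–0.30 regime typical
of deep Illumina data.

What the simulator does *not* emulate — platform-specific error profiles
(454 homopolymers, colour space), PCR/optical duplicates, indel errors in
reads, quality calibration drift — bounds what green tests show: they
demonstrate correctness (losslessness, bounds, determinism) on data with
realistic low-order statistics, not ratio parity with real instruments.

## Numerical and scale choices

* Problem sizes in the tests are chosen to finish in minutes on one core:
  genomes of 10–100 kb, coverages 2–40, with the level-3 quality claim and
  the depth/genome-size directional claims sized at the smallest data that
  exhibits them robustly.
* The reference index defaults to $2^{20}$ slots (configurable to the
  published geometry); at desk-scale loads the probe-8 discard fraction is
  effectively zero. A uniform-hash simulation of the published human-genome
  load (90.6M groups into $2^{28}$ slots, occupancy 0.34) discards only
  ~0.06% of pointers; discard rates of several percent require either ~80%
  load or heavy 32-mer duplication, as real genomes' repeat content
  provides.
* Ties are pinned everywhere a choice could diverge between encoder and
  decoder: model selection prefers order-$k$; the lossy within-mode search
  prefers the closest, then the smaller value; the line-delta search
  prefers smaller increments then larger columns.
* Degenerate inputs — empty files, length-1 reads, all-`#` tails, reads of
  `N`, missing qualities (`*`), unmapped records — are first-class test
  cases, handled in the formats rather than rejected.

## Known limitations

Streaming only: no random access into containers. Substitution-only
alignment in the read mapper (no indels; indel-containing records are
handled by the SAM codecs, whose CIGARs carry them). Phred+64 input is not
supported. The `META` block uses R serialization, so containers are a
format of this package, not an interchange standard.
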