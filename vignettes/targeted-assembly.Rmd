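---
title: "Targeted assembly by iterative read baiting: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted assembly by iterative read baiting: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebait)
```

## The procedure and its assumptions

`rebait` reconstructs a genomic region of interest from whole-genome
shotgun reads without assembling the genome. The loop alternates three
operations — recruit reads that share exact k-mers with a bait, assemble
the recruited reads de novo, replace the bait by the assembly — and stops
each target on a per-target completion criterion. The procedure rests on
three assumptions:

* **Seeding.** The reference shares at least one exact k-mer (31 bp by
  default) with reads of the target region. A homolog from a related
  species works when conserved stretches of ≥ 31 bp survive the
  divergence; at a uniform 5 % per-base substitution rate roughly
  `0.95^31` ≈ 20 % of windows are intact, at 10 % about 4 % are, so a
  query of a few hundred bases almost always carries a seed — but a
  uniformly 10 %-diverged 650 bp query has a non-negligible chance
  (~8 %) of carrying none. Real interspecies queries are safer than this
  uniform model because their divergence is concentrated in variable
  regions.
* **Extension.** Reads overlapping the current assembly end by ≥ k are
  recruited, and their mates reach up to an insert length beyond it, so
  each iteration extends a target by roughly the insert size minus k per
  flank. Recovering a 30 kb molecule from a 1 kb seed therefore takes on
  the order of 50 iterations with a 300 bp insert library.
* **Contrast.** The loop is selective because unrelated reads share no
  31-mer with the bait by chance (random collision probability per
  window is ~4^-31). Repeats shared between the target and the rest of
  the genome do recruit foreign reads; the contig length filter
  (`min_contig`) is the built-in remedy, keeping repeat-induced
  fragments out of the next bait.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 bp | recruitment k-mer length; canonical (strand-symmetric) exact matching |
| `min_hits` | 1 | k-mers a read must share with the bait to be recruited |
| `min_overlap` | 40 bp | minimum exact suffix–prefix overlap for a merge |
| `min_contig` | 0 (off) | length filter applied before completion testing and re-baiting |
| `trim_to` | off | truncate reads from the 3' end before assembly (low-quality tails break exact overlaps) |
| `min_identity` | 0.5 | identity gate for a completing homology match |
| `max_iterations` | unset | safety cap; the implicit criterion bounds every run regardless |

Completion criteria are declared per reference entry as description tags
(`crit=exhaustive`, `crit=total_size:N`, `crit=longest:N`, `crit=n50:N`,
`crit=homology`), with OR semantics when several are given. A thread
whose entries carry no tag uses the run-level default. A thread holding
several query entries (grouped via `grouping=`) completes in homology
mode only when *every* query has a completing match; its progress is
tracked per query, and the thread continues while any query's aligned
span grows.

## The built-in assembler

The assembler is a deterministic greedy exact-overlap merger, not an
error-correcting OLC assembler: the surrounding loop, not the assembler,
is this package's contribution, and the adapter contract
(`register_assembler()`: a working directory with pair-aware FASTQ in,
`contigs.fasta` out) admits real assemblers where error tolerance
matters. Duplicate and contained reads are collapsed first; then the
pair of sequences with the longest exact suffix–prefix overlap ≥
`min_overlap` (both orientations considered) is merged repeatedly. All
sequences are kept in canonical orientation (lexicographic minimum of
sequence and reverse complement), and ties on overlap length are broken
on the canonical form of the would-be merged sequence (compared over a
bounded prefix, then by length and content). Consequences worth knowing:

* identical read multisets yield byte-identical assemblies regardless of
  input order;
* pairing information plays no role in assembly (only in recruitment);
* sequencing errors break overlaps instead of being corrected — the
  `trim_to` parameter is the workaround for systematically bad read
  tails (e.g. homopolymer artifacts near read ends).

## Homology matching

The homology criterion aligns each query against every contig with an
affine semi-global dynamic program: global in the query, free leading
and trailing *target* positions, scores match +1, mismatch −2, gap open
−4, gap extension −1 (a gap of length L costs 4 + L). These scores are
this package's convention; the method the package implements prescribes
only "the entire reference aligned, indels allowed". Terminal query
gaps are permitted but pay the normal affine cost, which gives a
well-defined best alignment even when the contig covers only part of
the query.

A match is *completing* when (i) the alignment path spans the query
from first to last base, (ii) at least 95 % of query bases sit in
match/mismatch columns — tolerating short internal indels while
rejecting the degenerate case where a contig covering only part of a
query gets bridged by one long internal gap — and (iii) identity over
the spanned columns is at least `min_identity`. The 0.5 default
identity gate excludes full-length alignments of unrelated sequences,
whose identity under this scoring settles near 0.3–0.45. `query_aligned`
(the number of query bases aligned to target bases) is the progress
metric: a homology thread stops when no query's value grows between
iterations.

Coordinates are 0-based half-open internally (`MatchResult`), 1-based
inclusive in extracted-record ids and all files.

## Circularization

A circular molecule — or one unit of a tandem repeat array, which is
indistinguishable from a circle to an overlap assembler — assembled
linearly carries a duplicated junction: its ends are identical over the
junction length. `find_end_overlap()` reports the longest exact
prefix/suffix identity (≥ 20 bp by default, capped at half the sequence
so homopolymers and low-complexity sequences cannot trivially match
themselves); `circularize()` trims it and reports the
rotation-canonical form — the least rotation over both strands — which
is the comparison form for circular products. Junction matching is
exact by design: junction duplications produced by an exact-overlap
assembler are exact.

## The synthetic data generator

`simulate_genome()` emulates the data regime the method targets: a
large single-copy background chromosome (500 kb by default) carrying an
embedded tandem array (8 kb unit × 10) and single-copy loci (650–1800
bp), plus a *separate* circular replicon (30 kb, 20 copies per genome) —
the mitochondrial-genome analogue. `simulate_reads()` draws paired-end
fragments uniformly per molecule copy (so the replicon is 20-fold
over-covered relative to the chromosome, and replicon fragments may
span the origin), with optional uniform substitution errors;
`diverge()` manufactures "related species" queries with seeded
substitutions and short indels. Everything is a pure function of its
seed.

The default per-copy coverage of 2.5× puts 50× over the 20-copy
replicon — the multi-copy recovery regime. Single-copy loci are not
recoverable at 2.5× (coverage gaps longer than a read are certain over
500 kb), so the homology-extraction scenario uses 30×, a typical
whole-genome sequencing depth. The end-to-end tests use problem sizes
of 20–500 kb backgrounds and 5–30 kb targets; the multi-versus-single
equivalence check runs on a 40 kb background with a 6 kb replicon,
equivalence being a structural property that does not depend on scale.

What passing these tests does *not* show about real data: the error
model is substitution-only and uniform, reads have no quality
structure, divergence has no conserved/variable block structure, and
the background is random sequence without genome-scale repeat families.
Results on real libraries depend on read quality (see `trim_to`) and on
repeat content (see `min_contig`).

## Numerical and procedural choices

* **"No new information" is tested on orientation-canonical contig
  multisets**, not byte equality — assemblers may flip or reorder
  contigs between otherwise identical iterations, and byte equality
  would loop forever on a strand flip.
* **Terminated threads leave the general bait** (their last assembly is
  still written to outputs), so a stalled thread cannot keep recruiting
  for others. When general baiting itself finds no new reads the whole
  run stops, as the method prescribes; an exhaustive thread stopped this
  way has, by construction, already stopped changing.
* **Exhaustive threads report a stall as success** ("exhausted"): the
  implicit criterion *is* their completion criterion. Non-exhaustive
  threads report `stalled` distinctly, and a thread whose first
  screen recruits nothing reports `failed` ("no reads matched
  reference").
* **Additional bait participates in the first general screen only**; it
  never enters per-thread specific baits, so a permissive bait set
  cannot contaminate a specific target.
* **Termination** is guaranteed without any explicit criterion: the
  general ledger can grow at most once per read, and every stall rule
  is absorbing.
* **IUPAC ambiguity codes other than N are read as N**; N never
  participates in k-mers (windows containing it are skipped), and
  contigs never contain characters outside A/C/G/T/N.

## Known limitations

* Exhaustive assembly of a target *embedded* in a well-covered
  background (e.g. a tandem array in a deeply sequenced genome) crawls
  into the flanking sequence until a coverage gap stops it; the target
  itself is still recovered as the dominant contig, but iteration
  counts grow with flank coverage. Size criteria or `max_iterations`
  bound this when it matters.
* The built-in assembler does not correct sequencing errors; at
  realistic error rates an external assembler via the adapter contract
  is the right choice, exactly as the method intends.
* Alignment memory is one byte per DP cell (query length × contig
  length), which bounds practical homology queries to a few kb against
  contigs of a few hundred kb.
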