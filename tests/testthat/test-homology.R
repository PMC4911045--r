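# Semi-global alignment, best-match selection, and region extraction.

test_that("exact containment aligns full-query with exact coordinates", {
  set.seed(30)
  target <- random_dna(1000)
  q <- substr(target, 301, 500)
  m <- semiglobal_align(q, target)
  expect_true(m$full_query)
  expect_equal(m$identity, 1.0)
  expect_equal(m$strand, "+")
  expect_equal(m$target_start, 300L)  # 0-based half-open
  expect_equal(m$target_end, 500L)
  expect_equal(m$query_aligned, 200)

  # reverse-complement containment flips the strand, same span
  m2 <- semiglobal_align(revcomp(q), target)
  expect_true(m2$full_query)
  expect_equal(m2$identity, 1.0)
  expect_equal(m2$strand, "-")
  expect_equal(m2$target_start, 300L)
  expect_equal(m2$target_end, 500L)
})

test_that("substitutions and indels score as the DP oracle prescribes", {
  set.seed(31)
  target <- random_dna(300)
  # three guaranteed substitutions and one 2 bp deletion in the target
  q <- target
  flip <- function(s, i) {
    old <- substr(s, i, i)
    substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    s
  }
  q <- flip(flip(flip(q, 50), 150), 250)
  tdel <- paste0(substr(target, 1, 199), substr(target, 202, 300))
  m <- semiglobal_align(q, tdel)
  expect_equal(m$score, oracle_sg_best(q, tdel))
  # 298 aligned columns are M (3 mismatches), 2 are query-gap columns
  expect_true(m$full_query)
  expect_equal(m$identity, 295 / 300)
})

test_that("alignment score equals the exhaustive DP oracle on small pairs", {
  set.seed(32)
  seqs <- vapply(sample(1:40, 12, replace = TRUE), random_dna, character(1))
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i == j) next
      expect_equal(semiglobal_align(seqs[i], seqs[j])$score,
                   oracle_sg_best(seqs[i], seqs[j]))
    }
  }
})

test_that("strand symmetry: aligning against revcomp flips strand only", {
  set.seed(33)
  q <- random_dna(120)
  t <- paste0(random_dna(200), q, random_dna(150))
  a <- semiglobal_align(q, t)
  b <- semiglobal_align(q, revcomp(t))
  expect_equal(a$score, b$score)
  expect_true(a$strand != b$strand)
  expect_equal(a$target_end - a$target_start,
               b$target_end - b$target_start)
})

test_that("best_match gates unrelated sequences and tracks progress", {
  set.seed(34)
  locus <- random_dna(500)
  asm <- as_assembly(c(random_dna(800),
                       paste0(random_dna(100), locus, random_dna(120)),
                       random_dna(400)))
  # a 10%-diverged query still completes and finds the right contig
  q <- diverge(locus, 0.10, seed = 35)
  bm <- best_match(seq_records(q, id = "q"), asm, min_identity = 0.5)
  expect_true(bm$completing)
  locus_contig <- which(vapply(asm$seq, function(s)
    grepl(locus, s, fixed = TRUE) ||
      grepl(revcomp(locus), s, fixed = TRUE), logical(1)))
  expect_equal(bm$contig_id, asm$id[locus_contig])

  # random unrelated queries never pass the identity gate
  for (seed in 36:40) {
    set.seed(seed)
    rq <- random_dna(500)
    bm2 <- best_match(seq_records(rq, id = "rq"), as_assembly(random_dna(5000)),
                      min_identity = 0.5)
    expect_false(bm2$completing)
  }
  expect_null(best_match(seq_records("ACGT"), as_assembly(character(0))))
})

test_that("a truncated target yields a partial match that cannot extract", {
  set.seed(41)
  locus <- random_dna(600)
  asm <- as_assembly(substr(locus, 1, 250))  # assembly covers query start only
  bm <- best_match(seq_records(locus, id = "q"), asm)
  expect_false(bm$completing)
  expect_lt(bm$query_aligned, 600)
  expect_gt(bm$query_aligned, 100)
  expect_error(extract_region(bm, asm), "non-completing")
})

test_that("extract_region returns the span in query orientation", {
  set.seed(42)
  target <- random_dna(900)
  q <- substr(target, 201, 650)
  asm <- as_assembly(target)
  stored <- asm$seq[1L]  # canonical orientation, may be the revcomp
  m <- best_match(seq_records(q, id = "q"), asm)
  reg <- extract_region(m, asm, name = "thr")
  expect_equal(reg$seq, q)
  expect_match(reg$id, "^thr\\|contig_1:")

  # minus-strand match: extraction reverse complements the slice
  m2 <- best_match(seq_records(revcomp(q), id = "q2"), asm)
  reg2 <- extract_region(m2, asm, name = "thr")
  expect_equal(reg2$seq, revcomp(q))
  # involution: the two extractions are reverse complements of each other
  expect_equal(reg2$seq, revcomp(reg$seq))

  # boundary: a match spanning the whole contig returns the whole contig
  mall <- best_match(seq_records(stored, id = "full"), asm)
  expect_equal(extract_region(mall, asm)$seq, stored)

  # extraction coordinates recover an embedded locus exactly even for a
  # substitution-diverged query (error-free contig)
  locus <- substr(target, 301, 700)
  dq <- diverge(locus, 0.08, seed = 43)
  md <- best_match(seq_records(dq, id = "dq"), asm)
  expect_true(md$completing)
  expect_equal(extract_region(md, asm)$seq, locus)
})
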