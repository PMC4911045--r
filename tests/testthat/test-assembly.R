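# The greedy exact-overlap assembler, the length filter, and the
# assembler adapter contract.

canon1 <- function(s) pmin(s, revcomp(s))

test_that("two overlapping reads merge into the expected contig", {
  asm <- greedy_assemble(c("ACGTACGTAA", "CGTAACCGGT"),
                         assembler_params(min_overlap = 5))
  expect_equal(length(asm), 1L)
  expect_equal(asm$seq, canon1("ACGTACGTAACCGGT"))
  expect_equal(asm$reads_used, 2)

  # maximum overlap below the cutoff: no merge
  asm2 <- greedy_assemble(c("ACGTACGTAA", "GTAACCGGTT"),
                          assembler_params(min_overlap = 5))
  expect_equal(length(asm2), 2L)

  expect_error(greedy_assemble(character(0)), "no reads")
})

test_that("tiling reads reconstruct the source sequence", {
  set.seed(20)
  truth <- random_dna(2000)
  asm <- greedy_assemble(tiling_reads(truth, 100L, 25L),
                         assembler_params(min_overlap = 40))
  expect_equal(length(asm), 1L)
  expect_equal(asm$seq, canon1(truth))
})

test_that("reconstruction holds across sizes and coverages", {
  set.seed(21)
  for (len in c(1000L, 4000L, 10000L)) {
    truth <- random_dna(len)
    # ~15x coverage of 100 bp reads at random positions, both strands;
    # both sequence ends are covered so the whole truth is recoverable
    n <- ceiling(15 * len / 100)
    starts <- c(1L, len - 99L,
                sample(len - 99L, n - 2L, replace = TRUE))
    reads <- substring(truth, starts, starts + 99L)
    flip <- runif(n) < 0.5
    reads[flip] <- revcomp(reads[flip])
    asm <- greedy_assemble(reads, assembler_params(min_overlap = 40))
    expect_equal(asm$seq[1L], canon1(truth))
    # conservation: contig alphabet is A/C/G/T/N only
    expect_false(any(grepl("[^ACGTN]", asm$seq)))
    # read accounting: every input read lands in exactly one contig
    expect_equal(sum(asm$reads_used), n)
  }
})

test_that("assembly is deterministic and independent of read order", {
  set.seed(22)
  truth <- random_dna(3000)
  starts <- sample(2901L, 300L, replace = TRUE)
  reads <- substring(truth, starts, starts + 99L)
  a1 <- greedy_assemble(reads)
  a2 <- greedy_assemble(rev(reads))
  a3 <- greedy_assemble(sample(reads))
  expect_identical(a1$seq, a2$seq)
  expect_identical(a1$seq, a3$seq)
  expect_identical(a1$reads_used, a2$reads_used)
})

test_that("duplicate and contained reads are collapsed", {
  set.seed(23)
  truth <- random_dna(400)
  reads <- c(truth,                       # full sequence
             substr(truth, 50, 200),      # contained
             revcomp(substr(truth, 100, 300)),  # contained, other strand
             truth,                       # duplicate
             substr(truth, 380, 400))     # short, contained
  asm <- greedy_assemble(reads, assembler_params(min_overlap = 40))
  expect_equal(length(asm), 1L)
  expect_equal(asm$seq, canon1(truth))
  expect_equal(asm$reads_used, 5)
})

test_that("trim_to truncates reads from the 3' end before assembly", {
  set.seed(24)
  truth <- random_dna(500)
  reads <- tiling_reads(truth, 100L, 20L)
  # corrupt the last 30 bases of every read
  bad <- paste0(substr(reads, 1, 70),
                vapply(rep(30, length(reads)), random_dna, character(1)))
  whole <- greedy_assemble(bad, assembler_params(min_overlap = 40))
  trimmed <- greedy_assemble(bad, assembler_params(min_overlap = 40,
                                                   trim_to = 70))
  expect_gt(length(whole), 1L)  # corrupted tails break the overlaps
  expect_equal(trimmed$seq[1L], canon1(substr(truth, 1, 470)))
})

test_that("length filter drops short contigs and can empty an assembly", {
  asm <- as_assembly(c(strrep("A", 500), strrep("C", 80), strrep("G", 30)))
  expect_equal(nchar(length_filter(asm, 100)$seq), 500L)
  expect_identical(length_filter(asm, 0), asm)
  expect_equal(length(length_filter(asm, 1000)), 0L)
  expect_equal(total_size(length_filter(asm, 1000)), 0L)
})

test_that("assembly statistics and canonical form behave", {
  asm <- as_assembly(c("ACGTACGTAC", "TTTT", "GGGGGG"))
  expect_equal(total_size(asm), 20L)
  expect_equal(longest_contig(asm), 10L)
  expect_equal(asm$id, c("contig_1", "contig_2", "contig_3"))
  flipped <- as_assembly(c("AAAA", revcomp("ACGTACGTAC"), "GGGGGG"))
  expect_identical(canonical_form(asm),
                   canonical_form(as_assembly(c("TTTT", "ACGTACGTAC",
                                                "CCCCCC"))))
  expect_identical(canonical_form(flipped)[3L],
                   canonical_form(asm)[3L])
})

test_that("assembler adapters honour the working-directory contract", {
  # built-in adapter routes to the greedy assembler
  rs <- make_reads(c("ACGTACGTAA", "CGTAACCGGT"), ids = c("x", "y"))
  asm <- run_assembler(rs, adapter = "internal",
                       params = assembler_params(min_overlap = 5))
  expect_equal(asm$seq, canon1("ACGTACGTAACCGGT"))

  expect_error(run_assembler(rs, adapter = "no_such"), "unknown")

  # adapter producing no contigs.fasta violates the contract
  register_assembler("broken", function(workdir, paired) invisible(NULL))
  expect_error(run_assembler(rs, adapter = "broken"), "contigs.fasta")

  # adapter producing an empty contigs.fasta violates the contract
  register_assembler("empty", function(workdir, paired) {
    file.create(file.path(workdir, "contigs.fasta"))
  })
  expect_error(run_assembler(rs, adapter = "empty"), "empty")

  # a well-behaved external-style adapter sees pair-aware FASTQ input
  register_assembler("passthrough", function(workdir, paired) {
    stopifnot(file.exists(file.path(workdir,
      if (paired) "reads_1.fastq" else "reads.fastq")))
    recs <- read_sequences(file.path(workdir,
      if (paired) "reads_1.fastq" else "reads.fastq"))
    write_sequences(seq_records(paste(recs$seq, collapse = ""),
                                id = "contig"),
                    file.path(workdir, "contigs.fasta"))
  })
  got <- run_assembler(rs, adapter = "passthrough")
  expect_equal(total_size(got), 20L)
  prs <- make_reads(c("ACGTACGTAA", "CGTAACCGGT"), ids = c("p/1", "p/2"),
                    pairing = "two-file", mate = c(2L, 1L))
  got2 <- run_assembler(prs, adapter = "passthrough")
  expect_equal(total_size(got2), 10L)  # only mate 1 reaches reads_1.fastq
})
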