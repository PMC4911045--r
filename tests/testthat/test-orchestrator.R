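# The main loop: thread splitting, general/specific baiting, iteration
# control, termination, and outputs.

micro_fixture <- function() {
  g <- simulate_genome(background_len = 20000, replicon_len = 5000,
                       replicon_copies = 10, tandem_unit_len = 1000,
                       tandem_copies = 3, locus_lens = c(650), seed = 7)
  rs <- simulate_reads(g, coverage = 5, seed = 8)
  list(genome = g, reads = rs)
}

test_that("split_threads maps entries to threads with criteria", {
  set.seed(80)
  refs <- seq_records(vapply(rep(60, 10), random_dna, character(1)),
                      id = paste0("t", 1:10))
  expect_length(split_threads(refs, multi = TRUE), 10L)
  expect_length(split_threads(refs[1:3, ], multi = FALSE), 1L)

  grp <- split_threads(refs, multi = TRUE,
                       grouping = list(both = c("t1", "t2")))
  expect_length(grp, 9L)
  both <- grp[[which(vapply(grp, `[[`, "", "name") == "both")]]
  expect_equal(nrow(both$refs), 2L)
  # a group name colliding with an ungrouped entry id is rejected
  expect_error(split_threads(refs, multi = TRUE,
                             grouping = list(t10 = c("t1", "t2"))),
               "duplicate thread names")

  dup <- seq_records(c("ACGTACGT", "ACGTACGT"), id = c("a", "a"))
  expect_error(split_threads(dup, multi = TRUE), "duplicate")
  expect_error(split_threads(refs, multi = TRUE,
                             grouping = list(g = "nope")), "unknown entry")

  tagged <- seq_records(c("ACGTACGT", "ACGTACGT"), id = c("a", "b"),
                        desc = c("crit=longest:500", ""))
  ths <- split_threads(tagged, multi = TRUE,
                       default_criterion = criterion("homology"))
  expect_equal(ths[[1L]]$criteria, list(criterion("longest", 500)))
  expect_equal(ths[[2L]]$criteria, list(criterion("homology")))
})

test_that("make_general_bait combines refs first, assemblies later", {
  set.seed(81)
  refs <- seq_records(vapply(rep(60, 2), random_dna, character(1)),
                      id = c("a", "b"))
  ths <- split_threads(refs, multi = TRUE)
  add <- seq_records(random_dna(50), id = "extra")
  expect_length(make_general_bait(ths, add, first_iteration = TRUE), 3L)
  expect_length(make_general_bait(ths, NULL, first_iteration = TRUE), 2L)

  ths[[1L]]$assembly <- as_assembly(c(random_dna(100), random_dna(90)))
  ths[[2L]]$assembly <- as_assembly(vapply(rep(80, 3), random_dna,
                                           character(1)))
  later <- make_general_bait(ths, add, first_iteration = FALSE)
  expect_length(later, 5L)  # additional bait is first-iteration only

  # terminated threads drop out of the general bait
  ths[[2L]]$state <- "complete"
  expect_length(make_general_bait(ths, NULL, first_iteration = FALSE), 2L)
  ths[[1L]]$state <- "stalled"
  expect_length(make_general_bait(ths, NULL, first_iteration = FALSE), 0L)
})

test_that("an exhaustive run recovers a circular replicon exactly", {
  fx <- micro_fixture()
  ref <- seq_records(diverge(substr(fx$genome$replicon, 2001, 3000),
                             0.05, seed = 9), id = "mt")
  run <- bait_assemble(ref, fx$reads,
                       default_criterion = criterion("exhaustive"))
  expect_s3_class(run, "bait_run")
  th <- run$threads[[1L]]
  expect_equal(th$state, "complete")
  expect_match(th$reason, "exhausted")
  asm <- final_assembly(run)
  cc <- circularize(asm$seq[which.max(nchar(asm$seq))])
  expect_false(is.null(cc))
  expect_equal(nchar(cc$seq), 5000L)
  expect_equal(cc$canonical, rotation_canonical(fx$genome$replicon))

  # reproducibility: identical runs give byte-identical outputs
  run2 <- bait_assemble(ref, fx$reads,
                        default_criterion = criterion("exhaustive"))
  expect_identical(final_assembly(run2)$seq, asm$seq)
})

test_that("size criteria terminate earlier than exhaustive runs", {
  fx <- micro_fixture()
  ref <- seq_records(diverge(substr(fx$genome$replicon, 2001, 3000),
                             0.05, seed = 9), id = "mt",
                     desc = "crit=total_size:3000")
  run <- bait_assemble(ref, fx$reads)
  th <- run$threads[[1L]]
  expect_equal(th$state, "complete")
  expect_match(th$reason, "total_size:3000")
  expect_gte(total_size(th$assembly), 3000L)
  ex <- bait_assemble(seq_records(diverge(substr(fx$genome$replicon, 2001,
                                                 3000), 0.05, seed = 9),
                                  id = "mt"),
                      fx$reads, default_criterion = criterion("exhaustive"))
  expect_lt(run$general$iterations, ex$general$iterations)
})

test_that("runs terminate with documented reasons on adversarial input", {
  fx <- micro_fixture()
  # a reference sharing no 31-mer with any read
  set.seed(82)
  ref <- seq_records(random_dna(500), id = "nowhere")
  run <- bait_assemble(ref, fx$reads)
  expect_equal(run$threads[[1L]]$state, "failed")
  expect_match(run$threads[[1L]]$reason, "no reads matched reference")
  expect_equal(run$general$iterations, 1L)

  # new reads that do not change the assembly: stalls, does not loop
  set.seed(83)
  tsec <- random_dna(130)
  reads <- make_reads(c(tsec, substr(tsec, 95, 125)),
                      ids = c("whole", "late"))
  ref2 <- seq_records(substr(tsec, 1, 100), id = "t",
                      desc = "crit=total_size:99999")
  run2 <- bait_assemble(ref2, reads)
  expect_equal(run2$threads[[1L]]$state, "stalled")
  expect_match(run2$threads[[1L]]$reason,
               "assembly unchanged|no new reads")
  expect_lte(run2$general$iterations, length(reads))

  # max_iterations caps a run that would continue
  mt <- seq_records(diverge(substr(fx$genome$replicon, 2001, 3000),
                            0.05, seed = 9), id = "mt")
  capped <- bait_assemble(mt, fx$reads, max_iterations = 2)
  expect_equal(capped$general$iterations, 2L)
  expect_equal(capped$threads[[1L]]$state, "stalled")
  expect_match(capped$threads[[1L]]$reason, "max iterations")
})

test_that("stall on unchanged assembly is reported when reads keep coming", {
  # T[1:130] assembles from the first read; a 31 bp read whose only k-mer
  # spans position 95-125 is recruited on iteration 2 (absent from the
  # 100 bp reference, present in the iteration-1 assembly) but is contained
  # in the existing contig, so iteration 2 changes nothing.
  set.seed(84)
  tsec <- random_dna(130)
  reads <- make_reads(c(tsec, substr(tsec, 95, 125)),
                      ids = c("whole", "late"))
  ref <- seq_records(substr(tsec, 1, 100), id = "t",
                     desc = "crit=total_size:99999")
  run <- bait_assemble(ref, reads)
  th <- run$threads[[1L]]
  expect_equal(th$state, "stalled")
  expect_equal(th$reason, "assembly unchanged")
  expect_equal(run$general$iterations, 2L)
  expect_setequal(th$ledger$names, c("whole", "late"))
})

test_that("multi-mode runs write per-thread outputs and logs", {
  fx <- micro_fixture()
  locus <- fx$genome$loci[["locus_1"]]
  # high coverage for the single-copy locus
  rs <- simulate_reads(fx$genome, coverage = 25, seed = 85)
  refs <- seq_records(
    c(diverge(substr(fx$genome$replicon, 1, 800), 0.05, seed = 86), locus),
    id = c("mt", "loc"),
    desc = c("crit=total_size:2000", "crit=homology"))
  out <- withr::local_tempdir()
  run <- bait_assemble(refs, rs, multi = TRUE, out_dir = out)
  expect_equal(vapply(run$threads, `[[`, "", "state"),
               c("complete", "complete"))
  expect_true(file.exists(file.path(out, "log.txt")))
  expect_true(file.exists(file.path(out, "mt", "final.fasta")))
  expect_true(file.exists(file.path(out, "loc", "final.fasta")))
  expect_true(file.exists(file.path(out, "loc", "final_extracted.fasta")))
  expect_true(file.exists(file.path(out, "mt", "iteration_001",
                                    "bait.fasta")))
  ext <- read_sequences(file.path(out, "loc", "final_extracted.fasta"))
  expect_equal(ext$seq, locus)
  expect_true(screen_efficiency_property(run, rs))
})
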