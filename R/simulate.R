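# Seeded synthetic genomes and paired-end read sets with the structure the
# method assumes: a large single-copy background chromosome carrying an
# embedded tandem-repeat array and single-copy loci, plus a separate
# high-copy circular replicon (the mitochondrial-genome analogue). All
# randomness is controlled by explicit seeds so every fixture is exactly
# reproducible.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n, gc = 0.5) {
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

#' Simulate a genome with embedded multi-copy and single-copy targets
#'
#' Produces a linear background chromosome into which a tandem-repeat
#' region (`tandem_copies` direct repeats of a random unit) and several
#' single-copy loci are inserted at random positions, plus a separate
#' circular replicon present at `replicon_copies` per genome. A truth
#' table records the exact 1-based inclusive coordinates of every feature.
#'
#' @param background_len length of the background chromosome before
#'   insertions (bp).
#' @param replicon_len length of the circular replicon (bp).
#' @param replicon_copies copy number of the replicon (>= 1).
#' @param tandem_unit_len length of the tandem repeat unit (bp).
#' @param tandem_copies number of tandem copies inserted as one array.
#' @param locus_lens lengths of the single-copy loci to embed.
#' @param gc GC fraction of all random sequence.
#' @param seed integer seed; the genome is fully determined by it.
#' @return a `sim_genome`: list with `chromosome`, `replicon`,
#'   `tandem_unit`, `loci` (named character vector), `truth` (data.frame
#'   of feature coordinates), and `params`.
#' @export
simulate_genome <- function(background_len = 500000L, replicon_len = 30000L,
                            replicon_copies = 20L, tandem_unit_len = 8000L,
                            tandem_copies = 10L,
                            locus_lens = c(650L, 1200L, 1800L),
                            gc = 0.5, seed = 1L) {
  stopifnot(background_len > 0L, replicon_len > 0L, tandem_unit_len > 0L,
            tandem_copies >= 1L, all(locus_lens > 0L))
  if (replicon_copies < 1L)
    stop("the replicon must be present in at least one copy")
  tandem_total <- tandem_unit_len * tandem_copies
  if (tandem_total > background_len || any(locus_lens > background_len) ||
      replicon_len > background_len)
    stop("embedded features must not be larger than the background")
  with_seed(seed, {
    background <- random_seq(background_len, gc)
    replicon <- random_seq(replicon_len, gc)
    tandem_unit <- random_seq(tandem_unit_len, gc)
    loci <- vapply(locus_lens, random_seq, character(1L), gc = gc)
    names(loci) <- paste0("locus_", seq_along(loci))

    inserts <- c(list(tandem = strrep(tandem_unit, tandem_copies)),
                 as.list(loci))
    # insertion points in the original background, kept well apart
    pts <- sort(sample.int(background_len - 1L, length(inserts)))
    chrom <- background
    truth <- data.frame(feature = character(0L), molecule = character(0L),
                        start = integer(0L), end = integer(0L),
                        copies = integer(0L), stringsAsFactors = FALSE)
    shift <- 0L
    for (i in seq_along(inserts)) {
      at <- pts[i] + shift  # insert after position `at` in current chrom
      piece <- inserts[[i]]
      chrom <- paste0(substr(chrom, 1L, at), piece,
                      substr(chrom, at + 1L, nchar(chrom)))
      truth <- rbind(truth, data.frame(
        feature = names(inserts)[i], molecule = "chromosome",
        start = at + 1L, end = at + nchar(piece),
        copies = if (names(inserts)[i] == "tandem") tandem_copies else 1L,
        stringsAsFactors = FALSE))
      shift <- shift + nchar(piece)
    }
    truth <- rbind(truth, data.frame(
      feature = "replicon", molecule = "replicon",
      start = 1L, end = replicon_len, copies = replicon_copies,
      stringsAsFactors = FALSE))
    structure(list(
      chromosome = chrom, replicon = replicon, tandem_unit = tandem_unit,
      loci = loci, truth = truth,
      params = list(background_len = background_len,
                    replicon_len = replicon_len,
                    replicon_copies = replicon_copies,
                    tandem_unit_len = tandem_unit_len,
                    tandem_copies = tandem_copies,
                    locus_lens = locus_lens, gc = gc, seed = seed)),
      class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> chromosome %d bp; replicon %d bp x%d; tandem unit %d bp x%d; %d loci\n",
    nchar(x$chromosome), nchar(x$replicon), x$params$replicon_copies,
    x$params$tandem_unit_len, x$params$tandem_copies, length(x$loci)))
  invisible(x)
}

#' Simulate paired-end reads from a simulated genome
#'
#' Fragments are drawn uniformly per molecule copy, so multi-copy features
#' (the replicon, the tandem array) are proportionally over-covered, as in
#' real whole-genome data. Fragments from the circular replicon may span
#' its origin. `coverage` is the per-copy (single-copy) depth: a feature
#' with copy number c receives c times that depth.
#'
#' @param genome a [simulate_genome()] result.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment (insert) size distribution.
#' @param coverage per-copy fold coverage (> 0).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a [read_set()] of interleaved mate pairs; the attribute
#'   `"sim_truth"` records each pair's source molecule, start, and insert
#'   length.
#' @export
simulate_reads <- function(genome, read_len = 100L, insert_mean = 300L,
                           insert_sd = 30L, coverage = 2.5,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"))
  if (coverage <= 0) stop("coverage must be positive")
  if (read_len > insert_mean)
    stop("read_len must not exceed the mean insert size")
  chrom_len <- nchar(genome$chromosome)
  rep_len <- nchar(genome$replicon)
  copies <- genome$params$replicon_copies
  gsize <- chrom_len + rep_len * copies
  n_pairs <- round(gsize * coverage / (2 * read_len))
  with_seed(seed, {
    mol <- sample(c("chromosome", "replicon"), n_pairs, replace = TRUE,
                  prob = c(chrom_len, rep_len * copies))
    ins <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- pmin(ins, ifelse(mol == "chromosome", chrom_len, rep_len))
    start <- integer(n_pairs)
    is_chr <- mol == "chromosome"
    n_chr <- sum(is_chr)
    # linear: fragment fully inside; circular: start anywhere, may wrap
    start[is_chr] <- floor(runif(n_chr) *
                             (chrom_len - ins[is_chr] + 1L)) + 1L
    start[!is_chr] <- floor(runif(n_pairs - n_chr) * rep_len) + 1L
    frag <- character(n_pairs)
    frag[is_chr] <- substring(genome$chromosome, start[is_chr],
                              start[is_chr] + ins[is_chr] - 1L)
    if (any(!is_chr)) {
      rep2 <- paste0(genome$replicon, genome$replicon)
      frag[!is_chr] <- substring(rep2, start[!is_chr],
                                 start[!is_chr] + ins[!is_chr] - 1L)
    }
    r1 <- substring(frag, 1L, read_len)
    r2 <- revcomp(substring(frag, ins - read_len + 1L, ins))
    if (error_rate > 0) {
      r1 <- mutate_seqs(r1, error_rate)
      r2 <- mutate_seqs(r2, error_rate)
    }
    ids <- sprintf("sim_%06d", seq_len(n_pairs))
    recs <- seq_records(
      seq = as.vector(rbind(r1, r2)),
      id = as.vector(rbind(paste0(ids, "/1"), paste0(ids, "/2"))),
      qual = strrep("I", read_len))
    mate <- as.vector(rbind(seq(2L, 2L * n_pairs, by = 2L),
                            seq(1L, 2L * n_pairs, by = 2L)))
    rs <- read_set(recs, pairing = "interleaved", mate = mate)
    attr(rs, "sim_truth") <- data.frame(
      pair = ids, molecule = mol, start = start, insert = ins,
      stringsAsFactors = FALSE)
    rs
  })
}

# independent per-base substitutions to a different base
mutate_seqs <- function(seqs, rate) {
  nmut <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(nmut > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(chars), nmut[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Diverge a sequence to emulate a related species
#'
#' Applies seeded point substitutions and short (1--3 bp) indels at the
#' given per-base rates; used to manufacture cross-species references and
#' queries for the homology and seeding scenarios.
#'
#' @param seq a single sequence.
#' @param sub_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base probability of starting a 1--3 bp insertion
#'   or deletion.
#' @param seed integer seed.
#' @return the diverged sequence (a single string).
#' @export
diverge <- function(seq, sub_rate, indel_rate = 0, seed = 1L) {
  seq <- single_seq(seq)
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (sub_rate > 0) {
      hit <- which(runif(length(chars)) < sub_rate)
      for (p in hit)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    if (indel_rate > 0) {
      out <- character(0L)
      i <- 1L
      n <- length(chars)
      while (i <= n) {
        if (runif(1L) < indel_rate) {
          len <- sample.int(3L, 1L)
          if (runif(1L) < 0.5) {  # insertion before position i
            out <- c(out, sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     chars[i])
            i <- i + 1L
          } else {                # deletion of up to `len` bases
            i <- i + len
          }
        } else {
          out <- c(out, chars[i])
          i <- i + 1L
        }
      }
      chars <- out
    }
    paste(chars, collapse = "")
  })
}
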