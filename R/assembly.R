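# De novo assembly of recruited reads: a deterministic greedy exact-overlap
# assembler, the contig length filter, and the adapter contract through
# which external assemblers can be plugged in.

#' Assembler parameters
#'
#' @param min_overlap minimum exact suffix-prefix overlap (bp) for merging
#'   two sequences (default 40).
#' @param min_contig contigs shorter than this are dropped by the length
#'   filter before completion testing and re-baiting; 0 disables the filter.
#' @param trim_to optional length (bp) to which reads are truncated from the
#'   3' end before assembly; useful when low-quality read tails break exact
#'   overlaps.
#' @return an `assembler_params` object.
#' @export
assembler_params <- function(min_overlap = 40L, min_contig = 0L,
                             trim_to = NULL) {
  min_overlap <- as.integer(min_overlap)
  min_contig <- as.integer(min_contig)
  stopifnot(min_overlap >= 1L, min_contig >= 0L)
  if (!is.null(trim_to)) {
    trim_to <- as.integer(trim_to)
    stopifnot(trim_to >= 1L)
  }
  structure(list(min_overlap = min_overlap, min_contig = min_contig,
                 trim_to = trim_to), class = "assembler_params")
}

new_assembly <- function(seq, reads_used = rep(NA_real_, length(seq))) {
  seq <- as.character(seq)
  o <- order(-nchar(seq), seq)
  seq <- seq[o]
  reads_used <- reads_used[o]
  structure(list(id = if (length(seq)) paste0("contig_", seq_along(seq))
                 else character(0L),
                 seq = seq, reads_used = as.numeric(reads_used)),
            class = "assembly")
}

#' Coerce contig sequences to an assembly object
#'
#' @param seq character vector of contig sequences.
#' @param reads_used optional per-contig read counts.
#' @return an `assembly` object; contigs are named `contig_1..n` by
#'   decreasing length.
#' @export
as_assembly <- function(seq, reads_used = rep(NA_real_, length(seq))) {
  new_assembly(clean_seq(seq), reads_used)
}

#' @export
length.assembly <- function(x) length(x$seq)

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d contig(s), total %d bp, longest %d bp\n",
              length(x), total_size(x),
              if (length(x)) longest_contig(x) else 0L))
  invisible(x)
}

#' Total assembly size in bp
#' @param asm an assembly.
#' @return integer.
#' @export
total_size <- function(asm) {
  stopifnot(inherits(asm, "assembly"))
  sum(nchar(asm$seq))
}

#' Length of the longest contig
#' @param asm an assembly.
#' @return integer (0 for an empty assembly).
#' @export
longest_contig <- function(asm) {
  stopifnot(inherits(asm, "assembly"))
  if (length(asm) == 0L) return(0L)
  max(nchar(asm$seq))
}

#' Orientation-canonical comparison form of an assembly
#'
#' The sorted multiset of per-contig canonical sequences (each the
#' lexicographic minimum of the contig and its reverse complement).
#' Assemblies that differ only by contig order or strand compare equal on
#' this form, which is how "no new information" is detected across
#' iterations.
#'
#' @param asm an assembly.
#' @return sorted character vector.
#' @export
canonical_form <- function(asm) {
  stopifnot(inherits(asm, "assembly"))
  if (length(asm) == 0L) return(character(0L))
  rc <- revcomp(asm$seq)
  sort(pmin(asm$seq, rc))
}

#' Greedy exact-overlap assembly
#'
#' Collapses duplicate and contained reads, then repeatedly merges the pair
#' of sequences with the longest exact suffix-prefix overlap of at least
#' `min_overlap` bp, considering both orientations; ties on overlap length
#' break on the canonical form of the merged sequence, so the result is a
#' function of the input read multiset only, independent of input order.
#' Unmerged sequences are emitted as singleton contigs. Pairing information
#' is not used at this stage (it contributes to recruitment only).
#'
#' @param reads a [read_set()], [seq_records()], or character vector.
#' @param params an [assembler_params()].
#' @return an `assembly`; contigs are named `contig_1..n` by decreasing
#'   length.
#' @export
greedy_assemble <- function(reads, params = assembler_params()) {
  stopifnot(inherits(params, "assembler_params"))
  seqs <- unname(as_seq_vector(reads))
  if (length(seqs) == 0L) stop("no reads to assemble")
  if (!is.null(params$trim_to))
    seqs <- substr(seqs, 1L, params$trim_to)
  res <- .greedy_assemble_cpp(seqs, params$min_overlap)
  new_assembly(res$seq, res$reads_used)
}

#' Drop contigs below a minimum length
#'
#' The filtered assembly is what feeds completion testing and the next
#' bait file; keeping repeat-induced short contigs out of the bait stops
#' repeats from dragging in unrelated reads.
#'
#' @param asm an assembly.
#' @param min_contig minimum contig length in bp (0 = no filtering).
#' @return the filtered assembly (possibly empty).
#' @export
length_filter <- function(asm, min_contig) {
  stopifnot(inherits(asm, "assembly"))
  min_contig <- as.integer(min_contig)
  if (min_contig <= 0L) return(asm)
  keep <- nchar(asm$seq) >= min_contig
  new_assembly(asm$seq[keep], asm$reads_used[keep])
}

# ---------------------------------------------------------------------------
# assembler adapters

.assemblers <- new.env(parent = emptyenv())

#' Register an assembler adapter
#'
#' An adapter is a function `function(workdir, paired)` run in a working
#' directory where the recruited reads have been written as FASTQ
#' (`reads.fastq`, or `reads_1.fastq`/`reads_2.fastq` when pairing is
#' declared); it must deposit its contigs as `contigs.fasta` in that
#' directory. The built-in adapter `"internal"` bypasses the directory
#' contract and calls [greedy_assemble()] directly.
#'
#' @param name adapter name.
#' @param fun the adapter function.
#' @param internal if `TRUE`, `fun` is called as
#'   `fun(reads, params)` in memory and must return an assembly.
#' @return `name`, invisibly.
#' @export
register_assembler <- function(name, fun, internal = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, list(fun = fun, internal = internal), envir = .assemblers)
  invisible(name)
}

#' Run a (possibly external) assembler through the adapter contract
#'
#' @param reads a [read_set()].
#' @param adapter registered adapter name (default `"internal"`).
#' @param params an [assembler_params()].
#' @param workdir working directory for non-internal adapters (a temporary
#'   directory by default).
#' @return an `assembly`.
#' @export
run_assembler <- function(reads, adapter = "internal",
                          params = assembler_params(), workdir = NULL) {
  if (!exists(adapter, envir = .assemblers, inherits = FALSE))
    stop("unknown assembler adapter: '", adapter, "'")
  entry <- get(adapter, envir = .assemblers, inherits = FALSE)
  if (entry$internal) return(entry$fun(reads, params))
  if (is.null(workdir)) {
    workdir <- tempfile("asm_work_")
    on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(inherits(reads, "read_set"))
  if (reads$pairing == "single" || all(is.na(reads$mate))) {
    write_sequences(reads, file.path(workdir, "reads.fastq"),
                    format = "fastq")
  } else {
    idx <- seq_len(length(reads))
    first <- !is.na(reads$mate) & idx < reads$mate
    unpaired <- is.na(reads$mate)
    r1 <- which(first | unpaired)
    r2 <- reads$mate[first]
    rec1 <- reads$records[r1, , drop = FALSE]
    rec2 <- reads$records[r2, , drop = FALSE]
    class(rec1) <- class(rec2) <- c("seq_records", "data.frame")
    write_sequences(rec1, file.path(workdir, "reads_1.fastq"),
                    format = "fastq")
    write_sequences(rec2, file.path(workdir, "reads_2.fastq"),
                    format = "fastq")
  }
  entry$fun(workdir, paired = reads$pairing != "single")
  out <- file.path(workdir, "contigs.fasta")
  if (!file.exists(out))
    stop("assembler adapter '", adapter, "' did not produce contigs.fasta")
  contigs <- tryCatch(read_sequences(out, format = "fasta"),
                      error = function(e) NULL)
  if (is.null(contigs) || nrow(contigs) == 0L)
    stop("assembler adapter '", adapter,
         "' produced an empty or unreadable contigs.fasta")
  new_assembly(contigs$seq)
}

# default adapter: the built-in greedy assembler
register_assembler("internal",
                   function(reads, params) greedy_assemble(reads, params),
                   internal = TRUE)
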