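# k-mer baiting: an exact, strand-symmetric k-mer membership index over the
# current bait sequences, and read recruitment against it.

#' Build a k-mer bait index
#'
#' Indexes the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every length-`k` window over A/C/G/T of every
#' bait sequence, so membership is strand-symmetric. Windows containing N
#' are skipped.
#'
#' @param baits bait sequences: a character vector, [seq_records()] table,
#'   or [read_set()].
#' @param k k-mer length (1--31); 31 matches the seeding behaviour the
#'   method was designed around.
#' @return a `bait_index` object.
#' @export
bait_index <- function(baits, k = 31L) {
  seqs <- as_seq_vector(baits)
  k <- as.integer(k)
  ptr <- .kmer_index_build(seqs, k)
  if (length(seqs) > 0L && all(nchar(seqs) < k))
    warning("all bait sequences are shorter than k = ", k,
            "; the index is empty", call. = FALSE)
  structure(list(ptr = ptr, k = k), class = "bait_index")
}

as_seq_vector <- function(x) {
  if (inherits(x, "read_set")) x <- x$records
  if (inherits(x, "seq_records")) {
    out <- x$seq
    names(out) <- x$id
    return(out)
  }
  if (inherits(x, "assembly")) {
    out <- x$seq
    names(out) <- x$id
    return(out)
  }
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Number of distinct canonical k-mers in a bait index
#' @param index a [bait_index()].
#' @return integer count.
#' @export
n_kmers <- function(index) {
  stopifnot(inherits(index, "bait_index"))
  .kmer_index_size(index$ptr)
}

#' Test k-mers for index membership
#'
#' @param index a [bait_index()].
#' @param kmers character vector of length-`k` strings (either strand).
#' @return logical vector.
#' @export
has_kmer <- function(index, kmers) {
  stopifnot(inherits(index, "bait_index"))
  .kmer_index_has(index$ptr, toupper(as.character(kmers)))
}

#' @export
print.bait_index <- function(x, ...) {
  cat(sprintf("<bait_index> k = %d, %d canonical k-mers\n",
              x$k, as.integer(n_kmers(x))))
  invisible(x)
}

#' Recruit reads sharing k-mers with the bait
#'
#' A read is recruited when at least `min_hits` of its k-windows (on either
#' strand) are present in the index. Reads shorter than `k` never match.
#'
#' @param reads a [read_set()], [seq_records()], or character vector (named
#'   to supply read ids).
#' @param index a [bait_index()].
#' @param min_hits minimum number of matching k-windows (default 1).
#' @return character vector of recruited read ids.
#' @export
screen <- function(reads, index, min_hits = 1L) {
  stopifnot(inherits(index, "bait_index"))
  seqs <- as_seq_vector(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  hits <- .kmer_index_hits(index$ptr, unname(seqs))
  ids[hits >= min_hits]
}

#' Close a set of read ids under mate pairing
#'
#' When pairing information is available, the mate of every recruited read
#' is recruited too: a mate anchored next to the target region extends the
#' recruited set beyond the current assembly ends, which is how pairing
#' information accelerates target growth.
#'
#' @param ids character vector of read ids.
#' @param reads the [read_set()] the ids refer to.
#' @return character vector: `ids` plus all their mates.
#' @export
expand_with_mates <- function(ids, reads) {
  stopifnot(inherits(reads, "read_set"))
  if (length(ids) == 0L) return(character(0L))
  idx <- match(ids, reads$records$id)
  if (anyNA(idx))
    stop("internal error: unknown read id: ", ids[which(is.na(idx))[1L]])
  mates <- reads$mate[idx]
  mates <- mates[!is.na(mates)]
  unique(c(ids, reads$records$id[mates]))
}

#' Create an empty recruitment ledger
#'
#' A ledger accumulates the read names recruited for one scope (the general
#' pool or one target thread) across iterations; names only ever grow, and
#' `new_this_iteration` signals whether the last update added any.
#'
#' @return a `recruit_ledger` object.
#' @export
new_ledger <- function() {
  structure(list(names = character(0L), new_this_iteration = FALSE),
            class = "recruit_ledger")
}

#' Add recruited read names to a ledger
#'
#' @param ledger a [new_ledger()] object.
#' @param ids character vector of read ids recruited this iteration.
#' @return the updated ledger; `new_this_iteration` is `TRUE` iff the name
#'   set grew.
#' @export
update_ledger <- function(ledger, ids) {
  stopifnot(inherits(ledger, "recruit_ledger"))
  before <- length(ledger$names)
  ledger$names <- unique(c(ledger$names, ids))
  ledger$new_this_iteration <- length(ledger$names) > before
  ledger
}
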