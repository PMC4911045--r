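# Circularization helpers: a circular molecule (or a tandem-repeat unit,
# which behaves like one) assembled linearly carries a duplicated junction
# -- its two ends are identical over the junction length. These helpers
# detect such end overlaps and trim or join accordingly.

#' Longest identical end overlap of a sequence
#'
#' The longest prefix of `seq` that is also its suffix, if at least
#' `min_len` bp; overlaps are capped at half the sequence length so that
#' repetitive sequences do not trivially match themselves.
#'
#' @param seq a single sequence.
#' @param min_len minimum overlap length in bp (default 20).
#' @return overlap length in bp, or 0 if none qualifies.
#' @export
find_end_overlap <- function(seq, min_len = 20L) {
  seq <- single_seq(seq)
  .end_overlap_cpp(seq, as.integer(min_len))
}

#' Circularize a contig by trimming its duplicated end overlap
#'
#' @param seq a single sequence.
#' @param min_len minimum end overlap to accept as a junction (default 20).
#' @return `NULL` when the ends do not overlap by at least `min_len`;
#'   otherwise a list with `seq` (the sequence with the terminal overlap
#'   removed), `overlap` (bp trimmed), `circular = TRUE`, and `canonical`
#'   (the [rotation_canonical()] form for comparisons).
#' @export
circularize <- function(seq, min_len = 20L) {
  seq <- single_seq(seq)
  ov <- .end_overlap_cpp(seq, as.integer(min_len))
  if (ov == 0L) return(NULL)
  out <- substr(seq, 1L, nchar(seq) - ov)
  list(seq = out, overlap = ov, circular = TRUE,
       canonical = rotation_canonical(out))
}

#' Merge two contigs on an identical end overlap
#'
#' Finds the longest exact suffix(a)/prefix(b) overlap of at least
#' `min_len` bp over both orientations of `b` and returns the merged
#' sequence; the merge is symmetric in its arguments up to orientation.
#'
#' @param a,b single sequences.
#' @param min_len minimum overlap length (default 20).
#' @return the merged sequence, or `NULL` when no overlap qualifies.
#' @export
merge_pair <- function(a, b, min_len = 20L) {
  a <- single_seq(a)
  b <- single_seq(b)
  min_len <- as.integer(min_len)
  o_f <- .suffix_prefix_cpp(a, b, min_len)
  b_rc <- revcomp(b)
  o_r <- .suffix_prefix_cpp(a, b_rc, min_len)
  if (o_f == 0L && o_r == 0L) return(NULL)
  if (o_f >= o_r) {
    paste0(a, substr(b, o_f + 1L, nchar(b)))
  } else {
    paste0(a, substr(b_rc, o_r + 1L, nchar(b_rc)))
  }
}
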