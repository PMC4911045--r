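#' Reverse complement
#'
#' @param x character vector of DNA sequences over A, C, G, T, N.
#' @return character vector of reverse complements; names are preserved.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  out <- .revcomp_cpp(as.character(x))
  names(out) <- names(x)
  out
}

# Uppercase and map every character outside {A,C,G,T,N} (lowercase handled
# by the uppercasing; other IUPAC ambiguity codes, gaps) to N. The k-mer
# index is defined over {A,C,G,T} only.
clean_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Rotation-canonical form of a (circular) sequence
#'
#' The lexicographically least string among all rotations of the sequence
#' and all rotations of its reverse complement. Two assemblies of the same
#' circular molecule that differ by rotation and/or strand have identical
#' rotation-canonical forms, which makes this the natural comparison form
#' for circularized products.
#'
#' @param seq a single DNA sequence.
#' @return a single string.
#' @export
rotation_canonical <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  f <- .least_rotation_cpp(seq)
  r <- .least_rotation_cpp(revcomp(seq))
  if (r < f) r else f
}
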