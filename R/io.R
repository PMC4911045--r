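# FASTA/FASTQ input and output, read sets with pairing, and completion
# criterion tags embedded in reference description lines.

#' Construct a sequence record table
#'
#' The package's in-memory representation of FASTA/FASTQ records: a
#' data.frame with columns `id` (first whitespace-delimited token of the
#' header), `desc` (remainder of the header, possibly empty), `seq`
#' (uppercase, alphabet A/C/G/T/N) and `qual` (per-base quality string,
#' `NA` for FASTA records).
#'
#' @param seq character vector of sequences.
#' @param id character vector of record ids (defaults to `seq1`, `seq2`, ...).
#' @param desc character vector of description strings.
#' @param qual optional character vector of quality strings (same lengths
#'   as `seq`).
#' @return a `seq_records` data.frame.
#' @export
seq_records <- function(seq, id = NULL, desc = "", qual = NA_character_) {
  seq <- clean_seq(as.character(seq))
  n <- length(seq)
  if (is.null(id)) id <- paste0("seq", seq_len(n))
  id <- as.character(id)
  desc <- rep_len(as.character(desc), n)
  qual <- rep_len(as.character(qual), n)
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  bad <- which(!is.na(qual) & nchar(qual) != nchar(seq))
  if (length(bad))
    stop("quality length differs from sequence length for record ", bad[1L])
  structure(
    data.frame(id = id, desc = desc, seq = seq, qual = qual,
               stringsAsFactors = FALSE),
    class = c("seq_records", "data.frame"))
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Sequences are uppercased on input and characters outside A/C/G/T/N
#' (including IUPAC ambiguity codes other than N) are replaced by N.
#' Multi-line FASTA is accepted.
#'
#' @param path file path.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (detect from the first
#'   character: `>` for FASTA, `@` for FASTQ).
#' @return a [seq_records()] data.frame in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    if (identical(first, ">")) format <- "fasta"
    else if (identical(first, "@")) format <- "fastq"
    else stop("cannot detect sequence format of ", path,
              " (first character is neither '>' nor '@')")
  }
  if (format == "fasta") {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    headers <- names(x)
    qual <- rep(NA_character_, length(x))
  } else {
    # strict 4-line FASTQ (Biostrings tolerates malformed quality lines)
    lines <- readLines(path)
    if (length(lines) == 0L || length(lines) %% 4L != 0L)
      stop("parse error in ", path,
           ": FASTQ line count is not a multiple of 4")
    l1 <- lines[seq(1L, length(lines), by = 4L)]
    sq <- lines[seq(2L, length(lines), by = 4L)]
    l3 <- lines[seq(3L, length(lines), by = 4L)]
    qual <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(!startsWith(l1, "@") | !startsWith(l3, "+"))
    if (length(bad))
      stop("parse error in ", path, ": malformed FASTQ record ", bad[1L])
    bad <- which(nchar(qual) != nchar(sq))
    if (length(bad))
      stop("parse error in ", path, ": quality length differs from ",
           "sequence length for record ", bad[1L])
    headers <- sub("^@", "", l1)
    x <- sq
  }
  headers[is.na(headers)] <- ""
  id <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S*\\s*", "", headers)
  if (any(!nzchar(id)))
    stop("parse error in ", path, ": empty id for record ",
         which(!nzchar(id))[1L])
  seq_records(seq = as.character(x), id = id, desc = desc, qual = qual)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA output is wrapped at 70 columns. Records without quality strings
#' are written to FASTQ with a constant quality of `I`.
#'
#' @param records a [seq_records()] data.frame or a `read_set`.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (inherits(records, "read_set")) records <- records$records
  headers <- ifelse(nzchar(records$desc),
                    paste(records$id, records$desc), records$id)
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- headers
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  } else {
    qual <- records$qual
    missing_q <- is.na(qual)
    qual[missing_q] <- vapply(nchar(records$seq[missing_q]),
                              function(n) strrep("I", n), character(1L))
    q <- Biostrings::BStringSet(qual)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Construct a read set
#'
#' A read set couples sequence records with a pairing declaration and a
#' symmetric, irreflexive mate mapping (stored as record indices).
#'
#' @param records a [seq_records()] data.frame.
#' @param pairing `"single"`, `"two-file"`, or `"interleaved"`.
#' @param mate integer vector of mate indices (`NA` for unpaired records).
#' @return a `read_set` object.
#' @export
read_set <- function(records, pairing = "single", mate = NULL) {
  stopifnot(inherits(records, "seq_records"))
  n <- nrow(records)
  if (anyDuplicated(records$id))
    stop("duplicate read id: ",
         records$id[duplicated(records$id)][1L])
  if (is.null(mate)) mate <- rep(NA_integer_, n)
  stopifnot(length(mate) == n)
  ok <- !is.na(mate)
  if (any(mate[ok] == seq_len(n)[ok])) stop("a read cannot be its own mate")
  if (any(ok) && !all(mate[mate[ok]] == seq_len(n)[ok]))
    stop("mate mapping is not symmetric")
  structure(list(records = records, pairing = pairing, mate = mate),
            class = "read_set")
}

#' @export
length.read_set <- function(x) nrow(x$records)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%s pairing, %d mate pairs)\n",
              length(x), x$pairing, sum(!is.na(x$mate)) %/% 2L))
  invisible(x)
}

#' Load reads from one or more FASTA/FASTQ files
#'
#' In `"two-file"` mode paths are taken pairwise (file 1 with file 2, file 3
#' with file 4, ...) and the i-th read of the first file of a pair is mated
#' with the i-th read of the second; the files of a pair must contain equal
#' numbers of reads. In `"interleaved"` mode consecutive reads within each
#' file are mated. Read ids must be unique within a file; trailing `/1` and
#' `/2` suffixes are ignored for mate bookkeeping but retained in output.
#'
#' @param paths character vector of file paths.
#' @param paired `"single"`, `"two-file"`, or `"interleaved"`.
#' @param format passed to [read_sequences()].
#' @return a [read_set()].
#' @export
load_reads <- function(paths, paired = c("single", "two-file", "interleaved"),
                       format = "auto") {
  paired <- match.arg(paired)
  if (paired == "two-file" && length(paths) %% 2L != 0L)
    stop("two-file pairing requires an even number of read files")
  recs <- lapply(paths, read_sequences, format = format)
  for (i in seq_along(recs)) {
    if (anyDuplicated(recs[[i]]$id))
      stop("duplicate read id in ", paths[i], ": ",
           recs[[i]]$id[duplicated(recs[[i]]$id)][1L])
  }
  counts <- vapply(recs, nrow, integer(1L))
  all <- do.call(rbind, recs)
  class(all) <- c("seq_records", "data.frame")
  n <- nrow(all)
  mate <- rep(NA_integer_, n)
  if (paired == "two-file") {
    offset <- 0L
    for (i in seq(1L, length(recs), by = 2L)) {
      n1 <- counts[i]; n2 <- counts[i + 1L]
      if (n1 != n2)
        stop("mate files ", paths[i], " and ", paths[i + 1L],
             " contain unequal read counts (", n1, " vs ", n2, ")")
      idx1 <- offset + seq_len(n1)
      idx2 <- offset + n1 + seq_len(n2)
      mate[idx1] <- idx2
      mate[idx2] <- idx1
      offset <- offset + n1 + n2
    }
  } else if (paired == "interleaved") {
    offset <- 0L
    for (i in seq_along(recs)) {
      ni <- counts[i]
      if (ni %% 2L != 0L)
        stop("interleaved file ", paths[i], " has an odd number of reads")
      odd <- offset + seq(1L, ni, by = 2L)
      mate[odd] <- odd + 1L
      mate[odd + 1L] <- odd
      offset <- offset + ni
    }
  }
  read_set(all, pairing = paired, mate = mate)
}

#' Subset a read set by read ids
#'
#' Record order, qualities, and pairing (restricted to the selected ids)
#' are preserved.
#'
#' @param reads a [read_set()].
#' @param ids character vector of read ids; must all be present.
#' @return a [read_set()].
#' @export
extract_reads <- function(reads, ids) {
  stopifnot(inherits(reads, "read_set"))
  idx <- match(ids, reads$records$id)
  if (anyNA(idx))
    stop("internal error: unknown read id: ", ids[which(is.na(idx))[1L]])
  keep <- sort(unique(idx))
  recs <- reads$records[keep, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("seq_records", "data.frame")
  pos <- integer(length(reads$mate))
  pos[keep] <- seq_along(keep)
  mate <- reads$mate[keep]
  mate_new <- ifelse(!is.na(mate) & mate %in% keep, pos[mate], NA_integer_)
  read_set(recs, pairing = reads$pairing, mate = as.integer(mate_new))
}

# ---------------------------------------------------------------------------
# completion criteria

.criterion_kinds <- c("exhaustive", "total_size", "longest", "n50", "homology")

#' Completion criterion specification
#'
#' @param kind one of `"exhaustive"`, `"total_size"`, `"longest"`, `"n50"`,
#'   `"homology"`.
#' @param threshold positive integer threshold in bp; required for the size
#'   criteria (`total_size`, `longest`, `n50`) and forbidden otherwise.
#' @return a `criterion` object.
#' @export
criterion <- function(kind, threshold = NULL) {
  kind <- match.arg(kind, .criterion_kinds)
  needs <- kind %in% c("total_size", "longest", "n50")
  if (needs) {
    if (is.null(threshold) || length(threshold) != 1L || is.na(threshold) ||
        !is.numeric(threshold) || threshold != trunc(threshold) ||
        threshold <= 0)
      stop("criterion '", kind, "' requires a positive integer threshold")
    threshold <- as.integer(threshold)
  } else {
    if (!is.null(threshold))
      stop("criterion '", kind, "' does not take a threshold")
    threshold <- NULL
  }
  structure(list(kind = kind, threshold = threshold), class = "criterion")
}

#' @export
format.criterion <- function(x, ...) {
  if (is.null(x$threshold)) x$kind else paste0(x$kind, ":", x$threshold)
}

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion>", format(x), "\n")
  invisible(x)
}

#' Parse completion criterion tags from a description line
#'
#' Reference entries may carry per-target completion criteria in their
#' FASTA description as `crit=<kind>` or `crit=<kind>:<threshold>` tokens,
#' several of which may be joined with `;` (OR semantics: the target is
#' complete when any criterion is met). Text around the tags is ignored, so
#' the tags coexist with free-form descriptions.
#'
#' @param description the description string (header text after the id).
#' @param default a [criterion()] used when no tag is present.
#' @return a list of [criterion()] objects.
#' @examples
#' parse_criterion_tag("mt target crit=exhaustive", criterion("homology"))
#' parse_criterion_tag("crit=longest:50000;crit=n50:40000",
#'                     criterion("exhaustive"))
#' @export
parse_criterion_tag <- function(description, default = criterion("exhaustive")) {
  stopifnot(inherits(default, "criterion"))
  if (is.na(description)) description <- ""
  m <- gregexpr("crit=[^;[:space:]]+", description)[[1L]]
  if (m[1L] == -1L) return(list(default))
  tokens <- regmatches(description, list(m))[[1L]]
  lapply(tokens, function(tok) {
    body <- sub("^crit=", "", tok)
    parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
    kind <- parts[1L]
    if (!kind %in% .criterion_kinds)
      stop("unknown completion criterion kind: '", kind, "'")
    if (length(parts) == 1L) return(criterion(kind))
    thr <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(thr) || thr != trunc(thr) || thr <= 0)
      stop("invalid criterion threshold in tag '", tok,
           "': must be a positive integer")
    criterion(kind, thr)
  })
}
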