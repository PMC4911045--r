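# Homology matching ("full-length query" completion): semi-global alignment
# of a query against contigs -- global in the query, free end gaps in the
# target -- and extraction of the matched region in query orientation.

#' Semi-global alignment of a query against a target sequence
#'
#' Affine-gap dynamic programming (match +1, mismatch -2, gap open -4, gap
#' extend -1; a gap of length L costs 4 + L), global in the query with free
#' leading/trailing target positions. Terminal query gaps are permitted but
#' scored, so a target that covers only part of the query yields a partial
#' result whose `query_aligned` grows as the assembly extends. Both target
#' strands are tried and the better score kept (ties prefer `+`).
#'
#' Coordinates are 0-based half-open on the forward strand of the target.
#'
#' @param query a single sequence (string or one-row [seq_records()]).
#' @param target a single sequence, typically a contig.
#' `query_aligned` counts the query bases actually aligned to target bases
#' (match/mismatch columns); `full_query` is `TRUE` when the alignment path
#' spans the query from its first to its last base without terminal query
#' gaps. `identity` is the fraction of matching columns over all columns of
#' that span, internal gap columns included.
#'
#' @return a `match_result`: list with `contig_id`, `strand`,
#'   `target_start`, `target_end`, `query_aligned`, `identity`,
#'   `full_query`, and `score`.
#' @export
semiglobal_align <- function(query, target) {
  q <- single_seq(query)
  t_fwd <- single_seq(target)
  tid <- single_id(target)
  a_f <- .sg_align_cpp(q, t_fwd)
  a_r <- .sg_align_cpp(q, revcomp(t_fwd))
  if (a_r$score > a_f$score) {
    n <- nchar(t_fwd)
    res <- a_r
    strand <- "-"
    ts <- n - res$target_end
    te <- n - res$target_start
  } else {
    res <- a_f
    strand <- "+"
    ts <- res$target_start
    te <- res$target_end
  }
  structure(list(
    contig_id = tid,
    strand = strand,
    target_start = ts,
    target_end = te,
    query_aligned = res$query_aligned,
    identity = if (res$columns > 0) res$matches / res$columns else 0,
    full_query = res$full_query,
    score = res$score,
    query_len = nchar(q)), class = "match_result")
}

single_seq <- function(x) {
  if (inherits(x, "seq_records")) {
    stopifnot(nrow(x) == 1L)
    return(x$seq)
  }
  x <- as.character(x)
  stopifnot(length(x) == 1L, nzchar(x))
  unname(x)
}

single_id <- function(x) {
  if (inherits(x, "seq_records")) return(x$id)
  nm <- names(x)
  if (!is.null(nm) && nzchar(nm[1L])) nm[1L] else NA_character_
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %s strand %s [%d,%d) identity %.3f query %d/%d%s\n",
    if (is.na(x$contig_id)) "?" else x$contig_id, x$strand,
    x$target_start, x$target_end, x$identity,
    x$query_aligned, x$query_len,
    if (x$full_query) " (full query)" else ""))
  invisible(x)
}

#' Best homology match of a query across an assembly
#'
#' Aligns the query against every contig (both strands) and returns the
#' best result. The match is *completing* -- satisfying the homology
#' completion criterion -- when the alignment spans the whole query
#' (`full_query`), at least 95% of the query bases are aligned to target
#' bases (so short internal indels are tolerated but a contig covering
#' only part of the query is not mistaken for a full match), and identity
#' is at least `min_identity`; otherwise the result with the most aligned
#' query bases is returned for progress tracking, flagged
#' `completing = FALSE`.
#'
#' @param query a single query sequence.
#' @param asm an assembly.
#' @param min_identity identity gate for a completing match (default 0.5);
#'   excludes degenerate full-length alignments of unrelated sequences.
#' @return a `match_result` with an added `completing` flag, or `NULL` for
#'   an empty assembly.
#' @export
best_match <- function(query, asm, min_identity = 0.5) {
  stopifnot(inherits(asm, "assembly"))
  if (length(asm) == 0L) return(NULL)
  results <- lapply(seq_along(asm$seq), function(i) {
    m <- semiglobal_align(query, asm$seq[i])
    m$contig_id <- asm$id[i]
    m
  })
  completing <- vapply(results, function(m)
    m$full_query && m$identity >= min_identity &&
      m$query_aligned >= 0.95 * m$query_len, logical(1L))
  if (any(completing)) {
    cand <- results[completing]
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1L), "score"))]]
    best$completing <- TRUE
  } else {
    qa <- vapply(results, `[[`, numeric(1L), "query_aligned")
    sc <- vapply(results, `[[`, numeric(1L), "score")
    best <- results[[order(-qa, -sc)[1L]]]
    best$completing <- FALSE
  }
  best
}

#' Extract the matched region from an assembly in query orientation
#'
#' @param match a completing [best_match()]/[semiglobal_align()] result
#'   (`full_query` must be `TRUE`).
#' @param asm the assembly the match refers to.
#' @param name prefix for the output record id; the id is composed of this
#'   name, the contig id, and the 1-based inclusive coordinates of the
#'   matched span.
#' @return a one-row [seq_records()] with the matched region, reverse
#'   complemented for `-` strand matches so it reads in query orientation.
#' @export
extract_region <- function(match, asm, name = "region") {
  stopifnot(inherits(match, "match_result"), inherits(asm, "assembly"))
  if (!isTRUE(match$full_query))
    stop("internal error: extract_region() called on a non-completing match")
  i <- which(asm$id == match$contig_id)[1L]
  if (is.na(i))
    stop("internal error: contig '", match$contig_id, "' not in assembly")
  region <- substr(asm$seq[i], match$target_start + 1L, match$target_end)
  if (match$strand == "-") region <- revcomp(region)
  id <- sprintf("%s|%s:%d-%d%s", name, match$contig_id,
                match$target_start + 1L, match$target_end,
                if (match$strand == "-") "(-)" else "")
  seq_records(seq = region, id = id)
}
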