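# Completion testing: the N50 statistic and per-thread criterion
# evaluation (continue / complete / stalled) each iteration.

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L contain at least
#' half of the total assembly size (computed by sorting descending and
#' cumulating).
#'
#' @param lengths numeric vector of contig lengths (non-empty).
#' @return a single length; always an element of `lengths`.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4: 5 + 4 = 9 >= 15 / 2
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || anyNA(lengths))
    stop("n50() requires a non-empty vector of lengths")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

# Evaluate one thread's criteria against this iteration's length-filtered
# assembly. `thread` is the orchestrator's thread state (see split_threads);
# returns the updated thread. Terminal states are absorbing.
#
# Completion (checked first, OR over declared criteria):
#   - total_size / longest / n50 >= threshold
#   - homology: every query of the thread has a completing full-length match
# Stall (implicit "no new information" criterion, always active):
#   - no new reads were recruited this iteration
#   - the assembly's orientation-canonical form equals the previous one
#   - the filtered assembly is empty
#   - homology-only threads: no query's aligned span increased
# A stalled thread whose criteria include `exhaustive` has reached its
# success state and is reported complete ("exhausted").

#' Evaluate completion criteria for one target thread
#'
#' @param thread a thread state as produced by [split_threads()].
#' @param asm the length-filtered assembly of the current iteration.
#' @param had_new_reads whether this iteration's screen recruited at least
#'   one new read for this thread.
#' @param min_identity identity gate for homology matches.
#' @return the updated thread, with `state` one of `"running"`,
#'   `"complete"`, `"stalled"` and a human-readable `reason`.
#' @export
evaluate_thread <- function(thread, asm, had_new_reads, min_identity = 0.5) {
  stopifnot(inherits(thread, "target_thread"), inherits(asm, "assembly"))
  if (thread$state != "running") return(thread)

  kinds <- vapply(thread$criteria, `[[`, character(1L), "kind")
  thread$assembly <- asm

  # homology matches (needed for both completion and progress tracking)
  matches <- NULL
  if ("homology" %in% kinds && length(asm) > 0L) {
    matches <- lapply(seq_len(nrow(thread$refs)), function(i)
      best_match(thread$refs[i, , drop = FALSE], asm, min_identity))
    thread$matches <- matches
  }

  # --- explicit criteria (OR semantics) ---
  for (cr in thread$criteria) {
    met <- switch(cr$kind,
      total_size = total_size(asm) >= cr$threshold,
      longest    = longest_contig(asm) >= cr$threshold,
      n50        = length(asm) > 0L && n50(nchar(asm$seq)) >= cr$threshold,
      homology   = !is.null(matches) &&
        all(vapply(matches, function(m) isTRUE(m$completing), logical(1L))),
      exhaustive = FALSE)
    if (isTRUE(met)) {
      thread$state <- "complete"
      thread$reason <- paste0("criterion met: ", format(cr))
      return(thread)
    }
  }

  # --- implicit "no new information" criterion ---
  stall <- NULL
  cform <- canonical_form(asm)
  if (!had_new_reads) {
    stall <- "no new reads"
  } else if (length(asm) == 0L) {
    stall <- "empty assembly after length filter"
  } else if (!is.null(thread$prev_canonical) &&
             identical(cform, thread$prev_canonical)) {
    stall <- "assembly unchanged"
  } else if (all(kinds == "homology")) {
    qa <- vapply(matches, function(m)
      if (is.null(m)) 0 else m$query_aligned, numeric(1L))
    if (!is.null(thread$prev_matched) && all(qa <= thread$prev_matched)) {
      stall <- "matched region did not grow"
    }
    thread$prev_matched <- pmax(qa,
      if (is.null(thread$prev_matched)) 0 else thread$prev_matched)
  } else if ("homology" %in% kinds && !is.null(matches)) {
    qa <- vapply(matches, function(m)
      if (is.null(m)) 0 else m$query_aligned, numeric(1L))
    thread$prev_matched <- pmax(qa,
      if (is.null(thread$prev_matched)) 0 else thread$prev_matched)
  }

  if (!is.null(stall)) {
    if ("exhaustive" %in% kinds && length(asm) > 0L) {
      thread$state <- "complete"
      thread$reason <- paste0("exhausted: ", stall)
    } else {
      thread$state <- "stalled"
      thread$reason <- stall
    }
    return(thread)
  }

  thread$prev_canonical <- cform
  thread$state <- "running"
  thread$reason <- "criteria not yet met"
  thread
}
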