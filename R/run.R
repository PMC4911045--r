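# The main loop: general baiting over the full read set, per-thread
# specific baiting, de novo assembly, completion testing, and iteration
# control, for single- and multi-target runs.

new_thread <- function(name, refs, criteria) {
  structure(list(
    name = name,
    refs = refs,
    criteria = criteria,
    state = "running",
    reason = "not started",
    ledger = new_ledger(),
    assembly = NULL,
    raw_assembly = NULL,
    matches = NULL,
    prev_canonical = NULL,
    prev_matched = NULL,
    specific_iterations = 0L,
    history = list()), class = "target_thread")
}

#' @export
print.target_thread <- function(x, ...) {
  cat(sprintf("<target_thread> %s [%s] criteria: %s\n", x$name, x$state,
              paste(vapply(x$criteria, format, character(1L)),
                    collapse = " | ")))
  invisible(x)
}

#' Split reference entries into target threads
#'
#' In multi mode every reference entry becomes its own thread (named by
#' the entry id) unless an explicit `grouping` assigns several entries to
#' one named thread (e.g. two primer-delimited query fragments of the same
#' locus). In single mode all entries form one thread. Per-thread
#' completion criteria are taken from `crit=` tags on the entry
#' description lines (see [parse_criterion_tag()]), falling back to
#' `default_criterion`.
#'
#' @param reference a [seq_records()] table of reference/query entries.
#' @param multi logical: one thread per entry?
#' @param grouping optional named list: thread name -> character vector of
#'   entry ids.
#' @param default_criterion a [criterion()] for untagged entries.
#' @return list of `target_thread` objects.
#' @export
split_threads <- function(reference, multi = FALSE, grouping = NULL,
                          default_criterion = criterion("exhaustive")) {
  stopifnot(inherits(reference, "seq_records"), nrow(reference) > 0L)
  mk <- function(name, rows) {
    refs <- reference[rows, , drop = FALSE]
    class(refs) <- c("seq_records", "data.frame")
    crits <- unlist(lapply(refs$desc, parse_criterion_tag,
                           default = default_criterion), recursive = FALSE)
    crits <- unique(crits)
    new_thread(name, refs, crits)
  }
  if (!multi) {
    name <- if (nrow(reference) == 1L) reference$id else "target"
    return(list(mk(name, seq_len(nrow(reference)))))
  }
  grouped_ids <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(grouped_ids))
    stop("an entry may belong to at most one thread group")
  bad <- setdiff(grouped_ids, reference$id)
  if (length(bad)) stop("grouping refers to unknown entry: ", bad[1L])
  threads <- lapply(names(grouping), function(g)
    mk(g, which(reference$id %in% grouping[[g]])))
  rest_idx <- which(!(reference$id %in% grouped_ids))
  threads <- c(threads, lapply(rest_idx, function(i)
    mk(reference$id[i], i)))
  nms <- vapply(threads, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate thread names: ", nms[duplicated(nms)][1L])
  threads
}

#' Assemble the general bait for one iteration
#'
#' On the first iteration the bait is every thread's reference entries
#' plus the optional additional-bait sequences; on later iterations it is
#' the union of the current (length-filtered) assemblies of all still
#' running threads, so terminated threads stop influencing recruitment.
#'
#' @param threads list of `target_thread` objects.
#' @param additional optional [seq_records()] of additional bait.
#' @param first_iteration logical.
#' @return named character vector of bait sequences.
#' @export
make_general_bait <- function(threads, additional = NULL,
                              first_iteration = TRUE) {
  if (first_iteration) {
    seqs <- unlist(lapply(threads, function(th) {
      out <- th$refs$seq
      names(out) <- th$refs$id
      out
    }))
    if (!is.null(additional) && nrow(additional) > 0L) {
      add <- additional$seq
      names(add) <- additional$id
      seqs <- c(seqs, add)
    }
    return(seqs)
  }
  running <- Filter(function(th) th$state == "running", threads)
  unlist(lapply(running, function(th) {
    if (is.null(th$assembly) || length(th$assembly) == 0L)
      return(character(0L))
    out <- th$assembly$seq
    names(out) <- paste(th$name, th$assembly$id, sep = ".")
    out
  }))
}

thread_bait <- function(th, first_iteration) {
  if (first_iteration || is.null(th$assembly)) {
    out <- th$refs$seq
    names(out) <- th$refs$id
    out
  } else {
    out <- th$assembly$seq
    names(out) <- th$assembly$id
    out
  }
}

#' Run the iterative baiting and assembly loop
#'
#' Each iteration: (1) the full read set is screened once against the
#' general bait and newly recruited read names (plus their mates) join the
#' general ledger; (2) each running thread screens only the
#' generally-recruited reads against its own bait (its references on the
#' first iteration, its previous length-filtered assembly afterwards),
#' extracts its cumulative recruited reads, assembles them de novo,
#' applies the length filter, and tests its completion criteria; (3) the
#' run stops when every thread is terminal, when general baiting finds no
#' new reads, or when `max_iterations` is reached.
#'
#' @param reference reference/query sequences: a FASTA path or a
#'   [seq_records()] table. Entry description lines may carry `crit=` tags.
#' @param reads the read set: a [read_set()], or character vector of
#'   FASTA/FASTQ paths interpreted with `paired`.
#' @param paired pairing mode used when `reads` is a vector of paths.
#' @param bait optional additional bait: FASTA path or [seq_records()];
#'   used for the first general baiting step only.
#' @param multi run one thread per reference entry?
#' @param grouping optional thread grouping, see [split_threads()].
#' @param default_criterion completion criterion for untagged entries.
#' @param assembler assembler adapter name (default `"internal"`).
#' @param params an [assembler_params()].
#' @param k k-mer length for recruitment (default 31).
#' @param min_hits minimum shared k-mers for recruitment (default 1).
#' @param min_identity identity gate for homology matches.
#' @param max_iterations optional safety cap on iterations.
#' @param out_dir optional output directory; when given, per-iteration
#'   baits, read-name lists and assemblies, the final per-thread FASTA
#'   (and extracted regions for homology threads), and a run log are
#'   written beneath it.
#' @param verbose print one line per thread per iteration.
#' @return a `bait_run` object: list with `threads`, `general`
#'   (iteration count and ledger), and the effective configuration.
#' @export
bait_assemble <- function(reference, reads,
                          paired = c("single", "two-file", "interleaved"),
                          bait = NULL, multi = FALSE, grouping = NULL,
                          default_criterion = criterion("exhaustive"),
                          assembler = "internal",
                          params = assembler_params(), k = 31L,
                          min_hits = 1L, min_identity = 0.5,
                          max_iterations = NULL, out_dir = NULL,
                          verbose = FALSE) {
  paired <- match.arg(paired)
  if (is.character(reference)) reference <- read_sequences(reference)
  stopifnot(inherits(reference, "seq_records"))
  if (is.character(reads)) reads <- load_reads(reads, paired = paired)
  stopifnot(inherits(reads, "read_set"))
  if (is.character(bait)) bait <- read_sequences(bait)
  if (!is.null(max_iterations))
    stopifnot(max_iterations >= 1L)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  threads <- split_threads(reference, multi = multi, grouping = grouping,
                           default_criterion = default_criterion)
  general <- new_ledger()
  general_history <- list()
  log_lines <- character(0L)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }

  iter <- 0L
  repeat {
    running <- which(vapply(threads, function(t) t$state == "running",
                            logical(1L)))
    if (length(running) == 0L) break
    iter <- iter + 1L

    # (1) general baiting over the full read set
    gbait <- make_general_bait(threads, additional = bait,
                               first_iteration = iter == 1L)
    if (length(gbait) == 0L) break
    gindex <- bait_index(gbait, k = k)
    gids <- expand_with_mates(screen(reads, gindex, min_hits = min_hits),
                              reads)
    general <- update_ledger(general, gids)
    general_history[[iter]] <- list(bait = gbait, new = general$new_this_iteration)

    if (iter == 1L && length(general$names) == 0L) {
      for (i in running) {
        threads[[i]]$state <- "failed"
        threads[[i]]$reason <- "no reads matched reference"
        note("iter %d thread %s: failed (no reads matched reference)",
             iter, threads[[i]]$name)
      }
      break
    }
    if (iter > 1L && !general$new_this_iteration) {
      for (i in running) {
        kinds <- vapply(threads[[i]]$criteria, `[[`, character(1L), "kind")
        if ("exhaustive" %in% kinds && !is.null(threads[[i]]$assembly) &&
            length(threads[[i]]$assembly) > 0L) {
          threads[[i]]$state <- "complete"
          threads[[i]]$reason <- "exhausted: no new reads (general baiting)"
        } else {
          threads[[i]]$state <- "stalled"
          threads[[i]]$reason <- "no new reads (general baiting)"
        }
        note("iter %d thread %s: %s (%s)", iter, threads[[i]]$name,
             threads[[i]]$state, threads[[i]]$reason)
      }
      break
    }
    pool <- extract_reads(reads, general$names)

    # (2) per-thread specific baiting, assembly, completion testing
    for (i in running) {
      th <- threads[[i]]
      sbait <- thread_bait(th, iter == 1L)
      if (multi) {
        sindex <- bait_index(sbait, k = k)
        sids <- expand_with_mates(
          screen(pool, sindex, min_hits = min_hits), reads)
        th$ledger <- update_ledger(th$ledger, sids)
      } else {
        th$ledger <- update_ledger(th$ledger, general$names)
      }
      had_new <- th$ledger$new_this_iteration
      th$specific_iterations <- th$specific_iterations + 1L

      if (length(th$ledger$names) == 0L) {
        th$state <- "failed"
        th$reason <- "no reads matched reference"
        threads[[i]] <- th
        note("iter %d thread %s: failed (no reads matched reference)",
             iter, th$name)
        next
      }

      treads <- extract_reads(reads, th$ledger$names)
      asm_raw <- tryCatch(
        run_assembler(treads, adapter = assembler, params = params),
        error = function(e) e)
      if (inherits(asm_raw, "error")) {
        th$state <- "failed"
        th$reason <- paste0("assembler error: ",
                            conditionMessage(asm_raw))
        threads[[i]] <- th
        note("iter %d thread %s: failed (%s)", iter, th$name, th$reason)
        next
      }
      th$raw_assembly <- asm_raw
      asm <- length_filter(asm_raw, params$min_contig)
      th <- evaluate_thread(th, asm, had_new, min_identity = min_identity)
      th$history[[iter]] <- list(
        iteration = iter,
        bait = unname(sbait),
        ledger_names = th$ledger$names,
        n_contigs = length(asm),
        total = total_size(asm))
      threads[[i]] <- th
      note("iter %d thread %s: %s (%s); %d reads, %d contig(s), %d bp",
           iter, th$name, th$state, th$reason,
           length(th$ledger$names), length(asm), total_size(asm))
      if (!is.null(out_dir))
        persist_iteration(out_dir, th, iter, sbait, asm_raw, asm)
    }

    if (!is.null(max_iterations) && iter >= max_iterations) {
      for (i in seq_along(threads)) {
        if (threads[[i]]$state == "running") {
          threads[[i]]$state <- "stalled"
          threads[[i]]$reason <- "max iterations reached"
          note("iter %d thread %s: stalled (max iterations reached)",
               iter, threads[[i]]$name)
        }
      }
      break
    }
  }

  # final products: per-thread assemblies and extracted homology regions
  for (i in seq_along(threads)) {
    th <- threads[[i]]
    th$extracted <- extract_thread_regions(th)
    threads[[i]] <- th
  }
  if (!is.null(out_dir)) persist_final(out_dir, threads, log_lines)

  structure(list(
    threads = threads,
    general = list(iterations = iter, ledger = general,
                   history = general_history),
    log = log_lines,
    config = list(multi = multi, k = k, min_hits = min_hits,
                  min_identity = min_identity, assembler = assembler,
                  params = params,
                  default_criterion = default_criterion)),
    class = "bait_run")
}

extract_thread_regions <- function(th) {
  if (th$state != "complete" || is.null(th$matches)) return(NULL)
  completing <- Filter(function(m) isTRUE(m$completing), th$matches)
  if (length(completing) == 0L) return(NULL)
  recs <- lapply(completing, extract_region, asm = th$assembly,
                 name = th$name)
  out <- do.call(rbind, recs)
  class(out) <- c("seq_records", "data.frame")
  out
}

persist_iteration <- function(out_dir, th, iter, sbait, asm_raw, asm) {
  d <- file.path(out_dir, th$name, sprintf("iteration_%03d", iter))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_sequences(seq_records(unname(sbait),
                              id = names(sbait)),
                  file.path(d, "bait.fasta"))
  writeLines(th$ledger$names, file.path(d, "read_names.txt"))
  write_asm <- function(a, path) {
    if (length(a) > 0L)
      write_sequences(seq_records(a$seq, id = a$id), path)
  }
  write_asm(asm_raw, file.path(d, "assembly.fasta"))
  write_asm(asm, file.path(d, "assembly_filtered.fasta"))
}

persist_final <- function(out_dir, threads, log_lines) {
  for (th in threads) {
    d <- file.path(out_dir, th$name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(th$assembly) && length(th$assembly) > 0L)
      write_sequences(seq_records(th$assembly$seq, id = th$assembly$id),
                      file.path(d, "final.fasta"))
    if (!is.null(th$extracted))
      write_sequences(th$extracted, file.path(d, "final_extracted.fasta"))
  }
  writeLines(log_lines, file.path(out_dir, "log.txt"))
}

#' @export
print.bait_run <- function(x, ...) {
  cat(sprintf("<bait_run> %d thread(s), %d general iteration(s), %d reads recruited\n",
              length(x$threads), x$general$iterations,
              length(x$general$ledger$names)))
  for (th in x$threads) {
    asm <- th$assembly
    cat(sprintf("  %-12s %-9s %s; %d contig(s), %d bp\n",
                th$name, th$state, th$reason,
                if (is.null(asm)) 0L else length(asm),
                if (is.null(asm)) 0L else total_size(asm)))
  }
  invisible(x)
}

#' @export
summary.bait_run <- function(object, ...) {
  df <- do.call(rbind, lapply(object$threads, function(th) {
    asm <- th$assembly
    data.frame(
      thread = th$name,
      state = th$state,
      reason = th$reason,
      iterations = th$specific_iterations,
      reads = length(th$ledger$names),
      contigs = if (is.null(asm)) 0L else length(asm),
      total_bp = if (is.null(asm)) 0L else total_size(asm),
      longest_bp = if (is.null(asm)) 0L else longest_contig(asm),
      stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Retrieve a thread's final assembly from a run
#'
#' @param run a [bait_assemble()] result.
#' @param thread thread name (may be omitted for single-thread runs).
#' @return an `assembly`.
#' @export
final_assembly <- function(run, thread = NULL) {
  stopifnot(inherits(run, "bait_run"))
  if (is.null(thread)) {
    stopifnot(length(run$threads) == 1L)
    return(run$threads[[1L]]$assembly)
  }
  nm <- vapply(run$threads, `[[`, character(1L), "name")
  i <- match(thread, nm)
  if (is.na(i)) stop("no thread named '", thread, "'")
  run$threads[[i]]$assembly
}

#' Verify the restricted-screening equivalence of a finished run
#'
#' Specific baiting screens only the generally-recruited reads, which is
#' sound because every thread's bait is part of the general bait of the
#' same iteration. This verification hook replays each thread's
#' per-iteration baits against the *full* read set and checks that (a)
#' every read any thread recruited is in the general ledger and (b) the
#' unrestricted screens reproduce each thread's recruited read sets.
#'
#' @param run a completed [bait_assemble()] result.
#' @param reads the read set the run was executed on.
#' @return `TRUE` if the property holds, otherwise `FALSE`.
#' @export
screen_efficiency_property <- function(run, reads) {
  stopifnot(inherits(run, "bait_run"), inherits(reads, "read_set"))
  if (!isTRUE(run$config$multi)) return(TRUE)  # no restriction to verify
  general_names <- run$general$ledger$names
  for (th in run$threads) {
    if (length(th$history) == 0L) next
    cumulative <- character(0L)
    for (h in th$history) {
      if (is.null(h)) next
      idx <- bait_index(h$bait, k = run$config$k)
      ids <- expand_with_mates(
        screen(reads, idx, min_hits = run$config$min_hits), reads)
      if (!all(ids %in% general_names)) return(FALSE)
      cumulative <- unique(c(cumulative, ids))
      if (!setequal(cumulative, h$ledger_names)) return(FALSE)
    }
  }
  TRUE
}
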