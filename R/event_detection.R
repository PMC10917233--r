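#' Maximal mismatch stretches of an alignment, on functional coordinates
#'
#' Walks the alignment columns and marks functional positions that are
#' substituted or deleted in the observed sequence; an insertion in the
#' observed sequence marks the two flanking functional positions so that a
#' length change is never invisible. An observed `N` column counts as a
#' match. Maximal runs of marked positions are returned as stretches.
#'
#' @param aln An `sgc_alignment` from [align_global()].
#' @return data.frame with integer columns `start`, `end` (1-based inclusive
#'   functional positions), sorted by `start`; zero rows when the alignment
#'   is mismatch-free.
#' @export
mismatch_stretches <- function(aln) {
  stopifnot(inherits(aln, "sgc_alignment"))
  L <- max(aln$fun_pos, na.rm = TRUE)
  mism <- logical(L)
  f <- aln$fun_chars; o <- aln$obs_chars; fp <- aln$fun_pos
  for (i in seq_along(f)) {
    if (f[i] != "-" && o[i] != "-") {
      if (o[i] != f[i] && o[i] != "N") mism[fp[i]] <- TRUE
    } else if (o[i] == "-") {
      mism[fp[i]] <- TRUE                      # deletion in observed
    } else {                                   # insertion in observed
      prev <- if (i > 1L) max(fp[seq_len(i - 1L)], na.rm = TRUE) else -Inf
      if (is.finite(prev)) mism[prev] <- TRUE
      nxt <- fp[-seq_len(i)]
      nxt <- nxt[!is.na(nxt)]
      if (length(nxt)) mism[nxt[1L]] <- TRUE else if (is.finite(prev)) mism[L] <- TRUE
    }
  }
  runs_to_intervals(mism)
}

runs_to_intervals <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Merge mismatch stretches into candidate gene conversion events
#'
#' Consecutive stretches are merged when they lie within `window`
#' nucleotides of each other; merged units spanning fewer than
#' `min_event_span` nucleotides are then discarded as hypermutation-like
#' (the minimum-span rule is applied after merging, so two 1-nt mismatches
#' 2 nt apart merge to span >= 3 and survive, while an isolated point
#' mutation never yields an event).
#'
#' @param stretches data.frame from [mismatch_stretches()] (sorted,
#'   non-overlapping).
#' @param window Merge window in nt.
#' @param min_event_span Minimum merged span in nt.
#' @param gap_semantics `"between"` (default): merge when the number of
#'   intervening functional positions, `next_start - prev_end - 1`, is
#'   `<= window`; `"endpoints"`: merge when `next_start - prev_end <= window`.
#' @return data.frame with columns `start`, `end`, `n_stretches`,
#'   `member_starts`, `member_ends` (comma-separated member stretch bounds),
#'   sorted by `start`.
#' @export
merge_stretches <- function(stretches, window, min_event_span = 3L,
                            gap_semantics = c("between", "endpoints")) {
  gap_semantics <- match.arg(gap_semantics)
  empty <- data.frame(start = integer(), end = integer(),
                      n_stretches = integer(),
                      member_starts = character(),
                      member_ends = character())
  if (nrow(stretches) == 0L) return(empty)
  stopifnot(!is.unsorted(stretches$start))
  grp <- integer(nrow(stretches))
  grp[1L] <- 1L
  for (i in seq_len(nrow(stretches))[-1L]) {
    gap <- stretches$start[i] - stretches$end[i - 1L] - 1L
    lim <- if (gap_semantics == "between") window else window - 1L
    grp[i] <- if (gap <= lim) grp[i - 1L] else grp[i - 1L] + 1L
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(stretches)), grp), function(ix) {
    data.frame(start = min(stretches$start[ix]),
               end = max(stretches$end[ix]),
               n_stretches = length(ix),
               member_starts = paste(stretches$start[ix], collapse = ","),
               member_ends = paste(stretches$end[ix], collapse = ","))
  }))
  rownames(out) <- NULL
  out <- out[out$end - out$start + 1L >= min_event_span, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect candidate events under the strict and loose definitions
#'
#' Runs one global alignment and merges its mismatch stretches twice: with
#' the loose window (default 6, favouring longer proposed conversions) and
#' the strict window (default 3, splitting possibly unrelated conversions).
#' Every strict event is contained in exactly one loose event.
#'
#' @param observed Observed DNA string.
#' @param functional Functional-allele DNA string.
#' @param params An [sgc_params()] object.
#' @return list with elements `loose` and `strict` (each a data.frame as
#'   from [merge_stretches()]), plus the `alignment` used.
#' @export
detect_candidates <- function(observed, functional, params = sgc_params()) {
  aln <- align_global(observed, functional, params)
  st <- mismatch_stretches(aln)
  list(
    loose = merge_stretches(st, params$merge_window_loose,
                            params$min_event_span, params$merge_gap_semantics),
    strict = merge_stretches(st, params$merge_window_strict,
                             params$min_event_span, params$merge_gap_semantics),
    alignment = aln
  )
}
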