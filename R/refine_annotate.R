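#' Merge adjacent same-donor events separated by functional==donor sequence
#'
#' Two consecutive events nominated from the same pseudogene whose
#' intervening functional segment is identical to the donor's projected
#' segment are, in all likelihood, one conversion tract interrupted by a
#' silent (identical) stretch; they are merged into a single event and the
#' Levenshtein distance is recomputed on the merged segment. Events with
#' different donors, or with a non-identical intervening segment, are left
#' untouched. The operation is idempotent.
#'
#' @param events data.frame with `min_start`, `min_end`, `donor`,
#'   `match_status` for a single sequence, sorted by `min_start`.
#' @param aln The observed-vs-functional `sgc_alignment` for the sequence.
#' @param observed Observed DNA string.
#' @param projection A `donor_projection`.
#' @return The pruned event data.frame (same columns), sorted.
#' @export
prune_merge <- function(events, aln, observed, projection) {
  if (nrow(events) <= 1L) return(events)
  stopifnot(!is.unsorted(events$min_start))
  fun <- projection$functional
  i <- 1L
  while (i < nrow(events)) {
    a <- events[i, ]; b <- events[i + 1L, ]
    mergeable <- FALSE
    if (!is.na(a$donor) && !is.na(b$donor) && a$donor == b$donor &&
        b$min_start > a$min_end + 1L) {
      gs <- a$min_end + 1L; ge <- b$min_start - 1L
      fun_seg <- substring(fun, gs, ge)
      don_seg <- donor_segment(projection, a$donor, gs, ge)
      mergeable <- identical(fun_seg, don_seg)
    } else if (!is.na(a$donor) && !is.na(b$donor) && a$donor == b$donor &&
               b$min_start <= a$min_end + 1L) {
      mergeable <- TRUE  # touching/adjacent same-donor events
    }
    if (mergeable) {
      events$min_end[i] <- max(a$min_end, b$min_end)
      obs_iv <- fun_interval_to_obs(aln, events$min_start[i], events$min_end[i])
      obs_seg <- if (is.na(obs_iv[1L])) "" else
        substring(observed, obs_iv[1L], obs_iv[2L])
      events$levenshtein[i] <- levenshtein(
        obs_seg, donor_segment(projection, a$donor,
                               events$min_start[i], events$min_end[i]))
      events <- events[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  rownames(events) <- NULL
  events
}

#' Extend an event to its maximum-length definition
#'
#' The minimum definition of an event is bounded by visible mismatches, but
#' the converted tract can extend into flanking sequence where functional
#' allele and donor are 100% identical (a silent conversion edge). The
#' maximum definition grows the interval outward from the minimum interval
#' while the functional base equals the donor base aligned at that
#' position, stopping at the first disagreement (or donor gap, or sequence
#' end). Unmatched events cannot be extended: max equals min.
#'
#' @param event One-row data.frame with `min_start`, `min_end`, `donor`.
#' @param projection A `donor_projection`.
#' @return list: `max_start`, `max_end`, `identical_flank_5len`,
#'   `identical_flank_3len`.
#' @export
extend_max <- function(event, projection) {
  if (is.na(event$donor)) {
    return(list(max_start = event$min_start, max_end = event$min_end,
                identical_flank_5len = 0L, identical_flank_3len = 0L))
  }
  fun <- strsplit(projection$functional, "", fixed = TRUE)[[1]]
  don <- projection$donor_at[event$donor, ]
  s <- event$min_start
  while (s > 1L && don[s - 1L] != "-" && don[s - 1L] == fun[s - 1L]) s <- s - 1L
  e <- event$min_end
  L <- length(fun)
  while (e < L && don[e + 1L] != "-" && don[e + 1L] == fun[e + 1L]) e <- e + 1L
  list(max_start = s, max_end = e,
       identical_flank_5len = event$min_start - s,
       identical_flank_3len = e - event$min_end)
}

#' Extract the functional-allele flank strings around an event
#'
#' @param event One-row data.frame with `min_start`, `min_end`.
#' @param functional Functional-allele string.
#' @param flank_len Flank length in nt (default 10); truncated at the
#'   sequence ends.
#' @return list with `flank5` and `flank3` strings.
#' @export
flank_context <- function(event, functional, flank_len = 10L) {
  L <- nchar(functional)
  f5 <- if (event$min_start > 1L)
    substring(functional, max(1L, event$min_start - flank_len),
              event$min_start - 1L) else ""
  f3 <- if (event$min_end < L)
    substring(functional, event$min_end + 1L,
              min(L, event$min_end + flank_len)) else ""
  list(flank5 = f5, flank3 = f3)
}

# 3'-most base position of every AID motif occurrence, forward strand.
motif_end_positions <- function(functional, motifs) {
  L <- nchar(functional)
  if (L < 3L) return(integer())
  starts <- seq_len(L - 2L)
  tris <- substring(functional, starts, starts + 2L)
  sort(starts[tris %in% motifs] + 2L)
}

#' Distance from a position to the nearest AID hotspot motif 5' of it
#'
#' AID (activation-induced cytidine deaminase) initiates both gene
#' conversion and hypermutation at preferred trinucleotide hotspots. The
#' distance is counted from the 3'-most base of the nearest motif lying
#' strictly 5' of the position: 0 when the position immediately follows a
#' motif; `NA` when no motif occurs 5' of it.
#'
#' @param position Integer vector of functional-allele positions (for an
#'   event, its `min_start` or `max_start`).
#' @param functional Functional-allele string.
#' @param motifs Character vector of trinucleotide motifs (forward strand).
#' @return Integer vector of distances (`NA` where no 5' motif exists).
#' @export
aid_distance <- function(position, functional,
                         motifs = sgc_params()$aid_motifs) {
  ends <- motif_end_positions(functional, motifs)
  vapply(position, function(p) {
    prior <- ends[ends < p]
    if (length(prior) == 0L) NA_integer_ else as.integer(p - max(prior) - 1L)
  }, NA_integer_)
}

#' Does a conversion event introduce a new AID hotspot?
#'
#' Compares the AID motif content of the observed sequence over the event's
#' minimum interval (padded by 2 nt on each side, so motifs straddling the
#' event edge are seen) with the corresponding functional-allele window:
#' `TRUE` iff some motif occurs in the converted window but nowhere in the
#' functional window. A conversion that only destroys motifs returns
#' `FALSE`.
#'
#' @param event One-row data.frame with `min_start`, `min_end`.
#' @param aln The observed-vs-functional `sgc_alignment`.
#' @param observed Observed DNA string.
#' @param functional Functional-allele string.
#' @param motifs Trinucleotide motif set.
#' @param pad Window padding in nt (default 2 = motif length - 1).
#' @return Logical.
#' @export
introduces_new_hotspot <- function(event, aln, observed, functional,
                                   motifs = sgc_params()$aid_motifs,
                                   pad = 2L) {
  ws <- max(1L, event$min_start - pad)
  we <- min(nchar(functional), event$min_end + pad)
  fun_win <- substring(functional, ws, we)
  obs_iv <- fun_interval_to_obs(aln, ws, we)
  if (is.na(obs_iv[1L])) return(FALSE)
  obs_win <- substring(observed, obs_iv[1L], obs_iv[2L])
  present <- function(s) {
    if (nchar(s) < 3L) return(character())
    st <- seq_len(nchar(s) - 2L)
    intersect(motifs, substring(s, st, st + 2L))
  }
  length(setdiff(present(obs_win), present(fun_win))) > 0L
}
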