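#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitution, insertion, deletion each cost 1),
#' the match-quality measure used throughout donor assignment: the number of
#' edits required to convert the donor pseudogene segment into the observed
#' segment.
#'
#' @param a,b Character strings.
#' @return Non-negative integer.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Seeded local search of a query against the pseudogene library
#'
#' Donor nomination mimics a seeded aligner: a donor is considered only if
#' it shares at least one exact `seed_len`-mer (default 6, sampled every
#' `seed_step` positions, forward strand only) with the query; seeded donors
#' are then aligned locally (Smith-Waterman, affine gaps, the `params`
#' scores) and hits scoring below `min_local_score` are discarded. Queries
#' shorter than `seed_len` skip the seed gate and are aligned exhaustively.
#' One best local hit per donor is reported.
#'
#' @param query DNA string (an event segment or a full observed sequence).
#' @param library Named character vector of donor sequences.
#' @param params An [sgc_params()] object.
#' @return data.frame sorted by identity (matches / alignment columns)
#'   descending, then score descending, then donor name ascending; columns
#'   `donor`, `q_start`, `q_end`, `d_start`, `d_end` (1-based inclusive),
#'   `identity`, `score`, `mismatches`, `aln_len`.
#' @export
local_search <- function(query, library, params = sgc_params()) {
  if (length(library) == 0L) stop("empty donor library")
  stopifnot(!is.null(names(library)))
  empty <- data.frame(donor = character(), q_start = integer(),
                      q_end = integer(), d_start = integer(),
                      d_end = integer(), identity = numeric(),
                      score = numeric(), mismatches = integer(),
                      aln_len = integer())
  if (!nzchar(query)) return(empty)
  k <- params$seed_len
  if (nchar(query) >= k) {
    starts <- seq.int(1L, nchar(query) - k + 1L, by = params$seed_step)
    qmers <- unique(substring(query, starts, starts + k - 1L))
    seeded <- vapply(library, function(d) {
      if (nchar(d) < k) return(FALSE)
      ds <- seq_len(nchar(d) - k + 1L)
      any(qmers %in% substring(d, ds, ds + k - 1L))
    }, TRUE)
    candidates <- library[seeded]
  } else {
    candidates <- library
  }
  if (length(candidates) == 0L) return(empty)
  mat <- substitution_matrix(params)
  rows <- lapply(names(candidates), function(nm) {
    la <- Biostrings::pairwiseAlignment(
      pattern = query, subject = candidates[[nm]], type = "local",
      substitutionMatrix = mat,
      gapOpening = params$align_gap_open,
      gapExtension = params$align_gap_extend)
    sc <- Biostrings::score(la)
    if (sc < params$min_local_score) return(NULL)
    len <- Biostrings::nchar(la)
    data.frame(donor = nm,
               q_start = Biostrings::start(Biostrings::pattern(la)),
               q_end = Biostrings::end(Biostrings::pattern(la)),
               d_start = Biostrings::start(Biostrings::subject(la)),
               d_end = Biostrings::end(Biostrings::subject(la)),
               identity = Biostrings::nmatch(la) / len,
               score = sc,
               mismatches = Biostrings::nmismatch(la),
               aln_len = len)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  ord <- order(-hits$identity, -hits$score, hits$donor)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Nominate the donor pseudogene for one candidate event
#'
#' Three alignment sets are consulted in order: (a) hits obtained from the
#' loose-definition event segment itself, (b) hits of the full-length
#' observed sequence restricted to those overlapping the event, (c) hits
#' from the strict-definition sub-segments. Within a set, candidates are
#' ranked by identity, then score, then name; the best-ranked donor whose
#' Levenshtein distance to the event's observed segment satisfies
#' `lev <= suboptimal_ratio * w` (event width `w`) is nominated as
#' `optimal`. If no candidate in any set is adequate, the assignment is
#' `suboptimal` (best available donor, for `w > suboptimal_min_width`;
#' callers then re-annotate the strict sub-events) or `unmatched`.
#'
#' The reported Levenshtein distance always compares the event's observed
#' segment with the nominated donor's segment projected over the same
#' functional interval, so distances are comparable across events.
#'
#' @param event One-row data.frame with `start`, `end` (functional coords).
#' @param aln The observed-vs-functional `sgc_alignment`.
#' @param observed Observed DNA string.
#' @param projection A `donor_projection` from [project_donors()].
#' @param library Named character vector of donor sequences.
#' @param params An [sgc_params()] object.
#' @param full_hits Optional precomputed [local_search()] result for the
#'   full-length observed sequence (set b), to avoid recomputation.
#' @param strict_sub Optional data.frame of strict-definition sub-events
#'   within this event (set c queries).
#' @return list: `donor` (name or `NA`), `levenshtein`, `match_status`
#'   (`optimal`/`suboptimal`/`unmatched`), `co_best` (character vector of
#'   other donors tied at the best identity in the decisive set).
#' @export
annotate_donor <- function(event, aln, observed, projection, library,
                           params = sgc_params(), full_hits = NULL,
                           strict_sub = NULL) {
  w <- event$end - event$start + 1L
  obs_iv <- fun_interval_to_obs(aln, event$start, event$end)
  obs_seg <- if (is.na(obs_iv[1L])) "" else
    substring(observed, obs_iv[1L], obs_iv[2L])

  lev_for <- function(donor) {
    levenshtein(obs_seg, donor_segment(projection, donor, event$start, event$end))
  }

  # The three alignment sets, lazily evaluated: the full-length search is
  # only run when the event-segment search yields no adequate donor.
  set_thunks <- list(
    event = function() local_search(obs_seg, library, params),
    full = function() {
      fh <- if (is.null(full_hits)) local_search(observed, library, params)
            else full_hits
      if (nrow(fh) && !is.na(obs_iv[1L])) {
        ov <- fh$q_start <= obs_iv[2L] & fh$q_end >= obs_iv[1L]
        fh[ov, , drop = FALSE]
      } else fh[0, , drop = FALSE]
    },
    strict = function() {
      rows <- list()
      if (!is.null(strict_sub) && nrow(strict_sub)) {
        for (i in seq_len(nrow(strict_sub))) {
          siv <- fun_interval_to_obs(aln, strict_sub$start[i], strict_sub$end[i])
          if (is.na(siv[1L])) next
          sseg <- substring(observed, siv[1L], siv[2L])
          rows[[length(rows) + 1L]] <- local_search(sseg, library, params)
        }
      }
      if (length(rows)) do.call(rbind, rows) else
        data.frame(donor = character(), q_start = integer(),
                   q_end = integer(), d_start = integer(), d_end = integer(),
                   identity = numeric(), score = numeric(),
                   mismatches = integer(), aln_len = integer())
    }
  )

  unmatched <- list(donor = NA_character_, levenshtein = NA_integer_,
                    match_status = "unmatched", co_best = character())
  best_seen <- NULL
  for (thunk in set_thunks) {
    set <- thunk()
    if (nrow(set) == 0L) next
    donors <- unique(set$donor)
    levs <- vapply(donors, lev_for, 0L)
    top_identity <- max(set$identity)
    ranked <- donors  # already in ranked order (unique keeps first occurrence)
    for (d in ranked) {
      if (levs[[d]] <= params$suboptimal_ratio * w) {
        ties <- unique(set$donor[set$identity == set$identity[set$donor == d][1L]])
        return(list(donor = d, levenshtein = levs[[d]],
                    match_status = "optimal",
                    co_best = setdiff(ties, d)))
      }
    }
    cand_best <- ranked[which.min(levs[ranked])]
    if (is.null(best_seen) || levs[[cand_best]] < best_seen$levenshtein) {
      ties <- unique(set$donor[set$identity == top_identity])
      best_seen <- list(donor = cand_best, levenshtein = levs[[cand_best]],
                        co_best = setdiff(ties, cand_best))
    }
  }
  if (is.null(best_seen)) return(unmatched)
  if (w > params$suboptimal_min_width) {
    c(best_seen[c("donor", "levenshtein")],
      list(match_status = "suboptimal", co_best = best_seen$co_best))
  } else {
    unmatched
  }
}
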