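#' Detect and annotate gene conversion events in one sequence
#'
#' Runs the full per-sequence pipeline: global alignment to the functional
#' allele, mismatch-stretch merging under the loose and strict windows,
#' donor nomination through the three alignment sets, replacement of
#' inadequately matched wide events by their strict sub-events, pruning of
#' same-donor events separated by functional==donor sequence, and
#' minimum/maximum interval, flank, AID-distance and new-hotspot
#' annotation.
#'
#' @param observed Observed DNA string.
#' @param refset A [reference_set()].
#' @param params An [sgc_params()] object.
#' @param projection Optional precomputed [project_donors()] result (reuse
#'   it across sequences; it only depends on the reference set and scores).
#' @return data.frame with one row per annotated event: `event_index`,
#'   `min_start`, `min_end`, `max_start`, `max_end`, `donor`,
#'   `levenshtein`, `match_status`, `definition` (`loose` or `strict`, the
#'   latter for sub-events that replaced an inadequately matched loose
#'   parent, whose interval is kept in `parent_start`/`parent_end`),
#'   `co_best`, `identical_flank_5len`, `identical_flank_3len`, `flank5`,
#'   `flank3`, `aid_distance_5prime`, `introduces_new_hotspot`.
#' @export
detect_events <- function(observed, refset, params = sgc_params(),
                          projection = NULL) {
  if (is.null(projection)) projection <- project_donors(refset, params)
  fun <- unname(refset$functional)
  library <- refset$pseudogenes
  cand <- detect_candidates(observed, fun, params)
  aln <- cand$alignment
  loose <- cand$loose
  strict <- cand$strict
  empty <- event_frame(0L)
  if (nrow(loose) == 0L) return(empty)

  full_hits <- local_search(observed, library, params)
  rows <- list()
  for (i in seq_len(nrow(loose))) {
    ev <- loose[i, ]
    sub <- strict[strict$start >= ev$start & strict$end <= ev$end, , drop = FALSE]
    asg <- annotate_donor(ev, aln, observed, projection, library, params,
                          full_hits = full_hits, strict_sub = sub)
    subdividable <- nrow(sub) > 1L ||
      (nrow(sub) == 1L && (sub$start[1L] != ev$start || sub$end[1L] != ev$end))
    if (identical(asg$match_status, "suboptimal") && subdividable) {
      # inadequately matched wide event: annotate its strict sub-events
      # separately and report those instead, keeping the parent interval
      for (j in seq_len(nrow(sub))) {
        sev <- sub[j, ]
        sasg <- annotate_donor(sev, aln, observed, projection, library,
                               params, full_hits = full_hits,
                               strict_sub = NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          min_start = sev$start, min_end = sev$end,
          donor = sasg$donor, levenshtein = sasg$levenshtein,
          match_status = sasg$match_status, definition = "strict",
          parent_start = ev$start, parent_end = ev$end,
          co_best = paste(sasg$co_best, collapse = ","),
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        min_start = ev$start, min_end = ev$end,
        donor = asg$donor, levenshtein = asg$levenshtein,
        match_status = asg$match_status, definition = "loose",
        parent_start = NA_integer_, parent_end = NA_integer_,
        co_best = paste(asg$co_best, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$min_start), , drop = FALSE]
  rownames(events) <- NULL
  events <- prune_merge(events, aln, observed, projection)
  if (nrow(events) == 0L) return(empty)

  n <- nrow(events)
  events$max_start <- events$max_end <- NA_integer_
  events$identical_flank_5len <- events$identical_flank_3len <- NA_integer_
  events$flank5 <- events$flank3 <- NA_character_
  events$introduces_new_hotspot <- NA
  for (i in seq_len(n)) {
    ext <- extend_max(events[i, ], projection)
    events$max_start[i] <- ext$max_start
    events$max_end[i] <- ext$max_end
    events$identical_flank_5len[i] <- ext$identical_flank_5len
    events$identical_flank_3len[i] <- ext$identical_flank_3len
    fl <- flank_context(events[i, ], fun, params$flank_len)
    events$flank5[i] <- fl$flank5
    events$flank3[i] <- fl$flank3
    events$introduces_new_hotspot[i] <-
      introduces_new_hotspot(events[i, ], aln, observed, fun,
                             params$aid_motifs)
  }
  events$aid_distance_5prime <- aid_distance(events$min_start, fun,
                                             params$aid_motifs)
  events$event_index <- seq_len(n)
  events[, c("event_index", "min_start", "min_end", "max_start", "max_end",
             "donor", "levenshtein", "match_status", "definition",
             "parent_start", "parent_end", "co_best",
             "identical_flank_5len", "identical_flank_3len",
             "flank5", "flank3", "aid_distance_5prime",
             "introduces_new_hotspot")]
}

event_frame <- function(n) {
  data.frame(event_index = integer(n), min_start = integer(n),
             min_end = integer(n), max_start = integer(n),
             max_end = integer(n), donor = character(n),
             levenshtein = integer(n), match_status = character(n),
             definition = character(n), parent_start = integer(n),
             parent_end = integer(n), co_best = character(n),
             identical_flank_5len = integer(n),
             identical_flank_3len = integer(n),
             flank5 = character(n), flank3 = character(n),
             aid_distance_5prime = integer(n),
             introduces_new_hotspot = logical(n),
             stringsAsFactors = FALSE)
}

#' Annotate a whole repertoire
#'
#' Applies [detect_events()] to every record and returns a tidy event table
#' plus the per-record summary. Records may be given as a named character
#' vector of sequences or as a data.frame with columns `id`, `seq` and
#' optional `bird`, `tissue`, `isotype` metadata.
#'
#' @param records Named character vector or data.frame (see above).
#' @param refset A [reference_set()].
#' @param params An [sgc_params()] object.
#' @param metadata Optional data.frame joined on `id` to supply `bird`,
#'   `tissue`, `isotype` when `records` is a character vector.
#' @return list with `events` (one row per event, including all columns of
#'   [detect_events()] plus `sequence_id`, `bird`, `tissue`, `isotype`) and
#'   `records` (one row per input with `n_events`).
#' @export
annotate_repertoire <- function(records, refset, params = sgc_params(),
                                metadata = NULL) {
  recs <- as_records(records, metadata)
  if (anyDuplicated(recs$id)) stop("duplicate sequence id(s)")
  projection <- project_donors(refset, params)
  all_events <- vector("list", nrow(recs))
  n_events <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ev <- detect_events(recs$seq[i], refset, params, projection)
    n_events[i] <- nrow(ev)
    if (nrow(ev)) {
      ev$sequence_id <- recs$id[i]
      ev$bird <- recs$bird[i]
      ev$tissue <- recs$tissue[i]
      ev$isotype <- recs$isotype[i]
      all_events[[i]] <- ev
    }
  }
  events <- do.call(rbind, all_events)
  if (is.null(events)) {
    events <- event_frame(0L)
    events$sequence_id <- character()
    events$bird <- events$tissue <- events$isotype <- character()
  }
  front <- c("sequence_id", "bird", "tissue", "isotype")
  events <- events[, c(front, setdiff(names(events), front))]
  rownames(events) <- NULL
  recs$n_events <- n_events
  list(events = events, records = recs)
}

as_records <- function(records, metadata = NULL) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("sequence vector must be named by id")
    recs <- data.frame(id = names(records), seq = unname(records),
                       stringsAsFactors = FALSE)
  } else {
    recs <- as.data.frame(records, stringsAsFactors = FALSE)
    if (!all(c("id", "seq") %in% names(recs)))
      stop("records data.frame needs columns 'id' and 'seq'")
  }
  if (!is.null(metadata)) {
    stopifnot("id" %in% names(metadata))
    recs <- merge(recs, metadata, by = "id", all.x = TRUE, sort = FALSE)
  }
  for (col in c("bird", "tissue", "isotype")) {
    if (!col %in% names(recs)) recs[[col]] <- NA_character_
  }
  recs[, c("id", "seq", "bird", "tissue", "isotype")]
}
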