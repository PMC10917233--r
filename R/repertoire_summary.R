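#' Per-position event coverage over the functional allele
#'
#' Counts, for every functional-allele position, how many events cover it
#' under the chosen interval definition — the positional event map that
#' reveals conversion hotspots along the V region. An event-track table
#' (one row per event with its interval and donor) is attached for
#' per-sequence plotting.
#'
#' @param events Annotated event data.frame (needs `min_start`/`min_end` or
#'   `max_start`/`max_end`, and any grouping columns used).
#' @param functional_length Length of the functional allele.
#' @param definition `"min"` (default) or `"max"`.
#' @param group_by Optional character vector of grouping columns (e.g.
#'   `"bird"`, `"donor"`).
#' @return list of class `positional_coverage`: `profile` (data.frame
#'   `position`, grouping columns, `count`) and `tracks` (per-event rows).
#' @export
positional_coverage <- function(events, functional_length,
                                definition = c("min", "max"),
                                group_by = NULL) {
  definition <- match.arg(definition)
  scol <- paste0(definition, "_start"); ecol <- paste0(definition, "_end")
  stopifnot(all(c(scol, ecol) %in% names(events)))
  count_one <- function(ev) {
    counts <- integer(functional_length)
    for (i in seq_len(nrow(ev))) {
      ix <- ev[[scol]][i]:ev[[ecol]][i]
      counts[ix] <- counts[ix] + 1L
    }
    data.frame(position = seq_len(functional_length), count = counts)
  }
  if (is.null(group_by)) {
    profile <- count_one(events)
  } else {
    stopifnot(all(group_by %in% names(events)))
    key <- interaction(events[group_by], drop = TRUE, sep = "\r")
    parts <- lapply(split(seq_len(nrow(events)), key), function(ix) {
      p <- count_one(events[ix, , drop = FALSE])
      for (g in group_by) p[[g]] <- events[[g]][ix[1L]]
      p
    })
    profile <- do.call(rbind, parts)
    rownames(profile) <- NULL
    profile <- profile[, c("position", group_by, "count")]
  }
  tracks <- data.frame(
    sequence_id = if ("sequence_id" %in% names(events))
      events$sequence_id else NA_character_,
    start = events[[scol]], end = events[[ecol]],
    donor = if ("donor" %in% names(events)) events$donor else NA_character_,
    stringsAsFactors = FALSE)
  structure(list(profile = profile, tracks = tracks,
                 definition = definition,
                 functional_length = functional_length),
            class = "positional_coverage")
}

#' Per-position diversity profile of the pseudogene library
#'
#' For each functional-allele position, the base composition of the donor
#' library (projected onto functional coordinates) is summarised by a Hill
#' number: the effective number of equally frequent bases, ranging from 1
#' (monomorphic column) to 4 (all four bases equifrequent). The default
#' order q = 1 is the exponential of the Shannon entropy; q = 0 gives
#' richness and q = 2 the inverse Simpson index. Gap and N characters are
#' excluded from the frequencies; a column with no bases at all scores
#' `NA`.
#'
#' @param x A [reference_set()], a `donor_projection`, or a character
#'   matrix (sequences x positions) of aligned library columns.
#' @param q Hill-number order, one of 0, 1, 2. Default 1.
#' @param params Alignment parameters (used only when `x` is a reference
#'   set that still needs projecting).
#' @return data.frame `position`, `score` of class `diversity_profile`.
#' @export
diversity_profile <- function(x, q = 1, params = sgc_params()) {
  stopifnot(q %in% c(0, 1, 2))
  mat <- if (inherits(x, "reference_set")) {
    project_donors(x, params)$donor_at
  } else if (inherits(x, "donor_projection")) {
    x$donor_at
  } else if (is.matrix(x) && is.character(x)) {
    x
  } else stop("x must be a reference_set, donor_projection or character matrix")
  score <- apply(mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return(NA_real_)
    p <- tabulate(factor(col, levels = c("A", "C", "G", "T")), nbins = 4L)
    p <- p / sum(p)
    p <- p[p > 0]
    switch(as.character(q),
           "0" = length(p),
           "1" = exp(-sum(p * log(p))),
           "2" = 1 / sum(p^2))
  })
  structure(data.frame(position = seq_len(ncol(mat)), score = score),
            class = c("diversity_profile", "data.frame"))
}

#' Pseudogene usage table with "preferred" donor calls
#'
#' Usage of each donor pseudogene as a percentage of donor-assigned events
#' within each group (typically each bird). Unmatched events are excluded
#' from the denominator and reported separately. A donor is
#' `preferred_all` when its usage exceeds `threshold` percent in every
#' group, and `preferred_any` when it does so in at least one group.
#'
#' @param events Annotated event data.frame.
#' @param group_by Grouping column name (default `"bird"`); `NA` labels are
#'   pooled as `"(ungrouped)"`.
#' @param threshold Percent threshold for the preferred call (default 2).
#' @return list of class `usage_table`: `usage` (data.frame `group`,
#'   `donor`, `n_events`, `percent`), `donors` (data.frame `donor`,
#'   `mean_percent`, `preferred_all`, `preferred_any`), and
#'   `unmatched` (data.frame `group`, `n_unmatched`).
#' @export
pseudogene_usage <- function(events, group_by = "bird", threshold = 2) {
  stopifnot(group_by %in% names(events))
  grp <- as.character(events[[group_by]])
  grp[is.na(grp)] <- "(ungrouped)"
  matched <- !is.na(events$donor)
  groups <- unique(grp)
  empty_groups <- groups[!groups %in% grp[matched]]
  if (length(empty_groups))
    warning("group(s) with zero matched events excluded: ",
            paste(empty_groups, collapse = ", "))
  usage <- do.call(rbind, lapply(setdiff(groups, empty_groups), function(g) {
    sel <- matched & grp == g
    tab <- table(events$donor[sel])
    data.frame(group = g, donor = names(tab),
               n_events = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  if (is.null(usage))
    usage <- data.frame(group = character(), donor = character(),
                        n_events = integer(), percent = numeric())
  used_groups <- unique(usage$group)
  donors <- unique(usage$donor)
  donor_summary <- do.call(rbind, lapply(donors, function(d) {
    pc <- vapply(used_groups, function(g) {
      v <- usage$percent[usage$group == g & usage$donor == d]
      if (length(v)) v else 0
    }, 0)
    data.frame(donor = d, mean_percent = mean(pc),
               preferred_all = all(pc > threshold),
               preferred_any = any(pc > threshold),
               stringsAsFactors = FALSE)
  }))
  if (is.null(donor_summary))
    donor_summary <- data.frame(donor = character(), mean_percent = numeric(),
                                preferred_all = logical(),
                                preferred_any = logical())
  unmatched <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, n_unmatched = sum(!matched & grp == g),
               stringsAsFactors = FALSE)
  }))
  structure(list(usage = usage, donors = donor_summary,
                 unmatched = unmatched, threshold = threshold),
            class = "usage_table")
}

#' Pseudogene usage versus germline distance
#'
#' Pairs each donor's mean usage with its germline distance (kb) from the
#' functional gene and reports the Spearman rank correlation. With up to 7
#' paired donors the permutation p-value is exact (all n! rank
#' permutations); above that the large-sample approximation of
#' `stats::cor.test` is used. Fewer than 3 paired donors: table only, no
#' correlation. Tied or constant ranks use the midrank convention; a
#' zero-variance margin yields rho = 0 by convention.
#'
#' @param usage A `usage_table` from [pseudogene_usage()].
#' @param distances_kb Named numeric vector of donor distances in kb.
#' @return list of class `usage_distance`: `table` (data.frame `donor`,
#'   `distance_kb`, `mean_percent`), `rho`, `p_value` (both `NA` when < 3
#'   pairs).
#' @export
usage_vs_distance <- function(usage, distances_kb) {
  stopifnot(inherits(usage, "usage_table"), !is.null(names(distances_kb)))
  d <- usage$donors
  common <- intersect(d$donor, names(distances_kb))
  tab <- data.frame(donor = common,
                    distance_kb = unname(distances_kb[common]),
                    mean_percent = d$mean_percent[match(common, d$donor)],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$distance_kb), ]
  rownames(tab) <- NULL
  rho <- p_value <- NA_real_
  n <- nrow(tab)
  if (n >= 3L) {
    rho <- spearman_rho(tab$distance_kb, tab$mean_percent)
    p_value <- spearman_perm_p(tab$distance_kb, tab$mean_percent, rho)
  }
  structure(list(table = tab, rho = rho, p_value = p_value),
            class = "usage_distance")
}

# Spearman rho with midranks; 0 when either margin is constant.
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry)
}

spearman_perm_p <- function(x, y, rho_obs, max_exact_n = 7L) {
  n <- length(x)
  if (n <= max_exact_n) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(ix) spearman_rho(x, y[ix]))
    mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  } else {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  }
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' AID-distance distributions of events versus the positional baseline
#'
#' Histogram (percent of events per distance) of the 5' distance to the
#' nearest AID hotspot motif, for event start positions under the minimum
#' or maximum definition, compared with the baseline distribution computed
#' at every position of the functional allele. When a grouping column is
#' given, per-group percentages are averaged across groups.
#'
#' @param events Annotated event data.frame.
#' @param functional Functional-allele string.
#' @param definition `"min"` (default) or `"max"`.
#' @param motifs Trinucleotide motif set.
#' @param group_by Optional grouping column (e.g. `"bird"`).
#' @return list of class `aid_histogram`: `event` (data.frame `distance`,
#'   `percent`), `baseline` (same shape, over all allele positions), and
#'   `n_events`. Positions with no 5' motif are excluded from both.
#' @export
aid_distance_distribution <- function(events, functional,
                                      definition = c("min", "max"),
                                      motifs = sgc_params()$aid_motifs,
                                      group_by = NULL) {
  definition <- match.arg(definition)
  scol <- paste0(definition, "_start")
  dists <- aid_distance(events[[scol]], functional, motifs)
  hist_pct <- function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0L)
      return(data.frame(distance = integer(), percent = numeric()))
    tab <- table(d)
    data.frame(distance = as.integer(names(tab)),
               percent = 100 * as.integer(tab) / length(d))
  }
  if (is.null(group_by)) {
    event_hist <- hist_pct(dists)
  } else {
    stopifnot(group_by %in% names(events))
    parts <- lapply(split(dists, events[[group_by]]), hist_pct)
    merged <- do.call(rbind, parts)
    if (nrow(merged)) {
      agg <- stats::aggregate(percent ~ distance, data = merged,
                              FUN = function(v) sum(v) / length(parts))
      event_hist <- agg[order(agg$distance), ]
      rownames(event_hist) <- NULL
    } else event_hist <- merged
  }
  base <- aid_distance(seq_len(nchar(functional)), functional, motifs)
  structure(list(event = event_hist, baseline = hist_pct(base),
                 definition = definition, n_events = sum(!is.na(dists))),
            class = "aid_histogram")
}

#' False-discovery control mode: run the pipeline with surrogate donors
#'
#' Estimates how often the detector calls conversion events in sequences
#' that should not gene convert, by swapping the pseudogene library for a
#' surrogate donor set (in the original design, same-family germline V
#' alleles of a species without gene conversion). The pipeline is otherwise
#' identical; the fraction of sequences containing at least one event is
#' returned.
#'
#' @param sequences Named character vector of observed sequences.
#' @param functional_allele Named length-1 character vector.
#' @param family_donors Named character vector of surrogate donor alleles
#'   (must not include the functional allele itself).
#' @param params An [sgc_params()] object.
#' @return list: `rate` (fraction of sequences with >= 1 event),
#'   `n_sequences`, `n_with_events`, `events` (the full event table).
#' @export
control_mode_rate <- function(sequences, functional_allele, family_donors,
                              params = sgc_params()) {
  if (length(family_donors) == 0L) stop("empty donor family")
  if (!is.null(names(functional_allele)) &&
      names(functional_allele) %in% names(family_donors))
    family_donors <- family_donors[setdiff(names(family_donors),
                                           names(functional_allele))]
  if (length(family_donors) == 0L)
    stop("donor family contains only the functional allele")
  refset <- reference_set(functional_allele, family_donors)
  res <- annotate_repertoire(sequences, refset, params)
  n_with <- sum(res$records$n_events > 0L)
  list(rate = n_with / nrow(res$records),
       n_sequences = nrow(res$records),
       n_with_events = n_with,
       events = res$events)
}

#' Per-group sequence-level event statistics
#'
#' @param records Per-record data.frame from [annotate_repertoire()] (needs
#'   `n_events` and any grouping column).
#' @param group_by Optional grouping column (default none: one overall row).
#' @return data.frame: `group`, `n_sequences`, `pct_with_event`,
#'   `pct_with_2plus`, `mean_events`, `median_events`.
#' @export
sequence_event_stats <- function(records, group_by = NULL) {
  stopifnot("n_events" %in% names(records))
  one <- function(v, g) {
    data.frame(group = g, n_sequences = length(v),
               pct_with_event = 100 * mean(v >= 1L),
               pct_with_2plus = 100 * mean(v >= 2L),
               mean_events = mean(v), median_events = stats::median(v),
               stringsAsFactors = FALSE)
  }
  if (is.null(group_by)) return(one(records$n_events, "all"))
  stopifnot(group_by %in% names(records))
  parts <- lapply(split(records$n_events, records[[group_by]]),
                  function(v) v)
  out <- do.call(rbind, Map(one, parts, names(parts)))
  rownames(out) <- NULL
  out
}
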