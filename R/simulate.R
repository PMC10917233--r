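#' Simulator configuration
#'
#' Describes the generative model for a synthetic repertoire: each sequence
#' starts as the functional allele, a number of non-overlapping conversion
#' tracts (drawn from the donor library and implanted through the
#' donor-to-functional projection) replace segments of it, and uniform
#' per-site hypermutation noise is applied afterwards over the whole
#' sequence. Optional AID-seeded placement starts tracts at most
#' `aid_offset_max` nt 3' of a hotspot motif; optional template jumping
#' splices two independently simulated molecules at a random point,
#' emulating the PCR chimera artifact.
#'
#' @param n_sequences Number of sequences to simulate. Default 100.
#' @param events_per_sequence Mean of the Poisson number of tracts per
#'   sequence (default 2); `events_min`/`events_max` clamp the draw
#'   (defaults 0 and Inf).
#' @param events_min,events_max Bounds on the per-sequence tract count.
#' @param tract_min,tract_max Tract length bounds in nt (defaults 10 and
#'   300; conversion tracts are expected to reach up to ~300 nt).
#' @param donor_weights Optional named numeric sampling weights over the
#'   donor library (default uniform).
#' @param shm_rate Per-site substitution probability applied after
#'   implanting (default 0.005).
#' @param min_tract_diff Minimum number of positions inside a sampled tract
#'   at which donor and functional allele must differ; tracts are resampled
#'   until satisfied (default 1, so every implanted tract is in principle
#'   visible).
#' @param aid_seeded Logical: place tract starts just 3' of AID motifs
#'   (default FALSE = uniform placement).
#' @param aid_offset_max Maximum offset from a motif 3' end for AID-seeded
#'   placement. Default 3.
#' @param aid_motifs Motif set for seeded placement.
#' @param template_jump_rate Probability that a sequence is a chimera of
#'   two simulated molecules (default 0).
#' @param seed Integer seed fixing all randomness of one simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sequences = 100L,
                       events_per_sequence = 2,
                       events_min = 0L, events_max = Inf,
                       tract_min = 10L, tract_max = 300L,
                       donor_weights = NULL,
                       shm_rate = 0.005,
                       min_tract_diff = 1L,
                       aid_seeded = FALSE,
                       aid_offset_max = 3L,
                       aid_motifs = sgc_params()$aid_motifs,
                       template_jump_rate = 0,
                       seed = 1L) {
  cfg <- list(n_sequences = as.integer(n_sequences),
              events_per_sequence = as.numeric(events_per_sequence),
              events_min = as.integer(events_min),
              events_max = events_max,
              tract_min = as.integer(tract_min),
              tract_max = as.integer(tract_max),
              donor_weights = donor_weights,
              shm_rate = as.numeric(shm_rate),
              min_tract_diff = as.integer(min_tract_diff),
              aid_seeded = isTRUE(aid_seeded),
              aid_offset_max = as.integer(aid_offset_max),
              aid_motifs = toupper(aid_motifs),
              template_jump_rate = as.numeric(template_jump_rate),
              seed = as.integer(seed))
  stopifnot(cfg$n_sequences >= 1L,
            cfg$shm_rate >= 0, cfg$shm_rate <= 1,
            cfg$template_jump_rate >= 0, cfg$template_jump_rate <= 1,
            cfg$tract_min >= 3L, cfg$tract_min <= cfg$tract_max,
            cfg$min_tract_diff >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic germline reference set
#'
#' Builds a random functional V allele and a pseudogene library with
#' realistic divergence structure: variability is concentrated in a fixed
#' set of hypervariable blocks shared by all donors (emulating the
#' CDR-focused divergence of real V-region pseudogene libraries), with a
#' low background substitution rate elsewhere. Clustered divergence is what
#' makes conversion tracts appear as dense mismatch stretches rather than
#' isolated, hypermutation-like point differences.
#'
#' @param length Functional-allele length in nt. Default 300.
#' @param n_donors Number of pseudogenes. Default 8.
#' @param n_blocks Number of hypervariable blocks. Default 5.
#' @param block_len Integer length-2 vector: block length range. Default
#'   c(12, 30).
#' @param block_density Per-site substitution probability inside blocks.
#'   Default 0.45.
#' @param background_rate Per-site substitution probability outside blocks.
#'   Default 0.02.
#' @param distances Logical: attach synthetic germline distances (kb),
#'   increasing with donor index. Default FALSE.
#' @param seed Integer seed.
#' @return A [reference_set()] whose functional allele is named
#'   `"FUNCTIONAL"` and donors `"PG01"`, `"PG02"`, ...
#' @export
synthetic_reference_set <- function(length = 300L, n_donors = 8L,
                                    n_blocks = 5L, block_len = c(12L, 30L),
                                    block_density = 0.45,
                                    background_rate = 0.02,
                                    distances = FALSE, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  fun <- sample(bases, length, replace = TRUE)
  # non-overlapping hypervariable blocks, roughly evenly spread
  bounds <- floor(seq(1L, length + 1L, length.out = n_blocks + 1L))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    lo <- bounds[b]; hi <- bounds[b + 1L] - 1L
    len <- min(sample(block_len[1L]:block_len[2L], 1L), hi - lo + 1L)
    s <- sample(lo:(hi - len + 1L), 1L)
    s:(s + len - 1L)
  })
  in_block <- logical(length)
  for (iv in blocks) in_block[iv] <- TRUE
  donors <- vapply(seq_len(n_donors), function(i) {
    ch <- fun
    rate <- ifelse(in_block, block_density, background_rate)
    mut <- which(stats::runif(length) < rate)
    for (p in mut) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    paste(ch, collapse = "")
  }, "")
  names(donors) <- sprintf("PG%02d", seq_len(n_donors))
  dist_kb <- NULL
  if (distances) {
    dist_kb <- stats::setNames(cumsum(stats::runif(n_donors, 0.5, 3)),
                               names(donors))
  }
  reference_set(stats::setNames(paste(fun, collapse = ""), "FUNCTIONAL"),
                donors, dist_kb)
}

#' Simulate a repertoire with known implanted conversion tracts
#'
#' Generates `cfg$n_sequences` sequences from the functional allele with
#' implanted donor tracts and hypermutation noise, returning both the
#' sequences and the ground truth needed to score recovery. Deterministic
#' for a fixed `cfg` (the seed lives in the config; the caller's RNG state
#' is preserved).
#'
#' @param refset A [reference_set()].
#' @param cfg A [sim_config()].
#' @param params Alignment parameters used for the donor projection.
#' @return list of class `sim_repertoire`: `sequences` (named character
#'   vector), `truth` (data.frame `sequence_id`, `tract_index`, `donor`,
#'   `fun_start`, `fun_end`, `donor_start`, `donor_end`, `core_start`,
#'   `core_end`, `n_diff` — core is the first/last implanted position that
#'   differs from the functional allele, `NA` for fully silent tracts),
#'   `shm` (data.frame `sequence_id`, `position`), and `jumps` (data.frame
#'   `sequence_id`, `breakpoint`).
#' @export
simulate_repertoire <- function(refset, cfg = sim_config(),
                                params = sgc_params()) {
  stopifnot(inherits(refset, "reference_set"), inherits(cfg, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  projection <- project_donors(refset, params)
  fun_chars <- strsplit(projection$functional, "", fixed = TRUE)[[1]]
  L <- length(fun_chars)
  if (cfg$tract_min > L) stop("allele too short for the configured tracts")
  donors <- rownames(projection$donor_at)
  w <- if (is.null(cfg$donor_weights)) {
    stats::setNames(rep(1, length(donors)), donors)
  } else {
    stopifnot(all(names(cfg$donor_weights) %in% donors))
    missing <- setdiff(donors, names(cfg$donor_weights))
    c(cfg$donor_weights, stats::setNames(rep(0, length(missing)), missing))
  }
  motif_ends <- motif_end_positions(projection$functional, cfg$aid_motifs)

  sample_tract <- function(occupied) {
    for (attempt in seq_len(200L)) {
      len <- sample(cfg$tract_min:min(cfg$tract_max, L), 1L)
      if (cfg$aid_seeded && length(motif_ends)) {
        e <- motif_ends[sample.int(length(motif_ends), 1L)]
        s <- e + sample.int(cfg$aid_offset_max + 1L, 1L)  # offset 1..max+1
      } else {
        s <- sample.int(L - len + 1L, 1L)
      }
      if (s < 1L || s + len - 1L > L) next
      iv <- s:(s + len - 1L)
      if (any(occupied[iv])) next
      donor <- sample(names(w), 1L, prob = w)
      seg <- projection$donor_at[donor, iv]
      if (any(seg == "-")) next               # tract falls in a donor gap
      diff_ix <- iv[seg != fun_chars[iv]]
      if (length(diff_ix) < cfg$min_tract_diff) next
      return(list(donor = donor, start = s, end = s + len - 1L,
                  diff_ix = diff_ix))
    }
    NULL
  }

  simulate_molecule <- function() {
    chars <- fun_chars
    occupied <- logical(L)
    n_tracts <- stats::rpois(1L, cfg$events_per_sequence)
    n_tracts <- min(max(n_tracts, cfg$events_min), cfg$events_max)
    tracts <- list()
    while (length(tracts) < n_tracts) {
      tr <- sample_tract(occupied)
      if (is.null(tr)) break
      iv <- tr$start:tr$end
      chars[iv] <- projection$donor_at[tr$donor, iv]
      occupied[iv] <- TRUE
      tracts[[length(tracts) + 1L]] <- tr
    }
    shm_pos <- which(stats::runif(L) < cfg$shm_rate)
    for (p in shm_pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    list(chars = chars, tracts = tracts, shm = shm_pos)
  }

  seqs <- character(cfg$n_sequences)
  truth <- list(); shm_rows <- list(); jump_rows <- list()
  for (i in seq_len(cfg$n_sequences)) {
    id <- sprintf("seq%04d", i)
    mol <- simulate_molecule()
    if (cfg$template_jump_rate > 0 &&
        stats::runif(1L) < cfg$template_jump_rate) {
      mol2 <- simulate_molecule()
      bp <- sample.int(L - 1L, 1L)
      mol$chars <- c(mol$chars[seq_len(bp)], mol2$chars[(bp + 1L):L])
      keep1 <- vapply(mol$tracts, function(t) t$end <= bp, TRUE)
      keep2 <- vapply(mol2$tracts, function(t) t$start > bp, TRUE)
      mol$tracts <- c(mol$tracts[keep1], mol2$tracts[keep2])
      mol$shm <- c(mol$shm[mol$shm <= bp], mol2$shm[mol2$shm > bp])
      jump_rows[[length(jump_rows) + 1L]] <-
        data.frame(sequence_id = id, breakpoint = bp)
    }
    seqs[i] <- paste(mol$chars, collapse = "")
    names(seqs)[i] <- id
    if (length(mol$tracts)) {
      ord <- order(vapply(mol$tracts, `[[`, 0L, "start"))
      for (k in seq_along(ord)) {
        tr <- mol$tracts[[ord[k]]]
        dpos <- projection$donor_pos_at[tr$donor, c(tr$start, tr$end)]
        truth[[length(truth) + 1L]] <- data.frame(
          sequence_id = id, tract_index = k, donor = tr$donor,
          fun_start = tr$start, fun_end = tr$end,
          donor_start = dpos[1L], donor_end = dpos[2L],
          core_start = if (length(tr$diff_ix)) min(tr$diff_ix) else NA_integer_,
          core_end = if (length(tr$diff_ix)) max(tr$diff_ix) else NA_integer_,
          n_diff = length(tr$diff_ix),
          diff_pos = paste(tr$diff_ix, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    if (length(mol$shm)) {
      shm_rows[[length(shm_rows) + 1L]] <-
        data.frame(sequence_id = id, position = mol$shm)
    }
  }
  empty_truth <- data.frame(sequence_id = character(), tract_index = integer(),
                            donor = character(), fun_start = integer(),
                            fun_end = integer(), donor_start = integer(),
                            donor_end = integer(), core_start = integer(),
                            core_end = integer(), n_diff = integer(),
                            diff_pos = character())
  structure(list(
    sequences = seqs,
    truth = if (length(truth)) do.call(rbind, truth) else empty_truth,
    shm = if (length(shm_rows)) do.call(rbind, shm_rows) else
      data.frame(sequence_id = character(), position = integer()),
    jumps = if (length(jump_rows)) do.call(rbind, jump_rows) else
      data.frame(sequence_id = character(), breakpoint = integer()),
    config = cfg
  ), class = "sim_repertoire")
}

#' Score detected events against simulator ground truth
#'
#' A truth tract counts as detected when the union of predicted event
#' intervals for its sequence covers at least `overlap` of the tract's
#' truth interval. Under the maximum definition the truth interval is the
#' full implanted tract. Under the minimum definition it is the tract's
#' *detectable core*: the detector is, by contract, blind to silent tract
#' edges and to isolated 1-2 nt differences (the minimum-span rule), so
#' the core is computed by clustering the tract's true difference
#' positions with the same published merge arithmetic (positions within
#' `window` nt merge; clusters spanning under `min_span` nt are dropped)
#' and spanning the surviving clusters. This clustering is plain arithmetic
#' on the truth table — no alignment or detection code is involved. Tracts
#' with no surviving cluster (effectively silent) are not scoreable and
#' are excluded, with their count reported.
#'
#' Donor accuracy is the fraction of detected tracts whose
#' largest-overlap event names the true donor. The boundary error of a
#' detected tract compares the bounds of the union of its overlapping
#' events with the truth-interval bounds. Sequences without any truth
#' tract contribute to the false-positive statistics.
#'
#' @param truth Truth data.frame from [simulate_repertoire()].
#' @param events Annotated event data.frame (with `sequence_id`).
#' @param sequence_ids All simulated sequence ids (so conversion-free
#'   sequences are counted); defaults to those present in `truth`.
#' @param overlap Minimum fraction of the truth interval that must be
#'   covered (default 0.5).
#' @param definition `"min"` (default) or `"max"`: which predicted interval
#'   and which truth interval to compare.
#' @param window,min_span Merge arithmetic for the detectable core
#'   (defaults match the detector's loose window 6 and minimum span 3).
#' @return list of class `recovery_score`: `detection_rate`,
#'   `donor_accuracy`, `mean_boundary_error`, `n_truth`, `n_detected`,
#'   `n_unscoreable`, `fp_events_per_clean_sequence`, and `per_tract`
#'   (data.frame with one row per scoreable truth tract).
#' @export
score_recovery <- function(truth, events, sequence_ids = NULL,
                           overlap = 0.5, definition = c("min", "max"),
                           window = 6L, min_span = 3L) {
  definition <- match.arg(definition)
  scol <- paste0(definition, "_start"); ecol <- paste0(definition, "_end")
  if (is.null(sequence_ids)) sequence_ids <- unique(truth$sequence_id)
  extra <- setdiff(unique(events$sequence_id), sequence_ids)
  if (length(extra)) stop("events for unknown sequence id(s): ",
                          paste(utils::head(extra, 3L), collapse = ", "))
  if (definition == "min") {
    cores <- lapply(strsplit(truth$diff_pos, ","), function(s) {
      detectable_core(as.integer(s[nzchar(s)]), window, min_span)
    })
  } else {
    cores <- lapply(seq_len(nrow(truth)), function(i) {
      cbind(c(truth$fun_start[i], truth$fun_end[i]))
    })
  }
  scoreable <- !vapply(cores, is.null, TRUE)
  cores <- cores[scoreable]
  per <- data.frame(sequence_id = truth$sequence_id[scoreable],
                    donor = truth$donor[scoreable],
                    t_start = vapply(cores, function(m) min(m[1L, ]), 0L),
                    t_end = vapply(cores, function(m) max(m[2L, ]), 0L),
                    detected = FALSE, donor_correct = NA,
                    boundary_error = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per))) {
    ev <- events[events$sequence_id == per$sequence_id[i], , drop = FALSE]
    if (nrow(ev) == 0L) next
    # truth positions to recover: the core cluster intervals (min
    # definition) or the whole tract (max definition)
    target <- unlist(lapply(seq_len(ncol(cores[[i]])), function(k) {
      cores[[i]][1L, k]:cores[[i]][2L, k]
    }))
    ov <- pmin(ev[[ecol]], per$t_end[i]) - pmax(ev[[scol]], per$t_start[i]) + 1L
    hit <- which(ov > 0L)
    if (length(hit) == 0L) next
    pred_pos <- unlist(lapply(hit, function(j) ev[[scol]][j]:ev[[ecol]][j]))
    if (mean(target %in% pred_pos) >= overlap) {
      jbest <- hit[which.max(ov[hit])]
      per$detected[i] <- TRUE
      per$donor_correct[i] <- !is.na(ev$donor[jbest]) &&
        ev$donor[jbest] == per$donor[i]
      per$boundary_error[i] <-
        (abs(min(ev[[scol]][hit]) - per$t_start[i]) +
         abs(max(ev[[ecol]][hit]) - per$t_end[i])) / 2
    }
  }
  clean <- setdiff(sequence_ids, unique(truth$sequence_id))
  fp <- if (length(clean))
    sum(events$sequence_id %in% clean) / length(clean) else NA_real_
  structure(list(
    detection_rate = if (nrow(per)) mean(per$detected) else NA_real_,
    donor_accuracy = if (any(per$detected))
      mean(per$donor_correct[per$detected]) else NA_real_,
    mean_boundary_error = if (any(per$detected))
      mean(per$boundary_error[per$detected]) else NA_real_,
    n_truth = nrow(per),
    n_detected = sum(per$detected),
    n_unscoreable = sum(!scoreable),
    fp_events_per_clean_sequence = fp,
    per_tract = per
  ), class = "recovery_score")
}

# Cluster intervals of the truth difference positions that survive the
# published merge arithmetic: positions within `window` nt of each other
# cluster, clusters spanning < min_span nt are dropped. Returns a 2 x k
# matrix (row 1 starts, row 2 ends) or NULL when nothing survives. Pure
# integer arithmetic (independent of the detection path).
detectable_core <- function(diff_pos, window = 6L, min_span = 3L) {
  if (length(diff_pos) == 0L) return(NULL)
  diff_pos <- sort(diff_pos)
  cluster <- cumsum(c(0L, diff(diff_pos) > window + 1L))
  spans <- vapply(split(diff_pos, cluster),
                  function(p) c(min(p), max(p)), integer(2L))
  spans <- matrix(spans, nrow = 2L)
  keep <- spans[2L, ] - spans[1L, ] + 1L >= min_span
  if (!any(keep)) return(NULL)
  spans[, keep, drop = FALSE]
}
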