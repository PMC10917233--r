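#' Pipeline parameters
#'
#' Bundles every tunable threshold of the detection, donor-search and
#' annotation stages into a single validated object, so that a whole run is
#' reproducible from one record. All window and length parameters are in
#' nucleotides on the ungapped functional allele.
#'
#' @param merge_window_loose Maximum number of intervening identical
#'   positions between two mismatch stretches for them to be merged under
#'   the loose event definition. Default 6.
#' @param merge_window_strict Same, for the strict definition. Default 3.
#'   Must be `<= merge_window_loose`.
#' @param min_event_span Minimum span (nt) of a merged event; shorter merged
#'   units are discarded as hypermutation-like. Default 3.
#' @param seed_len Exact-match seed length gating the donor search; donors
#'   sharing no `seed_len`-mer with the query receive no hit. Default 6.
#' @param seed_step Step between successive seed start positions in the
#'   query. Default 1.
#' @param min_local_score Minimum raw local-alignment score for a donor hit
#'   to be reported. Interpreted on this package's scoring scale (see
#'   `align_match` etc.), not on any external tool's. Default 20.
#' @param suboptimal_ratio A donor assignment with Levenshtein distance
#'   greater than `suboptimal_ratio * w` for event width `w` is inadequate.
#'   Default 0.5.
#' @param suboptimal_min_width Inadequate assignments trigger re-annotation
#'   of the strict sub-events only when `w > suboptimal_min_width`.
#'   Default 10.
#' @param flank_len Length of the 5' and 3' functional-allele flank strings
#'   attached to every event. Default 10.
#' @param aid_motifs Character vector of trinucleotide AID hotspot motifs,
#'   searched on the forward strand only.
#' @param preferred_threshold Percent-of-events threshold above which a
#'   donor pseudogene is called "preferred" within a group. Default 2.
#' @param align_match,align_mismatch Match/mismatch scores for all pairwise
#'   alignments. Defaults +2/-3.
#' @param align_gap_open,align_gap_extend Affine gap penalties (positive
#'   numbers, subtracted). Defaults 5 and 2.
#' @param merge_gap_semantics Either `"between"` (default; stretches merge
#'   when the count of intervening functional positions is `<= x`) or
#'   `"endpoints"` (merge when `next_start - prev_end <= x`, i.e. the
#'   distance between endpoints).
#'
#' @return An object of class `sgc_params` (a named list).
#' @examples
#' p <- sgc_params()
#' p$merge_window_loose
#' @export
sgc_params <- function(merge_window_loose = 6L,
                       merge_window_strict = 3L,
                       min_event_span = 3L,
                       seed_len = 6L,
                       seed_step = 1L,
                       min_local_score = 20,
                       suboptimal_ratio = 0.5,
                       suboptimal_min_width = 10L,
                       flank_len = 10L,
                       aid_motifs = c("AGC", "AGT", "GGC", "GGT",
                                      "TGC", "AAC", "TAC"),
                       preferred_threshold = 2,
                       align_match = 2,
                       align_mismatch = -3,
                       align_gap_open = 5,
                       align_gap_extend = 2,
                       merge_gap_semantics = c("between", "endpoints")) {
  merge_gap_semantics <- match.arg(merge_gap_semantics)
  p <- list(
    merge_window_loose = as.integer(merge_window_loose),
    merge_window_strict = as.integer(merge_window_strict),
    min_event_span = as.integer(min_event_span),
    seed_len = as.integer(seed_len),
    seed_step = as.integer(seed_step),
    min_local_score = as.numeric(min_local_score),
    suboptimal_ratio = as.numeric(suboptimal_ratio),
    suboptimal_min_width = as.integer(suboptimal_min_width),
    flank_len = as.integer(flank_len),
    aid_motifs = toupper(as.character(aid_motifs)),
    preferred_threshold = as.numeric(preferred_threshold),
    align_match = as.numeric(align_match),
    align_mismatch = as.numeric(align_mismatch),
    align_gap_open = as.numeric(align_gap_open),
    align_gap_extend = as.numeric(align_gap_extend),
    merge_gap_semantics = merge_gap_semantics
  )
  validate_params(p)
  class(p) <- "sgc_params"
  p
}

validate_params <- function(p) {
  stopifnot(
    p$merge_window_strict >= 0L,
    p$merge_window_loose >= 0L,
    p$merge_window_strict <= p$merge_window_loose,
    p$min_event_span >= 1L,
    p$seed_len >= 1L,
    p$seed_step >= 1L,
    p$suboptimal_ratio >= 0,
    p$suboptimal_min_width >= 0L,
    p$flank_len >= 0L,
    p$preferred_threshold >= 0
  )
  if (!all(nchar(p$aid_motifs) == 3L))
    stop("aid_motifs must all be trinucleotides")
  if (!all(grepl("^[ACGT]+$", p$aid_motifs)))
    stop("aid_motifs must be DNA trinucleotides over {A,C,G,T}")
  invisible(p)
}

#' @export
print.sgc_params <- function(x, ...) {
  cat("sgcfinder parameters:\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, paste(val, collapse = ",")))
  }
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' The configuration is a plain-text `key = value` file (one per line, `#`
#' comments allowed). Vector values (the motif list) are comma-separated.
#' Unknown keys are an error so typos are not silently ignored.
#'
#' @param path File path.
#' @return `read_params()` returns an `sgc_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(sgc_params())
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line(s): ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  defaults <- sgc_params()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- trimws(strsplit(vals[i], ",")[[1]])
    if (keys[i] %in% c("aid_motifs", "merge_gap_semantics")) {
      args[[keys[i]]] <- v
    } else {
      args[[keys[i]]] <- as.numeric(v)
    }
  }
  do.call(sgc_params, args)
}

#' @rdname read_params
#' @param params An `sgc_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sgc_params"))
  lines <- vapply(names(params), function(nm) {
    sprintf("%s = %s", nm, paste(params[[nm]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
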