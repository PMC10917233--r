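#' Global pairwise alignment of an observed sequence to the functional allele
#'
#' End-to-end (Needleman-Wunsch) alignment under the affine scoring in
#' `params` (defaults: match +2, mismatch -3, gap open 5, gap extend 2).
#' The alignment engine is `Biostrings::pairwiseAlignment()`, so results are
#' deterministic for fixed inputs and scores. `N` in the observed sequence
#' is scored by the IUPAC fuzzy matrix during alignment; downstream
#' stretch-finding always treats an observed `N` column as a match so that
#' sequencing ambiguity never fabricates an event.
#'
#' @param observed Observed DNA string (may contain N).
#' @param functional Functional-allele DNA string.
#' @param params An [sgc_params()] object.
#' @return An object of class `sgc_alignment`: a list with per-column
#'   character vectors `fun_chars`, `obs_chars` (gap = `-`), integer vectors
#'   `fun_pos`, `obs_pos` (the 1-based position each column occupies in the
#'   ungapped sequence, `NA` at gap columns), and the alignment `score`.
#' @export
align_global <- function(observed, functional, params = sgc_params()) {
  if (!nzchar(observed) || !nzchar(functional))
    stop("cannot align empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = observed, subject = functional, type = "global",
    substitutionMatrix = substitution_matrix(params),
    gapOpening = params$align_gap_open,
    gapExtension = params$align_gap_extend)
  obs_al <- as.character(Biostrings::alignedPattern(pa))
  fun_al <- as.character(Biostrings::alignedSubject(pa))
  new_alignment(fun_al, obs_al, Biostrings::score(pa))
}

substitution_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = params$align_match, mismatch = params$align_mismatch,
    baseOnly = FALSE)
}

new_alignment <- function(fun_aligned, obs_aligned, score = NA_real_) {
  fun_chars <- strsplit(fun_aligned, "", fixed = TRUE)[[1]]
  obs_chars <- strsplit(obs_aligned, "", fixed = TRUE)[[1]]
  stopifnot(length(fun_chars) == length(obs_chars))
  if (any(fun_chars == "-" & obs_chars == "-"))
    stop("alignment column with gaps in both rows")
  fun_pos <- obs_pos <- rep(NA_integer_, length(fun_chars))
  fun_pos[fun_chars != "-"] <- seq_len(sum(fun_chars != "-"))
  obs_pos[obs_chars != "-"] <- seq_len(sum(obs_chars != "-"))
  structure(list(fun_chars = fun_chars, obs_chars = obs_chars,
                 fun_pos = fun_pos, obs_pos = obs_pos,
                 score = score),
            class = "sgc_alignment")
}

#' @export
print.sgc_alignment <- function(x, ...) {
  cat("sgc_alignment:", length(x$fun_chars), "columns, score", x$score, "\n")
  if (length(x$fun_chars) <= 120) {
    cat("  fun:", paste(x$fun_chars, collapse = ""), "\n")
    cat("  obs:", paste(x$obs_chars, collapse = ""), "\n")
  }
  invisible(x)
}

# Map a functional-allele interval to the observed-sequence interval it
# aligns to. Returns c(NA, NA) when the whole interval is deleted in the
# observed sequence.
fun_interval_to_obs <- function(aln, start, end) {
  cols <- which(!is.na(aln$fun_pos) & aln$fun_pos >= start & aln$fun_pos <= end)
  op <- aln$obs_pos[cols]
  op <- op[!is.na(op)]
  if (length(op) == 0L) return(c(NA_integer_, NA_integer_))
  c(min(op), max(op))
}

# Project each donor onto functional-allele coordinates via one global
# alignment per donor. donor_at[p] is the donor base aligned at functional
# position p ("-" where the donor has a gap); donor_pos_at[p] is that
# base's 1-based position in the donor (NA at gaps). Donor insertions
# relative to the functional allele are dropped from the projection; the
# libraries this targets are near-identical to the functional allele so the
# projection is stable.

#' Project the pseudogene library onto functional-allele coordinates
#'
#' Aligns every donor globally to the functional allele and records, for
#' each functional position, the donor base (or `-`) aligned there. This
#' projection is the shared coordinate frame used for donor-segment
#' extraction, maximum-length extension, event pruning, the per-position
#' diversity profile and tract implanting in the simulator.
#'
#' @param refset A [reference_set()].
#' @param params An [sgc_params()] object (alignment scores).
#' @return A list of class `donor_projection`: `donor_at` (character matrix,
#'   donors x functional positions), `donor_pos_at` (integer matrix, same
#'   shape), `functional` (the allele string).
#' @export
project_donors <- function(refset, params = sgc_params()) {
  fun <- unname(refset$functional)
  L <- nchar(fun)
  nms <- names(refset$pseudogenes)
  donor_at <- matrix("-", nrow = length(nms), ncol = L,
                     dimnames = list(nms, NULL))
  donor_pos_at <- matrix(NA_integer_, nrow = length(nms), ncol = L,
                         dimnames = list(nms, NULL))
  for (nm in nms) {
    aln <- align_global(refset$pseudogenes[[nm]], fun, params)
    keep <- !is.na(aln$fun_pos)
    donor_at[nm, aln$fun_pos[keep]] <- aln$obs_chars[keep]
    donor_pos_at[nm, aln$fun_pos[keep]] <- aln$obs_pos[keep]
  }
  structure(list(donor_at = donor_at, donor_pos_at = donor_pos_at,
                 functional = fun),
            class = "donor_projection")
}

# Donor segment over a functional interval, gaps removed.
donor_segment <- function(projection, donor, start, end) {
  chars <- projection$donor_at[donor, start:end]
  paste(chars[chars != "-"], collapse = "")
}
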