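#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased, `U` is mapped to `T`, and IMGT-style alignment
#' gaps (`.` characters) are removed; the gapped-to-ungapped position map of
#' each record is kept in the `"gap_map"` attribute for convenience when
#' region boundaries are given on the gapped reference. Characters outside
#' `{A,C,G,T,N}` (after these normalisations) are rejected, as are duplicate
#' record names and empty files.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences. The attribute `"gap_map"`
#'   is a list (one integer vector per record) mapping ungapped positions to
#'   their original gapped coordinates; it is `NULL`-free and only present
#'   when at least one record contained gaps.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(nms))) stop("FASTA record with empty name in ", path)
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop("duplicate FASTA name(s): ", paste(unique(dup), collapse = ", "))
  raw <- toupper(as.character(ss))
  raw <- chartr("U", "T", raw)
  gap_map <- vector("list", length(raw))
  seqs <- character(length(raw))
  for (i in seq_along(raw)) {
    chars <- strsplit(raw[i], "", fixed = TRUE)[[1]]
    keep <- chars != "." & chars != "-"
    if (!all(keep)) gap_map[[i]] <- which(keep)
    seqs[i] <- paste(chars[keep], collapse = "")
  }
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    stop("invalid characters in FASTA record(s): ",
         paste(nms[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("zero-length sequence after degapping in ", path)
  names(seqs) <- nms
  if (any(!vapply(gap_map, is.null, TRUE))) {
    names(gap_map) <- nms
    attr(seqs, "gap_map") <- gap_map
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

#' Assemble the germline reference set
#'
#' A reference set is the single functional V allele plus the pseudogene
#' donor library, optionally with germline distances (kb) from each
#' pseudogene to the functional gene. References must be unambiguous DNA:
#' `N` is allowed in repertoire reads but not here.
#'
#' @param functional_path FASTA with the functional allele. If it holds more
#'   than one record, `functional_name` must select one.
#' @param pseudogene_path FASTA with the pseudogene donor library (>= 1
#'   record, names distinct from the functional allele's).
#' @param distances_path Optional 2-column TSV (`name`, `kb`); names absent
#'   from the library are dropped with a warning because germline distance
#'   annotations are typically incomplete.
#' @param functional_name Name of the functional allele when
#'   `functional_path` has several records.
#' @return An object of class `reference_set` with elements `functional`
#'   (named length-1 character), `pseudogenes` (named character vector) and
#'   `distances_kb` (named numeric or `NULL`).
#' @export
load_reference_set <- function(functional_path, pseudogene_path,
                               distances_path = NULL,
                               functional_name = NULL) {
  fun <- read_fasta(functional_path)
  if (length(fun) > 1L) {
    if (is.null(functional_name))
      stop("functional FASTA has ", length(fun),
           " records; supply functional_name")
    if (!functional_name %in% names(fun))
      stop("functional_name '", functional_name, "' not found")
    fun <- fun[functional_name]
  }
  pg <- read_fasta(pseudogene_path)
  distances <- NULL
  if (!is.null(distances_path)) {
    d <- utils::read.delim(distances_path, header = FALSE,
                           col.names = c("name", "kb"),
                           colClasses = c("character", "numeric"))
    unknown <- setdiff(d$name, names(pg))
    if (length(unknown)) {
      warning("distance entries for unknown pseudogene(s) ignored: ",
              paste(unknown, collapse = ", "))
      d <- d[d$name %in% names(pg), , drop = FALSE]
    }
    distances <- stats::setNames(d$kb, d$name)
  }
  reference_set(fun, pg, distances)
}

#' @rdname load_reference_set
#' @param functional Named length-1 character vector (the allele).
#' @param pseudogenes Named character vector of donor sequences.
#' @param distances_kb Optional named numeric vector of distances in kb.
#' @export
reference_set <- function(functional, pseudogenes, distances_kb = NULL) {
  stopifnot(length(functional) == 1L, !is.null(names(functional)),
            nzchar(names(functional)))
  if (length(pseudogenes) < 1L) stop("reference set needs >= 1 pseudogene")
  if (is.null(names(pseudogenes)) || any(!nzchar(names(pseudogenes))))
    stop("pseudogenes must be named")
  if (anyDuplicated(names(pseudogenes)))
    stop("duplicate pseudogene names")
  if (names(functional) %in% names(pseudogenes))
    stop("functional allele name '", names(functional),
         "' collides with a pseudogene name")
  allseq <- c(functional, pseudogenes)
  if (any(grepl("N", allseq, fixed = TRUE)))
    stop("reference sequences must not contain N")
  if (any(!grepl("^[ACGT]+$", allseq)))
    stop("reference sequences must be DNA over {A,C,G,T}")
  if (!is.null(distances_kb)) {
    stopifnot(is.numeric(distances_kb), !is.null(names(distances_kb)))
    if (any(distances_kb < 0)) stop("distances must be >= 0")
    unknown <- setdiff(names(distances_kb), names(pseudogenes))
    if (length(unknown)) stop("distances for unknown pseudogene(s): ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(functional = functional,
                 pseudogenes = pseudogenes,
                 distances_kb = distances_kb),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:\n")
  cat("  functional:", names(x$functional),
      sprintf("(%d nt)\n", nchar(x$functional)))
  cat("  pseudogenes:", length(x$pseudogenes), "donors,",
      min(nchar(x$pseudogenes)), "-", max(nchar(x$pseudogenes)), "nt\n")
  if (!is.null(x$distances_kb))
    cat("  germline distances for", length(x$distances_kb), "donors\n")
  invisible(x)
}

#' Define a V-region map (FWR/CDR partition)
#'
#' Coordinates are 1-based inclusive on the ungapped functional allele.
#' Regions must be in ascending order, non-overlapping and within the allele.
#'
#' @param labels Character vector of region labels, a subset of
#'   FWR1/CDR1/FWR2/CDR2/FWR3/CDR3 in order.
#' @param starts,ends Integer vectors of 1-based inclusive bounds.
#' @param functional_length Length of the functional allele.
#' @return A data.frame of class `region_map` with columns
#'   `region`, `start`, `end`.
#' @export
region_map <- function(labels, starts, ends, functional_length) {
  allowed <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3")
  stopifnot(length(labels) == length(starts),
            length(starts) == length(ends))
  if (!all(labels %in% allowed))
    stop("region labels must be among ", paste(allowed, collapse = ", "))
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (any(starts < 1L) || any(ends > functional_length) || any(starts > ends))
    stop("region bounds outside [1, functional_length] or inverted")
  if (is.unsorted(match(labels, allowed), strictly = TRUE))
    stop("regions must appear in FWR1..CDR3 order")
  if (any(starts[-1] <= ends[-length(ends)]))
    stop("regions overlap or are out of order")
  structure(data.frame(region = labels, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            class = c("region_map", "data.frame"))
}

#' Label positions with their V region
#'
#' @param positions Integer vector of functional-allele positions.
#' @param map A `region_map`.
#' @return Character vector of region labels (`NA` outside all regions).
#' @export
assign_region <- function(positions, map) {
  stopifnot(inherits(map, "region_map"))
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(map))) {
    hit <- positions >= map$start[i] & positions <= map$end[i]
    out[hit] <- map$region[i]
  }
  out
}

event_table_columns <- c(
  "sequence_id", "bird", "tissue", "isotype", "event_index",
  "min_start", "min_end", "max_start", "max_end", "donor",
  "levenshtein", "match_status", "flank5", "flank3",
  "aid_distance_5prime", "introduces_new_hotspot"
)

#' Write / read the annotated event table
#'
#' One row per annotated event, TSV, coordinates 1-based inclusive on the
#' ungapped functional allele. Records with zero events contribute zero
#' rows. `read_event_table()` restores the column types so that a write/read
#' round trip is the identity.
#'
#' @param events Event data.frame as produced by [annotate_repertoire()].
#' @param path Output path.
#' @return `path` invisibly; `read_event_table()` returns the data.frame.
#' @export
write_event_table <- function(events, path) {
  missing_cols <- setdiff(event_table_columns, names(events))
  if (length(missing_cols))
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- events[, event_table_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write event table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(
                            sequence_id = "character", bird = "character",
                            tissue = "character", isotype = "character",
                            event_index = "integer",
                            min_start = "integer", min_end = "integer",
                            max_start = "integer", max_end = "integer",
                            donor = "character", levenshtein = "integer",
                            match_status = "character",
                            flank5 = "character", flank3 = "character",
                            aid_distance_5prime = "integer",
                            introduces_new_hotspot = "logical"))
  df$flank5[is.na(df$flank5)] <- ""
  df$flank3[is.na(df$flank3)] <- ""
  df
}
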