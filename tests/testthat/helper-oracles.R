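# Independent oracles used across the suite. These deliberately share no
# code with the package: plain dynamic programming and brute-force scans.

# Unit-cost edit distance by full DP.
lev_dp <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (A[i] != B[j]))
    }
  }
  d[n + 1L, m + 1L]
}

# Local alignment (Gotoh affine) with the package's default scores:
# match +2, mismatch -3, gap open 5, gap extend 2 (a length-k gap costs
# 5 + 2k, the Biostrings convention). Returns the optimal score and the
# identity (matches / alignment columns) of one optimal alignment, found
# by traceback preferring diagonal moves.
sw_local_oracle <- function(query, subject,
                            match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  A <- strsplit(query, "", fixed = TRUE)[[1]]
  B <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (move along subject)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in subject
  open <- gap_open + gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, E[i + 1L, j] - gap_ext)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, F[i, j + 1L] - gap_ext)
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
    }
  }
  best <- max(H)
  if (best <= 0) return(list(score = 0, identity = NA_real_))
  ix <- which(H == best, arr.ind = TRUE)[1L, ]
  i <- ix[1L]; j <- ix[2L]
  nm <- 0L; cols <- 0L
  state <- "H"
  while (i > 1L || j > 1L) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      if (i > 1L && j > 1L && H[i, j] == H[i - 1L, j - 1L] + s) {
        nm <- nm + (A[i - 1L] == B[j - 1L]); cols <- cols + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else if (H[i, j] == F[i, j]) {
        state <- "F"
      } else stop("oracle traceback failed")
    } else if (state == "E") {
      cols <- cols + 1L
      if (E[i, j] == H[i, j - 1L] - open) { j <- j - 1L; state <- "H" }
      else { j <- j - 1L }  # stay in E
    } else {
      cols <- cols + 1L
      if (F[i, j] == H[i - 1L, j] - open) { i <- i - 1L; state <- "H" }
      else { i <- i - 1L }
    }
  }
  list(score = best, identity = nm / cols)
}

# Brute-force 5' AID-motif distance: scan leftwards from the position.
aid_distance_bruteforce <- function(position, functional, motifs) {
  vapply(position, function(p) {
    q <- p - 1L
    while (q >= 3L) {
      if (substring(functional, q - 2L, q) %in% motifs)
        return(as.integer(p - q - 1L))
      q <- q - 1L
    }
    NA_integer_
  }, NA_integer_)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Mutate a DNA string at given positions (to a different random base).
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# Deterministic substitution by base rotation (A->C->G->T->A). Guarantees a
# mismatch at every listed position without creating shift homology, so the
# all-substitution global alignment is the optimum.
rotate_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  ch[positions] <- rot[ch[positions]]
  paste(ch, collapse = "")
}

# Hand-built donor projection for unit tests: donors given as full-length
# strings already in functional coordinates (no gaps).
fake_projection <- function(functional, donors) {
  mat <- do.call(rbind, lapply(donors, function(d)
    strsplit(d, "", fixed = TRUE)[[1]]))
  rownames(mat) <- names(donors)
  pos <- matrix(rep(seq_len(nchar(functional)), each = length(donors)),
                nrow = length(donors), dimnames = list(names(donors), NULL))
  structure(list(donor_at = mat, donor_pos_at = pos, functional = functional),
            class = "donor_projection")
}

# Gapless identity alignment for unit tests of refine/annotate operations.
identity_alignment <- function(functional, observed = functional) {
  sgcfinder:::new_alignment(functional, observed)
}
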