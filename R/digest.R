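#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal of lysine (K) or arginine (R), with
#' cleavage suppressed when the following residue is proline (the conventional
#' trypsin rule). Peptides with up to `max_missed_cleavages` internal missed
#' cleavage sites are enumerated.
#'
#' @param sequence Protein sequence (single string, 20 standard amino acids).
#' @param max_missed_cleavages Maximum number of internal missed cleavages
#'   (default 0).
#' @param protein_id Optional identifier used in error messages.
#'
#' @return A tibble with columns `peptide`, `start`, `end` (1-based inclusive
#'   coordinates on the protein) and `n_missed` (number of internal missed
#'   cleavage sites). At 0 missed cleavages the peptides tile the sequence.
#'
#' @examples
#' tryptic_digest("AAKPGGKCCR")
#' tryptic_digest("KR", max_missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, max_missed_cleavages = 0L,
                           protein_id = "<sequence>") {
  chars <- check_sequence(sequence, protein_id)
  stopifnot(max_missed_cleavages >= 0L)
  n <- length(chars)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  # fully-cleaved fragment boundaries
  starts <- c(1L, cut_after[cut_after < n] + 1L)
  ends <- c(cut_after[cut_after < n], n)
  k <- length(starts)
  out <- vector("list", max_missed_cleavages + 1L)
  for (m in 0:max_missed_cleavages) {
    idx <- seq_len(max(k - m, 0L))
    if (length(idx) == 0L) break
    s <- starts[idx]
    e <- ends[idx + m]
    out[[m + 1L]] <- tibble::tibble(
      peptide = vapply(seq_along(s), function(i) {
        paste(chars[s[i]:e[i]], collapse = "")
      }, character(1)),
      start = s, end = e, n_missed = m
    )
  }
  dplyr::bind_rows(out)
}

#' Count theoretically observable peptides
#'
#' Counts the distinct fully-cleaved (0 missed cleavages) tryptic peptides of a
#' protein whose length falls inside the observability window. This is the
#' denominator of the iBAQ calculation.
#'
#' @inheritParams tryptic_digest
#' @param window Length-2 numeric vector giving the inclusive peptide-length
#'   window considered observable by LC-MS/MS (default `c(7, 30)` residues;
#'   use `c(1, Inf)` to count all fully-cleaved peptides).
#'
#' @return Integer count (possibly 0; a protein whose tryptic peptides are all
#'   too short or too long has no observable peptides and an undefined iBAQ).
#' @export
observable_peptides <- function(sequence, window = c(7, 30),
                                protein_id = "<sequence>") {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  pep <- tryptic_digest(sequence, 0L, protein_id)
  len <- nchar(pep$peptide)
  length(unique(pep$peptide[len >= window[1] & len <= window[2]]))
}
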