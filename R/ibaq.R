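#' Intensity-based absolute quantification (iBAQ)
#'
#' For each protein and replicate, iBAQ is the sum of its peptide intensities
#' divided by the number of theoretically observable tryptic peptides. The
#' relative iBAQ normalises by the per-replicate sum over all quantified
#' proteins and is a proxy for the molar fraction of each protein in the
#' sample.
#'
#' Proteins with no observable peptide (an atypical tryptic cleavage-site
#' distribution, as for V-ATPase stator subunits G1/G2) but non-zero intensity
#' have an undefined iBAQ: they are flagged, excluded from the normalisation
#' denominator, and a warning is issued.
#'
#' @param intensities Peptide-intensity table: a data frame with columns
#'   `protein_id`, `peptide`, `replicate`, `intensity` (one row per peptide
#'   per replicate; intensities are arbitrary units >= 0). An optional
#'   `protein_score` column can be pre-filtered with [filter_protein_scores()].
#' @param sequences Named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences; names are protein ids.
#' @param window Observability window passed to [observable_peptides()].
#'
#' @return A tibble with one row per (protein, replicate): `protein_id`,
#'   `replicate`, `observable_peptides`, `ibaq`, `rel_ibaq`, `flagged`.
#'   `rel_ibaq` sums to 1 over unflagged proteins within each replicate.
#' @seealso [estimate_stoichiometry()], [top_n_database()]
#' @export
compute_ibaq <- function(intensities, sequences, window = c(7, 30)) {
  sequences <- as_sequence_vector(sequences)
  intensities <- tibble::as_tibble(intensities)
  required_columns(intensities, c("protein_id", "peptide", "replicate",
                                  "intensity"))
  stopifnot(all(intensities$intensity >= 0))
  unknown <- setdiff(unique(intensities$protein_id), names(sequences))
  if (length(unknown) > 0L) {
    stop("peptides map to unknown protein(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  is_sub <- mapply(grepl, intensities$peptide,
                   sequences[intensities$protein_id], fixed = TRUE)
  if (!all(is_sub)) {
    bad <- which(!is_sub)[1]
    stop("peptide '", intensities$peptide[bad],
         "' is not a substring of protein '", intensities$protein_id[bad],
         "'", call. = FALSE)
  }

  obs <- vapply(names(sequences), function(p) {
    observable_peptides(sequences[[p]], window, p)
  }, integer(1))

  quant <- intensities |>
    dplyr::group_by(.data$protein_id, .data$replicate) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop") |>
    dplyr::mutate(
      observable_peptides = unname(obs[.data$protein_id]),
      flagged = .data$observable_peptides == 0L & .data$total > 0,
      ibaq = ifelse(.data$flagged, NA_real_,
                    .data$total / .data$observable_peptides)
    )
  if (any(quant$flagged)) {
    warning("protein(s) with intensity but no observable peptide excluded ",
            "from normalisation: ",
            paste(unique(quant$protein_id[quant$flagged]), collapse = ", "),
            call. = FALSE)
  }
  quant |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(rel_ibaq = .data$ibaq / sum(.data$ibaq, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "replicate", "observable_peptides",
                  "ibaq", "rel_ibaq", "flagged") |>
    dplyr::arrange(.data$protein_id, .data$replicate)
}

#' Drop proteins below an upstream identification score
#'
#' Mirrors the conventional pre-quantification cleanup in which protein hits
#' with a search-engine score below a threshold are removed before iBAQ. The
#' score is treated as an opaque input column.
#'
#' @param intensities Peptide-intensity table with a `protein_score` column.
#' @param min_score Minimum retained score (default 100).
#' @export
filter_protein_scores <- function(intensities, min_score = 100) {
  required_columns(intensities, "protein_score")
  dplyr::filter(tibble::as_tibble(intensities),
                .data$protein_score >= min_score)
}

#' Median relative iBAQ per protein
#'
#' @param quant Output of [compute_ibaq()].
#' @return Tibble `protein_id`, `median_rel_ibaq`.
#' @export
median_rel_ibaq <- function(quant) {
  quant |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(median_rel_ibaq = median(.data$rel_ibaq, na.rm = TRUE),
                     .groups = "drop")
}

#' Estimate protein stoichiometry relative to a reference subunit
#'
#' Ratios of median relative iBAQ against a reference protein; with noise-free
#' input the ratios equal the planted copy-number ratios (e.g. the 3:3:3:3:1:1:1:1
#' stoichiometry of a V1-ATPase-like complex against a single-copy subunit).
#'
#' @param quant Output of [compute_ibaq()].
#' @param reference Reference protein id (ratio 1 by construction).
#' @param members Character vector of member protein ids (must contain
#'   `reference`).
#' @return Tibble `protein_id`, `ratio`, `ratio_sd` (spread of per-replicate
#'   ratios; NA with a single replicate).
#' @export
estimate_stoichiometry <- function(quant, reference, members) {
  stopifnot(reference %in% members)
  quant <- dplyr::filter(quant, .data$protein_id %in% members)
  ref <- dplyr::filter(quant, .data$protein_id == reference,
                       !is.na(.data$rel_ibaq), .data$rel_ibaq > 0)
  if (nrow(ref) == 0L) {
    stop("reference protein '", reference,
         "' has no positive iBAQ in any replicate", call. = FALSE)
  }
  ref <- dplyr::select(ref, "replicate", ref_rel = "rel_ibaq")
  per_rep <- quant |>
    dplyr::inner_join(ref, by = "replicate") |>
    dplyr::mutate(rep_ratio = .data$rel_ibaq / .data$ref_rel)
  med <- median_rel_ibaq(quant)
  ref_med <- med$median_rel_ibaq[med$protein_id == reference]
  per_rep |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(ratio_sd = stats::sd(.data$rep_ratio), .groups = "drop") |>
    dplyr::right_join(med, by = "protein_id") |>
    dplyr::mutate(ratio = .data$median_rel_ibaq / ref_med) |>
    dplyr::select("protein_id", "ratio", "ratio_sd") |>
    dplyr::arrange(.data$protein_id)
}

#' Select the top-N proteins by abundance
#'
#' Builds the reduced search database used for large-scale cross-linking: the
#' `n` proteins with the highest median relative iBAQ (default 400). Ties are
#' broken deterministically by lexicographic protein id.
#'
#' @param quant Output of [compute_ibaq()].
#' @param n Number of proteins to retain (default 400).
#' @return Character vector of protein ids, most abundant first.
#' @export
top_n_database <- function(quant, n = 400) {
  stopifnot(n >= 1)
  med <- median_rel_ibaq(quant)
  med <- med[order(-med$median_rel_ibaq, med$protein_id), ]
  if (n > nrow(med)) {
    warning("n = ", n, " exceeds the ", nrow(med),
            " quantified proteins; returning all", call. = FALSE)
    n <- nrow(med)
  }
  med$protein_id[seq_len(n)]
}

as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  sequences
}

required_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
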