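#' Membrane-topology segment tables
#'
#' A topology table annotates residue intervals of a protein with membrane
#' compartments: `cytosolic`, `TMH` (transmembrane helix) or `luminal`.
#' Coordinates are 1-based inclusive; segments of one protein must not
#' overlap (overlaps are rejected at load). Columns: `protein_id`, `start`,
#' `end`, `compartment`.
#'
#' @param segments A data frame in the schema above.
#' @param file Path to a tab-separated segment table.
#' @name topology-table
#' @export
validate_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  required_columns(segments, c("protein_id", "start", "end", "compartment"))
  stopifnot(all(segments$start <= segments$end),
            all(segments$compartment %in% c("cytosolic", "TMH", "luminal")))
  overlap <- segments |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(bad = dplyr::n() > 1 &&
                       any(.data$start[-1] <= .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(overlap$bad)) {
    stop("overlapping topology segments for protein(s): ",
         paste(overlap$protein_id[overlap$bad], collapse = ", "),
         call. = FALSE)
  }
  segments
}

#' @rdname topology-table
#' @export
read_segments <- function(file) {
  validate_segments(read.delim(file, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' Membrane compartment of a residue
#'
#' Returns the compartment of the unique segment covering the residue, or
#' `"unannotated"` when no segment covers it. Segment boundaries are
#' inclusive: a residue exactly at a boundary belongs to the segment that
#' lists it.
#'
#' @param protein Protein id.
#' @param residue Residue number (1-based; must be >= 1 and, when
#'   `protein_length` is given, within it).
#' @param segments Validated topology table (see [validate_segments()]).
#' @param protein_length Optional protein length for bounds checking.
#' @export
compartment_of <- function(protein, residue, segments,
                           protein_length = NULL) {
  if (residue < 1 || (!is.null(protein_length) && residue > protein_length)) {
    stop("residue ", residue, " out of range for protein '", protein, "'",
         call. = FALSE)
  }
  hit <- segments$protein_id == protein & segments$start <= residue &
    segments$end >= residue
  if (!any(hit)) "unannotated" else segments$compartment[which(hit)[1]]
}

#' Compartment label of a cross-link
#'
#' Classifies a cross-link by the unordered pair of compartments of its two
#' residues: `cyt-cyt`, `lum-lum`, `cyt-lum`, `involves-TMH` (either side in a
#' transmembrane helix) or `unannotated` (either side uncovered). Symmetric in
#' the two residues; this is how links across the membrane (e.g. a cytosolic
#' SV2A lysine to a luminal Synaptophysin lysine) are identified.
#'
#' @param links Cross-link table.
#' @param segments Validated topology table.
#' @return Character vector of labels, one per link.
#' @export
classify_link_topology <- function(links, segments) {
  vapply(seq_len(nrow(links)), function(i) {
    ca <- compartment_of(links$protein_a[i], links$residue_a[i], segments)
    cb <- compartment_of(links$protein_b[i], links$residue_b[i], segments)
    if (ca == "unannotated" || cb == "unannotated") return("unannotated")
    if (ca == "TMH" || cb == "TMH") return("involves-TMH")
    pair <- sort(c(ca, cb))
    if (all(pair == "cytosolic")) "cyt-cyt"
    else if (all(pair == "luminal")) "lum-lum"
    else "cyt-lum"
  }, character(1))
}

#' Per-compartment labelling report
#'
#' Counts chemically labelled residues per protein and compartment and flags
#' proteins whose luminal segments carry at least one label -- the
#' accessibility signal for luminal loops reachable by a non-membrane-
#' permeable reagent. Sites should already have passed
#' [filter_label_sites()].
#'
#' @param sites Label-site table with columns `protein_id`, `residue` (other
#'   columns such as `reagent` are preserved in grouping if present).
#' @param segments Validated topology table.
#' @return A list with `counts` (tibble `protein_id`, `compartment`,
#'   `n_sites`) and `luminal_flag` (tibble `protein_id`,
#'   `luminal_labelled`).
#' @export
accessibility_report <- function(sites, segments) {
  required_columns(sites, c("protein_id", "residue"))
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) == 0L) {
    return(list(counts = tibble::tibble(protein_id = character(),
                                        compartment = character(),
                                        n_sites = integer()),
                luminal_flag = tibble::tibble(protein_id = character(),
                                              luminal_labelled = logical())))
  }
  sites$compartment <- vapply(seq_len(nrow(sites)), function(i) {
    compartment_of(sites$protein_id[i], sites$residue[i], segments)
  }, character(1))
  counts <- sites |>
    dplyr::count(.data$protein_id, .data$compartment, name = "n_sites")
  flags <- counts |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(luminal_labelled = any(.data$compartment == "luminal" &
                                              .data$n_sites > 0),
                     .groups = "drop")
  list(counts = counts, luminal_flag = flags)
}

#' Proteolytic cleavage of a protein sequence
#'
#' Splits a sequence at the bond between positions `p` and `p + 1`, as for
#' botulinum neurotoxin B which cleaves Synaptobrevin-2 between Q76 and F77.
#' Fragment lengths always sum to the protein length. When an expected
#' residue letter is supplied it is checked against the sequence at `p`.
#'
#' @param sequence Protein sequence.
#' @param p Cleavage position (`1 <= p < nchar(sequence)`).
#' @param expected_residue Optional single letter expected at position `p`.
#' @return A list with `n_fragment` (residues `1..p`) and `c_fragment`
#'   (`p+1..end`), each carrying `start`/`end` attributes.
#' @export
cleave_sequence <- function(sequence, p, expected_residue = NULL) {
  n <- nchar(sequence)
  if (p < 1 || p >= n) {
    stop("cleavage position ", p, " out of range (protein length ", n, ")",
         call. = FALSE)
  }
  at <- substr(sequence, p, p)
  if (!is.null(expected_residue) && at != expected_residue) {
    stop("expected residue '", expected_residue, "' at position ", p,
         " but observed '", at, "'", call. = FALSE)
  }
  list(
    n_fragment = structure(substr(sequence, 1, p), start = 1L, end = p),
    c_fragment = structure(substr(sequence, p + 1, n),
                           start = p + 1L, end = as.integer(n))
  )
}
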