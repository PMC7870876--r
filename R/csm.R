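#' Cross-link spectrum match (CSM) tables
#'
#' A CSM table holds one row per cross-link spectrum match: the two matched
#' peptides (alpha/beta) with their protein coordinates and link positions,
#' fragment-ion annotations, and replicate/condition labels. The canonical
#' tab-separated schema has columns:
#'
#' `csm_id`, `spectrum_ref`, `protein_a`, `peptide_a`, `start_a`, `end_a`,
#' `link_pos_a`, `protein_b`, `peptide_b`, `start_b`, `end_b`, `link_pos_b`,
#' `fragments`, `replicate`, `condition`, `score`
#'
#' `start`/`end` are 1-based inclusive coordinates on the protein; `link_pos`
#' is 1-based within the peptide. The linked residue must be a lysine, or the
#' protein N-terminus (`start = 1`, `link_pos = 1`), matching BS3 chemistry.
#' `fragments` encodes the fragment-ion annotations as
#' `pep:series:index:relint` entries separated by `;`, e.g.
#' `"a:b:2:1.00;a:b:3:0.85;b:y:1:0.40"` (pep is `a` or `b`, series `b` or `y`,
#' index the 1-based series index, relint the relative intensity in \[0,1\]).
#'
#' @param file Path to a tab-separated CSM table. Common column aliases from
#'   upstream formatting tools (e.g. `Protein1`, `PepPos1`, `LinkPos1`) are
#'   mapped onto the canonical names; unknown columns are preserved untouched.
#' @return A tibble in the canonical schema.
#' @name csm-table
NULL

CSM_COLUMNS <- c("csm_id", "spectrum_ref",
                 "protein_a", "peptide_a", "start_a", "end_a", "link_pos_a",
                 "protein_b", "peptide_b", "start_b", "end_b", "link_pos_b",
                 "fragments", "replicate", "condition", "score")

CSM_ALIASES <- c(
  Protein1 = "protein_a", Protein2 = "protein_b",
  PepSeq1 = "peptide_a", PepSeq2 = "peptide_b",
  PepPos1 = "start_a", PepPos2 = "start_b",
  LinkPos1 = "link_pos_a", LinkPos2 = "link_pos_b",
  Score = "score", Condition = "condition", Replicate = "replicate",
  SpectrumID = "spectrum_ref"
)

#' @rdname csm-table
#' @export
read_csms <- function(file) {
  df <- tibble::as_tibble(read.delim(file, sep = "\t", header = TRUE,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE))
  hit <- names(df) %in% names(CSM_ALIASES)
  names(df)[hit] <- CSM_ALIASES[names(df)[hit]]
  if (!"end_a" %in% names(df) && all(c("start_a", "peptide_a") %in% names(df))) {
    df$end_a <- df$start_a + nchar(df$peptide_a) - 1L
    df$end_b <- df$start_b + nchar(df$peptide_b) - 1L
  }
  if (!"csm_id" %in% names(df)) df$csm_id <- seq_len(nrow(df))
  validate_csms(df)
}

#' @rdname csm-table
#' @param csms A CSM table (tibble).
#' @export
write_csms <- function(csms, file) {
  write.table(csms, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

validate_csms <- function(csms) {
  required_columns(csms, setdiff(CSM_COLUMNS, c("spectrum_ref", "score")))
  stopifnot(all(nzchar(csms$replicate)))
  bad_a <- csms$end_a - csms$start_a + 1L != nchar(csms$peptide_a)
  bad_b <- csms$end_b - csms$start_b + 1L != nchar(csms$peptide_b)
  if (any(bad_a | bad_b)) {
    stop("peptide coordinates inconsistent with sequence length in ",
         sum(bad_a | bad_b), " row(s)", call. = FALSE)
  }
  tibble::as_tibble(csms)
}

#' Absolute residue position of a cross-link site
#'
#' Converts a within-peptide link position to the absolute 1-based residue
#' number on the protein: `start + link_pos - 1`. This is the coordinate
#' behind residue-pair identities such as `G1-K21 x a1-K50`.
#'
#' @param start 1-based start of the peptide on the protein.
#' @param link_pos 1-based link position within the peptide.
#' @return Integer vector of absolute residue numbers.
#' @export
absolute_link_position <- function(start, link_pos) {
  stopifnot(all(start >= 1L), all(link_pos >= 1L))
  as.integer(start + link_pos - 1L)
}

#' Parse a fragment annotation string
#'
#' @param fragments Character vector of encoded fragment annotations (see
#'   [csm-table]).
#' @return A list of tibbles with columns `pep`, `series`, `index`, `relint`.
#' @export
parse_fragments <- function(fragments) {
  lapply(fragments, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(pep = character(), series = character(),
                            index = integer(), relint = numeric()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      pep = vapply(parts, `[`, character(1), 1L),
      series = vapply(parts, `[`, character(1), 2L),
      index = as.integer(vapply(parts, `[`, character(1), 3L)),
      relint = as.numeric(vapply(parts, `[`, character(1), 4L))
    )
  })
}

format_fragments <- function(pep, series, index, relint) {
  if (length(index) == 0L) return("")
  paste(sprintf("%s:%s:%d:%.2f", pep, series, index, relint), collapse = ";")
}

longest_adjacent_run <- function(index) {
  if (length(index) == 0L) return(0L)
  idx <- sort(unique(index))
  if (length(idx) == 1L) return(1L)
  runs <- rle(diff(idx) == 1L)
  adjacent <- runs$lengths[runs$values]
  if (length(adjacent) == 0L) 1L else max(adjacent) + 1L
}

#' Validate CSMs by fragment-ion coverage
#'
#' A CSM is considered validated when, for each of the two peptides, at least
#' one ion series (b or y) contains a run of `min_adjacent` or more consecutive
#' series indices whose relative intensities all reach `min_rel_intensity`.
#' This makes the manual "at least 4 adjacent fragments for both peptides with
#' reasonable intensity" rule mechanical; runs are counted within a single ion
#' series, never across series.
#'
#' @param fragments Character vector of encoded fragment annotations, or a CSM
#'   table (its `fragments` column is used).
#' @param min_adjacent Minimum run length (default 4).
#' @param min_rel_intensity Relative-intensity floor, as a fraction of the base
#'   peak (default 0.01).
#' @return Logical vector, one flag per CSM. CSMs without fragments fail.
#' @export
validate_fragments <- function(fragments, min_adjacent = 4,
                               min_rel_intensity = 0.01) {
  if (is.data.frame(fragments)) fragments <- fragments$fragments
  vapply(parse_fragments(fragments), function(fr) {
    fr <- fr[fr$relint >= min_rel_intensity, , drop = FALSE]
    ok_pep <- vapply(c("a", "b"), function(p) {
      any(vapply(c("b", "y"), function(s) {
        longest_adjacent_run(fr$index[fr$pep == p & fr$series == s])
      }, integer(1)) >= min_adjacent)
    }, logical(1))
    all(ok_pep)
  }, logical(1))
}

#' Detect homo-oligomeric CSMs
#'
#' A CSM is homo-oligomeric when both peptides map to the same protein and
#' their coordinate intervals overlap (identical sequences being the special
#' case of full overlap), or when both link positions resolve to the same
#' absolute residue. Such a link cannot come from a single protein copy and
#' therefore evidences an oligomer, e.g. the Synaptophysin K83-K83 dimer link.
#'
#' @param csms A CSM table.
#' @return Logical vector, one flag per CSM.
#' @export
is_homo_oligomer <- function(csms) {
  same_protein <- csms$protein_a == csms$protein_b
  overlap <- csms$start_a <= csms$end_b & csms$start_b <= csms$end_a
  same_residue <- absolute_link_position(csms$start_a, csms$link_pos_a) ==
    absolute_link_position(csms$start_b, csms$link_pos_b)
  same_protein & (overlap | same_residue)
}
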