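#' Aggregate CSMs to unique residue-pair cross-links
#'
#' Validated CSMs (see [validate_fragments()]) are grouped into one cross-link
#' per unique canonical residue pair per condition. The residue pair is put in
#' canonical order -- `(protein_a, residue_a) <= (protein_b, residue_b)`
#' lexicographically -- so that swapping the alpha/beta peptides of every CSM
#' leaves the result unchanged. Replicate support is the union of supporting
#' replicate ids; the link class is `homo_oligomeric` if any supporting CSM is
#' homo-oligomeric (see [is_homo_oligomer()]), otherwise `intra` for
#' same-protein pairs and `inter` across proteins. Conditions are never merged.
#'
#' @param csms A CSM table (see [csm-table]).
#' @param min_adjacent,min_rel_intensity Fragment-validation thresholds passed
#'   to [validate_fragments()]; CSMs failing validation are dropped with a
#'   message giving the count.
#' @param sequences Optional named vector of protein sequences; when supplied,
#'   rows whose link residue falls outside the protein length are dropped with
#'   a message.
#'
#' @return A cross-link tibble with columns `condition`, `protein_a`,
#'   `residue_a`, `protein_b`, `residue_b`, `link_class`, `csm_count`,
#'   `n_replicates`, `replicates` (comma-joined sorted replicate ids),
#'   `validated`. The sum of `csm_count` equals the number of validating CSMs.
#' @export
aggregate_csms <- function(csms, min_adjacent = 4, min_rel_intensity = 0.01,
                           sequences = NULL) {
  csms <- validate_csms(csms)
  ok <- validate_fragments(csms, min_adjacent, min_rel_intensity)
  if (any(!ok)) {
    message(sum(!ok), " CSM(s) failed fragment validation and were dropped")
    csms <- csms[ok, , drop = FALSE]
  }
  if (nrow(csms) == 0L) return(empty_links())

  res_a <- absolute_link_position(csms$start_a, csms$link_pos_a)
  res_b <- absolute_link_position(csms$start_b, csms$link_pos_b)
  if (!is.null(sequences)) {
    sequences <- as_sequence_vector(sequences)
    len_a <- nchar(sequences[csms$protein_a])
    len_b <- nchar(sequences[csms$protein_b])
    bad <- is.na(len_a) | is.na(len_b) | res_a > len_a | res_b > len_b
    if (any(bad)) {
      message(sum(bad), " CSM(s) with link residues outside the protein ",
              "length were dropped")
      csms <- csms[!bad, , drop = FALSE]
      res_a <- res_a[!bad]
      res_b <- res_b[!bad]
    }
  }
  homo <- is_homo_oligomer(csms)

  swap <- csms$protein_a > csms$protein_b |
    (csms$protein_a == csms$protein_b & res_a > res_b)
  pa <- ifelse(swap, csms$protein_b, csms$protein_a)
  pb <- ifelse(swap, csms$protein_a, csms$protein_b)
  ra <- ifelse(swap, res_b, res_a)
  rb <- ifelse(swap, res_a, res_b)

  tibble::tibble(condition = csms$condition, protein_a = pa, residue_a = ra,
                 protein_b = pb, residue_b = rb,
                 replicate = as.character(csms$replicate), homo = homo) |>
    dplyr::group_by(.data$condition, .data$protein_a, .data$residue_a,
                    .data$protein_b, .data$residue_b) |>
    dplyr::summarise(
      link_class = if (any(.data$homo)) "homo_oligomeric"
                   else if (.data$protein_a[1] == .data$protein_b[1]) "intra"
                   else "inter",
      csm_count = dplyr::n(),
      n_replicates = length(unique(.data$replicate)),
      replicates = paste(sort(unique(.data$replicate)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(validated = TRUE) |>
    dplyr::arrange(.data$condition, .data$protein_a, .data$residue_a,
                   .data$protein_b, .data$residue_b)
}

empty_links <- function() {
  tibble::tibble(condition = character(), protein_a = character(),
                 residue_a = integer(), protein_b = character(),
                 residue_b = integer(), link_class = character(),
                 csm_count = integer(), n_replicates = integer(),
                 replicates = character(), validated = logical())
}

#' Retain cross-links with sufficient replicate support
#'
#' Keeps validated cross-links observed in at least `min_replicates`
#' biological replicates (default 2). The operation is monotone (raising the
#' threshold only removes links) and idempotent.
#'
#' @param links Aggregated cross-link table (see [aggregate_csms()]).
#' @param min_replicates Minimum replicate support (>= 1).
#' @export
filter_replicates <- function(links, min_replicates = 2) {
  if (min_replicates < 1) stop("min_replicates must be >= 1", call. = FALSE)
  dplyr::filter(links, .data$n_replicates >= min_replicates, .data$validated)
}

#' Filter chemically labelled sites by localisation confidence
#'
#' Retains label sites whose modification-site localisation probability and
#' peptide identification score both reach their thresholds (defaults 0.75
#' and 80).
#'
#' @param sites Label-site table with columns `probability` and
#'   `peptide_score` (other columns are preserved).
#' @param min_probability,min_peptide_score Retention thresholds.
#' @export
filter_label_sites <- function(sites, min_probability = 0.75,
                               min_peptide_score = 80) {
  required_columns(sites, c("probability", "peptide_score"))
  dplyr::filter(tibble::as_tibble(sites),
                .data$probability >= min_probability,
                .data$peptide_score >= min_peptide_score)
}

#' Read / write cross-link tables
#'
#' Tab-separated I/O for the aggregated cross-link schema produced by
#' [aggregate_csms()].
#' @param file Path to a tab-separated cross-link table.
#' @param links A cross-link tibble.
#' @name link-table
#' @export
read_links <- function(file) {
  df <- tibble::as_tibble(read.delim(file, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE))
  required_columns(df, c("protein_a", "residue_a", "protein_b", "residue_b"))
  if (!"validated" %in% names(df)) df$validated <- TRUE
  df$replicates <- as.character(df$replicates)
  df
}

#' @rdname link-table
#' @export
write_links <- function(links, file) {
  write.table(links, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
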