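#' Load an atomic structure for cross-link mapping
#'
#' Reads a PDB or mmCIF file (via bio3d), keeps one C-alpha record per
#' residue, and attaches a chain-to-protein mapping. Several chains may map to
#' the same protein (multi-copy complexes); chains absent from the mapping are
#' loaded but flagged unmappable, and residues without coordinates are simply
#' absent from the resolved set.
#'
#' @param file Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain_map Named character vector `chain -> protein_id`, or a data
#'   frame with columns `chain` and `protein_id` (e.g. from
#'   [read_chain_map()]). May be empty, in which case no link can be mapped.
#' @param model_id Identifier stored on the model (defaults to the file name).
#' @return An object of class `svxl_structure`: a list with `model_id`,
#'   `atoms` (tibble `chain`, `resno`, `x`, `y`, `z`) and `chain_map`.
#' @export
load_structure <- function(file, chain_map = character(), model_id = NULL) {
  pdb <- if (grepl("\\.cif$", file, ignore.case = TRUE)) {
    bio3d::read.cif(file)
  } else {
    bio3d::read.pdb(file)
  }
  if (is.data.frame(chain_map)) {
    required_columns(chain_map, c("chain", "protein_id"))
    chain_map <- setNames(as.character(chain_map$protein_id),
                          as.character(chain_map$chain))
  }
  sel <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[sel$atom, , drop = FALSE]
  atoms <- tibble::tibble(chain = as.character(at$chain),
                          resno = as.integer(at$resno),
                          x = at$x, y = at$y, z = at$z) |>
    dplyr::distinct(.data$chain, .data$resno, .keep_all = TRUE)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(model_id = model_id %||% basename(file), atoms = atoms,
                 chain_map = chain_map),
            class = "svxl_structure")
}

#' @rdname load_structure
#' @export
read_chain_map <- function(file) {
  df <- read.delim(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required_columns(df, c("chain", "protein_id"))
  setNames(as.character(df$protein_id), as.character(df$chain))
}

#' @export
print.svxl_structure <- function(x, ...) {
  cat("svxl structure model '", x$model_id, "': ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$atoms), " C-alpha records\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# C-alpha coordinate of (chain, residue); NULL when unresolved
ca_coord <- function(model, chain, resno) {
  at <- model$atoms
  i <- which(at$chain == chain & at$resno == resno)
  if (length(i) == 0L) return(NULL)
  c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
}

chains_of <- function(model, protein) {
  names(model$chain_map)[model$chain_map == protein]
}

# Minimum C-alpha distance for one residue pair under the chain-pair rules.
# homo: the two residues must sit on distinct chains. Plain intra links prefer
# a single chain and fall back to inter-chain pairs only when no single chain
# resolves both residues.
min_pair_distance <- function(model, protein_a, residue_a,
                              protein_b, residue_b, homo = FALSE) {
  ch_a <- chains_of(model, protein_a)
  ch_b <- chains_of(model, protein_b)
  if (length(ch_a) == 0L || length(ch_b) == 0L) {
    return(list(status = "unmapped", distance = NA_real_,
                chain_a = NA_character_, chain_b = NA_character_))
  }
  intra <- identical(protein_a, protein_b) && !homo
  candidates <- expand.grid(chain_a = ch_a, chain_b = ch_b,
                            stringsAsFactors = FALSE)
  if (homo) {
    candidates <- candidates[candidates$chain_a != candidates$chain_b, ,
                             drop = FALSE]
  }
  dist_for <- function(cand) {
    d <- rep(NA_real_, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      a <- ca_coord(model, cand$chain_a[i], residue_a)
      b <- ca_coord(model, cand$chain_b[i], residue_b)
      if (!is.null(a) && !is.null(b)) d[i] <- sqrt(sum((a - b)^2))
    }
    d
  }
  if (intra) {
    same <- candidates[candidates$chain_a == candidates$chain_b, ,
                       drop = FALSE]
    d_same <- dist_for(same)
    if (any(!is.na(d_same))) {
      i <- which.min(d_same)
      return(list(status = "mapped", distance = d_same[i],
                  chain_a = same$chain_a[i], chain_b = same$chain_b[i]))
    }
  }
  d <- dist_for(candidates)
  if (all(is.na(d))) {
    return(list(status = "unmapped", distance = NA_real_,
                chain_a = NA_character_, chain_b = NA_character_))
  }
  i <- which.min(d)
  list(status = "mapped", distance = d[i],
       chain_a = candidates$chain_a[i], chain_b = candidates$chain_b[i])
}

#' Map cross-links onto a structure
#'
#' Computes, per cross-link, the C-alpha/C-alpha distance minimised over all
#' admissible chain pairs: every chain of each protein is a candidate, so a
#' link on a multi-copy subunit is mapped once, at the arrangement that best
#' explains it. Homo-oligomeric links must place their two residues on
#' distinct chains (they originate from two protein copies); plain
#' intra-molecular links prefer a single chain. Links whose residues are
#' unresolved in every candidate chain get status `unmapped` -- they are
#' reported, never dropped.
#'
#' @param links Cross-link table ([aggregate_csms()]).
#' @param model An `svxl_structure` from [load_structure()].
#' @param threshold Maximum cross-linker span in Angstrom (default 30, the
#'   conventional C-alpha limit for BS3).
#' @return The link table plus `status`, `distance`, `satisfied`, `chain_a`,
#'   `chain_b`.
#' @export
map_links <- function(links, model, threshold = 30) {
  stopifnot(inherits(model, "svxl_structure"))
  n <- nrow(links)
  homo <- if ("link_class" %in% names(links)) {
    links$link_class == "homo_oligomeric"
  } else {
    links$protein_a == links$protein_b & links$residue_a == links$residue_b
  }
  res <- lapply(seq_len(n), function(i) {
    min_pair_distance(model, links$protein_a[i], links$residue_a[i],
                      links$protein_b[i], links$residue_b[i], homo[i])
  })
  links$status <- vapply(res, `[[`, character(1), "status")
  links$distance <- vapply(res, `[[`, numeric(1), "distance")
  links$satisfied <- ifelse(links$status == "mapped",
                            links$distance <= threshold, NA)
  links$chain_a <- vapply(res, `[[`, character(1), "chain_a")
  links$chain_b <- vapply(res, `[[`, character(1), "chain_b")
  links
}

#' Cross-link distance histogram
#'
#' Bins mapped distances into half-open bins `[k*w, (k+1)*w)` and counts the
#' links satisfying the distance threshold.
#'
#' @param mapped Output of [map_links()] (unmapped rows are ignored).
#' @param bin_width Bin width in Angstrom (> 0).
#' @param threshold Satisfaction threshold in Angstrom (default 30).
#' @return A list with `histogram` (tibble `bin_start`, `bin_end`, `count`),
#'   `n_mapped` and `n_satisfied`.
#' @export
distance_histogram <- function(mapped, bin_width = 5, threshold = 30) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  d <- mapped$distance[mapped$status == "mapped"]
  if (length(d) == 0L) stop("no mapped distances", call. = FALSE)
  bin <- floor(d / bin_width)
  tab <- table(bin)
  list(
    histogram = tibble::tibble(
      bin_start = as.numeric(names(tab)) * bin_width,
      bin_end = (as.numeric(names(tab)) + 1) * bin_width,
      count = as.integer(tab)
    ),
    n_mapped = length(d),
    n_satisfied = sum(d <= threshold)
  )
}

#' Random-cross-linking null distribution
#'
#' Draws residue pairs uniformly (with replacement over pairs, excluding
#' identical-residue self pairs) from the set of cross-linked lysines mappable
#' to the structure and computes their distances exactly as [map_links()]
#' does. Under random pairing of the observed reactive sites the distance
#' distribution is broader and longer than the observed one; comparing the
#' two validates the distance restraints.
#'
#' @param model An `svxl_structure`.
#' @param source_residues Data frame of cross-linked residues with columns
#'   `protein_id`, `residue`. Residues unmappable to the structure are
#'   excluded; at least 2 mappable residues are required.
#' @param n_samples Number of pairs to draw.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A list with `distances`, `median`, `ecdf`, `n_samples`, `seed`,
#'   and `source` (the mappable residue set used).
#' @export
random_null <- function(model, source_residues, n_samples = 1e4, seed = 1) {
  required_columns(source_residues, c("protein_id", "residue"))
  src <- dplyr::distinct(tibble::as_tibble(source_residues),
                         .data$protein_id, .data$residue)
  mappable <- vapply(seq_len(nrow(src)), function(i) {
    any(vapply(chains_of(model, src$protein_id[i]), function(ch) {
      !is.null(ca_coord(model, ch, src$residue[i]))
    }, logical(1)))
  }, logical(1))
  src <- src[mappable, , drop = FALSE]
  n <- nrow(src)
  if (n < 2L) stop("need >= 2 mappable source residues", call. = FALSE)

  pairs <- combn(n, 2)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pick <- sample.int(ncol(pairs), n_samples, replace = TRUE)

  # distances for each distinct pair, computed once then indexed
  pair_dist <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    min_pair_distance(model, src$protein_id[i], src$residue[i],
                      src$protein_id[j], src$residue[j])$distance
  }, numeric(1))
  distances <- pair_dist[pick]
  list(distances = distances, median = median(distances, na.rm = TRUE),
       ecdf = stats::ecdf(distances[!is.na(distances)]),
       n_samples = n_samples, seed = seed, source = src)
}

#' Classify cross-links by conformational-state compatibility
#'
#' Maps each link onto two structural models (e.g. the open, fully assembled
#' conformation of an enzyme and a closed, inhibited one) and calls its state
#' compatibility: `a_exclusive` when satisfied only in model A, `b_exclusive`
#' when satisfied only in model B, `shared` when satisfied in both, `neither`
#' otherwise. Unmappable counts as not satisfied for exclusivity but is
#' reported distinctly in the per-model status.
#'
#' @param links Cross-link table.
#' @param model_a,model_b `svxl_structure` models of the two states.
#' @param threshold Distance threshold in Angstrom (default 30).
#' @return The link table plus `status_a`, `status_b` (each `satisfied`,
#'   `violated` or `unmappable`) and `verdict`.
#' @export
state_compatibility <- function(links, model_a, model_b, threshold = 30) {
  status_of <- function(model) {
    m <- map_links(links, model, threshold)
    ifelse(m$status == "unmapped", "unmappable",
           ifelse(m$satisfied, "satisfied", "violated"))
  }
  links$status_a <- status_of(model_a)
  links$status_b <- status_of(model_b)
  sa <- links$status_a == "satisfied"
  sb <- links$status_b == "satisfied"
  links$verdict <- dplyr::case_when(
    sa & !sb ~ "a_exclusive",
    !sa & sb ~ "b_exclusive",
    sa & sb ~ "shared",
    .default = "neither"
  )
  links
}
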