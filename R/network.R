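#' Build a protein-level interaction network from cross-links
#'
#' Inter-molecular and homo-oligomeric cross-links contribute edges (one edge
#' per unordered protein pair; homo-oligomeric links yield self-edges). Plain
#' intra-molecular links are excluded. Each edge carries its supporting link
#' count and a replicate tier: `tier = "multi"` when at least one supporting
#' link reaches `min_replicates` replicates, `"single"` otherwise -- the
#' grey/blue distinction used when such networks are drawn. Single-tier edges
#' are flagged, never silently dropped.
#'
#' @param links Aggregated cross-link table ([aggregate_csms()]).
#' @param min_replicates Replicate support defining the `"multi"` tier
#'   (default 2).
#' @return An edge tibble: `protein_a`, `protein_b` (sorted within the pair),
#'   `self_edge`, `n_links`, `max_replicates`, `tier`.
#' @export
build_network <- function(links, min_replicates = 2) {
  links <- dplyr::filter(links, .data$link_class %in%
                           c("inter", "homo_oligomeric"))
  if (nrow(links) == 0L) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          self_edge = logical(), n_links = integer(),
                          max_replicates = integer(), tier = character()))
  }
  pa <- pmin(links$protein_a, links$protein_b)
  pb <- pmax(links$protein_a, links$protein_b)
  tibble::tibble(protein_a = pa, protein_b = pb,
                 n_replicates = links$n_replicates,
                 homo = links$link_class == "homo_oligomeric") |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      self_edge = .data$protein_a[1] == .data$protein_b[1] && all(.data$homo),
      n_links = dplyr::n(),
      max_replicates = max(.data$n_replicates),
      .groups = "drop"
    ) |>
    dplyr::mutate(tier = ifelse(.data$max_replicates >= min_replicates,
                                "multi", "single")) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Degree of a protein in the interaction network
#'
#' Number of distinct partner proteins; self-edges (homo-oligomers) do not
#' count towards the degree. A protein absent from the network has degree 0.
#'
#' @param network Edge tibble from [build_network()].
#' @param protein Protein id.
#' @export
network_degree <- function(network, protein) {
  non_self <- dplyr::filter(network, !.data$self_edge)
  partners <- c(non_self$protein_b[non_self$protein_a == protein],
                non_self$protein_a[non_self$protein_b == protein])
  length(unique(partners))
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network[, c("protein_a", "protein_b", "n_links", "max_replicates",
                "tier", "self_edge")],
    directed = FALSE
  )
}

#' Enumerate connected sub-networks containing anchor proteins
#'
#' Finds all connected vertex subsets of the given size that contain every
#' anchor protein, together with their induced edges -- e.g. the ternary
#' networks around a pair of anchor proteins. Output order is deterministic
#' (members sorted within a subset, subsets sorted lexicographically).
#'
#' @param network Edge tibble from [build_network()].
#' @param anchors Character vector of anchor protein ids.
#' @param size Subset size (>= 2, >= number of anchors).
#' @return A list; each element has `members` (character vector) and `edges`
#'   (induced edge tibble). Empty when an anchor is missing from the network.
#' @export
extract_subnetworks <- function(network, anchors, size = 3) {
  stopifnot(size >= 2, size >= length(anchors))
  vertices <- sort(unique(c(network$protein_a, network$protein_b)))
  if (!all(anchors %in% vertices)) return(list())
  g <- as_igraph(network)
  others <- setdiff(vertices, anchors)
  k <- size - length(anchors)
  cand <- if (k == 0L) list(character(0)) else {
    if (length(others) < k) return(list())
    asplit(combn(others, k), 2)
  }
  out <- list()
  for (extra in cand) {
    members <- sort(c(anchors, as.character(extra)))
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::is_connected(sub)) {
      edges <- dplyr::filter(network, .data$protein_a %in% members &
                               .data$protein_b %in% members)
      out[[paste(members, collapse = "|")]] <-
        list(members = members, edges = edges)
    }
  }
  if (length(out) == 0L) return(list())
  out[order(names(out))]
}

#' Compare interaction networks across conditions
#'
#' Partitions edges by unordered protein pair into `retained` (present in
#' both), `lost` (A only) and `gained` (B only). With A the untreated crowded
#' membrane and B a more spacious one (vesicles fused with liposomes), the
#' retained set is the stable-interaction-module report: contacts maintained
#' once membrane crowding is relieved. Swapping A and B swaps lost and gained.
#'
#' @param network_a,network_b Edge tibbles from [build_network()], built at
#'   the same replicate tier.
#' @return A list with edge tibbles `retained`, `lost`, `gained` (pairs keyed
#'   on `protein_a`/`protein_b`).
#' @export
compare_conditions <- function(network_a, network_b) {
  key <- function(net) paste(net$protein_a, net$protein_b, sep = "|")
  ka <- key(network_a)
  kb <- key(network_b)
  list(
    retained = network_a[ka %in% kb, , drop = FALSE],
    lost = network_a[!ka %in% kb, , drop = FALSE],
    gained = network_b[!kb %in% ka, , drop = FALSE]
  )
}

#' Export a network
#'
#' Writes the edge list as GraphML (via igraph) and/or a flat tab-separated
#' edge table for downstream graph viewers.
#'
#' @param network Edge tibble from [build_network()].
#' @param graphml,edges Output paths (either may be `NULL` to skip).
#' @export
write_network <- function(network, graphml = NULL, edges = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  }
  if (!is.null(edges)) {
    write.table(network, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(network)
}
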