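# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own code paths.

# character-by-character trypsin scan: cleave after K/R unless next is P
oracle_digest0 <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  peps <- character()
  starts <- integer()
  cur <- ""
  cur_start <- 1L
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    cleave <- chars[i] %in% c("K", "R") &&
      (i == length(chars) || chars[i + 1] != "P")
    if (cleave || i == length(chars)) {
      peps <- c(peps, cur)
      starts <- c(starts, cur_start)
      cur <- ""
      cur_start <- i + 1L
    }
  }
  data.frame(peptide = peps, start = starts,
             end = starts + nchar(peps) - 1L)
}

# all peptides with up to m missed cleavages by joining adjacent fragments
oracle_digest <- function(sequence, m) {
  base <- oracle_digest0(sequence)
  out <- list()
  for (mm in 0:m) {
    for (i in seq_len(max(nrow(base) - mm, 0L))) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(base$peptide[i:(i + mm)], collapse = ""),
        start = base$start[i], end = base$end[i + mm], n_missed = mm
      )
    }
  }
  do.call(rbind, out)
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# longest run of consecutive integers, by exhaustive scan
oracle_longest_run <- function(idx) {
  idx <- sort(unique(idx))
  if (length(idx) == 0L) return(0L)
  best <- 1L
  run <- 1L
  for (i in seq_along(idx)[-1]) {
    run <- if (idx[i] == idx[i - 1] + 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

# minimal CSM row builder for hand-made cases
make_csm <- function(protein_a, start_a, link_pos_a,
                     protein_b, start_b, link_pos_b,
                     peptide_a = strrep("A", 8), peptide_b = strrep("G", 8),
                     fragments = "a:b:2:1.00;a:b:3:1.00;a:b:4:1.00;a:b:5:1.00;b:y:1:1.00;b:y:2:1.00;b:y:3:1.00;b:y:4:1.00",
                     replicate = "r1", condition = "untreated",
                     csm_id = 1L) {
  tibble::tibble(
    csm_id = csm_id, spectrum_ref = paste0("s", csm_id),
    protein_a = protein_a, peptide_a = peptide_a, start_a = start_a,
    end_a = start_a + nchar(peptide_a) - 1L, link_pos_a = link_pos_a,
    protein_b = protein_b, peptide_b = peptide_b, start_b = start_b,
    end_b = start_b + nchar(peptide_b) - 1L, link_pos_b = link_pos_b,
    fragments = fragments, replicate = replicate, condition = condition,
    score = 100
  )
}

# in-memory structure model from a coordinate table
toy_model <- function(coords, chain_map, model_id = "toy") {
  structure(list(model_id = model_id,
                 atoms = tibble::as_tibble(coords),
                 chain_map = chain_map),
            class = "svxl_structure")
}
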