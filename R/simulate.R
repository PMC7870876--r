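#' Ground truth for a synthetic cross-linking experiment
#'
#' Bundles everything the simulators need: proteins with per-vesicle copy
#' numbers, planted residue-residue contacts with a generating-state label,
#' noise/dropout/decoy parameters, replicate count and membrane-topology
#' segments. Contact residues must be lysines (or position 1, the protein
#' N-terminus), matching the chemistry of an amine-reactive cross-linker.
#'
#' Contact states: `open` contacts are geometrically satisfied only in the
#' open structural model, `closed` only in the closed model, `both` in both,
#' and `none` in neither (a crowding-style contact with no structural basis).
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`,
#'   `copy_number` (> 0).
#' @param true_contacts Tibble with columns `protein_a`, `residue_a`,
#'   `protein_b`, `residue_b`, `state` (one of `open`, `closed`, `both`,
#'   `none`).
#' @param decoy_rate Fraction of CSMs drawn from non-contact lysine pairs
#'   (in \[0, 1\]).
#' @param n_replicates Number of biological replicates (>= 1).
#' @param dropout Per-replicate probability that a true contact yields no CSM
#'   (in \[0, 1)).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 = noise-free).
#' @param topology Optional topology segment table ([validate_segments()]).
#' @param seed Integer seed; identical seed and parameters give byte-identical
#'   simulated tables.
#' @return An object of class `svxl_ground_truth`.
#' @export
ground_truth <- function(proteins, true_contacts, decoy_rate = 0.1,
                         n_replicates = 4, dropout = 0.2, noise_cv = 0.2,
                         topology = NULL, seed = 1) {
  proteins <- tibble::as_tibble(proteins)
  required_columns(proteins, c("protein_id", "sequence", "copy_number"))
  stopifnot(all(proteins$copy_number > 0), !anyDuplicated(proteins$protein_id),
            decoy_rate >= 0, decoy_rate <= 1, dropout >= 0, dropout < 1,
            noise_cv >= 0, n_replicates >= 1)
  for (i in seq_len(nrow(proteins))) {
    check_sequence(proteins$sequence[i], proteins$protein_id[i])
  }
  true_contacts <- tibble::as_tibble(true_contacts)
  required_columns(true_contacts, c("protein_a", "residue_a", "protein_b",
                                    "residue_b", "state"))
  stopifnot(all(true_contacts$state %in% c("open", "closed", "both", "none")))
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  check_site <- function(protein, residue) {
    s <- seqs[[protein]]
    if (is.null(s) || residue < 1 || residue > nchar(s)) {
      stop("contact residue ", protein, ":", residue, " out of range",
           call. = FALSE)
    }
    if (residue != 1L && substr(s, residue, residue) != "K") {
      stop("contact residue ", protein, ":", residue,
           " is not a lysine or the protein N-terminus", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(true_contacts))) {
    check_site(true_contacts$protein_a[i], true_contacts$residue_a[i])
    check_site(true_contacts$protein_b[i], true_contacts$residue_b[i])
  }
  if (!is.null(topology)) topology <- validate_segments(topology)
  structure(list(proteins = proteins, true_contacts = true_contacts,
                 decoy_rate = decoy_rate, n_replicates = n_replicates,
                 dropout = dropout, noise_cv = noise_cv, topology = topology,
                 seed = as.integer(seed)),
            class = "svxl_ground_truth")
}

#' @export
print.svxl_ground_truth <- function(x, ...) {
  cat("svxl ground truth: ", nrow(x$proteins), " proteins, ",
      nrow(x$true_contacts), " planted contacts, ", x$n_replicates,
      " replicates (dropout ", x$dropout, ", decoy rate ", x$decoy_rate,
      ", noise CV ", x$noise_cv, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# deterministic child RNG streams from the ground-truth seed
with_stream <- function(seed, offset, expr) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed + offset)
  force(expr)
}

random_sequence_blocks <- function(n_blocks, terminal) {
  pool <- setdiff(AA_STANDARD, c("K", "R", "P"))
  blocks <- vapply(seq_len(n_blocks), function(i) {
    paste0(paste(sample(pool, sample(7:11, 1), replace = TRUE),
                 collapse = ""),
           terminal[(i - 1L) %% length(terminal) + 1L])
  }, character(1))
  paste(blocks, collapse = "")
}

#' Default synthetic-vesicle ground truth
#'
#' Builds the standard desk-scale study system: a small membrane proteome
#' whose copy numbers emulate the established synaptic-vesicle stoichiometry
#' (70 copies of a Synaptobrevin-2-like protein, 31 of a Synaptophysin-like
#' one, 15 of a Synaptotagmin-1-like one, plus low-copy proton-pump subunits),
#' planted inter/intra/homo-oligomeric contacts with two contacts per
#' inter-protein pair, a pair of open-exclusive and closed-exclusive contacts
#' on the pump subunits, a crowding contact with no structural basis, and
#' cytosolic/TMH/luminal topology segments. Sequences are built from tryptic
#' blocks (7--11 residues plus K or R) so every planted lysine sits in an
#' observable, fragmentable peptide.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [ground_truth()] (e.g. `dropout`,
#'   `decoy_rate`, `noise_cv`, `n_replicates`).
#' @return An `svxl_ground_truth`.
#' @export
default_ground_truth <- function(seed = 1, ...) {
  spec <- tibble::tribble(
    ~protein_id, ~copy_number, ~n_blocks,
    "SYB2",  70, 12,
    "SYP",   31, 10,
    "SYT1",  15, 10,
    "VATPa1", 2, 14,
    "VATPd1", 2, 10,
    "VATPG1", 2,  8,
    "PRR",    2, 10
  )
  proteins <- with_stream(seed, 101L, {
    spec$sequence <- vapply(spec$n_blocks, function(nb) {
      random_sequence_blocks(nb, c("K", "K", "R"))
    }, character(1))
    spec[, c("protein_id", "sequence", "copy_number")]
  })
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  lys <- lapply(seqs, function(s) {
    which(strsplit(s, "")[[1]] == "K")
  })
  k <- function(p, i) lys[[p]][i]

  contacts <- tibble::tribble(
    ~protein_a, ~residue_a, ~protein_b, ~residue_b, ~state,
    # crowded-membrane inter contacts (two per protein pair)
    "SYB2", k("SYB2", 1), "SYP",  k("SYP", 2),  "both",
    "SYB2", k("SYB2", 3), "SYP",  k("SYP", 4),  "both",
    "SYB2", k("SYB2", 4), "SYT1", k("SYT1", 1), "both",
    "SYB2", k("SYB2", 6), "SYT1", k("SYT1", 3), "both",
    "SYB2", k("SYB2", 2), "VATPa1", k("VATPa1", 2), "both",
    "SYB2", k("SYB2", 7), "VATPa1", k("VATPa1", 5), "both",
    "SYP",  k("SYP", 1),  "SYT1", k("SYT1", 4), "both",
    "SYP",  k("SYP", 5),  "SYT1", k("SYT1", 5), "both",
    "SYP",  k("SYP", 3),  "VATPa1", k("VATPa1", 7), "both",
    "SYP",  k("SYP", 6),  "VATPa1", k("VATPa1", 8), "both",
    "VATPa1", k("VATPa1", 1), "VATPd1", k("VATPd1", 1), "both",
    "VATPa1", k("VATPa1", 4), "VATPd1", k("VATPd1", 3), "both",
    # conformational-state evidence on the proton-pump subunits
    "VATPG1", k("VATPG1", 1), "VATPa1", k("VATPa1", 3), "open",
    "VATPG1", k("VATPG1", 2), "VATPa1", k("VATPa1", 6), "open",
    "PRR", k("PRR", 5), "VATPa1", k("VATPa1", 6), "closed",
    "PRR", k("PRR", 5), "VATPd1", k("VATPd1", 4), "closed",
    # a crowding contact with no structural basis in either model
    "SYB2", k("SYB2", 5), "PRR", k("PRR", 2), "none",
    # homo-oligomer links (two copies of one protein)
    "SYP",  k("SYP", 2),  "SYP",  k("SYP", 2),  "both",
    "SYB2", k("SYB2", 1), "SYB2", k("SYB2", 1), "both",
    # plain intra-molecular links
    "VATPa1", k("VATPa1", 2), "VATPa1", k("VATPa1", 3), "both",
    "SYP",  k("SYP", 1),  "SYP",  k("SYP", 3),  "both",
    "SYT1", k("SYT1", 2), "SYT1", k("SYT1", 4), "both"
  )

  topology <- dplyr::bind_rows(lapply(names(seqs), function(p) {
    n <- nchar(seqs[[p]])
    third <- max(1L, n %/% 3L)
    tibble::tibble(
      protein_id = p,
      start = c(1L, third + 1L, 2L * third + 1L),
      end = c(third, 2L * third, n),
      compartment = c("cytosolic", "TMH", "luminal")
    )
  }))

  ground_truth(proteins, contacts, topology = topology, seed = seed, ...)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a peptide-intensity table
#'
#' For each protein, the detected peptides are its fully-cleaved tryptic
#' peptides inside the observability window. Each peptide intensity is
#' `copy_number x response factor x lognormal noise` (CV = `noise_cv`), with
#' response factors fixed per peptide given the seed and rescaled so their
#' per-protein mean is exactly 1 -- hence at `noise_cv = 0` relative iBAQ
#' recovers the copy-number fractions exactly.
#'
#' @param truth An `svxl_ground_truth`.
#' @param window Observability window (see [observable_peptides()]).
#' @param scale Overall intensity scale (arbitrary units).
#' @return Peptide-intensity tibble: `protein_id`, `peptide`, `replicate`,
#'   `intensity`.
#' @export
simulate_proteome <- function(truth, window = c(7, 30), scale = 1e6) {
  stopifnot(inherits(truth, "svxl_ground_truth"))
  with_stream(truth$seed, 202L, {
    rows <- lapply(seq_len(nrow(truth$proteins)), function(i) {
      p <- truth$proteins$protein_id[i]
      pep <- tryptic_digest(truth$proteins$sequence[i], 0L, p)
      len <- nchar(pep$peptide)
      pep <- unique(pep$peptide[len >= window[1] & len <= window[2]])
      if (length(pep) == 0L) return(NULL)
      r <- rlnorm(length(pep), 0, 0.5)
      r <- r / mean(r)
      base <- truth$proteins$copy_number[i] * r * scale
      dplyr::bind_rows(lapply(seq_len(truth$n_replicates), function(rep_i) {
        tibble::tibble(protein_id = p, peptide = pep,
                       replicate = paste0("r", rep_i),
                       intensity = base * lognormal_noise(length(pep),
                                                          truth$noise_cv))
      }))
    })
    dplyr::bind_rows(rows)
  })
}

# ---- toy structure generation ----------------------------------------------

truth_chain_table <- function(truth) {
  homo <- truth$true_contacts$protein_a == truth$true_contacts$protein_b &
    truth$true_contacts$residue_a == truth$true_contacts$residue_b
  multi <- unique(truth$true_contacts$protein_a[homo])
  if (length(multi) == 0L) multi <- truth$proteins$protein_id[1]
  n_copies <- ifelse(truth$proteins$protein_id %in% multi, 2L, 1L)
  tab <- tibble::tibble(
    protein_id = rep(truth$proteins$protein_id, n_copies),
    copy = unlist(lapply(n_copies, seq_len))
  )
  tab$chain <- LETTERS[seq_len(nrow(tab))]
  tab
}

# union-find over node keys
uf_find <- function(parent, x) {
  while (parent[[x]] != x) x <- parent[[x]]
  x
}

build_model <- function(truth, chains, close, far, model_id, jitter_seed) {
  node <- function(chain, residue) paste0(chain, ":", residue)
  all_nodes <- unique(c(node(close$chain_a, close$residue_a),
                        node(close$chain_b, close$residue_b),
                        node(far$chain_a, far$residue_a),
                        node(far$chain_b, far$residue_b)))
  parent <- setNames(all_nodes, all_nodes)
  for (i in seq_len(nrow(close))) {
    ra <- uf_find(parent, node(close$chain_a[i], close$residue_a[i]))
    rb <- uf_find(parent, node(close$chain_b[i], close$residue_b[i]))
    if (ra != rb) parent[[ra]] <- rb
  }
  comp <- vapply(all_nodes, function(x) uf_find(parent, x), character(1))
  for (i in seq_len(nrow(far))) {
    ca <- comp[[node(far$chain_a[i], far$residue_a[i])]]
    cb <- comp[[node(far$chain_b[i], far$residue_b[i])]]
    if (ca == cb) {
      stop("unsatisfiable geometry: ", far$chain_a[i], ":", far$residue_a[i],
           " and ", far$chain_b[i], ":", far$residue_b[i],
           " are required both close and far in model '", model_id, "'",
           call. = FALSE)
    }
  }
  comp_ids <- unique(comp)
  comp_origin <- cbind(300 * seq_along(comp_ids), 0, 0)
  rownames(comp_origin) <- comp_ids

  seq_len_of <- setNames(nchar(truth$proteins$sequence),
                         truth$proteins$protein_id)
  atoms <- with_stream(jitter_seed, 0L, {
    dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(ci) {
      p <- chains$protein_id[ci]
      n <- seq_len_of[[p]]
      idx <- seq_len(n) - 1L
      # default compact lattice per chain, far from all constraint components
      xyz <- cbind(300 * ci + 5 * (idx %% 8L),
                   2000 + 5 * ((idx %/% 8L) %% 8L),
                   5 * (idx %/% 64L))
      keys <- paste0(chains$chain[ci], ":", seq_len(n))
      hit <- keys %in% names(comp)
      if (any(hit)) {
        origins <- comp_origin[comp[keys[hit]], , drop = FALSE]
        xyz[hit, ] <- origins + matrix(runif(3 * sum(hit), -4, 4), ncol = 3)
      }
      tibble::tibble(chain = chains$chain[ci], resno = seq_len(n),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }))
  })
  structure(list(model_id = model_id, atoms = atoms,
                 chain_map = setNames(chains$protein_id, chains$chain)),
            class = "svxl_structure")
}

#' Simulate open- and closed-state toy structures
#'
#' Builds two explicit C-alpha point-set models that realise the planted
#' contact states: every `open`-labelled contact is within the cross-linker
#' span (<= 30 A) in the open model and far beyond it in the closed model
#' (and symmetrically for `closed`); `both`-labelled contacts are close in
#' both models and `none`-labelled contacts in neither. Proteins involved in
#' homo-oligomeric contacts are represented by two chain copies (at least one
#' protein always is), exercising multi-copy chain resolution. Construction
#' places close-constrained residues in shared small clusters and keeps
#' distinct clusters and unconstrained chains hundreds of Angstrom apart; a
#' contact required both close and far within one cluster is rejected as
#' unsatisfiable.
#'
#' @param truth An `svxl_ground_truth`; each state label used must have at
#'   least one contact.
#' @return A list with `open` and `closed` (`svxl_structure` objects) and
#'   `chain_map` (tibble `chain`, `protein_id`).
#' @export
simulate_structures <- function(truth) {
  stopifnot(inherits(truth, "svxl_ground_truth"))
  chains <- truth_chain_table(truth)
  tc <- truth$true_contacts
  homo <- tc$protein_a == tc$protein_b & tc$residue_a == tc$residue_b
  chain1 <- function(p) chains$chain[chains$protein_id == p][1]
  chain2 <- function(p) {
    ch <- chains$chain[chains$protein_id == p]
    ch[min(2L, length(ch))]
  }
  placed <- tibble::tibble(
    chain_a = vapply(tc$protein_a, chain1, character(1)),
    residue_a = tc$residue_a,
    chain_b = ifelse(homo, vapply(tc$protein_b, chain2, character(1)),
                     vapply(tc$protein_b, chain1, character(1))),
    residue_b = tc$residue_b,
    state = tc$state
  )
  close_in <- function(state_set) placed[placed$state %in% state_set, ]
  far_in <- function(state_set) placed[placed$state %in% state_set, ]
  list(
    open = build_model(truth, chains,
                       close = close_in(c("open", "both")),
                       far = far_in(c("closed", "none")),
                       model_id = "open", jitter_seed = truth$seed + 301L),
    closed = build_model(truth, chains,
                         close = close_in(c("closed", "both")),
                         far = far_in(c("open", "none")),
                         model_id = "closed", jitter_seed = truth$seed + 302L),
    chain_map = chains[, c("chain", "protein_id")]
  )
}

#' Write a structure model as PDB
#'
#' Emits one C-alpha ATOM record per residue via bio3d, suitable for
#' re-loading with [load_structure()].
#'
#' @param model An `svxl_structure`.
#' @param file Output PDB path.
#' @export
write_structure_pdb <- function(model, file) {
  at <- model$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain,
                   resid = rep("ALA", nrow(at)), elety = rep("CA", nrow(at)))
  invisible(file)
}

# ---- CSM simulation --------------------------------------------------------

# tryptic peptide (<=2 missed cleavages) carrying a link residue; prefers a
# peptide where the linked lysine is internal (missed cleavage at the link)
xl_peptide <- function(sequence, residue, protein_id) {
  pep <- tryptic_digest(sequence, 2L, protein_id)
  pep <- pep[pep$start <= residue & pep$end >= residue, , drop = FALSE]
  if (nrow(pep) == 0L) {
    stop("no tryptic peptide covers ", protein_id, ":", residue,
         call. = FALSE)
  }
  internal <- pep$end != residue & nchar(pep$peptide) >= 5 &
    nchar(pep$peptide) <= 40
  cand <- if (any(internal)) pep[internal, ] else pep
  cand <- cand[order(nchar(cand$peptide), cand$start), ]
  cand[1, ]
}

fragment_run <- function(peptide_len, run_len) {
  run_len <- min(run_len, peptide_len - 1L)
  start <- if (peptide_len - 1L > run_len) 2L else 1L
  seq.int(start, start + run_len - 1L)
}

make_fragments <- function(len_a, len_b, run_a, run_b) {
  ia <- fragment_run(len_a, run_a)
  ib <- fragment_run(len_b, run_b)
  format_fragments(
    pep = c(rep("a", length(ia)), rep("b", length(ib))),
    series = c(rep("b", length(ia)), rep("y", length(ib))),
    index = c(ia, ib),
    relint = round(runif(length(ia) + length(ib), 0.3, 1), 2)
  )
}

#' Simulate a CSM table
#'
#' Emits, per replicate, one CSM for each true contact with probability
#' `1 - dropout`, plus decoy CSMs drawn uniformly from eligible lysine pairs
#' not in the truth so that the expected decoy fraction equals `decoy_rate`.
#' Each CSM carries the tryptic peptide pair covering the linked residues
#' (homo-oligomeric truths emit identical peptides on both sides) and b/y
#' fragment-ion runs: true links get runs of `frag_run_true` adjacent indices
#' per peptide, and a fraction `decoy_short_frac` of decoys gets short runs of
#' `frag_run_short` (failing the adjacent-fragment validation). Deterministic
#' given the ground-truth seed.
#'
#' @param truth An `svxl_ground_truth`.
#' @param condition Condition label stored on every CSM.
#' @param frag_run_true,frag_run_short,decoy_short_frac Fragment-run controls.
#' @param cleavage Optional proteolytic-removal event for the condition, a
#'   list with `protein_id`, `p` (cleavage position) and `released` (`"n"` or
#'   `"c"`, which fragment is released): contacts and decoy sites on the
#'   released fragment emit no CSMs (e.g. the cytosolic part of
#'   Synaptobrevin-2 after neurotoxin cleavage).
#' @return A CSM table in the canonical schema (see [csm-table]).
#' @export
simulate_csms <- function(truth, condition = "untreated", frag_run_true = 4,
                          frag_run_short = 2, decoy_short_frac = 0.5,
                          cleavage = NULL) {
  stopifnot(inherits(truth, "svxl_ground_truth"))
  seqs <- setNames(truth$proteins$sequence, truth$proteins$protein_id)
  tc <- truth$true_contacts
  removed <- function(protein, residue) {
    if (is.null(cleavage) || protein != cleavage$protein_id) return(FALSE)
    if (cleavage$released == "n") residue <= cleavage$p
    else residue > cleavage$p
  }
  keep <- !vapply(seq_len(nrow(tc)), function(i) {
    removed(tc$protein_a[i], tc$residue_a[i]) ||
      removed(tc$protein_b[i], tc$residue_b[i])
  }, logical(1))
  tc <- tc[keep, , drop = FALSE]

  pep_cache <- new.env(parent = emptyenv())
  get_pep <- function(protein, residue) {
    key <- paste0(protein, ":", residue)
    if (is.null(pep_cache[[key]])) {
      pep_cache[[key]] <- xl_peptide(seqs[[protein]], residue, protein)
    }
    pep_cache[[key]]
  }

  # eligible decoy pool: lysine pairs (canonical order) not in the truth
  lys <- dplyr::bind_rows(lapply(names(seqs), function(p) {
    tibble::tibble(protein_id = p,
                   residue = which(strsplit(seqs[[p]], "")[[1]] == "K"))
  }))
  lys <- lys[!vapply(seq_len(nrow(lys)), function(i) {
    removed(lys$protein_id[i], lys$residue[i])
  }, logical(1)), , drop = FALSE]
  pair_key <- function(pa, ra, pb, rb) {
    swap <- pa > pb | (pa == pb & ra > rb)
    paste(ifelse(swap, pb, pa), ifelse(swap, rb, ra),
          ifelse(swap, pa, pb), ifelse(swap, ra, rb), sep = "|")
  }
  true_keys <- pair_key(tc$protein_a, tc$residue_a, tc$protein_b, tc$residue_b)
  grid <- expand.grid(i = seq_len(nrow(lys)), j = seq_len(nrow(lys)))
  grid <- grid[grid$i < grid$j, , drop = FALSE]
  decoy_pool <- tibble::tibble(
    protein_a = lys$protein_id[grid$i], residue_a = lys$residue[grid$i],
    protein_b = lys$protein_id[grid$j], residue_b = lys$residue[grid$j]
  )
  decoy_pool <- decoy_pool[!pair_key(decoy_pool$protein_a,
                                     decoy_pool$residue_a,
                                     decoy_pool$protein_b,
                                     decoy_pool$residue_b) %in% true_keys, ,
                           drop = FALSE]

  csm_row <- function(pa, ra, pb, rb, run_a, run_b, replicate) {
    match_a <- get_pep(pa, ra)
    match_b <- get_pep(pb, rb)
    tibble::tibble(
      protein_a = pa, peptide_a = match_a$peptide,
      start_a = match_a$start, end_a = match_a$end,
      link_pos_a = ra - match_a$start + 1L,
      protein_b = pb, peptide_b = match_b$peptide,
      start_b = match_b$start, end_b = match_b$end,
      link_pos_b = rb - match_b$start + 1L,
      fragments = make_fragments(nchar(match_a$peptide),
                                 nchar(match_b$peptide), run_a, run_b),
      replicate = replicate
    )
  }

  with_stream(truth$seed, 404L, {
    rows <- list()
    for (rep_i in seq_len(truth$n_replicates)) {
      rep_id <- paste0("r", rep_i)
      emitted <- runif(nrow(tc)) >= truth$dropout
      for (i in which(emitted)) {
        rows[[length(rows) + 1L]] <-
          csm_row(tc$protein_a[i], tc$residue_a[i], tc$protein_b[i],
                  tc$residue_b[i], frag_run_true, frag_run_true, rep_id)
      }
      n_true <- sum(emitted)
      n_decoy <- if (truth$decoy_rate > 0) {
        round(n_true * truth$decoy_rate / (1 - truth$decoy_rate))
      } else 0L
      if (n_decoy > 0L && nrow(decoy_pool) > 0L) {
        pick <- sample.int(nrow(decoy_pool), min(n_decoy, nrow(decoy_pool)))
        short <- runif(length(pick)) < decoy_short_frac
        for (d in seq_along(pick)) {
          dp <- decoy_pool[pick[d], ]
          run <- if (short[d]) frag_run_short else frag_run_true
          rows[[length(rows) + 1L]] <-
            csm_row(dp$protein_a, dp$residue_a, dp$protein_b, dp$residue_b,
                    run, run, rep_id)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    out$csm_id <- seq_len(nrow(out))
    out$spectrum_ref <- sprintf("spec_%05d", out$csm_id)
    out$condition <- condition
    out$score <- round(runif(nrow(out), 50, 300), 1)
    validate_csms(out[, CSM_COLUMNS])
  })
}

#' Planted inter-protein contact pairs
#'
#' The unordered inter-protein pairs (self pairs excluded) implied by the
#' planted contacts -- the reference set for network recovery.
#'
#' @param truth An `svxl_ground_truth`.
#' @param states Contact states counted as plantable network truth (default
#'   all states, since every emitted contact produces CSMs).
#' @export
true_inter_pairs <- function(truth,
                             states = c("open", "closed", "both", "none")) {
  tc <- truth$true_contacts
  tc <- tc[tc$state %in% states & tc$protein_a != tc$protein_b, ,
           drop = FALSE]
  unique(paste(pmin(tc$protein_a, tc$protein_b),
               pmax(tc$protein_a, tc$protein_b), sep = "|"))
}

#' Precision and recall of a recovered network against the planted truth
#'
#' @param truth An `svxl_ground_truth`.
#' @param network Edge tibble from [build_network()].
#' @return A list with `precision`, `recall`, `n_true`, `n_recovered`.
#' @export
network_recovery <- function(truth, network) {
  truth_pairs <- true_inter_pairs(truth)
  net <- network[!network$self_edge, , drop = FALSE]
  got <- unique(paste(net$protein_a, net$protein_b, sep = "|"))
  tp <- sum(got %in% truth_pairs)
  list(precision = if (length(got) > 0) tp / length(got) else NA_real_,
       recall = if (length(truth_pairs) > 0) tp / length(truth_pairs)
                else NA_real_,
       n_true = length(truth_pairs), n_recovered = length(got))
}

#' Write a complete simulated dataset to disk
#'
#' Emits every input the pipeline consumes: protein sequences (FASTA), the
#' two structural models (PDB) with their chain-to-protein table, the CSM and
#' peptide-intensity tables, topology segments, and a ground-truth manifest
#' (plain tab-separated tables plus a key-value parameter file).
#'
#' @param truth An `svxl_ground_truth`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  seqs <- Biostrings::AAStringSet(setNames(truth$proteins$sequence,
                                           truth$proteins$protein_id))
  Biostrings::writeXStringSet(seqs, path("proteins.fasta"))
  models <- simulate_structures(truth)
  write_structure_pdb(models$open, path("model_open.pdb"))
  write_structure_pdb(models$closed, path("model_closed.pdb"))
  write.table(models$chain_map, path("chain_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_csms(simulate_csms(truth), path("csms.tsv"))
  write.table(simulate_proteome(truth), path("intensities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth$topology)) {
    write.table(truth$topology, path("topology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(truth$proteins[, c("protein_id", "copy_number")],
              path("truth_proteins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$true_contacts, path("truth_contacts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  params <- c(seed = truth$seed, n_replicates = truth$n_replicates,
              dropout = truth$dropout, decoy_rate = truth$decoy_rate,
              noise_cv = truth$noise_cv)
  writeLines(paste(names(params), params, sep = "\t"),
             path("truth_params.tsv"))
  files <- c("proteins.fasta", "model_open.pdb", "model_closed.pdb",
             "chain_map.tsv", "csms.tsv", "intensities.tsv",
             "truth_proteins.tsv", "truth_contacts.tsv", "truth_params.tsv")
  if (!is.null(truth$topology)) files <- c(files, "topology.tsv")
  invisible(setNames(file.path(dir, files), files))
}
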