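test_that("ground truth validates contact chemistry and parameters", {
  prot <- tibble::tibble(protein_id = "P",
                         sequence = "AAAKGGGKCCCK", copy_number = 5)
  ok <- ground_truth(prot,
                     tibble::tibble(protein_a = "P", residue_a = 4L,
                                    protein_b = "P", residue_b = 8L,
                                    state = "both"))
  expect_s3_class(ok, "svxl_ground_truth")
  # a non-lysine, non-N-terminal contact residue is rejected
  expect_error(
    ground_truth(prot, tibble::tibble(protein_a = "P", residue_a = 2L,
                                      protein_b = "P", residue_b = 8L,
                                      state = "both")),
    "not a lysine")
  # position 1 is allowed (protein N-terminus)
  expect_s3_class(
    ground_truth(prot, tibble::tibble(protein_a = "P", residue_a = 1L,
                                      protein_b = "P", residue_b = 8L,
                                      state = "both")),
    "svxl_ground_truth")
  expect_error(
    ground_truth(dplyr::mutate(prot, sequence = "AABK"),
                 ok$true_contacts),
    "non-standard residue")
  expect_error(ground_truth(prot, ok$true_contacts, dropout = 1),
               "dropout")
})

test_that("simulation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(default_ground_truth(seed = 33), d1)
  write_simulation(default_ground_truth(seed = 33), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the tables
  d3 <- withr::local_tempdir()
  write_simulation(default_ground_truth(seed = 34), d3)
  expect_false(identical(readLines(file.path(d1, "csms.tsv")),
                         readLines(file.path(d3, "csms.tsv"))))
})

test_that("without dropout every true contact is supported in all replicates", {
  tr <- default_ground_truth(seed = 44, dropout = 0, decoy_rate = 0)
  links <- aggregate_csms(simulate_csms(tr))
  expect_true(all(links$n_replicates == tr$n_replicates))
  expect_equal(nrow(links), nrow(tr$true_contacts))
})

test_that("a clean simulation recovers exactly the planted link set", {
  tr <- default_ground_truth(seed = 44, dropout = 0, decoy_rate = 0)
  links <- aggregate_csms(simulate_csms(tr))
  tc <- tr$true_contacts
  canon <- function(pa, ra, pb, rb) {
    swap <- pa > pb | (pa == pb & ra > rb)
    paste(ifelse(swap, pb, pa), ifelse(swap, rb, ra),
          ifelse(swap, pa, pb), ifelse(swap, ra, rb))
  }
  expect_setequal(canon(links$protein_a, links$residue_a,
                        links$protein_b, links$residue_b),
                  canon(tc$protein_a, tc$residue_a,
                        tc$protein_b, tc$residue_b))
})

test_that("planted homo-oligomers emit identical peptide pairs", {
  tr <- default_ground_truth(seed = 44, dropout = 0, decoy_rate = 0)
  csms <- simulate_csms(tr)
  homo_truth <- tr$true_contacts$protein_a == tr$true_contacts$protein_b &
    tr$true_contacts$residue_a == tr$true_contacts$residue_b
  for (i in which(homo_truth)) {
    rows <- csms[csms$protein_a == tr$true_contacts$protein_a[i] &
                   absolute_link_position(csms$start_a, csms$link_pos_a) ==
                     tr$true_contacts$residue_a[i] &
                   csms$protein_b == csms$protein_a, ]
    hit <- rows[rows$peptide_a == rows$peptide_b, ]
    expect_gt(nrow(hit), 0)
    expect_true(all(is_homo_oligomer(hit)))
  }
})

test_that("toy structures realise the planted contact geometry", {
  tr <- default_ground_truth(seed = 55)
  mods <- simulate_structures(tr)
  tc <- tr$true_contacts
  links <- tibble::tibble(
    protein_a = tc$protein_a, residue_a = tc$residue_a,
    protein_b = tc$protein_b, residue_b = tc$residue_b,
    link_class = ifelse(tc$protein_a == tc$protein_b &
                          tc$residue_a == tc$residue_b,
                        "homo_oligomeric",
                        ifelse(tc$protein_a == tc$protein_b, "intra",
                               "inter")))
  in_open <- map_links(links, mods$open)
  in_closed <- map_links(links, mods$closed)
  for (i in seq_len(nrow(tc))) {
    st <- tc$state[i]
    open_ok <- in_open$status[i] == "mapped" && in_open$distance[i] <= 30
    closed_ok <- in_closed$status[i] == "mapped" &&
      in_closed$distance[i] <= 30
    if (st %in% c("open", "both")) expect_true(open_ok) else
      expect_false(open_ok)
    if (st %in% c("closed", "both")) expect_true(closed_ok) else
      expect_false(closed_ok)
  }
  # a planted two-chain homodimer self-link has a finite inter-chain distance
  homo <- links[links$link_class == "homo_oligomeric", ][1, ]
  m <- map_links(homo, mods$open)
  expect_equal(m$status, "mapped")
  expect_true(is.finite(m$distance))
  expect_true(m$chain_a != m$chain_b)
  # at least one protein is represented by two chain copies
  expect_gt(max(table(mods$chain_map$protein_id)), 1L)
})

test_that("conflicting geometric requirements are rejected", {
  prot <- tibble::tibble(protein_id = c("A", "B"),
                         sequence = c("AAAKGGGK", "CCCKDDDK"),
                         copy_number = c(1, 1))
  contacts <- tibble::tibble(protein_a = c("A", "A"),
                             residue_a = c(4L, 4L),
                             protein_b = c("B", "B"),
                             residue_b = c(4L, 4L),
                             state = c("open", "closed"))
  tr <- ground_truth(prot, contacts)
  expect_error(simulate_structures(tr), "unsatisfiable")
})

test_that("null distances are broader than planted contact distances", {
  tr <- default_ground_truth(seed = 66)
  mods <- simulate_structures(tr)
  links <- tibble::tibble(protein_a = tr$true_contacts$protein_a,
                          residue_a = tr$true_contacts$residue_a,
                          protein_b = tr$true_contacts$protein_b,
                          residue_b = tr$true_contacts$residue_b,
                          link_class = "inter")
  both <- tr$true_contacts$state == "both"
  observed <- map_links(links[both, ], mods$open)
  lys <- unique(dplyr::bind_rows(
    tibble::tibble(protein_id = links$protein_a,
                   residue = links$residue_a),
    tibble::tibble(protein_id = links$protein_b,
                   residue = links$residue_b)))
  null <- random_null(mods$open, lys, n_samples = 2000, seed = 5)
  expect_gte(null$median, median(observed$distance))
})

test_that("a cleavage event removes contacts on the released fragment", {
  tr <- default_ground_truth(seed = 77, dropout = 0, decoy_rate = 0)
  # release the N-terminal (cytosolic) two thirds of SYB2
  p_cut <- as.integer(nchar(tr$proteins$sequence[1]) * 2 / 3)
  csms <- simulate_csms(tr, condition = "bontb",
                        cleavage = list(protein_id = "SYB2", p = p_cut,
                                        released = "n"))
  res_a <- absolute_link_position(csms$start_a, csms$link_pos_a)
  res_b <- absolute_link_position(csms$start_b, csms$link_pos_b)
  on_released <- (csms$protein_a == "SYB2" & res_a <= p_cut) |
    (csms$protein_b == "SYB2" & res_b <= p_cut)
  expect_false(any(on_released))
  expect_true(all(csms$condition == "bontb"))
  # untreated simulation does involve the released region
  untreated <- simulate_csms(tr)
  res_u <- absolute_link_position(untreated$start_a, untreated$link_pos_a)
  expect_true(any(untreated$protein_a == "SYB2" & res_u <= p_cut))
})
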