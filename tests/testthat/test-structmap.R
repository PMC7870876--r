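# two chains of one protein plus a single-chain partner, exact coordinates
two_copy_model <- function() {
  toy_model(
    tibble::tibble(
      chain = c("A", "A", "B", "B", "C", "C"),
      resno = c(5L, 9L, 5L, 9L, 3L, 7L),
      x = c(0, 3, 100, 40, 0, 200),
      y = c(0, 4, 0, 0, 1, 0),
      z = 0
    ),
    chain_map = c(A = "P1", B = "P1", C = "P2")
  )
}

test_that("mapped distance is the Euclidean minimum over admissible chain pairs", {
  model <- two_copy_model()
  # P1:5 on chain A at (0,0,0) vs P2:3 on chain C at (0,1,0) -> 1 A;
  # chain B copy of P1:5 is 100 A away, so the minimum picks chain A
  link <- tibble::tibble(protein_a = "P1", residue_a = 5L,
                         protein_b = "P2", residue_b = 3L,
                         link_class = "inter")
  m <- map_links(link, model)
  expect_equal(m$status, "mapped")
  expect_equal(m$distance, 1)
  expect_true(m$satisfied)
  expect_equal(m$chain_a, "A")
  # 3-4-5 triangle within one chain
  intra <- tibble::tibble(protein_a = "P1", residue_a = 5L,
                          protein_b = "P1", residue_b = 9L,
                          link_class = "intra")
  expect_equal(map_links(intra, model)$distance, 5)
})

test_that("mapping is symmetric and unresolved residues give unmapped status", {
  model <- two_copy_model()
  fwd <- tibble::tibble(protein_a = "P1", residue_a = 5L,
                        protein_b = "P2", residue_b = 3L,
                        link_class = "inter")
  rev <- tibble::tibble(protein_a = "P2", residue_a = 3L,
                        protein_b = "P1", residue_b = 5L,
                        link_class = "inter")
  expect_equal(map_links(fwd, model)$distance, map_links(rev, model)$distance)

  absent <- tibble::tibble(protein_a = "P1", residue_a = 99L,
                           protein_b = "P2", residue_b = 3L,
                           link_class = "inter")
  m <- map_links(absent, model)
  expect_equal(m$status, "unmapped")
  expect_true(is.na(m$distance))
  # empty chain mapping: nothing maps
  bare <- two_copy_model()
  bare$chain_map <- character()
  expect_equal(map_links(fwd, bare)$status, "unmapped")
})

test_that("homo-oligomeric links require two distinct chains", {
  model <- two_copy_model()
  homo <- tibble::tibble(protein_a = "P1", residue_a = 5L,
                         protein_b = "P1", residue_b = 5L,
                         link_class = "homo_oligomeric")
  m <- map_links(homo, model)
  expect_equal(m$status, "mapped")
  expect_equal(m$distance, 100)  # chain A residue 5 to chain B residue 5
  expect_true(m$chain_a != m$chain_b)
  # a single-chain model cannot place the two copies
  single <- toy_model(tibble::tibble(chain = "C", resno = 3L,
                                     x = 0, y = 0, z = 0),
                      chain_map = c(C = "P2"))
  homo2 <- tibble::tibble(protein_a = "P2", residue_a = 3L,
                          protein_b = "P2", residue_b = 3L,
                          link_class = "homo_oligomeric")
  expect_equal(map_links(homo2, single)$status, "unmapped")
})

test_that("minimum property holds against a brute-force all-chain-pairs oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n_chain <- 4
    atoms <- dplyr::bind_rows(lapply(seq_len(n_chain), function(ci) {
      tibble::tibble(chain = LETTERS[ci], resno = 1:6,
                     x = runif(6, 0, 80), y = runif(6, 0, 80),
                     z = runif(6, 0, 80))
    }))
    # two proteins, two copies each
    model <- toy_model(atoms, chain_map = c(A = "PX", B = "PX",
                                            C = "PY", D = "PY"))
    link <- tibble::tibble(protein_a = "PX", residue_a = sample(1:6, 1),
                           protein_b = "PY", residue_b = sample(1:6, 1),
                           link_class = "inter")
    got <- map_links(link, model)$distance
    dists <- c()
    for (ca in c("A", "B")) for (cb in c("C", "D")) {
      a <- atoms[atoms$chain == ca & atoms$resno == link$residue_a, ]
      b <- atoms[atoms$chain == cb & atoms$resno == link$residue_b, ]
      dists <- c(dists, sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
    }
    expect_equal(got, min(dists))
    expect_true(all(got <= dists))
  }
})

test_that("distance histogram bins are half-open and conserve mapped counts", {
  mapped <- tibble::tibble(status = c("mapped", "mapped", "mapped",
                                      "unmapped"),
                           distance = c(5, 29, 31, NA))
  h <- distance_histogram(mapped, bin_width = 10)
  expect_equal(h$n_satisfied, 2L)
  expect_equal(h$n_mapped, 3L)
  expect_equal(sum(h$histogram$count), 3L)
  # 29 falls in [20,30), 31 in [30,40)
  expect_equal(h$histogram$count[h$histogram$bin_start == 20], 1L)
  expect_equal(h$histogram$count[h$histogram$bin_start == 30], 1L)
  expect_error(distance_histogram(mapped, bin_width = 0), "bin_width")
})

test_that("satisfied count is non-decreasing in the threshold", {
  set.seed(61)
  mapped <- tibble::tibble(status = "mapped", distance = runif(50, 0, 60))
  counts <- vapply(seq(0, 70, by = 5), function(th) {
    distance_histogram(mapped, 5, threshold = th)$n_satisfied
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("null sampler matches exhaustive enumeration for three residues", {
  # 3 source lysines -> exactly 3 distinct pairs with known distances
  model <- toy_model(tibble::tibble(chain = "A", resno = c(1L, 2L, 3L),
                                    x = c(0, 3, 0), y = c(0, 4, 12), z = 0),
                     chain_map = c(A = "P"))
  src <- tibble::tibble(protein_id = "P", residue = 1:3)
  null <- random_null(model, src, n_samples = 1e5, seed = 7)
  # pair distances: 1-2 = 5, 1-3 = 12, 2-3 = sqrt(9+64) = sqrt(73)
  enum <- c(5, 12, sqrt(73))
  expect_setequal(round(unique(null$distances), 10), round(enum, 10))
  expect_equal(mean(null$distances), mean(enum), tolerance = 0.01)
  expect_equal(null$median, sqrt(73))  # middle of the three pair distances
})

test_that("null sampling is seed-reproducible and stable across seeds", {
  model <- toy_model(tibble::tibble(chain = "A", resno = 1:6,
                                    x = c(0, 10, 20, 5, 40, 8),
                                    y = c(0, 0, 7, 30, 2, 9), z = 0),
                     chain_map = c(A = "P"))
  src <- tibble::tibble(protein_id = "P", residue = 1:6)
  a <- random_null(model, src, n_samples = 1e5, seed = 11)
  b <- random_null(model, src, n_samples = 1e5, seed = 11)
  expect_identical(a$distances, b$distances)
  c <- random_null(model, src, n_samples = 1e5, seed = 12)
  grid <- seq(0, 50, by = 0.5)
  ks <- max(abs(a$ecdf(grid) - c$ecdf(grid)))
  expect_lt(ks, 0.05)
})

test_that("degenerate null inputs behave as specified", {
  coincident <- toy_model(tibble::tibble(chain = "A", resno = 1:3,
                                         x = 1, y = 2, z = 3),
                          chain_map = c(A = "P"))
  src <- tibble::tibble(protein_id = "P", residue = 1:3)
  null <- random_null(coincident, src, n_samples = 100, seed = 3)
  expect_true(all(null$distances == 0))
  expect_error(random_null(coincident,
                           tibble::tibble(protein_id = "P", residue = 1L),
                           100, 1),
               "mappable")
  # unmappable residues are excluded from the source set before the check
  expect_error(random_null(coincident,
                           tibble::tibble(protein_id = "P",
                                          residue = c(1L, 99L)),
                           100, 1),
               "mappable")
})

test_that("state compatibility verdicts follow the satisfaction rule", {
  open <- toy_model(tibble::tibble(chain = c("A", "B"), resno = c(1L, 1L),
                                   x = c(0, 10), y = 0, z = 0),
                    chain_map = c(A = "P1", B = "P2"), model_id = "open")
  closed <- toy_model(tibble::tibble(chain = c("A", "B"), resno = c(1L, 1L),
                                     x = c(0, 100), y = 0, z = 0),
                      chain_map = c(A = "P1", B = "P2"), model_id = "closed")
  link <- tibble::tibble(protein_a = "P1", residue_a = 1L,
                         protein_b = "P2", residue_b = 1L,
                         link_class = "inter")
  call <- state_compatibility(link, open, closed)
  expect_equal(call$verdict, "a_exclusive")
  expect_equal(call$status_b, "violated")
  # satisfied in both models -> shared
  shared <- state_compatibility(link, open, open)
  expect_equal(shared$verdict, "shared")
  # unmappable on one side counts as not satisfied but is reported distinctly
  noB <- toy_model(tibble::tibble(chain = "A", resno = 1L,
                                  x = 0, y = 0, z = 0),
                   chain_map = c(A = "P1"))
  part <- state_compatibility(link, open, noB)
  expect_equal(part$verdict, "a_exclusive")
  expect_equal(part$status_b, "unmappable")
})

test_that("structures written as PDB round-trip through the loader", {
  tr <- default_ground_truth(seed = 19)
  mods <- simulate_structures(tr)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(mods$open, f)
  back <- load_structure(f, chain_map = mods$chain_map)
  expect_setequal(unique(back$atoms$chain), unique(mods$open$atoms$chain))
  counts_back <- table(back$atoms$chain)
  counts_orig <- table(mods$open$atoms$chain)
  expect_equal(as.integer(counts_back[names(counts_orig)]),
               as.integer(counts_orig))
  # coordinates survive to PDB precision
  m1 <- map_links(tibble::tibble(protein_a = tr$proteins$protein_id[1],
                                 residue_a = tr$true_contacts$residue_a[1],
                                 protein_b = tr$true_contacts$protein_b[1],
                                 residue_b = tr$true_contacts$residue_b[1],
                                 link_class = "inter"), back)
  expect_equal(m1$status, "mapped")
})
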