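# Molecules, XYZ I/O, orbital indexing, neighbor lists, dataset container.

test_that("XYZ files parse, round-trip, and report malformed input", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water frame",
               "O 0 0 0", "H 0.9584 0 0", "H -0.2392 0.9281 0"), path)
  mols <- read_xyz(path)
  expect_length(mols, 1L)
  expect_identical(mols[[1]]$atomic_numbers, c(8L, 1L, 1L))
  expect_equal(mols[[1]]$positions[2, 1], 0.9584)

  # multi-frame round trip
  set.seed(4)
  frames <- lapply(1:3, function(k) {
    molecule(c(8L, 1L, 1L), toy_water$molecule$positions +
               matrix(rnorm(9, sd = 0.05), 3, 3), sprintf("frame %d", k))
  })
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, p2)
  back <- read_xyz(p2)
  for (k in 1:3) {
    expect_equal(back[[k]]$positions, frames[[k]]$positions, tolerance = 1e-6)
    expect_identical(back[[k]]$atomic_numbers, frames[[k]]$atomic_numbers)
  }

  # count line promises more atoms than present
  p3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "broken", "O 0 0 0", "H 1 0 0", "H 0 1 0"), p3)
  expect_error(read_xyz(p3), "truncated")
  p4 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad element", "Qq 0 0 0", "H 1 0 0"), p4)
  expect_error(read_xyz(p4), "unknown element")
})

test_that("orbital index is deterministic, atom-major, and bijective", {
  # H atom, one s shell
  h1 <- molecule(1L, matrix(0, 1, 3))
  oi <- build_orbital_index(h1, toy_h2$basis)
  expect_identical(oi$atom_offsets, 0L)
  expect_identical(oi$atom_counts, 1L)

  # heavy atom with (s, p): 1 + 3 orbitals; water-like molecule: 4 + 1 + 1
  oi <- build_orbital_index(toy_water$molecule, toy_water$basis)
  expect_identical(oi$atom_counts, c(4L, 1L, 1L))
  expect_identical(oi$atom_offsets, c(0L, 4L, 5L))
  expect_identical(oi$n_ao, 6L)
  # bijection: every (atom, shell, m) appears exactly once, m runs -l..l
  lab <- oi$orbital_labels
  key <- paste(lab$atom, lab$shell, lab$m)
  expect_identical(anyDuplicated(key), 0L)
  psel <- lab$l == 1L
  expect_identical(lab$m[psel], -1:1)
  expect_error(build_orbital_index(toy_water$molecule, toy_h2$basis),
               "no entry")
})

test_that("neighbor pairs match a brute-force all-pairs scan", {
  two <- molecule(c(1L, 1L), rbind(c(0, 0, 0), c(1, 0, 0)))
  np <- neighbor_pairs(two, 5)
  expect_identical(sort(np$i), 1:2)
  expect_equal(np$r_ij[1, ], -np$r_ij[2, ])
  expect_length(neighbor_pairs(molecule(c(1L, 1L),
                                        rbind(c(0, 0, 0), c(6, 0, 0))), 5)$i, 0L)

  for (seed in 1:20) {
    mol <- random_molecule(8L, seed, spread = 3)
    r_c <- runif(1, 1, 6)
    np <- neighbor_pairs(mol, r_c)
    got <- sort(paste(np$i, np$j))
    want <- character(0)
    for (i in 1:8) for (j in 1:8) {
      if (i != j && sqrt(sum((mol$positions[j, ] - mol$positions[i, ])^2)) < r_c) {
        want <- c(want, paste(i, j))
      }
    }
    expect_identical(got, sort(want))
    expect_equal(np$dist, sqrt(rowSums(np$r_ij^2)))
  }
})

test_that("dataset container round-trips records and metadata losslessly", {
  ds <- generate_dataset(toy_h2$molecule, 10, 0.03, 5, toy_h2$basis,
                         toy_h2$params, toy_h2$n_electrons)
  path <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds$records, path, toy_h2$basis, meta = ds$meta)
  back <- read_dataset(path)
  expect_length(back$records, 10L)
  for (k in c(1L, 5L, 10L)) {
    expect_identical(back$records[[k]]$H, ds$records[[k]]$H)
    expect_identical(back$records[[k]]$S, ds$records[[k]]$S)
    expect_identical(back$records[[k]]$E, ds$records[[k]]$E)
    expect_identical(back$records[[k]]$F, ds$records[[k]]$F)
    expect_identical(back$records[[k]]$molecule$positions,
                     ds$records[[k]]$molecule$positions)
  }
  expect_identical(back$meta$seed, 5L)

  # missing group is a format error
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$overlap <- NULL
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_dataset(p2), "missing group.*overlap")
})
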