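# The extended-Hueckel reference surface and dataset generation.

test_that("Hamiltonian structure follows the Wolfsberg-Helmholz form", {
  ts <- toy_water
  oidx <- build_orbital_index(ts$molecule, ts$basis)
  S <- overlap_matrix(ts$molecule, ts$basis)
  H <- hueckel_hamiltonian(ts$molecule, ts$basis, ts$params, S = S)
  h <- schnorblite:::onsite_energies(oidx, ts$molecule, ts$params)
  expect_identical(diag(H), h)
  expect_identical(h[1:4], c(-32.4, -14.8, -14.8, -14.8))
  # zero overlap implies zero coupling
  off <- H[upper.tri(H)]
  expect_identical(off[S[upper.tri(S)] == 0], numeric(sum(S[upper.tri(S)] == 0)))
  expect_equal(H[1, 5], 0.5 * 1.75 * (-32.4 - 13.6) * S[1, 5])
  # missing shell entry is a configuration error
  bad <- ts$params; bad$h[["8"]] <- -32.4
  expect_error(hueckel_hamiltonian(ts$molecule, ts$basis, bad), "shell 2")
})

test_that("H2 generalized eigenvalues match the 2x2 closed form", {
  hs <- hs_matrices(hueckel_surface(toy_h2$basis, toy_h2$params, 2L),
                    toy_h2$molecule)
  s <- hs$S[1, 2]; h <- -13.6; K <- 1.75
  eps <- schnorblite:::generalized_eigen(hs$H, hs$S, values_only = TRUE)
  expect_equal(eps, sort(c(h * (1 + K * s) / (1 + s),
                           h * (1 - K * s) / (1 - s))), tolerance = 1e-12)
})

test_that("reference energies and forces are consistent and invariant", {
  ts <- toy_water
  ef <- reference_energy_forces(ts$molecule, ts$basis, ts$params,
                                ts$n_electrons)
  # translational invariance: forces sum to zero
  expect_lt(max(abs(colSums(ef$F))), 1e-4)
  # cross-check against a coarser finite-difference step
  fd <- fd_gradient(ts$molecule, function(m) {
    schnorblite:::hueckel_energy(m, ts$basis, ts$params, ts$n_electrons)
  }, step = 1e-3)
  expect_lt(max(abs(ef$F + fd)), 1e-3)
  # energy invariant under rotation and translation
  rot <- random_rotation(9)
  molr <- ts$molecule; molr$positions <- molr$positions %*% t(rot$R)
  molt <- ts$molecule; molt$positions <- molt$positions + rep(1, 3)
  E0 <- schnorblite:::hueckel_energy(ts$molecule, ts$basis, ts$params,
                                     ts$n_electrons)
  expect_equal(schnorblite:::hueckel_energy(molr, ts$basis, ts$params,
                                            ts$n_electrons), E0,
               tolerance = 1e-8)
  expect_equal(schnorblite:::hueckel_energy(molt, ts$basis, ts$params,
                                            ts$n_electrons), E0,
               tolerance = 1e-10)
  # generalized eigenvalues invariant under global translation
  e0 <- schnorblite:::generalized_eigen(
    hueckel_hamiltonian(ts$molecule, ts$basis, ts$params),
    overlap_matrix(ts$molecule, ts$basis), values_only = TRUE)
  e1 <- schnorblite:::generalized_eigen(
    hueckel_hamiltonian(molt, ts$basis, ts$params),
    overlap_matrix(molt, ts$basis), values_only = TRUE)
  expect_lt(max(abs(e0 - e1)), 1e-10)
})

test_that("dataset generation is seeded, respects sigma, and stays covariant", {
  ts <- toy_water
  d1 <- generate_dataset(ts$molecule, 5, 0.05, 3, ts$basis, ts$params,
                         ts$n_electrons)
  d2 <- generate_dataset(ts$molecule, 5, 0.05, 3, ts$basis, ts$params,
                         ts$n_electrons)
  expect_identical(d1$records[[4]]$H, d2$records[[4]]$H)
  expect_identical(d1$records[[4]]$molecule$positions,
                   d2$records[[4]]$molecule$positions)

  # sigma = 0: every record is the template record
  d0 <- generate_dataset(ts$molecule, 3, 0, 3, ts$basis, ts$params,
                         ts$n_electrons)
  expect_identical(d0$records[[1]]$H, d0$records[[3]]$H)
  expect_identical(d0$records[[2]]$molecule$positions, ts$molecule$positions)

  # each record satisfies the rotation oracle under random rotors
  for (k in 1:2) {
    rec <- d1$records[[k]]
    for (rs in 1:3) {
      rot <- random_rotation(700 + 10 * k + rs)
      rr <- rotate_record(rec, rot, ts$basis)
      molr <- rec$molecule
      molr$positions <- molr$positions %*% t(rot$R)
      expect_lt(max(abs(rr$S - overlap_matrix(molr, ts$basis))), 1e-8)
      expect_lt(max(abs(rr$H - hueckel_hamiltonian(molr, ts$basis,
                                                   ts$params))), 1e-8)
    }
  }
  expect_identical(d1$meta$seed, 3)
})

test_that("hueckel parameter files round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_hueckel_params(toy_water$params, path)
  back <- read_hueckel_params(path)
  expect_identical(back$h, toy_water$params$h)
  expect_identical(back$K, toy_water$params$K)
  expect_identical(back$n_valence, toy_water$params$n_valence)
})
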