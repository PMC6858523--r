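# Spectra, density matrices, populations, moments, DOS, gradients, gaps.

test_that("solve_orbitals satisfies its eigenproblem contract", {
  # S = I reduces to an ordinary symmetric eigendecomposition
  set.seed(14)
  A <- matrix(rnorm(25), 5); Hm <- (A + t(A)) / 2
  sp <- solve_orbitals(Hm, diag(5), 4L)
  ev <- eigen(Hm, symmetric = TRUE)
  expect_equal(sp$epsilon, sort(ev$values), tolerance = 1e-12)
  expect_lt(max(abs(t(sp$C) %*% sp$C - diag(5))), 1e-10)
  expect_identical(sp$occupation, c(2, 2, 0, 0, 0))

  # residual contract on random SPD instances
  for (seed in 1:25) {
    set.seed(seed)
    nn <- sample(3:8, 1)
    A <- matrix(rnorm(nn^2), nn); Hm <- (A + t(A)) / 2
    Bm <- matrix(rnorm(nn^2), nn)
    Sm <- crossprod(Bm) / nn + diag(nn)
    sp <- solve_orbitals(Hm, Sm, 2L)
    expect_lt(max(abs(Hm %*% sp$C - Sm %*% sp$C %*% diag(sp$epsilon))), 1e-7)
    expect_lt(max(abs(t(sp$C) %*% Sm %*% sp$C - diag(nn))), 1e-8)
    expect_true(all(diff(sp$epsilon) >= 0))
  }

  # indefinite overlap is rejected
  expect_error(solve_orbitals(diag(3), diag(c(1, 1, -1)), 2L),
               "ill-conditioned")
})

test_that("density matrix is an idempotent closed-shell projector", {
  hs <- hs_matrices(hueckel_surface(toy_water$basis, toy_water$params, 8L),
                    toy_water$molecule)
  sp <- solve_orbitals(hs$H, hs$S, 8L)
  P <- density_matrix(sp)
  expect_identical(P, t(P))
  expect_equal(sum(P * hs$S), 8, tolerance = 1e-10)      # Tr(P S) = n_elec
  expect_lt(max(abs(P %*% hs$S %*% P - 2 * P)), 1e-8)     # P S P = 2 P
  sp0 <- solve_orbitals(hs$H, hs$S, 0L)
  expect_identical(density_matrix(sp0), matrix(0, 6, 6))
  spodd <- sp; spodd$n_electrons <- 3L
  expect_error(density_matrix(spodd), "even")
})

test_that("Loewdin charges and bond orders satisfy the closed-form identities", {
  # symmetric H2, 2 electrons: neutral atoms, bond order exactly 1
  hs <- hs_matrices(hueckel_surface(toy_h2$basis, toy_h2$params, 2L),
                    toy_h2$molecule)
  sp <- solve_orbitals(hs$H, hs$S, 2L)
  oidx <- build_orbital_index(toy_h2$molecule, toy_h2$basis)
  popl <- loewdin_analysis(density_matrix(sp), hs$S, oidx, c(1, 1))
  expect_equal(popl$charges, c(0, 0), tolerance = 1e-10)
  expect_equal(popl$bond_orders[1, 2], 1, tolerance = 1e-10)

  # charge-sum identity on random distorted geometries
  for (seed in 1:6) {
    ds <- generate_dataset(toy_water$molecule, 1, 0.08, seed,
                           toy_water$basis, toy_water$params, 8L)
    rec <- ds$records[[1]]
    spw <- solve_orbitals(rec$H, rec$S, 8L)
    oi <- build_orbital_index(rec$molecule, toy_water$basis)
    nval <- valence_counts(toy_water$params, rec$molecule)
    pw <- loewdin_analysis(density_matrix(spw), rec$S, oi, nval)
    expect_equal(sum(pw$charges), sum(nval) - 8, tolerance = 1e-8)
    expect_identical(pw$bond_orders, t(pw$bond_orders))
  }

  # separated fragments: block-diagonal overlap, no inter-fragment bond order
  far <- molecule(c(1L, 1L, 1L, 1L),
                  rbind(c(0, 0, 0), c(0.75, 0, 0),
                        c(50, 0, 0), c(50.75, 0, 0)))
  Sfar <- overlap_matrix(far, toy_h2$basis)
  Hfar <- hueckel_hamiltonian(far, toy_h2$basis, toy_h2$params, S = Sfar)
  spf <- solve_orbitals(Hfar, Sfar, 4L)
  oif <- build_orbital_index(far, toy_h2$basis)
  pf <- loewdin_analysis(density_matrix(spf), Sfar, oif, rep(1, 4))
  expect_lt(pf$bond_orders[1, 3], 1e-12)
  expect_lt(pf$bond_orders[2, 4], 1e-12)
  expect_equal(pf$bond_orders[1, 2], 1, tolerance = 1e-8)
})

test_that("multipole moments respect symmetry and origin independence", {
  # homonuclear symmetric H2: zero dipole
  hs <- hs_matrices(hueckel_surface(toy_h2$basis, toy_h2$params, 2L),
                    toy_h2$molecule)
  sp <- solve_orbitals(hs$H, hs$S, 2L)
  P <- density_matrix(sp)
  mom <- multipole_moments(P, hs$S, toy_h2$molecule, toy_h2$basis, c(1, 1))
  expect_lt(max(abs(mom$dipole)), 1e-10)

  # neutral system: dipole independent of origin
  hsw <- hs_matrices(hueckel_surface(toy_water$basis, toy_water$params, 8L),
                     toy_water$molecule)
  spw <- solve_orbitals(hsw$H, hsw$S, 8L)
  Pw <- density_matrix(spw)
  nval <- valence_counts(toy_water$params, toy_water$molecule)
  m0 <- multipole_moments(Pw, hsw$S, toy_water$molecule, toy_water$basis, nval)
  m1 <- multipole_moments(Pw, hsw$S, toy_water$molecule, toy_water$basis, nval,
                          origin = c(1.3, -0.7, 0.4))
  expect_lt(max(abs(m0$dipole - m1$dipole)), 1e-8)
  expect_identical(m0$quadrupole, t(m0$quadrupole))
  # traceless option has zero trace
  mt <- multipole_moments(Pw, hsw$S, toy_water$molecule, toy_water$basis,
                          nval, traceless = TRUE)
  expect_lt(abs(sum(diag(mt$quadrupole))), 1e-10)

  # one-orbital atom with P = 2: dipole = (n_val - 2) * r * conversion
  h1 <- molecule(1L, matrix(c(0.5, -0.2, 0.9), 1))
  S1 <- overlap_matrix(h1, toy_h2$basis)
  m1a <- multipole_moments(matrix(2), S1, h1, toy_h2$basis, n_valence = 1)
  expect_equal(m1a$dipole, (1 - 2) * c(0.5, -0.2, 0.9) * 4.803204,
               tolerance = 1e-8)
})

test_that("DOS curves integrate to the orbital count and broaden correctly", {
  d1 <- dos_curve(0, sigma = 0.2, grid = seq(-3, 3, length.out = 2001))
  expect_equal(d1$energy[which.max(d1$dos)], 0, tolerance = 5e-3)
  area <- sum(d1$dos) * diff(d1$energy[1:2])
  expect_equal(area, 1, tolerance = 1e-3)

  # two frames: total area equals the mean orbital count per frame
  d2 <- dos_curve(list(c(-1, 1), c(-1.5, 0.5, 2)), sigma = 0.3,
                  grid = seq(-6, 6, length.out = 4001))
  expect_equal(sum(d2$dos) * diff(d2$energy[1:2]), 2.5, tolerance = 1e-3)

  # frame-to-frame energy scatter widens the combined peak (variances add)
  g <- seq(-4, 4, length.out = 4001)
  single <- dos_curve(0, sigma = 0.3, grid = g)
  spread <- dos_curve(list(-0.5, 0.5), sigma = 0.3, grid = g)
  var1 <- sum(single$dos * g^2) / sum(single$dos)
  var2 <- sum(spread$dos * g^2) / sum(spread$dos)
  expect_gt(var2, var1 + 0.2)
  expect_error(dos_curve(numeric(0), 0.1), "empty")
  expect_error(dos_curve(1, -0.1), "sigma")
})

test_that("HOMO-LUMO gap arithmetic and guards", {
  fake <- structure(list(epsilon = c(-10, -5, 1), occupation = c(2, 2, 0),
                         n_electrons = 4L), class = "slite_spectrum")
  expect_equal(homo_lumo_gap(fake), 6)
  degen <- structure(list(epsilon = c(-5, -5), occupation = c(2, 0),
                          n_electrons = 2L), class = "slite_spectrum")
  expect_equal(homo_lumo_gap(degen), 0)
  full <- structure(list(epsilon = c(-5, -4), occupation = c(2, 2),
                         n_electrons = 4L), class = "slite_spectrum")
  expect_error(homo_lumo_gap(full), "virtual")
  # H2 closed form
  hs <- hs_matrices(hueckel_surface(toy_h2$basis, toy_h2$params, 2L),
                    toy_h2$molecule)
  sp <- solve_orbitals(hs$H, hs$S, 2L)
  s <- hs$S[1, 2]
  expect_equal(homo_lumo_gap(sp),
               -13.6 * (1 - 1.75 * s) / (1 - s) -
                 (-13.6) * (1 + 1.75 * s) / (1 + s), tolerance = 1e-10)
  expect_s3_class(tidy(sp), "tbl_df")
  expect_equal(glance(sp)$gap, homo_lumo_gap(sp))
})

test_that("orbital-energy gradients match finite differences and vanish under
           translation", {
  surf <- hueckel_surface(toy_water$basis, toy_water$params, 8L)
  mol <- toy_water$molecule
  for (m in c(1L, 4L)) {
    g <- orbital_energy_gradient(surf, mol, m)
    fd <- fd_gradient(mol, function(mm) {
      hs <- hs_matrices(surf, mm)
      schnorblite:::generalized_eigen(hs$H, hs$S, values_only = TRUE)[m]
    })
    expect_lt(max(abs(g - fd)), 1e-4)
    expect_lt(max(abs(colSums(g))), 1e-6)
  }
  # randomly initialised model surface obeys the same contract
  mdl <- tiny_model(toy_water$basis, seed = 17)
  gm <- orbital_energy_gradient(mdl, mol, 2L)
  fdm <- fd_gradient(mol, function(mm) {
    hs <- hs_matrices(mdl, mm)
    schnorblite:::generalized_eigen(hs$H, hs$S, values_only = TRUE)[2]
  })
  expect_lt(max(abs(gm - fdm)), 1e-4)

  # duplicated far-apart fragments make every level degenerate
  far <- molecule(c(1L, 1L, 1L, 1L),
                  rbind(c(0, 0, 0), c(0.75, 0, 0),
                        c(50, 0, 0), c(50.75, 0, 0)))
  surf2 <- hueckel_surface(toy_h2$basis, toy_h2$params, 4L)
  expect_error(orbital_energy_gradient(surf2, far, 1L), "degenerate")
  expect_error(orbital_energy_gradient(surf, mol, 99L), "out of range")
})
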