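# The network: activations, radial filters, symmetry and gradient contracts.

test_that("shifted softplus has the defining values and asymptotics", {
  expect_identical(ssp(0), 0)
  expect_equal(ssp(50) - 50, -log(2), tolerance = 1e-9)
  g <- seq(-5, 5, length.out = 101)
  expect_true(all(diff(ssp(g)) > 0))
  # large negative arguments decay to -log(2)
  expect_equal(ssp(-200), -log(2))
  # complex analyticity: complex-step derivative equals the sigmoid
  x0 <- 0.37
  expect_equal(Im(ssp(x0 + 1i * 1e-20)) / 1e-20,
               1 / (1 + exp(-x0)), tolerance = 1e-12)
})

test_that("radial filter respects grid, cutoff and exact zero beyond r_c", {
  cfg <- toy_water |> (\(ts) model_config(ts$basis, B = 8L, D = 2L,
                                          T_interactions = 1L,
                                          n_hidden = 8L))()
  par <- init_params(cfg, toy_water$basis, seed = 2)
  mp <- par$schnet[[1]]$filt
  expect_identical(radial_filter(cfg$r_c, mp, cfg), matrix(0, 1, cfg$B))
  expect_identical(radial_filter(cfg$r_c + 1, mp, cfg), matrix(0, 1, cfg$B))
  # Gaussian expansion component k equals 1 at r = k * delta_mu
  k <- 7L
  rf <- schnorblite:::radial_filter_forward(mp, k * cfg$delta_mu, cfg)
  expect_equal(rf$rbf[1, k + 1L], 1)
  expect_equal(rf$fcut[1], 0.5 * (1 + cos(pi * k * cfg$delta_mu / cfg$r_c)))
  # cosine cutoff is 1/2 at half the cutoff radius
  rf2 <- schnorblite:::radial_filter_forward(mp, cfg$r_c / 2, cfg)
  expect_equal(rf2$fcut[1], 0.5)
})

test_that("forward pass is deterministic with symmetric matrices and the
           expected block structure", {
  mdl <- tiny_model(toy_water$basis, seed = 5)
  mol <- toy_water$molecule
  p1 <- predict_electronic(mdl, mol)
  p2 <- predict_electronic(mdl, mol)
  expect_identical(p1$H, p2$H)
  expect_identical(p1$E, p2$E)
  expect_identical(p1$H, t(p1$H))
  expect_identical(p1$S, t(p1$S))
  oidx <- build_orbital_index(mol, toy_water$basis)
  expect_identical(dim(p1$H), c(oidx$n_ao, oidx$n_ao))
  expect_true(is.finite(p1$E))
  # atoms with fewer orbitals than n_ao_max: no out-of-block leakage by
  # construction (total dimension equals the orbital-index total)
  expect_identical(nrow(p1$S), 6L)
  # on-site overlap blocks are per-element constants: both H atoms share one
  expect_identical(p1$S[5, 5], p1$S[6, 6])
})

test_that("atom representations are rotation/translation invariant and pair
           coefficients rotation invariant", {
  mdl <- tiny_model(toy_water$basis, seed = 6)
  mol <- toy_water$molecule
  x0 <- atom_representations(mdl, mol)
  pf0 <- pair_features(mdl, mol)
  for (seed in 1:5) {
    rot <- random_rotation(800 + seed)
    molr <- mol
    molr$positions <- mol$positions %*% t(rot$R) + rep(0.3, 3)
    xr <- atom_representations(mdl, molr)
    expect_lt(max(abs(xr$final - x0$final)), 1e-6)
    pfr <- pair_features(mdl, molr)
    for (s in seq_along(pf0$p)) {
      expect_lt(max(abs(pfr$p[[s]] - pf0$p[[s]])), 1e-6)
    }
  }
  # identical atoms in a symmetric dimer share a representation
  h2m <- toy_h2$molecule
  mdl2 <- tiny_model(toy_h2$basis, seed = 3)
  xh <- atom_representations(mdl2, h2m)
  expect_equal(xh$final[1, ], xh$final[2, ], tolerance = 1e-10)
})

test_that("pair features are index-symmetric where the construction demands", {
  mdl <- tiny_model(toy_water$basis, seed = 8)
  pf <- pair_features(mdl, toy_water$molecule)
  pl <- pf$pairs
  # factorised pair representation is symmetric: h_ij = h_ji
  for (s in seq_along(pf$h)) {
    for (p in seq_along(pl$i)) {
      q <- which(pl$i == pl$j[p] & pl$j == pl$i[p])
      expect_identical(pf$h[[s]][p, ], pf$h[[s]][q, ])
    }
  }
  # lambda = 0 basis factors are constant across the direction slices
  B <- mdl$config$B; D <- mdl$config$D
  om0 <- pf$omega[[1]]
  for (d in 2:D) {
    expect_identical(om0[, (d - 1) * B + seq_len(B)], om0[, seq_len(B)])
  }
  # angular products re-multiply: Omega^l = prod of omega^(0..l)
  if (length(pf$omega) >= 3) {
    expect_equal(pf$Omega[[3]], pf$omega[[1]] * pf$omega[[2]] * pf$omega[[3]],
                 tolerance = 1e-12)
  }
  # diatomic: no third atom, so the environment sums vanish and p reduces
  # to the direct pair path
  mdl2 <- tiny_model(toy_h2$basis, seed = 3)
  fw <- schnorblite:::model_forward(mdl2, toy_h2$molecule, what = "hs")
  st <- fw$cache$schnorb[[1]]
  expect_equal(st$p, st$pairm$out, tolerance = 1e-12)
})

test_that("permuting atoms permutes blocks, forces and representations", {
  mdl <- tiny_model(toy_water$basis, seed = 9)
  mol <- toy_water$molecule
  perm <- c(3L, 1L, 2L)
  molp <- molecule(mol$atomic_numbers[perm], mol$positions[perm, ],
                   mol$comment)
  p0 <- predict_electronic(mdl, mol)
  pp <- predict_electronic(mdl, molp)
  expect_equal(pp$E, p0$E, tolerance = 1e-8)
  expect_equal(pp$F, p0$F[perm, ], tolerance = 1e-8)
  oidx <- build_orbital_index(mol, toy_water$basis)
  oidxp <- build_orbital_index(molp, toy_water$basis)
  for (a in 1:3) for (b in 1:3) {
    ia <- schnorblite:::atom_orbitals(oidxp, a)
    jb <- schnorblite:::atom_orbitals(oidxp, b)
    ia0 <- schnorblite:::atom_orbitals(oidx, perm[a])
    jb0 <- schnorblite:::atom_orbitals(oidx, perm[b])
    expect_equal(pp$H[ia, jb], p0$H[ia0, jb0], tolerance = 1e-8)
    expect_equal(pp$S[ia, jb], p0$S[ia0, jb0], tolerance = 1e-8)
  }
})

test_that("analytic forces and loss gradients match finite differences", {
  mdl <- tiny_model(toy_water$basis, seed = 12, B = 12L, D = 3L, T = 2L)
  for (seed in 1:3) {
    mol <- random_molecule(3L, 900 + seed, spread = 1.2, zpool = c(8L, 1L))
    ef <- energy_forces(mdl, mol)
    fd <- fd_gradient(mol, function(m) {
      schnorblite:::model_forward(mdl, m, what = "energy")$E
    })
    expect_lt(max(abs(ef$F + fd)), 1e-4)
    expect_lt(max(abs(colSums(ef$F))), 1e-6)
  }
  # rotated geometry: identical energy
  mol <- toy_water$molecule
  rot <- random_rotation(31)
  molr <- mol; molr$positions <- mol$positions %*% t(rot$R)
  expect_equal(energy_forces(mdl, molr)$E, energy_forces(mdl, mol)$E,
               tolerance = 1e-6)
})

test_that("model checkpoints round-trip to identical predictions", {
  mdl <- tiny_model(toy_water$basis, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(mdl, path)
  back <- read_checkpoint(path)
  p0 <- predict_electronic(mdl, toy_water$molecule, forces = FALSE)
  p1 <- predict_electronic(back, toy_water$molecule, forces = FALSE)
  expect_identical(p0$H, p1$H)
  expect_identical(p0$S, p1$S)
  expect_identical(p0$E, p1$E)
  expect_error(read_checkpoint(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("unsupported elements are rejected with a clear error", {
  mdl <- tiny_model(toy_h2$basis, seed = 1)
  molx <- molecule(c(8L, 1L), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(schnorblite:::model_forward(mdl, molx), "no embedding")
})
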