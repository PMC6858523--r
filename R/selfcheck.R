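#' Fast invariant self-check
#'
#' Runs a compact version of the package's core numerical contracts:
#' analytic integrals against quadrature, Wigner-block composition and the
#' sampled-harmonics oracle, generator rotation equivariance, eigensolver
#' residuals, Loewdin identities, and gradient checks on both the generator
#' surface and a randomly initialised model.
#'
#' @param seed integer seed for the randomised checks.
#' @return a tibble with columns `group`, `passed`, `detail`; one row per
#'   check group.
#' @export
selfcheck <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rows <- list()
  note <- function(group, passed, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      group = group, passed = passed, detail = detail)
  }

  # integrals vs quadrature
  err <- 0
  for (k in 1:8) {
    l1 <- sample(0:3, 1); l2 <- sample(0:3, 1)
    m1 <- sample(-l1:l1, 1); m2 <- sample(-l2:l2, 1)
    al <- stats::runif(1, 0.2, 2); be <- stats::runif(1, 0.2, 2)
    A <- stats::runif(3, -1, 1); B <- stats::runif(3, -1, 1)
    mom <- if (k %% 2 == 0) c(1L, 0L, 0L) else c(0L, 0L, 0L)
    blk <- shell_pair_block(gaussian_shell(l1, al, 1),
                            gaussian_shell(l2, be, 1), A, B, moment = mom)
    qd <- primitive_quadrature(l1, m1, al, A, l2, m2, be, B, moment = mom)
    err <- max(err, abs(blk[m1 + l1 + 1L, m2 + l2 + 1L] - qd))
  }
  note("integrals", err < 1e-6, sprintf("max |analytic - quadrature| = %.2e", err))

  # Wigner blocks: composition + sampled-harmonics oracle
  r1 <- random_rotation(seed + 11L); r2 <- random_rotation(seed + 12L)
  r12 <- rotor(r2$R %*% r1$R)
  werr <- 0
  for (l in 0:3) {
    werr <- max(werr, max(abs(wigner_d_real(l, r12) -
                                wigner_d_real(l, r2) %*% wigner_d_real(l, r1))))
  }
  pts <- matrix(stats::rnorm(150), ncol = 3)
  for (l in 2:3) {
    D <- wigner_d_real(l, r1)
    Dls <- t(qr.solve(solid_harmonics(l, pts),
                      solid_harmonics(l, pts %*% t(r1$R))))
    werr <- max(werr, max(abs(D - Dls)))
  }
  note("rotations", werr < 1e-9, sprintf("max Wigner deviation = %.2e", werr))

  # generator equivariance
  ts <- toy_system("water")
  rot <- random_rotation(seed + 21L)
  S0 <- overlap_matrix(ts$molecule, ts$basis)
  H0 <- hueckel_hamiltonian(ts$molecule, ts$basis, ts$params, S = S0)
  molr <- ts$molecule
  molr$positions <- molr$positions %*% t(rot$R)
  W <- wigner_ao_matrix(build_orbital_index(ts$molecule, ts$basis), rot)
  eerr <- max(abs(overlap_matrix(molr, ts$basis) - W %*% S0 %*% t(W)))
  eerr <- max(eerr, max(abs(hueckel_hamiltonian(molr, ts$basis, ts$params) -
                              W %*% H0 %*% t(W))))
  note("equivariance", eerr < 1e-8, sprintf("max block-transform residual = %.2e", eerr))

  # eigensolver contract
  res <- 0
  for (k in 1:20) {
    nn <- sample(3:8, 1)
    A <- matrix(stats::rnorm(nn^2), nn); Hr <- (A + t(A)) / 2
    Bm <- matrix(stats::rnorm(nn^2), nn)
    Sr <- crossprod(Bm) / nn + diag(nn)
    Sr <- Sr / max(diag(Sr)); diag(Sr) <- 1
    sp <- solve_orbitals(Hr, Sr, 2L)
    res <- max(res,
               max(abs(Hr %*% sp$C - Sr %*% sp$C %*% diag(sp$epsilon))),
               max(abs(t(sp$C) %*% Sr %*% sp$C - diag(nn))))
  }
  h2 <- toy_system("h2")
  hs <- hs_matrices(hueckel_surface(h2$basis, h2$params, 2L), h2$molecule)
  s12 <- hs$S[1, 2]
  closed <- sort(c(-13.6 * (1 + 1.75 * s12) / (1 + s12),
                   -13.6 * (1 - 1.75 * s12) / (1 - s12)))
  ceig <- max(abs(generalized_eigen(hs$H, hs$S, values_only = TRUE) - closed))
  note("eigensolver", res < 1e-7 && ceig < 1e-10,
       sprintf("max residual = %.2e, closed-form dev = %.2e", res, ceig))

  # Loewdin identities
  spec <- solve_orbitals(hs$H, hs$S, 2L)
  P <- density_matrix(spec)
  popl <- loewdin_analysis(P, hs$S, build_orbital_index(h2$molecule, h2$basis),
                           valence_counts(h2$params, h2$molecule))
  lerr <- max(abs(sum(popl$charges)), abs(popl$bond_orders[1, 2] - 1))
  note("loewdin", lerr < 1e-10,
       sprintf("charge-sum and H2 bond-order deviation = %.2e", lerr))

  # gradient contracts
  surf <- hueckel_surface(h2$basis, h2$params, 2L)
  g <- orbital_energy_gradient(surf, h2$molecule, 1L)
  fd <- matrix(0, 2, 3); hstep <- 1e-4
  for (a in 1:2) for (cc in 1:3) {
    mp <- h2$molecule; mp$positions[a, cc] <- mp$positions[a, cc] + hstep
    mm <- h2$molecule; mm$positions[a, cc] <- mm$positions[a, cc] - hstep
    e1 <- generalized_eigen(hueckel_hamiltonian(mp, h2$basis, h2$params),
                            overlap_matrix(mp, h2$basis), values_only = TRUE)[1]
    e2 <- generalized_eigen(hueckel_hamiltonian(mm, h2$basis, h2$params),
                            overlap_matrix(mm, h2$basis), values_only = TRUE)[1]
    fd[a, cc] <- (e1 - e2) / (2 * hstep)
  }
  gerr <- max(abs(g - fd))
  cfg <- model_config(ts$basis, B = 8L, D = 2L, T_interactions = 1L,
                      n_hidden = 8L)
  mdl <- schnorb_model(cfg, init_params(cfg, ts$basis, seed = seed), ts$basis)
  ef <- energy_forces(mdl, ts$molecule)
  fdm <- matrix(0, 3, 3)
  for (a in 1:3) for (cc in 1:3) {
    mp <- ts$molecule; mp$positions[a, cc] <- mp$positions[a, cc] + hstep
    mm <- ts$molecule; mm$positions[a, cc] <- mm$positions[a, cc] - hstep
    fdm[a, cc] <- -(model_forward(mdl, mp, "energy")$E -
                      model_forward(mdl, mm, "energy")$E) / (2 * hstep)
  }
  gerr <- max(gerr, max(abs(ef$F - fdm)))
  note("gradients", gerr < 1e-4,
       sprintf("max |analytic - finite difference| = %.2e", gerr))

  do.call(rbind, rows)
}
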