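# Properties derived from an (H, S) pair: spectra, populations, moments,
# densities of states, orbital-energy gradients.

# Generalized symmetric eigensolve via S^{-1/2}. Returns ascending values
# (and vectors unless values_only).
generalized_eigen <- function(H, S, values_only = FALSE) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) {
    stop("overlap matrix is ill-conditioned (eigenvalue < 1e-10)")
  }
  X <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  Ht <- X %*% H %*% X
  Ht <- (Ht + t(Ht)) / 2
  eh <- eigen(Ht, symmetric = TRUE)
  ord <- order(eh$values)
  eps <- eh$values[ord]
  if (values_only) return(eps)
  list(values = eps, vectors = X %*% eh$vectors[, ord, drop = FALSE])
}

# Deterministic orientation of eigenvector columns: within each numerically
# degenerate group, rotate so the submatrix at the first independent pivot
# rows is lower-triangular with positive diagonal; isolated columns get the
# sign of their largest-magnitude entry.
orient_columns <- function(C, eps, tol = 1e-8) {
  n <- ncol(C)
  grp <- cumsum(c(1, diff(eps) > tol))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    k <- length(cols)
    if (k > 1L) {
      B <- C[, cols, drop = FALSE]
      piv <- integer(0)
      for (r in seq_len(nrow(B))) {
        cand <- B[c(piv, r), , drop = FALSE]
        if (qr(cand, tol = 1e-10)$rank > length(piv)) piv <- c(piv, r)
        if (length(piv) == k) break
      }
      G <- B[piv, , drop = FALSE]
      qrq <- qr(t(G))
      Q <- qr.Q(qrq)
      B <- B %*% Q
      for (jj in seq_len(k)) if (B[piv[jj], jj] < 0) B[, jj] <- -B[, jj]
      C[, cols] <- B
    } else {
      j <- cols
      if (C[which.max(abs(C[, j])), j] < 0) C[, j] <- -C[, j]
    }
  }
  C
}

#' Solve the molecular-orbital eigenproblem
#'
#' Solves `H c_m = eps_m S c_m` by symmetric orthogonalisation
#' (`S^{-1/2}` transformation). Columns of `C` are S-orthonormal
#' (`C^T S C = I`); degenerate subspaces are returned with a deterministic
#' orientation so repeated solves are comparable.
#'
#' @param H symmetric Hamiltonian matrix (eV).
#' @param S symmetric positive-definite overlap matrix.
#' @param n_electrons even electron count (fills the lowest orbitals with
#'   occupation 2).
#' @return an object of class `slite_spectrum` with fields `epsilon`
#'   (ascending, eV), `C` (coefficients, column m), `occupation` and
#'   `n_electrons`.
#' @export
solve_orbitals <- function(H, S, n_electrons) {
  ge <- generalized_eigen(H, S)
  C <- orient_columns(ge$vectors, ge$values)
  nocc <- as.integer(n_electrons) %/% 2L
  occ <- rep(0, length(ge$values))
  occ[seq_len(min(nocc, length(occ)))] <- 2
  structure(list(epsilon = ge$values, C = C, occupation = occ,
                 n_electrons = as.integer(n_electrons)),
            class = "slite_spectrum")
}

#' @export
print.slite_spectrum <- function(x, ...) {
  cat("<slite_spectrum> ", length(x$epsilon), " orbitals, ",
      sum(x$occupation > 0), " occupied; gap = ",
      sprintf("%.4f", homo_lumo_gap(x)), " eV\n", sep = "")
  invisible(x)
}

#' Closed-shell density matrix
#'
#' `P = 2 sum_occ c_m c_m^T` from the S-orthonormal coefficients.
#'
#' @param spec a [solve_orbitals()] result.
#' @return symmetric `n_ao x n_ao` matrix.
#' @export
density_matrix <- function(spec) {
  if (spec$n_electrons %% 2L != 0L) {
    stop("density_matrix supports closed shells only (even n_electrons)")
  }
  occ <- which(spec$occupation > 0)
  if (!length(occ)) return(matrix(0, nrow(spec$C), nrow(spec$C)))
  Cocc <- spec$C[, occ, drop = FALSE]
  2 * tcrossprod(Cocc)
}

#' Loewdin population analysis
#'
#' Symmetrically orthogonalised density `P^L = S^{1/2} P S^{1/2}`; the
#' partial charge of atom i is its valence electron count minus the summed
#' diagonal of its block, and the bond order between atoms i and j is the
#' sum of squared inter-atomic elements of `P^L`.
#'
#' @param P density matrix from [density_matrix()].
#' @param S overlap matrix.
#' @param oidx orbital index from [build_orbital_index()].
#' @param n_valence numeric vector of per-atom valence electron counts.
#' @return an object of class `slite_population`: `charges` (per atom, e) and
#'   `bond_orders` (symmetric matrix, diagonal zero).
#' @export
loewdin_analysis <- function(P, S, oidx, n_valence) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) {
    stop("overlap matrix is ill-conditioned (eigenvalue < 1e-10)")
  }
  Shalf <- es$vectors %*% (t(es$vectors) * sqrt(es$values))
  PL <- Shalf %*% P %*% Shalf
  n <- length(oidx$atom_counts)
  charges <- numeric(n)
  bo <- matrix(0, n, n)
  for (a in seq_len(n)) {
    ia <- atom_orbitals(oidx, a)
    charges[a] <- n_valence[a] - sum(diag(PL)[ia])
    if (a < n) {
      for (b in (a + 1L):n) {
        ib <- atom_orbitals(oidx, b)
        bo[a, b] <- bo[b, a] <- sum(PL[ia, ib]^2)
      }
    }
  }
  structure(list(charges = charges, bond_orders = bo),
            class = "slite_population")
}

#' Electronic dipole and quadrupole moments
#'
#' `dipole = sum_i q_i (r_i - o) - Tr(P M^(1))` with nuclear charges `q_i`
#' taken as valence electron counts (consistent with the valence-only
#' generator) and analytic moment integrals `M`. The quadrupole is the plain
#' (non-traceless) second moment; set `traceless = TRUE` for the traceless
#' form.
#'
#' @param P density matrix.
#' @param S overlap matrix.
#' @param mol a [molecule()].
#' @param basis a [basis_set()].
#' @param n_valence per-atom valence electron counts (nuclear charges of the
#'   valence-only model).
#' @param origin reference point (Angstrom), default the coordinate origin.
#' @param traceless report the traceless quadrupole.
#' @return an object of class `slite_moments`: `dipole` (Debye), `quadrupole`
#'   (Debye * Angstrom, symmetric 3x3) and `origin`.
#' @export
multipole_moments <- function(P, S, mol, basis, n_valence,
                              origin = c(0, 0, 0), traceless = FALSE) {
  if (nrow(P) != nrow(S)) stop("P and S dimensions differ")
  M1 <- moment_integrals(mol, basis, 1L)
  M2 <- moment_integrals(mol, basis, 2L)
  if (nrow(M1$x) != nrow(P)) stop("moment integrals do not match the density basis")
  nel <- sum(P * S)                     # Tr(P S)
  pos <- sweep(mol$positions, 2, origin)
  dip_nuc <- colSums(n_valence * pos)
  el1 <- c(sum(P * M1$x), sum(P * M1$y), sum(P * M1$z)) - origin * nel
  dipole <- (dip_nuc - el1) * EANG_DEBYE
  comp <- list(c("x", "x"), c("x", "y"), c("x", "z"),
               c("y", "y"), c("y", "z"), c("z", "z"))
  nm2 <- c("xx", "xy", "xz", "yy", "yz", "zz")
  ax <- c(x = 1L, y = 2L, z = 3L)
  quad <- matrix(0, 3, 3)
  for (k in seq_along(comp)) {
    a <- comp[[k]][1]; b <- comp[[k]][2]
    ia <- ax[[a]]; ib <- ax[[b]]
    el <- sum(P * M2[[nm2[k]]]) - origin[ia] * sum(P * M1[[b]]) -
      origin[ib] * sum(P * M1[[a]]) + origin[ia] * origin[ib] * nel
    nuc <- sum(n_valence * pos[, ia] * pos[, ib])
    quad[ia, ib] <- quad[ib, ia] <- (nuc - el) * EANG_DEBYE
  }
  if (traceless) quad <- 1.5 * quad - 0.5 * sum(diag(quad)) * diag(3)
  structure(list(dipole = dipole, quadrupole = quad, origin = origin),
            class = "slite_moments")
}

#' Gaussian-broadened density of states
#'
#' Sum of unit-area Gaussians centered at each orbital energy, averaged over
#' frames.
#'
#' @param epsilon numeric vector of orbital energies, or a list of such
#'   vectors (one per frame).
#' @param sigma Gaussian broadening (eV, > 0).
#' @param grid energy grid (eV); default spans the levels plus `4 sigma`
#'   margins with 400 points.
#' @return a tibble of class `slite_dos` with columns `energy` and `dos`.
#' @export
dos_curve <- function(epsilon, sigma, grid = NULL) {
  if (!is.list(epsilon)) epsilon <- list(epsilon)
  if (!length(epsilon) || !length(epsilon[[1]])) stop("empty orbital-energy input")
  if (sigma <= 0) stop("sigma must be > 0")
  all_eps <- unlist(epsilon)
  if (is.null(grid)) {
    grid <- seq(min(all_eps) - 4 * sigma, max(all_eps) + 4 * sigma,
                length.out = 400L)
  }
  dos <- numeric(length(grid))
  for (fr in epsilon) {
    for (e0 in fr) {
      dos <- dos + stats::dnorm(grid, mean = e0, sd = sigma)
    }
  }
  out <- tibble::tibble(energy = grid, dos = dos / length(epsilon))
  class(out) <- c("slite_dos", class(out))
  out
}

#' HOMO-LUMO gap
#'
#' @param spec a [solve_orbitals()] result with at least one occupied and one
#'   virtual orbital.
#' @return gap in eV (>= 0).
#' @export
homo_lumo_gap <- function(spec) {
  nocc <- sum(spec$occupation > 0)
  if (nocc < 1L) stop("no occupied orbitals")
  if (nocc >= length(spec$epsilon)) stop("no virtual orbitals (all occupied)")
  spec$epsilon[nocc + 1L] - spec$epsilon[nocc]
}

# ---------------------------------------------------------------------------
# Electronic surfaces: a common interface for "things that map a geometry to
# (H, S, E, F)" — the Hueckel generator and trained models both implement it,
# so dynamics, gradients and gap optimisation run on either.

#' Hueckel generator as an electronic surface
#'
#' Wraps a basis + parameter set + electron count as a surface object
#' implementing [hs_matrices()], [hs_gradients()] and [energy_forces()].
#'
#' @param basis a [basis_set()].
#' @param params a [hueckel_params()].
#' @param n_electrons even electron count.
#' @return an object of classes `slite_hueckel_surface` and `slite_surface`.
#' @export
hueckel_surface <- function(basis, params, n_electrons) {
  structure(list(basis = basis, params = params,
                 n_electrons = as.integer(n_electrons)),
            class = c("slite_hueckel_surface", "slite_surface"))
}

#' Hamiltonian and overlap matrices of a surface at a geometry
#' @param surface a `slite_surface` object.
#' @param mol a [molecule()].
#' @return list with `H` (eV) and `S`.
#' @export
hs_matrices <- function(surface, mol) UseMethod("hs_matrices")

#' Position derivatives of H and S
#'
#' Derivatives of every matrix entry with respect to every atomic coordinate.
#'
#' @inheritParams hs_matrices
#' @return list with 4-D arrays `dH` and `dS` of shape
#'   `(n_ao, n_ao, n_atoms, 3)` in eV/Angstrom and 1/Angstrom.
#' @export
hs_gradients <- function(surface, mol) UseMethod("hs_gradients")

#' Total energy and analytic forces of a surface at a geometry
#' @inheritParams hs_matrices
#' @return list with `E` (eV) and `F` (`n x 3`, eV/Angstrom).
#' @export
energy_forces <- function(surface, mol) UseMethod("energy_forces")

#' @export
hs_matrices.slite_hueckel_surface <- function(surface, mol) {
  S <- overlap_matrix(mol, surface$basis)
  H <- hueckel_hamiltonian(mol, surface$basis, surface$params, S = S)
  list(H = H, S = S)
}

#' @export
hs_gradients.slite_hueckel_surface <- function(surface, mol) {
  # complex-step through the integral engine: exact to double precision
  oidx <- build_orbital_index(mol, surface$basis)
  h <- onsite_energies(oidx, mol, surface$params)
  hfac <- 0.5 * surface$params$K * outer(h, h, "+")
  n <- n_atoms(mol)
  nao <- oidx$n_ao
  dH <- array(0, c(nao, nao, n, 3))
  dS <- array(0, c(nao, nao, n, 3))
  eps <- 1e-20
  for (a in seq_len(n)) {
    for (c in 1:3) {
      molc <- mol
      molc$positions <- mol$positions + 0i
      molc$positions[a, c] <- molc$positions[a, c] + 1i * eps
      dSc <- Im(overlap_matrix(molc, surface$basis)) / eps
      dHc <- hfac * dSc
      diag(dHc) <- 0
      dS[, , a, c] <- dSc
      dH[, , a, c] <- dHc
    }
  }
  list(dH = dH, dS = dS)
}

#' @export
energy_forces.slite_hueckel_surface <- function(surface, mol) {
  reference_energy_forces(mol, surface$basis, surface$params,
                          surface$n_electrons)
}

#' Gradient of one orbital energy with respect to atomic positions
#'
#' First-order perturbation formula `d eps_m / dr = c_m^T (dH/dr -
#' eps_m dS/dr) c_m` with S-normalised coefficients, using the surface's
#' exact matrix derivatives. Requires `eps_m` to be separated from its
#' neighbors by more than `1e-6` eV (the gradient of a degenerate level is
#' not well-defined).
#'
#' @param surface a `slite_surface`.
#' @param mol a [molecule()].
#' @param m orbital index (1-based, ascending energy order).
#' @return `n x 3` matrix of gradients (eV/Angstrom).
#' @export
orbital_energy_gradient <- function(surface, mol, m) {
  hs <- hs_matrices(surface, mol)
  ge <- generalized_eigen(hs$H, hs$S)
  eps <- ge$values
  m <- as.integer(m)
  if (m < 1L || m > length(eps)) stop("orbital index out of range")
  sep <- min(c(if (m > 1L) eps[m] - eps[m - 1L],
               if (m < length(eps)) eps[m + 1L] - eps[m]))
  if (sep <= 1e-6) {
    stop("orbital ", m, " is degenerate (separation ", format(sep),
         " eV <= 1e-6); its gradient is ill-defined")
  }
  cm <- ge$vectors[, m]
  gr <- hs_gradients(surface, mol)
  n <- n_atoms(mol)
  out <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (c in 1:3) {
      out[a, c] <- sum(cm * ((gr$dH[, , a, c] - eps[m] * gr$dS[, , a, c]) %*% cm))
    }
  }
  out
}
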