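# Analytic one-electron integrals over contracted spherical Gaussians.
#
# Strategy: Obara-Saika 1-D recurrences over Cartesian primitive pairs (the
# 3-D integral factorises into x/y/z tables), Cartesian monomials are then
# combined through the solid-harmonic term tables, contracted over unit-
# normalised primitives and finally scaled so that every AO has unit
# self-overlap. All internal arithmetic is in atomic units (Bohr); public
# matrices carry Angstrom-based units where dimensionful.
#
# The code path is complex-analytic in the atomic positions (no abs/max on
# values), so complex-step differentiation through any integral is exact.

# 1-D Obara-Saika overlap tables S[i+1, j+1] = <x_A^i | x_B^j> for one
# primitive pair, vectorised over pairs: returns array [np, imax+1, jmax+1].
os_1d_table <- function(a, b, Ax, Bx, imax, jmax) {
  p <- a + b
  mu <- a * b / p
  Px <- (a * Ax + b * Bx) / p
  XPA <- Px - Ax
  XPB <- Px - Bx
  np <- length(a)
  S <- array(if (is.complex(Ax) || is.complex(Bx)) 0i else 0,
             dim = c(np, imax + 1L, jmax + 1L))
  S[, 1L, 1L] <- sqrt(pi / p) * exp(-mu * (Ax - Bx)^2)
  i2p <- 1 / (2 * p)
  if (imax >= 1L) {
    for (i in 1:imax) {
      term <- XPA * S[, i, 1L]
      if (i >= 2L) term <- term + (i - 1) * i2p * S[, i - 1L, 1L]
      S[, i + 1L, 1L] <- term
    }
  }
  if (jmax >= 1L) {
    for (j in 1:jmax) {
      for (i in 0:imax) {
        term <- XPB * S[, i + 1L, j]
        if (i >= 1L) term <- term + i * i2p * S[, i, j]
        if (j >= 2L) term <- term + (j - 1) * i2p * S[, i + 1L, j - 1L]
        S[, i + 1L, j + 1L] <- term
      }
    }
  }
  S
}

# <x_A^i | x^e | x_B^j> from the plain table via x = x_A + Ax (binomial shift).
os_1d_moment <- function(S, i, j, e, Ax) {
  if (e == 0L) return(S[, i + 1L, j + 1L])
  acc <- 0
  for (s in 0:e) {
    acc <- acc + choose(e, s) * Ax^(e - s) * S[, i + s + 1L, j + 1L]
  }
  acc
}

# Unit-normalisation constants for spherical primitives: <prim|prim> = 1.
# The norm is m-independent; computed from the m = -l column's term table.
prim_norm <- function(l, alpha) {
  terms <- solid_harmonic_terms[[l + 1L]]
  tt <- terms[[1L]]
  val <- 0
  # 1-D even-moment integrals int x^n exp(-2 alpha x^2) dx
  g1 <- function(n, al) {
    if (n %% 2L == 1L) return(rep(0, length(al)))
    dfact <- if (n == 0L) 1 else prod(seq(1, n - 1, by = 2))
    dfact / (4 * al)^(n / 2) * sqrt(pi / (2 * al))
  }
  for (r1 in seq_len(nrow(tt))) {
    for (r2 in seq_len(nrow(tt))) {
      val <- val + tt[r1, "c"] * tt[r2, "c"] *
        g1(tt[r1, "i"] + tt[r2, "i"], alpha) *
        g1(tt[r1, "j"] + tt[r2, "j"], alpha) *
        g1(tt[r1, "k"] + tt[r2, "k"], alpha)
    }
  }
  1 / sqrt(val)
}

# Contracted spherical block for one shell pair, optional Cartesian moment
# monomial (ex, ey, ez) measured from the coordinate origin. A, B in Bohr.
# Returns (2l1+1) x (2l2+1); contraction over unit-normalised primitives,
# no final per-shell scaling (the callers apply it).
shell_pair_block <- function(sh1, sh2, A, B, moment = c(0L, 0L, 0L)) {
  l1 <- sh1$l; l2 <- sh2$l
  n1 <- length(sh1$exponents); n2 <- length(sh2$exponents)
  a <- rep(sh1$exponents, times = n2)
  b <- rep(sh2$exponents, each = n1)
  w <- rep(sh1$coefficients * sh1$prim_norms, times = n2) *
    rep(sh2$coefficients * sh2$prim_norms, each = n1)
  Sx <- os_1d_table(a, b, A[1], B[1], l1 + moment[1], l2)
  Sy <- os_1d_table(a, b, A[2], B[2], l1 + moment[2], l2)
  Sz <- os_1d_table(a, b, A[3], B[3], l1 + moment[3], l2)
  t1 <- solid_harmonic_terms[[l1 + 1L]]
  t2 <- solid_harmonic_terms[[l2 + 1L]]
  cplx <- is.complex(A) || is.complex(B)
  out <- matrix(if (cplx) 0i else 0, 2L * l1 + 1L, 2L * l2 + 1L)
  for (m1 in seq_along(t1)) {
    tt1 <- t1[[m1]]
    for (m2 in seq_along(t2)) {
      tt2 <- t2[[m2]]
      acc <- 0
      for (r1 in seq_len(nrow(tt1))) {
        for (r2 in seq_len(nrow(tt2))) {
          vx <- os_1d_moment(Sx, tt1[r1, "i"], tt2[r2, "i"], moment[1], A[1])
          vy <- os_1d_moment(Sy, tt1[r1, "j"], tt2[r2, "j"], moment[2], A[2])
          vz <- os_1d_moment(Sz, tt1[r1, "k"], tt2[r2, "k"], moment[3], A[3])
          acc <- acc + tt1[r1, "c"] * tt2[r2, "c"] * sum(w * vx * vy * vz)
        }
      }
      out[m1, m2] <- acc
    }
  }
  out
}

# Iterate over shell-pair blocks of a molecule, calling
# fun(rows, cols, sh1, sh2, A_bohr, B_bohr, f1, f2) for every ordered pair of
# shells with atom1 <= atom2 (the caller mirrors).
with_shell_pairs <- function(mol, basis, fun, oidx = NULL) {
  n <- n_atoms(mol)
  pos <- mol$positions / BOHR_ANGSTROM
  zs <- mol$atomic_numbers
  if (is.null(oidx)) oidx <- build_orbital_index(mol, basis)
  for (a1 in seq_len(n)) {
    sh1l <- basis_shells(basis, zs[a1])
    f1v <- vapply(sh1l, function(s) s$norm_factor, numeric(1))
    row0 <- oidx$atom_offsets[a1]
    for (a2 in a1:n) {
      sh2l <- basis_shells(basis, zs[a2])
      f2v <- vapply(sh2l, function(s) s$norm_factor, numeric(1))
      col0 <- oidx$atom_offsets[a2]
      r <- row0
      for (s1 in seq_along(sh1l)) {
        d1 <- 2L * sh1l[[s1]]$l + 1L
        cc <- col0
        for (s2 in seq_along(sh2l)) {
          d2 <- 2L * sh2l[[s2]]$l + 1L
          if (a1 < a2 || s2 >= s1) {
            fun(r + seq_len(d1), cc + seq_len(d2), sh1l[[s1]], sh2l[[s2]],
                pos[a1, ], pos[a2, ], f1v[s1], f2v[s2])
          }
          cc <- cc + d2
        }
        r <- r + d1
      }
    }
  }
  oidx
}

#' Analytic overlap matrix
#'
#' Overlap of all contracted spherical Gaussian AOs, computed by Obara-Saika
#' recursion over Cartesian primitives followed by the solid-harmonic
#' transformation. AOs are normalised, so the diagonal is exactly 1.
#'
#' @param mol a [molecule()] (positions in Angstrom).
#' @param basis a [basis_set()].
#' @param check_condition flag near-linear-dependence (smallest eigenvalue
#'   below `1e-8`) via attribute `conditioning_warning`; disable in hot loops.
#' @param oidx optional precomputed [build_orbital_index()].
#' @return symmetric positive-definite `n_ao x n_ao` matrix with unit
#'   diagonal. If the smallest eigenvalue falls below `1e-8` the result
#'   carries attribute `conditioning_warning = TRUE`.
#' @export
overlap_matrix <- function(mol, basis, check_condition = TRUE, oidx = NULL) {
  cplx <- is.complex(mol$positions)
  if (is.null(oidx)) oidx <- build_orbital_index(mol, basis)
  plan <- overlap_plan(mol, basis)
  n <- n_atoms(mol)
  posb <- matrix(as.complex(mol$positions / BOHR_ANGSTROM), n, 3)
  S <- .overlap_kernel(posb, plan$shell_atom, plan$shell_l, plan$shell_off,
                       plan$prim_start, plan$prim_count, plan$prim_exp,
                       plan$prim_wcoef, plan$shell_norm, oidx$n_ao)
  if (!cplx) {
    S <- Re(S)
    S <- (S + t(S)) / 2
    if (check_condition) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8) attr(S, "conditioning_warning") <- TRUE
    }
  }
  S
}

# Flat shell description consumed by the compiled kernel.
overlap_plan <- function(mol, basis) {
  shell_atom <- integer(0); shell_l <- integer(0); shell_off <- integer(0)
  prim_start <- integer(0); prim_count <- integer(0)
  prim_exp <- numeric(0); prim_wcoef <- numeric(0); shell_norm <- numeric(0)
  off <- 0L
  for (a in seq_len(n_atoms(mol))) {
    for (sh in basis_shells(basis, mol$atomic_numbers[a])) {
      shell_atom <- c(shell_atom, a)
      shell_l <- c(shell_l, sh$l)
      shell_off <- c(shell_off, off)
      prim_start <- c(prim_start, length(prim_exp))
      prim_count <- c(prim_count, length(sh$exponents))
      prim_exp <- c(prim_exp, sh$exponents)
      prim_wcoef <- c(prim_wcoef, sh$coefficients * sh$prim_norms)
      shell_norm <- c(shell_norm, sh$norm_factor)
      off <- off + 2L * sh$l + 1L
    }
  }
  list(shell_atom = shell_atom, shell_l = shell_l, shell_off = shell_off,
       prim_start = prim_start, prim_count = prim_count, prim_exp = prim_exp,
       prim_wcoef = prim_wcoef, shell_norm = shell_norm)
}

# Pure-R overlap via the same Obara-Saika path as the moment integrals;
# retained as an independent cross-check of the compiled kernel.
overlap_matrix_r <- function(mol, basis) {
  cplx <- is.complex(mol$positions)
  oidx <- build_orbital_index(mol, basis)
  S <- matrix(if (cplx) 0i else 0, oidx$n_ao, oidx$n_ao)
  with_shell_pairs(mol, basis, function(rows, cols, sh1, sh2, A, B, f1, f2) {
    blk <- f1 * f2 * shell_pair_block(sh1, sh2, A, B)
    S[rows, cols] <<- blk
    S[cols, rows] <<- t(blk)
  }, oidx = oidx)
  if (!cplx) S <- (S + t(S)) / 2
  S
}

#' Analytic multipole-moment integrals
#'
#' Matrices of `<phi_mu | x^e | phi_nu>` for the Cartesian monomials of the
#' requested order, origin at the coordinate origin, in Angstrom^order.
#'
#' @param mol a [molecule()].
#' @param basis a [basis_set()].
#' @param order 1 (components x, y, z) or 2 (xx, xy, xz, yy, yz, zz).
#' @return named list of symmetric `n_ao x n_ao` matrices.
#' @export
moment_integrals <- function(mol, basis, order = 1L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  comps <- if (order == 1L) {
    list(x = c(1L, 0L, 0L), y = c(0L, 1L, 0L), z = c(0L, 0L, 1L))
  } else {
    list(xx = c(2L, 0L, 0L), xy = c(1L, 1L, 0L), xz = c(1L, 0L, 1L),
         yy = c(0L, 2L, 0L), yz = c(0L, 1L, 1L), zz = c(0L, 0L, 2L))
  }
  oidx <- build_orbital_index(mol, basis)
  mats <- lapply(comps, function(cm) matrix(0, oidx$n_ao, oidx$n_ao))
  with_shell_pairs(mol, basis, function(rows, cols, sh1, sh2, A, B, f1, f2) {
    for (nm in names(comps)) {
      blk <- f1 * f2 * shell_pair_block(sh1, sh2, A, B, moment = comps[[nm]])
      mats[[nm]][rows, cols] <<- blk
      mats[[nm]][cols, rows] <<- t(blk)
    }
  }, oidx = oidx)
  scale <- BOHR_ANGSTROM^order
  lapply(mats, function(m) scale * (m + t(m)) / 2)
}

#' Numerical quadrature oracle for primitive integrals
#'
#' Independent check of the analytic integrals: evaluates
#' `<prim1 | x^e | prim2>` for two unit-normalised spherical Gaussian
#' primitives by tensor-product Gauss-Hermite quadrature over the Gaussian
#' product, which is exact for the polynomial prefactors involved.
#'
#' @param l1,m1,alpha,A angular momentum, magnetic index, exponent (Bohr^-2)
#'   and center (Bohr) of the bra primitive.
#' @param l2,m2,beta,B the same for the ket primitive.
#' @param moment integer Cartesian powers `c(ex, ey, ez)` of the operator.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @return the integral (Bohr^order units).
#' @export
primitive_quadrature <- function(l1, m1, alpha, A, l2, m2, beta, B,
                                 moment = c(0L, 0L, 0L), n_nodes = 14L) {
  gh <- pracma::gaussHermite(n_nodes)
  p <- alpha + beta
  P <- (alpha * A + beta * B) / p
  pref <- exp(-alpha * beta / p * sum((A - B)^2))
  # grid: r = P + u / sqrt(p), weight e^{-u^2} absorbed by GH
  g <- expand.grid(ix = seq_len(n_nodes), iy = seq_len(n_nodes),
                   iz = seq_len(n_nodes))
  pts <- cbind(P[1] + gh$x[g$ix] / sqrt(p),
               P[2] + gh$x[g$iy] / sqrt(p),
               P[3] + gh$x[g$iz] / sqrt(p))
  wts <- gh$w[g$ix] * gh$w[g$iy] * gh$w[g$iz] / p^1.5
  y1 <- solid_harmonics(l1, sweep(pts, 2, A))[, m1 + l1 + 1L]
  y2 <- solid_harmonics(l2, sweep(pts, 2, B))[, m2 + l2 + 1L]
  op <- pts[, 1]^moment[1] * pts[, 2]^moment[2] * pts[, 3]^moment[3]
  n1 <- prim_norm(l1, alpha); n2 <- prim_norm(l2, beta)
  n1 * n2 * pref * sum(wts * y1 * y2 * op)
}
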