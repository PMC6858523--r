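# Proper rotations and Wigner-D matrices for real spherical harmonics.

#' Haar-uniform random rotation
#'
#' Samples a proper rotation matrix uniformly over SO(3) by normalising a
#' 4-vector of seeded standard Gaussian draws to a unit quaternion. The
#' global RNG state is left untouched.
#'
#' @param seed integer seed; the same seed always yields the same rotor.
#' @return an object of class `slite_rotor` wrapping the 3x3 matrix `R`.
#' @export
random_rotation <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  rotor(quaternion_matrix(q))
}

quaternion_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Wrap a 3x3 proper rotation matrix
#' @param R orthogonal 3x3 matrix with determinant +1.
#' @return an object of class `slite_rotor`.
#' @export
rotor <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) stop("R must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10) {
    stop("R must be a proper rotation (orthogonal, det = +1)")
  }
  structure(list(R = R), class = "slite_rotor")
}

#' @export
print.slite_rotor <- function(x, ...) {
  cat("<slite_rotor>\n"); print(x$R); invisible(x)
}

#' Real Wigner-D matrix
#'
#' Rotation matrix `D^(l)(R)` acting on real spherical harmonics, ordered
#' m = -l..+l, such that `Y_lm(R r) = sum_m' D[m, m'] Y_lm'(r)`. Computed by
#' the Ivanic-Ruedenberg real-harmonic recursion (no complex intermediates).
#'
#' @param l angular momentum, 0..3.
#' @param rot a [rotor()].
#' @return orthogonal `(2l+1) x (2l+1)` matrix.
#' @export
wigner_d_real <- function(l, rot) {
  if (!inherits(rot, "slite_rotor")) rot <- rotor(rot)
  if (l < 0L || l > 3L) stop("unsupported angular momentum: l must be in 0..3")
  wigner_blocks(l, rot)[[l + 1L]]
}

#' All Wigner-D blocks up to a maximum angular momentum
#' @param lmax maximum l (0..3).
#' @param rot a [rotor()].
#' @return list of matrices `D^(0)..D^(lmax)` (index l + 1).
#' @export
wigner_blocks <- function(lmax, rot) {
  if (!inherits(rot, "slite_rotor")) rot <- rotor(rot)
  R <- rot$R
  # D^(1) in real-harmonic (y, z, x) ordering: permutation of Cartesian axes
  pm <- c(2L, 3L, 1L)   # m = -1, 0, 1  ->  y, z, x
  D1 <- R[pm, pm]
  out <- list(matrix(1, 1, 1))
  if (lmax >= 1L) out[[2L]] <- D1
  if (lmax >= 2L) {
    r <- function(i, j) D1[i + 2L, j + 2L]   # indices -1..1
    for (l in 2L:max(2L, lmax)) {
      if (l > lmax) break
      Mprev <- out[[l]]                       # D^(l-1), indices -(l-1)..(l-1)
      Mp <- function(a, b) Mprev[a + l, b + l]
      P <- function(i, a, b) {
        if (abs(b) < l) {
          r(i, 0) * Mp(a, b)
        } else if (b == l) {
          r(i, 1) * Mp(a, l - 1L) - r(i, -1) * Mp(a, -(l - 1L))
        } else {
          r(i, 1) * Mp(a, -(l - 1L)) + r(i, -1) * Mp(a, l - 1L)
        }
      }
      D <- matrix(0, 2L * l + 1L, 2L * l + 1L)
      for (m in -l:l) {
        for (mp in -l:l) {
          denom <- if (abs(mp) < l) (l + mp) * (l - mp) else (2 * l) * (2 * l - 1)
          dm0 <- as.numeric(m == 0L)
          u <- sqrt((l + m) * (l - m) / denom)
          v <- 0.5 * sqrt((1 + dm0) * (l + abs(m) - 1) * (l + abs(m)) / denom) *
            (1 - 2 * dm0)
          w <- -0.5 * sqrt((l - abs(m) - 1) * (l - abs(m)) / denom) * (1 - dm0)
          val <- 0
          if (u != 0) val <- val + u * P(0, m, mp)
          if (v != 0) {
            V <- if (m == 0L) {
              P(1, 1L, mp) + P(-1, -1L, mp)
            } else if (m > 0L) {
              P(1, m - 1L, mp) * sqrt(1 + as.numeric(m == 1L)) -
                P(-1, -m + 1L, mp) * (1 - as.numeric(m == 1L))
            } else {
              P(1, m + 1L, mp) * (1 - as.numeric(m == -1L)) +
                P(-1, -m - 1L, mp) * sqrt(1 + as.numeric(m == -1L))
            }
            val <- val + v * V
          }
          if (w != 0) {
            W <- if (m > 0L) {
              P(1, m + 1L, mp) + P(-1, -m - 1L, mp)
            } else {
              P(1, m - 1L, mp) - P(-1, -m + 1L, mp)
            }
            val <- val + w * W
          }
          D[m + l + 1L, mp + l + 1L] <- val
        }
      }
      out[[l + 1L]] <- D
    }
  }
  out
}

# Block-diagonal AO rotation matrix: one D^(l) block per (atom, shell).
wigner_ao_matrix <- function(oidx, rot) {
  lab <- oidx$orbital_labels
  lmax <- max(lab$l)
  blocks <- wigner_blocks(lmax, rot)
  W <- matrix(0, oidx$n_ao, oidx$n_ao)
  start <- 1L
  while (start <= oidx$n_ao) {
    l <- lab$l[start]
    idx <- start:(start + 2L * l)
    W[idx, idx] <- blocks[[l + 1L]]
    start <- start + 2L * l + 1L
  }
  W
}

#' Rotate an electronic record
#'
#' Applies a rigid rotation consistently to all parts of a record: positions
#' and forces rotate as vectors, every shell-pair block of H and S transforms
#' as `D^(l_mu) M D^(l_nu)^T`, and the total energy is unchanged. This is the
#' data-augmentation transform used during training.
#'
#' @param rec an [electronic_record()].
#' @param rot a [rotor()].
#' @param basis the [basis_set()] the record's matrices are expressed in.
#' @return the rotated [electronic_record()].
#' @export
rotate_record <- function(rec, rot, basis) {
  if (!inherits(rot, "slite_rotor")) rot <- rotor(rot)
  oidx <- build_orbital_index(rec$molecule, basis)
  if (oidx$n_ao != nrow(rec$H)) {
    stop("record matrices (", nrow(rec$H), ") do not match basis dimension (",
         oidx$n_ao, ")")
  }
  W <- wigner_ao_matrix(oidx, rot)
  mol <- rec$molecule
  mol$positions <- mol$positions %*% t(rot$R)
  electronic_record(
    molecule = mol,
    H = W %*% rec$H %*% t(W),
    S = W %*% rec$S %*% t(W),
    E = rec$E,
    F = rec$F %*% t(rot$R),
    n_electrons = rec$n_electrons
  )
}
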