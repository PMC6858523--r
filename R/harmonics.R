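# Real solid harmonics up to l = 3, as monomial term tables.
#
# Convention: Racah-style real solid harmonics without Condon-Shortley phase,
# m ordered -l..+l (so l = 1 is (y, z, x)). Each entry is a matrix with
# columns (i, j, k, c) meaning c * x^i y^j z^k. All m within one l carry the
# same spherical norm, which keeps per-shell AO normalisation m-independent
# and Wigner blocks orthogonal.

solid_harmonic_terms <- local({
  s3 <- sqrt(3); s15 <- sqrt(15); s58 <- sqrt(5 / 8); s38 <- sqrt(3 / 8)
  tl <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    colnames(m) <- c("i", "j", "k", "c")
    m
  }
  list(
    # l = 0
    list(tl(0, 0, 0, 1)),
    # l = 1: y, z, x
    list(tl(0, 1, 0, 1), tl(0, 0, 1, 1), tl(1, 0, 0, 1)),
    # l = 2
    list(
      tl(1, 1, 0, s3),                                   # m = -2: sqrt(3) xy
      tl(0, 1, 1, s3),                                   # m = -1: sqrt(3) yz
      tl(0, 0, 2, 1, 2, 0, 0, -0.5, 0, 2, 0, -0.5),      # m =  0: z^2 - (x^2+y^2)/2
      tl(1, 0, 1, s3),                                   # m = +1: sqrt(3) xz
      tl(2, 0, 0, s3 / 2, 0, 2, 0, -s3 / 2)              # m = +2: sqrt(3)/2 (x^2-y^2)
    ),
    # l = 3
    list(
      tl(2, 1, 0, 3 * s58, 0, 3, 0, -s58),               # m = -3
      tl(1, 1, 1, s15),                                  # m = -2
      tl(0, 1, 2, 4 * s38, 2, 1, 0, -s38, 0, 3, 0, -s38),# m = -1
      tl(0, 0, 3, 1, 2, 0, 1, -1.5, 0, 2, 1, -1.5),      # m =  0
      tl(1, 0, 2, 4 * s38, 3, 0, 0, -s38, 1, 2, 0, -s38),# m = +1
      tl(2, 0, 1, s15 / 2, 0, 2, 1, -s15 / 2),           # m = +2
      tl(3, 0, 0, s58, 1, 2, 0, -3 * s58)                # m = +3
    )
  )
})

#' Evaluate real solid harmonics at Cartesian points
#'
#' Computes the homogeneous degree-`l` real solid harmonics (m = -l..+l,
#' Racah-style normalisation, no Condon-Shortley phase) at each row of `xyz`.
#' On the unit sphere these coincide with real spherical harmonics up to the
#' common factor `sqrt((2l+1)/(4 pi))`.
#'
#' @param l angular momentum, 0..3.
#' @param xyz numeric `n x 3` matrix of points.
#' @return numeric `n x (2l+1)` matrix, columns ordered m = -l..+l.
#' @export
solid_harmonics <- function(l, xyz) {
  if (l < 0L || l > 3L) stop("angular momentum l must be in 0..3")
  xyz <- matrix(xyz, ncol = 3)
  terms <- solid_harmonic_terms[[l + 1L]]
  out <- matrix(0, nrow(xyz), 2L * l + 1L)
  for (mi in seq_along(terms)) {
    tt <- terms[[mi]]
    acc <- 0
    for (r in seq_len(nrow(tt))) {
      acc <- acc + tt[r, "c"] * xyz[, 1]^tt[r, "i"] * xyz[, 2]^tt[r, "j"] *
        xyz[, 3]^tt[r, "k"]
    }
    out[, mi] <- acc
  }
  out
}
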