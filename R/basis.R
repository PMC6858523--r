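#' Contracted Gaussian shell
#'
#' One shell of spherical (real solid-harmonic) contracted Gaussians: angular
#' momentum `l` (0 = s ... 3 = f), primitive exponents in Bohr^-2 and
#' contraction coefficients applied to unit-normalised primitives. A shell
#' contributes `2l + 1` atomic orbitals with magnetic index m = -l ... +l.
#'
#' @param l angular momentum, integer 0..3.
#' @param exponents strictly positive primitive exponents (Bohr^-2).
#' @param coefficients contraction coefficients, same length as `exponents`.
#' @return an object of class `slite_shell`.
#' @export
gaussian_shell <- function(l, exponents, coefficients) {
  l <- as.integer(l)
  if (l < 0L || l > 3L) stop("angular momentum l must be in 0..3")
  exponents <- as.numeric(exponents)
  coefficients <- as.numeric(coefficients)
  if (!length(exponents) || length(exponents) != length(coefficients)) {
    stop("exponents and coefficients must have equal, positive length")
  }
  if (any(exponents <= 0)) stop("exponents must be strictly positive")
  # Unit norms of the spherical primitives and the contracted-shell
  # normalisation factor (same-center same-l primitive overlap has the
  # closed form (2 sqrt(ab)/(a+b))^(l + 3/2)).
  pn <- prim_norm(l, exponents)
  ssmat <- outer(exponents, exponents, function(a, b) {
    (2 * sqrt(a * b) / (a + b))^(l + 1.5)
  })
  self <- as.numeric(t(coefficients) %*% ssmat %*% coefficients)
  structure(list(l = l, exponents = exponents, coefficients = coefficients,
                 prim_norms = pn, norm_factor = 1 / sqrt(self)),
            class = "slite_shell")
}

#' Basis set: ordered shells per element
#'
#' @param shells named list, element symbol or nuclear charge -> list of
#'   [gaussian_shell()] objects in a fixed order.
#' @param name identifier string.
#' @return an object of class `slite_basis`; shells are keyed by nuclear charge.
#' @export
basis_set <- function(shells, name = "custom") {
  if (!length(shells) || is.null(names(shells))) {
    stop("shells must be a named list keyed by element")
  }
  keys <- names(shells)
  z <- suppressWarnings(as.integer(keys))
  z[is.na(z)] <- symbol_to_z(keys[is.na(z)])
  out <- stats::setNames(shells, as.character(z))
  for (el in out) {
    if (!length(el) || !all(vapply(el, inherits, TRUE, "slite_shell"))) {
      stop("each element entry must be a non-empty list of gaussian_shell objects")
    }
  }
  structure(list(shells = out, name = as.character(name)[1]), class = "slite_basis")
}

basis_shells <- function(basis, z) {
  sh <- basis$shells[[as.character(z)]]
  if (is.null(sh)) {
    stop("basis '", basis$name, "' has no entry for element Z = ", z,
         " (", z_to_symbol(z), ")")
  }
  sh
}

#' Number of atomic orbitals an element contributes
#' @param basis a [basis_set()].
#' @param z nuclear charge.
#' @return integer, sum of `2l + 1` over the element's shells.
#' @export
n_ao_element <- function(basis, z) {
  sum(vapply(basis_shells(basis, z), function(s) 2L * s$l + 1L, integer(1)))
}

#' Deterministic atomic-orbital indexing for a molecule
#'
#' Orbitals are ordered atom-major, then by the shell order listed in the
#' basis, then by magnetic index m = -l ... +l. The index is the contract
#' between matrices (H, S, density) and the atoms/shells that generated them.
#'
#' @param mol a [molecule()].
#' @param basis a [basis_set()] covering every element in `mol`.
#' @return an object of class `slite_orbindex` with `atom_offsets` (0-based
#'   starting row per atom), `atom_counts`, `n_ao` (total dimension) and
#'   `orbital_labels`, parallel vectors atom, shell, l, m per global orbital.
#' @export
build_orbital_index <- function(mol, basis) {
  n <- n_atoms(mol)
  counts <- integer(n)
  atom <- integer(0); shell <- integer(0); lv <- integer(0); mv <- integer(0)
  for (a in seq_len(n)) {
    shl <- basis_shells(basis, mol$atomic_numbers[a])
    for (s in seq_along(shl)) {
      l <- shl[[s]]$l
      ms <- seq.int(-l, l)
      atom <- c(atom, rep.int(a, 2L * l + 1L))
      shell <- c(shell, rep.int(s, 2L * l + 1L))
      lv <- c(lv, rep.int(l, 2L * l + 1L))
      mv <- c(mv, ms)
    }
    counts[a] <- sum(vapply(shl, function(s) 2L * s$l + 1L, integer(1)))
  }
  offsets <- cumsum(c(0L, counts[-n]))
  structure(
    list(atom_offsets = as.integer(offsets), atom_counts = counts,
         n_ao = sum(counts),
         orbital_labels = list(atom = atom, shell = shell, l = lv, m = mv)),
    class = "slite_orbindex"
  )
}

# 1-based orbital rows belonging to atom a.
atom_orbitals <- function(oidx, a) {
  seq.int(oidx$atom_offsets[a] + 1L, oidx$atom_offsets[a] + oidx$atom_counts[a])
}

#' Read a basis set from JSON
#'
#' Format: `{"name": "...", "elements": {"8": [{"l": 0, "exp": [...], "coef":
#' [...]}, ...], ...}}`. Element keys may be symbols or nuclear charges.
#'
#' @param path path to a JSON basis file.
#' @return a [basis_set()].
#' @export
read_basis <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$elements)) stop("basis JSON must contain an 'elements' map")
  shells <- lapply(raw$elements, function(el) {
    lapply(el, function(s) {
      gaussian_shell(s$l, unlist(s$exp), unlist(s$coef))
    })
  })
  basis_set(shells, name = if (is.null(raw$name)) "unnamed" else raw$name)
}

#' Write a basis set to JSON
#' @param basis a [basis_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  elements <- lapply(basis$shells, function(el) {
    lapply(el, function(s) list(l = s$l, exp = s$exponents, coef = s$coefficients))
  })
  jsonlite::write_json(list(name = basis$name, elements = elements), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
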