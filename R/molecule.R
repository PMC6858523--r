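#' Create a molecule
#'
#' A molecule is the geometric input to everything in the package: a vector of
#' nuclear charges and an `n x 3` matrix of Cartesian positions in Angstrom.
#'
#' @param atomic_numbers integer vector of nuclear charges (>= 1), or element
#'   symbols which are resolved to nuclear charges.
#' @param positions numeric `n x 3` matrix of Cartesian coordinates (Angstrom).
#' @param comment free-text comment carried through file round trips.
#' @return An object of class `slite_molecule` with fields `atomic_numbers`,
#'   `positions` and `comment`.
#' @examples
#' mol <- molecule(c("O", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.9584, 0, 0), c(-0.2392, 0.9281, 0)))
#' n_atoms(mol)
#' @export
molecule <- function(atomic_numbers, positions, comment = "") {
  if (is.character(atomic_numbers)) atomic_numbers <- symbol_to_z(atomic_numbers)
  atomic_numbers <- as.integer(atomic_numbers)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L) {
    stop("positions must be an n x 3 numeric matrix")
  }
  if (length(atomic_numbers) != nrow(positions)) {
    stop("length(atomic_numbers) must equal nrow(positions)")
  }
  if (any(atomic_numbers < 1L)) stop("atomic numbers must be >= 1")
  if (nrow(positions) > 1L) {
    d <- as.matrix(stats::dist(positions))
    if (min(d[upper.tri(d)]) <= 0) stop("distinct atoms must not coincide")
  }
  dimnames(positions) <- NULL
  structure(
    list(atomic_numbers = atomic_numbers, positions = positions,
         comment = as.character(comment)[1]),
    class = "slite_molecule"
  )
}

#' @export
print.slite_molecule <- function(x, ...) {
  cat("<slite_molecule> ", n_atoms(x), " atoms: ",
      paste(z_to_symbol(x$atomic_numbers), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `slite_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$atomic_numbers)

#' Read molecules from a multi-frame XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom; multiple frames may be concatenated.
#'
#' @param path path to an XYZ file.
#' @return a list of [molecule()] objects, one per frame.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  mols <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("XYZ parse error at line ", i, ": malformed atom-count line")
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error at line ", i, ": truncated frame (expected ", n, " atoms)")
    }
    comment <- lines[i + 1L]
    syms <- character(n)
    pos <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L) {
        stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
      syms[k] <- tok[1]
      pos[k, ] <- xyz
    }
    mols[[length(mols) + 1L]] <- molecule(syms, pos, comment)
    i <- i + 2L + n
  }
  if (!length(mols)) stop("XYZ parse error: file contains no frames")
  mols
}

#' Write molecules to a multi-frame XYZ file
#' @param mols a [molecule()] or list of molecules.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mols, path) {
  if (inherits(mols, "slite_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    writeLines(as.character(n_atoms(mol)), con)
    writeLines(mol$comment, con)
    sym <- z_to_symbol(mol$atomic_numbers)
    for (k in seq_len(n_atoms(mol))) {
      writeLines(sprintf("%s %.10f %.10f %.10f", sym[k],
                         mol$positions[k, 1], mol$positions[k, 2],
                         mol$positions[k, 3]), con)
    }
  }
  invisible(path)
}

#' Enumerate ordered neighbor pairs within a cutoff
#'
#' Returns both `(i, j)` and `(j, i)` for every distinct pair with
#' interatomic distance strictly below `r_c`; `r_ij` points from atom `i`
#' to atom `j`.
#'
#' @param mol a [molecule()].
#' @param r_c cutoff radius in Angstrom (> 0).
#' @return a list with integer vectors `i`, `j`, matrix `r_ij` (`p x 3`) and
#'   vector `dist`; zero-length fields when no pair is inside the cutoff.
#' @export
neighbor_pairs <- function(mol, r_c) {
  if (r_c <= 0) stop("r_c must be > 0")
  n <- n_atoms(mol)
  pos <- mol$positions
  ii <- integer(0); jj <- integer(0)
  if (n > 1L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dvec <- pos[idx[, 2], , drop = FALSE] - pos[idx[, 1], , drop = FALSE]
    dd <- sqrt(rowSums(dvec^2))
    keep <- dd < r_c
    ii <- c(idx[keep, 1], idx[keep, 2])
    jj <- c(idx[keep, 2], idx[keep, 1])
  }
  rij <- pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE]
  list(i = as.integer(ii), j = as.integer(jj), r_ij = rij,
       dist = sqrt(rowSums(rij^2)))
}
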