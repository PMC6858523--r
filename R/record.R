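#' Electronic-structure record
#'
#' One training sample: a geometry with its Hamiltonian and overlap matrices,
#' total energy and atomic forces. Units: H and E in eV, S dimensionless,
#' F in eV/Angstrom, positions in Angstrom.
#'
#' @param molecule a [molecule()].
#' @param H symmetric `n_ao x n_ao` Hamiltonian matrix (eV).
#' @param S symmetric positive-definite overlap matrix with unit diagonal.
#' @param E total energy (eV).
#' @param F `n x 3` matrix of atomic forces (eV/Angstrom).
#' @param n_electrons even electron count.
#' @param validate check the record invariants (symmetry, unit diagonal of S,
#'   positive definiteness, near-zero force sum).
#' @return an object of class `slite_record`.
#' @export
electronic_record <- function(molecule, H, S, E, F, n_electrons,
                              validate = TRUE) {
  H <- as.matrix(H); S <- as.matrix(S); F <- as.matrix(F)
  n_electrons <- as.integer(n_electrons)
  if (validate) {
    scl <- max(abs(H), 1)
    if (max(abs(H - t(H))) > 1e-10 * scl) stop("H must be symmetric")
    if (max(abs(S - t(S))) > 1e-10) stop("S must be symmetric")
    if (max(abs(diag(S) - 1)) > 1e-10) stop("S must have unit diagonal")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("S must be positive definite")
    }
    if (n_electrons %% 2L != 0L) stop("n_electrons must be even (closed shell)")
    if (max(abs(colSums(F))) > 1e-4) {
      stop("force components must sum to ~0 (<= 1e-4 eV/Angstrom)")
    }
  }
  structure(list(molecule = molecule, H = H, S = S, E = as.numeric(E), F = F,
                 n_electrons = n_electrons),
            class = "slite_record")
}

#' @export
print.slite_record <- function(x, ...) {
  cat("<slite_record> ", n_atoms(x$molecule), " atoms, ", nrow(x$H),
      " AOs, E = ", sprintf("%.6f", x$E), " eV, ", x$n_electrons,
      " electrons\n", sep = "")
  invisible(x)
}

#' Write a dataset of electronic records to a JSON container
#'
#' Plain-text container with the groups `positions`, `atomic_numbers`,
#' `hamiltonian`, `overlap`, `energy`, `forces` and a `meta` block (basis
#' name, units, generator parameters, seed). Doubles are serialised at full
#' precision, so a read-back is elementwise identical.
#'
#' @param records list of [electronic_record()] objects sharing one basis.
#' @param path output path.
#' @param basis the [basis_set()] the records refer to.
#' @param meta named list of extra metadata (generator parameters, seed, ...).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path, basis, meta = list()) {
  if (!length(records)) stop("cannot write an empty dataset")
  payload <- list(
    meta = c(list(format = "schnorblite-dataset", version = 1L,
                  basis = basis$name,
                  units = list(positions = "Angstrom", hamiltonian = "eV",
                               energy = "eV", forces = "eV/Angstrom")),
             meta),
    atomic_numbers = lapply(records, function(r) r$molecule$atomic_numbers),
    positions = lapply(records, function(r) r$molecule$positions),
    hamiltonian = lapply(records, function(r) r$H),
    overlap = lapply(records, function(r) r$S),
    energy = vapply(records, function(r) r$E, numeric(1)),
    forces = lapply(records, function(r) r$F),
    n_electrons = vapply(records, function(r) r$n_electrons, integer(1))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a dataset of electronic records
#' @param path path written by [write_dataset()].
#' @return list with elements `records` (list of [electronic_record()]) and
#'   `meta` (named list).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  req <- c("positions", "atomic_numbers", "hamiltonian", "overlap",
           "energy", "forces", "n_electrons", "meta")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("dataset format error: missing group(s) ", paste(missing, collapse = ", "))
  }
  nrec <- length(raw$energy)
  lens <- c(length(raw$positions), length(raw$atomic_numbers),
            length(raw$hamiltonian), length(raw$overlap), length(raw$forces),
            length(raw$n_electrons))
  if (any(lens != nrec)) stop("dataset format error: group lengths differ")
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r) {
    as.numeric(unlist(r))
  }))
  records <- lapply(seq_len(nrec), function(k) {
    electronic_record(
      molecule = molecule(unlist(raw$atomic_numbers[[k]]),
                          as_mat(raw$positions[[k]])),
      H = as_mat(raw$hamiltonian[[k]]), S = as_mat(raw$overlap[[k]]),
      E = raw$energy[[k]], F = as_mat(raw$forces[[k]]),
      n_electrons = raw$n_electrons[[k]], validate = FALSE
    )
  })
  list(records = records, meta = lapply(raw$meta, function(m) {
    if (is.list(m)) lapply(m, unlist) else m
  }))
}
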