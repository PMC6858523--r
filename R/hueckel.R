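# Extended-Hueckel-style synthetic reference surface.
#
# The generator plays the role of an electronic-structure code: it produces
# (H, S, E, F) records that are smooth in the geometry, exactly rotation-
# covariant block-wise, and have a non-trivial spectrum, without any SCF.

#' Parameters of the extended-Hueckel reference model
#'
#' @param h named list: element (symbol or Z) -> numeric vector of on-site
#'   orbital energies in eV, one per shell in basis order (negative for
#'   bound orbitals).
#' @param K Wolfsberg-Helmholz-type constant (> 0, dimensionless).
#' @param repulsion_a pairwise repulsion amplitude (eV).
#' @param repulsion_d repulsion length scale (Angstrom, > 0).
#' @param n_valence named list: element -> valence electron count (>= 1).
#' @return an object of class `slite_hueckel`.
#' @export
hueckel_params <- function(h, K = 1.75, repulsion_a = 100,
                           repulsion_d = 0.35, n_valence = list()) {
  if (K <= 0) stop("K must be > 0")
  if (repulsion_d <= 0) stop("repulsion_d must be > 0")
  fixkeys <- function(x) {
    if (!length(x)) return(x)
    keys <- names(x)
    z <- suppressWarnings(as.integer(keys))
    z[is.na(z)] <- symbol_to_z(keys[is.na(z)])
    stats::setNames(x, as.character(z))
  }
  nv <- fixkeys(n_valence)
  if (length(nv) && any(unlist(nv) < 1)) stop("n_valence must be >= 1")
  structure(list(h = fixkeys(h), K = K, repulsion_a = repulsion_a,
                 repulsion_d = repulsion_d, n_valence = nv),
            class = "slite_hueckel")
}

# On-site energy per orbital, following the orbital index.
onsite_energies <- function(oidx, mol, params) {
  lab <- oidx$orbital_labels
  z <- mol$atomic_numbers[lab$atom]
  vapply(seq_len(oidx$n_ao), function(k) {
    hv <- params$h[[as.character(z[k])]]
    if (is.null(hv) || lab$shell[k] > length(hv)) {
      stop("hueckel params: no on-site energy for element Z = ", z[k],
           ", shell ", lab$shell[k])
    }
    hv[lab$shell[k]]
  }, numeric(1))
}

#' Extended-Hueckel Hamiltonian matrix
#'
#' `H[mu, mu] = h_mu`; `H[mu, nu] = 0.5 K (h_mu + h_nu) S[mu, nu]` off the
#' diagonal. Inherits the exact block-wise rotational covariance of the
#' overlap matrix.
#'
#' @param mol a [molecule()].
#' @param basis a [basis_set()].
#' @param params a [hueckel_params()].
#' @param S optional precomputed overlap matrix (recomputed when `NULL`).
#' @param oidx optional precomputed [build_orbital_index()].
#' @return symmetric `n_ao x n_ao` matrix in eV.
#' @export
hueckel_hamiltonian <- function(mol, basis, params, S = NULL, oidx = NULL) {
  if (is.null(oidx)) oidx <- build_orbital_index(mol, basis)
  if (is.null(S)) S <- overlap_matrix(mol, basis, oidx = oidx)
  h <- onsite_energies(oidx, mol, params)
  H <- 0.5 * params$K * outer(h, h, "+") * S
  diag(H) <- h
  H
}

# Electronic + repulsion energy (eV); real geometries only (the eigensolve
# needs real symmetric input). oidx/h may be precomputed for hot loops.
hueckel_energy <- function(mol, basis, params, n_electrons,
                           oidx = NULL, h = NULL) {
  if (is.null(oidx)) oidx <- build_orbital_index(mol, basis)
  if (is.null(h)) h <- onsite_energies(oidx, mol, params)
  S <- overlap_matrix(mol, basis, check_condition = FALSE, oidx = oidx)
  H <- 0.5 * params$K * outer(h, h, "+") * S
  diag(H) <- h
  eps <- generalized_eigen(H, S, values_only = TRUE)
  nocc <- n_electrons %/% 2L
  if (nocc < length(eps)) {
    if (eps[nocc + 1L] - eps[nocc] < 1e-8) {
      stop("degenerate reference spectrum (HOMO-LUMO splitting < 1e-8 eV); ",
           "redraw the geometry")
    }
  }
  pos <- mol$positions
  n <- n_atoms(mol)
  erep <- 0
  if (n > 1L) {
    d <- as.matrix(stats::dist(pos))
    erep <- params$repulsion_a * sum(exp(-d[upper.tri(d)] / params$repulsion_d))
  }
  2 * sum(eps[seq_len(nocc)]) + erep
}

#' Reference total energy and forces
#'
#' `E = 2 sum_occ eps_m + sum_(i<j) a exp(-d_ij / d)` with the orbital
#' energies from the generalized eigenproblem of the Hueckel (H, S) pair.
#' Forces are the negative central finite-difference gradient of `E`
#' (step 1e-4 Angstrom per coordinate).
#'
#' @param mol a [molecule()].
#' @param basis a [basis_set()].
#' @param params a [hueckel_params()].
#' @param n_electrons even electron count, at most `2 n_ao`.
#' @param step finite-difference step (Angstrom).
#' @return list with `E` (eV) and `F` (`n x 3`, eV/Angstrom).
#' @export
reference_energy_forces <- function(mol, basis, params, n_electrons,
                                    step = 1e-4) {
  if (n_electrons %% 2L != 0L) stop("n_electrons must be even")
  oidx <- build_orbital_index(mol, basis)
  h <- onsite_energies(oidx, mol, params)
  E0 <- hueckel_energy(mol, basis, params, n_electrons, oidx = oidx, h = h)
  n <- n_atoms(mol)
  F <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (c in 1:3) {
      mp <- mol; mp$positions[a, c] <- mp$positions[a, c] + step
      mm <- mol; mm$positions[a, c] <- mm$positions[a, c] - step
      F[a, c] <- -(hueckel_energy(mp, basis, params, n_electrons, oidx, h) -
                     hueckel_energy(mm, basis, params, n_electrons, oidx, h)) /
        (2 * step)
    }
  }
  list(E = E0, F = F)
}

# Full record (H, S, E, F) for one geometry.
reference_record <- function(mol, basis, params, n_electrons) {
  S <- overlap_matrix(mol, basis)
  H <- hueckel_hamiltonian(mol, basis, params, S = S)
  ef <- reference_energy_forces(mol, basis, params, n_electrons)
  electronic_record(mol, H, S, ef$E, ef$F, n_electrons)
}

#' Generate a dataset by randomized distortion of a template geometry
#'
#' Each record's geometry is the template plus i.i.d. Gaussian displacements
#' of scale `sigma`; geometries with any interatomic distance below 0.5
#' Angstrom or with a degenerate frontier spectrum are rejected and redrawn.
#'
#' @param template a [molecule()].
#' @param n number of records.
#' @param sigma per-coordinate displacement scale (Angstrom).
#' @param seed integer seed; the dataset is reproducible per seed.
#' @param basis a [basis_set()].
#' @param params a [hueckel_params()].
#' @param n_electrons even electron count.
#' @return list with `records` (list of [electronic_record()]) and `meta`
#'   (template, sigma, seed, generator parameters).
#' @export
generate_dataset <- function(template, n, sigma, seed, basis, params,
                             n_electrons) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  na <- n_atoms(template)
  records <- vector("list", n)
  for (k in seq_len(n)) {
    rejections <- 0L
    repeat {
      disp <- matrix(stats::rnorm(3 * na, sd = sigma), na, 3)
      mol <- template
      mol$positions <- template$positions + disp
      ok <- TRUE
      if (na > 1L) {
        d <- as.matrix(stats::dist(mol$positions))
        if (min(d[upper.tri(d)]) < 0.5) ok <- FALSE
      }
      if (ok) {
        rec <- tryCatch(reference_record(mol, basis, params, n_electrons),
                        error = function(e) NULL)
        if (!is.null(rec)) { records[[k]] <- rec; break }
      }
      rejections <- rejections + 1L
      if (rejections >= 100L) {
        stop("geometry generation failed: 100 consecutive rejections ",
             "(sigma too large or template too compact)")
      }
    }
  }
  list(records = records,
       meta = list(generator = "extended-hueckel", sigma = sigma, seed = seed,
                   n = n, n_electrons = n_electrons, K = params$K,
                   repulsion_a = params$repulsion_a,
                   repulsion_d = params$repulsion_d))
}

#' Read Hueckel parameters from JSON
#'
#' Format: `{"h": {"8": [-32.4, -14.8], ...}, "K": 1.75, "repulsion_a": ...,
#' "repulsion_d": ..., "n_valence": {"8": 6, ...}}`.
#'
#' @param path path to a JSON parameter file.
#' @return a [hueckel_params()].
#' @export
read_hueckel_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  hueckel_params(h = lapply(as.list(raw$h), as.numeric), K = raw$K,
                 repulsion_a = raw$repulsion_a, repulsion_d = raw$repulsion_d,
                 n_valence = lapply(as.list(raw$n_valence), as.numeric))
}

#' Write Hueckel parameters to JSON
#' @param params a [hueckel_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hueckel_params <- function(params, path) {
  jsonlite::write_json(list(h = params$h, K = params$K,
                            repulsion_a = params$repulsion_a,
                            repulsion_d = params$repulsion_d,
                            n_valence = params$n_valence),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Per-atom valence electron counts
#' @param params a [hueckel_params()].
#' @param mol a [molecule()].
#' @return numeric vector, one entry per atom.
#' @export
valence_counts <- function(params, mol) {
  vapply(mol$atomic_numbers, function(z) {
    v <- params$n_valence[[as.character(z)]]
    if (is.null(v)) stop("no valence count for element Z = ", z)
    as.numeric(v)
  }, numeric(1))
}

#' Built-in toy systems
#'
#' Small self-contained molecule + basis + Hueckel parameter bundles used
#' throughout examples and tests: `"h2"` (two H, one s shell each), `"water"`
#' (bent 3-atom molecule, s+p on the heavy atom) and `"chain4"` (planar
#' 4-atom chain with s+p shells). The h2 and water templates sit at the
#' minimum of their own generator surface (repulsion amplitudes chosen so
#' the chemistry-like template geometry is the equilibrium); the chain4
#' template is a thermal-style off-equilibrium configuration.
#'
#' @param name one of `"h2"`, `"water"`, `"chain4"`.
#' @return list with `molecule`, `basis`, `params`, `n_electrons`.
#' @export
toy_system <- function(name = c("h2", "water", "chain4")) {
  name <- match.arg(name)
  h_s <- list(gaussian_shell(0L, c(1.3097, 0.2331), c(0.4301, 0.6789)))
  switch(
    name,
    h2 = list(
      molecule = molecule(c(1L, 1L), rbind(c(0, 0, 0), c(0.752, 0, 0)),
                          "H2 toy (relaxed)"),
      basis = basis_set(list("1" = h_s), "toy-h2"),
      params = hueckel_params(h = list("1" = -13.6), K = 1.75,
                              repulsion_a = 18, repulsion_d = 0.30,
                              n_valence = list("1" = 1)),
      n_electrons = 2L
    ),
    water = list(
      molecule = molecule(c(8L, 1L, 1L),
                          rbind(c(-0.0167, -0.0212, 0), c(0.9298, 0.0406, 0),
                                c(-0.1931, 0.9107, 0)),
                          "bent water-like toy (relaxed)"),
      basis = basis_set(list(
        "8" = list(gaussian_shell(0L, c(5.03, 1.17), c(0.45, 0.63)),
                   gaussian_shell(1L, c(1.45, 0.35), c(0.51, 0.61))),
        "1" = h_s
      ), "toy-water"),
      params = hueckel_params(h = list("8" = c(-32.4, -14.8), "1" = -13.6),
                              K = 1.75, repulsion_a = 4, repulsion_d = 0.33,
                              n_valence = list("8" = 6, "1" = 1)),
      n_electrons = 8L
    ),
    chain4 = list(
      molecule = molecule(c(6L, 6L, 6L, 6L),
                          rbind(c(0, 0, 0), c(1.40, 0.40, 0),
                                c(2.80, 0, 0), c(4.20, 0.40, 0)),
                          "planar 4-atom chain toy"),
      basis = basis_set(list(
        "6" = list(gaussian_shell(0L, c(3.0, 0.7), c(0.5, 0.6)),
                   gaussian_shell(1L, c(1.1, 0.3), c(0.5, 0.6)))
      ), "toy-chain4"),
      params = hueckel_params(h = list("6" = c(-21.4, -11.4)), K = 1.75,
                              repulsion_a = 130, repulsion_d = 0.35,
                              n_valence = list("6" = 4)),
      n_electrons = 16L
    )
  )
}
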