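# The deep tensor network: continuous-filter convolutional encoder of atomic
# environments, factorised pair features with angular-momentum products, and
# linear heads for the Hamiltonian/overlap blocks plus an atom-wise energy
# head.
#
# The whole forward pass is written to be complex-analytic in the atomic
# positions (branching only on real parts), so complex-step differentiation
# is exact; parameter and position gradients are produced by the hand-written
# reverse pass in model-grad.R.

#' Shifted softplus activation
#'
#' `ssp(x) = ln(0.5 e^x + 0.5)`, zero at zero, used throughout the network.
#' Numerically stabilised for large arguments and analytic in complex inputs.
#'
#' @param x numeric (or complex) scalar, vector or array.
#' @return same shape as `x`.
#' @export
ssp <- function(x) {
  out <- x
  big <- Re(x) > 30
  out[big] <- x[big] + log(1 + exp(-x[big]))
  out[!big] <- log(1 + exp(x[!big]))
  out - log(2)
}

# d ssp / dx = logistic sigmoid.
ssp_grad <- function(x) {
  out <- x
  big <- Re(x) > 30
  out[big] <- 1 / (1 + exp(-x[big]))
  out[!big] <- exp(x[!big]) / (1 + exp(x[!big]))
  out
}

#' Model configuration
#'
#' Architecture hyperparameters. `B` is the atom-feature width, `D` the
#' number of learned projection directions for covariant pair features, `T`
#' the number of environment-encoder interactions, and `L` the maximum basis
#' angular momentum, which instantiates `2L + 1` pair-interaction blocks
#' (feature orders l = 0..2L). `r_c`, `delta_mu`, `gamma` parameterise the
#' radial filter: Gaussian expansion of the distance on a grid of spacing
#' `delta_mu` up to `r_c`, width parameter `gamma`, cosine cutoff at `r_c`.
#'
#' @param basis the [basis_set()] the predicted matrices live in.
#' @param elements nuclear charges the model supports (defaults to all
#'   elements of the basis).
#' @param B atom-feature width (reference scale 1000; desk-scale default 64).
#' @param D projection directions (default 4).
#' @param T_interactions number of environment-encoder interactions.
#' @param L maximum basis angular momentum (0..3); default from the basis.
#' @param r_c cutoff radius (Angstrom).
#' @param delta_mu radial grid spacing (Angstrom).
#' @param gamma radial width parameter (Angstrom^-2).
#' @param n_hidden hidden width of the two-layer perceptrons.
#' @param share_w_dir share the 3 x D direction projection across angular
#'   channels instead of learning one per channel.
#' @return an object of class `slite_config`.
#' @export
model_config <- function(basis, elements = NULL, B = 64L, D = 4L,
                         T_interactions = 3L, L = NULL, r_c = 6.0,
                         delta_mu = 0.1, gamma = 10.0, n_hidden = 64L,
                         share_w_dir = FALSE) {
  zs <- sort(as.integer(names(basis$shells)))
  if (is.null(elements)) elements <- zs
  elements <- sort(as.integer(elements))
  lmax_basis <- max(vapply(basis$shells, function(el) {
    max(vapply(el, function(s) s$l, integer(1)))
  }, integer(1)))
  if (is.null(L)) L <- lmax_basis
  if (B < 1L || D < 1L || T_interactions < 1L) stop("B, D, T must be >= 1")
  if (L < 0L || L > 3L) stop("L must be in 0..3")
  if (r_c <= 0 || delta_mu <= 0 || gamma <= 0) {
    stop("r_c, delta_mu and gamma must be > 0")
  }
  n_ao_max <- max(vapply(elements, function(z) n_ao_element(basis, z),
                         integer(1)))
  structure(list(
    B = as.integer(B), D = as.integer(D), T = as.integer(T_interactions),
    L = as.integer(L), r_c = r_c, delta_mu = delta_mu, gamma = gamma,
    n_hidden = as.integer(n_hidden), n_ao_max = as.integer(n_ao_max),
    elements = elements, basis_name = basis$name,
    share_w_dir = isTRUE(share_w_dir),
    mu_grid = seq(0, r_c, by = delta_mu)
  ), class = "slite_config")
}

# Glorot-uniform matrix.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

mlp_init <- function(nin, nh, nout) {
  list(W1 = glorot(nin, nh), b1 = numeric(nh),
       W2 = glorot(nh, nout), b2 = numeric(nout))
}

#' Initialise model parameters
#'
#' Glorot-uniform linear weights, zero biases, seeded standard-normal
#' embeddings scaled by `1/sqrt(B)`; per-element constant on-site overlap
#' blocks start at the identity (the analytic self-overlap of normalised
#' AOs). Parameters are shared across atoms and pairs within a layer but
#' never across layers.
#'
#' @param config a [model_config()].
#' @param basis the matching [basis_set()].
#' @param seed integer seed.
#' @return nested parameter list of class `slite_params`.
#' @export
init_params <- function(config, basis, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  B <- config$B; D <- config$D; nh <- config$n_hidden
  nrbf <- length(config$mu_grid)
  nblk <- config$n_ao_max^2
  embed <- matrix(stats::rnorm(length(config$elements) * B) / sqrt(B),
                  length(config$elements), B)
  rownames(embed) <- as.character(config$elements)
  schnet <- lapply(seq_len(config$T), function(t) {
    list(W_in = glorot(B, B), filt = mlp_init(nrbf, nh, B),
         atom = mlp_init(B, nh, B))
  })
  schnorb <- lapply(seq_len(2L * config$L + 1L), function(s) {
    lam <- s - 1L
    out <- list(Wl1 = glorot(B, B), bl1 = numeric(B),
                Wl2 = glorot(B, B), bl2 = numeric(B),
                filt = mlp_init(nrbf, nh, B),
                atom = mlp_init(B, nh, B),
                pair = mlp_init(B, nh, B),
                env = mlp_init(B, nh, B))
    if (lam > 0L && !config$share_w_dir) out$Wdir <- glorot(3L, D)
    out
  })
  shared_wdir <- if (config$share_w_dir) glorot(3L, D) else NULL
  heads <- list(
    hoff = lapply(seq_len(2L * config$L + 1L), function(s) {
      list(W = glorot(B * D, nblk), b = numeric(nblk))
    }),
    hon = lapply(seq_len(2L * config$L + 1L), function(s) {
      list(W = glorot(B * D, nblk), b = numeric(nblk))
    }),
    soff = lapply(seq_len(2L * config$L + 1L), function(s) {
      list(W = glorot(B * D, nblk), b = numeric(nblk))
    }),
    s_on = stats::setNames(lapply(config$elements, function(z) {
      diag(n_ao_element(basis, z))
    }), as.character(config$elements))
  )
  p <- list(embed = embed, schnet = schnet, schnorb = schnorb, heads = heads,
            energy = mlp_init(B, nh, 1L))
  if (!is.null(shared_wdir)) p$shared_wdir <- shared_wdir
  structure(p, class = "slite_params")
}

#' Bundle config, parameters and basis into a model
#'
#' The model implements the electronic-surface interface ([hs_matrices()],
#' [energy_forces()], [hs_gradients()]), so everything downstream (spectra,
#' properties, dynamics, gap optimisation) runs on it interchangeably with
#' the reference generator.
#'
#' @param config a [model_config()].
#' @param params a matching [init_params()] parameter set.
#' @param basis the [basis_set()].
#' @return object of classes `slite_model` and `slite_surface`.
#' @export
schnorb_model <- function(config, params, basis) {
  structure(list(config = config, params = params, basis = basis),
            class = c("slite_model", "slite_surface"))
}

#' @export
print.slite_model <- function(x, ...) {
  cfg <- x$config
  cat("<slite_model> B=", cfg$B, " D=", cfg$D, " T=", cfg$T, " L=", cfg$L,
      " (", 2 * cfg$L + 1, " pair blocks), r_c=", cfg$r_c, " A, elements: ",
      paste(cfg$elements, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Two-layer perceptron forward; returns output plus cache for the backward
# pass.
mlp_forward <- function(mp, x) {
  pre <- x %*% mp$W1 + rep(mp$b1, each = nrow(x))
  act <- ssp(pre)
  out <- act %*% mp$W2 + rep(mp$b2, each = nrow(x))
  list(out = out, pre = pre, act = act, x = x)
}

# Radial filter: mlp over the Gaussian distance expansion times the cosine
# cutoff. Exactly zero at and beyond r_c.
radial_filter_forward <- function(mp, dist, config) {
  rbf <- exp(-config$gamma * (outer(dist, config$mu_grid, "-"))^2)
  inside <- Re(dist) < config$r_c
  fcut <- 0.5 * (1 + cos(pi * dist / config$r_c)) * inside
  mf <- mlp_forward(mp, rbf)
  list(out = mf$out * fcut, rbf = rbf, fcut = fcut, inside = inside, mlp = mf)
}

#' Radial filter values
#'
#' Filter-network output `mlp(g(r)) f_cutoff(r)` for given distances: the
#' Gaussian grid expansion `g`, a two-layer perceptron, and the cosine
#' cutoff, which makes the filter exactly zero for `r >= r_c`.
#'
#' @param dist numeric vector of distances (Angstrom).
#' @param mp filter parameters (one `filt` entry of [init_params()]).
#' @param config a [model_config()].
#' @return `length(dist) x B` matrix.
#' @export
radial_filter <- function(dist, mp, config) {
  radial_filter_forward(mp, dist, config)$out
}

# Forward pass. what = "all" computes H, S, E; "energy" skips pair features
# and heads (used by force evaluations); "hs" skips the energy head.
# Positions may be complex (complex-step); the neighbor list is always built
# from the real part.
model_forward <- function(model, mol, what = "all") {
  config <- model$config; params <- model$params; basis <- model$basis
  pos <- mol$positions
  n <- n_atoms(mol)
  zc <- as.character(mol$atomic_numbers)
  if (!all(zc %in% rownames(params$embed))) {
    stop("model has no embedding for element(s) ",
         paste(setdiff(unique(zc), rownames(params$embed)), collapse = ", "))
  }
  oidx <- build_orbital_index(mol, basis)
  if (any(oidx$atom_counts > config$n_ao_max)) {
    stop("an atom exceeds the configured n_ao_max")
  }
  rmol <- mol
  rmol$positions <- Re(pos)
  pl <- neighbor_pairs(rmol, config$r_c)
  P <- length(pl$i)
  B <- config$B; D <- config$D
  # aggregation matrices: M1 sums over pairs by first index, M2 by second
  M1 <- matrix(0, n, max(P, 1L)); M2 <- matrix(0, n, max(P, 1L))
  if (P > 0L) {
    M1[cbind(pl$i, seq_len(P))] <- 1
    M2[cbind(pl$j, seq_len(P))] <- 1
  }
  cplx <- is.complex(pos)
  if (P > 0L) {
    dvec <- pos[pl$j, , drop = FALSE] - pos[pl$i, , drop = FALSE]
    dist <- sqrt(dvec[, 1]^2 + dvec[, 2]^2 + dvec[, 3]^2)
    unit <- dvec / dist
  } else {
    dvec <- matrix(if (cplx) 0i else 0, 0, 3); dist <- dvec[, 1]; unit <- dvec
  }
  cache <- list(oidx = oidx, pl = pl, M1 = M1, M2 = M2, dvec = dvec,
                dist = dist, unit = unit, n = n, P = P, zc = zc, what = what)

  x <- params$embed[zc, , drop = FALSE]
  if (cplx) x <- x + 0i
  cache$x0 <- x
  # environment encoder
  cache$schnet <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    sp <- params$schnet[[t]]
    st <- list()
    if (P > 0L) {
      st$filt <- radial_filter_forward(sp$filt, dist, config)
      st$y <- x %*% sp$W_in
      st$contrib <- st$y[pl$j, , drop = FALSE] * st$filt$out
      st$conv <- M1 %*% st$contrib
    } else {
      st$conv <- matrix(if (cplx) 0i else 0, n, B)
    }
    st$atom <- mlp_forward(sp$atom, st$conv)
    st$x_in <- x
    x <- x + st$atom$out
    cache$schnet[[t]] <- st
  }
  # pair-interaction phase
  nlam <- 2L * config$L + 1L
  cache$schnorb <- vector("list", nlam)
  omegas <- vector("list", nlam)
  for (s in seq_len(nlam)) {
    lam <- s - 1L
    sp <- params$schnorb[[s]]
    st <- list(x_in = x)
    if (P > 0L) {
      st$filt <- radial_filter_forward(sp$filt, dist, config)
      st$f <- x %*% sp$Wl1 + rep(sp$bl1, each = n)
      st$fi <- st$f[pl$i, , drop = FALSE]
      st$fj <- st$f[pl$j, , drop = FALSE]
      st$fac <- st$fi * st$fj * st$filt$out
      st$pre2 <- st$fac %*% sp$Wl2 + rep(sp$bl2, each = P)
      st$h <- ssp(st$pre2)
      st$agg <- M1 %*% st$h
    } else {
      st$agg <- matrix(if (cplx) 0i else 0, n, B)
    }
    st$atom <- mlp_forward(sp$atom, st$agg)
    x <- x + st$atom$out
    if (what != "energy" && P > 0L) {
      st$pairm <- mlp_forward(sp$pair, st$h)
      st$envm <- mlp_forward(sp$env, st$h)
      penv <- st$envm$out
      st$rows1 <- M1 %*% penv
      st$cols2 <- M2 %*% penv
      st$p <- st$pairm$out + st$cols2[pl$j, , drop = FALSE] +
        st$rows1[pl$i, , drop = FALSE] - 2 * penv
      if (lam == 0L) {
        omegas[[s]] <- st$p[, rep(seq_len(B), D), drop = FALSE]
      } else {
        Wdir <- if (config$share_w_dir) params$shared_wdir else sp$Wdir
        st$dirproj <- unit %*% Wdir
        omegas[[s]] <- st$p[, rep(seq_len(B), D), drop = FALSE] *
          st$dirproj[, rep(seq_len(D), each = B), drop = FALSE]
      }
    }
    cache$schnorb[[s]] <- st
  }
  cache$x_final <- x
  out <- list(cache = cache)

  if (what != "energy" && P > 0L) {
    Omegas <- vector("list", nlam)
    Omegas[[1L]] <- omegas[[1L]]
    if (nlam > 1L) {
      for (s in 2:nlam) Omegas[[s]] <- Omegas[[s - 1L]] * omegas[[s]]
    }
    cache$omegas <- omegas
    cache$Omegas <- Omegas
    out$cache <- cache
    hm <- assemble_matrices(params, config, cache)
    out$H <- hm$H
    out$S <- hm$S
  } else if (what != "energy") {
    # isolated atom: only on-site overlap constants survive
    nao <- oidx$n_ao
    H <- matrix(0, nao, nao); S <- matrix(0, nao, nao)
    for (a in seq_len(n)) {
      ia <- atom_orbitals(oidx, a)
      S[ia, ia] <- params$heads$s_on[[zc[a]]]
    }
    out$H <- H; out$S <- S
  }
  if (what != "hs") {
    em <- mlp_forward(params$energy, x)
    cache$energym <- em
    out$cache <- cache
    out$E <- sum(em$out)
  }
  out
}

# Hamiltonian/overlap assembly from angular-momentum features: linear heads
# per feature order, off-site and on-site blocks separate, crop to each
# atom's orbital count, symmetrise.
assemble_matrices <- function(params, config, cache) {
  oidx <- cache$oidx; pl <- cache$pl
  n <- cache$n; P <- cache$P
  nmax <- config$n_ao_max
  nlam <- 2L * config$L + 1L
  cplx <- is.complex(cache$Omegas[[1L]])
  zero <- if (cplx) 0i else 0
  hoff <- matrix(zero, P, nmax^2); son_off <- matrix(zero, P, nmax^2)
  honp <- matrix(zero, P, nmax^2)
  for (s in seq_len(nlam)) {
    Om <- cache$Omegas[[s]]
    hoff <- hoff + Om %*% params$heads$hoff[[s]]$W +
      rep(params$heads$hoff[[s]]$b, each = P)
    honp <- honp + Om %*% params$heads$hon[[s]]$W +
      rep(params$heads$hon[[s]]$b, each = P)
    son_off <- son_off + Om %*% params$heads$soff[[s]]$W +
      rep(params$heads$soff[[s]]$b, each = P)
  }
  hon <- cache$M1 %*% honp
  nao <- oidx$n_ao
  H <- matrix(zero, nao, nao); S <- matrix(zero, nao, nao)
  cnt <- oidx$atom_counts
  for (p in seq_len(P)) {
    i <- pl$i[p]; j <- pl$j[p]
    ri <- atom_orbitals(oidx, i); cj <- atom_orbitals(oidx, j)
    blkH <- matrix(hoff[p, ], nmax, nmax)[seq_len(cnt[i]), seq_len(cnt[j]),
                                          drop = FALSE]
    blkS <- matrix(son_off[p, ], nmax, nmax)[seq_len(cnt[i]), seq_len(cnt[j]),
                                             drop = FALSE]
    H[ri, cj] <- H[ri, cj] + blkH
    S[ri, cj] <- S[ri, cj] + blkS
  }
  for (a in seq_len(n)) {
    ia <- atom_orbitals(oidx, a)
    H[ia, ia] <- H[ia, ia] +
      matrix(hon[a, ], nmax, nmax)[seq_len(cnt[a]), seq_len(cnt[a]),
                                   drop = FALSE]
    S[ia, ia] <- S[ia, ia] + params$heads$s_on[[cache$zc[a]]]
  }
  list(H = (H + t(H)) / 2, S = (S + t(S)) / 2)
}

#' Predict electronic structure for a geometry
#'
#' Full forward pass: Hamiltonian and overlap matrices, total energy, and
#' analytic forces (exact negative gradient of the predicted energy from the
#' reverse pass). Deterministic given the parameters.
#'
#' @param model a [schnorb_model()].
#' @param mol a [molecule()].
#' @param forces include analytic forces.
#' @return an object of class `slite_prediction` with `H` (eV), `S`, `E`
#'   (eV) and `F` (eV/Angstrom, when requested).
#' @export
predict_electronic <- function(model, mol, forces = TRUE) {
  fw <- model_forward(model, mol, what = "all")
  out <- list(H = fw$H, S = fw$S, E = fw$E, F = NULL)
  if (forces) {
    bw <- model_backward(model, fw$cache, dE = 1)
    out$F <- -bw$dpos
  }
  structure(out, class = "slite_prediction")
}

#' @export
print.slite_prediction <- function(x, ...) {
  cat("<slite_prediction> ", nrow(x$H), " AOs, E = ", sprintf("%.6f", x$E),
      " eV\n", sep = "")
  invisible(x)
}

#' Rotationally invariant atom representations
#'
#' Runs the forward pass and returns the per-atom feature vectors: the
#' output of the environment encoder (`x^T`, after the cfconv interaction
#' refinements) and the final representations after the pair-interaction
#' refinements. Both are invariant under rotation and translation and
#' equivariant under atom permutation.
#'
#' @param model a [schnorb_model()].
#' @param mol a [molecule()].
#' @return list with `encoder` and `final`, each `n x B`.
#' @export
atom_representations <- function(model, mol) {
  fw <- model_forward(model, mol, what = "energy")
  list(encoder = fw$cache$schnorb[[1]]$x_in, final = fw$cache$x_final)
}

#' Pair features of the interaction phase
#'
#' Exposes the internal pair quantities for a geometry: the factorised pair
#' representations `h` and invariant pair coefficients `p` per angular
#' channel, the direction-projected basis factors `omega` and their
#' accumulated angular products `Omega`, along with the neighbor-pair list
#' they are indexed by.
#'
#' @param model a [schnorb_model()].
#' @param mol a [molecule()].
#' @return list with `pairs` (neighbor list), `h`, `p` (lists over channels
#'   lambda = 0..2L of `P x B` matrices), `omega`, `Omega` (`P x B*D`).
#' @export
pair_features <- function(model, mol) {
  fw <- model_forward(model, mol, what = "hs")
  st <- fw$cache$schnorb
  list(pairs = fw$cache$pl,
       h = lapply(st, function(s) s$h),
       p = lapply(st, function(s) s$p),
       omega = fw$cache$omegas,
       Omega = fw$cache$Omegas)
}

#' @export
hs_matrices.slite_model <- function(surface, mol) {
  fw <- model_forward(surface, mol, what = "hs")
  list(H = fw$H, S = fw$S)
}

#' @export
energy_forces.slite_model <- function(surface, mol) {
  fw <- model_forward(surface, mol, what = "energy")
  bw <- model_backward(surface, fw$cache, dE = 1)
  list(E = fw$E, F = -bw$dpos)
}

#' @export
hs_gradients.slite_model <- function(surface, mol) {
  # complex-step through the full forward pass, coordinate by coordinate
  fw0 <- model_forward(surface, mol, what = "hs")
  nao <- nrow(fw0$H)
  n <- n_atoms(mol)
  dH <- array(0, c(nao, nao, n, 3)); dS <- array(0, c(nao, nao, n, 3))
  eps <- 1e-20
  for (a in seq_len(n)) {
    for (c in 1:3) {
      molc <- mol
      molc$positions <- mol$positions + 0i
      molc$positions[a, c] <- molc$positions[a, c] + 1i * eps
      fwc <- model_forward(surface, molc, what = "hs")
      dH[, , a, c] <- Im(fwc$H) / eps
      dS[, , a, c] <- Im(fwc$S) / eps
    }
  }
  list(dH = dH, dS = dS)
}
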