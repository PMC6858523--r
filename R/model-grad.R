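# Hand-written reverse pass through the network: exact gradients of any
# linear functional of (H, S, E) with respect to all parameters and all
# atomic positions. The code is complex-safe (plain t()/%*%, no conjugation),
# which the training loss exploits: the mixed second derivative needed for
# the force term is obtained by running this same backward pass at
# complex-stepped positions.

zero_like <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, zero_like)
    attributes(out) <- attributes(x)
    out
  } else {
    x * 0
  }
}

# Elementwise combination of two parameter-shaped nested lists.
param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

param_map1 <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) param_map1(f, x))
    attributes(out) <- attributes(a)
    out
  } else {
    f(a)
  }
}

# Backward through a two-layer perceptron given its forward cache.
mlp_backward <- function(mp, mf, dout) {
  dact <- dout %*% t(mp$W2)
  dpre <- dact * ssp_grad(mf$pre)
  list(dx = dpre %*% t(mp$W1),
       gW1 = t(mf$x) %*% dpre, gb1 = colSums(dpre),
       gW2 = t(mf$act) %*% dout, gb2 = colSums(dout))
}

add_mlp_grads <- function(g, bk) {
  g$W1 <- g$W1 + bk$gW1; g$b1 <- g$b1 + bk$gb1
  g$W2 <- g$W2 + bk$gW2; g$b2 <- g$b2 + bk$gb2
  g
}

# Backward through the radial filter; returns mlp grads and the distance
# gradient.
radial_filter_backward <- function(rf, mp, dout, dist, config) {
  dmlpout <- dout * rf$fcut
  dfcut <- rowSums(dout * rf$mlp$out)
  bk <- mlp_backward(mp, rf$mlp, dmlpout)
  drbf <- bk$dx
  diff <- outer(dist, config$mu_grid, "-")
  ddist <- rowSums(drbf * (-2 * config$gamma * diff) * rf$rbf) +
    dfcut * (-0.5 * pi / config$r_c * sin(pi * dist / config$r_c) * rf$inside)
  list(bk = bk, ddist = ddist)
}

# Reverse pass. dH/dS are gradients of the objective with respect to the
# *symmetrised* predicted matrices; dE with respect to the energy. Returns
# parameter gradients (same shape as params) and position gradients.
model_backward <- function(model, cache, dH = NULL, dS = NULL, dE = 0) {
  config <- model$config; params <- model$params
  n <- cache$n; P <- cache$P; pl <- cache$pl
  B <- config$B; D <- config$D
  M1 <- cache$M1; M2 <- cache$M2
  gr <- zero_like(params)
  dx <- matrix(0, n, B)
  ddist <- numeric(max(P, 1L))[seq_len(P)]
  dunit <- matrix(0, max(P, 1L), 3)[seq_len(P), , drop = FALSE]
  nlam <- 2L * config$L + 1L
  nmax <- config$n_ao_max
  cnt <- cache$oidx$atom_counts

  # ---- energy head
  if (dE != 0) {
    em <- cache$energym
    if (is.null(em)) stop("cache lacks the energy head (forward ran with what='hs')")
    dout <- matrix(dE, n, 1)
    bk <- mlp_backward(params$energy, em, dout)
    gr$energy <- add_mlp_grads(gr$energy, bk)
    dx <- dx + bk$dx
  }

  # ---- matrix heads
  dOmega <- NULL
  if ((!is.null(dH) || !is.null(dS)) && P > 0L) {
    oidx <- cache$oidx
    zero <- if (is.complex(cache$x_final)) 0i else 0
    dhoff <- matrix(zero, P, nmax^2)
    dsoff <- matrix(zero, P, nmax^2)
    dhon_atom <- matrix(zero, n, nmax^2)
    symg <- function(G) if (is.null(G)) NULL else (G + t(G)) / 2
    dHs <- symg(dH); dSs <- symg(dS)
    for (p in seq_len(P)) {
      i <- pl$i[p]; j <- pl$j[p]
      ri <- atom_orbitals(oidx, i); cj <- atom_orbitals(oidx, j)
      if (!is.null(dHs)) {
        pad <- matrix(zero, nmax, nmax)
        pad[seq_len(cnt[i]), seq_len(cnt[j])] <- dHs[ri, cj]
        dhoff[p, ] <- as.vector(pad)
      }
      if (!is.null(dSs)) {
        pad <- matrix(zero, nmax, nmax)
        pad[seq_len(cnt[i]), seq_len(cnt[j])] <- dSs[ri, cj]
        dsoff[p, ] <- as.vector(pad)
      }
    }
    for (a in seq_len(n)) {
      ia <- atom_orbitals(oidx, a)
      if (!is.null(dHs)) {
        pad <- matrix(zero, nmax, nmax)
        pad[seq_len(cnt[a]), seq_len(cnt[a])] <- dHs[ia, ia]
        dhon_atom[a, ] <- as.vector(pad)
      }
      if (!is.null(dSs)) {
        key <- cache$zc[a]
        gr$heads$s_on[[key]] <- gr$heads$s_on[[key]] + dSs[ia, ia]
      }
    }
    dhon_pair <- dhon_atom[pl$i, , drop = FALSE]
    dOmega <- vector("list", nlam)
    for (s in seq_len(nlam)) {
      Om <- cache$Omegas[[s]]
      acc <- matrix(zero, P, B * D)
      if (!is.null(dHs)) {
        acc <- acc + dhoff %*% t(params$heads$hoff[[s]]$W) +
          dhon_pair %*% t(params$heads$hon[[s]]$W)
        gr$heads$hoff[[s]]$W <- gr$heads$hoff[[s]]$W + t(Om) %*% dhoff
        gr$heads$hoff[[s]]$b <- gr$heads$hoff[[s]]$b + colSums(dhoff)
        gr$heads$hon[[s]]$W <- gr$heads$hon[[s]]$W + t(Om) %*% dhon_pair
        gr$heads$hon[[s]]$b <- gr$heads$hon[[s]]$b + colSums(dhon_pair)
      }
      if (!is.null(dSs)) {
        acc <- acc + dsoff %*% t(params$heads$soff[[s]]$W)
        gr$heads$soff[[s]]$W <- gr$heads$soff[[s]]$W + t(Om) %*% dsoff
        gr$heads$soff[[s]]$b <- gr$heads$soff[[s]]$b + colSums(dsoff)
      }
      dOmega[[s]] <- acc
    }
  }

  # ---- angular product rule: dOmega -> domega
  domega <- NULL
  if (!is.null(dOmega)) {
    domega <- vector("list", nlam)
    for (s in seq_len(nlam)) domega[[s]] <- 0
    for (l in seq_len(nlam)) {
      for (lam in seq_len(l)) {
        pr <- dOmega[[l]]
        for (l2 in seq_len(l)) {
          if (l2 != lam) pr <- pr * cache$omegas[[l2]]
        }
        domega[[lam]] <- domega[[lam]] + pr
      }
    }
  }

  # ---- pair-interaction stages, reverse order
  for (s in rev(seq_len(nlam))) {
    sp <- params$schnorb[[s]]
    st <- cache$schnorb[[s]]
    lam <- s - 1L
    dh <- 0
    if (!is.null(domega) && P > 0L) {
      dom <- domega[[s]]
      if (lam == 0L) {
        dp <- 0
        for (d in seq_len(D)) {
          dp <- dp + dom[, (d - 1L) * B + seq_len(B), drop = FALSE]
        }
      } else {
        Wdir <- if (config$share_w_dir) params$shared_wdir else sp$Wdir
        dp <- 0
        ddirproj <- matrix(0, P, D)
        for (d in seq_len(D)) {
          blk <- dom[, (d - 1L) * B + seq_len(B), drop = FALSE]
          dp <- dp + blk * st$dirproj[, d]
          ddirproj[, d] <- rowSums(blk * st$p)
        }
        gWdir <- t(cache$unit) %*% ddirproj
        if (config$share_w_dir) {
          gr$shared_wdir <- gr$shared_wdir + gWdir
        } else {
          gr$schnorb[[s]]$Wdir <- gr$schnorb[[s]]$Wdir + gWdir
        }
        dunit <- dunit + ddirproj %*% t(Wdir)
      }
      # p = pair + cols2[pj,] + rows1[pi,] - 2 env
      dppair <- dp
      dpenv <- t(M2) %*% (M2 %*% dp) + t(M1) %*% (M1 %*% dp) - 2 * dp
      bkp <- mlp_backward(sp$pair, st$pairm, dppair)
      gr$schnorb[[s]]$pair <- add_mlp_grads(gr$schnorb[[s]]$pair, bkp)
      bke <- mlp_backward(sp$env, st$envm, dpenv)
      gr$schnorb[[s]]$env <- add_mlp_grads(gr$schnorb[[s]]$env, bke)
      dh <- dh + bkp$dx + bke$dx
    }
    # atom refinement path
    bka <- mlp_backward(sp$atom, st$atom, dx)
    gr$schnorb[[s]]$atom <- add_mlp_grads(gr$schnorb[[s]]$atom, bka)
    if (P > 0L) {
      dagg <- bka$dx
      dh <- dh + dagg[pl$i, , drop = FALSE]
      dpre2 <- dh * ssp_grad(st$pre2)
      gr$schnorb[[s]]$Wl2 <- gr$schnorb[[s]]$Wl2 + t(st$fac) %*% dpre2
      gr$schnorb[[s]]$bl2 <- gr$schnorb[[s]]$bl2 + colSums(dpre2)
      dfac <- dpre2 %*% t(sp$Wl2)
      dfi <- dfac * st$fj * st$filt$out
      dfj <- dfac * st$fi * st$filt$out
      dfiltout <- dfac * st$fi * st$fj
      rb <- radial_filter_backward(st$filt, sp$filt, dfiltout, cache$dist,
                                   config)
      gr$schnorb[[s]]$filt <- add_mlp_grads(gr$schnorb[[s]]$filt, rb$bk)
      ddist <- ddist + rb$ddist
      df <- M1 %*% dfi + M2 %*% dfj
      gr$schnorb[[s]]$Wl1 <- gr$schnorb[[s]]$Wl1 + t(st$x_in) %*% df
      gr$schnorb[[s]]$bl1 <- gr$schnorb[[s]]$bl1 + colSums(df)
      dx <- dx + df %*% t(sp$Wl1)
    }
  }

  # ---- environment-encoder stages, reverse order
  for (t in rev(seq_len(config$T))) {
    sp <- params$schnet[[t]]
    st <- cache$schnet[[t]]
    bka <- mlp_backward(sp$atom, st$atom, dx)
    gr$schnet[[t]]$atom <- add_mlp_grads(gr$schnet[[t]]$atom, bka)
    if (P > 0L) {
      dconv <- bka$dx
      dcontrib <- dconv[pl$i, , drop = FALSE]
      dy_pairs <- dcontrib * st$filt$out
      dfiltout <- dcontrib * st$y[pl$j, , drop = FALSE]
      rb <- radial_filter_backward(st$filt, sp$filt, dfiltout, cache$dist,
                                   config)
      gr$schnet[[t]]$filt <- add_mlp_grads(gr$schnet[[t]]$filt, rb$bk)
      ddist <- ddist + rb$ddist
      dy <- M2 %*% dy_pairs
      gr$schnet[[t]]$W_in <- gr$schnet[[t]]$W_in + t(st$x_in) %*% dy
      dx <- dx + dy %*% t(sp$W_in)
    }
  }

  # ---- embeddings
  for (a in seq_len(n)) {
    key <- cache$zc[a]
    gr$embed[key, ] <- gr$embed[key, ] + dx[a, ]
  }

  # ---- positions
  dpos <- matrix(0, n, 3)
  if (P > 0L) {
    dist <- cache$dist; dvec <- cache$dvec; unit <- cache$unit
    ddvec <- dunit / dist
    ddist <- ddist - rowSums(dunit * dvec) / dist^2
    ddvec <- ddvec + ddist * unit
    dpos <- M2 %*% ddvec - M1 %*% ddvec
  }
  list(grads = gr, dpos = dpos)
}

#' Combined training loss
#'
#' Squared-Frobenius errors of the Hamiltonian and overlap matrices plus a
#' weighted energy term and a force term,
#' `|H - H~|_F^2 + |S - S~|_F^2 + rho |E - E~|^2 +
#'  (1-rho)/n sum_i |F_i + dE~/dr_i|^2`.
#'
#' @param pred a [predict_electronic()] result (with forces when `rho < 1`).
#' @param ref an [electronic_record()] with matching shapes.
#' @param rho energy/force trade-off in `[0, 1]`.
#' @return list with `total` and the components `h`, `s`, `e`, `f`.
#' @export
combined_loss <- function(pred, ref, rho) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (!all(dim(pred$H) == dim(ref$H))) stop("H shape mismatch")
  if (!all(dim(pred$S) == dim(ref$S))) stop("S shape mismatch")
  lh <- sum((ref$H - pred$H)^2)
  ls <- sum((ref$S - pred$S)^2)
  le <- rho * (ref$E - pred$E)^2
  lf <- 0
  if (rho < 1) {
    if (is.null(pred$F)) stop("force term requested (rho < 1) but prediction has no forces")
    na <- nrow(ref$F)
    lf <- (1 - rho) / na * sum((ref$F - pred$F)^2)
  }
  list(total = lh + ls + le + lf, h = lh, s = ls, e = le, f = lf)
}

# Loss + parameter gradients for one record. The H/S/E terms flow through
# one real reverse pass; the force term uses the complex-step directional
# derivative: grad_theta [v . dE/dr] = Im(grad_theta E(r + i eps v)) / eps.
loss_and_grads <- function(model, rec, rho) {
  fw <- model_forward(model, rec$molecule, what = "all")
  bwF <- model_backward(model, fw$cache, dE = 1)
  Fpred <- -bwF$dpos
  pred <- list(H = fw$H, S = fw$S, E = fw$E, F = Fpred)
  loss <- combined_loss(pred, rec, rho)
  bw <- model_backward(model, fw$cache,
                       dH = 2 * (fw$H - rec$H),
                       dS = 2 * (fw$S - rec$S),
                       dE = 2 * rho * (fw$E - rec$E))
  grads <- bw$grads
  if (rho < 1) {
    na <- nrow(rec$F)
    resid <- rec$F - Fpred            # = F_ref + dE/dr
    eps <- 1e-20
    molc <- rec$molecule
    molc$positions <- molc$positions + 1i * eps * resid
    fwc <- model_forward(model, molc, what = "energy")
    bwc <- model_backward(model, fwc$cache, dE = 1)
    scale <- 2 * (1 - rho) / na
    grads <- param_map2(function(g, gc) g + scale * Im(gc) / eps,
                        grads, bwc$grads)
  }
  list(loss = loss, grads = grads, pred = pred)
}
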