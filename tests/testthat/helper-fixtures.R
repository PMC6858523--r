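# Shared fixtures, built in code.

toy_h2 <- toy_system("h2")
toy_water <- toy_system("water")
toy_chain <- toy_system("chain4")

tiny_model <- function(basis, seed = 1L, B = 8L, D = 2L, T = 1L, nh = 8L) {
  cfg <- model_config(basis, B = B, D = D, T_interactions = T, n_hidden = nh)
  schnorb_model(cfg, init_params(cfg, basis, seed = seed), basis)
}

# Central finite-difference gradient of a scalar function of the geometry.
fd_gradient <- function(mol, f, step = 1e-4) {
  n <- n_atoms(mol)
  g <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (cc in 1:3) {
      mp <- mol; mp$positions[a, cc] <- mp$positions[a, cc] + step
      mm <- mol; mm$positions[a, cc] <- mm$positions[a, cc] - step
      g[a, cc] <- (f(mp) - f(mm)) / (2 * step)
    }
  }
  g
}

random_molecule <- function(n, seed, spread = 1.6, zpool = c(1L, 8L)) {
  set.seed(seed)
  repeat {
    pos <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    d <- as.matrix(stats::dist(pos))
    if (n == 1L || min(d[upper.tri(d)]) > 0.7) break
  }
  molecule(sample(zpool, n, replace = TRUE), pos)
}

# One shared desk-scale training run, reused by every test that needs a
# trained model (training is the expensive step; its properties are checked
# from multiple angles on the same fit).
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ts <- toy_system("water")
    ds <- generate_dataset(ts$molecule, 200, 0.05, 11, ts$basis, ts$params,
                          ts$n_electrons)
    cfg <- model_config(ts$basis, B = 64L, D = 4L, T_interactions = 3L,
                        L = 1L, n_hidden = 64L)
    init <- schnorb_model(cfg, init_params(cfg, ts$basis, seed = 7), ts$basis)
    fit <- train_model(init, ds$records,
                       train_config(rho = 0.1, max_epochs = 50L, seed = 7,
                                    augment = TRUE))
    cache <<- list(ts = ts, ds = ds, init = init, fit = fit)
    cache
  }
})
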