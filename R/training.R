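# Training: Adam on the combined (H, S, E, F) loss with on-the-fly rotation
# augmentation and a patience-based learning-rate decay schedule.

#' Training configuration
#'
#' @param rho energy/force trade-off of the combined loss, in `[0, 1]`.
#' @param lr0 initial learning rate.
#' @param decay learning-rate decay factor applied after `patience` epochs
#'   without validation improvement (0 < decay < 1).
#' @param patience epochs without improvement before the rate is decayed.
#' @param lr_min training stops once the learning rate falls to or below
#'   this value.
#' @param batch_size mini-batch size.
#' @param max_epochs hard epoch cap.
#' @param seed integer seed controlling the split, shuffling, and
#'   augmentation rotors.
#' @param augment rotate every training sample (geometry, H, S, F
#'   consistently) with a fresh random rotor each epoch.
#' @param split named fractions `train`/`val`/`test` summing to 1.
#' @param val_improvement relative decrease of the best validation loss that
#'   counts as improvement (guards against float-noise resets).
#' @return an object of class `slite_trainconfig`.
#' @export
train_config <- function(rho = 0.1, lr0 = 1e-3, decay = 0.8, patience = 15L,
                         lr_min = 5e-6, batch_size = 8L, max_epochs = 100L,
                         seed = 1L, augment = TRUE,
                         split = c(train = 0.75, val = 0.15, test = 0.10),
                         val_improvement = 1e-4) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
  if (lr_min >= lr0) stop("lr_min must be below lr0")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(rho = rho, lr0 = lr0, decay = decay,
                 patience = as.integer(patience), lr_min = lr_min,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 augment = isTRUE(augment), split = split,
                 val_improvement = val_improvement),
            class = "slite_trainconfig")
}

# One learning-rate schedule update. Returns the new schedule state; pure so
# the rule is unit-testable with scripted losses.
schedule_step <- function(state, val_loss, cfg) {
  improved <- val_loss < state$best * (1 - cfg$val_improvement)
  if (improved) {
    state$best <- val_loss
    state$bad_epochs <- 0L
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    if (state$bad_epochs > cfg$patience) {
      state$lr <- state$lr * cfg$decay
      state$bad_epochs <- 0L
    }
  }
  state$improved <- improved
  state
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  mh <- param_map1(function(m) m / c1, state$m)
  vh <- param_map1(function(v) v / c2, state$v)
  upd <- param_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
  state$params <- param_map2(function(p, u) p - lr * u, params, upd)
  state
}

# Mean loss over records without touching parameters (forces included so the
# force term is evaluated exactly as in training).
evaluate_loss <- function(model, records, rho) {
  acc <- c(total = 0, h = 0, s = 0, e = 0, f = 0)
  for (rec in records) {
    pred <- predict_electronic(model, rec$molecule, forces = rho < 1)
    l <- combined_loss(pred, rec, rho)
    acc <- acc + c(l$total, l$h, l$s, l$e, l$f)
  }
  acc / length(records)
}

#' Train a model on electronic records
#'
#' Adam on mini-batches of the combined loss. When augmentation is on, every
#' training sample is rotated by a fresh random rotor each epoch (positions,
#' forces and the Wigner-transformed H/S together), which is how the network
#' learns rotational covariance. The learning rate is multiplied by `decay`
#' after `patience` epochs without validation improvement; training stops at
#' `lr <= lr_min` or `max_epochs`, and the parameters with the lowest
#' validation loss are returned.
#'
#' @param model a [schnorb_model()] (initial parameters).
#' @param records list of [electronic_record()] objects.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `slite_fit`: `model` (best parameters),
#'   `history` (per-epoch tibble), `best_epoch`, `split` (index lists),
#'   `cfg`.
#' @export
train_model <- function(model, records, cfg = train_config(),
                        verbose = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  nrec <- length(records)
  idx <- sample.int(nrec)
  ntr <- round(cfg$split[["train"]] * nrec)
  nva <- round(cfg$split[["val"]] * nrec)
  if (ntr < 1L || nva < 1L) stop("empty train or validation split")
  split <- list(train = idx[seq_len(ntr)],
                val = idx[ntr + seq_len(nva)],
                test = idx[setdiff(seq_len(nrec), seq_len(ntr + nva))])
  train_recs <- records[split$train]
  val_recs <- records[split$val]

  basis <- model$basis
  state <- list(m = zero_like(model$params), v = zero_like(model$params),
                t = 0L, params = model$params)
  sched <- list(lr = cfg$lr0, best = Inf, bad_epochs = 0L, improved = FALSE)
  best_params <- model$params
  best_epoch <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    cur <- schnorb_model(model$config, state$params, basis)
    epoch_recs <- train_recs
    if (cfg$augment) {
      epoch_recs <- lapply(train_recs, function(r) {
        rotate_record(r, random_rotation(sample.int(2147483646L, 1L)), basis)
      })
    }
    ord <- sample.int(length(epoch_recs))
    tacc <- c(total = 0, h = 0, s = 0, e = 0, f = 0)
    nb <- 0
    for (bstart in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, length(ord))]
      gacc <- NULL
      for (ri in bidx) {
        cur <- schnorb_model(model$config, state$params, basis)
        lg <- loss_and_grads(cur, epoch_recs[[ri]], cfg$rho)
        if (!is.finite(lg$loss$total)) {
          stop("non-finite training loss at epoch ", epoch)
        }
        tacc <- tacc + c(lg$loss$total, lg$loss$h, lg$loss$s, lg$loss$e,
                         lg$loss$f)
        gacc <- if (is.null(gacc)) lg$grads else {
          param_map2(`+`, gacc, lg$grads)
        }
      }
      gacc <- param_map1(function(g) g / length(bidx), gacc)
      state <- adam_update(state$params, gacc, state, sched$lr)
      nb <- nb + 1
    }
    tacc <- tacc / length(epoch_recs)
    cur <- schnorb_model(model$config, state$params, basis)
    vacc <- evaluate_loss(cur, val_recs, cfg$rho)
    sched <- schedule_step(sched, vacc[["total"]], cfg)
    if (sched$improved) {
      best_params <- state$params
      best_epoch <- epoch
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = sched$lr,
      train_total = tacc[["total"]], train_h = tacc[["h"]],
      train_s = tacc[["s"]], train_e = tacc[["e"]], train_f = tacc[["f"]],
      val_total = vacc[["total"]], val_h = vacc[["h"]], val_s = vacc[["s"]],
      val_e = vacc[["e"]], val_f = vacc[["f"]],
      improved = sched$improved
    )
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4g  val %.4g%s", epoch,
                      sched$lr, tacc[["total"]], vacc[["total"]],
                      if (sched$improved) " *" else ""))
    }
    if (sched$lr <= cfg$lr_min) break
  }
  history <- do.call(rbind, hist)
  structure(list(model = schnorb_model(model$config, best_params, basis),
                 history = history, best_epoch = best_epoch, split = split,
                 cfg = cfg),
            class = "slite_fit")
}

#' @export
print.slite_fit <- function(x, ...) {
  cat("<slite_fit> ", nrow(x$history), " epochs, best epoch ", x$best_epoch,
      " (val loss ", sprintf("%.5g", min(x$history$val_total)), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#' @param x a `slite_fit`.
#' @param ... unused.
#' @return tibble with one row per epoch (losses, learning rate).
#' @method tidy slite_fit
#' @export
tidy.slite_fit <- function(x, ...) x$history

#' One-row training summary
#' @param x a `slite_fit`.
#' @param ... unused.
#' @return tibble with epochs run, best epoch, best validation loss and
#'   final learning rate.
#' @method glance slite_fit
#' @export
glance.slite_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_total = min(x$history$val_total),
    best_val_h = x$history$val_h[which.min(x$history$val_total)],
    final_lr = x$history$lr[nrow(x$history)],
    n_train = length(x$split$train),
    n_val = length(x$split$val),
    n_test = length(x$split$test)
  )
}

#' Per-orbital tidy summary of a spectrum
#' @param x a `slite_spectrum`.
#' @param ... unused.
#' @return tibble with orbital index, energy (eV) and occupation.
#' @method tidy slite_spectrum
#' @export
tidy.slite_spectrum <- function(x, ...) {
  tibble::tibble(orbital = seq_along(x$epsilon), energy = x$epsilon,
                 occupation = x$occupation)
}

#' One-row spectrum summary
#' @param x a `slite_spectrum`.
#' @param ... unused.
#' @return tibble with electron count, HOMO, LUMO and gap (eV).
#' @method glance slite_spectrum
#' @export
glance.slite_spectrum <- function(x, ...) {
  nocc <- sum(x$occupation > 0)
  tibble::tibble(
    n_electrons = x$n_electrons,
    homo = x$epsilon[nocc],
    lumo = if (nocc < length(x$epsilon)) x$epsilon[nocc + 1L] else NA_real_,
    gap = if (nocc < length(x$epsilon)) homo_lumo_gap(x) else NA_real_
  )
}
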