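# Loss, schedule, and seeded optimisation behaviour.

test_that("combined loss reproduces hand-computed values and edge cases", {
  rec <- schnorblite:::reference_record(toy_h2$molecule, toy_h2$basis,
                                        toy_h2$params, 2L)
  perfect <- list(H = rec$H, S = rec$S, E = rec$E, F = rec$F)
  l0 <- combined_loss(perfect, rec, rho = 0.5)
  expect_identical(l0$total, 0)

  # 1x1 toy evaluated by hand: H term 1, S term 0, energy term 0.5 * 4,
  # force term (1 - rho)/1 * |dF|^2
  ref <- list(H = matrix(1), S = matrix(1), E = 2,
              F = matrix(c(0, 0, 0), 1), n_electrons = 2L)
  pred <- list(H = matrix(0), S = matrix(1), E = 0,
               F = matrix(c(0.5, 0, 0), 1))
  l <- combined_loss(pred, ref, rho = 0.5)
  expect_equal(l$h, 1)
  expect_equal(l$s, 0)
  expect_equal(l$e, 0.5 * 4)
  expect_equal(l$f, 0.5 * 0.25)
  expect_equal(l$total, l$h + l$s + l$e + l$f, tolerance = 1e-10)

  # rho = 1 removes the force weight entirely
  l1 <- combined_loss(list(H = pred$H, S = pred$S, E = pred$E, F = NULL),
                      ref, rho = 1)
  expect_identical(l1$f, 0)
  expect_error(combined_loss(list(H = matrix(0, 2, 2), S = pred$S,
                                  E = 0, F = NULL), ref, 1),
               "shape mismatch")
})

test_that("the learning-rate schedule follows the decay/patience rule", {
  cfg <- train_config(patience = 0L, decay = 0.8, lr0 = 1e-3)
  st <- list(lr = cfg$lr0, best = Inf, bad_epochs = 0L)
  scripted <- c(10, 9, 9.2, 8, 8.5, 8.4, 7)   # improvements at 1, 2, 4, 7
  lrs <- numeric(0)
  for (v in scripted) {
    st <- schnorblite:::schedule_step(st, v, cfg)
    lrs <- c(lrs, st$lr)
  }
  # with patience 0 the rate decays on every non-improving epoch
  expect_equal(lrs, 1e-3 * 0.8^c(0, 0, 1, 1, 2, 3, 3))
  expect_true(all(diff(lrs) <= 0))

  # improvement must beat the relative threshold
  cfg2 <- train_config(patience = 0L, val_improvement = 1e-2)
  st2 <- list(lr = cfg2$lr0, best = 100, bad_epochs = 0L)
  st2 <- schnorblite:::schedule_step(st2, 99.95, cfg2)
  expect_false(st2$improved)
})

test_that("a tiny seeded run descends and stops at the rate floor", {
  ts <- toy_h2
  ds <- generate_dataset(ts$molecule, 20, 0.04, 8, ts$basis, ts$params, 2L)
  mdl <- tiny_model(ts$basis, seed = 4, B = 8L, D = 2L, T = 1L)
  cfg <- train_config(rho = 0.5, max_epochs = 15L, batch_size = 4L,
                      seed = 8, augment = FALSE,
                      split = c(train = 0.7, val = 0.2, test = 0.1))
  fit <- train_model(mdl, ds$records, cfg)
  h <- fit$history
  expect_lt(h$train_total[nrow(h)], h$train_total[1])
  expect_true(all(diff(h$lr) <= 1e-12))
  expect_equal(h$val_total[fit$best_epoch], min(h$val_total),
               tolerance = 1e-4)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$best_epoch, fit$best_epoch)

  # lr floor terminates training: demanding a 99% improvement per epoch
  # guarantees decay from epoch 2 on (patience 0), so the floor is reached
  # almost immediately
  cfg2 <- train_config(rho = 1, lr0 = 1e-3, lr_min = 9.9e-4, patience = 0L,
                       max_epochs = 50L, seed = 8, augment = FALSE,
                       val_improvement = 0.99,
                       split = c(train = 0.7, val = 0.2, test = 0.1))
  fit2 <- train_model(mdl, ds$records, cfg2)
  expect_lt(nrow(fit2$history), 50L)
  expect_lte(fit2$history$lr[nrow(fit2$history)], 9.9e-4)
})

test_that("a student recovers a random teacher of identical architecture", {
  ts <- toy_h2
  teacher <- tiny_model(ts$basis, seed = 21, B = 8L, D = 2L, T = 1L)
  set.seed(33)
  recs <- lapply(1:60, function(k) {
    mol <- ts$molecule
    mol$positions <- mol$positions + matrix(rnorm(6, sd = 0.05), 2, 3)
    pred <- predict_electronic(teacher, mol)
    electronic_record(mol, pred$H, pred$S, pred$E, pred$F, 2L,
                      validate = FALSE)
  })
  student <- tiny_model(ts$basis, seed = 22, B = 8L, D = 2L, T = 1L)
  cfg <- train_config(rho = 1, max_epochs = 40L, batch_size = 8L, seed = 5,
                      augment = FALSE,
                      split = c(train = 0.7, val = 0.2, test = 0.1))
  fit <- train_model(student, recs, cfg)
  # validation H error well below the teacher-output variance
  Hs <- sapply(recs[fit$split$val], function(r) as.vector(r$H))
  teacher_var <- sum(apply(Hs, 1, stats::var))
  expect_lt(min(fit$history$val_h), 0.1 * teacher_var)
})
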