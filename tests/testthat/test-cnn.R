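test_that("model heads have the required output ranges and shapes", {
  g <- tiny_grid()
  probe <- matrix(rnorm(3 * g$n_points), 3)
  cl <- build_cnn(tiny_arch("classifier"), g$n_points, seed = 1)
  sc <- predict(cl, probe, check_trained = FALSE)
  expect_equal(dim(sc), c(3L, 5L))
  expect_true(all(sc >= 0 & sc <= 1))
  rg <- build_cnn(tiny_arch("regressor"), g$n_points, seed = 1)
  out <- predict(rg, probe, check_trained = FALSE)
  expect_equal(dim(out), c(3L, 6L))
  # same seed -> identical initialisation
  cl2 <- build_cnn(tiny_arch("classifier"), g$n_points, seed = 1)
  expect_identical(predict(cl2, probe, check_trained = FALSE), sc)
  # untrained prediction is refused by default
  expect_error(predict(cl, probe), "untrained")
  expect_error(build_cnn(tiny_arch(), 4), "too short")
})

test_that("training reduces loss and honours the early-stopping contract", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  tr <- generate_dataset(80, "train", refs, noiseless_cfg(), seed = 21)
  va <- generate_dataset(40, "validation", refs, noiseless_cfg(), seed = 22)
  m <- build_cnn(tiny_arch("classifier"), g$n_points, seed = 2)
  cfg <- training_config(max_epochs = 8, batch_size = 16, patience = 7,
                         seed = 3)
  m <- train_cnn(m, tr, va, cfg)
  h <- m$history
  expect_true(nrow(h) >= 1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # restored weights belong to the best validation epoch
  expect_equal(m$best_val_loss, min(h$val_loss))
  ns <- asNamespace("sersmix")
  final_val <- ns$cnn_dataset_loss(m$params, m$architecture, va$x,
                                   matrix(as.numeric(va$presence),
                                          nrow(va$presence)))
  expect_equal(final_val, min(h$val_loss), tolerance = 1e-12)
})

test_that("training is deterministic under fixed seeds", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  tr <- generate_dataset(60, "train", refs, seed = 31)
  va <- generate_dataset(30, "validation", refs, seed = 32)
  cfg <- training_config(max_epochs = 3, batch_size = 16, patience = 2,
                         seed = 7)
  run <- function() {
    m <- build_cnn(tiny_arch("regressor"), g$n_points, seed = 5)
    train_cnn(m, tr, va, cfg)$history$val_loss
  }
  v1 <- run(); v2 <- run()
  expect_equal(v1, v2, tolerance = 1e-4)
})

test_that("an overfit classifier memorises its training samples", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  tr <- generate_dataset(20, "train", refs, noiseless_cfg(), seed = 41)
  m <- build_cnn(tiny_arch("classifier"), g$n_points, seed = 6)
  cfg <- training_config(max_epochs = 200, batch_size = 10, patience = 199,
                         learning_rate = 3e-3, seed = 8)
  m <- train_cnn(m, tr, tr, cfg)
  sc <- predict(m, tr$x)
  present <- tr$presence == 1L
  expect_true(all(sc[present] > 0.5))
  # inference is deterministic: duplicated rows give identical scores
  dup <- tr$x[c(1, 1, 2, 2), ]
  sd <- predict(m, dup)
  expect_identical(sd[1, ], sd[2, ])
  expect_identical(sd[3, ], sd[4, ])
})

test_that("the regressor recovers single-target contributions", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  tr <- generate_dataset(400, "train", refs, noiseless_cfg(), seed = 51)
  va <- generate_dataset(80, "validation", refs, noiseless_cfg(), seed = 52)
  m <- build_cnn(tiny_arch("regressor"), g$n_points, seed = 9)
  cfg <- training_config(max_epochs = 12, batch_size = 32, patience = 11,
                         seed = 10)
  m <- train_cnn(m, tr, va, cfg)
  # noiseless single-target probes: contribution argmax lands on the target
  blank <- make_blank(g, noise_config(0, 0, 0.1))
  set.seed(53)
  hits <- 0L
  for (t in 1:5) {
    ctr <- numeric(5); ctr[t] <- 1
    smp <- compose_mixture(ctr, refs, blank, noiseless_cfg(), scale = 1)
    pred <- predict(m, matrix(smp$spectrum$intensities, 1))
    hits <- hits + (which.max(pred[1, 1:5]) == t)
  }
  expect_gte(hits, 4L)
})

test_that("label shape must match the head before any training happens", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  tr <- generate_dataset(20, "train", refs, seed = 61)
  m <- build_cnn(tiny_arch("classifier"), g$n_points, seed = 11)
  bad <- list(x = tr$x, y = cbind(tr$contributions, tr$norm_factor))
  cfg <- training_config(max_epochs = 2, batch_size = 10, patience = 1)
  expect_error(train_cnn(m, bad, bad, cfg), "5 label columns")
})

test_that("an untrained network scores at chance-level AUC", {
  refs <- default_reference_library()
  ho <- generate_dataset(600, "test", refs, seed = 301)
  m <- build_cnn(cnn_architecture(head = "classifier"), 660, seed = 204)
  sc <- predict(m, ho$x, check_trained = FALSE)
  auc <- roc_curve(as.vector(sc), as.vector(ho$presence))$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("shuffled-label training degrades F1 to the prevalence baseline", {
  refs <- default_reference_library()
  tr <- generate_dataset(1000, "train", refs, seed = 91)
  va <- generate_dataset(300, "validation", refs, seed = 92)
  set.seed(93)
  shuf <- list(x = tr$x,
               y = matrix(as.numeric(tr$presence[sample.int(1000), ]), 1000))
  m <- build_cnn(cnn_architecture(head = "classifier"), 660, seed = 94)
  m <- train_cnn(m, shuf, list(x = va$x,
                               y = matrix(as.numeric(va$presence), 300)),
                 training_config(max_epochs = 2, patience = 1, seed = 95))
  calls <- (predict(m, va$x) >= 0.5) + 0L
  rep <- classification_report(calls, va$presence)
  prevalence <- mean(va$presence)
  baseline_f1 <- 2 * prevalence / (1 + prevalence)
  expect_lt(abs(rep$micro$f1 - baseline_f1), 0.1)
})

test_that("architecture search is seeded and honours degenerate spaces", {
  g <- tiny_grid()
  refs <- default_reference_library(g)
  opt <- generate_dataset(60, "optimization", refs, seed = 71)
  single <- list(filters_base = 4L, kernel = 5L, pool = 2L,
                 dense_units = 8L, dropout = 0)
  a1 <- search_architecture(single, opt, n_trials = 1L, seed = 1, epochs = 2)
  expect_equal(a1$conv_blocks[[1]]$filters, 4L)
  expect_equal(a1$dense_units, 8L)
  two <- list(filters_base = c(4L, 6L), kernel = 5L, pool = 2L,
              dense_units = c(8L, 12L), dropout = 0)
  b1 <- search_architecture(two, opt, n_trials = 3L, seed = 2, epochs = 2)
  b2 <- search_architecture(two, opt, n_trials = 3L, seed = 2, epochs = 2)
  expect_identical(unclass(b1)[c("conv_blocks", "dense_units", "dropout")],
                   unclass(b2)[c("conv_blocks", "dense_units", "dropout")])
  expect_error(search_architecture(list(kernel = integer(0)), opt, 1),
               "empty candidate")
})
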