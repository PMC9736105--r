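test_that("pseudo-label loss matches closed forms and an lse oracle", {
  # uniform logits, k = 3 -> ln 3
  expect_equal(pseudo_label_loss(matrix(0, 4, 3), c(1, 2, 3, 1)), log(3),
               tolerance = 1e-12)
  # a dominant logit drives the loss toward zero
  expect_lt(pseudo_label_loss(matrix(c(50, 0, 0), 1), 1), 1e-12)
  expect_gt(pseudo_label_loss(matrix(c(50, 0, 0), 1), 2), 49)
  # random case against an independent log-sum-exp computation
  L <- withr::with_seed(1, matrix(rnorm(20 * 4, sd = 3), 20, 4))
  y <- withr::with_seed(2, sample(1:4, 20, TRUE))
  oracle <- mean(vapply(1:20, function(i) {
    log(sum(exp(L[i, ]))) - L[i, y[i]]
  }, numeric(1)))
  expect_equal(pseudo_label_loss(L, y), oracle, tolerance = 1e-9)
  expect_error(pseudo_label_loss(matrix(c(1, NA), 1), 1), "finite")
  expect_error(pseudo_label_loss(matrix(0, 2, 3), c(1, 4)), "range")
})

test_that("a zero learning rate leaves all parameters unchanged", {
  bb <- build_backbone(backbone_config("tiny", init_seed = 1))
  imgs <- generate_dataset(2, size = 64, rng_seed = 1)
  head <- new_classifier_head(128, 3, init_seed = 2)
  cfg <- train_config(learning_rate = 0, epochs = 1, rng_seed = 3)
  res <- train_epoch(bb, head, imgs, rep(1:3, 2), cfg, epoch_seed = 4)
  expect_equal(res$head$W, head$W)
  expect_equal(res$backbone$fc[[1]]$W, bb$fc[[1]]$W)
  expect_true(is.finite(res$loss))
})

test_that("one SGD step on one sample matches the analytic head gradient", {
  # frozen backbone = fixed features; head-only softmax regression
  x <- c(0.5, -1, 2)
  head <- list(W = matrix(c(0.1, -0.2, 0.3, 0, 0.2, -0.1), 2, 3, byrow = TRUE),
               b = c(0, 0), k = 2L)
  cfg <- train_config(learning_rate = 0.05, momentum = 0, batch_size = 1,
                      uniform_label_sampling = FALSE, clip_grad_norm = Inf)
  res <- ripecluster:::sgd_epoch(list(), head, matrix(x, 1), 1L, cfg,
                                 epoch_seed = 1)
  z <- as.vector(head$W %*% x + head$b)
  p <- exp(z) / sum(exp(z))
  grad_W <- (p - c(1, 0)) %*% t(x)      # d loss / d W for label 1
  expect_equal(res$head$W, head$W - 0.05 * grad_W, tolerance = 1e-12)
  expect_equal(res$head$b, head$b - 0.05 * (p - c(1, 0)), tolerance = 1e-12)
  expect_equal(res$loss, -log(p[1]), tolerance = 1e-12)
})

test_that("head-only training on a separable toy is non-increasing in loss", {
  X <- rbind(matrix(c(2, 0), 20, 2, byrow = TRUE),
             matrix(c(-2, 0), 20, 2, byrow = TRUE)) +
    withr::with_seed(5, matrix(rnorm(80, sd = 0.1), 40, 2))
  y <- rep(1:2, each = 20)
  head <- new_classifier_head(2, 2, init_seed = 6)
  cfg <- train_config(learning_rate = 0.01, momentum = 0, batch_size = 40,
                      uniform_label_sampling = FALSE, clip_grad_norm = Inf)
  losses <- numeric(6)
  state <- NULL
  for (e in 1:6) {
    res <- ripecluster:::sgd_epoch(list(), head, X, y, cfg, state = state,
                                   epoch_seed = e)
    losses[e] <- res$loss
    head <- res$head; state <- res$state
  }
  expect_true(all(diff(losses) <= 1e-10))
  expect_lt(losses[6], losses[1])
})

test_that("one loop round equals the manual composition of its stages", {
  imgs <- generate_dataset(5, size = 64, rng_seed = 20)
  bc <- backbone_config("tiny", init_seed = 21)
  cfg <- train_config(epochs = 1, rng_seed = 22)
  model <- run_deepcluster(imgs, bc, k = 3, config = cfg, n_restarts = 3)
  # manual composition with the same derived seeds
  bb <- build_backbone(bc)
  cf <- ripecluster:::extract_conv_features(bb, imgs)
  feats <- ripecluster:::fc_forward(bb$fc, cf)
  red <- fit_reduction(feats)
  reduced <- l2_normalize(apply_reduction(red, feats))
  cl <- kmeans_fit(reduced, 3, n_restarts = 3,
                   rng_seed = ripecluster:::derive_seed(22L, 1L, 1L))
  expect_identical(model$clustering$assignments, cl$assignments)
  head <- new_classifier_head(128, 3,
                              init_seed = ripecluster:::derive_seed(22L, 1L, 2L))
  res <- train_epoch(bb, head, imgs, cl$assignments, cfg, conv_features = cf,
                     epoch_seed = ripecluster:::derive_seed(22L, 1L, 3L))
  expect_equal(model$history$loss[1], res$loss, tolerance = 1e-12)
  expect_equal(model$head$W, res$head$W, tolerance = 1e-12)
})

test_that("two runs with identical seeds give identical histories", {
  imgs <- generate_dataset(4, size = 64, rng_seed = 30)
  run <- function() run_deepcluster(imgs, backbone_config("tiny", init_seed = 31),
                                    k = 3,
                                    config = train_config(epochs = 3, rng_seed = 32),
                                    n_restarts = 2)
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$head$W, m2$head$W)
  # cluster sizes never collapse to zero
  expect_true(all(as.matrix(m1$history[, grep("^size_", names(m1$history))]) > 0))
})

test_that("identify_maturity is deterministic and exposes softmax probabilities", {
  imgs <- generate_dataset(4, size = 64, rng_seed = 40)
  model <- run_deepcluster(imgs, backbone_config("tiny", init_seed = 41), k = 3,
                           config = train_config(epochs = 2, rng_seed = 42),
                           n_restarts = 2)
  img <- imgs[[1]]
  pred <- identify_maturity(model, list(img, img))
  expect_equal(pred[1], pred[2])
  probs <- attr(pred, "probabilities")
  expect_equal(unname(rowSums(probs)), c(1, 1), tolerance = 1e-12)
  expect_error(identify_maturity(structure(list(), class = "rc_model"), imgs),
               "trained")
})
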