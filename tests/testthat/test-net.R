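# Network: loss analytics, gradients, training and inference contracts.

test_that("loss matches its analytic values on degenerate inputs", {
  m <- array(c(1, 0, 0, 1, 0, 0, 0, 1), dim = c(2, 2, 2))
  big <- 20
  # prob == target (hard labels via saturated logits) -> loss ~ 0
  l0 <- attachment_loss(ifelse(m == 1, big, -big), m)
  expect_lt(l0$loss, 1e-3)
  # prob == 1 - target -> overlap 0; soft dice collapses to its
  # eps-smoothed floor 1/(sum p + sum m + 1), the dice loss term is maximal
  l1 <- attachment_loss(ifelse(m == 1, -big, big), m)
  expect_equal(l1$dice, 1 / (5 + 3 + 1), tolerance = 1e-3)
  # uniform prob 0.5: BCE term = ln 2 per voxel
  l2 <- attachment_loss(array(0, dim(m)), m)
  expect_equal(l2$bce, log(2), tolerance = 1e-12)
  expect_error(attachment_loss(array(0, c(2, 2, 2)), array(0.5, c(2, 2, 2))),
               "binary")
  expect_error(attachment_loss(numeric(7), m), "mismatch")
})

test_that("analytic loss gradients match finite differences on a toy grid", {
  cfg <- net_config(2, c(4, 4, 4), levels = 2, base_channels = 4, seed = 7)
  params <- attachnet:::net_init(cfg)
  pd <- attachnet:::padded_dims(cfg$dims, cfg$levels)
  set.seed(42)
  x <- matrix(rnorm(2 * prod(cfg$dims)), nrow = 2)
  mask <- array(rbinom(prod(cfg$dims), 1, 0.3), dim = cfg$dims)
  r <- attachnet:::net_sample_grad(params, cfg, x, mask, pd)
  g <- r$grads
  dirs <- lapply(g, function(layer) lapply(layer, function(p) {
    d <- p; d[] <- rnorm(length(p)); d
  }))
  gd <- 0
  for (nm in names(g)) for (pn in names(g[[nm]]))
    gd <- gd + sum(g[[nm]][[pn]] * dirs[[nm]][[pn]])
  h <- 1e-5
  shift <- function(s) {
    p2 <- params
    for (nm in names(g)) for (pn in names(g[[nm]]))
      p2[[nm]][[pn]] <- params[[nm]][[pn]] + s * dirs[[nm]][[pn]]
    attachnet:::net_sample_grad(p2, cfg, x, mask, pd, want_grad = FALSE)$loss
  }
  fd <- (shift(h) - shift(-h)) / (2 * h)
  expect_lt(abs(gd - fd) / abs(fd), 1e-4)
})

test_that("batched gradients equal the sum of per-sample gradients", {
  cfg <- net_config(1, c(4, 4, 4), levels = 2, base_channels = 4, seed = 9)
  params <- attachnet:::net_init(cfg)
  pd <- attachnet:::padded_dims(cfg$dims, cfg$levels)
  set.seed(4)
  xs <- lapply(1:3, function(i) matrix(rnorm(prod(cfg$dims)), nrow = 1))
  ms <- lapply(1:3, function(i) array(rbinom(prod(cfg$dims), 1, 0.3),
                                      dim = cfg$dims))
  rb <- attachnet:::net_batch_grad(params, cfg, xs, ms, pd)
  gsum <- NULL
  for (i in 1:3) {
    ri <- attachnet:::net_sample_grad(params, cfg, xs[[i]], ms[[i]], pd)
    if (is.null(gsum)) gsum <- ri$grads
    else for (nm in names(gsum)) for (pn in names(gsum[[nm]]))
      gsum[[nm]][[pn]] <- gsum[[nm]][[pn]] + ri$grads[[nm]][[pn]]
  }
  for (nm in names(gsum)) for (pn in names(gsum[[nm]]))
    expect_lt(max(abs(gsum[[nm]][[pn]] - rb$grads[[nm]][[pn]])),
              1e-8 * (1 + max(abs(gsum[[nm]][[pn]]))))
})

test_that("training is deterministic under a fixed seed and loss decreases", {
  ds <- fixture_dataset()
  model <- fixture_model()
  cfg <- net_config(3, model$grid$dims, levels = 2, base_channels = 6,
                    max_epochs = 5, patience = 100, val_fraction = 0, seed = 31)
  n1 <- train_attachment_net(ds, cfg, model = model)
  n2 <- train_attachment_net(ds, cfg, model = model)
  expect_identical(n1$log$train_loss[1], n2$log$train_loss[1])
  expect_identical(n1$params$head$W, n2$params$head$W)
  # learning sanity: loss decreases over the first epochs
  expect_lt(n1$log$train_loss[5], n1$log$train_loss[1])
})

test_that("the network has the capacity to memorize a small training set", {
  model <- fixture_model()
  ds <- generate_dataset(model, 10, 3, seed = 11)
  cfg <- net_config(3, model$grid$dims, levels = 2, base_channels = 8,
                    lr = 3e-3, max_epochs = 300, patience = 1e9,
                    val_fraction = 0, seed = 5)
  net <- train_attachment_net(ds, cfg, model = model)
  d <- vapply(ds$samples, function(s) {
    pr <- predict(net, array(s$df, dim = c(3, model$grid$dims)),
                  restrict_to_surface = FALSE)
    dice(pr$mask, s$mask > 0.5)
  }, numeric(1))
  # nearly all samples are memorized essentially perfectly; the plain
  # Dice+BCE objective occasionally pins one small-mask sample near zero
  # (a known small-target pathology), which caps the mean
  expect_gte(sum(d >= 0.95), 8)
  expect_gte(mean(d), 0.85)
})

test_that("input shape mismatches are rejected", {
  ds <- fixture_dataset()
  model <- fixture_model()
  cfg1 <- net_config(1, model$grid$dims, levels = 2, base_channels = 4,
                     max_epochs = 1, seed = 1)
  # F=3 dataset fed to an F=1 network
  expect_error(train_attachment_net(ds, cfg1, model = model), "channels")
  cfg_bad <- net_config(3, c(10, 10, 10), levels = 2, base_channels = 4,
                        max_epochs = 1, seed = 1)
  expect_error(train_attachment_net(ds, cfg_bad, model = model), "grid")
})

test_that("inference is deterministic, in range and shape-checked", {
  ds <- fixture_dataset()
  model <- fixture_model()
  cfg <- net_config(3, model$grid$dims, levels = 2, base_channels = 6,
                    max_epochs = 3, patience = 100, val_fraction = 0, seed = 8)
  net <- train_attachment_net(ds, cfg, model = model)
  df <- array(ds$samples[[1]]$df, dim = c(3, model$grid$dims))
  p1 <- predict(net, df)
  p2 <- predict(net, df)
  expect_identical(p1$prob, p2$prob)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_identical(dim(p1$prob), model$grid$dims)
  expect_error(predict(net, df[1:2, , , , drop = FALSE]), "shape")
  # duplicated identical frames are a valid input
  df_dup <- df
  df_dup[2, , , ] <- df[1, , , ]
  df_dup[3, , , ] <- df[1, , , ]
  expect_silent(predict(net, df_dup))
  # permuting input frames changes the probabilities measurably
  df_perm <- df[c(2, 3, 1), , , , drop = FALSE]
  expect_gt(mean(abs(predict(net, df_perm)$prob - p1$prob)), 0)
  # surface restriction confines the mask to surface voxels
  keep <- array(FALSE, dim = model$grid$dims)
  keep[net$surface_voxels] <- TRUE
  expect_true(all(keep[predict(net, df)$mask]))
})
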