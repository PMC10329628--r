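# Metrics, statistics and the registration validation protocol.

test_that("dice handles the standard and degenerate cases", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0)
  expect_equal(dice(a, b), 2 * 2 / (4 + 6))  # |A|=4, |B|=6, overlap 2 -> 0.4
  expect_equal(dice(a, a), 1)
  expect_equal(dice(c(1, 0), c(0, 1)), 0)
  expect_equal(dice(numeric(3), numeric(3)), 1)  # both empty
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(1, c(1, 0)), "mismatch")
})

test_that("dice complements the soft-dice loss term in the hard limit", {
  set.seed(2)
  m <- rbinom(200, 1, 0.3)
  p <- rbinom(200, 1, 0.3)
  l <- attachment_loss(ifelse(p == 1, 30, -30), m)
  # eps = 1 shifts the soft value slightly; compare with matching smoothing
  hard <- (2 * sum(p * m) + 1) / (sum(p) + sum(m) + 1)
  expect_equal(l$dice, hard, tolerance = 1e-6)
})

test_that("wilcoxon rank-sum matches exhaustive enumeration at 3 vs 3", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  w <- wilcoxon_ranksum(a, b)
  # oracle: enumerate all 20 assignments of ranks 1..6 to group A
  combs <- utils::combn(6, 3)
  rs <- colSums(matrix((1:6)[combs], nrow = 3))
  obs <- sum(rank(c(a, b))[1:3])
  p_exact <- mean(abs(rs - mean(rs)) >= abs(obs - mean(rs)) - 1e-9)
  expect_equal(w$p_value, p_exact, tolerance = 1e-12)
  expect_equal(p_exact, 0.1)  # smallest attainable two-sided p at 3 vs 3
  # identical constant samples -> p = 1
  expect_equal(wilcoxon_ranksum(rep(2, 5), rep(2, 4))$p_value, 1)
  # rank invariance under a common shift
  w2 <- wilcoxon_ranksum(a + 100, b + 100)
  expect_equal(w2$p_value, w$p_value)
})

test_that("lilliefors is calibrated on normal data and rejects exponential", {
  set.seed(9)
  reps <- replicate(40, lilliefors(rnorm(500))$p_value)
  expect_gte(mean(reps > 0.05), 0.90)
  expect_lt(lilliefors(rexp(200))$p_value, 0.01)
  s <- lilliefors(rnorm(100))$statistic
  expect_gte(s, 0); expect_lte(s, 1)
  expect_equal(lilliefors(rep(1, 10))$p_value, 0)
  expect_error(lilliefors(c(1, 2, 3)))
})

test_that("comparison reports are recomputable from raw errors", {
  set.seed(12)
  errs <- list(none = rexp(30, 1), good = rexp(30, 3))
  rep <- comparison_report(errs)
  expect_equal(rep$summary$median[1], median(errs$none))
  expect_equal(rep$summary$iqr[2], IQR(errs$good))
  expect_equal(rep$wilcoxon_p["none", "good"],
               wilcoxon_ranksum(errs$none, errs$good)$p_value)
  expect_true(all(rep$wilcoxon_p >= 0 & rep$wilcoxon_p <= 1, na.rm = TRUE))
})

test_that("order consistency enumerates permutations and handles stubs", {
  ds <- fixture_dataset()
  model <- fixture_model()
  cfg <- net_config(3, model$grid$dims, levels = 2, base_channels = 6,
                    max_epochs = 2, patience = 100, val_fraction = 0, seed = 3)
  net <- train_attachment_net(ds, cfg, model = model)
  df <- array(ds$samples[[1]]$df, dim = c(3, model$grid$dims))
  oc <- order_consistency(net, df)
  expect_equal(oc$n_orderings, 6L)  # 3! orderings
  expect_length(oc$dsc, 5L)
  expect_true(all(oc$dsc >= 0 & oc$dsc <= 1))
  # constant-output stub: saturate the head bias so every ordering predicts
  # the full surface mask
  stub <- net
  stub$params$head$W[] <- 0
  stub$params$head$b <- 30
  oc2 <- order_consistency(stub, df)
  expect_equal(unname(oc2$dsc), rep(1, 5))
  # F = 1: single ordering, consistency 1 by definition
  ds1 <- ds
  ds1$samples <- lapply(ds1$samples, function(s) {
    s$df <- s$df[1, , , , drop = FALSE]; s
  })
  cfg1 <- net_config(1, model$grid$dims, levels = 2, base_channels = 6,
                     max_epochs = 2, patience = 100, val_fraction = 0, seed = 3)
  net1 <- train_attachment_net(ds1, cfg1, model = model)
  oc1 <- order_consistency(net1, array(ds1$samples[[1]]$df,
                                       dim = c(1, model$grid$dims)))
  expect_equal(oc1$n_orderings, 1L)
  expect_equal(oc1$mean, 1)
})

test_that("registration cases split the cloud and score held-out errors", {
  model <- fixture_model()
  ds <- fixture_dataset()
  s <- ds$samples[[1]]
  fr <- s$frames_meta[[1]]
  case <- build_registration_case(model, fr, s$attachment$nodes,
                                  n_steps = 1L)
  expect_setequal(c(case$control_nodes, case$held_out_nodes),
                  fr$visible_nodes)
  expect_length(intersect(case$control_nodes, case$held_out_nodes), 0)
  expect_equal(length(case$control_nodes),
               max(3L, round(0.15 * length(fr$visible_nodes))))
  expect_true(all(case$errors_mm >= 0))
  # control points are the most deformed ones
  mag <- sqrt(rowSums(fr$displacements[fr$visible_nodes, ]^2))
  expect_gte(min(mag[fr$visible_nodes %in% case$control_nodes]),
             max(mag[fr$visible_nodes %in% case$held_out_nodes]) - 1e-12)
  # zero-deformation frame: all errors vanish for any candidate set
  fr0 <- fr
  fr0$displacements <- fr$displacements * 0
  case0 <- build_registration_case(model, fr0, integer(0), n_steps = 1L)
  expect_lt(max(case0$errors_mm), 1e-6)
  # degenerate cloud rejected
  fr_small <- fr
  fr_small$visible_nodes <- fr$visible_nodes[1:5]
  expect_error(build_registration_case(model, fr_small, integer(0)),
               "degenerate")
})

test_that("true attachments register better than no attachments", {
  model <- fixture_model()
  ds <- fixture_dataset()
  med_true <- med_none <- numeric(0)
  for (s in ds$samples[1:4]) {
    fr <- s$frames_meta[[1]]
    ct <- build_registration_case(model, fr, s$attachment$nodes, n_steps = 1L)
    cn <- build_registration_case(model, fr, integer(0), n_steps = 1L)
    med_true <- c(med_true, median(ct$errors_mm))
    med_none <- c(med_none, median(cn$errors_mm))
  }
  expect_lt(median(med_true), median(med_none))
})
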