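# Metrics and experiment drivers: Dice overlap against ground-truth
# attachment masks, frame-order consistency of multi-view predictions,
# registration-based validation with nodal target errors under candidate
# attachment sets, and the associated non-parametric statistics.

#' Dice similarity coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|); defined as 1 when both masks are empty (both
#' predict "no attachment").
#'
#' @param a,b binary arrays/vectors of equal shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("mask shape mismatch")
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Frame-order consistency of a multi-view prediction
#'
#' Runs the network on every permutation of the input frames and reports the
#' Dice overlap of each permuted prediction's mask with the first
#' (identity-order) prediction.
#'
#' @param net a trained \code{attachment_net} with F input channels, F <= 4.
#' @param df input array (F x n_x x n_y x n_z).
#' @param ... passed to \code{predict.attachment_net}.
#' @return list with \code{n_orderings}, \code{dsc} (vector, one per
#'   non-identity ordering), \code{mean}, \code{sd}.
#' @export
order_consistency <- function(net, df, ...) {
  if (is.null(net$params)) stop("untrained model")
  FF <- net$config$in_channels
  if (FF > 4) stop("factorial enumeration limited to F <= 4")
  perms <- permutations(FF)
  preds <- lapply(seq_len(nrow(perms)), function(i)
    predict(net, df[perms[i, ], , , , drop = FALSE], ...)$mask)
  dscs <- if (nrow(perms) > 1)
    vapply(preds[-1], dice, numeric(1), b = preds[[1]]) else numeric(0)
  list(n_orderings = nrow(perms), dsc = dscs,
       mean = if (length(dscs)) mean(dscs) else 1,
       sd = if (length(dscs) > 1) stats::sd(dscs) else 0)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Build a registration validation case from a simulated frame
#'
#' Mirrors the point-cloud protocol used for intraoperative validation: the
#' visible cloud is ranked by displacement magnitude, the most deformed
#' \code{control_fraction} (default 15 percent) drives the FE registration
#' as prescribed targets, the remainder is held out; the candidate
#' attachment set is fixed at zero displacement, the model is registered and
#' nodal L2 errors (mm) are measured on the held-out points.
#'
#' @param model a \code{hex_model}.
#' @param frame one frame of a sample record (with \code{visible_nodes} and
#'   \code{displacements}).
#' @param attachments candidate attachment node set (may be empty).
#' @param mat a \code{material}.
#' @param control_fraction fraction of the cloud used as control points.
#' @param ... passed to \code{\link{solve_static}}.
#' @return object of class \code{registration_case}: \code{control_nodes},
#'   \code{held_out_nodes}, \code{errors_mm} (held-out nodal L2 errors),
#'   \code{converged}.
#' @export
build_registration_case <- function(model, frame, attachments,
                                    mat = material(),
                                    control_fraction = 0.15, ...) {
  vis <- frame$visible_nodes
  if (length(vis) < 20) stop("degenerate cloud: fewer than 20 points")
  disp <- frame$displacements
  mag <- sqrt(rowSums(disp[vis, , drop = FALSE]^2))
  n_ctl <- max(3L, round(control_fraction * length(vis)))
  ctl <- vis[order(mag, decreasing = TRUE)[seq_len(n_ctl)]]
  held <- setdiff(vis, ctl)
  if (length(held) == 0L) stop("control set swallowed the whole cloud")
  # nodes already fixed by the candidate attachments cannot also be driven
  ctl_eff <- setdiff(ctl, attachments)
  targets <- model$nodes[ctl_eff, , drop = FALSE] +
    disp[ctl_eff, , drop = FALSE]
  res <- register_deformation(model, mat, attachments, ctl_eff, targets, ...)
  true_pos <- model$nodes[held, , drop = FALSE] + disp[held, , drop = FALSE]
  pred_pos <- model$nodes[held, , drop = FALSE] +
    res$displacements[held, , drop = FALSE]
  case <- list(control_nodes = ctl, held_out_nodes = held,
               errors_mm = 1000 * sqrt(rowSums((pred_pos - true_pos)^2)),
               converged = res$converged)
  class(case) <- "registration_case"
  case
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties, tie-corrected normal
#' approximation otherwise; two identical constant samples give p = 1.
#'
#' @param a,b numeric error samples (each n >= 2).
#' @return list with \code{statistic} (rank-sum W) and \code{p_value}.
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = length(a) <= 10 &&
                                              length(b) <= 10))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov distance to a normal distribution with estimated mean
#' and standard deviation. A zero-variance sample is degenerate and rejects
#' normality trivially.
#'
#' @param x numeric sample, n >= 4.
#' @return list with \code{statistic} (in [0, 1]) and \code{p_value}.
#' @export
lilliefors <- function(x) {
  stopifnot(length(x) >= 4)
  if (stats::sd(x) == 0) return(list(statistic = 1, p_value = 0))
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p_value = lt$p.value)
}

#' Summarize error distributions and pairwise tests across conditions
#'
#' @param errors named list of numeric error vectors (mm), one per
#'   attachment condition.
#' @return object of class \code{comparison_report}: per-condition median,
#'   IQR, mean, sd and normality p-value, plus a matrix of pairwise
#'   two-sided Wilcoxon rank-sum p-values; raw errors are retained so the
#'   summaries are recomputable.
#' @export
comparison_report <- function(errors) {
  stopifnot(is.list(errors), length(names(errors)) == length(errors))
  summary <- do.call(rbind, lapply(names(errors), function(nm) {
    e <- errors[[nm]]
    data.frame(condition = nm, n = length(e), median = stats::median(e),
               iqr = stats::IQR(e), mean = mean(e), sd = stats::sd(e),
               normality_p = if (length(e) >= 4) lilliefors(e)$p_value else NA)
  }))
  k <- length(errors)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(errors), names(errors)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    p <- wilcoxon_ranksum(errors[[i]], errors[[j]])$p_value
    pmat[i, j] <- pmat[j, i] <- p
  }
  rep <- list(summary = summary, wilcoxon_p = pmat, raw = errors)
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (errors in mm):\n")
  print(x$summary, row.names = FALSE)
  cat("pairwise two-sided Wilcoxon rank-sum p-values:\n")
  print(round(x$wilcoxon_p, 4))
  invisible(x)
}

#' Input-representation comparison experiment
#'
#' Trains and evaluates the three arms of the input-encoding comparison on
#' one shared synthetic dataset: (i) the displacement-based legacy encoding
#' (3 Gaussian-splatted displacement channels + SDF) with a single frame,
#' (ii) position distance fields with a single frame, (iii) position
#' distance fields with F frames, all at the same parameter and data budget.
#' Reports mean +/- sd test DSC per arm and the relative improvement of the
#' multi-frame arm over the single-frame position arm.
#'
#' @param mesh rest \code{surface_mesh} (for the legacy SDF channel).
#' @param model the \code{hex_model}.
#' @param train_ds,test_ds datasets generated on \code{model} with F frames.
#' @param frames F of the multi-frame arm (the datasets' frame count).
#' @param legacy_dims grid dims of the legacy encoding (historically 64^3;
#'   reduced grids keep the comparison budget-matched at desk scale).
#' @param net_args list of overrides for \code{\link{net_config}} shared by
#'   all arms (e.g. levels, base_channels, max_epochs).
#' @param seed seed for the arms' initialization/batching.
#' @param verbose print progress.
#' @return object of class \code{table_input_comparison}: data.frame
#'   \code{results} (arm, frames, dsc_mean, dsc_sd), scalar
#'   \code{improvement_pct} = (DSC_F - DSC_1)/DSC_1 * 100, and the trained
#'   nets.
#' @export
table1_experiment <- function(mesh, model, train_ds, test_ds,
                              frames = train_ds$frames,
                              legacy_dims = c(16L, 16L, 16L),
                              net_args = list(), seed = 1L,
                              verbose = FALSE) {
  stopifnot(train_ds$frames == frames, test_ds$frames == frames)
  dims <- model$grid$dims

  subset_frames <- function(ds, keep) {
    ds$samples <- lapply(ds$samples, function(s) {
      s$df <- s$df[keep, , , , drop = FALSE]
      s
    })
    ds$frames <- length(keep)
    ds
  }
  legacy_grid <- fit_grid(mesh, legacy_dims)
  legacy_sdf <- signed_distance_field(mesh, legacy_grid)
  add_legacy <- function(ds) {
    ds$samples <- lapply(ds$samples, function(s) {
      rec <- list(attachment = s$attachment, frames = s$frames_meta)
      s$legacy <- encode_legacy(rec, model, mesh, legacy_grid,
                                sdf = legacy_sdf)
      s$legacy_mask <- legacy_position_mask(s$attachment$nodes, model,
                                            legacy_grid)
      s
    })
    ds
  }

  cfg_of <- function(in_ch, dims_) do.call(net_config, utils::modifyList(
    list(in_channels = in_ch, dims = dims_, seed = seed), net_args))

  arms <- list()
  # legacy displacement arm (F = 1)
  if (verbose) message("arm 1/3: legacy displacement encoding (F=1)")
  tr_l <- add_legacy(train_ds); te_l <- add_legacy(test_ds)
  tr_l$samples <- lapply(tr_l$samples, function(s) { s$mask <- s$legacy_mask; s })
  te_l$samples <- lapply(te_l$samples, function(s) { s$mask <- s$legacy_mask; s })
  net_legacy <- train_attachment_net(tr_l, cfg_of(4L, legacy_grid$dims),
                                     inputs = "legacy", verbose = verbose)
  arms$legacy_displacement_f1 <- list(
    net = net_legacy,
    dsc = test_dsc(net_legacy, te_l$samples, inputs = "legacy"))
  # position arm, single frame
  if (verbose) message("arm 2/3: position distance field (F=1)")
  tr_1 <- subset_frames(train_ds, 1L); te_1 <- subset_frames(test_ds, 1L)
  net_f1 <- train_attachment_net(tr_1, cfg_of(1L, dims), model = model,
                                 verbose = verbose)
  arms$positions_f1 <- list(net = net_f1, dsc = test_dsc(net_f1, te_1$samples))
  # position arm, F frames
  if (verbose) message(sprintf("arm 3/3: position distance fields (F=%d)", frames))
  net_fF <- train_attachment_net(train_ds, cfg_of(as.integer(frames), dims),
                                 model = model, verbose = verbose)
  arms$positions_fF <- list(net = net_fF, dsc = test_dsc(net_fF, test_ds$samples))

  means <- vapply(arms, function(a) mean(a$dsc), numeric(1))
  res <- data.frame(
    arm = c("legacy displacement", "positions", "positions"),
    frames = c(1L, 1L, frames),
    dsc_mean = unname(means),
    dsc_sd = vapply(arms, function(a) stats::sd(a$dsc), numeric(1)))
  out <- list(results = res,
              improvement_pct = 100 * (means[["positions_fF"]] -
                                         means[["positions_f1"]]) /
                means[["positions_f1"]],
              arms = arms)
  class(out) <- "table_input_comparison"
  out
}

#' @export
print.table_input_comparison <- function(x, ...) {
  cat("input-representation comparison (test DSC):\n")
  df <- x$results
  df$dsc <- sprintf("%.3f +/- %.3f", df$dsc_mean, df$dsc_sd)
  print(df[, c("arm", "frames", "dsc")], row.names = FALSE)
  cat(sprintf("multi-frame improvement over single-frame positions: %.1f%%\n",
              x$improvement_pct))
  invisible(x)
}

# per-sample test DSC of a net on encoded samples
test_dsc <- function(net, samples, inputs = "df") {
  vapply(samples, function(s) {
    pr <- predict(net, array(s[[inputs]], dim = c(net$config$in_channels,
                                                  net$config$dims)))
    dice(pr$mask, s$mask > 0.5)
  }, numeric(1))
}

# attachment mask on an arbitrary grid by binning node rest positions
# (the legacy 64^3 arm has no node<->voxel bijection)
legacy_position_mask <- function(nodes, model, grid) {
  d <- grid$dims
  mask <- array(0, dim = d)
  if (length(nodes)) {
    ijk <- floor(sweep(model$nodes[nodes, , drop = FALSE], 2, grid$origin,
                       `-`) / grid$spacing)
    ijk[, 1] <- pmin(pmax(ijk[, 1], 0), d[1] - 1)
    ijk[, 2] <- pmin(pmax(ijk[, 2], 0), d[2] - 1)
    ijk[, 3] <- pmin(pmax(ijk[, 3], 0), d[3] - 1)
    mask[cell_index(ijk, d)] <- 1
  }
  mask
}
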