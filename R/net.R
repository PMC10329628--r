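# Volumetric U-shaped convolutional network mapping F distance-field
# channels to a per-voxel attachment probability.  Feature maps are stored
# as (channels x voxels) matrices in x-fastest voxel order, so 3x3x3
# convolutions are im2col + BLAS matrix products; max-pooling halves each
# axis and nearest-neighbour upsampling with skip concatenation restores it.
# Trained with BCE + soft-Dice loss and AdamW.  Everything (forward,
# backward, optimizer) is explicit, which keeps inference and training
# deterministic and dependency-free.

#' Network configuration
#'
#' @param in_channels number of input channels (F frames, or 4 for the
#'   displacement-based legacy encoding).
#' @param dims grid dims (n_x, n_y, n_z) the network operates on.
#' @param levels resolution levels (default 3); inputs are zero-padded to a
#'   multiple of 2^(levels-1) per axis and cropped back.
#' @param base_channels channels at the finest level, doubled per level.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay (conv weights only).
#' @param batch_size minibatch size (default 5).
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation loss.
#' @param val_fraction held-out validation fraction of the training set.
#' @param seed RNG seed for initialization and batching.
#' @param threshold probability cutoff for the binary mask.
#' @param norm use per-channel instance normalization (default TRUE).
#' @return object of class \code{net_config}.
#' @export
net_config <- function(in_channels, dims, levels = 3L, base_channels = 16L,
                       lr = 1e-3, weight_decay = 1e-2, batch_size = 5L,
                       max_epochs = 60L, patience = 8L, val_fraction = 0.1,
                       seed = 1L, threshold = 0.5, norm = TRUE) {
  stopifnot(in_channels >= 1, length(dims) == 3, levels >= 1,
            threshold > 0, threshold < 1)
  cfg <- list(in_channels = as.integer(in_channels), dims = as.integer(dims),
              levels = as.integer(levels),
              base_channels = as.integer(base_channels), lr = lr,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              val_fraction = val_fraction, seed = as.integer(seed),
              threshold = threshold, norm = isTRUE(norm))
  class(cfg) <- "net_config"
  cfg
}

# padded dims: multiple of 2^(levels-1), at least 2^(levels-1)
padded_dims <- function(dims, levels) {
  m <- 2L^(levels - 1L)
  as.integer(ceiling(dims / m) * m)
}

channels_at <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

# conv parameter spec: list(name, cin, cout, k) with k in {1, 3}
net_layer_specs <- function(cfg) {
  L <- cfg$levels
  specs <- list()
  for (l in seq_len(L)) {
    cin <- if (l == 1) cfg$in_channels else channels_at(cfg, l - 1)
    specs[[paste0("enc", l, "a")]] <- c(cin = cin, cout = channels_at(cfg, l))
    specs[[paste0("enc", l, "b")]] <- c(cin = channels_at(cfg, l),
                                        cout = channels_at(cfg, l))
  }
  if (L > 1) for (l in (L - 1):1) {
    specs[[paste0("dec", l, "a")]] <- c(cin = channels_at(cfg, l) +
                                          channels_at(cfg, l + 1),
                                        cout = channels_at(cfg, l))
    specs[[paste0("dec", l, "b")]] <- c(cin = channels_at(cfg, l),
                                        cout = channels_at(cfg, l))
  }
  specs
}

# He-normal initialization of all parameters
net_init <- function(cfg) {
  specs <- net_layer_specs(cfg)
  params <- list()
  with_seed(substream_seed(cfg$seed, "net-init"), {
    for (nm in names(specs)) {
      cin <- specs[[nm]]["cin"]; cout <- specs[[nm]]["cout"]
      params[[nm]] <- list(
        W = matrix(stats::rnorm(cout * 27 * cin, sd = sqrt(2 / (27 * cin))),
                   nrow = cout),
        b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout))
    }
    c1 <- channels_at(cfg, 1)
    params$head <- list(W = matrix(stats::rnorm(c1, sd = sqrt(1 / c1)),
                                   nrow = 1),
                        b = 0)
  })
  params
}

# ---- layer primitives -------------------------------------------------

# expand a (C x B) per-sample statistic to (C x V*B)
expand_stat <- function(m, V) m[, rep(seq_len(ncol(m)), each = V), drop = FALSE]

conv_block_fwd <- function(par, x, d, B, norm) {
  cin <- nrow(x)
  V <- prod(d)
  cols <- cpp_im2col3(x, cin, d[1], d[2], d[3], B)
  z <- par$W %*% cols + par$b
  if (norm) {
    # instance normalization: per channel, per sample
    mu <- cpp_block_rowmeans(z, V, B)
    v <- cpp_block_rowmeans(z^2, V, B) - mu^2
    sE <- expand_stat(sqrt(v + 1e-5), V)
    xhat <- (z - expand_stat(mu, V)) / sE
    y <- xhat * par$gamma + par$beta
  } else {
    xhat <- NULL; sE <- NULL
    y <- z
  }
  mask <- y > 0
  y[!mask] <- 0
  list(y = y, cache = list(cols = cols, cin = cin, d = d, B = B, V = V,
                           xhat = xhat, sE = sE, mask = mask))
}

conv_block_bwd <- function(par, cache, gy, norm) {
  g <- gy * cache$mask
  if (norm) {
    dgamma <- rowSums(g * cache$xhat)
    dbeta <- rowSums(g)
    dxhat <- g * par$gamma
    m1 <- expand_stat(cpp_block_rowmeans(dxhat, cache$V, cache$B), cache$V)
    m2 <- expand_stat(cpp_block_rowmeans(dxhat * cache$xhat, cache$V, cache$B),
                      cache$V)
    gz <- (dxhat - m1 - cache$xhat * m2) / cache$sE
  } else {
    dgamma <- numeric(length(par$gamma)); dbeta <- numeric(length(par$beta))
    gz <- g
  }
  dW <- tcrossprod(gz, cache$cols)
  db <- rowSums(gz)
  gcols <- crossprod(par$W, gz)
  d <- cache$d
  dx <- matrix(cpp_col2im3(gcols, cache$cin, d[1], d[2], d[3], cache$B),
               nrow = cache$cin)
  list(dx = dx, grads = list(W = dW, b = db, gamma = dgamma, beta = dbeta))
}

# ---- full network -----------------------------------------------------

# x: (in_channels x prod(pdims)*B) matrix; B samples stacked along z
unet_forward <- function(params, cfg, x, pdims, B = 1L) {
  L <- cfg$levels
  caches <- list()
  run <- function(l, x, d) {
    a <- conv_block_fwd(params[[paste0("enc", l, "a")]], x, d, B, cfg$norm)
    b <- conv_block_fwd(params[[paste0("enc", l, "b")]], a$y, d, B, cfg$norm)
    caches[[paste0("enc", l, "a")]] <<- a$cache
    caches[[paste0("enc", l, "b")]] <<- b$cache
    if (l == L) return(b$y)
    pl <- cpp_maxpool3(b$y, nrow(b$y), d[1], d[2], d[3] * B)
    caches[[paste0("pool", l)]] <<- list(arg = pl$arg, n_in = length(b$y),
                                         c = nrow(b$y))
    sub <- run(l + 1, matrix(pl$y, nrow = nrow(b$y)), d %/% 2L)
    up <- matrix(cpp_upsample3(sub, nrow(sub), d[1] %/% 2L, d[2] %/% 2L,
                               d[3] %/% 2L * B), nrow = nrow(sub))
    cat_ <- rbind(up, b$y)
    da <- conv_block_fwd(params[[paste0("dec", l, "a")]], cat_, d, B, cfg$norm)
    db <- conv_block_fwd(params[[paste0("dec", l, "b")]], da$y, d, B, cfg$norm)
    caches[[paste0("dec", l, "a")]] <<- da$cache
    caches[[paste0("dec", l, "b")]] <<- db$cache
    caches[[paste0("split", l)]] <<- nrow(sub)
    db$y
  }
  y1 <- run(1L, x, pdims)
  logits <- params$head$W %*% y1 + params$head$b
  list(logits = as.numeric(logits), y1 = y1, caches = caches, B = B)
}

unet_backward <- function(params, cfg, fwd, dlogits, pdims) {
  L <- cfg$levels
  B <- fwd$B
  caches <- fwd$caches
  grads <- list()
  grads$head <- list(W = tcrossprod(matrix(dlogits, nrow = 1), fwd$y1),
                     b = sum(dlogits))
  gy1 <- crossprod(params$head$W, matrix(dlogits, nrow = 1))
  back <- function(l, gy, d) {
    if (l < L) {
      db <- conv_block_bwd(params[[paste0("dec", l, "b")]],
                           caches[[paste0("dec", l, "b")]], gy, cfg$norm)
      grads[[paste0("dec", l, "b")]] <<- db$grads
      da <- conv_block_bwd(params[[paste0("dec", l, "a")]],
                           caches[[paste0("dec", l, "a")]], db$dx, cfg$norm)
      grads[[paste0("dec", l, "a")]] <<- da$grads
      csub <- caches[[paste0("split", l)]]
      gup <- da$dx[seq_len(csub), , drop = FALSE]
      gskip <- da$dx[-seq_len(csub), , drop = FALSE]
      gsub <- matrix(cpp_upsample3_adj(gup, csub, d[1] %/% 2L, d[2] %/% 2L,
                                       d[3] %/% 2L * B), nrow = csub)
      gpool_out <- back(l + 1, gsub, d %/% 2L)
      pc <- caches[[paste0("pool", l)]]
      genc_b <- matrix(cpp_maxunpool3(gpool_out, pc$arg, pc$n_in),
                       nrow = pc$c) + gskip
    } else {
      genc_b <- gy
    }
    b <- conv_block_bwd(params[[paste0("enc", l, "b")]],
                        caches[[paste0("enc", l, "b")]], genc_b, cfg$norm)
    grads[[paste0("enc", l, "b")]] <<- b$grads
    a <- conv_block_bwd(params[[paste0("enc", l, "a")]],
                        caches[[paste0("enc", l, "a")]], b$dx, cfg$norm)
    grads[[paste0("enc", l, "a")]] <<- a$grads
    if (l == 1) return(invisible(NULL))
    a$dx
  }
  back(1L, gy1, pdims)
  grads
}

# ---- loss -------------------------------------------------------------

#' Dice + binary-cross-entropy segmentation loss
#'
#' loss = BCE(sigmoid(logits), mask) + (1 - softDice), with BCE averaged per
#' voxel and softDice = (2 sum(p m) + eps) / (sum p + sum m + eps), eps = 1.
#'
#' @param logits numeric vector/array of pre-sigmoid network outputs.
#' @param mask binary target of the same length.
#' @return list with \code{loss}, \code{bce}, \code{dice} (soft Dice value),
#'   and \code{dlogits} (gradient of the loss w.r.t. the logits).
#' @export
attachment_loss <- function(logits, mask) {
  z <- as.numeric(logits)
  m <- as.numeric(mask)
  if (length(z) != length(m)) stop("logit / mask shape mismatch")
  if (any(m != 0 & m != 1)) stop("target mask must be binary")
  nv <- length(z)
  p <- 1 / (1 + exp(-z))
  bce <- mean(pmax(z, 0) - z * m + log1p(exp(-abs(z))))
  eps <- 1
  A <- sum(p * m); B <- sum(p) + sum(m)
  dice <- (2 * A + eps) / (B + eps)
  dD_dp <- (2 * m * (B + eps) - (2 * A + eps)) / (B + eps)^2
  # BCE gradient is exact in the logits; the dice term chains through sigmoid
  dlogits <- (p - m) / nv - dD_dp * p * (1 - p)
  list(loss = bce + (1 - dice), bce = bce, dice = dice, dlogits = dlogits)
}

# zero-pad (C x V) map from dims to pdims; returns matrix (C x prod(pdims))
pad_map <- function(x, dims, pdims) {
  if (all(dims == pdims)) return(x)
  C <- nrow(x)
  arr <- array(0, dim = c(C, pdims))
  arr[, seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <-
    array(x, dim = c(C, dims))
  matrix(arr, nrow = C)
}

crop_vec <- function(v, pdims, dims) {
  if (all(dims == pdims)) return(array(v, dim = dims))
  arr <- array(v, dim = pdims)
  arr[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])]
}

embed_vec <- function(v, dims, pdims) {
  if (all(dims == pdims)) return(as.numeric(v))
  arr <- array(0, dim = pdims)
  arr[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- v
  as.numeric(arr)
}

# loss and (summed) gradient for a minibatch of samples
net_batch_grad <- function(params, cfg, xs, masks, pdims, want_grad = TRUE) {
  B <- length(xs)
  Vp <- prod(pdims)
  xp <- do.call(cbind, lapply(xs, pad_map, dims = cfg$dims, pdims = pdims))
  fwd <- unet_forward(params, cfg, xp, pdims, B)
  losses <- numeric(B)
  dices <- numeric(B)
  logits_list <- vector("list", B)
  dl <- if (want_grad) numeric(Vp * B)
  for (b in seq_len(B)) {
    sl <- fwd$logits[(b - 1L) * Vp + seq_len(Vp)]
    logits <- crop_vec(sl, pdims, cfg$dims)
    ls <- attachment_loss(logits, masks[[b]])
    losses[b] <- ls$loss
    dices[b] <- ls$dice
    logits_list[[b]] <- logits
    if (want_grad)
      dl[(b - 1L) * Vp + seq_len(Vp)] <-
        embed_vec(array(ls$dlogits, dim = cfg$dims), cfg$dims, pdims)
  }
  out <- list(losses = losses, dices = dices, logits = logits_list)
  if (want_grad) out$grads <- unet_backward(params, cfg, fwd, dl, pdims)
  out
}

# single-sample convenience wrapper (gradient checks, prediction internals)
net_sample_grad <- function(params, cfg, x, mask, pdims, want_grad = TRUE) {
  r <- net_batch_grad(params, cfg, list(x), list(mask), pdims, want_grad)
  list(loss = r$losses[1], dice = r$dices[1], logits = r$logits[[1]],
       grads = r$grads)
}

# ---- optimizer --------------------------------------------------------

adamw_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adamw_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[pn]] / (1 - beta1^t)
      vhat <- state$v[[nm]][[pn]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (pn == "W") upd <- upd + lr * wd * params[[nm]][[pn]]
      params[[nm]][[pn]] <- params[[nm]][[pn]] - upd
    }
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------

#' Train the attachment network on a synthetic dataset
#'
#' Splits the dataset 90/10 into train/validation (seeded), minimizes the
#' Dice+BCE loss with AdamW, and applies early stopping on the validation
#' loss, returning the best-validation parameters.
#'
#' @param dataset an \code{attachment_dataset} (or any list of samples with
#'   \code{df} and \code{mask}), with frame count matching
#'   \code{cfg$in_channels}.
#' @param cfg a \code{\link{net_config}}.
#' @param model optional \code{hex_model}; when given, the voxels of its
#'   surface nodes are stored so predictions can be restricted to
#'   physically meaningful (surface) voxels.
#' @param inputs optional name of the per-sample input field (default
#'   \code{"df"}; the legacy arm trains on \code{"legacy"} encodings).
#' @param verbose print per-epoch progress.
#' @return object of class \code{attachment_net} with \code{params},
#'   \code{config}, \code{log} (per-epoch train/val loss and val DSC) and
#'   \code{best_epoch}.
#' @export
train_attachment_net <- function(dataset, cfg, model = NULL, inputs = "df",
                                 verbose = FALSE) {
  stopifnot(inherits(cfg, "net_config"))
  samples <- dataset$samples
  if (length(samples) == 0L) stop("empty dataset")
  getx <- function(s) {
    x <- s[[inputs]]
    if (is.null(dim(x))) stop("sample lacks input field ", inputs)
    nc <- dim(x)[1]
    if (nc != cfg$in_channels)
      stop(sprintf("input has %d channels but the network expects %d",
                   nc, cfg$in_channels))
    matrix(x, nrow = nc)
  }
  d0 <- dim(samples[[1]][[inputs]])[-1]
  if (!all(d0 == cfg$dims))
    stop(sprintf("input grid %s does not match network grid %s",
                 paste(d0, collapse = "x"), paste(cfg$dims, collapse = "x")))
  pdims <- padded_dims(cfg$dims, cfg$levels)
  params <- net_init(cfg)
  state <- list(m = adamw_init(params), v = adamw_init(params))
  n <- length(samples)
  log <- NULL
  best <- list(loss = Inf, params = params, epoch = 0L)
  with_seed(substream_seed(cfg$seed, "train"), {
    n_val <- max(if (n >= 10) 1L else 0L, round(cfg$val_fraction * n))
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    t_step <- 0L
    bad_epochs <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      tr_loss <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        r <- net_batch_grad(params, cfg,
                            lapply(samples[batch], getx),
                            lapply(samples[batch], `[[`, "mask"), pdims)
        gacc <- r$grads
        for (nm in names(gacc)) for (pn in names(gacc[[nm]]))
          gacc[[nm]][[pn]] <- gacc[[nm]][[pn]] / length(batch)
        t_step <- t_step + 1L
        st <- adamw_step(params, gacc, state, cfg$lr, cfg$weight_decay, t_step)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + sum(r$losses)
      }
      tr_loss <- tr_loss / length(ord)
      # validation
      if (length(val_idx)) {
        vl <- 0; vd <- 0
        for (start in seq(1, length(val_idx), by = cfg$batch_size)) {
          vb <- val_idx[start:min(start + cfg$batch_size - 1L, length(val_idx))]
          r <- net_batch_grad(params, cfg, lapply(samples[vb], getx),
                              lapply(samples[vb], `[[`, "mask"), pdims,
                              want_grad = FALSE)
          vl <- vl + sum(r$losses)
          for (k in seq_along(vb)) {
            pm <- (1 / (1 + exp(-r$logits[[k]]))) >= cfg$threshold
            vd <- vd + dice(pm, samples[[vb[k]]]$mask > 0.5)
          }
        }
        vl <- vl / length(val_idx); vd <- vd / length(val_idx)
      } else {
        vl <- tr_loss; vd <- NA_real_
      }
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = vl, val_dsc = vd))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val DSC %.3f",
                        epoch, tr_loss, vl, vd))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= cfg$patience) break
      }
    }
  })
  net <- list(params = best$params, config = cfg, log = log,
              best_epoch = best$epoch,
              surface_voxels = if (!is.null(model))
                cell_index(model$node_to_voxel[model$surface_nodes, ,
                                               drop = FALSE], cfg$dims))
  class(net) <- "attachment_net"
  net
}

#' @export
print.attachment_net <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("attachment_net: %d input channels, grid %s, %d levels, %d parameters\n",
              cfg$in_channels, paste(cfg$dims, collapse = "x"), cfg$levels, np))
  if (!is.null(x$log))
    cat(sprintf("  trained %d epochs (best val loss %.4f at epoch %d)\n",
                nrow(x$log), min(x$log$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict an attachment mask from distance-field input
#'
#' Deterministic inference: forward pass, sigmoid, threshold. When the
#' network stores the model's surface voxels and
#' \code{restrict_to_surface} is on, the binary mask is intersected with
#' them (interior attachment voxels are physically meaningless).
#'
#' @param object a trained \code{attachment_net}.
#' @param df input array (in_channels x n_x x n_y x n_z).
#' @param restrict_to_surface intersect the mask with surface voxels when
#'   available (default TRUE).
#' @param ... unused.
#' @return list with \code{prob} (3D array in [0,1]) and \code{mask}
#'   (binary 3D array at the configured threshold).
#' @export
predict.attachment_net <- function(object, df, restrict_to_surface = TRUE,
                                   ...) {
  cfg <- object$config
  dm <- dim(df)
  if (length(dm) != 4 || dm[1] != cfg$in_channels || !all(dm[-1] == cfg$dims))
    stop(sprintf("input shape (%s) does not match network (%d x %s)",
                 paste(dm, collapse = ","), cfg$in_channels,
                 paste(cfg$dims, collapse = "x")))
  pdims <- padded_dims(cfg$dims, cfg$levels)
  xp <- pad_map(matrix(df, nrow = cfg$in_channels), cfg$dims, pdims)
  fwd <- unet_forward(object$params, cfg, xp, pdims)
  prob <- array(1 / (1 + exp(-crop_vec(fwd$logits, pdims, cfg$dims))),
                dim = cfg$dims)
  mask <- prob >= cfg$threshold
  if (restrict_to_surface && !is.null(object$surface_voxels)) {
    keep <- array(FALSE, dim = cfg$dims)
    keep[object$surface_voxels] <- TRUE
    mask <- mask & keep
  }
  list(prob = prob, mask = mask)
}
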