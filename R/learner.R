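# A small 3D encoder-decoder segmentation learner with softmax output.
# Architecture (channels C = n_channels_base):
#   conv 3^3 (1 -> C) + ReLU
#   avgpool 2x  ->  conv 3^3 (C -> 2C) + ReLU  ->  nearest upsample 2x
#   skip-concatenate -> conv 3^3 (3C -> C) + ReLU -> conv 1^3 (C -> 4)
#   softmax over classes
# Trained with SGD on cross-entropy plus soft-Dice loss over randomly sampled
# patches (foreground-oversampled so rare classes are seen). Deliberately far
# smaller than clinical segmentation networks: the benchmarking logic being
# exercised is architecture-agnostic.

#' Initialize model weights from a configuration and seed
#'
#' Deterministic for a fixed (config, seed) pair, so independent sites holding
#' the same global configuration initialize identically.
#'
#' @param config an `fsb_model_config`.
#' @param seed integer seed.
#' @return an object of class `fsb_model_weights`: named parameter blocks
#'   plus the `config_hash` of the configuration that shaped them.
#' @export
init_model <- function(config, seed = 1L) {
  C <- config$n_channels_base
  K <- config$n_classes
  he <- function(dims) {
    fan_in <- prod(dims[seq_len(4)])
    array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
  }
  blocks <- with_seed(derive_seed(seed, "init"), list(
    w1 = he(c(3, 3, 3, 1, C)), b1 = numeric(C),
    w2 = he(c(3, 3, 3, C, 2 * C)), b2 = numeric(2 * C),
    w3 = he(c(3, 3, 3, 3 * C, C)), b3 = numeric(C),
    w4 = he(c(1, 1, 1, C, K)), b4 = numeric(K)
  ))
  structure(list(blocks = blocks, config_hash = config$config_hash,
                 trained_sites = character()),
            class = "fsb_model_weights")
}

#' @export
print.fsb_model_weights <- function(x, ...) {
  np <- sum(vapply(x$blocks, length, 0L))
  cat(sprintf("<model weights>: %d parameters in %d blocks (config %s)%s\n",
              np, length(x$blocks), substr(x$config_hash, 1, 8),
              if (length(x$trained_sites))
                sprintf(", trained on {%s}",
                        paste(x$trained_sites, collapse = ", ")) else ""))
  invisible(x)
}

#' Flatten model weights to a single numeric vector (and back)
#'
#' The round trip `unflatten_weights(flatten_weights(w), w)` is lossless.
#'
#' @param w an `fsb_model_weights`.
#' @return numeric vector of all parameters in block order.
#' @export
flatten_weights <- function(w) {
  unlist(lapply(w$blocks, as.numeric), use.names = FALSE)
}

#' @rdname flatten_weights
#' @param vec numeric vector as produced by [flatten_weights()].
#' @param template an `fsb_model_weights` supplying block names and shapes.
#' @export
unflatten_weights <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template$blocks)) {
    blk <- template$blocks[[nm]]
    n <- length(blk)
    piece <- vec[pos + seq_len(n)]
    if (!is.null(dim(blk))) dim(piece) <- dim(blk)
    out$blocks[[nm]] <- piece
    pos <- pos + n
  }
  abort_if(pos != length(vec), "weight vector length mismatch")
  out
}

# forward pass keeping intermediates for backprop; x is (D,H,W,1)
net_forward <- function(blocks, x) {
  dims <- dim(x)
  a1 <- conv3d_fwd(x, blocks$w1, blocks$b1, dim(x), dim(blocks$w1))
  r1 <- pmax(a1, 0); dim(r1) <- dim(a1)
  p <- avgpool2_fwd(r1, dim(r1))
  a2 <- conv3d_fwd(p, blocks$w2, blocks$b2, dim(p), dim(blocks$w2))
  r2 <- pmax(a2, 0); dim(r2) <- dim(a2)
  u <- upsample2_fwd(r2, dim(r2))
  cat4 <- array(c(r1, u), dim = c(dims[1:3], dim(r1)[4] + dim(u)[4]))
  a3 <- conv3d_fwd(cat4, blocks$w3, blocks$b3, dim(cat4), dim(blocks$w3))
  r3 <- pmax(a3, 0); dim(r3) <- dim(a3)
  logits <- conv3d_fwd(r3, blocks$w4, blocks$b4, dim(r3), dim(blocks$w4))
  list(x = x, a1 = a1, r1 = r1, p = p, a2 = a2, r2 = r2, u = u,
       cat4 = cat4, a3 = a3, r3 = r3, logits = logits)
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  pr <- e / rowSums(e)
  array(pr, dim = d)
}

# gradient of (cross-entropy + soft-Dice) w.r.t. logits, given softmax
# probabilities P (D,H,W,K) and one-hot targets Y. The Dice term averages
# over the classes present in the patch, so absent classes are not actively
# suppressed by every patch that happens to lack them.
loss_and_grad <- function(P, Y) {
  d <- dim(P)
  nvox <- prod(d[1:3])
  K <- d[4]
  eps <- 1e-5
  Pm <- matrix(P, ncol = K)
  Ym <- matrix(Y, ncol = K)
  ce <- -mean(log(pmax(rowSums(Pm * Ym), 1e-12)))
  s_py <- colSums(Pm * Ym)
  s_p <- colSums(Pm)
  s_y <- colSums(Ym)
  present <- which(s_y > 0)
  num <- 2 * s_py + eps
  den <- s_p + s_y + eps
  dice <- 1 - mean((num / den)[present])
  # dL/dP for the Dice part, then chain through softmax together with CE
  gP <- matrix(0, nrow = nvox, ncol = K)
  for (k in present)
    gP[, k] <- -(2 * Ym[, k] / den[k] - num[k] / den[k]^2) / length(present)
  dot <- rowSums(gP * Pm)
  glog_dice <- Pm * (gP - dot)
  glog <- (Pm - Ym) / nvox + glog_dice
  list(loss = ce + dice, glogits = array(glog, dim = d))
}

net_backward <- function(blocks, fw, glogits) {
  C <- dim(blocks$w1)[5]
  g4 <- conv3d_bwd(fw$r3, blocks$w4, glogits, dim(fw$r3), dim(blocks$w4))
  da3 <- g4$gx * (fw$a3 > 0); dim(da3) <- dim(fw$a3)
  g3 <- conv3d_bwd(fw$cat4, blocks$w3, da3, dim(fw$cat4), dim(blocks$w3))
  gcat <- g3$gx
  d <- dim(fw$r1)
  n1 <- prod(d)
  gr1 <- array(gcat[seq_len(n1)], dim = d)
  gu <- array(gcat[n1 + seq_len(length(gcat) - n1)], dim = dim(fw$u))
  gr2 <- upsample2_bwd(gu, dim(fw$r2))
  da2 <- gr2 * (fw$a2 > 0); dim(da2) <- dim(fw$a2)
  g2 <- conv3d_bwd(fw$p, blocks$w2, da2, dim(fw$p), dim(blocks$w2))
  gr1 <- gr1 + avgpool2_bwd(g2$gx, dim(fw$r1))
  da1 <- gr1 * (fw$a1 > 0); dim(da1) <- dim(fw$a1)
  g1 <- conv3d_bwd(fw$x, blocks$w1, da1, dim(fw$x), dim(blocks$w1))
  list(w1 = g1$gw, b1 = g1$gb, w2 = g2$gw, b2 = g2$gb,
       w3 = g3$gw, b3 = g3$gb, w4 = g4$gw, b4 = g4$gb)
}

one_hot4 <- function(mask, K) {
  d <- dim(mask)
  Y <- matrix(0, nrow = prod(d), ncol = K)
  Y[cbind(seq_len(prod(d)), as.integer(mask) + 1L)] <- 1
  array(Y, dim = c(d, K))
}

# sample a patch origin; with probability `oversample` the patch is centred on
# a random foreground voxel of a random class present in the case
sample_patch_origin <- function(mask, psize, oversample) {
  d <- dim(mask)
  abort_if(any(psize > d), "patch larger than volume")
  if (runif(1) < oversample) {
    present <- sort(unique(mask[mask > 0]))
    if (length(present)) {
      cls <- if (length(present) == 1) present else
        present[sample.int(length(present), 1)]
      idx <- which(mask == cls)
      v <- idx[sample.int(length(idx), 1)]
      ctr <- arrayInd(v, d)
      org <- pmin(pmax(as.integer(ctr) - psize %/% 2L, 1L),
                  d - psize + 1L)
      return(org)
    }
  }
  vapply(seq_len(3), function(a)
    if (d[a] == psize[a]) 1L else sample.int(d[a] - psize[a] + 1L, 1), 0L)
}

#' Train model weights for one local epoch
#'
#' Performs `config$batches_per_epoch` optimizer steps (SGD with momentum and
#' global gradient-norm clipping; the velocity is reset at the start of every
#' epoch, so a local epoch is self-contained and no optimizer state crosses
#' federation rounds) on randomly sampled patches of the site's training
#' cases, oversampling pathology-containing patches so every present class is
#' drawn with nonzero probability. Deterministic given (weights, data,
#' config, `epoch_seed`). The mean batch loss of the epoch is attached as
#' attribute `"epoch_loss"`.
#'
#' @param w an `fsb_model_weights` matching `config`.
#' @param train_cases a preprocessed `fsb_site_dataset` (training subset).
#' @param config the shared `fsb_model_config`.
#' @param epoch_seed integer seed for this epoch's sampling.
#' @return updated `fsb_model_weights`.
#' @export
train_local_epoch <- function(w, train_cases, config, epoch_seed = 1L) {
  abort_if(!identical(w$config_hash, config$config_hash),
           "weights were initialized under a different configuration")
  n <- length(train_cases$volumes)
  abort_if(n < 1L, "no training cases")
  psize <- config$patch_size
  lr <- config$learning_rate
  K <- config$n_classes
  losses <- numeric(config$batches_per_epoch)
  momentum <- config$momentum %||% 0
  clip <- config$clip_grad_norm %||% Inf
  vel <- NULL
  with_seed(epoch_seed, {
    for (b in seq_len(config$batches_per_epoch)) {
      gacc <- NULL
      lsum <- 0
      for (s in seq_len(config$batch_size)) {
        ci <- sample.int(n, 1)
        m <- train_cases$masks[[ci]]
        org <- sample_patch_origin(m, psize, config$foreground_oversample)
        sl <- lapply(seq_len(3), function(a) org[a] + seq_len(psize[a]) - 1L)
        xp <- train_cases$volumes[[ci]][sl[[1]], sl[[2]], sl[[3]],
                                        drop = FALSE]
        mp <- m[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
        dim(xp) <- c(psize, 1L)
        fw <- net_forward(w$blocks, xp)
        P <- softmax4(fw$logits)
        lg <- loss_and_grad(P, one_hot4(mp, K))
        lsum <- lsum + lg$loss
        g <- net_backward(w$blocks, fw, lg$glogits)
        gacc <- if (is.null(gacc)) g else mapply(`+`, gacc, g,
                                                 SIMPLIFY = FALSE)
      }
      losses[b] <- lsum / config$batch_size
      gacc <- lapply(gacc, `/`, config$batch_size)
      gnorm <- sqrt(sum(vapply(gacc, function(a) sum(a^2), 0)))
      if (is.finite(clip) && gnorm > clip)
        gacc <- lapply(gacc, `*`, clip / gnorm)
      vel <- if (is.null(vel) || momentum == 0) gacc else
        mapply(function(v, g) momentum * v + g, vel, gacc, SIMPLIFY = FALSE)
      if (lr != 0) {
        for (nm in names(w$blocks)) {
          w$blocks[[nm]] <- w$blocks[[nm]] - lr * vel[[nm]]
        }
      }
    }
  })
  attr(w, "epoch_loss") <- mean(losses)
  w
}

#' Predict per-voxel class probabilities for a full volume
#'
#' The volume is covered by overlapping patches (stride defaulting to half the
#' patch size); per-patch softmax maps are accumulated and renormalized by the
#' per-voxel cover count, so the probability-simplex invariant holds at every
#' voxel.
#'
#' @param w an `fsb_model_weights`.
#' @param volume preprocessed 3D numeric array.
#' @param config the shared `fsb_model_config`.
#' @param stride integer patch stride (scalar or length 3); defaults to half
#'   the patch size.
#' @return an `fsb_prob_map`: a (D, H, W, n_classes) array.
#' @export
predict_probabilities <- function(w, volume, config, stride = NULL) {
  abort_if(length(dim(volume)) != 3, "volume must be a 3D array")
  d <- dim(volume)
  psize <- config$patch_size
  abort_if(any(psize > d), "patch larger than volume")
  if (is.null(stride)) stride <- pmax(psize %/% 2L, 1L)
  stride <- rep(as.integer(stride), length.out = 3)
  starts <- lapply(seq_len(3), function(a) {
    s <- unique(c(seq(1L, d[a] - psize[a] + 1L, by = stride[a]),
                  d[a] - psize[a] + 1L))
    as.integer(s)
  })
  K <- config$n_classes
  acc <- array(0, dim = c(d, K))
  cnt <- array(0, dim = d)
  for (k0 in starts[[3]]) for (j0 in starts[[2]]) for (i0 in starts[[1]]) {
    sl <- list(i0 + seq_len(psize[1]) - 1L, j0 + seq_len(psize[2]) - 1L,
               k0 + seq_len(psize[3]) - 1L)
    xp <- volume[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    dim(xp) <- c(psize, 1L)
    fw <- net_forward(w$blocks, xp)
    P <- softmax4(fw$logits)
    acc[sl[[1]], sl[[2]], sl[[3]], ] <- acc[sl[[1]], sl[[2]], sl[[3]], ,
                                            drop = FALSE] + P
    cnt[sl[[1]], sl[[2]], sl[[3]]] <- cnt[sl[[1]], sl[[2]], sl[[3]]] + 1
  }
  out <- acc / as.vector(cnt)
  structure(out, class = "fsb_prob_map")
}

#' @export
print.fsb_prob_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<probability map>: %s voxels x %d classes\n",
              paste(d[1:3], collapse = "x"), d[4]))
  invisible(x)
}

#' Decode a probability map to a label mask
#'
#' Per-voxel argmax over classes; ties break toward the lower class index
#' (so an exactly uniform voxel decodes to background).
#'
#' @param p an `fsb_prob_map` (or plain 4D probability array).
#' @return 3D integer label mask with labels `0 .. n_classes - 1`.
#' @export
predict_segmentation <- function(p) {
  d <- dim(p)
  abort_if(length(d) != 4, "probability map must be a 4D array")
  m <- matrix(as.numeric(p), ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), dim = d[1:3])
}

#' Train a local model for several epochs
#'
#' Sequential local training at one site, with the same per-epoch seed
#' derivation a federation uses, so a one-site federation and local training
#' coincide exactly.
#'
#' @param dataset preprocessed training `fsb_site_dataset`.
#' @param config shared `fsb_model_config`.
#' @param n_epochs number of epochs.
#' @param seed master seed.
#' @param site_id site label used in seed derivation (defaults to the
#'   dataset's own).
#' @return `fsb_model_weights` with an `"epoch_loss"` attribute holding the
#'   per-epoch mean loss trace.
#' @export
train_local_model <- function(dataset, config, n_epochs, seed = 1L,
                              site_id = dataset$profile$site_id) {
  w <- init_model(config, derive_seed(seed, "init"))
  trace <- numeric(n_epochs)
  for (t in seq_len(n_epochs)) {
    w <- train_local_epoch(w, dataset, config,
                           derive_seed(seed, "train", site_id, t, 1L))
    trace[t] <- attr(w, "epoch_loss")
  }
  w$trained_sites <- site_id
  attr(w, "epoch_loss") <- trace
  w
}
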