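# Small convolutional age classifier. Two convolution layers with ReLU,
# a dense softmax head, minibatch SGD with momentum. Convolutions are done
# as im2col index lookups + BLAS matrix multiplies, so the whole net is
# plain R yet fast enough for desk-scale images (L = 64 in tests). This is
# a deliberately small stand-in for a deep residual network: the encoder,
# age binning and median-of-top-3 aggregation around it are the parts with
# scientific content.

#' CNN training configuration
#'
#' @param epochs training epochs (default 30).
#' @param lr learning rate (default 0.05).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size minibatch size (default 32).
#' @param conv1,conv2 filter counts of the two convolution layers
#'   (defaults 8 and 16).
#' @param k1,k2 kernel sizes (defaults 5 and 3).
#' @param stride stride of both convolutions (default 2).
#' @param lr_decay multiplicative learning-rate decay per epoch
#'   (default 0.97).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(epochs = 30, lr = 0.05, momentum = 0.9,
                       batch_size = 32, conv1 = 8, conv2 = 16,
                       k1 = 5, k2 = 3, stride = 2, lr_decay = 0.97) {
  structure(list(epochs = epochs, lr = lr, momentum = momentum,
                 batch_size = batch_size, conv1 = conv1, conv2 = conv2,
                 k1 = k1, k2 = k2, stride = stride, lr_decay = lr_decay),
            class = "cnn_config")
}

# im2col index matrix for an H x H x C input, kernel k, stride s.
# column m corresponds to output position (i, j), m = i + (j-1)*O;
# rows run over (patch row, patch col, channel).
im2col_idx <- function(H, C, k, s) {
  O <- (H - k) %/% s + 1
  if (O < 1) stop("kernel larger than input")
  patch <- as.matrix(expand.grid(r = 0:(k - 1), c = 0:(k - 1),
                                 ch = 0:(C - 1)))
  out <- as.matrix(expand.grid(i = seq_len(O), j = seq_len(O)))
  idx <- matrix(0L, nrow(patch), nrow(out))
  for (m in seq_len(nrow(out))) {
    r0 <- (out[m, "i"] - 1) * s
    c0 <- (out[m, "j"] - 1) * s
    idx[, m] <- (r0 + patch[, "r"] + 1L) +
      (c0 + patch[, "c"]) * H +
      patch[, "ch"] * H * H
  }
  list(idx = idx, O = O)
}

cnn_forward <- function(v0, net, keep = FALSE) {
  cols1 <- matrix(v0[net$ic1$idx], nrow = nrow(net$ic1$idx))
  z1 <- net$W1 %*% cols1 + as.vector(net$b1)
  a1 <- pmax(z1, 0)
  v1 <- as.vector(t(a1))
  cols2 <- matrix(v1[net$ic2$idx], nrow = nrow(net$ic2$idx))
  z2 <- net$W2 %*% cols2 + as.vector(net$b2)
  a2 <- pmax(z2, 0)
  f <- as.vector(a2)
  z3 <- drop(net$W3 %*% f + net$b3)
  z3 <- z3 - max(z3)
  p <- exp(z3) / sum(exp(z3))
  if (!keep) return(p)
  list(p = p, f = f, a2 = a2, cols2 = cols2, a1 = a1, cols1 = cols1)
}

#' Train the convolutional age classifier
#'
#' Minibatch SGD with momentum on cross-entropy, deterministic given the
#' seed (single-threaded). Inputs are `microbiota_image`s (or plain
#' L x L x 3 arrays, values 0-255); labels are bin indices into the
#' supplied `age_bins` scheme.
#'
#' @param images list of L x L x 3 arrays.
#' @param bin_labels integer bin index per image (see
#'   [assign_age_bin()]); every bin in 1..nrow(bins) must be present.
#' @param bins the `age_bins` scheme (class = bin; midpoints used at
#'   prediction time).
#' @param config a `cnn_config`.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return object of class `cnn_age_model` with weights, per-epoch
#'   `loss`, the bin scheme and the training config.
#' @export
train_cnn_age <- function(images, bin_labels, bins, config = cnn_config(),
                          seed = 1, verbose = FALSE) {
  stopifnot(inherits(bins, "age_bins"), length(images) == length(bin_labels))
  K <- nrow(bins)
  if (K < 2) stop("need at least 2 age bins")
  present <- sort(unique(bin_labels))
  if (anyNA(bin_labels)) stop("NA bin label (age outside scheme?)")
  if (!all(seq_len(K) %in% present))
    stop("bin(s) absent from training data: ",
         paste(setdiff(seq_len(K), present), collapse = ", "))
  dims <- dim(images[[1]])
  H <- dims[1]
  C <- dims[3]
  set.seed(seed)

  ic1 <- im2col_idx(H, C, config$k1, config$stride)
  ic2 <- im2col_idx(ic1$O, config$conv1, config$k2, config$stride)
  n_in1 <- config$k1^2 * C
  n_in2 <- config$k2^2 * config$conv1
  n_flat <- config$conv2 * ic2$O^2

  net <- list(
    W1 = matrix(stats::rnorm(config$conv1 * n_in1, 0, sqrt(2 / n_in1)),
                config$conv1, n_in1),
    b1 = matrix(0, config$conv1, 1),
    W2 = matrix(stats::rnorm(config$conv2 * n_in2, 0, sqrt(2 / n_in2)),
                config$conv2, n_in2),
    b2 = matrix(0, config$conv2, 1),
    W3 = matrix(stats::rnorm(K * n_flat, 0, sqrt(2 / n_flat)), K, n_flat),
    b3 = matrix(0, K, 1),
    ic1 = ic1, ic2 = ic2)

  # precompute the col2im scatter map for conv2's input gradient
  grp2 <- as.vector(net$ic2$idx)
  ugrp2 <- sort(unique(grp2))

  vel <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0,
              b2 = net$b2 * 0, W3 = net$W3 * 0, b3 = net$b3 * 0)
  xs <- lapply(images, function(im) as.vector(im) / 255)
  n <- length(xs)
  lr <- config$lr
  losses <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1, n)]
      g <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0,
                b2 = net$b2 * 0, W3 = net$W3 * 0, b3 = net$b3 * 0)
      for (i in bidx) {
        fw <- cnn_forward(xs[[i]], net, keep = TRUE)
        y <- bin_labels[i]
        ep_loss <- ep_loss - log(max(fw$p[y], 1e-12))
        dz3 <- fw$p
        dz3[y] <- dz3[y] - 1
        g$W3 <- g$W3 + dz3 %*% t(fw$f)
        g$b3 <- g$b3 + dz3
        da2 <- matrix(drop(crossprod(net$W3, dz3)), nrow = config$conv2)
        da2[fw$a2 <= 0] <- 0
        g$W2 <- g$W2 + da2 %*% t(fw$cols2)
        g$b2 <- g$b2 + rowSums(da2)
        dcols2 <- crossprod(net$W2, da2)
        rs <- rowsum(as.vector(dcols2), grp2)
        dv1 <- numeric(net$ic1$O^2 * config$conv1)
        dv1[ugrp2] <- rs
        da1 <- t(matrix(dv1, ncol = config$conv1))
        da1[fw$a1 <= 0] <- 0
        g$W1 <- g$W1 + da1 %*% t(fw$cols1)
        g$b1 <- g$b1 + rowSums(da1)
      }
      nb <- length(bidx)
      for (nm in names(vel)) {
        vel[[nm]] <- config$momentum * vel[[nm]] - lr * g[[nm]] / nb
        net[[nm]] <- net[[nm]] + vel[[nm]]
      }
    }
    losses[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
    lr <- lr * config$lr_decay
  }
  structure(list(net = net, loss = losses, bins = bins, config = config,
                 input_dim = dims, seed = seed),
            class = "cnn_age_model")
}

#' @export
print.cnn_age_model <- function(x, ...) {
  cat("CNN age model:", nrow(x$bins), "bins, input",
      paste(x$input_dim, collapse = "x"), "| final loss",
      round(x$loss[length(x$loss)], 4), "\n")
  invisible(x)
}

#' Predict microbiota age with the CNN
#'
#' Takes the three highest-probability age bins, maps each to its
#' midpoint, and returns the median of the three midpoints as the
#' microbiota age.
#'
#' @param model a `cnn_age_model`.
#' @param image an L x L x 3 array matching the model's input shape.
#' @return list with `top3` (bin indices), `top3_midpoints`,
#'   `microbiota_age`, `probs`.
#' @export
predict_age_cnn <- function(model, image) {
  stopifnot(inherits(model, "cnn_age_model"))
  if (!all(dim(image) == model$input_dim))
    stop("image shape ", paste(dim(image), collapse = "x"),
         " does not match model input ",
         paste(model$input_dim, collapse = "x"))
  p <- cnn_forward(as.vector(image) / 255, model$net)
  top3 <- order(-p)[seq_len(min(3, length(p)))]
  mids <- model$bins$midpoint[top3]
  list(top3 = top3, top3_midpoints = mids,
       microbiota_age = stats::median(mids), probs = p)
}

#' Predict microbiota ages for a list of images
#'
#' @param model a `cnn_age_model`.
#' @param images list of images.
#' @return numeric vector of microbiota ages.
#' @export
predict_ages_cnn <- function(model, images) {
  vapply(images, function(im) predict_age_cnn(model, im)$microbiota_age, 0)
}

#' CNN-based microbiota-for-age Z score
#'
#' Delegates to [compute_maz()] using CNN microbiota ages.
#'
#' @param model a `cnn_age_model`.
#' @param images list of images.
#' @param chronological_ages chronological ages (years).
#' @param reference a `healthy_reference` built from CNN microbiota ages
#'   of healthy samples.
#' @param sample_ids optional identifiers.
#' @return data.frame as from [compute_maz()].
#' @export
compute_maz_cnn <- function(model, images, chronological_ages, reference,
                            sample_ids = NULL) {
  ma <- predict_ages_cnn(model, images)
  compute_maz(ma, chronological_ages, reference, sample_ids = sample_ids)
}
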