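# A small 1-D convolutional network with squeeze-excitation channel
# attention for 100 x 6 signal fragments, implemented directly on BLAS
# matrix products (im2col + GEMM): no deep-learning framework exists in the
# target environment, and the network is small enough that explicit
# backpropagation in R trains in seconds per epoch on one CPU.
#
# Architecture: 4 Conv1D blocks (valid convolution, kernel 5, ReLU), max
# pooling (width 2, stride 2) after the first three blocks, channel
# attention before global average pooling, then one fully connected layer
# and softmax over 2 classes:
#   100x6 -conv-> 96x32 -pool-> 48x32 -conv-> 44x64 -pool-> 22x64
#   -conv-> 18x64 -pool-> 9x64 -conv-> 5x128 -CA-> GAP -> FC -> softmax

#' Model hyperparameter specification
#'
#' Layer counts and ordering follow the reference architecture (4 Conv1D,
#' 3 Pool1D, channel attention before GAP, FC + softmax over 2 classes);
#' filter counts, kernel size and the squeeze-excitation reduction are
#' explicit stand-ins chosen small enough for CPU training.
#'
#' @param input_len Fragment length (100).
#' @param n_channels Input channels (6).
#' @param filters Filter counts of the 4 convolution blocks.
#' @param kernel_size Convolution kernel length.
#' @param attention Enable the channel-attention (squeeze-excitation) block.
#' @param reduction Squeeze-excitation reduction factor.
#' @param n_classes Output classes.
#' @param classes Class labels, in output order.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(input_len = 100, n_channels = 6,
                       filters = c(32, 64, 64, 128), kernel_size = 5,
                       attention = TRUE, reduction = 4, n_classes = 2,
                       classes = c("WBC", "TUMOR")) {
  stop_if(length(filters) != 4, "the reference architecture has 4 conv blocks")
  stop_if(n_classes != length(classes), "classes must match n_classes")
  # lengths through the conv/pool stack (valid conv, pool /2)
  L <- input_len
  lens <- integer(0)
  for (i in 1:4) {
    L <- L - kernel_size + 1
    stop_if(L < 1, "input too short for this conv stack")
    lens <- c(lens, L)
    if (i < 4) {
      stop_if(L %% 2 != 0, "length %d not divisible by 2 before pool %d", L, i)
      L <- L / 2
      lens <- c(lens, L)
    }
  }
  structure(list(input_len = input_len, n_channels = n_channels,
                 filters = filters, kernel_size = kernel_size,
                 attention = attention, reduction = reduction,
                 n_classes = n_classes, classes = classes, lens = lens),
            class = "model_spec")
}

# ---- array helpers -------------------------------------------------------

# gather-index matrix turning X[B, L, C] into the (B*P) x (C*k) im2col form;
# memoised per (B, L, C, k) - batches of equal size reuse the index
.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(B, L, C, k) {
  key <- paste(B, L, C, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- L - k + 1
  b_r <- rep(seq_len(B), P)
  pos_r <- rep(seq_len(P), each = B)
  dk_c <- rep(seq_len(k), C)
  c_c <- rep(seq_len(C), each = k)
  l <- outer(pos_r, dk_c, "+") - 1L            # (B*P) x (C*k) sample index
  idx <- matrix(b_r, B * P, C * k) + (l - 1L) * B +
    matrix((c_c - 1L) * B * L, B * P, C * k, byrow = TRUE)
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

conv_fwd <- function(X, W, b, idx) {
  B <- dim(X)[1]
  M <- X[idx]
  dim(M) <- dim(idx)
  Y <- M %*% W
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(B, nrow(idx) / B, ncol(W))
  list(Y = Y, M = M)
}

conv_bwd <- function(dY, M, W, xdim, k, need_dx = TRUE) {
  B <- xdim[1]; L <- xdim[2]; C <- xdim[3]
  F <- ncol(W)
  P <- L - k + 1
  dim(dY) <- c(B * P, F)
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  if (!need_dx) return(list(dW = dW, db = db, dX = NULL))
  dM <- tcrossprod(dY, W)
  # scatter-add back through the gather index (positions are distinct
  # within one kernel offset, so k flat-indexed adds suffice)
  idx <- im2col_idx(B, L, C, k)
  dX <- numeric(B * L * C)
  for (dk in seq_len(k)) {
    cols <- dk + (seq_len(C) - 1L) * k
    tp <- idx[, cols]
    dX[tp] <- dX[tp] + dM[, cols]
  }
  dim(dX) <- xdim
  list(dW = dW, db = db, dX = dX)
}

pool_fwd <- function(X) {
  P <- dim(X)[2]
  X1 <- X[, seq(1, P, 2), , drop = FALSE]
  X2 <- X[, seq(2, P, 2), , drop = FALSE]
  mask <- X1 >= X2
  list(Y = X2 + (X1 - X2) * mask, mask = mask)
}

pool_bwd <- function(dY, mask, xdim) {
  dX <- array(0, xdim)
  P <- xdim[2]
  dX[, seq(1, P, 2), ] <- dY * mask
  dX[, seq(2, P, 2), ] <- dY * !mask
  dX
}

# averaging matrix for GAP over the length axis: [P*F x F]
gap_mat <- function(P, F) kronecker(diag(F), matrix(1 / P, P, 1))

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- model ---------------------------------------------------------------

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

#' Build an untrained classifier
#'
#' Deterministic He-normal initialization under `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class `cytonet_model`.
#' @export
build_model <- function(spec = model_spec(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$kernel_size
  cin <- c(spec$n_channels, spec$filters[-4])
  par <- list()
  with_seed(seed, {
    for (i in 1:4) {
      par[[paste0("W", i)]] <- he_init(cin[i] * k, spec$filters[i], cin[i] * k)
      par[[paste0("b", i)]] <- numeric(spec$filters[i])
    }
    F4 <- spec$filters[4]
    if (spec$attention) {
      Fr <- max(1, F4 %/% spec$reduction)
      par$Wse1 <- he_init(F4, Fr, F4); par$bse1 <- numeric(Fr)
      par$Wse2 <- he_init(Fr, F4, Fr); par$bse2 <- numeric(F4)
    }
    par$Wfc <- he_init(F4, spec$n_classes, F4)
    par$bfc <- numeric(spec$n_classes)
  })
  structure(list(spec = spec, par = par, seed = seed),
            class = "cytonet_model")
}

#' Number of trainable parameters
#' @param model A `cytonet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$par, length, numeric(1)))

# full forward pass; returns softmax probabilities and (optionally) the
# cached intermediates needed for backprop
cytonet_forward <- function(model, X, keep = FALSE) {
  spec <- model$spec; p <- model$par
  B <- dim(X)[1]; k <- spec$kernel_size
  cache <- list(X = X)
  A <- X
  for (i in 1:4) {
    d <- dim(A)
    idx <- im2col_idx(B, d[2], d[3], k)
    cv <- conv_fwd(A, p[[paste0("W", i)]], p[[paste0("b", i)]], idx)
    Z <- cv$Y
    R <- Z * (Z > 0)                    # ReLU
    if (keep) {
      cache[[paste0("M", i)]] <- cv$M
      cache[[paste0("relu", i)]] <- Z > 0
      cache[[paste0("xdim", i)]] <- d
    }
    if (i < 4) {
      pl <- pool_fwd(R)
      if (keep) {
        cache[[paste0("pmask", i)]] <- pl$mask
        cache[[paste0("pdim", i)]] <- dim(R)
      }
      A <- pl$Y
    } else A <- R
  }
  P4 <- dim(A)[2]; F4 <- dim(A)[3]
  K <- gap_mat(P4, F4)
  Am <- matrix(A, B)
  if (spec$attention) {
    z <- Am %*% K
    s1 <- z %*% p$Wse1; s1 <- sweep(s1, 2, p$bse1, "+"); s1r <- s1 * (s1 > 0)
    s2 <- sigmoid(sweep(s1r %*% p$Wse2, 2, p$bse2, "+"))
    s2rep <- s2[, rep(seq_len(F4), each = P4), drop = FALSE]
    Ym <- Am * s2rep
    if (keep) cache <- c(cache, list(z = z, s1 = s1, s1r = s1r, s2 = s2,
                                     s2rep = s2rep, Am = Am))
  } else Ym <- Am
  g <- Ym %*% K
  logits <- sweep(g %*% p$Wfc, 2, p$bfc, "+")
  m <- apply(logits, 1, max)
  el <- exp(logits - m)
  prob <- el / rowSums(el)
  if (keep) cache <- c(cache, list(A4 = A, Ym = Ym, g = g, K = K,
                                   P4 = P4, F4 = F4, prob = prob))
  list(prob = prob, cache = if (keep) cache)
}

# backward pass: returns gradients in the same shape as model$par
cytonet_backward <- function(model, cache, y_onehot) {
  spec <- model$spec; p <- model$par; k <- spec$kernel_size
  B <- nrow(y_onehot)
  gr <- list()
  dlogits <- (cache$prob - y_onehot) / B
  gr$Wfc <- crossprod(cache$g, dlogits)
  gr$bfc <- colSums(dlogits)
  dg <- tcrossprod(dlogits, p$Wfc)
  P4 <- cache$P4; F4 <- cache$F4
  dYm <- dg %*% t(cache$K)              # gap backward
  if (spec$attention) {
    dAm <- dYm * cache$s2rep
    ds2 <- (dYm * cache$Am) %*% (cache$K * P4)   # sum over length axis
    dpre2 <- ds2 * cache$s2 * (1 - cache$s2)
    gr$Wse2 <- crossprod(cache$s1r, dpre2)
    gr$bse2 <- colSums(dpre2)
    ds1 <- tcrossprod(dpre2, p$Wse2) * (cache$s1 > 0)
    gr$Wse1 <- crossprod(cache$z, ds1)
    gr$bse1 <- colSums(ds1)
    dz <- tcrossprod(ds1, p$Wse1)
    dAm <- dAm + dz[, rep(seq_len(F4), each = P4), drop = FALSE] / P4
  } else dAm <- dYm
  dA <- array(dAm, dim(cache$A4))
  for (i in 4:1) {
    if (i < 4) dA <- pool_bwd(dA, cache[[paste0("pmask", i)]],
                              cache[[paste0("pdim", i)]])
    dZ <- dA * cache[[paste0("relu", i)]]
    cb <- conv_bwd(dZ, cache[[paste0("M", i)]], p[[paste0("W", i)]],
                   cache[[paste0("xdim", i)]], k, need_dx = i > 1)
    gr[[paste0("W", i)]] <- cb$dW
    gr[[paste0("b", i)]] <- cb$db
    dA <- cb$dX
  }
  gr
}

#' Class probabilities for a batch of fragments
#'
#' @param model A trained or untrained `cytonet_model`.
#' @param x Array `[N, input_len, 6]`, a single `[input_len, 6]` matrix, or a
#'   `fragment_tensor`.
#' @param batch_size Forward-pass batch size.
#' @return Matrix `[N, n_classes]` of softmax probabilities (columns named by
#'   class).
#' @export
predict_cytonet <- function(model, x, batch_size = 1024) {
  stopifnot(inherits(model, "cytonet_model"))
  x <- as_fragment_array(x, model$spec)
  N <- dim(x)[1]
  out <- matrix(NA_real_, N, model$spec$n_classes,
                dimnames = list(NULL, model$spec$classes))
  for (s in seq(1, N, batch_size)) {
    e <- min(N, s + batch_size - 1)
    out[s:e, ] <- cytonet_forward(model, x[s:e, , , drop = FALSE])$prob
  }
  out
}

as_fragment_array <- function(x, spec) {
  if (inherits(x, "fragment_tensor")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  stop_if(length(dim(x)) != 3 || dim(x)[2] != spec$input_len ||
            dim(x)[3] != spec$n_channels,
          "fragments must be [N, %d, %d]", spec$input_len, spec$n_channels)
  x
}

#' Training configuration
#'
#' @param split_fraction Training fraction of the stratified split (0.7).
#' @param epochs Maximum epochs (training may stop earlier when the training
#'   loss plateaus; the reference training converges in about 100 epochs).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for split, shuffling and initialization.
#' @param patience Early-stopping patience: epochs without training-loss
#'   improvement greater than `min_delta`.
#' @param min_delta Minimum loss improvement counted by `patience`.
#' @param balanced Balance classes within each epoch by oversampling the
#'   minority class.
#' @return An object of class `training_config`.
#' @export
training_config <- function(split_fraction = 0.7, epochs = 100,
                            batch_size = 64, learning_rate = 1e-3, seed = 1,
                            patience = 8, min_delta = 1e-4, balanced = TRUE) {
  stop_if(split_fraction <= 0 || split_fraction >= 1,
          "split_fraction must be in (0, 1)")
  stop_if(epochs < 1, "epochs must be >= 1")
  structure(list(split_fraction = split_fraction, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed, patience = patience, min_delta = min_delta,
                 balanced = balanced),
            class = "training_config")
}

encode_labels <- function(y, classes) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    stop_if(!all(y %in% classes), "labels must be among: %s",
            paste(classes, collapse = ", "))
    y <- match(y, classes) - 1L
  }
  as.integer(y)
}

adam_step <- function(par, gr, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(gr)) {
    g <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

#' Train the classifier
#'
#' Stratified train/test split (7:3 by default) with recorded seed,
#' cross-entropy loss, Adam, balanced minibatch sampling, per-epoch training
#' loss and held-out accuracy curves. Training stops when the cross-entropy
#' on the training stream plateaus (never later than `cfg$epochs`); the
#' held-out split is only ever used for the logged accuracy curve and final
#' evaluation, not for the stopping rule.
#'
#' @param model A [build_model()] result.
#' @param x Fragment array `[N, input_len, n_channels]`.
#' @param y Labels: class names, factor, or integers 0..n_classes-1 in the
#'   order of `model$spec$classes`.
#' @param cfg A [training_config()].
#' @return List with `model` (trained), `history` (epoch, train_loss,
#'   test_accuracy), `split` (train/test indices), `cfg`.
#' @export
train_cytonet <- function(model, x, y, cfg = training_config()) {
  stopifnot(inherits(model, "cytonet_model"), inherits(cfg, "training_config"))
  x <- as_fragment_array(x, model$spec)
  yi <- encode_labels(y, model$spec$classes)
  N <- dim(x)[1]
  stop_if(length(yi) != N, "x and y lengths differ")
  stop_if(length(unique(yi)) < 2, "need both classes in the dataset")
  nc <- model$spec$n_classes
  with_seed(cfg$seed, {
    train_idx <- unlist(lapply(sort(unique(yi)), function(cl) {
      i <- which(yi == cl)
      sample(i, round(length(i) * cfg$split_fraction))
    }))
    train_idx <- sample(train_idx)
  })
  test_idx <- setdiff(seq_len(N), train_idx)
  stop_if(length(unique(yi[train_idx])) < 2 || length(unique(yi[test_idx])) < 2,
          "both classes must be present in both splits")
  par <- model$par
  st <- list(m = lapply(par, function(p) p * 0),
             v = lapply(par, function(p) p * 0))
  hist_loss <- hist_acc <- numeric(0)
  best <- Inf; stale <- 0; t <- 0
  xte <- x[test_idx, , , drop = FALSE]; yte <- yi[test_idx]
  for (epoch in seq_len(cfg$epochs)) {
    idx <- with_seed(cfg$seed + 1000 + epoch, {
      if (cfg$balanced) {
        by_cl <- lapply(sort(unique(yi[train_idx])), function(cl)
          sample(train_idx[yi[train_idx] == cl]))
        nmax <- max(lengths(by_cl))
        sample(unlist(lapply(by_cl, function(i) i[(seq_len(nmax) - 1) %% length(i) + 1])))
      } else sample(train_idx)
    })
    losses <- numeric(0)
    for (s in seq(1, length(idx), cfg$batch_size)) {
      bi <- idx[s:min(length(idx), s + cfg$batch_size - 1)]
      xb <- x[bi, , , drop = FALSE]
      yb <- yi[bi]
      model$par <- par
      fw <- cytonet_forward(model, xb, keep = TRUE)
      pb <- fw$prob[cbind(seq_along(bi), yb + 1)]
      losses <- c(losses, -mean(log(pmax(pb, 1e-12))))
      onehot <- matrix(0, length(bi), nc)
      onehot[cbind(seq_along(bi), yb + 1)] <- 1
      gr <- cytonet_backward(model, fw$cache, onehot)
      t <- t + 1
      upd <- adam_step(par, gr, st, cfg$learning_rate, t)
      par <- upd$par; st <- upd$st
    }
    model$par <- par
    ep_loss <- mean(losses)
    pred <- max.col(predict_cytonet(model, xte)) - 1
    acc <- mean(pred == yte)
    hist_loss <- c(hist_loss, ep_loss)
    hist_acc <- c(hist_acc, acc)
    if (best - ep_loss > cfg$min_delta) { best <- ep_loss; stale <- 0 }
    else stale <- stale + 1
    if (stale >= cfg$patience || ep_loss < 1e-4) break
  }
  model$par <- par
  list(model = model,
       history = data.frame(epoch = seq_along(hist_loss),
                            train_loss = hist_loss,
                            test_accuracy = hist_acc),
       split = list(train = sort(train_idx), test = test_idx),
       cfg = cfg)
}

#' Confusion matrix and per-class true-positive rates
#'
#' @param model A `cytonet_model`.
#' @param x Test fragments.
#' @param y Test labels.
#' @return An object of class `confusion_matrix`: `counts` (rows = truth,
#'   columns = prediction), `tpr` per class, `accuracy`, `n`.
#' @export
evaluate_cytonet <- function(model, x, y) {
  x <- as_fragment_array(x, model$spec)
  stop_if(dim(x)[1] == 0, "empty test set")
  yi <- encode_labels(y, model$spec$classes)
  pred <- max.col(predict_cytonet(model, x)) - 1
  confusion_matrix(yi, pred, model$spec$classes)
}

#' @rdname evaluate_cytonet
#' @param truth,prediction Integer class codes (0-based) or class names.
#' @param classes Class labels.
#' @export
confusion_matrix <- function(truth, prediction, classes = c("WBC", "TUMOR")) {
  truth <- encode_labels(truth, classes)
  prediction <- encode_labels(prediction, classes)
  counts <- table(factor(truth, seq_along(classes) - 1, classes),
                  factor(prediction, seq_along(classes) - 1, classes))
  counts <- unclass(counts)
  tpr <- diag(counts) / pmax(rowSums(counts), 1)
  structure(list(counts = counts, tpr = tpr,
                 accuracy = sum(diag(counts)) / sum(counts),
                 n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$counts)
  cat(sprintf("TPR: %s | accuracy %.2f%% (n = %d)\n",
              paste(sprintf("%s %.2f%%", names(x$tpr), 100 * x$tpr),
                    collapse = ", "),
              100 * x$accuracy, x$n))
  invisible(x)
}

#' Rectangular gating baseline
#'
#' The transparent comparison arm: a cell is called a tumor cell iff its
#' electrical diameter exceeds `diameter_cut` and its Opacity_2/0.5 is below
#' `opacity_cut` (tumor cells are larger and less opaque).
#'
#' @param features Feature data.frame (see [compute_features()]).
#' @param diameter_cut Diameter threshold, um.
#' @param opacity_cut Opacity_2/0.5 threshold.
#' @return Character vector of predicted labels ("WBC"/"TUMOR").
#' @export
gating_baseline <- function(features, diameter_cut, opacity_cut) {
  stop_if(!is.numeric(diameter_cut) || !is.numeric(opacity_cut) ||
            is.na(diameter_cut) || is.na(opacity_cut), "cuts must be numeric")
  if (nrow(features) == 0) return(character(0))
  ifelse(features$estimated_diameter > diameter_cut &
           features$opacity_2_05 < opacity_cut, "TUMOR", "WBC")
}
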