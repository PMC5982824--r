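# Convolutional network engine for 12 x 11 summary-statistic images.
#
# Convolutions are evaluated as gather + matrix product: for each kernel tap
# (a row/column offset, possibly dilated) the zero-padded input is gathered
# into a column block, and one BLAS gemm against the stacked filter matrix
# gives all output channels at once. Activations live in matrices of shape
# (batch * positions) x channels, image-major then row-major, which keeps
# every step a dense matrix operation.

#' Architecture of the sweep-image classifier
#'
#' Three convolutional branches look at the image at different horizontal
#' scales: square 3x3 filters, and 2x2 filters dilated 1x3 and 1x4 so their
#' receptive fields stretch across distant subwindows. Each branch is
#' conv-conv-maxpool-dropout; the flattened branches are concatenated and
#' passed through two dense layers with dropout onto a 5-way softmax.
#'
#' Filter counts, dense widths and dropout rates are tunable; the defaults
#' are conventional image-classification settings sized for a 12 x 11 input.
#'
#' @param input_shape image dimensions, rows x columns.
#' @param n_classes number of output classes.
#' @param n_filters convolution filters per layer.
#' @param dense widths of the two fully connected layers.
#' @param dropout_conv dropout rate after each branch's pooling.
#' @param dropout_dense dropout rate after each dense layer.
#' @param branches list of per-branch `filter`, `dilation`, `pool` (each
#'   length-2 integer) and optional `padding` ("same", the default, keeps the
#'   image size; "valid" shrinks it). The default follows the three-branch
#'   multiscale layout; 12-row filters with valid padding (e.g.
#'   `filter = c(12, 3), padding = "valid"`) give the row-order-free variant
#'   that collapses the statistic dimension entirely.
#' @return List of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(12L, 11L), n_classes = 5L,
                     n_filters = 16L, dense = c(64L, 32L),
                     dropout_conv = 0.25, dropout_dense = 0.5,
                     branches = list(
                       sq3 = list(filter = c(3L, 3L), dilation = c(1L, 1L), pool = c(2L, 2L)),
                       dil3 = list(filter = c(2L, 2L), dilation = c(1L, 3L), pool = c(1L, 2L)),
                       dil4 = list(filter = c(2L, 2L), dilation = c(1L, 4L), pool = c(1L, 2L)))) {
  for (bn in names(branches)) {
    br <- branches[[bn]]
    pad <- if (is.null(br$padding)) "same" else br$padding
    eff <- (br$filter - 1L) * br$dilation + 1L
    if (any(eff > input_shape)) {
      stop("branch '", bn, "': dilated filter (", eff[1], "x", eff[2],
           ") exceeds the input image (", input_shape[1], "x", input_shape[2], ")")
    }
    if (pad == "same") {
      after <- input_shape
    } else {
      a1 <- input_shape - (br$filter - 1L) * br$dilation
      f2 <- pmin(br$filter, a1)
      after <- a1 - (f2 - 1L) * br$dilation
    }
    if (any(after < 1L) || any(after %/% br$pool < 1L)) {
      stop("branch '", bn, "': pool size incompatible with the convolved image")
    }
  }
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 n_filters = as.integer(n_filters), dense = as.integer(dense),
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 branches = branches),
            class = "cnn_spec")
}

# tap offsets for a (possibly dilated) filter; "same" centers the receptive
# field with zero padding, "valid" anchors it at the top-left and shrinks the
# output grid
tap_offsets <- function(filter, dilation, padding = "same") {
  eff <- (filter - 1L) * dilation
  pad <- if (padding == "same") eff %/% 2L else c(0L, 0L)
  expand.grid(dr = seq(0L, eff[1], by = dilation[1]) - pad[1],
              dc = seq(0L, eff[2], by = dilation[2]) - pad[2])
}

# base gather index (length Hout*Wout, 0 = zero pad) for one tap offset
tap_index <- function(Hin, Win, Hout, Wout, dr, dc) {
  rc <- expand.grid(c = seq_len(Wout), r = seq_len(Hout))  # row-major positions
  r2 <- rc$r + dr
  c2 <- rc$c + dc
  ok <- r2 >= 1L & r2 <= Hin & c2 >= 1L & c2 <= Win
  ifelse(ok, (r2 - 1L) * Win + c2, 0L)
}

# geometry of one convolution layer: base gather indices plus output dims
conv_geom <- function(Hin, Win, filter, dilation, padding = "same") {
  if (padding == "same") {
    Hout <- Hin
    Wout <- Win
  } else {
    eff <- (filter - 1L) * dilation
    Hout <- Hin - eff[1]
    Wout <- Win - eff[2]
    if (Hout < 1L || Wout < 1L) stop("valid convolution output would be empty")
  }
  off <- tap_offsets(filter, dilation, padding)
  base <- lapply(seq_len(nrow(off)),
                 function(t) tap_index(Hin, Win, Hout, Wout, off$dr[t], off$dc[t]))
  list(base = base, Hout = Hout, Wout = Wout, P_in = Hin * Win,
       P_out = Hout * Wout)
}

# expand a base index to a batch of B images; pad entries point at the extra
# zero row (B * P + 1) of the padded activation matrix
expand_index <- function(base, B, P) {
  off <- rep((seq_len(B) - 1L) * P, each = length(base))
  full <- rep(base, B) + off
  full[rep(base == 0L, B)] <- B * P + 1L
  full
}

gather_pad <- function(X, idx) {
  rbind(X, 0)[idx, , drop = FALSE]
}

conv_forward <- function(X, W, b, idxs, n_in) {
  K <- length(idxs)
  cin <- ncol(X)
  n_out <- length(idxs[[1]])
  Xp <- rbind(X, 0)
  Xcol <- matrix(0, n_out, K * cin)
  for (t in seq_len(K)) {
    Xcol[, ((t - 1L) * cin + 1L):(t * cin)] <- Xp[idxs[[t]], , drop = FALSE]
  }
  Z <- Xcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  A <- Z
  A[A < 0] <- 0
  list(A = A, Xcol = Xcol, mask = Z > 0, n_in = n_in)
}

conv_backward <- function(dA, cache, W, idxs, cin) {
  dZ <- dA * cache$mask
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, W)
  dX <- matrix(0, cache$n_in, cin)
  for (t in seq_along(idxs)) {
    blk <- dXcol[, ((t - 1L) * cin + 1L):(t * cin), drop = FALSE]
    idx <- idxs[[t]]
    valid <- idx <= cache$n_in
    iv <- idx[valid]
    dX[iv, ] <- dX[iv, ] + blk[valid, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# pooling gather indices: one base index per pool tap, all valid
pool_indices <- function(H, W, ph, pw) {
  Ho <- H %/% ph
  Wo <- W %/% pw
  rc <- expand.grid(c = seq_len(Wo), r = seq_len(Ho))
  taps <- expand.grid(b = seq_len(pw) - 1L, a = seq_len(ph) - 1L)
  idxs <- lapply(seq_len(nrow(taps)), function(t) {
    r2 <- (rc$r - 1L) * ph + taps$a[t] + 1L
    c2 <- (rc$c - 1L) * pw + taps$b[t] + 1L
    (r2 - 1L) * W + c2
  })
  list(idxs = idxs, Ho = Ho, Wo = Wo)
}

pool_forward <- function(A, pool_idx, B, P_in) {
  idxs <- lapply(pool_idx$idxs, expand_index, B = B, P = P_in)
  Ap <- rbind(A, -Inf)
  M <- Ap[idxs[[1]], , drop = FALSE]
  AM <- matrix(1L, nrow(M), ncol(M))
  if (length(idxs) > 1) {
    for (t in 2:length(idxs)) {
      Ct <- Ap[idxs[[t]], , drop = FALSE]
      sel <- Ct > M
      M[sel] <- Ct[sel]
      AM[sel] <- t
    }
  }
  list(M = M, AM = AM, idxs = idxs, n_in = nrow(A))
}

pool_backward <- function(dM, cache, C) {
  dA <- matrix(0, cache$n_in, C)
  for (t in seq_along(cache$idxs)) {
    contrib <- dM * (cache$AM == t)
    idx <- cache$idxs[[t]]
    dA[idx, ] <- dA[idx, ] + contrib
  }
  dA
}

# (B*Po) x C  ->  B x (Po*C) per-image flattening (and its inverse)
flatten_act <- function(A, B, Po) {
  C <- ncol(A)
  X <- aperm(array(A, c(Po, B, C)), c(2, 1, 3))
  dim(X) <- c(B, Po * C)
  X
}

unflatten_act <- function(X, B, Po) {
  C <- ncol(X) / Po
  A <- aperm(array(X, c(B, Po, C)), c(2, 1, 3))
  dim(A) <- c(B * Po, C)
  A
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

#' Build an untrained sweep-image classifier
#'
#' Allocates and initializes all parameters (He-normal weights, zero biases).
#' Initialization is driven by R's RNG, so two builds under the same seed are
#' identical.
#'
#' @param spec a [cnn_spec()].
#' @param seed optional integer passed to [set.seed()] before initialization.
#' @return Object of class `sweep_cnn`.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- spec$input_shape[1]
  W <- spec$input_shape[2]
  P <- H * W
  FN <- spec$n_filters
  params <- list()
  geom <- list()
  concat <- 0L
  for (bn in names(spec$branches)) {
    br <- spec$branches[[bn]]
    pad <- if (is.null(br$padding)) "same" else br$padding
    g1 <- conv_geom(H, W, br$filter, br$dilation, pad)
    # second layer reuses the branch filter, clipped to the (possibly
    # shrunken) first-layer output so valid-padding branches stay legal
    f2 <- pmin(br$filter, c(g1$Hout, g1$Wout))
    g2 <- conv_geom(g1$Hout, g1$Wout, f2, br$dilation, pad)
    params[[paste0(bn, "_W1")]] <- he_init(length(g1$base), FN)
    params[[paste0(bn, "_b1")]] <- numeric(FN)
    params[[paste0(bn, "_W2")]] <- he_init(length(g2$base) * FN, FN)
    params[[paste0(bn, "_b2")]] <- numeric(FN)
    pidx <- pool_indices(g2$Hout, g2$Wout, br$pool[1], br$pool[2])
    if (pidx$Ho < 1L || pidx$Wo < 1L) {
      stop("branch '", bn, "': pool size incompatible with the convolved image")
    }
    geom[[bn]] <- list(g1 = g1, g2 = g2, pool = pidx, Po = pidx$Ho * pidx$Wo)
    concat <- concat + geom[[bn]]$Po * FN
  }
  d <- spec$dense
  params$Wd1 <- he_init(concat, d[1])
  params$bd1 <- numeric(d[1])
  params$Wd2 <- he_init(d[1], d[2])
  params$bd2 <- numeric(d[2])
  params$Wout <- he_init(d[2], spec$n_classes)
  params$bout <- numeric(spec$n_classes)
  structure(list(spec = spec, params = params, geom = geom, concat = concat,
                 classes = class_levels(), history = NULL),
            class = "sweep_cnn")
}

#' @exportS3Method base::print
print.sweep_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<sweep_cnn> ", length(x$spec$branches), "-branch convolutional classifier, ",
      np, " parameters", sep = "")
  if (!is.null(x$history)) cat(", trained ", nrow(x$history), " epochs", sep = "")
  cat("\n")
  invisible(x)
}

# full forward pass; features: B x (H*W) matrix in row-major image order
cnn_forward <- function(model, feat, training = FALSE, dropout_rng = TRUE) {
  spec <- model$spec
  p <- model$params
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; P <- H * W
  B <- nrow(feat)
  X0 <- matrix(as.vector(t(feat)), ncol = 1)
  caches <- list(B = B)
  flat <- vector("list", length(spec$branches))
  names(flat) <- names(spec$branches)
  for (bn in names(spec$branches)) {
    g <- model$geom[[bn]]
    idx1 <- lapply(g$g1$base, expand_index, B = B, P = g$g1$P_in)
    idx2 <- lapply(g$g2$base, expand_index, B = B, P = g$g2$P_in)
    c1 <- conv_forward(X0, p[[paste0(bn, "_W1")]], p[[paste0(bn, "_b1")]], idx1,
                       n_in = B * g$g1$P_in)
    c2 <- conv_forward(c1$A, p[[paste0(bn, "_W2")]], p[[paste0(bn, "_b2")]], idx2,
                       n_in = B * g$g2$P_in)
    pl <- pool_forward(c2$A, g$pool, B, g$g2$P_out)
    Xf <- flatten_act(pl$M, B, g$Po)
    drop_mask <- NULL
    if (training && spec$dropout_conv > 0) {
      drop_mask <- matrix(stats::runif(length(Xf)) >= spec$dropout_conv,
                          nrow(Xf), ncol(Xf)) / (1 - spec$dropout_conv)
      Xf <- Xf * drop_mask
    }
    flat[[bn]] <- Xf
    caches[[bn]] <- list(idx1 = idx1, idx2 = idx2, c1 = c1, c2 = c2, pl = pl,
                         drop = drop_mask)
  }
  Xc <- do.call(cbind, flat)
  Z1 <- Xc %*% p$Wd1 + rep(p$bd1, each = B)
  A1 <- pmax(Z1, 0)
  D1 <- NULL
  if (training && spec$dropout_dense > 0) {
    D1 <- matrix(stats::runif(length(A1)) >= spec$dropout_dense,
                 nrow(A1), ncol(A1)) / (1 - spec$dropout_dense)
    A1 <- A1 * D1
  }
  Z2 <- A1 %*% p$Wd2 + rep(p$bd2, each = B)
  A2 <- pmax(Z2, 0)
  D2 <- NULL
  if (training && spec$dropout_dense > 0) {
    D2 <- matrix(stats::runif(length(A2)) >= spec$dropout_dense,
                 nrow(A2), ncol(A2)) / (1 - spec$dropout_dense)
    A2 <- A2 * D2
  }
  Zo <- A2 %*% p$Wout + rep(p$bout, each = B)
  Zo <- Zo - apply(Zo, 1, max)
  E <- exp(Zo)
  probs <- E / rowSums(E)
  caches$dense <- list(Xc = Xc, Z1 = Z1, A1 = A1, D1 = D1, Z2 = Z2, A2 = A2, D2 = D2)
  list(probs = probs, caches = caches)
}

cnn_backward <- function(model, fwd, Y) {
  spec <- model$spec
  p <- model$params
  B <- fwd$caches$B
  P <- prod(spec$input_shape)
  d <- fwd$caches$dense
  grads <- list()
  dZo <- (fwd$probs - Y) / B
  grads$Wout <- crossprod(d$A2, dZo)
  grads$bout <- colSums(dZo)
  dA2 <- tcrossprod(dZo, p$Wout)
  if (!is.null(d$D2)) dA2 <- dA2 * d$D2
  dZ2 <- dA2 * (d$Z2 > 0)
  grads$Wd2 <- crossprod(d$A1, dZ2)
  grads$bd2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, p$Wd2)
  if (!is.null(d$D1)) dA1 <- dA1 * d$D1
  dZ1 <- dA1 * (d$Z1 > 0)
  grads$Wd1 <- crossprod(d$Xc, dZ1)
  grads$bd1 <- colSums(dZ1)
  dXc <- tcrossprod(dZ1, p$Wd1)
  col0 <- 0L
  FN <- spec$n_filters
  for (bn in names(spec$branches)) {
    g <- model$geom[[bn]]
    cb <- fwd$caches[[bn]]
    ncols <- g$Po * FN
    dXf <- dXc[, (col0 + 1L):(col0 + ncols), drop = FALSE]
    col0 <- col0 + ncols
    if (!is.null(cb$drop)) dXf <- dXf * cb$drop
    dM <- unflatten_act(dXf, B, g$Po)
    dA_pool <- pool_backward(dM, cb$pl, FN)
    bk2 <- conv_backward(dA_pool, cb$c2, p[[paste0(bn, "_W2")]], cb$idx2, FN)
    grads[[paste0(bn, "_W2")]] <- bk2$dW
    grads[[paste0(bn, "_b2")]] <- bk2$db
    bk1 <- conv_backward(bk2$dX, cb$c1, p[[paste0(bn, "_W1")]], cb$idx1, 1L)
    grads[[paste0(bn, "_W1")]] <- bk1$dW
    grads[[paste0(bn, "_b1")]] <- bk1$db
  }
  grads
}

#' Training configuration
#'
#' Adam optimization with validation-accuracy early stopping: training halts
#' once the validation accuracy has failed to improve on its running best by
#' at least `min_delta` for `patience` consecutive epochs, and the weights
#' from the best epoch are restored.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs hard epoch cap.
#' @param min_delta minimum validation-accuracy improvement that resets
#'   patience (default 0.001).
#' @param patience epochs without improvement tolerated before stopping.
#' @param val_fraction fraction of the training rows held out (stratified by
#'   class) as the validation set when no explicit validation set is given.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 40L, min_delta = 0.001, patience = 5L,
                         val_fraction = 0.1) {
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), min_delta = min_delta,
                 patience = as.integer(patience), val_fraction = val_fraction),
            class = "train_config")
}

feature_cols <- function(df, w = NULL) {
  fn <- grep("_win[0-9]+$", names(df), value = TRUE)
  if (!length(fn)) stop("no feature columns (<stat>_win<i>) found")
  fn
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x[, feature_cols(x), drop = FALSE])
}

adam_step <- function(state, params, grads, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mh <- state$m[[nm]] / (1 - b1^t)
    vh <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

#' Train the convolutional sweep classifier
#'
#' @param model a [build_cnn()] model (or NULL to build one from `spec`).
#' @param data tibble with a `label` column and the `<stat>_win<i>` feature
#'   columns (e.g. from [build_training_set()]); rows with `set == "test"`
#'   are ignored here.
#' @param config a [train_config()].
#' @param spec a [cnn_spec()] used when `model` is NULL.
#' @param quiet suppress per-epoch messages.
#' @return The trained `sweep_cnn`, with a `history` tibble (per-epoch
#'   training loss and validation accuracy).
#' @export
train_cnn <- function(model = NULL, data, config = train_config(),
                      spec = cnn_spec(), quiet = TRUE) {
  if (is.null(model)) model <- build_cnn(spec)
  if ("set" %in% names(data)) data <- data[data$set == "train", , drop = FALSE]
  if (!nrow(data)) stop("empty training set")
  labs <- factor(as.character(data$label), levels = model$classes)
  if (anyNA(labs)) stop("labels outside the known classes")
  if (length(unique(labs)) < 2) stop("training set must contain at least 2 classes")
  X <- as_feature_matrix(data)
  n <- nrow(X)
  # stratified validation split
  val_idx <- unlist(lapply(split(seq_len(n), labs, drop = TRUE), function(ix) {
    k <- max(1L, round(length(ix) * config$val_fraction))
    ix[sample.int(length(ix), k)]
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Y <- matrix(0, n, model$spec$n_classes)
  Y[cbind(seq_len(n), as.integer(labs))] <- 1
  state <- list(m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  best_acc <- -Inf
  best_params <- model$params
  wait <- 0L
  tstep <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    losses <- c()
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      fwd <- cnn_forward(model, X[bi, , drop = FALSE], training = TRUE)
      pr <- pmax(fwd$probs, 1e-12)
      losses <- c(losses, -mean(rowSums(Y[bi, , drop = FALSE] * log(pr))))
      grads <- cnn_backward(model, fwd, Y[bi, , drop = FALSE])
      tstep <- tstep + 1L
      upd <- adam_step(state, model$params, grads, config$learning_rate, tstep)
      state <- upd$state
      model$params <- upd$params
    }
    val_pred <- cnn_forward(model, X[val_idx, , drop = FALSE])$probs
    val_acc <- mean(max.col(val_pred) == as.integer(labs[val_idx]))
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = mean(losses),
                                    val_accuracy = val_acc)
    if (!quiet) message(sprintf("epoch %d: loss %.4f val_acc %.4f", epoch,
                                mean(losses), val_acc))
    if (val_acc > best_acc + config$min_delta) {
      best_acc <- val_acc
      best_params <- model$params
      wait <- 0L
    } else {
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_params <- model$params
      }
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  model$history <- dplyr::bind_rows(hist)
  model
}
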