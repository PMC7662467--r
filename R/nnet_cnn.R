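# 1-D CNN sleep-wake classifier on instantaneous heart rate + delayed SpO2.
# Five convolution blocks (each halving the sequence length), two dense
# layers, dropout and a softmax head; trained with Adam.

#' Sleep-wake classifier configuration
#'
#' Defaults follow the reference architecture: 5-min (300 samples at 1 Hz)
#' two-channel input, five convolution blocks of 10 filters, kernel 8,
#' strides 1 and 2 (each block halves its input length: 300 -> 150 -> 75 ->
#' 38 -> 19 -> 10), two 20-node dense layers, dropout 0.5 on the last
#' convolution block and both dense layers, L2 beta = 0.3, Adam at 1e-3,
#' batch size 100.
#'
#' @param input_span_s input window length, seconds at 1 Hz.
#' @param epoch_s hypnogram epoch length.
#' @param conv_blocks,filters,kernel,strides convolution architecture.
#' @param fc_nodes dense-layer widths.
#' @param dropout_p dropout probability during training.
#' @param l2_beta,learning_rate,batch_size,epochs optimizer settings.
#' @param n_channels input channels (IHR + delayed SpO2).
#' @param seed RNG seed.
#' @return list of class `sleepwake_config`.
#' @export
sleepwake_config <- function(input_span_s = 300, epoch_s = 30,
                             conv_blocks = 5, filters = 10, kernel = 8,
                             strides = c(1, 2), fc_nodes = c(20, 20),
                             dropout_p = 0.5, l2_beta = 0.3,
                             learning_rate = 1e-3, batch_size = 100,
                             epochs = 120, n_channels = 2, seed = 1L) {
  structure(list(input_span_s = input_span_s, epoch_s = epoch_s,
                 conv_blocks = conv_blocks, filters = filters,
                 kernel = kernel, strides = strides, fc_nodes = fc_nodes,
                 dropout_p = dropout_p, l2_beta = l2_beta,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, n_channels = n_channels, seed = seed),
            class = "sleepwake_config")
}

# 'same'-padded 1-D convolution forward via shift-accumulate.
# X: [B, L, Cin]; W: [k, Cin, f]; returns [B, Lout, f], Lout = ceil(L/s)
conv1d_forward <- function(X, W, b, stride) {
  B <- dim(X)[1]; L <- dim(X)[2]; Cin <- dim(X)[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  pad_l <- (k - 1) %/% 2; pad_r <- k - 1 - pad_l
  Lp <- L + pad_l + pad_r
  Xp <- array(0, c(B, Lp, Cin))
  Xp[, (pad_l + 1):(pad_l + L), ] <- X
  out_pos <- seq(1, L, by = stride)
  Lout <- length(out_pos)
  Y <- matrix(rep(b, each = B * Lout), B * Lout, f)
  for (kk in seq_len(k)) {
    sl <- matrix(Xp[, out_pos + kk - 1, , drop = FALSE], B * Lout, Cin)
    Y <- Y + sl %*% matrix(W[kk, , ], Cin, f)
  }
  array(Y, c(B, Lout, f))
}

# gradient of conv1d_forward wrt inputs and weights
conv1d_backward <- function(X, W, stride, dY) {
  B <- dim(X)[1]; L <- dim(X)[2]; Cin <- dim(X)[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  pad_l <- (k - 1) %/% 2; pad_r <- k - 1 - pad_l
  Lp <- L + pad_l + pad_r
  Xp <- array(0, c(B, Lp, Cin))
  Xp[, (pad_l + 1):(pad_l + L), ] <- X
  out_pos <- seq(1, L, by = stride)
  Lout <- length(out_pos)
  dYm <- matrix(dY, B * Lout, f)
  dW <- array(0, dim(W))
  dXp <- array(0, c(B, Lp, Cin))
  for (kk in seq_len(k)) {
    pos <- out_pos + kk - 1
    sl <- matrix(Xp[, pos, , drop = FALSE], B * Lout, Cin)
    dW[kk, , ] <- t(sl) %*% dYm
    dsl <- array(dYm %*% t(matrix(W[kk, , ], Cin, f)), c(B, Lout, Cin))
    dXp[, pos, ] <- dXp[, pos, ] + dsl
  }
  list(dX = dXp[, (pad_l + 1):(pad_l + L), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

cnn_init <- function(cfg) {
  set.seed(cfg$seed)
  par <- list()
  cin <- cfg$n_channels
  L <- cfg$input_span_s
  glorot <- function(dims, fan_in, fan_out) {
    array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
  }
  for (bl in seq_len(cfg$conv_blocks)) {
    for (ci in seq_along(cfg$strides)) {
      nm <- sprintf("W_c%d_%d", bl, ci)
      par[[nm]] <- glorot(c(cfg$kernel, cin, cfg$filters),
                          cfg$kernel * cin, cfg$filters)
      par[[sprintf("b_c%d_%d", bl, ci)]] <- rep(0, cfg$filters)
      cin <- cfg$filters
      L <- ceiling(L / cfg$strides[ci])
    }
  }
  flat <- L * cfg$filters
  dims <- c(flat, cfg$fc_nodes, 2)
  for (d in seq_len(length(dims) - 1)) {
    par[[sprintf("W_f%d", d)]] <- glorot(c(dims[d], dims[d + 1]),
                                         dims[d], dims[d + 1])
    par[[sprintf("b_f%d", d)]] <- rep(0, dims[d + 1])
  }
  par
}

# forward through the CNN; drop_masks NULL for inference (expectation mode)
cnn_forward <- function(par, cfg, X, drop_masks = NULL, cache = FALSE) {
  acts <- list()
  A <- X
  ci_names <- character(0)
  for (bl in seq_len(cfg$conv_blocks)) {
    for (ci in seq_along(cfg$strides)) {
      nm <- sprintf("c%d_%d", bl, ci)
      W <- par[[paste0("W_", nm)]]; b <- par[[paste0("b_", nm)]]
      Z <- conv1d_forward(A, W, b, cfg$strides[ci])
      R <- pmax(Z, 0)
      if (cache) acts[[nm]] <- list(A_in = A, Z = Z)
      A <- R
      ci_names <- c(ci_names, nm)
    }
  }
  if (!is.null(drop_masks)) A <- A * drop_masks$conv
  B <- dim(A)[1]
  flat <- matrix(A, B, dim(A)[2] * dim(A)[3])
  if (cache) acts$flat_dims <- dim(A)
  H <- flat
  n_fc <- length(cfg$fc_nodes)
  for (d in seq_len(n_fc)) {
    Z <- sweep(H %*% par[[sprintf("W_f%d", d)]], 2, par[[sprintf("b_f%d", d)]], "+")
    R <- pmax(Z, 0)
    if (cache) acts[[sprintf("f%d", d)]] <- list(H_in = H, Z = Z)
    H <- R
    if (!is.null(drop_masks)) H <- H * drop_masks$fc[[d]]
  }
  logits <- sweep(H %*% par[[sprintf("W_f%d", n_fc + 1)]], 2,
                  par[[sprintf("b_f%d", n_fc + 1)]], "+")
  if (cache) acts$head_in <- H
  list(probs = softmax_rows(logits), acts = acts)
}

cnn_backward <- function(par, cfg, fw, y_onehot, drop_masks) {
  acts <- fw$acts
  B <- nrow(fw$probs)
  n_fc <- length(cfg$fc_nodes)
  g <- list()
  dlog <- (fw$probs - y_onehot) / B
  nm <- sprintf("W_f%d", n_fc + 1)
  g[[nm]] <- t(acts$head_in) %*% dlog
  g[[sprintf("b_f%d", n_fc + 1)]] <- colSums(dlog)
  dH <- dlog %*% t(par[[nm]])
  for (d in rev(seq_len(n_fc))) {
    dH <- dH * drop_masks$fc[[d]]
    dZ <- dH * (acts[[sprintf("f%d", d)]]$Z > 0)
    g[[sprintf("W_f%d", d)]] <- t(acts[[sprintf("f%d", d)]]$H_in) %*% dZ
    g[[sprintf("b_f%d", d)]] <- colSums(dZ)
    dH <- dZ %*% t(par[[sprintf("W_f%d", d)]])
  }
  dA <- array(dH, acts$flat_dims)
  dA <- dA * drop_masks$conv
  for (bl in rev(seq_len(cfg$conv_blocks))) {
    for (ci in rev(seq_along(cfg$strides))) {
      nm <- sprintf("c%d_%d", bl, ci)
      dZ <- dA * (acts[[nm]]$Z > 0)
      bk <- conv1d_backward(acts[[nm]]$A_in, par[[paste0("W_", nm)]],
                            cfg$strides[ci], dZ)
      g[[paste0("W_", nm)]] <- bk$dW
      g[[paste0("b_", nm)]] <- bk$db
      dA <- bk$dX
    }
  }
  g
}

#' Train the CNN sleep-wake classifier
#'
#' Input windows are 5-min two-channel (IHR, 20-s-delayed SpO2) segments,
#' each channel normalized per window by subtracting its median. Training
#' is deterministic given `cfg$seed`.
#'
#' @param windows list with `x` (`[n, 300, 2]` array) and `y` (character
#'   `"sleep"`/`"wake"`); both classes must be present.
#' @param cfg a [sleepwake_config()].
#' @param verbose print per-epoch loss.
#' @return list of class `sleepwake_model`.
#' @export
train_sleepwake <- function(windows, cfg = sleepwake_config(),
                            verbose = FALSE) {
  x <- windows$x; y <- windows$y
  if (dim(x)[2] < cfg$input_span_s) {
    stop("input windows shorter than ", cfg$input_span_s, " s", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  yi <- match(y, c("sleep", "wake"))
  if (anyNA(yi)) stop("labels must be 'sleep'/'wake'", call. = FALSE)
  par <- cnn_init(cfg)           # seeds the RNG
  x <- cnn_normalize(x)
  st <- adam_init(par)
  wnames <- grep("^W_", names(par), value = TRUE)
  n <- dim(x)[1]
  losses <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; seen <- 0
    for (s0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s0:min(n, s0 + cfg$batch_size - 1)]
      xb <- x[idx, , , drop = FALSE]
      yb <- yi[idx]
      masks <- cnn_drop_masks(cfg, length(idx))
      fw <- cnn_forward(par, cfg, xb, masks, cache = TRUE)
      onehot <- matrix(0, length(idx), 2)
      onehot[cbind(seq_along(idx), yb)] <- 1
      ce <- -mean(log(pmax(fw$probs[cbind(seq_along(idx), yb)], 1e-12)))
      grads <- cnn_backward(par, cfg, fw, onehot, masks)
      l2 <- add_l2(grads, par, cfg$l2_beta, wnames)
      upd <- adam_step(par, l2$grads, st, cfg$learning_rate)
      par <- upd$par; st <- upd$st
      ep_loss <- ep_loss + (ce + l2$penalty) * length(idx)
      seen <- seen + length(idx)
    }
    losses <- c(losses, ep_loss / seen)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
  }
  structure(list(par = par, cfg = cfg, loss_curve = losses),
            class = "sleepwake_model")
}

# per-window median subtraction, per channel
cnn_normalize <- function(x) {
  for (ch in seq_len(dim(x)[3])) {
    med <- apply(x[, , ch, drop = FALSE], 1, stats::median)
    x[, , ch] <- x[, , ch] - med
  }
  x
}

# inverted dropout masks (training); inference uses no masks
cnn_drop_masks <- function(cfg, B) {
  L <- cfg$input_span_s
  for (s in rep(cfg$strides, cfg$conv_blocks)) L <- ceiling(L / s)
  keep <- 1 - cfg$dropout_p
  conv <- array(stats::rbinom(B * L * cfg$filters, 1, keep) / keep,
                c(B, L, cfg$filters))
  fc <- lapply(cfg$fc_nodes, function(w)
    matrix(stats::rbinom(B * w, 1, keep) / keep, B, w))
  list(conv = conv, fc = fc)
}

#' Sleep/wake probabilities for prepared 5-min windows
#' @param model a `sleepwake_model`.
#' @param x array `[n, 300, 2]` of input windows.
#' @return matrix `[n, 2]` of (sleep, wake) probabilities.
#' @export
predict_sleepwake_probs <- function(model, x) {
  x <- cnn_normalize(x)
  cnn_forward(model$par, model$cfg, x)$probs
}

#' Score a recording's 30-s epochs as sleep or wake
#'
#' Builds the IHR (1 Hz, previous-value held) and 20-s-delayed SpO2
#' channels, takes the 5-min context window centred on each 30-s epoch
#' (edge-padded at the night's ends), and applies the CNN. An epoch is
#' wake when the wake output is greater than or equal to the sleep output.
#'
#' @param model a `sleepwake_model`.
#' @param rec a [recording()] (needs `r_peaks` or `ecg`, and `spo2`).
#' @return list of [hypno_epoch()] tiling the recording.
#' @export
predict_sleepwake <- function(model, rec) {
  chans <- sleepwake_channels(rec)
  if (is.null(chans)) stop("missing IHR source: recording has neither r_peaks nor ecg",
                           call. = FALSE)
  cfg <- model$cfg
  dur <- recording_duration(rec)
  n_ep <- floor(dur / cfg$epoch_s)
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  x <- array(0, c(n_ep, cfg$input_span_s, 2))
  half <- (cfg$input_span_s - cfg$epoch_s) / 2
  n <- length(chans$ihr)
  for (e in seq_len(n_ep)) {
    t0 <- (e - 1) * cfg$epoch_s - half
    idx <- floor(t0) + seq_len(cfg$input_span_s)
    idx <- pmin(n, pmax(1L, as.integer(idx)))
    x[e, , 1] <- chans$ihr[idx]
    x[e, , 2] <- chans$spo2_delayed[idx]
  }
  p <- predict_sleepwake_probs(model, x)
  states <- ifelse(p[, 2] >= p[, 1], "wake", "sleep")
  hypnogram_from_states(states)
}

# 1-Hz IHR and 20-s-delayed SpO2 channels over the whole recording
sleepwake_channels <- function(rec, delay_s = 20) {
  peaks <- rec$r_peaks
  if (is.null(peaks)) {
    if (is.null(rec$ecg)) return(NULL)
    peaks <- detect_r_peaks(rec$ecg)
  }
  dur <- recording_duration(rec)
  ihr_s <- ihr(peaks, duration_s = dur)
  sp <- rec$spo2
  tt <- 0:(ceiling(dur) - 1)
  del_idx <- pmin(length(sp$samples),
                  pmax(1L, as.integer(floor((tt + delay_s - sp$start_s) * sp$rate_hz) + 1L)))
  list(ihr = ihr_s$samples, spo2_delayed = sp$samples[del_idx])
}
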