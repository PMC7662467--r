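# Batched LSTM sequence classifier trained with Adam, cross-entropy +
# L2 loss and global-norm gradient clipping. Written in base R matrix ops;
# sizes here (9 inputs, 80 cells, 40-step windows) are small enough that
# BLAS-backed batching is fast.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Event-classifier configuration
#'
#' Defaults follow the reference architecture: 9 input features, 80 LSTM
#' cells, 4 output classes, 20-s windows (40 frames at the 0.5-s step),
#' Adam with learning rate 1e-3, L2 penalty beta = 0.05 and gradient
#' clipping (global norm 5). `epochs`/`batches_per_epoch` form the training
#' budget cap; desk-scale runs use far less.
#'
#' @param n_inputs,n_hidden_cells,n_outputs network sizes.
#' @param seq_span_s window span N in seconds.
#' @param frame_step_s feature-frame step in seconds.
#' @param epochs,batches_per_epoch,batch_size training budget.
#' @param learning_rate,l2_beta,grad_clip_norm optimizer settings.
#' @param early_stop_patience epochs of non-improving smoothed loss before
#'   stopping (0 disables early stopping; default off).
#' @param seed RNG seed for deterministic training.
#' @return list of class `event_model_config`.
#' @export
event_model_config <- function(n_inputs = 9, n_hidden_cells = 80,
                               n_outputs = 4, seq_span_s = 20,
                               frame_step_s = 0.5, epochs = 500,
                               batches_per_epoch = 500, batch_size = 32,
                               learning_rate = 0.001, l2_beta = 0.05,
                               grad_clip_norm = 5, early_stop_patience = 0,
                               seed = 1L) {
  cfg <- list(n_inputs = n_inputs, n_hidden_cells = n_hidden_cells,
              n_outputs = n_outputs, seq_span_s = seq_span_s,
              frame_step_s = frame_step_s, epochs = epochs,
              batches_per_epoch = batches_per_epoch, batch_size = batch_size,
              learning_rate = learning_rate, l2_beta = l2_beta,
              grad_clip_norm = grad_clip_norm,
              early_stop_patience = early_stop_patience, seed = seed)
  stopifnot(all(vapply(cfg[c("n_inputs", "n_hidden_cells", "n_outputs",
                             "seq_span_s", "epochs", "batches_per_epoch",
                             "batch_size", "learning_rate", "l2_beta",
                             "grad_clip_norm")], function(v) v > 0, TRUE)))
  structure(cfg, class = "event_model_config")
}

lstm_init <- function(cfg) {
  ni <- cfg$n_inputs; nh <- cfg$n_hidden_cells; no <- cfg$n_outputs
  r <- function(n, m) matrix(stats::runif(n * m, -0.08, 0.08), n, m)
  b <- rep(0, 4 * nh)
  b[(nh + 1):(2 * nh)] <- 1    # forget-gate bias init
  list(Wx = r(ni, 4 * nh), Wh = r(nh, 4 * nh), b = b,
       Why = r(nh, no), by = rep(0, no))
}

# forward pass over a batch; X is [B, T, ni]. Returns probs and (optionally)
# the cached gate activations for BPTT.
lstm_forward <- function(par, X, cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  nh <- ncol(par$Wh)
  nh <- nh / 4
  h <- matrix(0, B, nh); cst <- matrix(0, B, nh)
  caches <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], nrow = B)
    Z <- xt %*% par$Wx + h %*% par$Wh
    Z <- sweep(Z, 2, par$b, "+")
    i <- sigmoid(Z[, 1:nh, drop = FALSE])
    f <- sigmoid(Z[, (nh + 1):(2 * nh), drop = FALSE])
    o <- sigmoid(Z[, (2 * nh + 1):(3 * nh), drop = FALSE])
    g <- tanh(Z[, (3 * nh + 1):(4 * nh), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    if (cache) caches[[t]] <- list(xt = xt, i = i, f = f, o = o, g = g,
                                   c = cst, c_prev = c_prev, tc = tc,
                                   h_prev = h_prev)
  }
  logits <- sweep(h %*% par$Why, 2, par$by, "+")
  list(probs = softmax_rows(logits), h = h, caches = caches)
}

# BPTT gradients for mean cross-entropy over the batch
lstm_backward <- function(par, fw, y_onehot) {
  B <- nrow(fw$probs); nh <- ncol(fw$h)
  dlogits <- (fw$probs - y_onehot) / B
  g <- list(Wx = array(0, dim(par$Wx)), Wh = array(0, dim(par$Wh)),
            b = rep(0, length(par$b)), Why = t(fw$h) %*% dlogits,
            by = colSums(dlogits))
  dh <- dlogits %*% t(par$Why)
  dc <- matrix(0, B, nh)
  for (t in rev(seq_along(fw$caches))) {
    cc <- fw$caches[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dZi <- di * cc$i * (1 - cc$i)
    dZf <- df * cc$f * (1 - cc$f)
    dZo <- do_ * cc$o * (1 - cc$o)
    dZg <- dg * (1 - cc$g^2)
    dZ <- cbind(dZi, dZf, dZo, dZg)
    g$Wx <- g$Wx + t(cc$xt) %*% dZ
    g$Wh <- g$Wh + t(cc$h_prev) %*% dZ
    g$b <- g$b + colSums(dZ)
    dh <- dZ %*% t(par$Wh)
    dc <- dc * cc$f
  }
  g
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(par, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0)
}

adam_step <- function(par, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, st = st)
}

clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  grads
}

# L2 regularization on the weight matrices (not biases). The penalty is
# beta/2 times the MEAN squared weight over all weight parameters, so the
# effective strength is independent of architecture size; a raw sum would
# make the stated betas overwhelm the cross-entropy for any realistically
# sized network.
add_l2 <- function(grads, par, beta, weight_names) {
  n_all <- sum(vapply(par[weight_names], length, 0L))
  pen <- 0
  for (nm in weight_names) {
    grads[[nm]] <- grads[[nm]] + beta * par[[nm]] / n_all
    pen <- pen + sum(par[[nm]]^2)
  }
  list(grads = grads, penalty = beta * pen / (2 * n_all))
}

#' Build labelled training windows from per-frame features
#'
#' Slices a night's feature frames into windows of `seq_span_s` seconds
#' (40 frames by default); the window label is the per-frame label at the
#' window's centre, i.e. of the step the window scores
#' (see [predict_event_probs()]), so the target always has half a window
#' of context on each side and training matches the per-step prediction
#' convention with no systematic lag.
#'
#' Windows overlapping scored events are sampled densely
#' (`event_stride_frames`) and normal breathing sparsely
#' (`nor_stride_frames`), which roughly balances the four classes without
#' touching the loss (no class weighting is used).
#'
#' @param frames a `feature_frames` data.frame.
#' @param labels character vector of per-frame kinds (`NOR`/`OSA`/`CSA`/
#'   `HYP`), same length as `nrow(frames)`.
#' @param cfg an [event_model_config()].
#' @param nor_stride_frames stride between windows in normal spans.
#' @param event_stride_frames stride inside/near events.
#' @return list with `x` (array `[n, T, 9]`), `y` (character labels),
#'   `t_end` (window end times).
#' @export
make_event_windows <- function(frames, labels, cfg = event_model_config(),
                               nor_stride_frames = 20L,
                               event_stride_frames = 2L) {
  Tn <- as.integer(round(cfg$seq_span_s / cfg$frame_step_s))
  fm <- as.matrix(as.data.frame(frames)[, FEATURE_NAMES])
  n <- nrow(fm)
  if (n < Tn) stop("fewer frames than one window", call. = FALSE)
  half <- Tn %/% 2L
  centre_of <- function(end) end - half + 1L   # label point of a window
  near_event <- labels != "NOR"
  ends <- sort(unique(c(
    seq(Tn, n, by = nor_stride_frames),
    intersect(seq(Tn, n, by = event_stride_frames),
              which(near_event) + half - 1L))))
  ends <- ends[ends >= Tn & ends <= n]
  x <- array(0, c(length(ends), Tn, cfg$n_inputs))
  y <- character(length(ends))
  for (k in seq_along(ends)) {
    idx <- (ends[k] - Tn + 1L):ends[k]
    x[k, , ] <- fm[idx, ]
    y[k] <- labels[centre_of(ends[k])]
  }
  list(x = x, y = y, t_end = frames$t_s[ends],
       t_centre = frames$t_s[centre_of(ends)])
}

#' Train the LSTM event classifier
#'
#' Trains on labelled windows (see [make_event_windows()]) with Adam,
#' cross-entropy + L2 loss and gradient clipping. Features are
#' standardized with training-set statistics stored in the model.
#' Deterministic given `cfg$seed`.
#'
#' @param windows list with `x` (`[n, T, 9]` array) and `y` (labels); at
#'   least two classes must be present.
#' @param cfg an [event_model_config()].
#' @param verbose print per-epoch loss.
#' @return list of class `event_model`: parameters, config, feature
#'   normalization and the training-loss curve.
#' @export
train_event_model <- function(windows, cfg = event_model_config(),
                              verbose = FALSE) {
  x <- windows$x; y <- windows$y
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (dim(x)[3] != cfg$n_inputs) {
    stop("feature count mismatch: got ", dim(x)[3], ", config says ",
         cfg$n_inputs, call. = FALSE)
  }
  set.seed(cfg$seed)
  mu <- apply(x, 3, mean)
  sdv <- pmax(apply(x, 3, sd), 1e-6)
  for (j in seq_len(dim(x)[3])) x[, , j] <- (x[, , j] - mu[j]) / sdv[j]
  yi <- match(y, EVENT_KINDS)
  if (anyNA(yi)) stop("unknown event kind in labels", call. = FALSE)
  n <- dim(x)[1]
  par <- lstm_init(cfg)
  st <- adam_init(par)
  wnames <- c("Wx", "Wh", "Why")
  losses <- numeric(0)
  best <- Inf; wait <- 0
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    nb <- min(cfg$batches_per_epoch, ceiling(n / cfg$batch_size))
    ep_loss <- 0; seen <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1) * cfg$batch_size) %% n + 1):min(n, ((b - 1) * cfg$batch_size) %% n + cfg$batch_size)]
      xb <- x[idx, , , drop = FALSE]
      yb <- yi[idx]
      onehot <- matrix(0, length(idx), cfg$n_outputs)
      onehot[cbind(seq_along(idx), yb)] <- 1
      fw <- lstm_forward(par, xb, cache = TRUE)
      ce <- -mean(log(pmax(fw$probs[cbind(seq_along(idx), yb)], 1e-12)))
      grads <- lstm_backward(par, fw, onehot)
      l2 <- add_l2(grads, par, cfg$l2_beta, wnames)
      grads <- clip_global_norm(l2$grads, cfg$grad_clip_norm)
      upd <- adam_step(par, grads, st, cfg$learning_rate)
      par <- upd$par; st <- upd$st
      ep_loss <- ep_loss + (ce + l2$penalty) * length(idx)
      seen <- seen + length(idx)
    }
    losses <- c(losses, ep_loss / seen)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
    if (cfg$early_stop_patience > 0) {
      sm <- mean(utils::tail(losses, 5))
      if (sm < best - 1e-5) { best <- sm; wait <- 0 } else wait <- wait + 1
      if (wait >= cfg$early_stop_patience) break
    }
  }
  structure(list(par = par, cfg = cfg, feature_names = FEATURE_NAMES,
                 mu = mu, sd = sdv, loss_curve = losses),
            class = "event_model")
}

#' Per-step class probabilities from the LSTM event classifier
#'
#' One softmax row per 0.5-s feature step; step `t` is scored by the
#' `seq_span_s`-second window centred on it (the recording is processed
#' offline, so half a window of look-ahead is available and keeps the
#' target time in the middle of its context). Steps near the night's
#' edges reuse edge-padded context.
#'
#' @param model an `event_model` from [train_event_model()].
#' @param frames a `feature_frames` data.frame (columns must match the
#'   model's feature set in order).
#' @return data.frame of class `prob_series`: `t_s`, `p_nor`, `p_osa`,
#'   `p_csa`, `p_hyp`.
#' @export
predict_event_probs <- function(model, frames) {
  fdf <- as.data.frame(frames)
  have <- setdiff(names(fdf), "t_s")
  if (!identical(have, model$feature_names)) {
    stop("feature columns do not match the model (order matters): got ",
         paste(have, collapse = ","), call. = FALSE)
  }
  cfg <- model$cfg
  Tn <- as.integer(round(cfg$seq_span_s / cfg$frame_step_s))
  fm <- as.matrix(fdf[, model$feature_names])
  for (j in seq_len(ncol(fm))) fm[, j] <- (fm[, j] - model$mu[j]) / model$sd[j]
  n <- nrow(fm)
  if (n < 1) stop("no frames to score", call. = FALSE)
  probs <- matrix(0, n, 4)
  block <- 512L
  for (s0 in seq(1L, n, by = block)) {
    s1 <- min(n, s0 + block - 1L)
    nb <- s1 - s0 + 1L
    half <- Tn %/% 2L
    xb <- array(0, c(nb, Tn, ncol(fm)))
    for (k in seq_len(nb)) {
      i <- s0 + k - 1L
      idx <- (i + half - Tn + 1L):(i + half)   # window centred on step i
      idx[idx < 1L] <- 1L                      # edge padding
      idx[idx > n] <- n
      xb[k, , ] <- fm[idx, ]
    }
    probs[s0:s1, ] <- lstm_forward(model$par, xb)$probs
  }
  out <- data.frame(t_s = fdf$t_s, p_nor = probs[, 1], p_osa = probs[, 2],
                    p_csa = probs[, 3], p_hyp = probs[, 4])
  class(out) <- c("prob_series", "data.frame")
  out
}

#' Per-step hard labels from class probabilities
#'
#' Argmax per row; exact ties are broken by the fixed class order
#' NOR < OSA < CSA < HYP.
#'
#' @param probs a `prob_series` data.frame.
#' @return character vector of per-step kinds.
#' @export
decide_labels <- function(probs) {
  p <- as.matrix(as.data.frame(probs)[, c("p_nor", "p_osa", "p_csa", "p_hyp")])
  EVENT_KINDS[apply(p, 1, which.max)]
}
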