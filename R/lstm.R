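# Per-window LSTM sepsis predictor with hand-written backpropagation
# through time, balanced oversampling, the >0.5 lock rule, and random
# hyper-parameter search.
#
# Gate algebra per step (sigma = logistic, column blocks [input|forget|
# out|cell] of the combined weight matrices):
#   gate_i = sigma(W_ix x_t + W_ih h_{t-1} + b_i)      (input)
#   gate_f = sigma(W_fx x_t + W_fh h_{t-1} + b_f)      (forget)
#   gate_o = sigma(W_ox x_t + W_oh h_{t-1} + b_o)      (out)
#   c_star = tanh (W_cx x_t + W_ch h_{t-1} + b_c)      (candidate cell)
#   C_t    = gate_f * C_{t-1} + gate_i * c_star
#   h_t    = gate_o * tanh(C_t)                        (default)
#   h_t    = gate_f * tanh(C_t)                        (h_mode = "forget")
# The "forget" variant reproduces a published formulation that reuses the
# forget gate in the hidden-state update; the conventional output-gate
# update is the default.

GATE_I <- 1L; GATE_F <- 2L; GATE_O <- 3L; GATE_G <- 4L

gate_cols <- function(which, H) ((which - 1L) * H + 1L):(which * H)

#' LSTM training configuration
#'
#' The reference hyper-parameter grid is hidden layers \{1, 2, 3\},
#' neurons \{512, 800, 1024, 2048\}, dropout \{0, 0.1, 0.2, 0.3\}, epochs
#' \{1, 2\}, log-softmax classification, Adam optimization, and mini-batch
#' sizes of 1000 (non-text / clinical-text) or 500 (multi-modal); the
#' defaults here are desk-scale.
#'
#' @param hidden Hidden units per layer.
#' @param n_layers Number of stacked LSTM layers.
#' @param dropout Dropout fraction on layer outputs during training.
#' @param epochs Training epochs (each epoch covers the negative class
#'   once through balanced batches).
#' @param batch_size Episodes per mini-batch.
#' @param lr Adam step size.
#' @param h_mode `"output"` (conventional) or `"forget"` (reuse the forget
#'   gate in the hidden-state update).
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden = 16, n_layers = 1, dropout = 0, epochs = 1,
                         batch_size = 64, lr = 1e-3,
                         h_mode = c("output", "forget"), seed = 1) {
  h_mode <- match.arg(h_mode)
  stopifnot(hidden >= 1, n_layers >= 1, dropout >= 0, dropout < 1,
            epochs >= 1, batch_size >= 2)
  structure(
    list(hidden = as.integer(hidden), n_layers = as.integer(n_layers),
         dropout = dropout, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), lr = lr, h_mode = h_mode,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Initialize LSTM weights
#'
#' @param input_dim Input feature count per window.
#' @param config A [train_config()].
#' @return Nested weight list: per layer `Wx` (input x 4*hidden), `Wh`
#'   (hidden x 4*hidden), `b`; plus the 2-logit output head `Wy`, `by`.
#' @export
lstm_init <- function(input_dim, config) {
  with_seed_tag(config$seed, "init", {
    H <- config$hidden
    layers <- vector("list", config$n_layers)
    d_in <- input_dim
    for (l in seq_len(config$n_layers)) {
      k <- 1 / sqrt(H)
      layers[[l]] <- list(
        Wx = matrix(runif(d_in * 4 * H, -k, k), d_in, 4 * H),
        Wh = matrix(runif(H * 4 * H, -k, k), H, 4 * H),
        b = rep(0, 4 * H)
      )
      d_in <- H
    }
    list(layers = layers,
         head = list(Wy = matrix(runif(H * 2, -1 / sqrt(H), 1 / sqrt(H)),
                                 H, 2),
                     by = rep(0, 2)))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM step
#'
#' Advances the hidden and cell state by one window. Inputs may be a
#' single vector or a batch matrix (rows = batch).
#'
#' @param x Input vector (length D) or B x D matrix.
#' @param state List with `h` and `c` (vectors of length H or B x H
#'   matrices).
#' @param layer One layer's weights from [lstm_init()] (`Wx`, `Wh`, `b`).
#' @param h_mode `"output"` or `"forget"` hidden-state update.
#' @return List `h`, `c` (same shape as the inputs), plus the gate
#'   activations `i`, `f`, `o`, `g`.
#' @export
lstm_step <- function(x, state, layer, h_mode = c("output", "forget")) {
  h_mode <- match.arg(h_mode)
  if (is.null(dim(x))) x <- matrix(x, 1)
  h <- state$h; c_prev <- state$c
  if (is.null(dim(h))) h <- matrix(h, 1)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, 1)
  if (!all(is.finite(x))) abort("non-finite input to lstm_step.")
  H <- ncol(h)
  A <- x %*% layer$Wx + h %*% layer$Wh +
    matrix(layer$b, nrow(x), 4 * H, byrow = TRUE)
  gi <- sigmoid(A[, gate_cols(GATE_I, H), drop = FALSE])
  gf <- sigmoid(A[, gate_cols(GATE_F, H), drop = FALSE])
  go <- sigmoid(A[, gate_cols(GATE_O, H), drop = FALSE])
  gg <- tanh(A[, gate_cols(GATE_G, H), drop = FALSE])
  cc <- gf * c_prev + gi * gg
  hh <- if (h_mode == "output") go * tanh(cc) else gf * tanh(cc)
  list(h = hh, c = cc, i = gi, f = gf, o = go, g = gg)
}

# full forward pass over a padded batch; xs = list over time of B x D
# matrices. Returns per-layer caches and head log-probabilities.
lstm_forward <- function(weights, xs, config, train = FALSE) {
  B <- nrow(xs[[1]]); Tn <- length(xs)
  H <- config$hidden; L <- length(weights$layers)
  caches <- vector("list", L)
  inputs <- xs
  drop_masks <- vector("list", L)
  for (l in seq_len(L)) {
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache <- vector("list", Tn)
    outs <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      st <- lstm_step(inputs[[t]], list(h = h, c = cc),
                      weights$layers[[l]], config$h_mode)
      cache[[t]] <- list(x = inputs[[t]], h_prev = h, c_prev = cc,
                         i = st$i, f = st$f, o = st$o, g = st$g,
                         c = st$c, tc = tanh(st$c))
      h <- st$h; cc <- st$c
      outs[[t]] <- h
    }
    if (train && config$dropout > 0) {
      dm <- lapply(seq_len(Tn), function(t) {
        matrix(rbinom(B * H, 1, 1 - config$dropout), B, H) /
          (1 - config$dropout)
      })
      outs <- lapply(seq_len(Tn), function(t) outs[[t]] * dm[[t]])
      drop_masks[[l]] <- dm
    }
    caches[[l]] <- cache
    inputs <- outs
  }
  logits <- lapply(inputs, function(h) {
    h %*% weights$head$Wy +
      matrix(weights$head$by, nrow(h), 2, byrow = TRUE)
  })
  logp <- lapply(logits, function(z) {
    mx <- pmax(z[, 1], z[, 2])
    lse <- mx + log(exp(z[, 1] - mx) + exp(z[, 2] - mx))
    z - cbind(lse, lse)
  })
  list(caches = caches, tops = inputs, logp = logp,
       drop_masks = drop_masks)
}

# backward pass; y in {0,1}, seq_mask = B x T (1 inside the episode)
lstm_backward <- function(weights, fwd, y, seq_mask, config) {
  B <- length(y); Tn <- length(fwd$logp)
  H <- config$hidden; L <- length(weights$layers)
  denom <- sum(seq_mask)
  gWy <- weights$head$Wy * 0; gby <- weights$head$by * 0
  dh_in <- lapply(seq_len(Tn), function(t) matrix(0, B, H))
  for (t in seq_len(Tn)) {
    p <- exp(fwd$logp[[t]])
    dlog <- p
    dlog[cbind(seq_len(B), y + 1L)] <- dlog[cbind(seq_len(B), y + 1L)] - 1
    dlog <- dlog * seq_mask[, t] / denom
    gWy <- gWy + crossprod(fwd$tops[[t]], dlog)
    gby <- gby + colSums(dlog)
    dh_in[[t]] <- dlog %*% t(weights$head$Wy)
  }
  grads_layers <- vector("list", L)
  out_mode <- config$h_mode == "output"
  for (l in rev(seq_len(L))) {
    if (!is.null(fwd$drop_masks[[l]])) {
      dm <- fwd$drop_masks[[l]]
      dh_in <- lapply(seq_len(Tn), function(t) dh_in[[t]] * dm[[t]])
    }
    cache <- fwd$caches[[l]]
    Wx <- weights$layers[[l]]$Wx; Wh <- weights$layers[[l]]$Wh
    gWx <- Wx * 0; gWh <- Wh * 0; gb <- weights$layers[[l]]$b * 0
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    dx_out <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      cc <- cache[[t]]
      dh <- dh_in[[t]] + dh_next
      if (out_mode) {
        do_ <- dh * cc$tc
        dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
        df_h <- 0
      } else {
        do_ <- matrix(0, B, H)
        dc <- dh * cc$f * (1 - cc$tc^2) + dc_next
        df_h <- dh * cc$tc
      }
      di <- dc * cc$g
      dg <- dc * cc$i
      df <- dc * cc$c_prev + df_h
      dc_next <- dc * cc$f
      dA <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dg * (1 - cc$g^2))
      gWx <- gWx + crossprod(cc$x, dA)
      gWh <- gWh + crossprod(cc$h_prev, dA)
      gb <- gb + colSums(dA)
      dh_next <- dA %*% t(Wh)
      dx_out[[t]] <- dA %*% t(Wx)
    }
    grads_layers[[l]] <- list(Wx = gWx, Wh = gWh, b = gb)
    dh_in <- dx_out
  }
  list(layers = grads_layers, head = list(Wy = gWy, by = gby))
}

# --- Adam over an arbitrary nested weight tree ---------------------------

adam_tree_init <- function(w) {
  list(m = weights_scale(w, 0), v = weights_scale(w, 0), t = 0L)
}

adam_tree_step <- function(w, g, state, lr = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- weights_add(weights_scale(state$m, beta1),
                         weights_scale(g, 1 - beta1))
  state$v <- weights_add(weights_scale(state$v, beta2),
                         weights_scale(weights_map1(g, function(x) x^2),
                                       1 - beta2))
  mhat <- weights_scale(state$m, 1 / (1 - beta1^state$t))
  vhat <- weights_scale(state$v, 1 / (1 - beta2^state$t))
  step <- weights_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(w = weights_sub(w, step), state = state)
}

# --- batching -------------------------------------------------------------

#' Balanced oversampled mini-batches
#'
#' Every batch holds exactly `ceiling(batch_size / 2)` positive and
#' `floor(batch_size / 2)` negative episodes; the minority class is
#' resampled with replacement as needed. One pass covers the negative
#' class once.
#'
#' @param labels Logical (or 0/1) episode labels.
#' @param batch_size Episodes per batch.
#' @param seed Integer seed.
#' @return List of integer index vectors, each of length `batch_size`.
#' @export
make_balanced_batches <- function(labels, batch_size, seed = 1) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("both classes must be present to build balanced batches.")
  }
  n_pos <- as.integer(ceiling(batch_size / 2))
  n_neg <- as.integer(floor(batch_size / 2))
  with_seed_tag(seed, "batches", {
    neg_perm <- sample(neg)
    n_batches <- ceiling(length(neg) / n_neg)
    lapply(seq_len(n_batches), function(b) {
      lo <- (b - 1L) * n_neg + 1L
      hi <- min(b * n_neg, length(neg_perm))
      negs <- neg_perm[lo:hi]
      if (length(negs) < n_neg) {
        negs <- c(negs, sample(neg, n_neg - length(negs), replace = TRUE))
      }
      sample(c(sample(pos, n_pos, replace = TRUE), negs))
    })
  })
}

# pad a list of T_i x D matrices into time-major list + sequence mask
pad_batch <- function(mats) {
  B <- length(mats)
  lens <- vapply(mats, nrow, integer(1))
  Tn <- max(lens)
  D <- ncol(mats[[1]])
  seq_mask <- matrix(0, B, Tn)
  xs <- lapply(seq_len(Tn), function(t) {
    out <- matrix(0, B, D)
    for (b in seq_len(B)) {
      if (t <= lens[b]) out[b, ] <- mats[[b]][t, ]
    }
    out
  })
  for (b in seq_len(B)) seq_mask[b, seq_len(lens[b])] <- 1
  list(xs = xs, seq_mask = seq_mask)
}

masked_nll <- function(logp, y, seq_mask) {
  B <- length(y)
  total <- 0
  for (t in seq_along(logp)) {
    total <- total - sum(logp[[t]][cbind(seq_len(B), y + 1L)] * seq_mask[, t])
  }
  total / sum(seq_mask)
}

#' Train the per-window LSTM sepsis predictor
#'
#' Every window of an episode carries the episode label as its training
#' target; the loss is the masked negative log-likelihood of the
#' log-softmax head, averaged over real (unpadded) windows, optimized with
#' Adam over balanced mini-batches.
#'
#' @param grids Grid tibble (typically the training split) with completed
#'   `values` and a logical `label` column.
#' @param config A [train_config()].
#' @param init Optional initial weights (e.g. broadcast federated
#'   weights); fresh seeded initialization by default. The optimizer state
#'   is always fresh.
#' @return An `lstm_model`: `weights`, `config`, `input_dim`, and a
#'   per-batch `losses` tibble.
#' @export
train_lstm <- function(grids, config = train_config(), init = NULL) {
  if (nrow(grids) == 0L) abort("empty training set.")
  mats <- grids$values
  labels <- as.integer(grids$label)
  D <- ncol(mats[[1]])
  weights <- init %||% lstm_init(D, config)
  opt <- adam_tree_init(weights)
  losses <- list()
  for (ep in seq_len(config$epochs)) {
    batches <- make_balanced_batches(
      labels, min(config$batch_size, nrow(grids)),
      derive_seed(config$seed, paste0("epoch", ep))
    )
    with_seed_tag(config$seed, paste0("dropout", ep), {
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        pb <- pad_batch(mats[idx])
        fwd <- lstm_forward(weights, pb$xs, config, train = TRUE)
        loss <- masked_nll(fwd$logp, labels[idx], pb$seq_mask)
        grads <- lstm_backward(weights, fwd, labels[idx], pb$seq_mask, config)
        upd <- adam_tree_step(weights, grads, opt, lr = config$lr)
        weights <- upd$w; opt <- upd$state
        losses[[length(losses) + 1L]] <-
          tibble::tibble(epoch = ep, batch = bi, loss = loss)
      }
    })
  }
  structure(
    list(weights = weights, config = config, input_dim = D,
         losses = dplyr::bind_rows(losses)),
    class = "lstm_model"
  )
}

#' Per-window prediction trace for one episode
#'
#' Runs the model over the episode's windows, reports the positive-class
#' probability per window, locks at the first window with probability
#' strictly above 0.5 (later windows are ignored downstream), and scores
#' the episode with the lock-window probability, or the maximum window
#' probability if no window locks.
#'
#' @param model An `lstm_model`.
#' @param X Windows x features matrix for one episode.
#' @return List: `probs` (per window), `lock_window` (0-based index or
#'   `NA`), `episode_score`.
#' @export
predict_episode <- function(model, X) {
  if (ncol(X) != model$input_dim) abort("feature dimension mismatch.")
  xs <- lapply(seq_len(nrow(X)), function(t) matrix(X[t, ], 1))
  fwd <- lstm_forward(model$weights, xs, model$config, train = FALSE)
  probs <- vapply(fwd$logp, function(lp) exp(lp[1, 2]), numeric(1))
  trace_from_probs(probs)
}

# apply the >0.5 lock rule to a per-window probability sequence: lock at
# the first strictly-exceeding window, score with the lock probability or
# the maximum if no window locks
trace_from_probs <- function(probs) {
  lock <- which(probs > 0.5)
  lock_window <- if (length(lock)) lock[1] - 1L else NA_integer_
  score <- if (length(lock)) probs[lock[1]] else max(probs)
  list(probs = probs, lock_window = lock_window, episode_score = score)
}

#' Prediction traces for a grid collection
#'
#' @param model An `lstm_model`.
#' @param grids Grid tibble with completed `values`.
#' @return Tibble: `episode_id`, `label`, `onset_window`, `probs`
#'   (list-column), `lock_window`, `episode_score`.
#' @export
predict_cohort <- function(model, grids) {
  traces <- purrr::map(grids$values, predict_episode, model = model)
  tibble::tibble(
    episode_id = grids$episode_id,
    label = grids$label,
    onset_window = grids$onset_window,
    probs = purrr::map(traces, "probs"),
    lock_window = purrr::map_int(traces, "lock_window"),
    episode_score = purrr::map_dbl(traces, "episode_score")
  )
}

#' Random hyper-parameter search selected by tuning-split AUPRC
#'
#' Draws `n_draws` configurations uniformly without replacement from the
#' grid (capped at the grid size with a warning), trains each on the
#' training split, and returns the configuration with the highest AUPRC on
#' the tuning split; ties break toward the earlier draw.
#'
#' @param train_grids,tune_grids Grid tibbles for the two splits.
#' @param grid Named list of candidate values per [train_config()] field
#'   (e.g. `list(hidden = c(32, 64), n_layers = 1:2)`).
#' @param n_draws Number of configurations to evaluate (reference protocol:
#'   100).
#' @param seed Integer seed.
#' @param base_config Defaults for fields the grid does not vary.
#' @return List: `best_config`, `best_model`, `results` tibble (one row per
#'   draw with its tune AUPRC).
#' @export
random_search <- function(train_grids, tune_grids, grid, n_draws = 100,
                          seed = 1, base_config = train_config()) {
  space <- expand.grid(grid, stringsAsFactors = FALSE)
  if (n_draws > nrow(space)) {
    warn(sprintf("n_draws (%d) exceeds grid size (%d); capped.",
                 n_draws, nrow(space)))
    n_draws <- nrow(space)
  }
  draws <- with_seed_tag(seed, "search", sample.int(nrow(space), n_draws))
  results <- vector("list", n_draws)
  models <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    cfg <- base_config
    row <- space[draws[k], , drop = FALSE]
    for (nm in names(row)) cfg[[nm]] <- row[[nm]]
    cfg$seed <- derive_seed(seed, paste0("draw", k))
    cfg <- do.call(train_config, cfg[setdiff(names(cfg), NULL)])
    model <- train_lstm(train_grids, cfg)
    preds <- predict_cohort(model, tune_grids)
    results[[k]] <- tibble::tibble(
      draw = k,
      auprc = auprc(preds$episode_score, preds$label),
      !!!row
    )
    models[[k]] <- model
  }
  res <- dplyr::bind_rows(results)
  best <- which.max(res$auprc)   # which.max returns the earliest maximum
  list(best_config = models[[best]]$config, best_model = models[[best]],
       results = res)
}

#' @export
tidy.lstm_model <- function(x, ...) x$losses

#' @export
glance.lstm_model <- function(x, ...) {
  n_par <- length(weights_flatten(x$weights))
  tibble::tibble(
    hidden = x$config$hidden, n_layers = x$config$n_layers,
    dropout = x$config$dropout, epochs = x$config$epochs,
    n_parameters = n_par,
    final_loss = tail(x$losses$loss, 1)
  )
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "<lstm_model> %d layer(s) x %d hidden units, input dim %d, %s h-update\n",
    x$config$n_layers, x$config$hidden, x$input_dim, x$config$h_mode
  ))
  cat(sprintf("  trained %d batch(es); final loss %.4f\n",
              nrow(x$losses), tail(x$losses$loss, 1)))
  invisible(x)
}
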