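# Generative adversarial imputation (GAIN) for the missing-not-at-random
# strategy. A generator sees the observed entries plus noise in the missing
# slots and proposes a complete sample; a discriminator, given a hint that
# reveals most of the true mask, predicts which entries were observed. The
# generator minimizes the adversarial loss on missing entries plus
# alpha times the squared reconstruction error on observed entries.
#
# Both networks are fully connected (relu hidden layers, sigmoid outputs)
# with hand-written backpropagation and Adam updates; columns are min-max
# normalized internally and imputations are recombined with the observed
# entries on the original scale.

#' GAIN training configuration
#'
#' Reference-scale defaults follow the published hyper-parameters
#' (`alpha` from \{0.1, 1, 10, 100\}, batch 512, hint rate 0.9, 15,000
#' iterations); pass smaller `iterations`/`batch_size` for desk-scale runs.
#'
#' @param alpha Reconstruction-loss weight (default 100).
#' @param batch_size Mini-batch rows per iteration (default 512).
#' @param hint_rate Probability that a hint entry reveals the true mask
#'   component (default 0.9, in `(0, 1]`).
#' @param iterations Training iterations (default 15000).
#' @param hidden_dims Integer vector of hidden-layer widths for both
#'   networks; default two layers of width = feature count.
#' @param seed Integer seed.
#' @return A `gain_config` list.
#' @export
gain_config <- function(alpha = 100, batch_size = 512, hint_rate = 0.9,
                        iterations = 15000, hidden_dims = NULL, seed = 1) {
  if (!(hint_rate > 0 && hint_rate <= 1)) abort("`hint_rate` must be in (0, 1].")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  structure(
    list(alpha = alpha, batch_size = as.integer(batch_size),
         hint_rate = hint_rate, iterations = as.integer(iterations),
         hidden_dims = hidden_dims, seed = as.integer(seed)),
    class = "gain_config"
  )
}

# --- minimal MLP machinery (shared by generator and discriminator) -------

mlp_init <- function(dims) {
  # dims: c(in, hidden..., out); Xavier-style uniform init
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    k <- sqrt(6 / (dims[i] + dims[i + 1]))
    layers[[i]] <- list(
      W = matrix(runif(dims[i] * dims[i + 1], -k, k), dims[i], dims[i + 1]),
      b = rep(0, dims[i + 1])
    )
  }
  layers
}

# forward pass: relu hidden layers, sigmoid output; returns activations
mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- X
  n <- length(layers)
  for (i in seq_len(n)) {
    z <- acts[[i]] %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(X), length(layers[[i]]$b), byrow = TRUE)
    acts[[i + 1]] <- if (i < n) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

# backward pass given d(loss)/d(pre-activation of output layer);
# returns list(grads, dinput)
mlp_backward <- function(layers, acts, dout_pre) {
  n <- length(layers)
  grads <- vector("list", n)
  delta <- dout_pre
  for (i in rev(seq_len(n))) {
    grads[[i]] <- list(
      W = crossprod(acts[[i]], delta),
      b = colSums(delta)
    )
    dinput <- delta %*% t(layers[[i]]$W)
    if (i > 1L) {
      dinput <- dinput * (acts[[i]] > 0)  # relu derivative
    }
    delta <- dinput
  }
  list(grads = grads, dinput = delta)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0
  ))
}

adam_step <- function(layers, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# --- GAIN proper ----------------------------------------------------------

#' Sample a hint matrix for the GAIN discriminator
#'
#' Each entry reveals the true mask component with probability
#' `hint_rate` and carries the non-committal value 0.5 otherwise:
#' `H = B * M + 0.5 * (1 - B)` with `B ~ Bernoulli(hint_rate)`.
#'
#' @param M 0/1 mask matrix.
#' @param hint_rate Reveal probability.
#' @return Hint matrix of the same shape.
#' @export
sample_hint <- function(M, hint_rate) {
  B <- matrix(rbinom(length(M), 1, hint_rate), nrow(M), ncol(M))
  B * M + 0.5 * (1 - B)
}

normalize_minmax <- function(X, M) {
  lo <- apply(ifelse(M == 1, X, Inf), 2, min)
  hi <- apply(ifelse(M == 1, X, -Inf), 2, max)
  span <- hi - lo + 1e-6
  Xn <- sweep(sweep(X, 2, lo), 2, span, "/")
  Xn[M == 0] <- 0
  list(X = Xn, lo = lo, span = span)
}

denormalize_minmax <- function(Xn, lo, span) {
  sweep(sweep(Xn, 2, span, "*"), 2, lo, "+")
}

#' Train a GAIN imputation model
#'
#' @param X Numeric data matrix (rows = samples); entries with `M = 0` are
#'   ignored.
#' @param M 0/1 observation mask, same shape as `X`.
#' @param config A [gain_config()].
#' @return A `gain_model` with generator/discriminator weights,
#'   normalization statistics, and per-iteration loss traces (`d_loss`,
#'   `g_adv`, `g_mse`).
#' @export
train_gain <- function(X, M, config = gain_config()) {
  stopifnot(identical(dim(X), dim(M)))
  if (any(colSums(M) == 0)) {
    abort("every column needs at least one observed entry (normalization undefined).")
  }
  if (any(!is.finite(X[M == 1]))) abort("observed entries must be finite.")
  d <- ncol(X)
  n <- nrow(X)
  hidden <- config$hidden_dims %||% c(d, d)
  with_seed_tag(config$seed, "gain", {
    norm <- normalize_minmax(X, M)
    Xn <- norm$X
    G <- mlp_init(c(2 * d, hidden, d))
    D <- mlp_init(c(2 * d, hidden, d))
    sG <- adam_init(G); sD <- adam_init(D)
    d_loss <- g_adv <- g_mse <- numeric(config$iterations)
    bs <- min(config$batch_size, n)
    eps <- 1e-8
    for (it in seq_len(config$iterations)) {
      idx <- sample.int(n, bs)
      x <- Xn[idx, , drop = FALSE]
      m <- M[idx, , drop = FALSE]
      z <- matrix(runif(bs * d, 0, 0.01), bs, d)
      xt <- m * x + (1 - m) * z
      H <- sample_hint(m, config$hint_rate)

      # discriminator step (generator held fixed)
      gact <- mlp_forward(G, cbind(xt, m))
      ghat <- gact[[length(gact)]]
      xhat <- m * x + (1 - m) * ghat
      dact <- mlp_forward(D, cbind(xhat, H))
      dprob <- dact[[length(dact)]]
      d_loss[it] <- -mean(m * log(dprob + eps) + (1 - m) * log(1 - dprob + eps))
      dpre <- (dprob - m) / length(m)   # sigmoid + cross-entropy shortcut
      bD <- mlp_backward(D, dact, dpre)
      upd <- adam_step(D, bD$grads, sD, it)
      D <- upd$layers; sD <- upd$state

      # generator step (fresh forward through the updated discriminator)
      gact <- mlp_forward(G, cbind(xt, m))
      ghat <- gact[[length(gact)]]
      xhat <- m * x + (1 - m) * ghat
      dact <- mlp_forward(D, cbind(xhat, H))
      dprob <- dact[[length(dact)]]
      g_adv[it] <- -mean((1 - m) * log(dprob + eps))
      g_mse[it] <- sum(m * (x - ghat)^2) / sum(m)
      # adversarial gradient flows through D (held fixed) into xhat
      ddpre <- (-(1 - m) / (dprob + eps) / length(m)) * dprob * (1 - dprob)
      bD2 <- mlp_backward(D, dact, ddpre)
      dxhat <- bD2$dinput[, seq_len(d), drop = FALSE]
      dghat_adv <- dxhat * (1 - m)
      dghat_mse <- config$alpha * 2 * m * (ghat - x) / sum(m)
      dgpre <- (dghat_adv + dghat_mse) * ghat * (1 - ghat)
      bG <- mlp_backward(G, gact, dgpre)
      upd <- adam_step(G, bG$grads, sG, it)
      G <- upd$layers; sG <- upd$state
    }
    structure(
      list(G = G, D = D, lo = norm$lo, span = norm$span, d = d,
           config = config,
           losses = tibble::tibble(iteration = seq_len(config$iterations),
                                   d_loss = d_loss, g_adv = g_adv,
                                   g_mse = g_mse)),
      class = "gain_model"
    )
  })
}

#' Impute missing entries with a trained GAIN model
#'
#' Observed entries pass through untouched (the combination happens on the
#' original scale); missing entries are generator output, denormalized.
#'
#' @param model A `gain_model` from [train_gain()].
#' @param X Data matrix on the original scale.
#' @param M 0/1 observation mask.
#' @return Completed matrix, `M * X + (1 - M) * G(...)`.
#' @export
gain_impute_matrix <- function(model, X, M) {
  stopifnot(inherits(model, "gain_model"), identical(dim(X), dim(M)))
  if (ncol(X) != model$d) abort("column count differs from the trained model.")
  with_seed_tag(model$config$seed, "gain-impute", {
    Xn <- sweep(sweep(X, 2, model$lo), 2, model$span, "/")
    Xn[M == 0] <- 0
    z <- matrix(runif(length(X), 0, 0.01), nrow(X), ncol(X))
    xt <- M * Xn + (1 - M) * z
    gact <- mlp_forward(model$G, cbind(xt, M))
    ghat <- gact[[length(gact)]]
    imput <- denormalize_minmax(ghat, model$lo, model$span)
    M * X + (1 - M) * imput
  })
}

#' GAIN missingness strategy over a grid collection
#'
#' Stacks all episode windows into one matrix, trains GAIN on the training
#' episodes, and imputes every grid; observed cells are preserved.
#'
#' @param grids Grid tibble from [bin_events()].
#' @param config A [gain_config()].
#' @param train_ids Episode ids to train on (default: all in `grids`).
#' @return List with the completed `grids` (all-ones masks) and the fitted
#'   `model`.
#' @export
impute_gain <- function(grids, config = gain_config(), train_ids = NULL) {
  train <- if (is.null(train_ids)) grids else
    grids[grids$episode_id %in% train_ids, ]
  Xtr <- do.call(rbind, train$values)
  Mtr <- do.call(rbind, train$mask)
  model <- train_gain(Xtr, Mtr, config)
  out <- grids
  out$values <- purrr::map2(grids$values, grids$mask, function(v, m) {
    res <- gain_impute_matrix(model, v, m)
    dimnames(res) <- dimnames(v)
    res
  })
  out$mask <- purrr::map(grids$mask, function(m) { m[] <- 1; m })
  list(grids = out, model = model)
}

#' @export
tidy.gain_model <- function(x, ...) {
  tidyr::pivot_longer(x$losses, -"iteration",
                      names_to = "loss", values_to = "value")
}

#' @export
glance.gain_model <- function(x, ...) {
  tibble::tibble(
    iterations = x$config$iterations,
    alpha = x$config$alpha,
    hint_rate = x$config$hint_rate,
    final_d_loss = tail(x$losses$d_loss, 1),
    final_g_mse = tail(x$losses$g_mse, 1)
  )
}
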