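# Shared fixtures, all built in code.

# a small deterministic grid tibble with hand-controlled masks
toy_grids <- function(n_episodes = 4, n_windows = 6, n_channels = 3,
                      seed = 1) {
  nw <- as.integer(n_windows)
  chs <- paste0("ch", seq_len(n_channels))
  withr::with_seed(seed, {
    vals <- lapply(seq_len(n_episodes), function(i) {
      matrix(rnorm(nw * n_channels), nw, n_channels,
             dimnames = list(NULL, chs))
    })
    masks <- lapply(seq_len(n_episodes), function(i) {
      m <- matrix(rbinom(nw * n_channels, 1, 0.7), nw, n_channels,
                  dimnames = list(NULL, chs))
      m[1, 1] <- 1   # guarantee at least one observation per grid
      m
    })
    lab <- rep(c(TRUE, FALSE), length.out = n_episodes)
    tibble::tibble(
      episode_id = sprintf("e%02d", seq_len(n_episodes)),
      n_windows = rep(nw, n_episodes),
      label = lab,
      onset_window = ifelse(lab, nw - 1L, NA_integer_),
      values = vals,
      mask = masks
    )
  })
}

# mask the unobserved cells to zero, as bin_events does
zero_unobserved <- function(grids) {
  grids$values <- purrr::map2(grids$values, grids$mask, function(v, m) {
    v[m == 0] <- 0
    v
  })
  grids
}

# separable labeled episode grids for quick model training: positives have
# elevated means throughout
separable_grids <- function(n_pos = 12, n_neg = 48, n_windows = 10,
                            n_channels = 4, shift = 1.5, seed = 1) {
  nw <- as.integer(n_windows)
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    lab <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    vals <- lapply(seq_len(n), function(i) {
      matrix(rnorm(nw * n_channels, mean = if (lab[i]) shift else 0),
             nw, n_channels)
    })
    tibble::tibble(
      episode_id = sprintf("s%03d", seq_len(n)),
      n_windows = rep(nw, n),
      label = lab,
      onset_window = ifelse(lab, nw - 1L, NA_integer_),
      values = vals,
      mask = lapply(seq_len(n), function(i) matrix(1, nw, n_channels))
    )
  })
}

# correlated bivariate Gaussian with MCAR missingness, for imputation tests
mcar_bivariate <- function(n = 2000, rho = 0.9, obs_rate = 0.7, seed = 1) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
    X <- cbind(x1 * 2 + 5, x2 * 3 - 1)
    M <- matrix(rbinom(2 * n, 1, obs_rate), n, 2)
    M[1, ] <- 1   # keep both columns observed at least once
    list(X = X, M = M)
  })
}

column_mean_impute <- function(X, M) {
  colm <- colSums(X * M) / colSums(M)
  M * X + (1 - M) * matrix(colm, nrow(X), ncol(X), byrow = TRUE)
}

rmse_on_missing <- function(imputed, X, M) {
  miss <- M == 0
  sqrt(mean((imputed[miss] - X[miss])^2))
}

# brute-force AUROC: pairwise comparison probability over all pos x neg pairs
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# brute-force AUPRC: precision/recall at every distinct threshold, area of
# the right-continuous step curve in recall order
oracle_auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    call_pos <- scores >= ths[i]
    tp <- sum(call_pos & labels)
    rec[i] <- tp / sum(labels)
    prec[i] <- tp / sum(call_pos)
  }
  sum(diff(c(0, rec)) * prec)
}

# scalar-loop reference implementation of one LSTM step, written against
# the gate equations directly (per-gate matrices, no vectorization)
oracle_step <- function(x, h, c_prev, layer, h_mode) {
  H <- length(h)
  sig <- function(z) 1 / (1 + exp(-z))
  slice <- function(which) ((which - 1) * H + 1):(which * H)
  out_h <- numeric(H); out_c <- numeric(H)
  for (j in seq_len(H)) {
    a_i <- sum(x * layer$Wx[, slice(1)[j]]) +
      sum(h * layer$Wh[, slice(1)[j]]) + layer$b[slice(1)[j]]
    a_f <- sum(x * layer$Wx[, slice(2)[j]]) +
      sum(h * layer$Wh[, slice(2)[j]]) + layer$b[slice(2)[j]]
    a_o <- sum(x * layer$Wx[, slice(3)[j]]) +
      sum(h * layer$Wh[, slice(3)[j]]) + layer$b[slice(3)[j]]
    a_g <- sum(x * layer$Wx[, slice(4)[j]]) +
      sum(h * layer$Wh[, slice(4)[j]]) + layer$b[slice(4)[j]]
    gi <- sig(a_i); gf <- sig(a_f); go <- sig(a_o); gg <- tanh(a_g)
    out_c[j] <- gf * c_prev[j] + gi * gg
    gate_h <- if (h_mode == "output") go else gf
    out_h[j] <- gate_h * tanh(out_c[j])
  }
  list(h = out_h, c = out_c)
}
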