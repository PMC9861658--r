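# Simulated federated training: equal sharding, local client training,
# sample-size-weighted averaging ("simple") or a server-side optimizer step
# on the pseudo-gradient ("opt"), plus a length-prefixed socket transport
# for model weights.

#' Shard training episodes equally across clients
#'
#' Shard sizes differ by at most one; shards are disjoint and exhaustive
#' and the assignment is deterministic under the seed. When episode labels
#' are supplied the deal is class-stratified (shuffled positives dealt
#' round-robin, then shuffled negatives), so every client holds both
#' classes whenever that is arithmetically possible -- balanced
#' oversampling requires both classes on every client.
#'
#' @param episode_ids Vector of episode identifiers.
#' @param n_clients Number of clients; must not exceed the episode count.
#' @param seed Integer seed.
#' @param labels Optional logical episode labels for stratified dealing.
#' @return List of `n_clients` id vectors.
#' @export
shard_episodes <- function(episode_ids, n_clients, seed = 1, labels = NULL) {
  n <- length(episode_ids)
  if (n_clients < 1 || n_clients > n) {
    abort("`n_clients` must be between 1 and the number of episodes.")
  }
  with_seed_tag(seed, "shard", {
    perm <- if (is.null(labels)) {
      sample(episode_ids)
    } else {
      labels <- as.logical(labels)
      c(sample(episode_ids[labels]), sample(episode_ids[!labels]))
    }
    split(perm, rep_len(seq_len(n_clients), n))
  })
}

#' Weighted-average ("simple") federated aggregation
#'
#' Element-wise weighted average of client weights with weights
#' `S_c / S`, the client sample shares.
#'
#' @param updates List of client updates, each `list(weights, n)`.
#' @return Aggregated weight tree.
#' @export
aggregate_simple <- function(updates) {
  sizes <- vapply(updates, function(u) u$n, numeric(1))
  if (any(sizes < 1)) abort("client sample sizes must be >= 1.")
  total <- sum(sizes)
  acc <- weights_scale(updates[[1]]$weights, sizes[1] / total)
  for (i in seq_along(updates)[-1]) {
    acc <- weights_add(acc, weights_scale(updates[[i]]$weights,
                                          sizes[i] / total))
  }
  acc
}

#' Server-optimizer ("opt") federated aggregation
#'
#' Forms the pseudo-gradient `delta = W_r - weighted_average(updates)` and
#' applies a server optimizer step from `W_r`. With plain gradient descent
#' at `server_lr = 1` the result coincides with [aggregate_simple()].
#'
#' @param server_weights Current global weights `W_r`.
#' @param updates List of client updates (`list(weights, n)`).
#' @param server_lr Server step size (default 1).
#' @param server_state Optional Adam state carried across rounds when
#'   `method = "adam"`.
#' @param method `"sgd"` (default) or `"adam"`.
#' @return List: `weights` (new globals), `server_state`.
#' @export
aggregate_opt <- function(server_weights, updates, server_lr = 1,
                          server_state = NULL, method = c("sgd", "adam")) {
  method <- match.arg(method)
  avg <- aggregate_simple(updates)
  delta <- weights_sub(server_weights, avg)
  if (method == "sgd") {
    list(weights = weights_sub(server_weights, weights_scale(delta, server_lr)),
         server_state = NULL)
  } else {
    state <- server_state %||% adam_tree_init(server_weights)
    upd <- adam_tree_step(server_weights, delta, state, lr = server_lr)
    list(weights = upd$w, server_state = upd$state)
  }
}

#' Federation configuration
#'
#' @param n_clients Number of simulated clients.
#' @param n_rounds Rounds of broadcast / local training / aggregation
#'   (default 5).
#' @param aggregation `"simple"` or `"opt"`.
#' @param local_config A [train_config()] used by every client each round.
#' @param server_lr Server step size for `"opt"`.
#' @param server_method `"sgd"` or `"adam"` server optimizer for `"opt"`.
#' @param seed Integer seed for sharding and per-round client seeds.
#' @return A `federation_config` list.
#' @export
federation_config <- function(n_clients, n_rounds = 5,
                              aggregation = c("simple", "opt"),
                              local_config = train_config(),
                              server_lr = 1, server_method = "sgd",
                              seed = 1) {
  aggregation <- match.arg(aggregation)
  stopifnot(n_clients >= 1, n_rounds >= 1)
  structure(
    list(n_clients = as.integer(n_clients), n_rounds = as.integer(n_rounds),
         aggregation = aggregation, local_config = local_config,
         server_lr = server_lr, server_method = server_method,
         seed = as.integer(seed)),
    class = "federation_config"
  )
}

# per-round, per-client training seed; exported logic kept in one place so
# a single-client federation is bit-identical to the equivalent sequence
# of train_lstm() calls
client_round_seed <- function(seed, round, client) {
  derive_seed(seed, sprintf("round%d/client%d", round, client))
}

#' Run a simulated federation
#'
#' Each round broadcasts the global weights, trains a local model per
#' client on its shard (fresh local optimizer each round), aggregates with
#' the configured rule, and evaluates the aggregated global model on the
#' test split. With one client and `"simple"` aggregation the per-round
#' global models equal centralized training resumed round by round with
#' the same seeds.
#'
#' @param train_grids Training-split grid tibble (completed values).
#' @param test_grids Test-split grid tibble used for per-round evaluation.
#' @param config A [federation_config()].
#' @return A `federation_result`: `report` (one metrics row per round),
#'   `weights` (final globals), `round_weights` (list), `shards`.
#' @export
run_federation <- function(train_grids, test_grids, config) {
  shards <- shard_episodes(train_grids$episode_id, config$n_clients,
                           config$seed, labels = train_grids$label)
  global <- lstm_init(ncol(train_grids$values[[1]]), config$local_config)
  server_state <- NULL
  report <- vector("list", config$n_rounds)
  round_weights <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    updates <- vector("list", config$n_clients)
    for (ci in seq_len(config$n_clients)) {
      shard <- train_grids[train_grids$episode_id %in% shards[[ci]], ]
      local_cfg <- config$local_config
      local_cfg$seed <- client_round_seed(config$seed, r, ci)
      model <- tryCatch(
        train_lstm(shard, local_cfg, init = global),
        error = function(e) {
          abort(sprintf("client %d failed in round %d: %s; round aborted",
                        ci, r, conditionMessage(e)))
        }
      )
      updates[[ci]] <- list(weights = model$weights, n = nrow(shard))
    }
    if (config$aggregation == "simple") {
      global <- aggregate_simple(updates)
    } else {
      agg <- aggregate_opt(global, updates, config$server_lr,
                           server_state, config$server_method)
      global <- agg$weights
      server_state <- agg$server_state
    }
    round_weights[[r]] <- global
    eval_model <- structure(
      list(weights = global, config = config$local_config,
           input_dim = ncol(train_grids$values[[1]]),
           losses = tibble::tibble(loss = NA_real_)),
      class = "lstm_model"
    )
    preds <- predict_cohort(eval_model, test_grids)
    report[[r]] <- dplyr::mutate(evaluate_predictions(preds),
                                 round = r, .before = 1)
  }
  structure(
    list(report = dplyr::bind_rows(report), weights = global,
         round_weights = round_weights, shards = shards, config = config),
    class = "federation_result"
  )
}

#' @export
tidy.federation_result <- function(x, ...) x$report

#' @export
glance.federation_result <- function(x, ...) {
  last <- dplyr::slice_tail(x$report, n = 1)
  tibble::tibble(
    n_clients = x$config$n_clients, n_rounds = x$config$n_rounds,
    aggregation = x$config$aggregation,
    final_auprc = last$auprc, final_auroc = last$auroc,
    final_earliness_h = last$earliness_h
  )
}

# --- weight transport -----------------------------------------------------

#' Serialize model weights into a length-prefixed frame
#'
#' @param weights Nested weight tree.
#' @return Raw vector: 4-byte big-endian payload length, then the
#'   serialized payload.
#' @export
encode_weights_frame <- function(weights) {
  payload <- serialize(weights, NULL)
  c(writeBin(length(payload), raw(), size = 4L, endian = "big"), payload)
}

#' Decode a length-prefixed weight frame
#'
#' @param frame Raw vector from [encode_weights_frame()].
#' @return The weight tree; truncated or empty frames raise a protocol
#'   error.
#' @export
decode_weights_frame <- function(frame) {
  if (length(frame) < 4L) abort("protocol error: frame shorter than header.")
  n <- readBin(frame[1:4], "integer", size = 4L, endian = "big")
  if (n <= 0L) abort("protocol error: empty payload.")
  if (length(frame) < 4L + n) abort("protocol error: truncated frame.")
  unserialize(frame[5:(4L + n)])
}

#' Send a weight frame over a connection
#'
#' @param con Open binary connection (e.g. a localhost socket).
#' @param weights Weight tree.
#' @return Invisibly, the number of payload bytes written.
#' @export
send_weights <- function(con, weights) {
  frame <- encode_weights_frame(weights)
  writeBin(frame, con)
  flush(con)
  invisible(length(frame) - 4L)
}

#' Save a fitted model (weights plus configuration) as a checkpoint file
#'
#' The checkpoint is a single binary file holding a length-prefixed
#' serialized frame with the model's configuration embedded.
#'
#' @param model An `lstm_model` or `gain_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  writeBin(encode_weights_frame(model), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return The model object.
#' @export
load_checkpoint <- function(path) {
  decode_weights_frame(readBin(path, "raw", n = file.size(path)))
}

#' Receive a weight frame from a connection
#'
#' Blocks until the full frame announced by the length prefix has
#' arrived.
#'
#' @param con Open binary connection.
#' @return The weight tree.
#' @export
receive_weights <- function(con) {
  header <- readBin(con, "raw", n = 4L)
  if (length(header) < 4L) abort("protocol error: connection closed mid-header.")
  n <- readBin(header, "integer", size = 4L, endian = "big")
  if (n <= 0L) abort("protocol error: empty payload.")
  payload <- raw(0)
  while (length(payload) < n) {
    chunk <- readBin(con, "raw", n = n - length(payload))
    if (length(chunk) == 0L) {
      Sys.sleep(0.01)
      next
    }
    payload <- c(payload, chunk)
  }
  unserialize(payload)
}
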