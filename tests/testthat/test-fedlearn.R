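rand_weights <- function(seed, D = 3, H = 4) {
  cfg <- train_config(hidden = H, seed = seed)
  lstm_init(D, cfg)
}

test_that("sharding is equal, disjoint, exhaustive, and seeded", {
  ids <- sprintf("e%02d", 1:10)
  sh <- shard_episodes(ids, 2, seed = 1)
  expect_equal(lengths(sh), c(`1` = 5L, `2` = 5L), ignore_attr = TRUE)

  sh3 <- shard_episodes(sprintf("e%02d", 1:11), 3, seed = 1)
  expect_equal(sort(lengths(sh3), decreasing = TRUE), c(4L, 4L, 3L),
               ignore_attr = TRUE)
  expect_setequal(unlist(sh3), sprintf("e%02d", 1:11))
  expect_false(any(duplicated(unlist(sh3))))

  expect_setequal(unlist(shard_episodes(ids, 1, seed = 2)), ids)
  expect_error(shard_episodes(ids, 11, seed = 1), "between 1")
  expect_identical(shard_episodes(ids, 3, seed = 9),
                   shard_episodes(ids, 3, seed = 9))
})

test_that("weighted averaging satisfies its algebraic identities", {
  w <- rand_weights(1)
  # convexity: identical updates average to themselves
  same <- aggregate_simple(list(list(weights = w, n = 2),
                                list(weights = w, n = 5)))
  expect_equal(same, w, tolerance = 1e-12)

  # symmetry: +w and -w with equal sizes cancel
  neg <- fedsepsis:::weights_scale(w, -1)
  zero <- aggregate_simple(list(list(weights = w, n = 3),
                                list(weights = neg, n = 3)))
  expect_equal(max(abs(fedsepsis:::weights_flatten(zero))), 0,
               tolerance = 1e-12)

  # arithmetic: sizes (1, 3) on scalars 0 and 4 give 3
  s0 <- fedsepsis:::weights_scale(w, 0)
  s4 <- fedsepsis:::weights_map1(w, function(x) x * 0 + 4)
  agg <- aggregate_simple(list(list(weights = s0, n = 1),
                               list(weights = s4, n = 3)))
  expect_equal(unique(fedsepsis:::weights_flatten(agg)), 3)

  # permutation invariance in client order
  u1 <- list(weights = rand_weights(2), n = 2)
  u2 <- list(weights = rand_weights(3), n = 7)
  u3 <- list(weights = rand_weights(4), n = 1)
  expect_equal(aggregate_simple(list(u1, u2, u3)),
               aggregate_simple(list(u3, u1, u2)), tolerance = 1e-12)

  # equal shard sizes reduce to the unweighted mean
  eq <- aggregate_simple(list(list(weights = u1$weights, n = 4),
                              list(weights = u2$weights, n = 4)))
  manual <- fedsepsis:::weights_scale(
    fedsepsis:::weights_add(u1$weights, u2$weights), 0.5)
  expect_equal(eq, manual, tolerance = 1e-12)
})

test_that("server-optimizer aggregation reduces to averaging at unit step", {
  server <- rand_weights(5)
  updates <- list(list(weights = rand_weights(6), n = 3),
                  list(weights = rand_weights(7), n = 9))
  opt <- aggregate_opt(server, updates, server_lr = 1)
  simple <- aggregate_simple(updates)
  expect_equal(max(abs(fedsepsis:::weights_flatten(opt$weights) -
                       fedsepsis:::weights_flatten(simple))), 0,
               tolerance = 1e-10)

  # zero step and zero pseudo-gradient are both fixed points
  frozen <- aggregate_opt(server, updates, server_lr = 0)
  expect_equal(frozen$weights, server, tolerance = 1e-12)
  held <- aggregate_opt(server, list(list(weights = server, n = 4)),
                        server_lr = 1)
  expect_equal(held$weights, server, tolerance = 1e-12)
})

test_that("weight frames round-trip exactly and reject malformed input", {
  w <- rand_weights(8)
  frame <- encode_weights_frame(w)
  expect_identical(decode_weights_frame(frame), w)
  expect_error(decode_weights_frame(frame[1:3]), "header")
  expect_error(decode_weights_frame(frame[1:10]), "truncated")
  empty <- writeBin(0L, raw(), size = 4L, endian = "big")
  expect_error(decode_weights_frame(empty), "empty payload")
})

test_that("model checkpoints round-trip through a single binary file", {
  g <- separable_grids(n_pos = 4, n_neg = 8, n_windows = 5, seed = 20)
  m <- train_lstm(g, train_config(hidden = 4, batch_size = 8, seed = 1))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$config, m$config)
})

test_that("weights survive a localhost socket round trip bit-identically", {
  w <- rand_weights(9, D = 5, H = 6)
  port <- 30000 + (Sys.getpid() %% 2000)
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  client <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                             open = "w+b", timeout = 10)
  on.exit(close(client), add = TRUE)
  server_con <- socketAccept(srv, blocking = TRUE, open = "w+b", timeout = 10)
  on.exit(close(server_con), add = TRUE)

  send_weights(client, w)
  got <- receive_weights(server_con)
  expect_identical(got, w)

  # and back the other way
  send_weights(server_con, got)
  expect_identical(receive_weights(client), w)
})

test_that("a one-client federation equals resumed centralized training", {
  g <- separable_grids(n_pos = 8, n_neg = 24, n_windows = 6, seed = 10)
  local_cfg <- train_config(hidden = 4, epochs = 1, batch_size = 8,
                            lr = 1e-2, seed = 0)
  fed_cfg <- federation_config(n_clients = 1, n_rounds = 2,
                               aggregation = "simple",
                               local_config = local_cfg, seed = 33)
  fed <- run_federation(g, g, fed_cfg)

  # oracle: train round by round with the same per-round seeds, resuming
  # from the previous round's weights with a fresh optimizer
  w <- lstm_init(ncol(g$values[[1]]), local_cfg)
  for (r in 1:2) {
    cfg_r <- local_cfg
    cfg_r$seed <- fedsepsis:::client_round_seed(33, r, 1)
    w <- train_lstm(g, cfg_r, init = w)$weights
    expect_equal(fed$round_weights[[r]], w, tolerance = 1e-12)
  }
  expect_equal(fed$weights, w, tolerance = 1e-12)
})

test_that("a federation emits one evaluation row per round", {
  g <- separable_grids(n_pos = 8, n_neg = 24, n_windows = 6, seed = 11)
  fed_cfg <- federation_config(
    n_clients = 2, n_rounds = 5, aggregation = "simple",
    local_config = train_config(hidden = 4, epochs = 1, batch_size = 8,
                                lr = 1e-2, seed = 0),
    seed = 44
  )
  fed <- run_federation(g, g, fed_cfg)
  expect_equal(nrow(fed$report), 5L)
  expect_equal(fed$report$round, 1:5)
  expect_true(all(is.finite(fed$report$auprc)))
  expect_true(all(is.finite(fed$report$auroc)))

  # determinism of the whole federation under its seed
  fed2 <- run_federation(g, g, fed_cfg)
  expect_identical(fed$report, fed2$report)
  expect_equal(fed$weights, fed2$weights, tolerance = 0)
})
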