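test_that("window binning averages within-hour values and is order-invariant", {
  eps <- tibble::tibble(episode_id = "p1", start_h = 0, endpoint_h = 4,
                        n_windows = 4L, label = FALSE,
                        onset_window = NA_integer_)
  ev <- tibble::tibble(
    patient_id = "p1",
    time_h = c(0.2, 0.8, 2.5, 3.9),
    kind = "vital",
    channel = c("hr", "hr", "hr", "rr"),
    value = c(4, 6, 2.5, 7),
    text = NA_character_
  )
  g <- bin_events(ev, eps, c("hr", "rr"))
  v <- g$values[[1]]; m <- g$mask[[1]]
  expect_equal(unname(v[1, "hr"]), 5)      # mean of {4, 6}
  expect_equal(unname(m[1, "hr"]), 1)
  expect_equal(unname(m[2, "hr"]), 0)      # no values in window 1
  expect_equal(unname(v[3, "hr"]), 2.5)    # single value
  expect_equal(unname(v[4, "rr"]), 7)

  g2 <- bin_events(ev[c(3, 1, 4, 2), ], eps, c("hr", "rr"))
  expect_equal(g2$values, g$values)

  ev_bad <- dplyr::mutate(ev, value = replace(value, 2, NA))
  expect_warning(bin_events(ev_bad, eps, c("hr", "rr")), "rejected")
})

test_that("carry-forward imputation carries, overrides, and falls back to the mean", {
  m <- matrix(0, 7, 2, dimnames = list(NULL, c("a", "b")))
  v <- matrix(0, 7, 2, dimnames = list(NULL, c("a", "b")))
  m[4, 1] <- 1; v[4, 1] <- 2          # channel a observed once at window 3
  m[6, 1] <- 1; v[6, 1] <- 7          # later value overrides
  grids <- tibble::tibble(episode_id = "e", n_windows = 7L, label = FALSE,
                          onset_window = NA_integer_,
                          values = list(v), mask = list(m))
  out <- impute_carry_forward_mean(grids, c(a = 99, b = 1.5))
  va <- out$values[[1]][, "a"]
  expect_equal(va[5], 2)              # carried forward
  expect_equal(va[7], 7)              # overridden by the later observation
  expect_equal(va[1], 99)             # leading gap takes the global mean
  expect_equal(out$values[[1]][, "b"], rep(1.5, 7))  # never observed
  expect_true(all(out$mask[[1]] == 1))

  expect_error(impute_carry_forward_mean(grids, c(a = 1)), "every grid channel")
})

test_that("the distinct sentinel is verified absent and fills only missing cells", {
  g <- zero_unobserved(toy_grids(seed = 2))
  all_obs <- g
  all_obs$mask <- lapply(all_obs$mask, function(m) { m[] <- 1; m })
  expect_equal(impute_distinct_value(all_obs)$values, all_obs$values)

  mx <- max(unlist(purrr::map2(g$values, g$mask, function(v, m) v[m == 1])))
  expect_equal(default_sentinel(g), floor(mx) + 1)

  out <- impute_distinct_value(g)
  sent <- attr(out, "sentinel")
  for (i in seq_len(nrow(g))) {
    expect_equal(out$values[[i]][g$mask[[i]] == 0],
                 rep(sent, sum(g$mask[[i]] == 0)))
    expect_equal(out$values[[i]][g$mask[[i]] == 1],
                 g$values[[i]][g$mask[[i]] == 1])
  }

  collide <- g
  collide$values[[1]][which(collide$mask[[1]] == 1)[1]] <- 7
  expect_error(impute_distinct_value(collide, sentinel = 7), "collides")
})

test_that("the missingness filter drops episodes at or above the threshold", {
  half <- matrix(rep(c(1, 0), 12), 6, 4)        # 50% observed: retained
  full_missing <- matrix(0, 6, 4)               # dropped
  mk <- function(masks) {
    tibble::tibble(
      episode_id = sprintf("e%d", seq_along(masks)),
      n_windows = 6L, label = FALSE, onset_window = NA_integer_,
      values = lapply(masks, function(m) matrix(0, nrow(m), ncol(m))),
      mask = masks
    )
  }
  expect_equal(nrow(filter_missingness(mk(list(half)))), 1L)
  expect_equal(nrow(filter_missingness(mk(list(full_missing)))), 0L)

  # 10 episodes, exactly 2 built beyond the threshold -> 8 retained
  sparse <- matrix(0, 10, 4); sparse[1, 1] <- 1  # 97.5% missing
  masks <- c(rep(list(half), 8), list(sparse), list(full_missing))
  expect_equal(nrow(filter_missingness(mk(masks), threshold = 0.90)), 8L)

  # feature mode drops an episode whose single channel crosses the threshold
  one_bad <- matrix(1, 10, 4); one_bad[, 2] <- 0
  expect_equal(nrow(filter_missingness(mk(list(one_bad)), mode = "feature")),
               0L)
  expect_equal(nrow(filter_missingness(mk(list(one_bad)), mode = "episode")),
               1L)
})

test_that("stratified splitting omits small strata and hits exact counts", {
  mk_strata <- function(sizes, labels, lengths) {
    tibble::tibble(
      episode_id = sprintf("e%04d", seq_len(sum(sizes))),
      label = rep(labels, sizes),
      n_windows = rep(as.integer(lengths), sizes)
    )
  }
  # a stratum of exactly 5 is omitted entirely; one of 20 splits 16/2/2
  g <- mk_strata(c(5, 20), c(TRUE, FALSE), c(12, 24))
  s <- split_episodes(g, seed = 1)
  expect_equal(sum(s$split == "omitted"), 5L)
  tab <- table(s$split[s$split != "omitted"])
  expect_equal(unname(tab[c("train", "test", "tune")]), c(16L, 2L, 2L),
               ignore_attr = TRUE)

  # every retained episode appears in exactly one split
  expect_equal(sort(s$episode_id), sort(g$episode_id))
  expect_false(any(duplicated(s$episode_id)))

  expect_error(split_episodes(g, fractions = c(0.8, 0.1, 0.2)), "sum to 1")

  # determinism
  expect_identical(split_episodes(g, seed = 5), split_episodes(g, seed = 5))
})

test_that("large-cohort splits hit the 80/10/10 proportions and class balance", {
  withr::with_seed(10, {
    lengths <- sample(c(12, 24, 36, 48), 2000, replace = TRUE)
    labels <- runif(2000) < 0.095
  })
  g <- tibble::tibble(episode_id = sprintf("e%04d", 1:2000),
                      label = labels, n_windows = as.integer(lengths))
  s <- split_episodes(g, seed = 3)
  kept <- dplyr::left_join(s[s$split != "omitted", ], g, by = "episode_id")
  frac_train <- mean(kept$split == "train")
  expect_lt(abs(frac_train - 0.8), 0.02)
  overall_pos <- mean(kept$label)
  by_split <- tapply(kept$label, kept$split, mean)
  expect_true(all(abs(by_split - overall_pos) <= 0.015))
})

test_that("imputation strategies never alter observed cells", {
  g <- zero_unobserved(toy_grids(n_episodes = 6, seed = 8))
  gm <- global_channel_means(g)
  gm[!is.finite(gm)] <- 0
  for (out in list(impute_carry_forward_mean(g, gm),
                   impute_distinct_value(g))) {
    for (i in seq_len(nrow(g))) {
      obs <- g$mask[[i]] == 1
      expect_equal(out$values[[i]][obs], g$values[[i]][obs])
    }
  }
})

test_that("multi-modal assembly concatenates embeddings with aligned windows", {
  g <- toy_grids(n_episodes = 2, n_windows = 5, n_channels = 30, seed = 3)
  emb <- tibble::tibble(
    episode_id = g$episode_id,
    embedding = list(matrix(0, 5, 768), matrix(1, 5, 768))
  )
  mm <- assemble_multimodal(g, emb)
  expect_equal(ncol(mm$values[[1]]), 798L)   # 30 + 768
  expect_equal(mm$values[[1]][, 1:30], g$values[[1]], ignore_attr = TRUE)
  expect_true(all(mm$values[[1]][, 31:798] == 0))

  long_emb <- tibble::tibble(episode_id = g$episode_id,
                             embedding = list(matrix(0, 5, 3072),
                                              matrix(0, 5, 3072)))
  expect_equal(ncol(assemble_multimodal(g, long_emb)$values[[1]]), 3102L)

  bad <- tibble::tibble(episode_id = g$episode_id,
                        embedding = list(matrix(0, 4, 8), matrix(0, 5, 8)))
  expect_error(assemble_multimodal(g, bad), "align")
})

test_that("grid collections round-trip through delimited text", {
  g <- zero_unobserved(toy_grids(n_episodes = 3, seed = 30))
  stem <- file.path(withr::local_tempdir(), "grids")
  write_grids(g, stem)
  back <- read_grids(stem)
  expect_equal(back$episode_id, g$episode_id)
  expect_equal(back$label, g$label)
  for (i in seq_len(nrow(g))) {
    expect_equal(back$values[[i]], g$values[[i]])
    expect_equal(back$mask[[i]], 1 * g$mask[[i]])
  }
})

test_that("standardization centers training features and reapplies cleanly", {
  g <- zero_unobserved(toy_grids(n_episodes = 5, seed = 21))
  std <- standardize_grids(g)
  all_rows <- do.call(rbind, std$grids$values)
  expect_equal(unname(colMeans(all_rows)), rep(0, ncol(all_rows)),
               tolerance = 1e-10)
  other <- standardize_grids(g, std$stats)
  expect_equal(other$grids$values, std$grids$values)
})
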