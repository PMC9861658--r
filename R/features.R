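# Care-episode window grids: hourly binning, missingness representations,
# the <90%-missingness episode filter, and stratified splits.
#
# A grid collection is a tibble with one row per episode and matrix
# list-columns `values` (windows x channels) and `mask` (1 = observed), so
# the whole cohort stays pipeable while each episode keeps its natural
# matrix form.

#' Bin an event stream into per-episode hourly window grids
#'
#' Each cell of the grid is the arithmetic mean of the numeric values of
#' that channel falling in the half-open hour window `[k, k+1)` relative to
#' the episode start; windows with no value get `mask = 0`. Non-numeric
#' values in numeric channels are rejected with a warning. The result is
#' invariant to the ordering of the input records.
#'
#' @param events Event tibble (`patient_id`, `time_h`, `kind`, `channel`,
#'   `value`).
#' @param episodes Episode tibble from [select_cohort()].
#' @param channels Character vector fixing the channel order of the grids.
#' @return A tibble with one row per episode: `episode_id`, `n_windows`,
#'   `label`, `onset_window`, and matrix list-columns `values` and `mask`.
#' @export
bin_events <- function(events, episodes, channels) {
  numeric_events <- events |>
    dplyr::filter(.data$channel %in% channels)
  bad <- is.na(numeric_events$value)
  if (any(bad)) {
    warn(sprintf("rejected %d record(s) with non-numeric values in numeric channels",
                 sum(bad)))
    numeric_events <- numeric_events[!bad, ]
  }
  cells <- numeric_events |>
    dplyr::inner_join(
      dplyr::select(episodes, "episode_id", "start_h", "endpoint_h"),
      by = c(patient_id = "episode_id")
    ) |>
    dplyr::filter(.data$time_h >= .data$start_h,
                  .data$time_h < .data$endpoint_h) |>
    dplyr::mutate(window = as.integer(floor(.data$time_h - .data$start_h))) |>
    dplyr::group_by(.data$patient_id, .data$window, .data$channel) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  cell_split <- split(cells, cells$patient_id)
  grids <- episodes |>
    dplyr::transmute(.data$episode_id, .data$n_windows, .data$label,
                     .data$onset_window)
  grids$values <- purrr::map2(grids$episode_id, grids$n_windows, function(id, nw) {
    v <- matrix(NA_real_, nw, length(channels),
                dimnames = list(NULL, channels))
    cc <- cell_split[[id]]
    if (!is.null(cc)) {
      v[cbind(cc$window + 1L, match(cc$channel, channels))] <- cc$value
    }
    v
  })
  grids$mask <- purrr::map(grids$values, function(v) {
    m <- 1 * !is.na(v)
    dimnames(m) <- dimnames(v)
    m
  })
  grids$values <- purrr::map(grids$values, function(v) {
    v[is.na(v)] <- 0
    v
  })
  grids
}

grid_channels <- function(grids) {
  if (nrow(grids) == 0L) return(character())
  colnames(grids$values[[1]])
}

#' Per-channel means of observed cells, for mean-based imputation
#'
#' Compute on the training split only to keep imputation leakage-safe.
#'
#' @param grids Grid tibble from [bin_events()].
#' @return Named numeric vector of channel means (`NaN` for channels never
#'   observed).
#' @export
global_channel_means <- function(grids) {
  ch <- grid_channels(grids)
  sums <- rep(0, length(ch)); counts <- rep(0, length(ch))
  for (i in seq_len(nrow(grids))) {
    m <- grids$mask[[i]]
    sums <- sums + colSums(grids$values[[i]] * m)
    counts <- counts + colSums(m)
  }
  setNames(sums / counts, ch)
}

#' Carry-forward imputation with global-mean fallback
#'
#' Within an episode each missing cell takes the most recent observed value
#' of its channel; cells before the first observation, and channels never
#' observed in the episode, take the global training mean. The output mask
#' is all ones.
#'
#' @param grids Grid tibble.
#' @param global_means Named per-channel means from
#'   [global_channel_means()] computed on the training split.
#' @return The grid tibble with completed `values`.
#' @export
impute_carry_forward_mean <- function(grids, global_means) {
  ch <- grid_channels(grids)
  if (!all(ch %in% names(global_means))) {
    abort("`global_means` must cover every grid channel.")
  }
  gm <- global_means[ch]
  out <- grids
  out$values <- purrr::map2(grids$values, grids$mask, function(v, m) {
    for (j in seq_along(ch)) {
      obs <- which(m[, j] == 1)
      if (length(obs) == 0L) {
        v[, j] <- gm[j]
        next
      }
      last <- gm[j]
      for (k in seq_len(nrow(v))) {
        if (m[k, j] == 1) last <- v[k, j] else v[k, j] <- last
      }
    }
    v
  })
  out$mask <- purrr::map(grids$mask, function(m) {
    m[] <- 1
    m
  })
  out
}

#' Default missingness sentinel: an integer absent from all observed values
#'
#' @param grids Grid tibble.
#' @return `floor(max observed value) + 1`.
#' @export
default_sentinel <- function(grids) {
  mx <- -Inf
  for (i in seq_len(nrow(grids))) {
    obs <- grids$values[[i]][grids$mask[[i]] == 1]
    if (length(obs)) mx <- max(mx, max(obs))
  }
  if (!is.finite(mx)) return(1)
  floor(mx) + 1
}

#' Distinct-value missingness representation
#'
#' Missing cells are set to an integer sentinel that is verified to be
#' absent from every observed value in the data, flagging
#' missing-not-at-random cells explicitly; observed cells are unchanged.
#'
#' @param grids Grid tibble.
#' @param sentinel Integer sentinel; defaults to [default_sentinel()].
#' @return The grid tibble with sentinel-completed `values`.
#' @export
impute_distinct_value <- function(grids, sentinel = NULL) {
  if (is.null(sentinel)) sentinel <- default_sentinel(grids)
  for (i in seq_len(nrow(grids))) {
    obs <- grids$values[[i]][grids$mask[[i]] == 1]
    if (any(obs == sentinel)) {
      abort(sprintf("sentinel %s collides with an observed value", sentinel))
    }
  }
  out <- grids
  out$values <- purrr::map2(grids$values, grids$mask, function(v, m) {
    v[m == 0] <- sentinel
    v
  })
  out$mask <- purrr::map(grids$mask, function(m) {
    m[] <- 1
    m
  })
  attr(out, "sentinel") <- sentinel
  out
}

#' Drop episodes exceeding a missingness threshold
#'
#' With `mode = "episode"` (default) the missing fraction is aggregated
#' over all non-text cells of the episode and episodes at or above the
#' threshold are dropped; with `mode = "feature"` an episode is dropped if
#' any single channel reaches the threshold within it.
#'
#' @param grids Grid tibble (masks must be the observation masks, i.e.
#'   applied before any imputation).
#' @param threshold Missing-fraction threshold (default 0.90).
#' @param mode `"episode"` or `"feature"`.
#' @return The retained grid rows.
#' @export
filter_missingness <- function(grids, threshold = 0.90,
                               mode = c("episode", "feature")) {
  mode <- match.arg(mode)
  keep <- purrr::map_lgl(grids$mask, function(m) {
    if (mode == "episode") {
      mean(m == 0) < threshold
    } else {
      all(colMeans(m == 0) < threshold)
    }
  })
  grids[keep, ]
}

#' Stratified train/test/tune episode split
#'
#' Episodes are stratified by (label, episode length); strata with five or
#' fewer episodes are omitted entirely to keep the class and length
#' distributions of the three splits similar. Within each stratum the
#' split counts follow largest-remainder rounding of `fractions` and
#' episodes are assigned after a seeded shuffle.
#'
#' @param grids Grid tibble.
#' @param fractions Train/test/tune fractions summing to 1 (default
#'   80/10/10).
#' @param seed Integer seed.
#' @param min_stratum Strata of this size or smaller are omitted
#'   (default 5).
#' @return Tibble `episode_id`, `split` with levels `train`, `test`,
#'   `tune`, `omitted`.
#' @export
split_episodes <- function(grids, fractions = c(0.8, 0.1, 0.1), seed = 1,
                           min_stratum = 5) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must sum to 1.")
  }
  strata <- tibble::tibble(
    episode_id = grids$episode_id,
    label = grids$label,
    n_windows = grids$n_windows
  )
  with_seed_tag(seed, "split", {
    strata |>
      dplyr::group_by(.data$label, .data$n_windows) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n <= min_stratum) {
          return(tibble::tibble(episode_id = df$episode_id,
                                split = "omitted"))
        }
        counts <- largest_remainder(n, fractions)
        lab <- rep(c("train", "test", "tune"), counts)
        tibble::tibble(episode_id = sample(df$episode_id),
                       split = lab)
      }) |>
      dplyr::ungroup() |>
      dplyr::select("episode_id", "split")
  })
}

#' Serialize a grid collection as delimited text
#'
#' Writes two tab-separated files: `<stem>.episodes.tsv` (episode
#' metadata) and `<stem>.cells.tsv` (long-format values with their
#' observation mask), a layout that round-trips exactly through
#' [read_grids()].
#'
#' @param grids Grid tibble.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_grids <- function(grids, stem) {
  meta <- dplyr::select(grids, "episode_id", "n_windows", "label",
                        "onset_window")
  readr::write_tsv(meta, paste0(stem, ".episodes.tsv"))
  cells <- purrr::pmap(
    list(grids$episode_id, grids$values, grids$mask),
    function(id, v, m) {
      tibble::tibble(
        episode_id = id,
        window = rep(seq_len(nrow(v)) - 1L, ncol(v)),
        channel = rep(colnames(v) %||% sprintf("c%03d", seq_len(ncol(v))),
                      each = nrow(v)),
        value = as.vector(v),
        observed = as.integer(m)
      )
    })
  readr::write_tsv(dplyr::bind_rows(cells), paste0(stem, ".cells.tsv"))
  invisible(stem)
}

#' Read a grid collection written by [write_grids()]
#'
#' @param stem Path stem used when writing.
#' @return A grid tibble.
#' @export
read_grids <- function(stem) {
  meta <- readr::read_tsv(paste0(stem, ".episodes.tsv"),
                          col_types = readr::cols())
  cells <- readr::read_tsv(paste0(stem, ".cells.tsv"),
                           col_types = readr::cols())
  channels <- unique(cells$channel)
  by_ep <- split(cells, cells$episode_id)
  meta$values <- purrr::map2(meta$episode_id, meta$n_windows, function(id, nw) {
    cc <- by_ep[[id]]
    v <- matrix(0, nw, length(channels),
                dimnames = list(NULL, channels))
    v[cbind(cc$window + 1L, match(cc$channel, channels))] <- cc$value
    v
  })
  meta$mask <- purrr::map2(meta$episode_id, meta$n_windows, function(id, nw) {
    cc <- by_ep[[id]]
    m <- matrix(0, nw, length(channels),
                dimnames = list(NULL, channels))
    m[cbind(cc$window + 1L, match(cc$channel, channels))] <- cc$observed
    m
  })
  tibble::as_tibble(meta)
}

#' Standardize grid features to zero mean and unit variance
#'
#' Physiological channels live on very different scales (blood pressure
#' around 120, temperature around 37), which saturates recurrent gate
#' activations; training uses z-scored features. Statistics are computed
#' over every window of the supplied grids (use the training split) and
#' reapplied unchanged to other splits.
#'
#' @param grids Grid tibble with completed `values`.
#' @param stats Optional list with `center` and `scale` from a previous
#'   call; computed from `grids` when `NULL`.
#' @return List: `grids` (standardized), `stats`.
#' @export
standardize_grids <- function(grids, stats = NULL) {
  if (is.null(stats)) {
    all_rows <- do.call(rbind, grids$values)
    center <- colMeans(all_rows)
    scale <- apply(all_rows, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-8] <- 1
    stats <- list(center = center, scale = scale)
  }
  out <- grids
  out$values <- purrr::map(grids$values, function(v) {
    sweep(sweep(v, 2, stats$center), 2, stats$scale, "/")
  })
  list(grids = out, stats = stats)
}

#' Concatenate per-window text embeddings onto the non-text grid
#'
#' Each window's feature vector becomes `[non-text features, embedding]`,
#' so the channel count grows by the embedding dimension (e.g. 30 non-text
#' channels + a 768-dim short embedding = 798 channels). Embedding rows
#' must align with the grid windows.
#'
#' @param grids Grid tibble.
#' @param embeddings Tibble from [embed_episodes()] (`episode_id`,
#'   `embedding` matrix list-column).
#' @return The grid tibble with widened `values` and `mask` (embedding
#'   cells are marked observed).
#' @export
assemble_multimodal <- function(grids, embeddings) {
  emb <- embeddings$embedding[match(grids$episode_id, embeddings$episode_id)]
  if (any(purrr::map_lgl(emb, is.null))) {
    abort("`embeddings` must cover every episode in `grids`.")
  }
  out <- grids
  out$values <- purrr::pmap(list(grids$values, emb, grids$n_windows),
    function(v, e, nw) {
      if (nrow(e) != nw) abort("embedding rows must align with grid windows.")
      dm <- cbind(v, e)
      colnames(dm) <- c(colnames(v), sprintf("emb%04d", seq_len(ncol(e))))
      dm
    })
  out$mask <- purrr::map2(grids$mask, emb, function(m, e) {
    dm <- cbind(m, matrix(1, nrow(m), ncol(e)))
    dm
  })
  out
}
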