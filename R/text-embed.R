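# Per-window clinical-text embeddings with the short/long pooling scheme:
# token states from the last `layer_count` encoder layers are mean-pooled
# over tokens within each layer, then either averaged across layers
# ("short", hidden_size dims) or concatenated in layer order ("long",
# layer_count x hidden_size dims).
#
# The default backend is a deterministic surrogate whose per-token layer
# states are seeded pseudo-random vectors, so the text pathway is fully
# testable offline; a pretrained clinical transformer can be plugged in as
# an external adapter.

#' Specification of a note embedder
#'
#' @param backend `"surrogate"` (default, deterministic, no external
#'   weights) or `"pretrained"` (adapter hook for external clinical
#'   transformer weights; not bundled).
#' @param mode `"short"` (mean of the last layers, `hidden_size` dims) or
#'   `"long"` (concatenation, `layer_count * hidden_size` dims).
#' @param layer_count Number of final hidden layers pooled (default 4).
#' @param hidden_size Per-layer hidden width (default 768).
#' @param max_tokens Token cap per note (default 512); content beyond the
#'   cap never influences the embedding.
#' @param token_pool Token pooling within a layer: `"mean"` (default).
#' @param seed Seed for the surrogate backend.
#' @return An `embedder_spec` list with an `out_dim` field.
#' @export
#' @examples
#' embedder_spec(mode = "short")$out_dim  # 768
#' embedder_spec(mode = "long")$out_dim   # 3072
embedder_spec <- function(backend = c("surrogate", "pretrained"),
                          mode = c("short", "long"),
                          layer_count = 4, hidden_size = 768,
                          max_tokens = 512, token_pool = "mean", seed = 1) {
  backend <- match.arg(backend)
  mode <- match.arg(mode)
  stopifnot(layer_count >= 1, hidden_size >= 1, max_tokens >= 1)
  structure(
    list(backend = backend, mode = mode, layer_count = layer_count,
         hidden_size = hidden_size, max_tokens = max_tokens,
         token_pool = token_pool, seed = as.integer(seed),
         out_dim = if (mode == "short") hidden_size
                   else layer_count * hidden_size),
    class = "embedder_spec"
  )
}

tokenize_note <- function(text, max_tokens) {
  toks <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  head(toks, max_tokens)
}

# layer_count x hidden_size matrix of surrogate hidden states for a token;
# memoised in `cache` so repeated tokens cost one draw
surrogate_token_states <- function(token, spec, cache) {
  hit <- cache[[token]]
  if (!is.null(hit)) return(hit)
  states <- with_seed_tag(spec$seed, paste0("tok:", token), {
    matrix(rnorm(spec$layer_count * spec$hidden_size),
           spec$layer_count, spec$hidden_size)
  })
  cache[[token]] <- states
  states
}

#' Embed a single note
#'
#' Tokenizes (lowercased whitespace split), truncates to `max_tokens`,
#' obtains per-token states for the last `layer_count` layers, mean-pools
#' tokens within each layer, and combines layers per `spec$mode`.
#'
#' @param text Note text.
#' @param spec An [embedder_spec()].
#' @param .cache Internal token-state memo (environment); supply one to
#'   share across many notes.
#' @return Numeric vector of length `spec$out_dim`; a zero vector (with a
#'   warning) for empty text.
#' @export
embed_note <- function(text, spec, .cache = new.env(parent = emptyenv())) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (spec$backend == "pretrained") {
    abort(paste("the pretrained backend is an adapter for external",
                "transformer weights and is not bundled; use the",
                "surrogate backend"))
  }
  toks <- tokenize_note(text, spec$max_tokens)
  if (length(toks) == 0L) {
    warn("empty note text; returning a zero embedding")
    return(numeric(spec$out_dim))
  }
  acc <- matrix(0, spec$layer_count, spec$hidden_size)
  for (tk in toks) {
    acc <- acc + surrogate_token_states(tk, spec, .cache)
  }
  layer_vecs <- acc / length(toks)
  if (spec$mode == "short") {
    colMeans(layer_vecs)
  } else {
    as.vector(t(layer_vecs))
  }
}

#' Pool several note vectors within one time window
#'
#' @param vectors List of equal-length note embedding vectors.
#' @param dim Output dimension, used when `vectors` is empty.
#' @return The arithmetic mean vector; a zero vector when no notes fall in
#'   the window.
#' @export
window_pool <- function(vectors, dim) {
  if (length(vectors) == 0L) return(numeric(dim))
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L) abort("note vectors have mixed dimensions.")
  Reduce(`+`, vectors) / length(vectors)
}

#' Per-window text embeddings for every episode
#'
#' Embeds every note event falling inside an episode's span, pools notes
#' within each one-hour window by [window_pool()], and leaves all-zero rows
#' for windows without notes.
#'
#' @param events Event tibble (rows with `kind == "note"` are used).
#' @param episodes Episode tibble from [select_cohort()].
#' @param spec An [embedder_spec()].
#' @return Tibble: `episode_id`, `embedding` (windows x out_dim matrix
#'   list-column), `note_presence` (0/1 vector list-column).
#' @export
embed_episodes <- function(events, episodes, spec) {
  notes <- events |>
    dplyr::filter(.data$kind == "note") |>
    dplyr::inner_join(
      dplyr::select(episodes, "episode_id", "start_h", "endpoint_h"),
      by = c(patient_id = "episode_id")
    ) |>
    dplyr::filter(.data$time_h >= .data$start_h,
                  .data$time_h < .data$endpoint_h) |>
    dplyr::mutate(window = as.integer(floor(.data$time_h - .data$start_h)))
  cache <- new.env(parent = emptyenv())
  note_vecs <- purrr::map(notes$text, embed_note, spec = spec, .cache = cache)
  by_ep <- split(
    tibble::tibble(window = notes$window, vec = note_vecs),
    notes$patient_id
  )
  tibble::tibble(
    episode_id = episodes$episode_id,
    embedding = purrr::map2(episodes$episode_id, episodes$n_windows,
      function(id, nw) {
        mat <- matrix(0, nw, spec$out_dim)
        np <- by_ep[[id]]
        if (!is.null(np)) {
          for (w in unique(np$window)) {
            mat[w + 1L, ] <- window_pool(np$vec[np$window == w], spec$out_dim)
          }
        }
        mat
      }),
    note_presence = purrr::map2(episodes$episode_id, episodes$n_windows,
      function(id, nw) {
        pres <- integer(nw)
        np <- by_ep[[id]]
        if (!is.null(np)) pres[unique(np$window) + 1L] <- 1L
        pres
      })
  )
}
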