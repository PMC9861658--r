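#' Derive a reproducible sub-seed from a root seed and a tag
#'
#' All stochastic steps in the pipeline draw their own seed from a single
#' root seed through this function, so that modules can be re-run in any
#' order (or in isolation) without perturbing each other's random streams.
#' The derivation is a small deterministic integer hash of the tag folded
#' into the root seed; results stay inside the 32-bit signed range R
#' requires of `set.seed()`.
#'
#' @param seed Integer root seed.
#' @param tag Character scalar naming the consumer (e.g. `"cohort"`,
#'   `"round3/client2"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "notes")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(tag)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run code under a temporary RNG state seeded from (seed, tag); restores the
# caller's RNG afterwards so library users' random streams are untouched.
with_seed_tag <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  force(code)
}

# Largest-remainder apportionment of `n` items into proportions `fracs`.
# Deterministic, totals exactly n; ties go to the earlier fraction.
largest_remainder <- function(n, fracs) {
  stopifnot(abs(sum(fracs) - 1) < 1e-8)
  raw <- n * fracs
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Half-up rounding to `digits` decimals (R's round() is round-half-even;
# printed percentage deltas follow conventional half-up rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Apply a binary function elementwise across two congruent nested lists of
# numeric arrays (model weights); used by the federated aggregation rules.
weights_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- lapply(seq_along(a), function(i) weights_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    stopifnot(identical(dim(a), dim(b)), length(a) == length(b))
    f(a, b)
  }
}

weights_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, weights_map1, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

weights_scale <- function(w, s) weights_map1(w, function(x) x * s)
weights_add <- function(a, b) weights_map2(a, b, `+`)
weights_sub <- function(a, b) weights_map2(a, b, `-`)

# Flatten a nested weights list to a single numeric vector and back; used by
# the transport layer and by tests asserting exact round trips.
weights_flatten <- function(w) {
  unlist(w, use.names = FALSE)
}

check_fraction <- function(x, name, closed_hi = TRUE) {
  ok <- is.numeric(x) && all(x >= 0) && all(if (closed_hi) x <= 1 else x < 1)
  if (!ok) abort(sprintf("`%s` must be a fraction in [0, 1%s", name,
                         if (closed_hi) "]." else ")."))
  invisible(x)
}
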