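# Synthetic sparse-EHR cohort generation with planted Sepsis-3 ground truth.
#
# The generator emulates the statistical shape the downstream pipeline
# assumes -- episode-level sepsis prevalence around 9.5%, care-episode
# lengths capped at 48 one-hour windows, heavy per-channel missingness, and
# antimicrobial / culture / SOFA event streams that trigger (or provably
# fail) the Sepsis-3 rules -- while recording the planted truth so the
# labeler can be tested for exact recovery.

# baseline (mean, sd) per default physiological channel; channels outside
# this table are simulated as standard normal
.channel_stats <- function(channels) {
  defaults <- list(
    heart_rate = c(85, 15), resp_rate = c(18, 5), sbp = c(120, 20),
    dbp = c(65, 12), map = c(80, 13), temp_c = c(37, 0.7),
    spo2 = c(96, 3), lactate = c(1.8, 1.0), creatinine = c(1.1, 0.6),
    wbc = c(9, 4)
  )
  t(vapply(channels, function(ch) {
    if (ch %in% names(defaults)) defaults[[ch]] else c(0, 1)
  }, numeric(2)))
}

#' Configuration for the synthetic EHR cohort generator
#'
#' @param n_patients Number of patients to simulate.
#' @param target_prevalence Episode-level probability of sepsis; default
#'   0.095, matching the roughly 9.5% positive rate the pipeline is designed
#'   around.
#' @param episode_hours Length-2 numeric: range of hours from admission to
#'   the episode endpoint (sepsis onset for cases, discharge for controls).
#'   Endpoints beyond 48 h exercise the 48-window episode cap.
#' @param length_levels Number of discrete endpoint levels spread evenly
#'   over `episode_hours`. Episode lengths cluster at a few typical stay
#'   durations rather than spreading uniformly, which also keeps the
#'   (label, length) strata of the 80/10/10 split populated at desk-scale
#'   cohort sizes.
#' @param channels Character vector of non-text channel names.
#' @param missing_rate Per-channel probability that a window's observation
#'   is dropped. Scalar (recycled) or named vector over `channels`; each
#'   rate must be in `[0, 1]` and at least one must be `< 1`.
#' @param note_rate Expected number of free-text notes per one-hour window
#'   (Poisson).
#' @param signal_effect Peak mean shift, in channel standard deviations,
#'   applied to septic patients' observations: a persistent elevation of
#'   30% of the effect from admission on, ramping linearly to the full
#'   effect over the `signal_ramp` windows before onset. The note-token
#'   class signal scales with the same value. Zero removes all class
#'   signal, including from note text.
#' @param signal_ramp Number of pre-onset windows over which the mean shift
#'   ramps up.
#' @param age_range Range of simulated ages in years.
#' @param seed Integer root seed; fully determines the generated cohort.
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
synth_config <- function(n_patients,
                         target_prevalence = 0.095,
                         episode_hours = c(12, 48),
                         length_levels = 4,
                         channels = c("heart_rate", "resp_rate", "sbp",
                                      "dbp", "map", "temp_c", "spo2",
                                      "lactate", "creatinine", "wbc"),
                         missing_rate = 0.6,
                         note_rate = 0.3,
                         signal_effect = 1.5,
                         signal_ramp = 6,
                         age_range = c(16, 95),
                         seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 0) {
    abort("`n_patients` must be a non-negative count.")
  }
  check_fraction(target_prevalence, "target_prevalence")
  if (length(episode_hours) != 2 || episode_hours[1] < 1 ||
      episode_hours[1] > episode_hours[2]) {
    abort("`episode_hours` must be c(min, max) with min >= 1.")
  }
  if (length(missing_rate) == 1L) {
    missing_rate <- setNames(rep(missing_rate, length(channels)), channels)
  }
  if (!all(channels %in% names(missing_rate))) {
    abort("`missing_rate` must cover every channel (or be a scalar).")
  }
  missing_rate <- missing_rate[channels]
  check_fraction(missing_rate, "missing_rate")
  if (all(missing_rate >= 1)) {
    abort("at least one channel must have `missing_rate` < 1.")
  }
  if (signal_ramp < 1) abort("`signal_ramp` must be >= 1.")
  structure(
    list(n_patients = as.integer(n_patients),
         target_prevalence = target_prevalence,
         episode_hours = episode_hours,
         length_levels = as.integer(length_levels), channels = channels,
         missing_rate = missing_rate, note_rate = note_rate,
         signal_effect = signal_effect, signal_ramp = signal_ramp,
         age_range = age_range, seed = as.integer(seed)),
    class = "synth_config"
  )
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), time_h = double(),
                 kind = character(), channel = character(),
                 value = double(), text = character())
}

#' Simulate a synthetic EHR cohort with planted Sepsis-3 ground truth
#'
#' Returns a long event stream (one row per timestamped observation),
#' admission metadata, and the planted per-patient truth. For septic
#' patients the antimicrobial, culture, and SOFA events are placed so that
#' the Sepsis-3 rules hold at exactly the planted onset hour: two
#' antimicrobial doses and a culture order inside the 24 h pairing bound,
#' and a single SOFA observation rising at least 2 points above baseline
#' inside the -48 h/+24 h dysfunction window. Non-septic patients violate
#' at least one rule (a missing second dose, a culture outside the pairing
#' bound, or a SOFA series that never rises 2 points).
#'
#' @param config A [synth_config()].
#' @return A list of class `sepsis_cohort` with elements `events`
#'   (tibble: patient_id, time_h, kind, channel, value, text), `admissions`
#'   (patient_id, age_years, admit_h, discharge_h, death_h), `truth`
#'   (patient_id, true_septic, true_onset_h, suspicion_h, dysfunction_h,
#'   endpoint_h), and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n == 0L) {
    out <- list(
      events = empty_events(),
      admissions = tibble::tibble(patient_id = character(),
                                  age_years = double(), admit_h = double(),
                                  discharge_h = double(), death_h = double()),
      truth = tibble::tibble(patient_id = character(),
                             true_septic = logical(), true_onset_h = double(),
                             suspicion_h = double(), dysfunction_h = double(),
                             endpoint_h = double()),
      config = config
    )
    class(out) <- "sepsis_cohort"
    return(out)
  }

  patients <- with_seed_tag(config$seed, "cohort", {
    id <- sprintf("p%05d", seq_len(n))
    septic <- runif(n) < config$target_prevalence
    age <- runif(n, config$age_range[1], config$age_range[2])
    # endpoints sit on a discrete grid of typical stay lengths; the small
    # downward jitter keeps onset times real-valued without moving an
    # endpoint across a whole-hour window boundary
    levels <- round(seq(config$episode_hours[1], config$episode_hours[2],
                        length.out = config$length_levels))
    endpoint <- levels[sample.int(length(levels), n, replace = TRUE)] -
      runif(n, 0, 0.5)
    # controls: discharge at the endpoint; cases: onset at the endpoint and
    # discharge a little later (downstream truncates the episode at onset)
    discharge <- ifelse(septic, endpoint + runif(n, 2, 10), endpoint)
    death <- rep(NA_real_, n)
    dies <- !septic & runif(n) < 0.05
    death[dies] <- discharge[dies]
    list(id = id, septic = septic, age = age, endpoint = endpoint,
         discharge = discharge, death = death)
  })

  clinical <- with_seed_tag(config$seed, "clinical-events", {
    build_clinical_events(patients, config)
  })
  vitals <- with_seed_tag(config$seed, "vitals", {
    build_vital_events(patients, config)
  })

  truth <- tibble::tibble(
    patient_id = patients$id,
    true_septic = patients$septic,
    true_onset_h = ifelse(patients$septic, patients$endpoint, NA_real_),
    suspicion_h = clinical$suspicion_h,
    dysfunction_h = ifelse(patients$septic, patients$endpoint, NA_real_),
    endpoint_h = patients$endpoint
  )

  out <- list(
    events = dplyr::arrange(
      dplyr::bind_rows(clinical$events, vitals),
      .data$patient_id, .data$time_h
    ),
    admissions = tibble::tibble(
      patient_id = patients$id, age_years = patients$age, admit_h = 0,
      discharge_h = patients$discharge, death_h = patients$death
    ),
    truth = truth,
    config = config
  )
  if (config$note_rate > 0) {
    out$events <- dplyr::arrange(
      dplyr::bind_rows(out$events, simulate_notes(config, truth)),
      .data$patient_id, .data$time_h
    )
  }
  class(out) <- "sepsis_cohort"
  out
}

# antimicrobial-dose, culture-order, and SOFA event streams (the consumed
# RNG count per patient is fixed so event placement is stable)
build_clinical_events <- function(patients, config) {
  n <- length(patients$id)
  rows <- vector("list", n)
  suspicion_h <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    id <- patients$id[i]
    if (patients$septic[i]) {
      onset <- patients$endpoint[i]
      a1 <- max(0, onset - runif(1, 6, 12))
      a2 <- a1 + runif(1, 1, 3)
      cult <- a1 + runif(1, 3, min(20, max(4, onset - a1)))
      suspicion_h <- replace(suspicion_h, i, min(a1, cult))
      sofa_rise <- 2 + rbinom(1, 2, 0.4)
      rows[[i]] <- tibble::tibble(
        patient_id = id,
        time_h = c(a1, a2, cult, 0, onset),
        kind = c("antimicrobial_dose", "antimicrobial_dose",
                 "culture_order", "sofa_score", "sofa_score"),
        channel = c("abx", "abx", "culture", "sofa", "sofa"),
        value = c(1, 1, 1, rbinom(1, 1, 0.4), sofa_rise),
        text = NA_character_
      )
    } else {
      # controls exercise every failure mode of the Sepsis-3 rules
      u <- runif(1)
      end <- patients$endpoint[i]
      base_sofa <- tibble::tibble(
        patient_id = id, time_h = c(0, end * runif(1, 0.3, 0.9)),
        kind = "sofa_score", channel = "sofa",
        value = c(rbinom(1, 1, 0.3), rbinom(1, 1, 0.3)),
        text = NA_character_
      )
      extra <- if (u < 0.25) {
        # single antimicrobial dose: fails the two-dose requirement
        tibble::tibble(patient_id = id, time_h = end * runif(1, 0.1, 0.5),
                       kind = c("antimicrobial_dose"), channel = "abx",
                       value = 1, text = NA_character_)
      } else if (u < 0.45) {
        # dose pair with a culture past the 24 h bound
        a1 <- end * runif(1, 0.05, 0.2)
        tibble::tibble(patient_id = id,
                       time_h = c(a1, a1 + 1, a1 + 24 + runif(1, 1, 10)),
                       kind = c("antimicrobial_dose", "antimicrobial_dose",
                                "culture_order"),
                       channel = c("abx", "abx", "culture"),
                       value = 1, text = NA_character_)
      } else if (u < 0.6) {
        # valid suspicion but the SOFA series never rises 2 from baseline
        a1 <- end * runif(1, 0.05, 0.4)
        tibble::tibble(patient_id = id,
                       time_h = c(a1, a1 + 1.5, a1 + runif(1, 1, 10)),
                       kind = c("antimicrobial_dose", "antimicrobial_dose",
                                "culture_order"),
                       channel = c("abx", "abx", "culture"),
                       value = 1, text = NA_character_)
      } else {
        runif(3) # keep per-patient RNG use constant
        NULL
      }
      rows[[i]] <- dplyr::bind_rows(base_sofa, extra)
    }
  }
  list(events = dplyr::bind_rows(rows), suspicion_h = suspicion_h)
}

# vital/lab observations on the hourly grid, thinned by per-channel
# missingness; septic patients get a linear mean-shift ramp ending at onset
build_vital_events <- function(patients, config) {
  n_w <- pmax(1L, ceiling(patients$endpoint))
  pat_row <- rep(seq_along(patients$id), n_w)
  window <- unlist(lapply(n_w, function(k) seq_len(k) - 1L))
  n_chan <- length(config$channels)
  stats <- .channel_stats(config$channels)

  # expand (patient-window) x channel
  pw <- length(pat_row)
  pat_rep <- rep(pat_row, each = n_chan)
  win_rep <- rep(window, each = n_chan)
  chan_rep <- rep.int(seq_len(n_chan), pw)

  keep <- runif(pw * n_chan) >= config$missing_rate[chan_rep]
  pat_rep <- pat_rep[keep]; win_rep <- win_rep[keep]
  chan_rep <- chan_rep[keep]
  m <- length(pat_rep)
  if (m == 0L) return(empty_events())

  mu <- stats[chan_rep, 1]
  sd <- stats[chan_rep, 2]
  onset_w <- floor(patients$endpoint)
  # septic patients carry a mild persistent elevation from admission on
  # (they are sicker throughout) plus a linear ramp to the full effect over
  # the last `signal_ramp` pre-onset windows
  ramp <- rep(0, m)
  sep <- patients$septic[pat_rep]
  if (any(sep) && config$signal_effect != 0) {
    ramp[sep] <- 0.3 * config$signal_effect
    dist <- onset_w[pat_rep] - win_rep   # windows until onset
    in_ramp <- sep & dist >= 0 & dist < config$signal_ramp
    ramp[in_ramp] <- config$signal_effect *
      (0.3 + 0.7 * (1 - dist[in_ramp] / config$signal_ramp))
  }
  tibble::tibble(
    patient_id = patients$id[pat_rep],
    time_h = win_rep + runif(m),
    kind = "vital",
    channel = config$channels[chan_rep],
    value = rnorm(m, mu + ramp * sd, sd),
    text = NA_character_
  )
}

#' Simulate free-text note events carrying a class-separable token signal
#'
#' Notes are bags of tokens drawn from a shared base vocabulary mixed with a
#' class-specific vocabulary; the class-specific mixing weight grows with
#' `signal_effect` and is exactly zero when `signal_effect = 0`, in which
#' case the class-conditional token distributions are identical.
#'
#' @param config A [synth_config()].
#' @param truth The `truth` tibble from [simulate_cohort()] (needs
#'   `true_septic` and `endpoint_h`).
#' @return An event tibble of `kind = "note"` rows with the note text in the
#'   `text` column.
#' @export
simulate_notes <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  if (config$note_rate <= 0 || nrow(truth) == 0) return(empty_events())
  with_seed_tag(config$seed, "notes", {
    vocab_base <- sprintf("base%02d", 1:60)
    vocab_sep <- sprintf("sep%02d", 1:20)
    vocab_ctl <- sprintf("ctl%02d", 1:20)
    # clinical text is the weak, complementary modality: notes lean only
    # mildly toward the class vocabulary, so a text-only model sits far
    # below the tabular one while still adding signal in combination
    w_mix <- min(0.8, 0.12 * config$signal_effect)

    n_w <- pmax(1L, ceiling(truth$endpoint_h))
    pat_row <- rep(seq_len(nrow(truth)), n_w)
    window <- unlist(lapply(n_w, function(k) seq_len(k) - 1L))
    n_notes <- stats::rpois(length(pat_row), config$note_rate)
    keep <- n_notes > 0
    pat_note <- rep(pat_row[keep], n_notes[keep])
    win_note <- rep(window[keep], n_notes[keep])
    total <- length(pat_note)
    if (total == 0L) return(empty_events())

    lens <- sample(20:40, total, replace = TRUE)
    septic <- truth$true_septic[pat_note]
    texts <- character(total)
    for (i in seq_len(total)) {
      k <- lens[i]
      class_vocab <- if (septic[i]) vocab_sep else vocab_ctl
      from_class <- runif(k) < w_mix
      toks <- character(k)
      toks[from_class] <- sample(class_vocab, sum(from_class), replace = TRUE)
      toks[!from_class] <- sample(vocab_base, sum(!from_class), replace = TRUE)
      texts[i] <- paste(toks, collapse = " ")
    }
    tibble::tibble(
      patient_id = truth$patient_id[pat_note],
      time_h = win_note + runif(total),
      kind = "note", channel = "note", value = NA_real_, text = texts
    )
  })
}

#' Write an event stream (or any pipeline tibble) as delimited text
#'
#' Note rows carry their text payload in the `value` column on disk, as a
#' single `value` column holds either the numeric or the text payload.
#'
#' @param events Event tibble as produced by [simulate_cohort()].
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- dplyr::mutate(
    events,
    value = ifelse(.data$kind == "note", .data$text,
                   as.character(.data$value))
  )
  readr::write_tsv(dplyr::select(out, -"text"), path)
  invisible(path)
}

#' Read an event stream written by [write_events()]
#'
#' @param path File path.
#' @return An event tibble with numeric `value` and character `text`.
#' @export
read_events <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(), time_h = readr::col_double(),
    kind = readr::col_character(), channel = readr::col_character(),
    value = readr::col_character()
  ))
  dplyr::mutate(
    raw,
    text = ifelse(.data$kind == "note", .data$value, NA_character_),
    value = suppressWarnings(
      ifelse(.data$kind == "note", NA_real_, as.numeric(.data$value))
    )
  )
}
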