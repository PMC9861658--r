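# Sepsis-3 operationalization: suspected infection, organ dysfunction, and
# onset assignment, plus cohort selection with the 48-window episode cap.

#' Detect suspected-infection windows from antimicrobial and culture events
#'
#' Suspected infection requires at least two antimicrobial doses (any drug,
#' at distinct times) paired with a culture order: when the first dose
#' precedes the culture, the culture must follow within 24 h; when the
#' culture comes first, the first dose must follow within 72 h. Both bounds
#' are inclusive. The suspicion time is the earlier of the first dose and
#' the culture order.
#'
#' @param events Event tibble (columns `patient_id`, `time_h`, `kind`) for
#'   one or more patients, time-sorted within patient; rows of kind
#'   `antimicrobial_dose` and `culture_order` are used.
#' @return A tibble with one row per qualifying (dose-pair, culture)
#'   combination: `patient_id`, `suspicion_h`, `first_abx_h`, `culture_h`,
#'   `ordering` (`"abx_first"` or `"culture_first"`).
#' @export
detect_suspected_infection <- function(events) {
  stopifnot(all(c("patient_id", "time_h", "kind") %in% names(events)))
  bad <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(unsorted = is.unsorted(.data$time_h), .groups = "drop")
  if (any(bad$unsorted)) abort("events must be time-sorted within patient.")

  out <- events |>
    dplyr::filter(.data$kind %in% c("antimicrobial_dose", "culture_order")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      abx <- sort(unique(df$time_h[df$kind == "antimicrobial_dose"]))
      cult <- df$time_h[df$kind == "culture_order"]
      if (length(abx) < 2L || length(cult) == 0L) {
        return(tibble::tibble(suspicion_h = double(), first_abx_h = double(),
                              culture_h = double(), ordering = character()))
      }
      first_abx <- abx[1]
      ok_abx_first <- first_abx <= cult & (cult - first_abx) <= 24
      ok_cult_first <- cult < first_abx & (first_abx - cult) <= 72
      keep <- ok_abx_first | ok_cult_first
      tibble::tibble(
        suspicion_h = pmin(first_abx, cult[keep]),
        first_abx_h = first_abx,
        culture_h = cult[keep],
        ordering = ifelse(ok_abx_first[keep], "abx_first", "culture_first")
      )
    }) |>
    dplyr::ungroup()
  out
}

#' Assess organ dysfunction around a suspected-infection time
#'
#' The SOFA baseline is the latest score strictly before
#' `suspicion_h - 72`; absent any such score the baseline is zero. Organ
#' dysfunction holds if any score inside the inclusive window
#' `[suspicion_h - 48, suspicion_h + 24]` rises at least 2 points above the
#' baseline; the dysfunction time is the earliest such score time.
#'
#' @param sofa Tibble with `time_h` and `value` (SOFA score), time-sorted.
#' @param suspicion_h Suspicion time in hours.
#' @return A list with `flag` (logical), `dysfunction_h` (hours or `NA`),
#'   and `baseline` (integer).
#' @export
organ_dysfunction <- function(sofa, suspicion_h) {
  if (nrow(sofa) == 0L) {
    return(list(flag = FALSE, dysfunction_h = NA_real_, baseline = 0))
  }
  if (is.unsorted(sofa$time_h)) abort("SOFA series must be time-sorted.")
  pre <- sofa$value[sofa$time_h < suspicion_h - 72]
  baseline <- if (length(pre)) pre[length(pre)] else 0
  in_win <- sofa$time_h >= suspicion_h - 48 & sofa$time_h <= suspicion_h + 24
  qual <- in_win & (sofa$value - baseline) >= 2
  if (any(qual)) {
    list(flag = TRUE, dysfunction_h = min(sofa$time_h[qual]),
         baseline = baseline)
  } else {
    list(flag = FALSE, dysfunction_h = NA_real_, baseline = baseline)
  }
}

#' Assign a Sepsis-3 onset from suspicion windows and a SOFA series
#'
#' Each suspicion window is checked for organ dysfunction; a qualifying
#' pair contributes its dysfunction time as an onset candidate. Among the
#' windows where both criteria co-hold, the onset is the latest candidate
#' by default (`policy = "latest"`), with `"earliest"` available.
#'
#' @param suspicions Output of [detect_suspected_infection()] for one
#'   patient.
#' @param sofa SOFA tibble (`time_h`, `value`) for the same patient.
#' @param policy `"latest"` (default) or `"earliest"`.
#' @return One-row tibble: `onset_h`, `onset_window`, `suspicion_h`,
#'   `baseline` (all `NA` when no window qualifies).
#' @export
assign_onset <- function(suspicions, sofa, policy = c("latest", "earliest")) {
  policy <- match.arg(policy)
  none <- tibble::tibble(onset_h = NA_real_, onset_window = NA_integer_,
                         suspicion_h = NA_real_, baseline = NA_real_)
  if (nrow(suspicions) == 0L) return(none)
  cand <- purrr::map(suspicions$suspicion_h, organ_dysfunction, sofa = sofa)
  flag <- purrr::map_lgl(cand, "flag")
  if (!any(flag)) return(none)
  times <- purrr::map_dbl(cand, "dysfunction_h")[flag]
  pick <- if (policy == "latest") which.max(times) else which.min(times)
  i <- which(flag)[pick]
  tibble::tibble(
    onset_h = times[pick],
    onset_window = as.integer(floor(times[pick])),
    suspicion_h = suspicions$suspicion_h[i],
    baseline = as.double(cand[[i]]$baseline)
  )
}

#' Label Sepsis-3 onsets for every patient in an event stream
#'
#' Convenience wrapper composing [detect_suspected_infection()],
#' [organ_dysfunction()], and [assign_onset()] per patient. The result is
#' invariant to the on-disk ordering of event records (events are sorted
#' internally).
#'
#' @param events Event tibble covering any number of patients.
#' @param policy Onset policy passed to [assign_onset()].
#' @return A tibble with one row per patient appearing in `events`:
#'   `patient_id`, `septic`, `onset_h`, `onset_window`, `suspicion_h`,
#'   `baseline`.
#' @export
#' @examples
#' cohort <- simulate_cohort(synth_config(n_patients = 30, seed = 2))
#' label_sepsis3(cohort$events)
label_sepsis3 <- function(events, policy = c("latest", "earliest")) {
  policy <- match.arg(policy)
  events <- dplyr::arrange(events, .data$patient_id, .data$time_h)
  events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      susp <- detect_suspected_infection(
        dplyr::mutate(df, patient_id = "x")
      )
      sofa <- df |>
        dplyr::filter(.data$kind == "sofa_score") |>
        dplyr::select("time_h", "value")
      onset <- assign_onset(susp, sofa, policy = policy)
      dplyr::mutate(onset, septic = !is.na(.data$onset_h), .before = 1)
    }) |>
    dplyr::ungroup()
}

#' Select care episodes: adult patients, endpoint, and the 48-window cap
#'
#' Patients strictly older than `min_age` years are retained. The episode
#' endpoint is the earliest of first sepsis onset, death, and discharge;
#' the episode covers `[max(0, endpoint - max_windows), endpoint]`, later
#' binned into one-hour windows, so no episode exceeds `max_windows`
#' windows.
#'
#' @param admissions Tibble: `patient_id`, `age_years`, `discharge_h`, and
#'   optionally `death_h`.
#' @param onsets Output of [label_sepsis3()].
#' @param max_windows Episode cap in one-hour windows (default 48).
#' @param min_age Exclusive age threshold in years (default 15).
#' @return Episode tibble: `episode_id`, `start_h`, `endpoint_h`,
#'   `n_windows`, `label`, `onset_window` (index within the episode, `NA`
#'   for negatives).
#' @export
select_cohort <- function(admissions, onsets, max_windows = 48, min_age = 15) {
  if (!"death_h" %in% names(admissions)) admissions$death_h <- NA_real_
  missing_times <- is.na(admissions$discharge_h)
  if (any(missing_times)) {
    warn(sprintf("skipping %d admission(s) with missing discharge time",
                 sum(missing_times)))
    admissions <- admissions[!missing_times, ]
  }
  admissions |>
    dplyr::left_join(
      dplyr::select(onsets, "patient_id", "onset_h"), by = "patient_id"
    ) |>
    dplyr::filter(.data$age_years > min_age) |>
    dplyr::mutate(
      endpoint_h = pmin(
        dplyr::coalesce(.data$onset_h, Inf),
        dplyr::coalesce(.data$death_h, Inf),
        .data$discharge_h
      ),
      start_h = pmax(0, .data$endpoint_h - max_windows),
      n_windows = as.integer(ceiling(.data$endpoint_h - .data$start_h)),
      label = !is.na(.data$onset_h) & .data$onset_h <= .data$endpoint_h,
      onset_window = dplyr::if_else(
        .data$label,
        pmin(as.integer(floor(.data$onset_h - .data$start_h)),
             .data$n_windows - 1L),
        NA_integer_
      )
    ) |>
    dplyr::filter(.data$n_windows >= 1L) |>
    dplyr::transmute(
      episode_id = .data$patient_id, start_h = .data$start_h,
      endpoint_h = .data$endpoint_h, n_windows = .data$n_windows,
      label = .data$label, onset_window = .data$onset_window
    )
}
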