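mk_events <- function(abx = numeric(), culture = numeric(),
                      sofa_t = numeric(), sofa_v = numeric(), id = "p1") {
  tibble::tibble(
    patient_id = id,
    time_h = c(abx, culture, sofa_t),
    kind = c(rep("antimicrobial_dose", length(abx)),
             rep("culture_order", length(culture)),
             rep("sofa_score", length(sofa_t))),
    channel = c(rep("abx", length(abx)), rep("culture", length(culture)),
                rep("sofa", length(sofa_t))),
    value = c(rep(1, length(abx) + length(culture)), sofa_v),
    text = NA_character_
  ) |> dplyr::arrange(time_h)
}

test_that("suspected-infection pairing honors the 24 h and 72 h bounds", {
  # antimicrobials first, culture within 24 h
  s <- detect_suspected_infection(mk_events(abx = c(0, 6), culture = 20))
  expect_equal(nrow(s), 1L)
  expect_equal(s$ordering, "abx_first")
  expect_equal(s$suspicion_h, 0)

  # culture beyond 24 h of the first dose: no window
  expect_equal(nrow(detect_suspected_infection(
    mk_events(abx = c(0, 6), culture = 30))), 0L)

  # culture first, antimicrobials within 72 h
  s <- detect_suspected_infection(mk_events(abx = c(50, 60), culture = 0))
  expect_equal(nrow(s), 1L)
  expect_equal(s$ordering, "culture_first")
  expect_equal(s$suspicion_h, 0)

  # a single dose never qualifies
  expect_equal(nrow(detect_suspected_infection(
    mk_events(abx = 0, culture = 1))), 0L)

  # inclusive boundary: culture at exactly +24 h qualifies
  expect_equal(nrow(detect_suspected_infection(
    mk_events(abx = c(0, 2), culture = 24))), 1L)

  expect_error(detect_suspected_infection(
    tibble::tibble(patient_id = "p1", time_h = c(5, 1),
                   kind = c("antimicrobial_dose", "antimicrobial_dose"))),
    "time-sorted")
})

test_that("organ dysfunction uses the pre-72 h baseline and the -48/+24 window", {
  # no score before the lookback: baseline 0, a score of 2 at suspicion meets
  # the threshold exactly
  sofa <- tibble::tibble(time_h = 100, value = 2)
  od <- organ_dysfunction(sofa, suspicion_h = 100)
  expect_true(od$flag)
  expect_equal(od$baseline, 0)
  expect_equal(od$dysfunction_h, 100)

  # constant score 3 including before the lookback: baseline 3, no rise
  sofa <- tibble::tibble(time_h = c(0, 50, 100, 120), value = 3)
  od <- organ_dysfunction(sofa, suspicion_h = 100)
  expect_false(od$flag)
  expect_equal(od$baseline, 3)

  # a qualifying score outside the +24 h bound does not count
  sofa <- tibble::tibble(time_h = 130, value = 4)
  expect_false(organ_dysfunction(sofa, suspicion_h = 100)$flag)

  # empty series: flag false, baseline 0
  od <- organ_dysfunction(tibble::tibble(time_h = double(),
                                         value = double()), 10)
  expect_false(od$flag)
  expect_equal(od$baseline, 0)

  # earliest qualifying time wins within the window
  sofa <- tibble::tibble(time_h = c(60, 80, 110), value = c(1, 3, 4))
  expect_equal(organ_dysfunction(sofa, suspicion_h = 100)$dysfunction_h, 80)
})

test_that("onset assignment picks the latest qualifying window by default", {
  none <- assign_onset(
    tibble::tibble(patient_id = character(), suspicion_h = double(),
                   first_abx_h = double(), culture_h = double(),
                   ordering = character()),
    tibble::tibble(time_h = 10, value = 5))
  expect_true(is.na(none$onset_h))

  susp <- tibble::tibble(patient_id = "p1", suspicion_h = 38,
                         first_abx_h = 38, culture_h = 40,
                         ordering = "abx_first")
  sofa <- tibble::tibble(time_h = 40, value = 3)
  on <- assign_onset(susp, sofa)
  expect_equal(on$onset_h, 40)
  expect_equal(on$onset_window, 40L)

  # two qualifying suspicion windows with disjoint dysfunction windows:
  # latest dysfunction wins by default, earliest under the alternative
  susp2 <- tibble::tibble(patient_id = "p1", suspicion_h = c(10, 100),
                          first_abx_h = c(10, 100), culture_h = c(12, 102),
                          ordering = "abx_first")
  # the first score (value 3) is also the second window's baseline, so the
  # later score must rise at least 2 above it
  sofa2 <- tibble::tibble(time_h = c(12, 110), value = c(3, 6))
  expect_equal(assign_onset(susp2, sofa2)$onset_h, 110)
  expect_equal(assign_onset(susp2, sofa2, policy = "earliest")$onset_h, 12)

  # overlapping windows share their earliest qualifying dysfunction time
  susp3 <- tibble::tibble(patient_id = "p1", suspicion_h = c(10, 60),
                          first_abx_h = c(10, 60), culture_h = c(12, 62),
                          ordering = "abx_first")
  sofa3 <- tibble::tibble(time_h = c(12, 62), value = c(3, 4))
  expect_equal(assign_onset(susp3, sofa3)$onset_h, 12)
})

test_that("cohort selection applies the age rule, endpoint, and 48 h cap", {
  adm <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    age_years = c(15.0, 15.01, 40, 40),
    discharge_h = c(30, 30, 100, 10),
    death_h = NA_real_
  )
  onsets <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    onset_h = c(NA, NA, 60, NA)
  )
  eps <- select_cohort(adm, onsets)
  expect_false("a" %in% eps$episode_id)   # age 15.0 excluded (strict)
  expect_true("b" %in% eps$episode_id)    # age 15.01 included

  c_row <- eps[eps$episode_id == "c", ]
  expect_equal(c_row$endpoint_h, 60)      # onset precedes discharge
  expect_equal(c_row$start_h, 12)         # 60 - 48
  expect_equal(c_row$n_windows, 48L)

  d_row <- eps[eps$episode_id == "d", ]
  expect_equal(d_row$start_h, 0)
  expect_equal(d_row$n_windows, 10L)

  expect_warning(
    select_cohort(tibble::tibble(patient_id = "e", age_years = 50,
                                 discharge_h = NA_real_, death_h = NA_real_),
                  tibble::tibble(patient_id = "e", onset_h = NA_real_)),
    "missing discharge")
})

test_that("the labeler recovers every planted onset on a synthetic cohort", {
  co <- simulate_cohort(synth_config(n_patients = 200, note_rate = 0,
                                     seed = 7))
  onsets <- label_sepsis3(co$events)
  merged <- dplyr::left_join(co$truth, onsets, by = "patient_id")
  expect_equal(merged$septic, merged$true_septic)
  septic <- merged[merged$true_septic, ]
  expect_gt(nrow(septic), 0)
  expect_equal(septic$onset_h, septic$true_onset_h)
})

test_that("onset labels are invariant to event-record order on disk", {
  co <- simulate_cohort(synth_config(n_patients = 40, note_rate = 0,
                                     seed = 13))
  sorted <- label_sepsis3(co$events)
  shuffled <- withr::with_seed(99, co$events[sample(nrow(co$events)), ])
  expect_equal(label_sepsis3(shuffled), sorted)
})
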