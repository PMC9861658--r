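# End-to-end experiment orchestration: generate -> label -> featurize ->
# (embed) -> train or federate -> evaluate, under a named preset covering
# the three input-feature regimes (non-text, clinical-text, multi-modal),
# the three missingness strategies, and the single-server or federated
# setting.

#' Experiment preset
#'
#' @param modality `"non_text"`, `"clinical_text"`, or `"multi_modal"`.
#' @param missingness `"cfmean"` (carry-forward + global mean),
#'   `"distinct"` (sentinel), or `"gain"`.
#' @param setting `"single_server"` or `"federated"`.
#' @param aggregation Federated aggregation rule (`"simple"`/`"opt"`);
#'   only meaningful when `setting = "federated"`.
#' @param n_clients,n_rounds Federation shape (defaults 3 clients, 5
#'   rounds).
#' @param train_cfg A [train_config()] for the predictor (local config in
#'   the federated setting).
#' @param embed_spec An [embedder_spec()] for text modalities.
#' @param gain_cfg A [gain_config()] for the GAIN strategy.
#' @param seed Root seed for splitting, training, and federation.
#' @return An `experiment_preset` list.
#' @export
experiment_preset <- function(modality = c("non_text", "clinical_text",
                                           "multi_modal"),
                              missingness = c("cfmean", "distinct", "gain"),
                              setting = c("single_server", "federated"),
                              aggregation = c("simple", "opt"),
                              n_clients = 3, n_rounds = 5,
                              train_cfg = train_config(),
                              embed_spec = embedder_spec(),
                              gain_cfg = gain_config(iterations = 2000,
                                                     batch_size = 128),
                              seed = 1) {
  structure(
    list(modality = match.arg(modality),
         missingness = match.arg(missingness),
         setting = match.arg(setting),
         aggregation = match.arg(aggregation),
         n_clients = as.integer(n_clients),
         n_rounds = as.integer(n_rounds),
         train_cfg = train_cfg, embed_spec = embed_spec,
         gain_cfg = gain_cfg, seed = as.integer(seed)),
    class = "experiment_preset"
  )
}

# featurized splits for a cohort under a preset; shared by run_experiment
# and the directional checks
featurize_cohort <- function(cohort, preset) {
  onsets <- label_sepsis3(cohort$events)
  episodes <- select_cohort(cohort$admissions, onsets)
  grids <- bin_events(cohort$events, episodes, cohort$config$channels)
  grids <- filter_missingness(grids)
  episodes <- episodes[match(grids$episode_id, episodes$episode_id), ]
  assignment <- split_episodes(grids, seed = preset$seed)
  grids <- dplyr::left_join(grids, assignment, by = "episode_id")
  grids <- grids[grids$split != "omitted", ]

  train_ids <- grids$episode_id[grids$split == "train"]
  completed <- switch(
    preset$missingness,
    cfmean = {
      gm <- global_channel_means(grids[grids$split == "train", ])
      gm[!is.finite(gm)] <- 0
      impute_carry_forward_mean(grids, gm)
    },
    distinct = impute_distinct_value(grids),
    gain = impute_gain(grids, preset$gain_cfg, train_ids = train_ids)$grids
  )

  if (preset$modality != "non_text") {
    emb <- embed_episodes(cohort$events, episodes, preset$embed_spec)
    completed <- if (preset$modality == "multi_modal") {
      assemble_multimodal(completed, emb)
    } else {
      out <- completed
      out$values <- emb$embedding[match(out$episode_id, emb$episode_id)]
      out$mask <- purrr::map(out$values, function(v) {
        m <- v; m[] <- 1; m
      })
      out
    }
  }
  std <- standardize_grids(completed[completed$split == "train", ])
  list(
    train = std$grids,
    test = standardize_grids(completed[completed$split == "test", ],
                             std$stats)$grids,
    tune = standardize_grids(completed[completed$split == "tune", ],
                             std$stats)$grids,
    episodes = episodes,
    feature_stats = std$stats
  )
}

#' Run one end-to-end experiment
#'
#' Composes the whole pipeline -- synthetic cohort generation, Sepsis-3
#' labeling, episode selection, window binning, the <90% missingness
#' filter, stratified 80/10/10 splitting, the chosen missingness strategy
#' and modality, then single-server training or a simulated federation --
#' and evaluates on the held-out test split.
#'
#' @param preset An [experiment_preset()].
#' @param cohort_config A [synth_config()] (or a ready `sepsis_cohort`).
#' @return An `experiment_result`: `report` (one metrics row, or one per
#'   federated round), `manifest` (all seeds and configurations needed to
#'   re-run the experiment), and the fitted `model` or federation result.
#' @export
run_experiment <- function(preset, cohort_config) {
  stopifnot(inherits(preset, "experiment_preset"))
  cohort <- if (inherits(cohort_config, "sepsis_cohort")) cohort_config
            else simulate_cohort(cohort_config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  splits <- stage("featurize", featurize_cohort(cohort, preset))
  if (preset$setting == "single_server") {
    cfg <- preset$train_cfg
    cfg$seed <- derive_seed(preset$seed, "train")
    model <- stage("train", train_lstm(splits$train, cfg))
    preds <- stage("evaluate", predict_cohort(model, splits$test))
    report <- dplyr::mutate(evaluate_predictions(preds), round = NA_integer_,
                            .before = 1)
    fit <- model
  } else {
    fed_cfg <- federation_config(
      n_clients = preset$n_clients, n_rounds = preset$n_rounds,
      aggregation = preset$aggregation, local_config = preset$train_cfg,
      seed = derive_seed(preset$seed, "federation")
    )
    fit <- stage("federate",
                 run_federation(splits$train, splits$test, fed_cfg))
    report <- fit$report
  }
  structure(
    list(report = report,
         manifest = list(preset = unclass(preset),
                         cohort_config = unclass(cohort$config)),
         fit = fit, splits = splits),
    class = "experiment_result"
  )
}

#' @export
tidy.experiment_result <- function(x, ...) x$report

#' @export
print.experiment_result <- function(x, ...) {
  p <- x$manifest$preset
  cat(sprintf("<experiment_result> %s / %s / %s\n",
              p$modality, p$missingness, p$setting))
  print(x$report)
  invisible(x)
}
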