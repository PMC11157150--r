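## Pipeline orchestration: configuration, the simulate / train / analyze
## stages, and model persistence. A thin command-line wrapper over these
## functions ships in inst/cli/accbehav.R.

#' Default pipeline configuration
#'
#' Every defaulted value matches the standard analysis settings: ODBA
#' window 22 samples, 5 selected features under |r| < 0.9, 5 folds, 75/25
#' split, stock boosting hyperparameters, afternoons 12:00-17:59, at
#' least 30 recordings per mean-ODBA cell, 10 extreme days within
#' October-December, alpha 0.05.
#'
#' @return Nested named list; see the configuration section of the
#'   package vignette.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(train_bursts = NULL, scenario_bursts = NULL,
                 weather = NULL, out_dir = "accbehav-out"),
    dialect = list(format = "interleaved", col_behaviour = "behaviour"),
    preprocess = list(orientation_floor = 100, odba_window = 22L,
                      split_parts = 1L),
    selection = list(k = 5L, threshold = 0.9, folds = 5L),
    classifier = c(default_hyperparams(),
                   list(train_fraction = 0.75, folds = 5L, seed = 1L)),
    thermal = list(blackglobe = blackglobe_coefficients()),
    budget = list(tz_offset_hours = 0, join_tolerance_min = 30,
                  min_n = 30L, n_extreme_days = 10L,
                  months = c(10L, 11L, 12L)),
    models = list(k_blackglobe = 10L, k_hour = 8L, alpha = 0.05),
    simulate = list(seed = 1L, n_per_class = 170L, signals = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration merged over [default_pipeline_config()];
#' keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  config <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    config <- merge_config(config, yaml::read_yaml(path))
  }
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", name, ": ", conditionMessage(e)))
  })
}

config_dialect <- function(config) {
  burst_dialect(format = config$dialect$format,
                col_behaviour = config$dialect$col_behaviour)
}

#' Persist and restore a behaviour classifier
#'
#' The booster is written in the boosting library's native JSON text
#' format with a YAML sidecar holding feature names, class vocabulary,
#' hyperparameters and seed.
#'
#' @param model A `"behaviour_model"`.
#' @param dir Directory to write `model.json` and `model_meta.yaml` into.
#' @return `dir` (for save) or the restored model (for load).
#' @export
save_behaviour_model <- function(model, dir) {
  stopifnot(inherits(model, "behaviour_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.json"))
  yaml::write_yaml(list(features = model$features, classes = model$classes,
                        hp = model$hp, seed = model$seed),
                   file.path(dir, "model_meta.yaml"))
  invisible(dir)
}

#' @rdname save_behaviour_model
#' @export
load_behaviour_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model_meta.yaml"))
  booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  structure(list(booster = booster, features = unlist(meta$features),
                 classes = unlist(meta$classes), hp = meta$hp,
                 seed = meta$seed),
            class = "behaviour_model")
}

#' Simulate stage: write the fixture/scenario files
#'
#' @param config Pipeline configuration (see [read_pipeline_config()]).
#' @param scenario Optional [scenario_config()]; defaults to the standard
#'   2-individual, 20-day hot-season scenario at the configured seed.
#' @return Named paths of the written files, invisibly.
#' @export
run_simulate <- function(config = default_pipeline_config(),
                         scenario = NULL) {
  stage("simulate", {
    if (is.null(scenario)) {
      scenario <- scenario_config(seed = config$simulate$seed)
    }
    make_fixture_suite(config$paths$out_dir, seed = config$simulate$seed,
                       n_per_class = config$simulate$n_per_class,
                       config = scenario, signals = config$simulate$signals)
  })
}

#' Train stage: features, selection, classifier and confusion report
#'
#' Reads labelled bursts, centres them, extracts the 19 features,
#' selects the most predictive mutually non-redundant features, fits the
#' boosted classifier and writes the selection table, the
#' cross-validated confusion report and the persisted model.
#'
#' @param config Pipeline configuration.
#' @return List with `model`, `selection`, `report`, `features`.
#' @export
run_train <- function(config = default_pipeline_config()) {
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  labelled <- stage("read_bursts", {
    if (is.null(config$paths$train_bursts) ||
        !file.exists(config$paths$train_bursts)) {
      abort("labelled burst file not found")
    }
    read_bursts(config$paths$train_bursts, config_dialect(config))
  })
  if (config$preprocess$split_parts > 1L) {
    labelled <- stage("split_long_bursts",
                      split_long_bursts(labelled, config$preprocess$split_parts))
  }
  feats <- stage("features", {
    feature_matrix(center_bursts(labelled),
                   window = config$preprocess$odba_window)
  })
  hp <- config$classifier[names(default_hyperparams())]
  sel <- stage("select", {
    select_features(feats, k = config$selection$k,
                    threshold = config$selection$threshold, hp = hp,
                    folds = config$selection$folds,
                    seed = config$classifier$seed)
  })
  report <- stage("cross_validate", {
    cross_validate(feats, sel$feature, hp = hp,
                   folds = config$classifier$folds,
                   seed = config$classifier$seed)
  })
  model <- stage("train", {
    train_classifier(feats, sel$feature, hp = hp,
                     seed = config$classifier$seed)
  })
  write_selection(sel, file.path(out_dir, "selection.csv"))
  write_confusion_report(report, file.path(out_dir, "confusion.csv"))
  save_behaviour_model(model, out_dir)
  inform(sprintf("train: CV accuracy %.1f%% [%.1f%%, %.1f%%] on %d bursts",
                 100 * report$accuracy, 100 * report$ci["lower"],
                 100 * report$ci["upper"], report$n))
  invisible(list(model = model, selection = sel, report = report,
                 features = feats))
}

#' Analyze stage: predict, consolidate, aggregate and model
#'
#' Predicts behaviour for unlabelled bursts, consolidates to the 5
#' analysis categories, joins the blackglobe series, and fits the
#' afternoon heat-response models (time budgets and mean ODBA) plus the
#' hot/cool-day diel models, writing tidy cells and term tables.
#'
#' @param config Pipeline configuration.
#' @param model A `"behaviour_model"`; loaded from the output directory
#'   when `NULL`.
#' @return List with `records`, `budget`, `odba_cells`, `diel`,
#'   `heat_fits`, `odba_fits`, `diel_fits`, `extremes`.
#' @export
run_analyze <- function(config = default_pipeline_config(), model = NULL) {
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(model)) {
    model <- stage("load_model", load_behaviour_model(out_dir))
  }
  bursts <- stage("read_bursts", {
    if (is.null(config$paths$scenario_bursts) ||
        !file.exists(config$paths$scenario_bursts)) {
      abort("scenario burst file not found")
    }
    read_bursts(config$paths$scenario_bursts, config_dialect(config))
  })
  weather <- stage("read_weather", {
    if (is.null(config$paths$weather) || !file.exists(config$paths$weather)) {
      abort("weather file not found")
    }
    read_weather(config$paths$weather)
  })
  centred <- stage("preprocess", center_bursts(bursts))
  feats <- stage("features", {
    feature_matrix(centred, window = config$preprocess$odba_window)
  })
  records <- stage("predict", {
    tibble::tibble(
      individual_id = feats$individual_id,
      timestamp = feats$timestamp,
      behaviour = predict_behaviour(model, feats),
      odba = feats$odba
    )
  })
  records <- stage("consolidate", consolidate_records(records))
  thermal <- stage("thermal", {
    thermal_series(weather, config$thermal$blackglobe)
  })
  records <- stage("join_weather", {
    join_weather(records, thermal,
                 tolerance_min = config$budget$join_tolerance_min)
  })
  records <- add_time_fields(records, config$budget$tz_offset_hours)

  afternoon <- afternoon_filter(records)
  cells <- stage("time_budget", time_budget(afternoon))
  ocells <- stage("mean_odba_cells", {
    mean_odba_cells(afternoon, min_n = config$budget$min_n)
  })
  write_cells(cells, file.path(out_dir, "budget_cells.csv"))
  write_cells(ocells, file.path(out_dir, "odba_cells.csv"))

  extremes <- stage("extreme_days", {
    select_extreme_days(daily_max(weather), n = config$budget$n_extreme_days,
                        months = config$budget$months)
  })
  write_extreme_days(extremes, file.path(out_dir, "extreme_days.csv"))
  diel <- stage("diel_budget", diel_budget(records, extremes))
  write_cells(diel, file.path(out_dir, "diel_cells.csv"))

  fit_battery <- function(fitter, cells, tag) {
    fits <- list()
    for (b in analysis_categories()) {
      fits[[b]] <- tryCatch(fitter(cells, b), error = function(e) {
        inform(sprintf("%s model for %s skipped: %s", tag, b,
                       conditionMessage(e)))
        NULL
      })
      if (!is.null(fits[[b]])) {
        write_smooth_fit(fits[[b]],
                         file.path(out_dir, sprintf("%s_%s.csv", tag, b)))
      }
    }
    fits
  }
  heat_fits <- stage("heat_models", {
    fit_battery(function(cc, b) {
      fit_heat_model(cc, b, response = "proportion",
                     k_blackglobe = config$models$k_blackglobe,
                     k_hour = config$models$k_hour,
                     alpha = config$models$alpha)
    }, cells, "heat")
  })
  odba_fits <- stage("odba_models", {
    fit_battery(function(cc, b) {
      fit_heat_model(cc, b, response = "mean_odba",
                     k_blackglobe = config$models$k_blackglobe,
                     k_hour = config$models$k_hour,
                     alpha = config$models$alpha)
    }, ocells, "odba")
  })
  diel_fits <- stage("diel_models", {
    fit_battery(function(cc, b) {
      fit_diel_model(cc, b, k_hour = config$models$k_hour,
                     alpha = config$models$alpha)
    }, diel, "diel")
  })
  invisible(list(records = records, budget = cells, odba_cells = ocells,
                 diel = diel, heat_fits = heat_fits, odba_fits = odba_fits,
                 diel_fits = diel_fits, extremes = extremes))
}
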