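#' Experiment run configuration
#'
#' Bundles every choice that determines a full clean -> featurize ->
#' train -> evaluate run: architecture, filtering strategy, dataset
#' balancing, optional forage restriction, stage parameters, and the
#' seeds for splitting, balancing, and training. A run's resolved config
#' plus its input data fully determine its outputs.
#'
#' @param arch `"lstm"`, `"conv1d"`, or `"conv2d"`.
#' @param filtering `"filtered"` (bandstop + uninformative-data removal)
#'   or `"original"` (no cleaning).
#' @param balancing `"imbalanced"` (use all files) or `"balanced"`
#'   (count-balance behaviors first).
#' @param forage_species,forage_height Optional forage restriction.
#' @param split_seed,balance_seed,train_seed Integer seeds per stage.
#' @param epochs Training epochs (default 30).
#' @param t_fixed Fixed spectrogram frame count (default 98).
#' @param bandstop A [bandstop_spec].
#' @param block_size,threshold Uninformative-removal parameters.
#' @param stft,mel [stft_config()] and [mel_config()] stage configs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(arch = "lstm", filtering = c("filtered", "original"),
                       balancing = c("imbalanced", "balanced"),
                       forage_species = NULL, forage_height = NULL,
                       split_seed = 1L, balance_seed = 1L, train_seed = 1L,
                       epochs = 30L, t_fixed = 98L,
                       bandstop = bandstop_spec(),
                       block_size = 1100L, threshold = 100,
                       stft = stft_config(), mel = mel_config()) {
  filtering <- match.arg(filtering)
  balancing <- match.arg(balancing)
  arch <- match_enum(arch, c("lstm", "conv1d", "conv2d"), "arch")
  structure(list(arch = arch, filtering = filtering, balancing = balancing,
                 forage_species = forage_species,
                 forage_height = forage_height,
                 split_seed = as.integer(split_seed),
                 balance_seed = as.integer(balance_seed),
                 train_seed = as.integer(train_seed),
                 epochs = as.integer(epochs), t_fixed = as.integer(t_fixed),
                 bandstop = bandstop, block_size = as.integer(block_size),
                 threshold = threshold, stft = stft, mel = mel),
            class = "run_config")
}

clean_segment <- function(segment, cfg) {
  seg <- bandstop_filter(segment, cfg$bandstop)
  remove_uninformative(seg, cfg$block_size, cfg$threshold)
}

featurize_segment <- function(segment, cfg) {
  to_fixed_input(log_mel_spectrogram(segment, cfg$stft, cfg$mel),
                 cfg$t_fixed)
}

# Load, optionally clean, and featurize every manifest row. Segments that
# clean down to silence fall back to their uncleaned audio so the row
# count is preserved; the event is counted in the log.
prepare_features <- function(data_dir, manifest, cfg) {
  n_empty <- 0L
  feats <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    seg <- read_wav(file.path(data_dir, manifest$file[i]))
    if (cfg$filtering == "filtered") {
      cleaned <- clean_segment(seg, cfg)
      if (length(cleaned$samples) == 0L) {
        n_empty <- n_empty + 1L
      } else {
        seg <- cleaned
      }
    }
    feats[[i]] <- featurize_segment(seg, cfg)
  }
  list(features = feats, labels = manifest$behavior, n_empty = n_empty)
}

#' Run one end-to-end classification experiment
#'
#' Executes the four-step workflow on a WAV directory with a manifest:
#' data cleaning (when `filtering = "filtered"`), log-Mel featurization,
#' classifier training under the run seeds, and held-out evaluation.
#' Artifacts written to `out_dir`: `report.json` (confusion matrix and
#' metrics; deterministic given the config), `history.csv`,
#' `confusion_counts.csv`, `confusion_rownorm.csv`,
#' `resolved_config.yaml`, and `timings.txt` (wall-clock figures,
#' including the normalized processing speed, kept out of the
#' deterministic report).
#'
#' @param data_dir Directory containing the WAV files and
#'   `manifest.csv` (e.g. from [generate_dataset()]).
#' @param cfg A [run_config].
#' @param out_dir Output directory for artifacts (created if needed).
#' @param manifest Optional manifest `data.frame`; defaults to
#'   `data_dir/manifest.csv`.
#' @return An `evaluation_report` list with the trained model, confusion
#'   matrix, metrics, normalized processing speed, and counts.
#' @export
run_experiment <- function(data_dir, cfg = run_config(), out_dir = NULL,
                           manifest = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "read manifest"
  report <- tryCatch({
    if (is.null(manifest)) {
      manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
    }
    stage <- "forage filter"
    manifest <- filter_by_forage(manifest, cfg$forage_species,
                                 cfg$forage_height)
    if (nrow(manifest) == 0L) stop("no files match the forage filter")
    stage <- "balancing"
    if (cfg$balancing == "balanced") {
      manifest <- balance_by_count(manifest, cfg$balance_seed)
    }
    stage <- "split"
    splits <- split_manifest(manifest, split_spec(seed = cfg$split_seed))
    stage <- "featurization"
    tr <- prepare_features(data_dir, splits$train, cfg)
    va <- prepare_features(data_dir, splits$val, cfg)
    stage <- "training"
    if (length(va$features) == 0L) va <- list(features = NULL, labels = NULL,
                                              n_empty = 0L)
    model <- jaw_classifier(tr$features, tr$labels,
                            arch = cfg$arch,
                            x_val = va$features, y_val = va$labels,
                            epochs = cfg$epochs,
                            input_shape = c(cfg$t_fixed, cfg$mel$n_mels),
                            seed = cfg$train_seed)
    stage <- "evaluation"
    t0 <- proc.time()[["elapsed"]]
    te <- prepare_features(data_dir, splits$test, cfg)
    pred <- predict(model, te$features)
    elapsed <- proc.time()[["elapsed"]] - t0
    cm <- confusion_matrix(te$labels, pred)
    speed <- processing_speed(elapsed, sum(splits$test$duration_s))
    list(model = model,
         confusion = cm,
         confusion_rownorm = normalize_confusion(cm),
         metrics = precision_recall_f1(cm),
         metrics_macro = precision_recall_f1(cm, average = "macro"),
         speed_ms_per_s = speed,
         n_train = nrow(splits$train), n_val = nrow(splits$val),
         n_test = nrow(splits$test),
         n_cleaned_empty = tr$n_empty + va$n_empty + te$n_empty,
         config = cfg)
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "evaluation_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s / %s\n", x$config$arch,
              x$config$filtering, x$config$balancing))
  cat(sprintf("train/val/test: %d/%d/%d\n", x$n_train, x$n_val, x$n_test))
  print(x$metrics)
  cat(sprintf("processing speed: %.1f ms per 1 s of audio\n",
              x$speed_ms_per_s))
  invisible(x)
}

config_to_list <- function(cfg) {
  lapply(cfg, function(v) if (is.list(v)) lapply(unclass(v), identity) else v)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  deterministic <- list(
    arch = report$config$arch,
    filtering = report$config$filtering,
    balancing = report$config$balancing,
    n_train = report$n_train, n_val = report$n_val, n_test = report$n_test,
    confusion = unclass(report$confusion),
    confusion_rownorm = report$confusion_rownorm,
    per_class = report$metrics$per_class,
    overall_weighted = as.list(report$metrics$overall),
    overall_macro = as.list(report$metrics_macro$overall)
  )
  jsonlite::write_json(deterministic, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   file.path(out_dir, "confusion_counts.csv"))
  utils::write.csv(as.data.frame(report$confusion_rownorm),
                   file.path(out_dir, "confusion_rownorm.csv"))
  yaml::write_yaml(config_to_list(report$config),
                   file.path(out_dir, "resolved_config.yaml"))
  writeLines(sprintf("processing_speed_ms_per_s: %.3f",
                     report$speed_ms_per_s),
             file.path(out_dir, "timings.txt"))
  invisible(out_dir)
}

#' Run the full model/filtering/balancing comparison grid
#'
#' Enumerates the 3 architectures x 2 filtering strategies x 2 balancing
#' methods (12 runs) with shared seeds.
#'
#' @param data_dir Dataset directory.
#' @param base A [run_config] supplying everything except the grid axes.
#' @param out_dir Optional root directory; each cell writes to
#'   `<out_dir>/<arch>_<filtering>_<balancing>/`.
#' @return A named list of 12 `evaluation_report`s.
#' @export
run_experiment_grid <- function(data_dir, base = run_config(),
                                out_dir = NULL) {
  cells <- expand.grid(arch = c("conv1d", "conv2d", "lstm"),
                       filtering = c("original", "filtered"),
                       balancing = c("imbalanced", "balanced"),
                       stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base
    cfg$arch <- cells$arch[i]
    cfg$filtering <- cells$filtering[i]
    cfg$balancing <- cells$balancing[i]
    dir_i <- if (is.null(out_dir)) NULL else {
      file.path(out_dir, paste(cells$arch[i], cells$filtering[i],
                               cells$balancing[i], sep = "_"))
    }
    run_experiment(data_dir, cfg, dir_i)
  })
  names(reports) <- paste(cells$arch, cells$filtering, cells$balancing,
                          sep = "_")
  reports
}

#' Run the forage-stratified evaluation grid
#'
#' Trains and evaluates one model per forage condition: alfalfa only,
#' tall fescue only, short only, and tall only.
#'
#' @param data_dir Dataset directory.
#' @param base A [run_config]; its forage fields are overridden per run.
#' @param out_dir Optional root directory for per-run artifacts.
#' @return A named list of four `evaluation_report`s.
#' @export
run_forage_grid <- function(data_dir, base = run_config(), out_dir = NULL) {
  conditions <- list(
    alfalfa = list(species = "alfalfa", height = NULL),
    tall_fescue = list(species = "tall_fescue", height = NULL),
    short = list(species = NULL, height = "short"),
    tall = list(species = NULL, height = "tall")
  )
  reports <- lapply(names(conditions), function(nm) {
    cfg <- base
    cfg$forage_species <- conditions[[nm]]$species
    cfg$forage_height <- conditions[[nm]]$height
    dir_i <- if (is.null(out_dir)) NULL else file.path(out_dir, nm)
    run_experiment(data_dir, cfg, dir_i)
  })
  names(reports) <- names(conditions)
  reports
}
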