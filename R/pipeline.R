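#' Full-pipeline configuration
#'
#' Collects every setting of the classification chain in one list:
#' synthetic-data generation (or record paths), the denoising filter chain,
#' the segmentation window, the ICEEMD settings, the norm-entropy exponent,
#' the voting method and the evaluation scheme. Defaults are the package's
#' standard operating point: 1/45 Hz filters, 100/200 window, J = 50 noise
#' realizations at eps0 = 0.2, six modes, method-1 voting, five-class
#' evaluation.
#'
#' @param synthetic List of arguments for [generate_imbalanced_dataset()],
#'   or `NULL` when `data_dir` is given.
#' @param data_dir Directory of `<id>.csv` / `<id>_ann.json` records with
#'   `train_ids`/`test_ids` naming the split; ignored when `synthetic` is
#'   set.
#' @param train_ids,test_ids Record ids of the two splits when reading from
#'   `data_dir`.
#' @param filter A [filter_config()].
#' @param pre_samples,post_samples Segmentation window (sum 300).
#' @param J,eps0,L ICEEMD settings; `L` must be at least 6 for the
#'   36-element feature vector.
#' @param p Norm-entropy exponent.
#' @param method Voting method id, see [make_voting_ensemble()].
#' @param min_objects Tree capacity control.
#' @param scheme Evaluation scheme.
#' @param seed Master seed for generation, decomposition noise and
#'   subsampling.
#' @param out_dir Artifact directory, or `NULL` to keep results in memory
#'   only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = list(), data_dir = NULL,
                            train_ids = NULL, test_ids = NULL,
                            filter = filter_config(),
                            pre_samples = 100, post_samples = 200,
                            J = 50, eps0 = 0.2, L = 6, p = 1.1,
                            method = "method1", min_objects = 1000,
                            scheme = "five_class", seed = 1,
                            out_dir = NULL) {
  if (L < 6) stop("L must be at least 6 for the 36-element feature vector")
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 train_ids = train_ids, test_ids = test_ids,
                 filter = filter, pre_samples = pre_samples,
                 post_samples = post_samples, J = J, eps0 = eps0, L = L,
                 p = p, method = method, min_objects = min_objects,
                 scheme = scheme, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `filter` and
#' `synthetic` may be nested mappings.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$synthetic$mix)) y$synthetic$mix <- unlist(y$synthetic$mix)
  do.call(pipeline_config, y)
}

# Stable short hash of an R object (djb2 over its deparsed form), used to
# content-address cached stage outputs.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[ecgvote %s] %s", stage, sprintf(...)))
}

load_records <- function(dir, ids, fs = 360) {
  lapply(ids, function(id)
    read_ecg_csv(file.path(dir, paste0(id, ".csv")),
                 file.path(dir, paste0(id, "_ann.json")), record_id = id,
                 fs = fs))
}

features_for_records <- function(records, cfg, seed_offset) {
  segs <- unlist(lapply(records, function(rec) {
    segment_beats(denoise(rec, cfg$filter),
                  pre_samples = cfg$pre_samples,
                  post_samples = cfg$post_samples)
  }), recursive = FALSE)
  beat_feature_table(segs, J = cfg$J, eps0 = cfg$eps0, L = cfg$L, p = cfg$p,
                     seed = cfg$seed + seed_offset)
}

#' Run the full classification pipeline
#'
#' Executes generation/loading, denoising, segmentation, ICEEMD feature
#' extraction, ensemble training, prediction and evaluation from one
#' configuration. Feature tables are content-addressed by a hash of the
#' settings that determine them, so rerunning with only a different voting
#' method reuses the cached features (when `out_dir` is set).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return List with `metrics` (a `class_metrics`), `confusion`,
#'   `predictions` (data.frame of actual/predicted), `ensemble`, and the
#'   feature tables `train_features` / `test_features`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- if (quiet) function(...) invisible() else pipeline_log

  feat_cfg <- config[c("synthetic", "data_dir", "train_ids", "test_ids",
                       "filter", "pre_samples", "post_samples",
                       "J", "eps0", "L", "p", "seed")]
  hash <- config_hash(feat_cfg)
  cache <- if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    file.path(config$out_dir, sprintf("features_%s_%%s.csv", hash))
  }

  cached <- !is.null(cache) && file.exists(sprintf(cache, "train")) &&
    file.exists(sprintf(cache, "test"))
  if (cached) {
    log("features", "reusing cached feature tables (%s)", hash)
    train_feat <- utils::read.csv(sprintf(cache, "train"))
    test_feat <- utils::read.csv(sprintf(cache, "test"))
  } else {
    if (!is.null(config$data_dir)) {
      log("data", "loading records from %s", config$data_dir)
      train_recs <- load_records(config$data_dir, config$train_ids)
      test_recs <- load_records(config$data_dir, config$test_ids)
    } else {
      syn <- config$synthetic
      syn$seed <- syn$seed %||% config$seed
      log("data", "generating synthetic dataset (seed %d)", syn$seed)
      ds <- do.call(generate_imbalanced_dataset, syn)
      train_recs <- ds$train
      test_recs <- ds$test
    }
    log("features", "denoise + segment + ICEEMD (J=%d, eps0=%g, L=%d)",
        config$J, config$eps0, config$L)
    train_feat <- features_for_records(train_recs, config, seed_offset = 0L)
    test_feat <- features_for_records(test_recs, config,
                                      seed_offset = 500000L)
    if (!is.null(cache)) {
      utils::write.csv(train_feat, sprintf(cache, "train"), row.names = FALSE)
      utils::write.csv(test_feat, sprintf(cache, "test"), row.names = FALSE)
    }
  }

  fcols <- feature_names()
  if (config$scheme == "three_class") {
    train_feat <- train_feat[train_feat$label %in% aami_classes("three_class"), ]
    test_feat <- test_feat[test_feat$label %in% aami_classes("three_class"), ]
  }
  log("train", "fitting %s ensemble on %d beats", config$method,
      nrow(train_feat))
  ens <- train_voting_ensemble(train_feat[, fcols], train_feat$label,
                               method = config$method,
                               min_objects = config$min_objects,
                               seed = config$seed)
  log("predict", "classifying %d test beats", nrow(test_feat))
  pred <- predict_voting_ensemble(ens, test_feat[, fcols])

  cm <- confusion_from_predictions(test_feat$label, pred,
                                   scheme = config$scheme)
  metrics <- compute_metrics(cm)
  log("evaluate", "overall accuracy %.2f%%", attr(metrics, "OA"))

  if (!is.null(config$out_dir)) {
    write_confusion_csv(cm, file.path(config$out_dir, "confusion.csv"))
    metrics_report(metrics, file.path(config$out_dir, "report.json"))
    utils::write.csv(
      data.frame(record_id = test_feat$record_id,
                 r_index = test_feat$r_index,
                 actual = test_feat$label, predicted = pred),
      file.path(config$out_dir, "predictions.csv"), row.names = FALSE)
  }

  list(metrics = metrics, confusion = cm,
       predictions = data.frame(actual = test_feat$label, predicted = pred,
                                stringsAsFactors = FALSE),
       ensemble = ens, train_features = train_feat, test_features = test_feat)
}
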