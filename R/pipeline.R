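#' Pipeline configuration
#'
#' Bundles the per-stage configurations for the end-to-end run:
#' simulate -> segment -> artifact removal -> time-frequency images ->
#' split -> train -> evaluate (network and both LDA baselines). Stage
#' parameters are validated at construction time by building the underlying
#' stage configurations.
#'
#' @param n_windows_per_class Windows (recordings) per motion class.
#' @param seed Global seed; all stage seeds derive from it.
#' @param simulation Named list of [simulation_config()] overrides.
#' @param window_s,overlap_fraction Segmentation parameters.
#' @param artifact Named list: `n_harmonics`, `imf_line_ratio_threshold`,
#'   `notch_q`.
#' @param method Time-frequency method (`"HHT"`, `"STFT"` or `"CWT"`).
#' @param image_size Rendered image side length(s), divisible by 16.
#' @param image_scaling `"log"` (default) or `"linear"` contrast for
#'   [render_image()].
#' @param image_normalization `"per_example"` (default; the four channel
#'   images of one window share a normalization range, see
#'   [example_tf_images()]) or `"per_image"`.
#' @param model A [model_config()]; sized to `image_size`.
#' @param training A [train_config()].
#' @param baseline Named list: `wl_form` (for the TDF features) and `r_grid`
#'   (threshold-multiplier sweep; a coarse default keeps the run fast).
#' @param out_dir Output directory, or `NULL` for in-memory only.
#' @return Object of class `fessemg_pipeconfig`.
#' @export
pipeline_config <- function(n_windows_per_class = 60,
                            seed = 1L,
                            simulation = list(),
                            window_s = 0.5, overlap_fraction = 0.5,
                            artifact = list(n_harmonics = 5,
                                            imf_line_ratio_threshold = 0.3,
                                            notch_q = 30),
                            method = c("HHT", "STFT", "CWT"),
                            image_size = c(64, 64),
                            image_scaling = c("log", "linear"),
                            image_normalization = c("per_example", "per_image"),
                            model = NULL,
                            training = NULL,
                            baseline = list(wl_form = "conventional",
                                            r_grid = seq(0, 6, by = 0.5)),
                            out_dir = NULL) {
  method <- match.arg(method)
  image_scaling <- match.arg(image_scaling)
  image_normalization <- match.arg(image_normalization)
  simulation$seed <- simulation$seed %||% derive_seed(seed, 101)
  sim_cfg <- do.call(simulation_config, simulation)
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (is.null(model)) {
    prof <- desk_profile(seed = derive_seed(seed, 202))
    model <- prof$model
    model$input_shape <- as.integer(c(image_size, 3))
  }
  if (is.null(training))
    training <- train_config(epochs = 20, batch_size = 30,
                             seed = derive_seed(seed, 303))
  if (!all(model$input_shape[1:2] == image_size))
    stop_input("model input_shape must match image_size")
  structure(list(n_windows_per_class = as.integer(n_windows_per_class),
                 seed = as.integer(seed),
                 simulation = sim_cfg,
                 window_s = window_s,
                 overlap_fraction = overlap_fraction,
                 artifact = artifact,
                 method = method,
                 image_size = as.integer(image_size),
                 image_scaling = image_scaling,
                 image_normalization = image_normalization,
                 model = model,
                 training = training,
                 baseline = baseline,
                 out_dir = out_dir),
            class = "fessemg_pipeconfig")
}

#' Load a pipeline configuration from JSON
#'
#' Reads a nested JSON document whose top-level keys mirror
#' [pipeline_config()] arguments (`simulation`, `model`, `training` given as
#' named lists of overrides).
#'
#' @param path JSON file.
#' @return A `fessemg_pipeconfig`.
#' @export
load_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (k in c("n_windows_per_class", "seed", "window_s", "overlap_fraction",
              "method", "image_size", "out_dir"))
    if (!is.null(j[[k]])) args[[k]] <- j[[k]]
  if (!is.null(j$simulation)) args$simulation <- as.list(j$simulation)
  if (!is.null(j$artifact)) args$artifact <- as.list(j$artifact)
  if (!is.null(j$baseline)) args$baseline <- as.list(j$baseline)
  if (!is.null(j$model)) args$model <- do.call(model_config, as.list(j$model))
  if (!is.null(j$training)) args$training <- do.call(train_config, as.list(j$training))
  do.call(pipeline_config, args)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> segment -> artifact removal -> imaging -> split ->
#' network training -> evaluation, plus the two hand-crafted-feature LDA
#' baselines (time-domain features for motion, amplitude/spectral features
#' for fatigue) on the same split. Fully deterministic given the
#' configuration seed. When `config$out_dir` is set, per-stage outputs, a
#' run manifest and the final metric reports are written there; with
#' `resume = TRUE` stages with existing cached outputs are reused.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse cached stage outputs found in `out_dir`.
#' @param verbose Print per-stage progress.
#' @return List with `metrics` (network motion/fatigue and baseline
#'   motion/fatigue `fessemg_metrics`), `confusions`, `history`, `model`,
#'   `split` indices, `examples` count and the `config`.
#' @export
run_pipeline <- function(config, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "fessemg_pipeconfig"))
  say <- function(...) if (verbose) message("[fessemg] ", ...)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cache <- function(name, expr) {
    if (is.null(out_dir)) return(expr)
    f <- file.path(out_dir, paste0("stage_", name, ".rds"))
    if (resume && file.exists(f)) {
      say("stage ", name, ": reusing cached output")
      return(readRDS(f))
    }
    val <- expr
    saveRDS(val, f)
    val
  }

  say("stage simulate: ", config$n_windows_per_class, " windows/class")
  recs <- cache("simulate",
                generate_dataset(config$simulation, config$n_windows_per_class,
                                 duration_s = max(config$window_s, 0.5)))
  manifest <- attr(recs, "manifest")

  say("stage preprocess: segmentation + artifact removal (",
      length(recs), " recordings x ", config$simulation$n_channels, " channels)")
  art <- config$artifact
  examples_windows <- cache("preprocess", lapply(recs, function(r) {
    wins <- segment(r, window_s = config$window_s,
                    overlap_fraction = config$overlap_fraction)
    # one window per channel per recording at the default duration
    per_ch <- split(wins, vapply(wins, function(w) w$channel_id, integer(1)))
    lapply(per_ch, function(ws)
      remove_fes_artifacts(ws[[1]],
                           stim_freq_hz = config$simulation$stim_freq_hz,
                           n_harmonics = art$n_harmonics %||% 5,
                           imf_line_ratio_threshold = art$imf_line_ratio_threshold %||% 0.3,
                           notch_q = art$notch_q %||% 30))
  }))

  say("stage images: ", config$method, " ", config$image_size[1], "x",
      config$image_size[2])
  examples <- cache("images", lapply(examples_windows, function(ws) {
    imgs <- example_tf_images(ws, method = config$method,
                              out_size = config$image_size,
                              scaling = config$image_scaling %||% "log",
                              normalization = config$image_normalization %||% "per_example")
    labeled_example(imgs, ws[[1]]$motion_label, ws[[1]]$fatigue_label)
  }))

  say("stage split: ", paste(config$training$split, collapse = "/"))
  sp <- split_dataset(examples, fractions = config$training$split,
                      seed = config$training$seed)

  say("stage train: ", config$training$epochs, " epochs, ",
      n_parameters(build_model(config$model)), " parameters")
  model <- cache("model", {
    m <- build_model(config$model)
    m <- train_model(m, sp$train, sp$val, config$training)
    list(config = m$config, params = .net_get_params(m$ptr),
         state = .net_get_state(m$ptr), history = m$history)
  })
  # rebuild from the cached/serializable form
  net <- build_model(model$config)
  .net_set_params(net$ptr, model$params)
  .net_set_state(net$ptr, model$state)
  net$history <- model$history

  say("stage evaluate: network")
  test_motion <- vapply(sp$test, function(e) e$motion_label, character(1))
  test_fatigue <- vapply(sp$test, function(e) e$fatigue_label, character(1))
  pred <- predict(net, sp$test)
  cm_motion <- confusion_from_predictions(test_motion, pred$motion,
                                          labels = MOTION_LABELS)
  cm_fatigue <- confusion_from_predictions(test_fatigue, pred$fatigue,
                                           labels = FATIGUE_LABELS)
  metrics <- list(net_motion = metrics_from_counts(cm_motion),
                  net_fatigue = metrics_from_counts(cm_fatigue))

  say("stage evaluate: LDA baselines")
  win_sets <- lapply(sp$indices, function(ix) examples_windows[ix])
  lab <- function(ix, f) vapply(examples_windows[ix],
                                function(ws) ws[[1]][[f]], character(1))
  # TDF + LDA motion baseline; threshold epsilon = R * rest RMS, R swept on
  # the validation set (rest = sitting windows in the training set)
  rest_ix <- sp$indices$train[lab(sp$indices$train, "motion_label") == "sitting"]
  rest_rms <- if (length(rest_ix)) {
    sqrt(mean(unlist(lapply(examples_windows[rest_ix[1]],
                            function(ws) lapply(ws, `[[`, "samples")))^2))
  } else 0
  wl_form <- config$baseline$wl_form %||% "conventional"
  eps_sel <- select_zc_epsilon(win_sets$train, lab(sp$indices$train, "motion_label"),
                               win_sets$val, lab(sp$indices$val, "motion_label"),
                               rest_rms, r_grid = config$baseline$r_grid %||% seq(0, 6, 0.5),
                               wl_form = wl_form)
  ftr <- example_feature_matrix(win_sets$train, "tdf", epsilon = eps_sel$epsilon,
                                wl_form = wl_form)
  fte <- example_feature_matrix(win_sets$test, "tdf", epsilon = eps_sel$epsilon,
                                wl_form = wl_form)
  lda_m <- lda_fit(ftr, lab(sp$indices$train, "motion_label"))
  pred_m <- lda_predict(lda_m, fte)
  cm_lda_m <- confusion_from_predictions(test_motion, pred_m, labels = MOTION_LABELS)
  metrics$lda_motion <- metrics_from_counts(cm_lda_m)

  gtr <- example_feature_matrix(win_sets$train, "tff")
  gte <- example_feature_matrix(win_sets$test, "tff")
  lda_f <- lda_fit(gtr, lab(sp$indices$train, "fatigue_label"))
  pred_f <- lda_predict(lda_f, gte)
  cm_lda_f <- confusion_from_predictions(test_fatigue, pred_f, labels = FATIGUE_LABELS)
  metrics$lda_fatigue <- metrics_from_counts(cm_lda_f)

  confusions <- list(net_motion = cm_motion, net_fatigue = cm_fatigue,
                     lda_motion = cm_lda_m, lda_fatigue = cm_lda_f)

  if (!is.null(out_dir)) {
    write_manifest_csv(manifest, file.path(out_dir, "manifest.csv"))
    utils::write.csv(net$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    for (nm in names(metrics))
      write_metrics(metrics[[nm]], file.path(out_dir, paste0("metrics_", nm)))
    for (nm in names(confusions))
      write_confusion_csv(confusions[[nm]],
                          file.path(out_dir, paste0("confusion_", nm, ".csv")))
    run_meta <- list(seed = config$seed,
                     n_windows_per_class = config$n_windows_per_class,
                     method = config$method,
                     image_size = config$image_size,
                     epsilon_R = eps_sel$R,
                     package_version = as.character(utils::packageVersion("fessemg")),
                     r_version = R.version.string,
                     elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(run_meta, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = 6)
  }
  say(sprintf("done in %.1f s | net motion acc %.1f%%, net fatigue acc %.1f%%",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              overall_accuracy(metrics$net_motion),
              overall_accuracy(metrics$net_fatigue)))
  list(metrics = metrics, confusions = confusions, history = net$history,
       model = net, split = sp$indices, n_examples = length(examples),
       epsilon = eps_sel, config = config)
}
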