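#' Run the full analysis pipeline
#'
#' Executes the stages simulate (or load) -> [optional MBLL round trip]
#' -> denoise -> segment -> features -> cross-validated classification ->
#' interpretation, writing every artifact under `out_dir` plus a JSON
#' manifest with per-file MD5 hashes, the seed and the package version.
#' Rerunning with the same config and seed reproduces identical hashes.
#'
#' @param config Nested list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{Global seed; propagated to every stochastic stage.}
#'     \item{input}{Optional `list(record=, events=)` CSV paths to analyse
#'       instead of simulating; both must exist at invocation.}
#'     \item{simulate}{Optional overrides for [simulation_config()].}
#'     \item{mbll_roundtrip}{If TRUE, push the record through
#'       [forward_mbll()] and [od_to_concentration()] before denoising.}
#'     \item{denoise}{Optional overrides for [wavelet_config()].}
#'     \item{evaluate}{`list(models=, k=, epochs=, batch_size=,
#'       learning_rate=, svm_c=, svm_components=)`; models from `"svm"`,
#'       `"ann:<id>"`, `"cnn:<id>"`.}
#'     \item{interpret}{If TRUE, write PCA scatters and, when a CNN was
#'       trained, the filter channel attribution summary.}
#'   }
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$input)) {
    for (p in unlist(config$input)) {
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- "setup"
  note <- function(path) artifacts <<- c(artifacts, path)
  run_stage <- function(name, fun) {
    stage <<- name
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- acquire ---------------------------------------------------------
  sim <- NULL
  if (is.null(config$input)) {
    sim <- run_stage("simulate", function() {
      args <- config$simulate %||% list()
      args$seed <- seed
      do.call(simulation_config, args)
    })
    sess <- run_stage("simulate", function() simulate_session(sim))
    record <- sess$record
    onsets <- sess$onsets_s
    labels <- sess$labels
    run_stage("simulate", function() {
      write_record(record, file.path(out_dir, "record.csv"))
      write_events(onsets, labels, file.path(out_dir, "events.csv"))
    })
    note(file.path(out_dir, "record.csv"))
    note(file.path(out_dir, "record.csv.json"))
    note(file.path(out_dir, "events.csv"))
  } else {
    record <- run_stage("load", function()
      read_record(config$input$record, "hemodynamic"))
    ev <- run_stage("load", function() read_events(config$input$events))
    onsets <- ev$onsets_s
    labels <- ev$labels
  }

  # -- optional MBLL round trip ---------------------------------------
  if (isTRUE(config$mbll_roundtrip)) {
    record <- run_stage("mbll", function() {
      coeffs <- mbll_coefficients()
      od_to_concentration(forward_mbll(record, coeffs), coeffs)
    })
  }

  # -- denoise + segment + features -----------------------------------
  wcfg <- do.call(wavelet_config, config$denoise %||% list())
  denoised <- run_stage("denoise", function()
    denoise_record(record, wcfg))
  run_stage("denoise", function()
    write_record(denoised, file.path(out_dir, "denoised.csv")))
  note(file.path(out_dir, "denoised.csv"))
  note(file.path(out_dir, "denoised.csv.json"))
  trials <- run_stage("segment", function()
    segment_trials(denoised, onsets, labels))
  feats <- run_stage("features", function() extract_feature_table(trials))
  run_stage("features", function()
    utils::write.csv(cbind(as.data.frame(feats),
                           label = as.character(trials$labels)),
                     file.path(out_dir, "features.csv"),
                     row.names = FALSE))
  note(file.path(out_dir, "features.csv"))

  # -- evaluate --------------------------------------------------------
  ev_cfg <- config$evaluate %||% list()
  model_ids <- ev_cfg$models %||% c("svm", "cnn:CNN1-a")
  k <- ev_cfg$k %||% 10L
  tcfg <- train_config(epochs = ev_cfg$epochs %||% 30L,
                       batch_size = ev_cfg$batch_size %||% 32L,
                       learning_rate = ev_cfg$learning_rate %||% 1e-3,
                       seed = seed)
  sspec <- svm_spec(c_regularization = ev_cfg$svm_c %||% 1,
                    n_components = ev_cfg$svm_components %||% 20L)
  reports <- list()
  cnn_fit <- NULL
  for (mid in model_ids) {
    parts <- strsplit(mid, ":", fixed = TRUE)[[1]]
    fam <- parts[1]
    rep_m <- run_stage(paste0("evaluate:", mid), function() {
      switch(fam,
             svm = cross_validate(svm_pipeline(sspec), feats,
                                  trials$labels, k = k, seed = seed),
             ann = cross_validate(
               ann_pipeline(ann_structures()[[parts[2]]], tcfg),
               feats, trials$labels, k = k, seed = seed),
             cnn = cross_validate(
               cnn_pipeline(cnn_structures()[[parts[2]]], tcfg),
               trials, trials$labels, k = k, seed = seed),
             stop("unknown model id ", mid))
    })
    reports[[mid]] <- rep_m
    if (fam == "cnn" && is.null(cnn_fit)) {
      cnn_fit <- run_stage(paste0("train:", mid), function()
        train_cnn(trials, spec = cnn_structures()[[parts[2]]],
                  config = tcfg))
    }
  }
  run_stage("evaluate", function()
    jsonlite::write_json(lapply(reports, function(r)
      r[c("fold_accuracies", "mean_accuracy", "k", "seed", "spec_id")]),
      file.path(out_dir, "cv_reports.json"), auto_unbox = TRUE,
      digits = NA))
  note(file.path(out_dir, "cv_reports.json"))

  # -- interpret -------------------------------------------------------
  if (isTRUE(config$interpret %||% TRUE)) {
    run_stage("interpret", function() {
      utils::write.csv(pca_scatter(feats, trials$labels),
                       file.path(out_dir, "scatter_features.csv"),
                       row.names = FALSE)
      utils::write.csv(pca_scatter(trials, trials$labels),
                       file.path(out_dir, "scatter_raw.csv"),
                       row.names = FALSE)
      if (!is.null(cnn_fit)) {
        utils::write.csv(pca_scatter(cnn_feature_maps(cnn_fit, trials),
                                     trials$labels),
                         file.path(out_dir, "scatter_featuremap.csv"),
                         row.names = FALSE)
        attr_res <- filter_channel_attribution(cnn_fit, trials)
        summ <- data.frame(
          filter_id = vapply(attr_res, `[[`, numeric(1), "filter_id"),
          selected_channel = vapply(attr_res, `[[`, numeric(1),
                                    "selected_channel"),
          contrast = vapply(attr_res, `[[`, numeric(1), "contrast"))
        utils::write.csv(summ, file.path(out_dir, "attribution.csv"),
                         row.names = FALSE)
      }
    })
    note(file.path(out_dir, "scatter_features.csv"))
    note(file.path(out_dir, "scatter_raw.csv"))
    if (!is.null(cnn_fit)) {
      note(file.path(out_dir, "scatter_featuremap.csv"))
      note(file.path(out_dir, "attribution.csv"))
    }
  }

  manifest <- list(
    package = "nirsbci",
    version = tryCatch(as.character(utils::packageVersion("nirsbci")),
                       error = function(e) "dev"),
    seed = seed,
    config = config,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p)))),
    mean_accuracies = lapply(reports, `[[`, "mean_accuracy"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
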