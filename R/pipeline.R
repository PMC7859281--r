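pipeline_defaults <- function() {
  list(
    seed = 1L,
    # cohort
    n_healthy = 30L, n_impaired = 30L, states_k = 3L, components = 53L,
    scan_length_tp = 159L, obs_noise_sd = 0.2, stickiness = 0.85,
    score_slope = 12, score_noise_sd = 1.5, linked_state = 1L,
    # post-processing
    detrend_order = 3L, do_despike = TRUE, cutoff_hz = 0.15,
    # dFNC
    window_trs = 20L, gaussian_sigma = 3, step = 1L,
    # clustering (states_k = NA selects k by the elbow criterion)
    k_range = 2:6, n_replicates = 20L, max_iter = 1000L,
    # association
    alpha = 0.05,
    # classification (off by default)
    classify = FALSE, n_repeats = 10L, folds = 5L, beta = 1,
    # IO
    in_dir = NULL, out_dir = NULL)
}

#' Build a validated pipeline configuration
#'
#' Returns the full configuration for [run_pipeline], starting from
#' defaults and overridden by the named arguments.  Unknown keys are
#' rejected.
#'
#' @param ... named overrides of the default configuration (see Details).
#' @details Keys: `seed`; cohort (`n_healthy`, `n_impaired`, `states_k`,
#'   `components`, `scan_length_tp`, `obs_noise_sd`, `stickiness`,
#'   `score_slope`, `score_noise_sd`, `linked_state`); post-processing
#'   (`detrend_order`, `do_despike`, `cutoff_hz`); dFNC (`window_trs`,
#'   `gaussian_sigma`, `step`); clustering (`k_range`, `n_replicates`,
#'   `max_iter`); association (`alpha`); classification (`classify`,
#'   `n_repeats`, `folds`, `beta`); IO (`in_dir`, `out_dir`).  Setting
#'   `states_k = NA` selects `k` with [elbow_select_k] over `k_range`.
#' @return Named list of class `dfnc_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  override <- list(...)
  if (length(override) && is.null(names(override)))
    stop("pipeline_config: arguments must be named")
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, override, keep.null = TRUE)
  structure(cfg, class = "dfnc_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `dfnc_config` from [pipeline_config].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the validated `dfnc_config` (unknown keys in the file are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dfnc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_log <- function(manifest, stage, t0, ...) {
  manifest$stages[[stage]] <- c(
    list(elapsed_s = round(as.numeric(Sys.time()) - t0, 3)), list(...))
  manifest
}

write_stage_csv <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  path <- file.path(out_dir, name)
  utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic dFNC analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading time courses from
#' `in_dir`), post-processing, tapered sliding-window dFNC, state
#' clustering (fixed `k` or elbow selection), temporal feature extraction,
#' covariate-adjusted association with the clinical score, and (optionally)
#' conversion classification on the healthy/impaired labels.  All
#' randomness derives from `config$seed`; re-running with an identical
#' configuration reproduces identical outputs and file checksums.
#'
#' @param config a `dfnc_config` from [pipeline_config].
#' @return Object of class `dfnc_run`: the cohort, state model, feature
#'   and association tables, optional classification report, and a
#'   `manifest` (configuration snapshot, per-stage timings and row counts,
#'   warnings, and MD5 checksums of any files written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "dfnc_config"))
  if (!is.null(config$in_dir) && !dir.exists(config$in_dir))
    stop("run_pipeline: input directory does not exist: ", config$in_dir)
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(config = unclass(config), stages = list(),
                   warnings = character(0),
                   started = format(Sys.time(), usetz = TRUE))
  run_warn <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)

  # -- simulate / load -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort <- NULL
  if (is.null(config$in_dir)) {
    cohort <- generate_cohort(
      n_healthy = config$n_healthy, n_impaired = config$n_impaired,
      K = if (is.na(config$states_k)) 3L else config$states_k,
      C = config$components,
      stickiness = config$stickiness,
      score_model = list(state = config$linked_state,
                         slope = config$score_slope,
                         noise_sd = config$score_noise_sd),
      scan_length_tp = config$scan_length_tp,
      obs_noise_sd = config$obs_noise_sd)
    tcs <- cohort$timecourses
    clinical <- cohort$metadata
    if (!is.null(config$out_dir)) write_cohort(cohort, config$out_dir)
  } else {
    files <- sort(list.files(file.path(config$in_dir, "timecourses"),
                             full.names = TRUE))
    if (!length(files))
      stop("run_pipeline: no time-course files under ", config$in_dir)
    tcs <- lapply(files, load_timecourses)
    names(tcs) <- vapply(tcs, `[[`, "", "scan_id")
    clinical <- utils::read.csv(file.path(config$in_dir, "metadata.csv"),
                                stringsAsFactors = FALSE)
  }
  manifest <- stage_log(manifest, "input", t0, n_scans = length(tcs))

  # -- post-processing -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tcs <- lapply(tcs, postprocess, detrend_order = config$detrend_order,
                do_despike = config$do_despike, cutoff_hz = config$cutoff_hz)
  manifest <- stage_log(manifest, "postproc", t0, n_scans = length(tcs))

  # -- dFNC ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  taper <- build_taper(config$window_trs, config$gaussian_sigma)
  tensors <- lapply(tcs, sliding_window_fnc, taper = taper,
                    step = config$step)
  windows <- do.call(rbind, lapply(tensors, `[[`, "values"))
  wc <- vapply(tensors, function(t) nrow(t$values), integer(1))
  scan_of_window <- rep(names(tensors), wc)
  window_in_scan <- unlist(lapply(wc, seq_len), use.names = FALSE)
  sfnc <- lapply(tcs, static_fnc)
  manifest <- stage_log(manifest, "dfnc", t0, n_windows = nrow(windows),
                        windows_per_scan = unname(wc[1L]))

  # -- states ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  elbow <- NULL
  k <- config$states_k
  if (is.na(k)) {
    elbow <- elbow_select_k(windows, k_range = config$k_range,
                            n_replicates = config$n_replicates,
                            max_iter = config$max_iter)
    k <- elbow$k
    if (elbow$low_confidence)
      run_warn("elbow selection is low-confidence (no sharp elbow)")
  }
  model <- cluster_windows(windows, k, n_replicates = config$n_replicates,
                           max_iter = config$max_iter)
  svs <- assign_state_vectors(model$labels, scan_of_window, window_in_scan)
  state_fnc <- lapply(names(tensors), function(sc)
    subject_state_fnc(tensors[[sc]], svs[[sc]], k))
  names(state_fnc) <- names(tensors)
  n_missing <- sum(vapply(state_fnc, function(m) any(is.na(m[, 1L])),
                          logical(1)))
  if (n_missing)
    run_warn(sprintf("%d scan(s) never visit at least one state", n_missing))
  manifest <- stage_log(manifest, "states", t0, k = k,
                        state_sizes = model$sizes)

  # -- temporal features ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  feats <- feature_table(svs, k)
  if (!is.null(config$out_dir))
    write_stage_csv(feats, config$out_dir, "temporal_features.csv")
  manifest <- stage_log(manifest, "features", t0, n_rows = nrow(feats),
                        n_features = ncol(feats) - 1L)

  # -- association -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  hmm_cols <- grep("^a[0-9]+$", names(feats), value = TRUE)
  ocr_cols <- grep("^ocr[0-9]+$", names(feats), value = TRUE)
  families <- list(hmm = hmm_cols, ocr = ocr_cols)
  assoc_feats <- feats
  P <- ncol(windows)
  fnc_names <- sprintf("fnc%04d", seq_len(P))
  for (s in seq_len(k)) {
    m <- t(vapply(state_fnc, function(sf) sf[s, ], numeric(P)))
    cols <- paste0("state", s, "_", fnc_names)
    colnames(m) <- cols
    assoc_feats <- cbind(assoc_feats,
                         as.data.frame(m, optional = TRUE))
    families[[paste0("state_fnc_", s)]] <- cols
  }
  assoc <- run_association(assoc_feats, clinical, families = families,
                           alpha = config$alpha)
  if (!is.null(config$out_dir))
    write_stage_csv(as.data.frame(assoc), config$out_dir,
                    "association_table.csv")
  manifest <- stage_log(manifest, "associate", t0, n_tests = nrow(assoc),
                        n_significant = sum(assoc$significant, na.rm = TRUE))

  # -- classification (optional) --------------------------------------
  report <- NULL
  if (isTRUE(config$classify)) {
    t0 <- as.numeric(Sys.time())
    sfnc_mat <- t(vapply(sfnc, vectorize_fnc, numeric(P)))
    feat_mat <- cbind(sfnc_mat,
                      as.matrix(feats[, c(hmm_cols, ocr_cols)]))
    lab <- factor(clinical$group[match(names(sfnc), clinical$scan_id)])
    report <- evaluate_conversion(feat_mat, lab,
                                  n_repeats = config$n_repeats,
                                  folds = config$folds, beta = config$beta)
    manifest <- stage_log(manifest, "classify", t0,
                          mean_auc = report$mean$auc)
  }

  # -- manifest --------------------------------------------------------
  if (!is.null(config$out_dir)) {
    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(names(manifest$checksums))
  }
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(cohort = cohort, clinical = clinical, taper = taper,
                 tensors = tensors, state_model = model, elbow = elbow,
                 state_vectors = svs, state_fnc = state_fnc,
                 features = feats, association = assoc,
                 classification = report, manifest = manifest),
            class = "dfnc_run")
}

#' @export
print.dfnc_run <- function(x, ...) {
  cat("dFNC pipeline run\n")
  cat(sprintf("  scans: %d; windows/scan: %d; k = %d states\n",
              length(x$tensors),
              x$manifest$stages$dfnc$windows_per_scan,
              x$state_model$k))
  cat(sprintf("  association tests: %d (%d significant)\n",
              x$manifest$stages$associate$n_tests,
              x$manifest$stages$associate$n_significant))
  if (!is.null(x$classification))
    cat(sprintf("  classification mean AUC: %.3f\n",
                x$classification$mean$auc))
  if (length(x$manifest$warnings))
    cat("  warnings:\n", paste("   -", x$manifest$warnings,
                               collapse = "\n"), "\n")
  invisible(x)
}
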