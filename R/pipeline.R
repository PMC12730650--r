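# End-to-end orchestration: synthetic group EEG -> group average -> direct
# sonification -> membrane/mirror/laser simulation -> frame rendering ->
# binarization/cleaning/masking -> descriptors -> random-forest protocol,
# with one global seed, a complete run manifest, and reproducible outputs.

#' Pipeline configuration
#'
#' Nested parameter blocks, one per stage, every default reproducing the
#' reference protocol's stated settings (31 px / C = 2 adaptive threshold,
#' 3x3 elliptical opening, 10 fps, 275 s analysis window with 12 s / 0 s
#' group start offsets, noise injection sigma = 5, 100-tree random forest
#' seeded at 42). Override any block entry via `...` using nested lists,
#' e.g. `pipeline_config(eeg = list(duration = 120))`.
#'
#' @param ... Named blocks (`seed`, `out_dir`, `eeg`, `profiles`, `sonify`,
#'   `membrane`, `optics`, `render`, `frameproc`, `classify`) whose entries
#'   override the defaults.
#' @return An object of class `pipeline_config` (nested named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 42L,
    out_dir = NULL,
    eeg = list(n_subjects = 3L, n_channels = 19L, duration = 300, fs = 500,
               target_sd = 20),
    profiles = list(ad = "ad", nc = "nc"),
    sonify = list(mode = "mean", headroom = 0.99, fs_audio = 44100,
                  time_scale = 2.7),
    membrane = list(a = 0.04, m = 0.002, f01 = 187, q_factor = 50),
    optics = list(incidence_angle = 30, screen_width = 0.40,
                  screen_height = 0.60, mirror_to_screen = 0.50,
                  gain = 0.15, axis_delay = NULL),
    render = list(fps = 10, width = 160L, height = 120L, psf_sigma = 2,
                  exposure = NULL, noise_sigma = 2, black_level = 12,
                  sat_dwell = 0.002),
    frameproc = list(window = 31L, C = 2, weighting = "gaussian",
                     noise_sigma = 5, trim_start_ad = 12, trim_start_nc = 0,
                     duration = 275, mask_source = "binarized"),
    classify = list(n_estimators = 100L, random_state = 42L,
                    test_fraction = 0.20, k = 5L, mode = "frame")
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(overrides)) {
    if (is.list(defaults[[blk]])) {
      ov <- overrides[[blk]]
      unknown <- setdiff(names(ov), names(defaults[[blk]]))
      if (length(unknown)) {
        stop("unknown key(s) in block `", blk, "`: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      defaults[[blk]][names(ov)] <- ov
    } else {
      defaults[[blk]] <- overrides[[blk]]
    }
  }
  cfg <- structure(defaults, class = "pipeline_config")
  assert_valid_config(cfg)
  cfg
}

assert_valid_config <- function(cfg) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single number")
  chk(cfg$eeg$n_subjects >= 1, "eeg.n_subjects: must be >= 1")
  chk(cfg$eeg$duration > 0, "eeg.duration: must be > 0")
  chk(cfg$eeg$fs > 0, "eeg.fs: must be > 0")
  chk(cfg$eeg$n_channels >= 1, "eeg.n_channels: must be >= 1")
  chk(cfg$sonify$headroom > 0 && cfg$sonify$headroom <= 1,
      "sonify.headroom: must be in (0, 1]")
  chk(cfg$sonify$fs_audio > 0, "sonify.fs_audio: must be > 0")
  chk(cfg$sonify$time_scale > 0, "sonify.time_scale: must be > 0")
  chk(cfg$membrane$a > 0, "membrane.a: must be > 0")
  chk(cfg$membrane$m > 0, "membrane.m: must be > 0")
  chk(cfg$membrane$f01 > 0, "membrane.f01: must be > 0")
  chk(cfg$membrane$q_factor > 0, "membrane.q_factor: must be > 0")
  chk(cfg$optics$incidence_angle > 0 && cfg$optics$incidence_angle < 90,
      "optics.incidence_angle: must be in (0, 90)")
  chk(cfg$render$fps > 0, "render.fps: must be > 0")
  chk(cfg$render$width >= 8 && cfg$render$height >= 8,
      "render.width/height: must be >= 8 px")
  chk(cfg$render$noise_sigma >= 0, "render.noise_sigma: must be >= 0")
  chk(cfg$render$black_level >= 0 && cfg$render$black_level < 128,
      "render.black_level: must be in [0, 128)")
  chk(cfg$frameproc$mask_source %in% c("binarized", "cleaned"),
      "frameproc.mask_source: must be \"binarized\" or \"cleaned\"")
  chk(cfg$frameproc$window %% 2 == 1 && cfg$frameproc$window >= 3,
      "frameproc.window: must be an odd integer >= 3")
  chk(cfg$frameproc$noise_sigma >= 0, "frameproc.noise_sigma: must be >= 0")
  chk(is.null(cfg$frameproc$duration) || cfg$frameproc$duration > 0,
      "frameproc.duration: must be > 0 or null")
  chk(cfg$frameproc$trim_start_ad >= 0 && cfg$frameproc$trim_start_nc >= 0,
      "frameproc.trim_start_*: must be >= 0")
  chk(cfg$classify$test_fraction > 0 && cfg$classify$test_fraction < 1,
      "classify.test_fraction: must be in (0, 1)")
  chk(cfg$classify$k >= 2, "classify.k: must be >= 2")
  chk(cfg$classify$mode %in% c("frame", "grouped"),
      "classify.mode: must be \"frame\" or \"grouped\"")
  for (p in cfg$profiles) {
    chk(inherits(p, "synth_profile") || (is.character(p) && p %in% c("ad", "nc")),
        "profiles: entries must be \"ad\", \"nc\" or synth_profile objects")
  }
  if (length(v)) {
    stop("invalid pipeline config:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load and validate a pipeline configuration from YAML
#'
#' Reads a YAML file with the same nested block structure as
#' [pipeline_config()]; unknown keys and out-of-range values are rejected
#' with the offending keys named.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

as_profile <- function(p, seed) {
  if (inherits(p, "synth_profile")) p else synth_profile(p, seed = seed)
}

run_group <- function(group, cfg, seeds) {
  profile <- as_profile(cfg$profiles[[if (group == "Alzheimer") "ad" else "nc"]],
                        seeds[1])
  recs <- lapply(seq_len(cfg$eeg$n_subjects), function(i) {
    synth_eeg(profile, n_channels = cfg$eeg$n_channels,
              duration = cfg$eeg$duration, fs = cfg$eeg$fs,
              seed = seeds[i], target_sd = cfg$eeg$target_sd,
              group_label = if (group == "Alzheimer") "AD" else "NC")
  })
  avg <- group_average(recs)
  audio <- sonify_eeg(avg, mode = cfg$sonify$mode,
                      headroom = cfg$sonify$headroom,
                      fs_audio = cfg$sonify$fs_audio,
                      time_scale = cfg$sonify$time_scale)
  spec <- membrane_spec(a = cfg$membrane$a, m = cfg$membrane$m,
                        f01 = cfg$membrane$f01,
                        q_factor = cfg$membrane$q_factor)
  geom <- optical_geometry(incidence_angle = cfg$optics$incidence_angle,
                           screen_width = cfg$optics$screen_width,
                           screen_height = cfg$optics$screen_height,
                           mirror_to_screen = cfg$optics$mirror_to_screen)
  axis_delay <- if (is.null(cfg$optics$axis_delay)) {
    # quarter period of the played-back 10 Hz alpha rhythm
    1 / (4 * 10 * cfg$sonify$time_scale)
  } else cfg$optics$axis_delay
  traj <- simulate_spot_trajectory(audio, spec, geom,
                                   gain = cfg$optics$gain,
                                   axis_delay = axis_delay)
  exposure <- if (is.null(cfg$render$exposure)) 1 / cfg$render$fps else cfg$render$exposure
  frames <- render_frames(traj, fps = cfg$render$fps,
                          resolution = c(cfg$render$width, cfg$render$height),
                          psf_sigma = cfg$render$psf_sigma,
                          exposure = exposure,
                          noise_sigma = cfg$render$noise_sigma,
                          seed = seeds[cfg$eeg$n_subjects + 1],
                          black_level = cfg$render$black_level,
                          sat_dwell = cfg$render$sat_dwell)
  start_offset <- if (group == "Alzheimer") cfg$frameproc$trim_start_ad else cfg$frameproc$trim_start_nc
  mseq <- process_frames(frames, window = cfg$frameproc$window,
                         C = cfg$frameproc$C,
                         weighting = cfg$frameproc$weighting,
                         noise_sigma = cfg$frameproc$noise_sigma,
                         seed = seeds[cfg$eeg$n_subjects + 2],
                         start_offset = start_offset,
                         duration = cfg$frameproc$duration,
                         mask_source = cfg$frameproc$mask_source)
  features_from_frames(mseq, group_label = group,
                       source_id = paste0(tolower(group), "-run"))
}

#' Run the full pipeline end to end
#'
#' Executes, for each group, synthetic EEG generation (`n_subjects`
#' recordings), time-domain group averaging, sonification, membrane/laser
#' simulation, frame rendering, frame processing and feature extraction;
#' then the holdout + CV random-forest protocol on the combined feature
#' table. All randomness flows from `config$seed`; identical configurations
#' produce byte-identical feature tables and reports.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress and leakage messages.
#' @return List with `features` (tibble), `report` (`vib_report`), and
#'   `manifest` (every stage's parameters, sizes and output checksums).
#'   When `config$out_dir` is set, writes `features.csv`, `report.json`,
#'   `roc.csv` and `manifest.json` there.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_valid_config(config)
  note <- function(...) if (!quiet) message(...)
  ns <- config$eeg$n_subjects
  seeds <- withr::with_seed(config$seed,
                            sample.int(1000000L, 2L * (ns + 2L)))
  note("generating + processing Control group")
  f_nc <- run_group("Control", config, seeds[seq_len(ns + 2L)])
  note("generating + processing Alzheimer group")
  f_ad <- run_group("Alzheimer", config, seeds[(ns + 3L):(2L * (ns + 2L))])
  features <- dplyr::bind_rows(f_nc, f_ad)
  note(sprintf("classifying %d frames (%s mode)", nrow(features),
               config$classify$mode))
  report <- run_protocol(
    features,
    config = rf_config(n_estimators = config$classify$n_estimators,
                       random_state = config$classify$random_state),
    test_fraction = config$classify$test_fraction,
    k = config$classify$k, seed = config$seed,
    mode = config$classify$mode, quiet = quiet
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("vibrotrace")),
    seed = config$seed,
    derived_seeds = seeds,
    config = config_to_list(config),
    n_frames = nrow(features),
    n_frames_per_group = as.list(table(features$group_label)),
    n_train = report$n_train, n_test = report$n_test
  )
  out <- list(features = features, report = report, manifest = manifest)
  if (!is.null(config$out_dir)) {
    out$paths <- write_run_outputs(out, config$out_dir)
  }
  out
}

config_to_list <- function(cfg) {
  l <- unclass(cfg)
  l$profiles <- lapply(l$profiles, function(p) {
    if (inherits(p, "synth_profile")) {
      list(preset = p$preset, band_powers = as.list(p$band_powers),
           alpha_peak_hz = p$alpha_peak_hz, noise_floor = p$noise_floor)
    } else p
  })
  l
}

report_to_list <- function(report) {
  list(
    confusion = list(labels = class_levels(),
                     counts = unname(apply(report$confusion, 1, as.list))),
    per_class = lapply(seq_len(nrow(report$per_class)), function(i) {
      as.list(report$per_class[i, ])
    }),
    overall_accuracy = report$overall_accuracy,
    auc = report$auc,
    cv = if (!is.null(report$cv)) {
      list(k = report$cv$k, fold_accuracy = report$cv$fold_accuracy,
           mean = report$cv$mean, sd = report$cv$sd,
           ci95_normal = report$cv$ci95_normal, ci95_sd = report$cv$ci95_sd)
    },
    overfitting_gap = report$overfitting_gap,
    mode = report$mode,
    n_train = report$n_train, n_test = report$n_test
  )
}

write_run_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    report = file.path(out_dir, "report.json"),
    roc = file.path(out_dir, "roc.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(out$features, paths$features)
  jsonlite::write_json(report_to_list(out$report), paths$report,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(out$report$roc)) readr::write_csv(out$report$roc, paths$roc)
  manifest <- out$manifest
  p3 <- unlist(paths[c("features", "report", "roc")])
  manifest$checksums <- as.list(tools::md5sum(p3[file.exists(p3)]))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  paths
}
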