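# End-to-end orchestration: simulate -> preprocess -> montage -> spectra ->
# maps -> optional task contrast and IED analysis, with deterministic seeded
# outputs and a run manifest.

#' Pipeline configuration
#'
#' Nested list of stage parameters with sensible defaults; serialises
#' losslessly to/from JSON. Every random operation receives an explicit
#' seed derived from `seed`.
#'
#' @param seed master seed.
#' @param simulate list: `geometry` (kind for [make_geometry()]),
#'   `duration_s`, `fs`, plus optional `ied` (n_events, center_contact,
#'   sigma_mm, amplitude_uv) and `task` (intervals as onset/offset pairs,
#'   gain, gain_band, subset_ids) stages.
#' @param preprocess list: `cutoff`, `target_fs`, `notch_base`,
#'   `notch_harmonics`.
#' @param montage list: `scheme` (`"euclidean"` or `"ordinal"`),
#'   `max_skip`, `bin_width`, `range_mm`, `max_pairs_per_bin`.
#' @param spectral list: `nw`, `k`, `fmin`, `fmax`.
#' @param maps list: `min_pairs`, `scale`.
#' @param task NULL or list: `max_distance_mm`, `n_perm`, `alpha`.
#' @param ied NULL or list: `window_ms`, `n_perm`, `alpha`, `min_ied`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(geometry = "grid12x12",
                                            duration_s = 60, fs = 3052),
                            preprocess = list(cutoff = 255, target_fs = 512,
                                              notch_base = 60,
                                              notch_harmonics = c(120, 180, 240)),
                            montage = list(scheme = "euclidean", max_skip = 5,
                                           bin_width = 2, range_mm = c(2, 60),
                                           max_pairs_per_bin = 250),
                            spectral = list(nw = 3, k = 5, fmin = 2,
                                            fmax = 200),
                            maps = list(min_pairs = 5, scale = "linear"),
                            task = NULL, ied = NULL) {
  structure(list(seed = seed, simulate = simulate, preprocess = preprocess,
                 montage = montage, spectral = spectral, maps = maps,
                 task = task, ied = ied),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config configuration to write.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, bipolar
#' montage, spectra, distance maps, task contrast, IED analysis) and writes
#' every output (TSV maps and tables, JSON summaries) plus a run manifest
#' (config, seeds, package version, config file checksum) into a fresh run
#' directory. Re-running with the same config and seed reproduces the
#' outputs byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must not already contain a
#'   manifest).
#' @param recording optionally, a pre-existing `ieeg_recording` (skips the
#'   simulate stage).
#' @param arr electrode array accompanying `recording`.
#' @param ann [annotation_table()] accompanying `recording`.
#' @return Invisibly, a list of the in-memory results (`recording`, `arr`,
#'   `windows`, `pairs`, `spectra_ref`, `spectra_bip`, `map_z`, `map_pc`,
#'   `task`, `ied`, paths).
#' @export
run_pipeline <- function(config, out_dir, recording = NULL, arr = NULL,
                         ann = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(out_dir, "manifest.json"))) {
    stop("run directory already contains a manifest; refusing to overwrite",
         call. = FALSE)
  }
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ## simulate
  if (is.null(recording)) {
    stage("simulate", {
      sim <- config$simulate
      arr <- make_geometry(sim$geometry, seed = child_seed(seed, 10L))
      fc <- reference_field_config(seed = child_seed(seed, 11L))
      recording <- simulate_field(arr, fc, sim$duration_s, sim$fs,
                                   seed = child_seed(seed, 12L))
      ann <- annotation_table()
      if (!is.null(sim$ied) && sim$ied$n_events > 0) {
        icfg <- ied_config(sim$ied$n_events, sim$ied$center_contact,
                           sim$ied$sigma_mm %||% 8,
                           sim$ied$amplitude_uv %||% 400)
        inj <- inject_ieds(recording, arr, icfg,
                           seed = child_seed(seed, 13L))
        recording <- inj$recording
        ann <- rbind_annotations(ann, inj$annotations)
      }
      if (!is.null(sim$task)) {
        tsk <- inject_task_modulation(recording,
                                      sim$task$subset_ids,
                                      matrix(unlist(sim$task$intervals),
                                             ncol = 2, byrow = TRUE),
                                      sim$task$gain_band %||% c(50, 200),
                                      sim$task$gain %||% 1.5)
        recording <- tsk$recording
        ann <- rbind_annotations(ann, tsk$annotations)
        arr$subset[arr$contact_id %in% sim$task$subset_ids] <- TRUE
      }
      write_electrode_table(arr, file.path(out_dir, "electrodes.tsv"))
      write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    })
  }
  if (is.null(ann)) ann <- annotation_table()
  ## preprocess
  rec512 <- stage("preprocess", {
    pp <- config$preprocess
    r <- lowpass_downsample(recording, pp$cutoff, pp$target_fs)
    notch_line_noise(r, pp$notch_base, pp$notch_harmonics)
  })
  windows <- stage("preprocess", parse_baseline_windows(rec512, ann))
  ## montage
  pairs <- stage("montage", {
    mg <- config$montage
    p <- if (identical(mg$scheme, "ordinal"))
      enumerate_linear_ordinal_pairs(arr, mg$max_skip)
    else enumerate_omnidirectional_pairs(arr)
    p <- bin_pairs_by_distance(p, mg$bin_width, mg$range_mm)
    if (!is.null(mg$max_pairs_per_bin)) {
      p <- subsample_pairs(p, mg$max_pairs_per_bin,
                           seed = child_seed(seed, 20L))
    }
    p
  })
  write_pair_table(pairs, file.path(out_dir, "pairs.tsv"))
  ## spectra (baseline windows only)
  base_w <- select_windows(windows, label = "baseline")
  sp <- config$spectral
  spec_ref <- stage("spectral",
    multitaper_psd(base_w, sp$nw, sp$k, sp$fmin, sp$fmax))
  spec_bip <- stage("spectral",
    bipolar_psd(base_w, pairs, sp$nw, sp$k, sp$fmin, sp$fmax))
  write_spectra_tsv(spec_ref, file.path(out_dir, "spectra_referential.tsv"),
                    params = sp)
  ## maps
  map_z <- stage("maps", sqrt_zscore_map(spec_bip, pairs,
                                         config$maps$min_pairs))
  map_pc <- stage("maps", percent_change_map(spec_bip, spec_ref, pairs,
                                             scale = config$maps$scale,
                                             min_pairs = config$maps$min_pairs))
  write_map_tsv(map_z, file.path(out_dir, "map_zscored_sqrt_power.tsv"))
  write_map_tsv(map_pc, file.path(out_dir, "map_percent_change.tsv"))
  ## task contrast
  task_res <- NULL
  if (!is.null(config$task)) {
    task_res <- stage("task", {
      ct <- condition_difference_map(windows, pairs, arr,
                                     config$task$max_distance_mm %||% 40,
                                     sp$nw, sp$k)
      ct <- cluster_permutation_map(ct, config$task$n_perm %||% 1000L,
                                    config$task$alpha %||% 0.05,
                                    seed = child_seed(seed, 30L))
      write_map_tsv(ct$diff_map, file.path(out_dir, "task_difference.tsv"))
      write_map_tsv(ct$sig_mask, file.path(out_dir, "task_sig_mask.tsv"))
      hg <- high_gamma_metric(ct)
      utils::write.table(data.frame(bin_center_mm = names(hg),
                                    high_gamma_diff = hg),
                         file.path(out_dir, "task_high_gamma.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ct
    })
  }
  ## IED analysis
  ied_res <- NULL
  if (!is.null(config$ied)) {
    n_ied <- sum(ann$kind == "ied")
    if (!ied_inclusion(n_ied, config$ied$min_ied %||% 50L)) {
      writeLines(sprintf("ied stage skipped: %d IED windows below inclusion threshold",
                         n_ied),
                 file.path(out_dir, "ied_skipped.txt"))
    } else {
      ied_res <- stage("ied", {
        ied_w_ref <- center_ied_windows(rec512, ann)
        schemes <- build_density_schemes(arr)
        out <- list()
        for (dc in c("high", "low")) {
          prs <- schemes[[dc]]
          res <- ied_channel_cluster_test(
            apply_bipolar(ied_w_ref, prs),
            apply_bipolar(base_w, prs),
            window_ms = config$ied$window_ms %||% "instantaneous",
            n_perm = config$ied$n_perm %||% 1000L,
            alpha = config$ied$alpha %||% 0.05,
            seed = child_seed(seed, if (dc == "high") 40L else 41L))
          ext <- ied_extent_metrics(res, dc)
          utils::write.table(res$channels,
                             file.path(out_dir,
                                       sprintf("ied_channels_%s.tsv", dc)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          out[[dc]] <- list(result = res, extent = ext)
        }
        jsonlite::write_json(
          list(high = unclass(out$high$extent)[c("n_significant_channels",
                                                 "mean_width_ms")],
               low = unclass(out$low$extent)[c("n_significant_channels",
                                               "mean_width_ms")]),
          file.path(out_dir, "ied_extent.json"), auto_unbox = TRUE)
        out
      })
    }
  }
  ## manifest
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest <- list(package = "bprr",
                   version = as.character(utils::packageVersion("bprr")),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_windows = n_windows(windows),
                   n_pairs = nrow(pairs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(recording = recording, arr = arr, ann = ann,
                 windows = windows, pairs = pairs, spectra_ref = spec_ref,
                 spectra_bip = spec_bip, map_z = map_z, map_pc = map_pc,
                 task = task_res, ied = ied_res, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_annotations <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  annotation_table(out$onset_s, out$offset_s, out$kind)
}
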