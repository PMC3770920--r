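# End-to-end orchestration: simulate (or ingest) -> detect -> summarize,
# with validated configuration, stage logging, and a checksummed manifest.

#' Build a validated pipeline configuration
#'
#' @param seeds Integer vector of replicate seeds (one simulated culture per
#'   seed).
#' @param mea_presets Character vector of [mea_preset()] names to simulate
#'   (may be empty).
#' @param ca_presets Character vector of [ca_preset()] names (may be empty).
#' @param duration Recording length in seconds applied to every preset.
#' @param burst_params A [burst_detection_params()].
#' @param ca_params A [ca_detection_params()].
#' @param mea_overrides,ca_overrides Named lists forwarded to the generator
#'   configs (e.g. `list(n_electrodes = 16)`).
#' @param out_dir Output directory, or `NULL` to keep results in memory only.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seeds = 1L, mea_presets = "control-div26",
                            ca_presets = character(),
                            duration = 600,
                            burst_params = burst_detection_params(),
                            ca_params = ca_detection_params(),
                            mea_overrides = list(),
                            ca_overrides = list(),
                            out_dir = NULL) {
  stopifnot(length(seeds) >= 1, is.numeric(seeds))
  stopifnot(inherits(burst_params, "burst_detection_params"),
            inherits(ca_params, "ca_detection_params"))
  # validate presets and overrides eagerly, before any stage runs
  for (p in mea_presets) {
    do.call(mea_preset, c(list(name = p, duration = duration,
                               seed = seeds[1]), mea_overrides))
  }
  for (p in ca_presets) {
    do.call(ca_preset, c(list(name = p, duration = duration,
                              seed = seeds[1]), ca_overrides))
  }
  structure(
    list(seeds = as.integer(seeds), mea_presets = mea_presets,
         ca_presets = ca_presets, duration = duration,
         burst_params = burst_params, ca_params = ca_params,
         mea_overrides = mea_overrides, ca_overrides = ca_overrides,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration as YAML
#'
#' The YAML round trip reproduces an identical validated object.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    seeds = config$seeds, mea_presets = config$mea_presets,
    ca_presets = config$ca_presets, duration = config$duration,
    burst_params = unclass(config$burst_params),
    ca_params = unclass(config$ca_params),
    mea_overrides = config$mea_overrides,
    ca_overrides = config$ca_overrides,
    out_dir = config$out_dir)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    seeds = y$seeds,
    mea_presets = as.character(y$mea_presets %||% character()),
    ca_presets = as.character(y$ca_presets %||% character()),
    duration = y$duration,
    burst_params = do.call(burst_detection_params, y$burst_params),
    ca_params = do.call(ca_detection_params, y$ca_params),
    mea_overrides = y$mea_overrides %||% list(),
    ca_overrides = y$ca_overrides %||% list(),
    out_dir = y$out_dir)
}

#' Summarize replicate metric values as mean +/- SEM
#'
#' @param values Numeric vector, one value per replicate (culture or seed).
#' @param metric Metric name.
#' @param group Group label (preset name, day, ...).
#' @return A one-row data.frame with `metric`, `group`, `n`, `mean`, `sem`
#'   (`sem` is `NA` for a single replicate, not zero).
#' @export
#' @examples
#' summarize_replicates(c(2, 4, 6), "bursts_per_10min", "control-div26")
summarize_replicates <- function(values, metric = "metric",
                                 group = "group") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no replicate values", call. = FALSE)
  data.frame(metric = metric, group = group, n = length(values),
             mean = mean(values), sem = sem(values))
}

#' Run the full analysis pipeline
#'
#' For every (preset, seed) pair: simulates spike trains, computes the TSR,
#' detects bursts and superbursts, computes burst statistics; for calcium
#' presets, simulates traces and detects pulses and superoscillations.
#' Per-replicate metrics are then summarized as mean +/- SEM per preset.
#' When `config$out_dir` is set, all intermediate tables are written as CSV/
#' JSON and a manifest listing every file with its MD5 checksum is saved, so
#' a rerun with the same config reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages (default `TRUE`).
#' @return A list with `mea` (per-replicate burst statistics, long
#'   data.frame), `ca` (per-replicate calcium statistics), `summary`
#'   (mean +/- SEM per preset and metric), and `manifest` (data.frame of
#'   written files and checksums, or `NULL`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  written <- character()
  emit <- function(obj, name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
  }

  mea_rows <- list()
  for (preset in config$mea_presets) {
    for (seed in config$seeds) {
      say("stage mea/%s seed %d: simulate + detect", preset, seed)
      cfg <- do.call(mea_preset, c(list(name = preset,
                                        duration = config$duration,
                                        seed = seed),
                                   config$mea_overrides))
      res <- tryCatch({
        sim <- generate_spike_trains(cfg)
        tsr <- compute_tsr(sim$spikes, span = c(0, cfg$duration))
        bursts <- detect_bursts(tsr, config$burst_params,
                                spikes = sim$spikes, refine = "spikes")
        ind <- superburst_indicator(tsr, config$burst_params)
        sbs <- detect_superbursts(ind, config$burst_params, bursts = bursts,
                                  refine = "bursts")
        stats <- burst_statistics(rbind(bursts, sbs), window = cfg$duration)
        tag <- sprintf("%s_seed%d", preset, seed)
        emit(sim$spikes, paste0("spikes_", tag, ".csv"), write_spike_events)
        emit(rbind(bursts, sbs), paste0("intervals_", tag, ".csv"),
             write_intervals)
        emit(stats, paste0("burst_stats_", tag, ".json"), write_stats_json)
        stats
      }, error = function(e) {
        stop(sprintf("pipeline stage mea/%s seed %d failed: %s",
                     preset, seed, conditionMessage(e)), call. = FALSE)
      })
      mea_rows[[length(mea_rows) + 1L]] <- data.frame(
        preset = preset, seed = seed,
        as.data.frame(unclass(res)))
    }
  }
  mea <- if (length(mea_rows)) do.call(rbind, mea_rows) else NULL

  ca_rows <- list()
  for (preset in config$ca_presets) {
    for (seed in config$seeds) {
      say("stage ca/%s seed %d: simulate + detect", preset, seed)
      cfg <- do.call(ca_preset, c(list(name = preset,
                                       duration = config$duration,
                                       seed = seed),
                                  config$ca_overrides))
      res <- tryCatch({
        sim <- generate_calcium_traces(cfg)
        ev <- do.call(rbind, lapply(sim$traces, function(tr) {
          rbind(detect_ca_pulses(tr, config$ca_params),
                detect_superoscillations(tr, config$ca_params))
        }))
        st <- ca_statistics(ev, sim$traces, window = cfg$duration)
        tag <- sprintf("%s_seed%d", preset, seed)
        emit(sim$traces, paste0("traces_", tag, ".csv"), write_traces)
        emit(st, paste0("ca_stats_", tag, ".json"), write_stats_json)
        st
      }, error = function(e) {
        stop(sprintf("pipeline stage ca/%s seed %d failed: %s",
                     preset, seed, conditionMessage(e)), call. = FALSE)
      })
      res$preset <- preset
      res$seed <- seed
      ca_rows[[length(ca_rows) + 1L]] <- res
    }
  }
  ca <- if (length(ca_rows)) do.call(rbind, ca_rows) else NULL

  say("stage summarize")
  summ <- list()
  if (!is.null(mea)) {
    metrics <- setdiff(names(mea), c("preset", "seed"))
    for (preset in unique(mea$preset)) {
      for (m in metrics) {
        v <- mea[[m]][mea$preset == preset]
        if (all(is.na(v))) next
        summ[[length(summ) + 1L]] <- summarize_replicates(v, m, preset)
      }
    }
  }
  if (!is.null(ca)) {
    for (preset in unique(ca$preset)) {
      for (ty in unique(ca$cell_type)) {
        for (kind in unique(ca$kind)) {
          sel <- ca$preset == preset & ca$cell_type == ty & ca$kind == kind
          if (!any(sel)) next
          summ[[length(summ) + 1L]] <- summarize_replicates(
            ca$mean_duration[sel], paste0(ty, "_", kind, "_duration"),
            preset)
          summ[[length(summ) + 1L]] <- summarize_replicates(
            ca$events_per_10min[sel], paste0(ty, "_", kind, "_per_10min"),
            preset)
        }
      }
    }
  }
  summary <- if (length(summ)) do.call(rbind, summ) else NULL

  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!is.null(summary)) {
      p <- file.path(out_dir, "summary.csv")
      write.csv(summary, p, row.names = FALSE)
      written <- c(written, p)
    }
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(mea = mea, ca = ca, summary = summary, manifest = manifest)
}
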