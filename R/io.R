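# Readers/writers for localization tables (CSV and HDF5), run configuration
# and the end-to-end pipeline driver. Canonical units throughout: nm for
# space, seconds for time, 0-based integer frames.

loc_required_cols <- c("x_nm", "y_nm", "frame")
loc_optional_cols <- c("photons", "sigma_nm", "channel")

validate_localizations <- function(df, source = "input") {
  missing <- setdiff(loc_required_cols, names(df))
  if (length(missing)) {
    abort(
      sprintf("%s is missing required column(s): %s.",
              source, paste(missing, collapse = ", ")),
      class = "nanopaint_schema_error", missing_columns = missing
    )
  }
  if (!nrow(df)) {
    abort(sprintf("%s contains no localization records.", source),
          class = "nanopaint_schema_error")
  }
  ok <- is.finite(df$x_nm) & is.finite(df$y_nm) &
    is.finite(df$frame) & df$frame >= 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    inform(sprintf("%s: rejected %d record(s) with non-finite coordinates or negative frames.",
                   source, n_rejected))
  }
  out <- as_tibble(df[ok, , drop = FALSE])
  out$frame <- as.integer(out$frame)
  if (!"photons" %in% names(out)) out$photons <- NA_integer_
  if (!"sigma_nm" %in% names(out)) out$sigma_nm <- NA_real_
  if (!"channel" %in% names(out)) out$channel <- "default"
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read a localization table
#'
#' Reads per-event localization records from CSV (comma separated, header
#' row, `.` decimal) or HDF5 (one table per channel under
#' `/localizations/<channel>`). Required columns: `x_nm`, `y_nm`, `frame`;
#' optional: `photons`, `sigma_nm`, `channel`. Rows with non-finite
#' coordinates or negative frames are rejected, with the rejection count
#' reported and attached as attribute `"n_rejected"`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"hdf5"`.
#' @param channel For HDF5: which channel table(s) to read (default all,
#'   concatenated with their channel labels).
#' @return Localization tibble.
#' @export
read_localizations <- function(path, format = c("auto", "csv", "hdf5"),
                               channel = NULL) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    return(validate_localizations(df, source = path))
  }
  chans <- channel %||% {
    listing <- rhdf5::h5ls(path)
    listing$name[listing$group == "/localizations"]
  }
  if (!length(chans)) {
    abort(sprintf("%s holds no tables under /localizations.", path),
          class = "nanopaint_schema_error")
  }
  tabs <- map(chans, function(ch) {
    df <- as_tibble(rhdf5::h5read(path, paste0("localizations/", ch)))
    df[] <- lapply(df, as.vector) # drop 1d array dims
    if (!"channel" %in% names(df)) df$channel <- ch
    df
  })
  validate_localizations(bind_rows(tabs), source = path)
}

#' Write a localization table
#'
#' CSV output has columns `x_nm`, `y_nm`, `frame`, `photons`, `sigma_nm`,
#' `channel`; HDF5 output stores one table per channel under
#' `/localizations/<channel>`.
#'
#' @param events Localization tibble.
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(events, path,
                                format = c("auto", "csv", "hdf5")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  }
  if (!"channel" %in% names(events)) events$channel <- "default"
  cols <- intersect(c(loc_required_cols, loc_optional_cols), names(events))
  events <- events[, cols]
  if (format == "csv") {
    readr::write_csv(events, path, progress = FALSE)
  } else {
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "localizations")
    for (ch in unique(events$channel)) {
      sub <- as.data.frame(events[events$channel == ch, ])
      rhdf5::h5write(sub, path, paste0("localizations/", ch))
    }
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Write / read ground-truth site tables
#'
#' CSV with columns `x_nm`, `y_nm`, `cluster_id`, `protein`, `detected`.
#'
#' @param sites Ground-truth site tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_ground_truth <- function(sites, path) {
  cols <- intersect(c("x_nm", "y_nm", "cluster_id", "protein", "detected"),
                    names(sites))
  readr::write_csv(sites[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_clusters = 60L,
      pitch_nm = 900,
      jph2 = FALSE
    ),
    assembly = unclass(assembly_params()),
    kinetics = unclass(kinetics_params()),
    jph = unclass(jph_params()),
    render = list(pixel_size = 2, method = "gaussian", sigma = 12),
    segment = list(density_threshold = NULL, min_events = 10),
    puncta = list(smoothing_sigma = 7, min_separation = 20,
                  rel_threshold = 0.1, min_events = 10),
    qpaint = list(max_frame_gap = 2, max_jump = 20, min_dark_times = 10,
                  calibration_max_area = 4000, calibration_max_puncta = 1,
                  min_calibration_clusters = 20),
    coclustering = list(bin_width = 10, max_distance = 200,
                        min_ryr_count = 15, junction_dilate_nm = 100)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s)%s: %s.",
                  if (nzchar(path)) paste0(" under ", path) else "",
                  paste(unknown, collapse = ", ")),
          class = "nanopaint_schema_error")
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "/", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build or read a pipeline configuration
#'
#' `pipeline_config()` merges user overrides into the documented defaults and
#' rejects unknown keys; `read_pipeline_config()` does the same from a YAML
#' file. The fully resolved configuration is echoed into every output
#' directory by [run_pipeline()].
#'
#' @param ... Named overrides of top-level blocks (e.g.
#'   `simulate = list(n_clusters = 100)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(pipeline_defaults(), user)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path) %||% list()
  structure(merge_config(pipeline_defaults(), user), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "nanopaint_stage_error")) stop(e)
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "nanopaint_stage_error", parent = e)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate (when configured) -> render -> segment -> detect puncta
#' -> distance statistics -> qPAINT -> co-clustering (when a JPH2 channel is
#' present), writing all tabular outputs, the rendered raster, the resolved
#' configuration and a machine-readable JSON summary into `out_dir`. The run
#' is fully reproducible from (config, seed).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param events Optional localization tibble; when supplied the simulate
#'   stage is skipped and these events are analyzed.
#' @param seed Seed overriding `config$seed`.
#' @return Invisibly, a list with the key result objects and the `summary`
#'   list written to `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         events = NULL, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed)
  asm <- do.call(assembly_params, config$assembly)
  kin <- do.call(kinetics_params, config$kinetics)
  jphp <- do.call(jph_params, config$jph)
  yaml::write_yaml(
    c(unclass(config), list(resolved_seed = seed)),
    file.path(out_dir, "config_echo.yaml")
  )
  withr::with_seed(seed, {
    sites <- NULL
    jph_sites <- NULL
    jph_events <- NULL
    if (is.null(events)) {
      run_stage("simulate", {
        sites <- simulate_field(config$simulate$n_clusters, asm,
                                pitch_nm = config$simulate$pitch_nm)
        events <- simulate_paint_events(sites %>% filter(.data$detected),
                                        kin, channel = "ryr")
        write_ground_truth(sites, file.path(out_dir, "ground_truth_ryr.csv"))
        if (isTRUE(config$simulate$jph2)) {
          jph_sites <- place_jph2(sites, jphp, step_mean = asm$step_mean)
          jph_events <- simulate_paint_events(jph_sites, kin, channel = "jph2")
          write_ground_truth(jph_sites,
                             file.path(out_dir, "ground_truth_jph2.csv"))
        }
        write_localizations(
          bind_rows(events, jph_events),
          file.path(out_dir, "localizations.csv")
        )
      })
    }
    raster <- run_stage("render", {
      r <- render_density(events, pixel_size = config$render$pixel_size,
                          method = config$render$method,
                          sigma = config$render$sigma)
      write_raster(r, file.path(out_dir, "density.tif"))
      r
    })
    clusters <- run_stage("segment", {
      cs <- segment_clusters(raster, events,
                             density_threshold = config$segment$density_threshold,
                             min_events = config$segment$min_events)
      readr::write_csv(cs$clusters, file.path(out_dir, "clusters.csv"),
                       progress = FALSE)
      cs
    })
    puncta <- run_stage("puncta", {
      p <- detect_puncta(clusters,
                         smoothing_sigma = config$puncta$smoothing_sigma,
                         min_separation = config$puncta$min_separation,
                         rel_threshold = config$puncta$rel_threshold,
                         min_events = config$puncta$min_events)
      nnd <- nearest_neighbor_distances(p)
      fnd <- four_neighbor_distances(p)
      p <- p %>%
        left_join(nnd %>% select("cluster_id", "x_nm", "nnd_nm"),
                  by = c("cluster_id", "x_nm")) %>%
        left_join(fnd %>% select("cluster_id", "x_nm", "fournd_nm"),
                  by = c("cluster_id", "x_nm"))
      readr::write_csv(p, file.path(out_dir, "puncta.csv"), progress = FALSE)
      p
    })
    qp <- run_stage("qpaint", {
      est <- qpaint_indices(clusters, frame_time = kin$frame_time,
                            max_frame_gap = config$qpaint$max_frame_gap,
                            max_jump = config$qpaint$max_jump,
                            min_dark_times = config$qpaint$min_dark_times)
      calib_tab <- select_calibration_clusters(
        clusters, puncta,
        max_area_nm2 = config$qpaint$calibration_max_area,
        max_puncta = config$qpaint$calibration_max_puncta
      )
      calib <- tryCatch(
        calibrate_quantal_unit(
          est$qpaint_index[est$cluster_id %in% calib_tab$cluster_id],
          min_clusters = config$qpaint$min_calibration_clusters
        ),
        nanopaint_insufficient_data = function(e) NULL,
        nanopaint_calibration_failure = function(e) NULL
      )
      if (!is.null(calib)) est <- count_molecules(est, calib)
      est <- est %>% left_join(clusters$clusters, by = "cluster_id")
      readr::write_csv(est, file.path(out_dir, "qpaint.csv"), progress = FALSE)
      fit <- if (!is.null(calib)) {
        density_regression(est$area_nm2, est$count_raw)
      } else NULL
      list(estimates = est, calibration = calib, fit = fit)
    })
    cocluster <- NULL
    if (!is.null(jph_events) && nrow(jph_events)) {
      cocluster <- run_stage("coclustering", {
        dil <- config$coclustering$junction_dilate_nm
        pad <- ceiling(dil / clusters$raster$pixel_size) + 2L
        masks <- map(clusters$clusters$cluster_id, function(id) {
          dilate_mask(cluster_mask(clusters, id, pad_px = pad), dil)
        })
        names(masks) <- as.character(clusters$clusters$cluster_id)
        # assign JPH2 events to the dilated junction of the nearest cluster
        jl <- jph_events
        px <- events_to_pixels(jl, clusters$raster)
        ok <- !is.na(px$row)
        lab <- rep(NA_integer_, nrow(jl))
        lab[ok] <- clusters$labels[cbind(px$row[ok], px$col[ok])]
        for (i in seq_along(masks)) {
          id <- clusters$clusters$cluster_id[i]
          m <- masks[[i]]
          col <- floor((jl$x_nm - m$origin[1]) / m$pixel_size) + 1L
          row <- floor((jl$y_nm - m$origin[2]) / m$pixel_size) + 1L
          inside <- !is.na(col) & col >= 1 & col <= ncol(m$mask) &
            row >= 1 & row <= nrow(m$mask)
          inside[inside] <- m$mask[cbind(row[inside], col[inside])]
          lab[inside & (is.na(lab) | lab == 0L)] <- id
        }
        jl$cluster_id <- lab
        profile <- radial_density(
          puncta, jl %>% filter(!is.na(.data$cluster_id), .data$cluster_id > 0),
          masks, bin_width = config$coclustering$bin_width,
          max_distance = config$coclustering$max_distance
        )
        readr::write_csv(as_tibble(profile),
                         file.path(out_dir, "radial_profile.csv"),
                         progress = FALSE)
        profile
      })
    }
    nnd_vals <- nearest_neighbor_distances(puncta)$nnd_nm
    fnd_vals <- four_neighbor_distances(puncta)$fournd_nm
    summary <- list(
      seed = seed,
      n_events = nrow(events),
      n_clusters = nrow(clusters$clusters),
      mean_cluster_n_puncta = if (nrow(puncta))
        mean(count(puncta, .data$cluster_id)$n) else NA_real_,
      nnd_mean_nm = if (length(nnd_vals)) mean(nnd_vals) else NA_real_,
      fournd_mean_nm = if (length(fnd_vals)) mean(fnd_vals) else NA_real_,
      calibration_unit = if (!is.null(qp$calibration)) qp$calibration$unit
                         else NA_real_,
      density_slope_per_1000nm2 = if (!is.null(qp$fit)) 1000 * qp$fit$slope
                                  else NA_real_,
      packing_spacing_nm = if (!is.null(qp$fit)) qp$fit$spacing_nm
                           else NA_real_,
      coclustering_run = !is.null(cocluster),
      fold_enrichment_50nm = if (!is.null(cocluster))
        fold_enrichment(cocluster) else NA_real_
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(
      sites = sites, events = events, raster = raster, clusters = clusters,
      puncta = puncta, qpaint = qp, cocluster = cocluster, summary = summary
    ))
  })
}
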