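# End-to-end orchestration: a declarative config (JSON-serializable list),
# validation, and a run_pipeline() driver executing synth -> lipidomics ->
# vld -> md and writing per-stage CSV outputs plus a machine-readable
# report.

#' Default pipeline configuration
#'
#' Every module default is encoded here and can be overridden; the config
#' round-trips through JSON ([write_config()] / [read_config()]).
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("lipidomics", "vld", "md"),
    lipidomics = list(
      presets = c("muscle", "heart", "brain", "lung", "pancreas", "liver"),
      jitter = 0.1,
      tolerance_ppm = 5
    ),
    vld = list(
      conditions = c("NT", "AA", "DHA"),
      n_cells = NA_integer_, # NA: per-preset default
      n_frames = 300L,
      frame_interval = 5,
      shock_time = 60,
      noise_sd = 0.05,
      breakage_threshold = 10,
      window = 7L,
      baseline_noise_k = 3,
      run_length = 3L
    ),
    md = list(
      eq_box = c(30, 30),
      step_pct = 5,
      max_pct = 25,
      gamma_per_extension = c(0, 2, 5, 9, 14, 20), # mN/m targets for synth
      Lz = 10,
      pressure_n = 2000L,
      pressure_noise_sd = 100,
      bin_width = 2.5
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges and stage names; errors name the offending key.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(key, why) {
    stop(sprintf("invalid config: `%s` %s", key, why), call. = FALSE)
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (is.null(config$seed) || !is.finite(config$seed)) fail("seed", "must be an integer")
  bad <- setdiff(config$stages, c("lipidomics", "vld", "md"))
  if (length(bad)) fail("stages", paste("contains unknown stage:", paste(bad, collapse = ", ")))
  num_pos <- list(
    "lipidomics.tolerance_ppm" = config$lipidomics$tolerance_ppm,
    "vld.frame_interval" = config$vld$frame_interval,
    "vld.breakage_threshold" = config$vld$breakage_threshold,
    "vld.baseline_noise_k" = config$vld$baseline_noise_k,
    "md.step_pct" = config$md$step_pct,
    "md.Lz" = config$md$Lz,
    "md.bin_width" = config$md$bin_width
  )
  for (k in names(num_pos)) {
    v <- num_pos[[k]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)) {
      fail(k, "must be a positive number")
    }
  }
  if (!is.null(config$vld$noise_sd) &&
    (!is.numeric(config$vld$noise_sd) || config$vld$noise_sd < 0)) {
    fail("vld.noise_sd", "must be >= 0")
  }
  if (!is.null(config$vld$window) &&
    (config$vld$window %% 2 != 1 || config$vld$window < 3)) {
    fail("vld.window", "must be odd and >= 3")
  }
  unknown <- setdiff(
    names(config),
    c("seed", "out_dir", "stages", "lipidomics", "vld", "md")
  )
  if (length(unknown)) fail(unknown[1], "is not a recognized key")
  invisible(config)
}

#' @rdname read_config
#' @param config Config list to serialize.
#' @param file Path to a JSON file.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read / write a pipeline configuration
#'
#' Configurations serialize to JSON and round-trip losslessly.
#'
#' @return `read_config()`: the validated config list.
#' @export
read_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' Run the full pipeline
#'
#' Executes the requested stages in the order lipidomics -> vld -> md on
#' synthetic inputs generated from the master seed, and assembles a
#' machine-readable report: per-sample double-bond indexes, DHA/AA ratios
#' and PCA explained variances; per-condition VLD summaries (counts,
#' kinetics, surface metrics, breakage, count-bin distributions); and
#' surface tension per extension level with angle-distribution summaries.
#' With `out_dir` set, per-stage CSVs and a `report.json` are written;
#' re-running with the same config is bit-identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @return The report, invisibly (a nested list).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  report <- list(seed = config$seed)
  t_start <- proc.time()[["elapsed"]]

  if ("lipidomics" %in% config$stages) {
    lp <- config$lipidomics
    tabs <- lapply(seq_along(lp$presets), function(i) {
      gen_species_table(lp$presets[i],
        jitter = lp$jitter,
        seed = child_seed(config$seed, i)
      )
    })
    idx <- lapply(tabs, db_index)
    names(idx) <- lp$presets
    ratios <- vapply(tabs, dha_aa_ratio, 0)
    pca <- pca_db(do.call(rbind, idx))
    report$lipidomics <- list(
      db_index = do.call(rbind, idx),
      dha_aa_ratio = stats::setNames(ratios, lp$presets),
      pca_explained_pct = pca$explained_variance_pct
    )
    message(sprintf(
      "[lipidomics] %d presets profiled (%.1f s)",
      length(lp$presets), proc.time()[["elapsed"]] - t_start
    ))
  }

  if ("vld" %in% config$stages) {
    vp <- config$vld
    summaries <- list()
    bins <- list()
    for (i in seq_along(vp$conditions)) {
      cond <- vp$conditions[i]
      params <- condition_presets(cond)
      n <- if (is.na(vp$n_cells)) params$n_cells else as.integer(vp$n_cells)
      cohort <- gen_cell_cohort(params,
        n_cells = n, seed = child_seed(config$seed, 100 + i),
        n_frames = vp$n_frames, frame_interval = vp$frame_interval,
        shock_time = vp$shock_time, noise_sd = vp$noise_sd
      )
      res <- analyze_cohort(cohort,
        breakage_threshold = vp$breakage_threshold,
        window = vp$window, baseline_noise_k = vp$baseline_noise_k,
        run_length = vp$run_length
      )
      summaries[[cond]] <- res$summary
      bins[[cond]] <- res$count_bins
    }
    report$vld <- list(
      condition_summary = do.call(rbind, summaries),
      count_bins = bins
    )
    message(sprintf(
      "[vld] %d conditions analyzed (%.1f s)",
      length(vp$conditions), proc.time()[["elapsed"]] - t_start
    ))
  }

  if ("md" %in% config$stages) {
    mp <- config$md
    plan <- plan_extensions(mp$eq_box, mp$step_pct, mp$max_pct)
    gammas <- lapply(seq_len(nrow(plan)), function(i) {
      target <- mp$gamma_per_extension[min(i, length(mp$gamma_per_extension))]
      ser <- gen_pressure_series(target,
        Lz = mp$Lz, noise_sd = mp$pressure_noise_sd,
        n = mp$pressure_n, seed = child_seed(config$seed, 200 + i)
      )
      st <- surface_tension(ser)
      data.frame(
        level_pct = plan$level_pct[i], gamma_target = target,
        gamma = st$gamma, stderr = st$stderr
      )
    })
    # tilt angles broaden toward in-plane with extension
    traj <- gen_trajectory(
      n_lipids_per_leaflet = 48,
      angle_law = list(type = "normal", mean = 30, sd = 12),
      n_frames = 5L, seed = child_seed(config$seed, 300)
    )
    ad <- angle_distribution(traj$frames, traj$topology, bin_width = mp$bin_width)
    report$md <- list(
      extension_plan = plan,
      surface_tension = do.call(rbind, gammas),
      angle_mode_deg = ad$mid[which.max(ad$probability)]
    )
    message(sprintf("[md] tension + angles done (%.1f s)", proc.time()[["elapsed"]] - t_start))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$lipidomics)) {
      utils::write.csv(
        data.frame(
          sample = rownames(report$lipidomics$db_index),
          report$lipidomics$db_index,
          dha_aa_ratio = report$lipidomics$dha_aa_ratio
        ),
        file.path(config$out_dir, "db_index.csv"),
        row.names = FALSE
      )
      utils::write.csv(
        data.frame(
          component = seq_along(report$lipidomics$pca_explained_pct),
          explained_pct = report$lipidomics$pca_explained_pct
        ),
        file.path(config$out_dir, "pca.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(report$vld)) {
      utils::write.csv(report$vld$condition_summary,
        file.path(config$out_dir, "condition_summary.csv"),
        row.names = FALSE
      )
      utils::write.csv(
        data.frame(
          condition = rep(names(report$vld$count_bins), each = 4L),
          bin = unlist(lapply(report$vld$count_bins, names)),
          pct = unlist(report$vld$count_bins)
        ),
        file.path(config$out_dir, "counts.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(report$md)) {
      utils::write.csv(report$md$surface_tension,
        file.path(config$out_dir, "surface_tension.csv"),
        row.names = FALSE
      )
    }
    jsonlite::write_json(
      report_to_json(report),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}

# Flatten the report into JSON-friendly structures.
report_to_json <- function(report) {
  out <- list(seed = report$seed)
  if (!is.null(report$lipidomics)) {
    out$lipidomics <- list(
      db_index = as.data.frame(report$lipidomics$db_index),
      dha_aa_ratio = as.list(report$lipidomics$dha_aa_ratio),
      pca_explained_pct = report$lipidomics$pca_explained_pct
    )
  }
  if (!is.null(report$vld)) {
    out$vld <- list(
      condition_summary = report$vld$condition_summary,
      count_bins = lapply(report$vld$count_bins, as.list)
    )
  }
  if (!is.null(report$md)) {
    out$md <- report$md
  }
  out
}
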