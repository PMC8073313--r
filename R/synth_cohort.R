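# Synthetic cell cohorts under osmotic downshock, calibrated to the printed
# condition-level statistics: per-cell VLD counts (zero-inflated negative
# binomial), per-VLD 515-nm logistic formation traces, 543-nm breakage
# traces, and cell cross-section area series. Every generated object carries
# its ground truth so downstream estimators can be validated by parameter
# recovery.

# Frozen count-law calibrations (zero-inflated negative binomial).
# For each condition the three free parameters (structural zero fraction pi,
# conditional NB mean mu, dispersion size) are solved once, against
# closed-form NB probabilities, for the three published constraints:
#   overall mean  = printed mean counts per cell,
#   overall SD    = printed SEM * sqrt(printed n),
#   and one distribution feature: NT total zero probability 0.34,
#   AA P(1 <= X <= 5) = 0.48, DHA P(X > 10) = 0.50.
# test-synth.R re-verifies these numbers against the same closed forms.
.COUNT_CALIBRATION <- list(
  NT = list(
    pi = 0.330665968105, mu = 3.8 / (1 - 0.330665968105),
    size = 7.855495633886
  ),
  AA = list(
    pi = 0.155047296817, mu = 4.2 / (1 - 0.155047296817),
    size = 2.308602931387
  ),
  DHA = list(
    pi = 0.140882502878, mu = 11.4 / (1 - 0.140882502878),
    size = 3.799980916551
  )
)

#' Condition parameters for the synthetic cohort generator
#'
#' Bundles the per-condition statistical parameters the generator draws
#' from. Means and SEMs printed for a condition are encoded directly, with
#' SD = SEM * sqrt(n); unprinted quantities carry documented package
#' choices (see the methods vignette).
#'
#' @param label Condition label.
#' @param n_cells Default cohort size.
#' @param count_mean Mean VLDs per cell (overall, including zero-count
#'   cells).
#' @param count_zero Total probability of a zero-count cell.
#' @param count_size Negative-binomial dispersion (size) of the count law.
#' @param count_pi Structural zero-inflation of the count law.
#' @param count_mu Conditional negative-binomial mean of the count law.
#' @param tvmax_mean,tvmax_sd Time to maximal formation rate, s.
#' @param vmax_mean,vmax_sd Maximal relative-fluorescence rate, 1/s.
#' @param plateau_mean,plateau_sd Relative plateau amplitude.
#' @param surface_increase_mean,surface_increase_sd Percent surface
#'   increase.
#' @param t_surface_max_mean,t_surface_max_sd Time of maximal surface, s.
#' @param breakage_prob Probability a cell breaks.
#' @param t_breakage_mean,t_breakage_sd Breakage time, s.
#' @return A `condition_params` list.
#' @export
condition_params <- function(label, n_cells,
                             count_mean, count_zero, count_size, count_pi, count_mu,
                             tvmax_mean, tvmax_sd, vmax_mean, vmax_sd,
                             plateau_mean = 2.0, plateau_sd = 0.5,
                             surface_increase_mean, surface_increase_sd,
                             t_surface_max_mean, t_surface_max_sd,
                             breakage_prob, t_breakage_mean, t_breakage_sd) {
  p <- list(
    label = label, n_cells = as.integer(n_cells),
    count_mean = count_mean, count_zero = count_zero,
    count_size = count_size, count_pi = count_pi, count_mu = count_mu,
    tvmax_mean = tvmax_mean, tvmax_sd = tvmax_sd,
    vmax_mean = vmax_mean, vmax_sd = vmax_sd,
    plateau_mean = plateau_mean, plateau_sd = plateau_sd,
    surface_increase_mean = surface_increase_mean,
    surface_increase_sd = surface_increase_sd,
    t_surface_max_mean = t_surface_max_mean,
    t_surface_max_sd = t_surface_max_sd,
    breakage_prob = breakage_prob,
    t_breakage_mean = t_breakage_mean, t_breakage_sd = t_breakage_sd
  )
  if (p$breakage_prob < 0 || p$breakage_prob > 1) {
    stop("breakage_prob must be in [0, 1]", call. = FALSE)
  }
  pos <- c(
    "count_mean", "tvmax_mean", "vmax_mean", "plateau_mean",
    "surface_increase_mean", "t_surface_max_mean", "t_breakage_mean"
  )
  bad <- pos[vapply(pos, function(k) !is.finite(p[[k]]) || p[[k]] <= 0, TRUE)]
  if (length(bad)) stop("non-positive parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(p, class = "condition_params")
}

#' Packaged condition presets
#'
#' The four experimental conditions with their packaged defaults. Printed
#' condition statistics (mean +/- SEM at n): VLD counts NT 3.8 +/- 0.3
#' (n = 152), AA 4.2 +/- 0.4 (n = 103), DHA 11.4 +/- 0.7 (n = 148); tVmax
#' NT 622 +/- 21 s, AA 423 +/- 25 s, DHA 301 +/- 10 s; Vmax NT
#' 0.016 +/- 0.001, AA 0.018 +/- 0.002, DHA 0.024 +/- 0.002 1/s; surface
#' increase AA 12.6 +/- 2.8% (n = 96), NT-cracked 19.5 +/- 4.0% (n = 58);
#' t surface max DHA 137.7 +/- 6.6 s (n = 88), NT-VLD 227.3 +/- 14.0 s
#' (n = 47). SDs are SEM * sqrt(n). Quantities never printed (surface
#' increase for DHA / NT-VLD, t surface max for AA / NT-cracked, breakage
#' parameters) are package choices documented in the methods vignette.
#'
#' @param label One of `"NT"`, `"NT_VLD"`, `"NT_cracked"`, `"AA"`, `"DHA"`;
#'   omit for the full named list.
#' @return A `condition_params`, or a named list of all presets.
#' @export
condition_presets <- function(label = NULL) {
  cc <- .COUNT_CALIBRATION
  presets <- list(
    NT = condition_params("NT",
      n_cells = 152,
      count_mean = 3.8, count_zero = 0.34,
      count_size = cc$NT$size, count_pi = cc$NT$pi, count_mu = cc$NT$mu,
      tvmax_mean = 622, tvmax_sd = 21 * sqrt(152),
      vmax_mean = 0.016, vmax_sd = 0.001 * sqrt(152),
      surface_increase_mean = 17.5, surface_increase_sd = 5,
      t_surface_max_mean = 227.3, t_surface_max_sd = 14 * sqrt(47),
      breakage_prob = 0.25, t_breakage_mean = 400, t_breakage_sd = 120
    ),
    NT_VLD = condition_params("NT_VLD",
      n_cells = 47,
      count_mean = 3.8, count_zero = 0.34,
      count_size = cc$NT$size, count_pi = cc$NT$pi, count_mu = cc$NT$mu,
      tvmax_mean = 622, tvmax_sd = 21 * sqrt(152),
      vmax_mean = 0.016, vmax_sd = 0.001 * sqrt(152),
      surface_increase_mean = 17.5, surface_increase_sd = 5,
      t_surface_max_mean = 227.3, t_surface_max_sd = 14 * sqrt(47),
      breakage_prob = 0, t_breakage_mean = 400, t_breakage_sd = 120
    ),
    NT_cracked = condition_params("NT_cracked",
      n_cells = 58,
      count_mean = 1e-9, count_zero = 1, count_size = 1, count_pi = 1, count_mu = 1,
      tvmax_mean = 622, tvmax_sd = 21 * sqrt(152),
      vmax_mean = 0.016, vmax_sd = 0.001 * sqrt(152),
      surface_increase_mean = 19.5, surface_increase_sd = 4 * sqrt(58),
      t_surface_max_mean = 240, t_surface_max_sd = 100,
      breakage_prob = 1, t_breakage_mean = 400, t_breakage_sd = 120
    ),
    AA = condition_params("AA",
      n_cells = 103,
      count_mean = 4.2, count_zero = 0.2147,
      count_size = cc$AA$size, count_pi = cc$AA$pi, count_mu = cc$AA$mu,
      tvmax_mean = 423, tvmax_sd = 25 * sqrt(103),
      vmax_mean = 0.018, vmax_sd = 0.002 * sqrt(103),
      surface_increase_mean = 12.6, surface_increase_sd = 2.8 * sqrt(96),
      t_surface_max_mean = 180, t_surface_max_sd = 80,
      breakage_prob = 0.1, t_breakage_mean = 450, t_breakage_sd = 100
    ),
    DHA = condition_params("DHA",
      n_cells = 148,
      count_mean = 11.4, count_zero = 0.1437,
      count_size = cc$DHA$size, count_pi = cc$DHA$pi, count_mu = cc$DHA$mu,
      tvmax_mean = 301, tvmax_sd = 10 * sqrt(148),
      vmax_mean = 0.024, vmax_sd = 0.002 * sqrt(148),
      surface_increase_mean = 17, surface_increase_sd = 5,
      t_surface_max_mean = 137.7, t_surface_max_sd = 6.6 * sqrt(88),
      breakage_prob = 0.05, t_breakage_mean = 500, t_breakage_sd = 100
    )
  )
  if (is.null(label)) return(presets)
  if (!label %in% names(presets)) {
    stop(
      "unknown condition preset: ", label, " (use ",
      paste(names(presets), collapse = ", "), ")",
      call. = FALSE
    )
  }
  presets[[label]]
}

# Draw per-cell VLD counts from the condition's zero-inflated NB law.
draw_vld_counts <- function(params, n) {
  structural <- stats::rbinom(n, 1, params$count_pi) == 1L
  counts <- stats::rnbinom(n, size = params$count_size, mu = params$count_mu)
  counts[structural] <- 0L
  counts
}

#' Generate a synthetic cell cohort for one condition
#'
#' Draws per-cell VLD counts from the condition's zero-inflated negative
#' binomial; gives every VLD a 515-nm relative-fluorescence trace
#' A/(1 + exp(-k (t - tm))) + Gaussian noise with `tm` and the plateau `A`
#' drawn per condition and `k = 4 Vmax / A` so the drawn Vmax is the true
#' inflection slope; gives broken cells a 543-nm trace stepping to the
#' breakage threshold at the drawn breakage time and relaxing exponentially
#' to its final level; and gives every cell a cross-section area series
#' rising to the drawn maximal surface increase at the drawn time and
#' relaxing (Gaussian bump in time). Traces are emitted in absolute units
#' around a baseline of `f0` so the analysis side exercises its own
#' normalization. Ground truth is attached for every drawn quantity.
#'
#' @param params A `condition_params` (see [condition_presets()]).
#' @param n_cells Number of cells (default `params$n_cells`).
#' @param seed Integer seed; same seed, same cohort, bit for bit.
#' @param n_frames Frames per trace (default 300).
#' @param frame_interval Sampling interval in s (default 5).
#' @param shock_time Shock onset in s (default 60, leaving 12 baseline
#'   frames).
#' @param noise_sd Gaussian trace noise, relative units (default 0.05).
#' @param area_noise_frac Area noise as a fraction of the resting area
#'   (default 0.005).
#' @param f0 Baseline fluorescence, arbitrary units (default 100).
#' @param area0 Resting cross-section area, um^2 (default 450).
#' @return A `vld_cohort`: list with data frames `traces515` (`cell_id`,
#'   `roi_id`, `time_s`, `intensity`), `traces543` (`cell_id`, `time_s`,
#'   `intensity`), `areas` (`cell_id`, `time_s`, `area_um2`), ground-truth
#'   `truth_cells` and `truth_rois`, plus the generation settings.
#' @export
gen_cell_cohort <- function(params, n_cells = params$n_cells, seed = 1L,
                            n_frames = 300L, frame_interval = 5,
                            shock_time = 60, noise_sd = 0.05,
                            area_noise_frac = 0.005, f0 = 100, area0 = 450) {
  stopifnot(inherits(params, "condition_params"))
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  times <- seq(0, by = frame_interval, length.out = n_frames)
  if (sum(times < shock_time) < 3L) {
    stop("shock_time leaves fewer than 3 baseline frames", call. = FALSE)
  }
  with_seed(seed, {
    counts <- draw_vld_counts(params, n_cells)
    broken <- stats::rbinom(n_cells, 1, params$breakage_prob) == 1L

    # per-cell surface dynamics
    inc <- rlnorm_ms(n_cells, params$surface_increase_mean, params$surface_increase_sd)
    tsm <- rlnorm_ms(n_cells, params$t_surface_max_mean, params$t_surface_max_sd)
    t_brk <- rlnorm_ms(n_cells, params$t_breakage_mean, params$t_breakage_sd)

    tr <- times - shock_time
    area_rows <- vector("list", n_cells)
    t543_rows <- vector("list", n_cells)
    roi_rows <- list()
    truth_rois <- list()
    for (i in seq_len(n_cells)) {
      bump <- ifelse(tr < 0, 0, exp(-((tr - tsm[i]) / (0.4 * tsm[i]))^2 / 2))
      area <- area0 * (1 + inc[i] / 100 * bump) +
        stats::rnorm(n_frames, 0, area0 * area_noise_frac)
      area_rows[[i]] <- data.frame(
        cell_id = i, time_s = times, area_um2 = pmax(area, 1e-3)
      )

      if (broken[i]) {
        # step to the breakage threshold at t_breakage, then an exponential
        # approach to the final fill level
        m_final <- max(rlnorm_ms(1, 15, 3), 10.5)
        rel <- ifelse(tr < t_brk[i], 0,
          10 + (m_final - 10) * (1 - exp(-(tr - t_brk[i]) / 20))
        )
      } else {
        rel <- rep(0, n_frames)
      }
      y543 <- f0 * (1 + rel) + f0 * stats::rnorm(n_frames, 0, noise_sd)
      t543_rows[[i]] <- data.frame(cell_id = i, time_s = times, intensity = pmax(y543, 0))

      if (counts[i] > 0L) {
        tm <- rlnorm_ms(counts[i], params$tvmax_mean, params$tvmax_sd)
        vm <- rlnorm_ms(counts[i], params$vmax_mean, params$vmax_sd)
        A <- rlnorm_ms(counts[i], params$plateau_mean, params$plateau_sd)
        k <- 4 * vm / A
        for (j in seq_len(counts[i])) {
          rel515 <- A[j] / (1 + exp(-k[j] * (tr - tm[j])))
          y <- f0 * (1 + rel515) + f0 * stats::rnorm(n_frames, 0, noise_sd)
          roi_rows[[length(roi_rows) + 1L]] <- data.frame(
            cell_id = i, roi_id = j, time_s = times, intensity = pmax(y, 0)
          )
          truth_rois[[length(truth_rois) + 1L]] <- data.frame(
            cell_id = i, roi_id = j, tvmax = tm[j], vmax = vm[j], plateau = A[j]
          )
        }
      }
    }

    truth_cells <- data.frame(
      cell_id = seq_len(n_cells),
      vld_count = counts,
      broken = broken,
      t_breakage = ifelse(broken, t_brk, NA_real_),
      surface_increase_pct = inc,
      t_surface_max = tsm
    )
    structure(
      list(
        condition = params$label,
        traces515 = if (length(roi_rows)) do.call(rbind, roi_rows) else
          data.frame(cell_id = integer(), roi_id = integer(), time_s = numeric(), intensity = numeric()),
        traces543 = do.call(rbind, t543_rows),
        areas = do.call(rbind, area_rows),
        truth_cells = truth_cells,
        truth_rois = if (length(truth_rois)) do.call(rbind, truth_rois) else
          data.frame(cell_id = integer(), roi_id = integer(), tvmax = numeric(), vmax = numeric(), plateau = numeric()),
        shock_time = shock_time, frame_interval = frame_interval,
        n_frames = n_frames, f0 = f0, noise_sd = noise_sd,
        params = params, seed = as.integer(seed)
      ),
      class = "vld_cohort"
    )
  })
}

#' @export
print.vld_cohort <- function(x, ...) {
  cat(sprintf(
    "<vld_cohort> condition %s: %d cells, %d VLD traces, seed %d\n",
    x$condition, nrow(x$truth_cells), nrow(x$truth_rois), x$seed
  ))
  invisible(x)
}

#' Analyze a cohort with the trace pipeline
#'
#' Runs the full trace-analysis chain on a generated (or equivalently
#' structured) cohort: normalization and kinetics extraction per VLD trace,
#' VLD counting per cell (number of ROI traces with a detected formation
#' event), breakage calling on the 543-nm channel, and surface metrics from
#' the area series.
#'
#' @param cohort A `vld_cohort` (see [gen_cell_cohort()]).
#' @param breakage_threshold Relative-intensity breakage threshold
#'   (default 10).
#' @param ... Further arguments passed to [extract_kinetics()].
#' @return List with `kinetics` (per ROI), `cells` (per cell: `vld_count`,
#'   `broken`, `t_breakage`, `surface_increase_pct`, `t_surface_max`),
#'   `count_bins` and `summary` (the condition mean/SEM table).
#' @export
analyze_cohort <- function(cohort, breakage_threshold = 10, ...) {
  stopifnot(inherits(cohort, "vld_cohort"))
  shock <- cohort$shock_time

  kin <- list()
  tr <- cohort$traces515
  if (nrow(tr)) {
    for (key in split(seq_len(nrow(tr)), interaction(tr$cell_id, tr$roi_id, drop = TRUE))) {
      d <- tr[key, ]
      trace <- fluorescence_trace(d$time_s, d$intensity, channel = 515, shock_time = shock)
      k <- extract_kinetics(normalize_trace(trace), ...)
      kin[[length(kin) + 1L]] <- data.frame(
        cell_id = d$cell_id[1], roi_id = d$roi_id[1],
        event_detected = k$event_detected, t0 = k$t0, vmax = k$vmax,
        tvmax = k$tvmax, plateau = k$plateau
      )
    }
  }
  kinetics <- if (length(kin)) do.call(rbind, kin) else
    data.frame(
      cell_id = integer(), roi_id = integer(), event_detected = logical(),
      t0 = numeric(), vmax = numeric(), tvmax = numeric(), plateau = numeric()
    )

  cells <- cohort$truth_cells["cell_id"]
  detected <- kinetics[kinetics$event_detected, , drop = FALSE]
  cnt <- table(factor(detected$cell_id, levels = cells$cell_id))
  cells$vld_count <- as.integer(cnt)

  brk <- lapply(split(cohort$traces543, cohort$traces543$cell_id), function(d) {
    trace <- fluorescence_trace(d$time_s, d$intensity, channel = 543, shock_time = shock)
    b <- classify_breakage(normalize_trace(trace), threshold = breakage_threshold)
    data.frame(cell_id = d$cell_id[1], broken = b$broken, t_breakage = b$t_breakage)
  })
  brk <- do.call(rbind, brk)
  cells <- merge(cells, brk, by = "cell_id", sort = TRUE)

  surf <- lapply(split(cohort$areas, cohort$areas$cell_id), function(d) {
    s <- surface_metrics(d$time_s, d$area_um2, shock_time = shock)
    data.frame(
      cell_id = d$cell_id[1],
      surface_increase_pct = s$surface_increase_pct,
      t_surface_max = s$t_surface_max
    )
  })
  cells <- merge(cells, do.call(rbind, surf), by = "cell_id", sort = TRUE)

  # per-cell quantities summarize over cells, per-ROI kinetics over VLDs
  summ <- summarize_condition(
    cells[, c("vld_count", "surface_increase_pct", "t_surface_max", "broken")],
    condition = cohort$condition
  )
  if (sum(kinetics$event_detected) >= 2L) {
    summ <- rbind(
      summ,
      summarize_condition(
        kinetics[kinetics$event_detected, c("t0", "vmax", "tvmax", "plateau")],
        condition = cohort$condition
      )
    )
  }
  list(
    kinetics = kinetics,
    cells = cells,
    count_bins = bin_vld_counts(cells$vld_count),
    summary = summ
  )
}
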