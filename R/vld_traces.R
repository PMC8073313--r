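# Fluorescence-trace analysis for VLD formation under osmotic downshock:
# baseline normalization, formation kinetics (t0, Vmax, tVmax, plateau),
# breakage calling at 543 nm, VLD-count binning, and surface-expansion
# metrics from cross-section area series.

#' Construct a fluorescence trace
#'
#' A per-ROI time series of fluorescence recorded at the default 5-s frame
#' interval, with the osmotic downshock onset marked so that at least three
#' pre-shock samples are available for baseline estimation.
#'
#' @param times Acquisition times in s, strictly increasing.
#' @param values Fluorescence in arbitrary units, >= 0.
#' @param channel Emission channel: 515 (membrane, VLD formation) or 543
#'   (cytoplasmic fill upon breakage).
#' @param shock_time Osmotic downshock onset in s.
#' @return A `fluorescence_trace` object.
#' @export
fluorescence_trace <- function(times, values, channel = 515, shock_time = 0) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("fluorescence values must be >= 0", call. = FALSE)
  if (!channel %in% c(515, 543)) stop("channel must be 515 or 543", call. = FALSE)
  if (sum(times < shock_time) < 3L) {
    stop("need >= 3 pre-shock samples for baseline estimation", call. = FALSE)
  }
  structure(
    list(
      times = as.numeric(times), values = as.numeric(values),
      channel = channel, shock_time = shock_time
    ),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> %d samples @ %g nm, shock at %g s\n",
    length(x$times), x$channel, x$shock_time
  ))
  invisible(x)
}

#' Normalize a trace to basal fluorescence
#'
#' The baseline F0 is the mean of the pre-shock samples. The default mode
#' returns the relative fluorescence (F - F0)/F0, whose pre-shock mean is ~0;
#' `mode = "ratio"` returns F/F0 instead.
#'
#' @param trace A [fluorescence_trace()].
#' @param mode `"relative"` for (F - F0)/F0 (default) or `"ratio"` for F/F0.
#' @return A `fluorescence_trace` in dimensionless units, with attributes
#'   `f0` (baseline) and `baseline_sd` (pre-shock sd of the output).
#' @export
normalize_trace <- function(trace, mode = c("relative", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fluorescence_trace"))
  pre <- trace$times < trace$shock_time
  f0 <- mean(trace$values[pre])
  if (!is.finite(f0) || f0 <= 0) {
    stop("degenerate baseline: pre-shock mean fluorescence is not positive",
      call. = FALSE
    )
  }
  vals <- if (mode == "relative") (trace$values - f0) / f0 else trace$values / f0
  out <- trace
  out$values <- vals
  attr(out, "f0") <- f0
  attr(out, "baseline_sd") <- stats::sd(vals[pre])
  attr(out, "normalized") <- mode
  out
}

#' Extract VLD-formation kinetics from a normalized trace
#'
#' Works on the relative-fluorescence trace of one VLD region of interest.
#' The onset `t0` is the first post-shock time at which the smoothed trace
#' exceeds `baseline_noise_k` times the pre-shock noise sd for `run_length`
#' consecutive samples. The maximal formation rate `Vmax` is the maximum of
#' the Savitzky-Golay first derivative over the rising phase, i.e. between
#' `t0` and the first attainment of 95% of the plateau (restricting the
#' search to the rise keeps the noise maxima of the flat plateau tail from
#' inflating `Vmax` and dragging `tVmax` late); `tVmax` is the time of that
#' maximum. The plateau is the mean of the final `plateau_fraction` of
#' samples (or the asymptote of a logistic fit with
#' `plateau_mode = "logistic"`). All times are reported relative to the
#' shock.
#'
#' @param trace A trace normalized by [normalize_trace()] (relative mode).
#' @param window Odd Savitzky-Golay window length in samples (default 7).
#' @param order Polynomial order of the smoother (default 2).
#' @param baseline_noise_k Onset threshold in baseline sd units (default 3).
#' @param run_length Consecutive supra-threshold samples required (default 3).
#' @param plateau_fraction Final fraction of samples averaged for the
#'   plateau (default 0.1).
#' @param plateau_mode `"tail"` (default) or `"logistic"` (asymptote of a
#'   self-starting logistic fit, falling back to the tail mean if the fit
#'   fails).
#' @return A `kinetics_result`: list with `event_detected`, `t0`, `vmax`,
#'   `tvmax`, `plateau` (the last four `NA` when no event is detected).
#' @export
extract_kinetics <- function(trace, window = 7L, order = 2L,
                             baseline_noise_k = 3, run_length = 3L,
                             plateau_fraction = 0.1,
                             plateau_mode = c("tail", "logistic")) {
  plateau_mode <- match.arg(plateau_mode)
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is.null(attr(trace, "normalized"))) {
    stop("trace must be normalized with normalize_trace() first", call. = FALSE)
  }
  t <- trace$times
  y <- trace$values
  if (length(y) < window) stop("trace shorter than the smoothing window", call. = FALSE)
  dt <- mean(diff(t))
  sm <- sg_apply(y, window, order, deriv = 0L)
  dv <- sg_apply(y, window, order, deriv = 1L) / dt

  sigma_b <- attr(trace, "baseline_sd")
  if (!is.finite(sigma_b) || sigma_b == 0) sigma_b <- stats::sd(y[t < trace$shock_time])
  thresh <- baseline_noise_k * sigma_b

  none <- structure(
    list(
      event_detected = FALSE, t0 = NA_real_, vmax = NA_real_,
      tvmax = NA_real_, plateau = NA_real_
    ),
    class = "kinetics_result"
  )

  over <- !is.na(sm) & sm > thresh & t > trace$shock_time
  r <- rle(over)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0L) return(none)
  i0 <- sum(r$lengths[seq_len(hit[1] - 1L)]) + 1L

  n <- length(y)
  tail_idx <- seq.int(max(1L, floor(n * (1 - plateau_fraction)) + 1L), n)
  plateau <- mean(y[tail_idx])
  if (plateau_mode == "logistic") {
    fit <- tryCatch(
      stats::nls(y ~ A / (1 + exp(-k * (t - tm))),
        start = list(A = plateau, k = 4 * max(dv, na.rm = TRUE) / max(plateau, 1e-6), tm = t[i0]),
        control = stats::nls.control(warnOnly = TRUE)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) plateau <- stats::coef(fit)[["A"]]
  }
  if (!is.finite(plateau) || plateau <= 0) return(none)

  # rising phase: from onset to first attainment of 95% of the plateau
  reach <- which(!is.na(sm) & sm >= 0.95 * plateau & seq_len(n) >= i0)
  i_end <- if (length(reach)) reach[1] else n
  sel <- seq.int(i0, max(i_end, min(i0 + 2L, n)))
  sel <- sel[!is.na(dv[sel])]
  if (length(sel) == 0L) return(none)

  i_max <- sel[which.max(dv[sel])]
  vmax <- dv[i_max]
  if (!is.finite(vmax) || vmax <= 0) return(none)

  structure(
    list(
      event_detected = TRUE,
      t0 = t[i0] - trace$shock_time,
      vmax = vmax,
      tvmax = t[i_max] - trace$shock_time,
      plateau = plateau
    ),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  if (!x$event_detected) {
    cat("<kinetics_result> no VLD-formation event detected\n")
  } else {
    cat(sprintf(
      "<kinetics_result> t0 = %.1f s, Vmax = %.4f 1/s, tVmax = %.1f s, plateau = %.3f\n",
      x$t0, x$vmax, x$tvmax, x$plateau
    ))
  }
  invisible(x)
}

#' Call cell breakage from the 543-nm channel
#'
#' Upon membrane rupture the dye floods the cytoplasm and the relative
#' fluorescence at 543 nm rises steeply; relative intensities at or above the
#' threshold (default 10) are called bona fide breakage. The crossing time is
#' interpolated linearly between samples.
#'
#' @param trace543 A 543-nm trace normalized by [normalize_trace()].
#' @param threshold Relative-intensity breakage threshold (default 10).
#' @return A `breakage_call`: list with `broken`, `relative_intensity_max`,
#'   `t_breakage` (s relative to shock; `NA` when not broken).
#' @export
classify_breakage <- function(trace543, threshold = 10) {
  stopifnot(inherits(trace543, "fluorescence_trace"))
  if (is.null(attr(trace543, "normalized"))) {
    stop("trace must be normalized with normalize_trace() first", call. = FALSE)
  }
  y <- trace543$values
  t <- trace543$times
  m <- max(y)
  broken <- m >= threshold
  t_breakage <- NA_real_
  if (broken) {
    i <- which(y >= threshold)[1]
    if (i == 1L) {
      t_breakage <- t[1] - trace543$shock_time
    } else {
      frac <- (threshold - y[i - 1]) / (y[i] - y[i - 1])
      t_breakage <- t[i - 1] + frac * (t[i] - t[i - 1]) - trace543$shock_time
    }
  }
  structure(
    list(broken = broken, relative_intensity_max = m, t_breakage = t_breakage),
    class = "breakage_call"
  )
}

#' @export
print.breakage_call <- function(x, ...) {
  if (x$broken) {
    cat(sprintf(
      "<breakage_call> broken at t = %.1f s (max relative intensity %.1f)\n",
      x$t_breakage, x$relative_intensity_max
    ))
  } else {
    cat(sprintf(
      "<breakage_call> intact (max relative intensity %.2f)\n",
      x$relative_intensity_max
    ))
  }
  invisible(x)
}

#' Bin per-cell VLD counts into the standard distribution
#'
#' Bins are 0, 1-5, 6-10 and more than 10 VLDs per cell.
#'
#' @param counts Non-negative integer vector, one count per cell.
#' @return Named percentages (`"0"`, `"1-5"`, `"6-10"`, `">10"`) summing
#'   to 100.
#' @export
bin_vld_counts <- function(counts) {
  if (length(counts) == 0L) stop("empty count list", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  bins <- c(
    sum(counts == 0),
    sum(counts >= 1 & counts <= 5),
    sum(counts >= 6 & counts <= 10),
    sum(counts > 10)
  )
  stats::setNames(bins / length(counts) * 100, c("0", "1-5", "6-10", ">10"))
}

#' Surface-expansion metrics from a cell cross-section area series
#'
#' Adhered myoblasts are treated as hemispheres, so the cross-section area is
#' proportional to the hemisphere surface and percent changes in area equal
#' percent changes in surface. The initial surface is the pre-shock mean
#' area; the maximal post-shock area (of a lightly smoothed series, moving
#' mean of `smooth` samples, to keep single-frame noise from setting the
#' maximum) gives `surface_increase_pct` and its time `t_surface_max`
#' (relative to shock).
#'
#' @param times Times in s.
#' @param areas Cross-section areas in um^2, > 0.
#' @param shock_time Osmotic downshock onset in s.
#' @param smooth Odd moving-mean window (samples) applied before locating the
#'   maximum; 1 disables smoothing.
#' @return List with `surface_increase_pct`, `t_surface_max` and `degenerate`
#'   (`TRUE` when the series never rises above the initial surface).
#' @export
surface_metrics <- function(times, areas, shock_time = 0, smooth = 5L) {
  stopifnot(length(times) == length(areas))
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  pre <- times < shock_time
  if (!any(pre)) stop("need >= 1 pre-shock sample", call. = FALSE)
  a0 <- mean(areas[pre])
  sm <- areas
  if (smooth > 1L) {
    f <- stats::filter(areas, rep(1 / smooth, smooth), sides = 2)
    sm <- ifelse(is.na(f), areas, as.numeric(f))
  }
  post <- which(times >= shock_time)
  i_max <- post[which.max(sm[post])]
  inc <- (sm[i_max] - a0) / a0 * 100
  degenerate <- inc <= 0
  list(
    surface_increase_pct = max(inc, 0),
    t_surface_max = times[i_max] - shock_time,
    degenerate = degenerate
  )
}

#' Summarize per-cell measurements for one condition
#'
#' Produces the per-condition mean, SEM (= SD/sqrt(n)) and n for each
#' measured quantity, the way condition-level panels report them.
#'
#' @param records Data frame with any of the columns `vld_count`, `t0`,
#'   `vmax`, `tvmax`, `plateau`, `surface_increase_pct`, `t_surface_max`,
#'   `broken`.
#' @param condition Condition label for the output.
#' @return Data frame with one row per quantity: `condition`, `quantity`,
#'   `mean`, `sem`, `n`. The breakage fraction is reported as a proportion
#'   with a binomial SEM.
#' @export
summarize_condition <- function(records, condition = "condition") {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) stop("need >= 2 records per condition", call. = FALSE)
  quantities <- intersect(
    c(
      "vld_count", "t0", "vmax", "tvmax", "plateau",
      "surface_increase_pct", "t_surface_max"
    ),
    names(records)
  )
  rows <- lapply(quantities, function(q) {
    s <- mean_sem(records[[q]])
    data.frame(
      condition = condition, quantity = q,
      mean = s[["mean"]], sem = s[["sem"]], n = s[["n"]],
      stringsAsFactors = FALSE
    )
  })
  if ("broken" %in% names(records)) {
    b <- records$broken[!is.na(records$broken)]
    n <- length(b)
    p <- mean(b)
    rows <- c(rows, list(data.frame(
      condition = condition, quantity = "breakage_fraction",
      mean = p, sem = if (n >= 2) sqrt(p * (1 - p) / n) else NA_real_, n = n,
      stringsAsFactors = FALSE
    )))
  }
  do.call(rbind, rows)
}
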