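# VLD spot detection in time-lapse image stacks and the matching synthetic
# stack generator. Stacks are in-memory numeric arrays (height x width x
# frames); no binary image formats are involved.

# Separable Gaussian blur of a matrix (reflective edges).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Construct an image stack
#'
#' @param frames Numeric array height x width x n_frames.
#' @param pixel_size Pixel size in um (default 0.13).
#' @param frame_interval Frame interval in s (default 5).
#' @param channel Emission channel (default 515).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size = 0.13, frame_interval = 5,
                        channel = 515) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(
    list(
      frames = frames, pixel_size = pixel_size,
      frame_interval = frame_interval, channel = channel
    ),
    class = "image_stack"
  )
}

#' Detect VLD spots in an image stack
#'
#' Detects bright, approximately circular spots of diameter `d_min`..`d_max`
#' um inside the cell mask on the final frame (where VLDs are fully formed)
#' and confirms each candidate backward over the last `confirm_frames`
#' frames. Detection is a difference-of-Gaussians band-pass followed by
#' local-maximum extraction with a minimum separation of one expected spot
#' diameter and a robust (median + k * MAD) threshold. Deterministic given
#' its parameters.
#'
#' @param stack An [image_stack()] (515-nm channel).
#' @param mask Logical matrix (height x width): cell interior.
#' @param d_min,d_max Expected spot diameter range in um (defaults 1 and 3).
#' @param k_thresh Threshold in MAD units above the in-mask median of the
#'   band-passed image (default 6).
#' @param confirm_frames Trailing frames over which a spot must persist
#'   (default 3).
#' @return Data frame of ROIs: `row`, `col` (px), `radius_px`, `radius_um`.
#' @export
detect_vlds <- function(stack, mask, d_min = 1, d_max = 3, k_thresh = 6,
                        confirm_frames = 3L) {
  stopifnot(inherits(stack, "image_stack"), is.matrix(mask))
  dims <- dim(stack$frames)
  if (!all(dim(mask) == dims[1:2])) stop("mask shape must match frames", call. = FALSE)
  if (!any(mask)) stop("empty cell mask", call. = FALSE)
  px <- stack$pixel_size
  d_min_px <- d_min / px
  d_max_px <- d_max / px

  last <- stack$frames[, , dims[3]]
  # fill the outside of the cell with the in-mask median so the mask
  # boundary produces no band-pass edge response
  bg_med <- stats::median(last[mask])
  filled <- last
  filled[!mask] <- bg_med
  s1 <- d_min_px / 4
  s2 <- d_max_px / 2
  dog <- gaussian_blur(filled, s1) - gaussian_blur(filled, s2)

  vals <- dog[mask]
  med <- stats::median(vals)
  # lower-tail noise scale: spots only push the distribution upward
  noise_scale <- (med - stats::quantile(vals, 0.1587, names = FALSE)) /
    stats::qnorm(0.8413)
  thr <- med + k_thresh * max(noise_scale, 1e-12)

  r_sep <- max(1L, round(d_min_px)) # one expected diameter between spots
  H <- dims[1]; W <- dims[2]
  cand <- which(mask & dog > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(
      row = integer(), col = integer(),
      radius_px = numeric(), radius_um = numeric()
    ))
  }
  # local maxima within the separation window
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rr <- max(1L, r0 - r_sep):min(H, r0 + r_sep)
    cc <- max(1L, c0 - r_sep):min(W, c0 + r_sep)
    keep[i] <- dog[r0, c0] >= max(dog[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) > 1L) {
    # enforce the minimum separation between accepted spots (brightest wins)
    o <- order(dog[cand], decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    sel <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!sel[i]) next
      if (i < nrow(cand)) {
        later <- (i + 1):nrow(cand)
        d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
        sel[later][d2 < r_sep^2] <- FALSE
      }
    }
    cand <- cand[sel, , drop = FALSE]
  }

  # backward confirmation: the raw signal at the spot must stay elevated
  # over the trailing frames
  if (dims[3] >= confirm_frames && nrow(cand) > 0L) {
    bg <- stats::median(last[mask])
    noise <- stats::mad(last[mask])
    ok <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r0 <- cand[i, 1]; c0 <- cand[i, 2]
      rr <- max(1L, r0 - 1L):min(H, r0 + 1L)
      cc <- max(1L, c0 - 1L):min(W, c0 + 1L)
      for (f in (dims[3] - confirm_frames + 1L):dims[3]) {
        if (mean(stack$frames[rr, cc, f]) <= bg + 2 * noise) {
          ok[i] <- FALSE
          break
        }
      }
    }
    cand <- cand[ok, , drop = FALSE]
  }

  radius_px <- rep((d_min_px + d_max_px) / 4, nrow(cand))
  data.frame(
    row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
    radius_px = radius_px, radius_um = radius_px * px
  )
}

#' Generate a synthetic single-cell image stack
#'
#' Renders one cell (disk mask) whose VLDs are Gaussian spots appearing
#' with logistic intensity kinetics, over a constant background with
#' Poisson-Gaussian pixel noise. SNR is the final-frame spot peak amplitude
#' over the background noise sd.
#'
#' @param n_spots Number of VLD spots.
#' @param size Frame side in px (default 96).
#' @param n_frames Frames (default 6; spots reach full intensity by the
#'   final frame).
#' @param spot_diameter_um Spot diameter in um (default 1.8).
#' @param snr Peak signal-to-noise ratio (default 10).
#' @param pixel_size um per px (default 0.13).
#' @param frame_interval s between frames (default 5).
#' @param background Background level, counts (default 50).
#' @param seed Integer seed.
#' @return List with `stack` (an [image_stack()]), `mask`, and `truth`
#'   (data frame `row`, `col` of the true spot centers).
#' @export
gen_image_stack <- function(n_spots, size = 96L, n_frames = 6L,
                            spot_diameter_um = 1.8, snr = 10,
                            pixel_size = 0.13, frame_interval = 5,
                            background = 50, seed = 1L) {
  stopifnot(n_spots >= 0L, size >= 32L, n_frames >= 3L)
  center <- (size + 1) / 2
  radius <- size * 0.42
  rc <- expand.grid(row = seq_len(size), col = seq_len(size))
  mask <- matrix((rc$row - center)^2 + (rc$col - center)^2 <= radius^2, size, size)

  sigma_px <- spot_diameter_um / pixel_size / 2.355 # FWHM -> sd
  noise_sd <- sqrt(background) # Poisson-dominated
  amp <- snr * noise_sd

  with_seed(seed, {
    # non-overlapping spot centers inside the cell (>= 2 diameters apart)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    min_d2 <- (1.3 * spot_diameter_um / pixel_size)^2
    while (nrow(centers) < n_spots) {
      tries <- tries + 1L
      if (tries > 20000L) stop("could not place spots without overlap", call. = FALSE)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (radius - 2 * sigma_px)
      p <- c(center + rad * sin(ang), center + rad * cos(ang))
      if (nrow(centers) == 0L ||
        all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >= min_d2)) {
        centers <- rbind(centers, p)
      }
    }

    frames <- array(0, dim = c(size, size, n_frames))
    rowm <- matrix(rc$row, size, size)
    colm <- matrix(rc$col, size, size)
    for (f in seq_len(n_frames)) {
      # logistic rise reaching ~1 by the final frame
      g <- 1 / (1 + exp(-2 * (f - n_frames / 2)))
      img <- matrix(background * 0.2, size, size)
      img[mask] <- background
      if (n_spots > 0L) {
        for (s in seq_len(n_spots)) {
          img <- img + amp * g *
            exp(-((rowm - centers[s, 1])^2 + (colm - centers[s, 2])^2) /
              (2 * sigma_px^2))
        }
      }
      noisy <- stats::rpois(length(img), pmax(img, 0)) +
        stats::rnorm(length(img), 0, 1)
      frames[, , f] <- matrix(pmax(noisy, 0), size, size)
    }
    list(
      stack = image_stack(frames,
        pixel_size = pixel_size,
        frame_interval = frame_interval, channel = 515
      ),
      mask = mask,
      truth = data.frame(row = centers[, 1], col = centers[, 2])
    )
  })
}

#' Match detected spots to ground truth
#'
#' Greedy nearest matching within a tolerance radius; used to score
#' detection precision and recall against generated stacks.
#'
#' @param detected Data frame with `row`, `col`.
#' @param truth Data frame with `row`, `col`.
#' @param tol_px Match radius in px (default 8).
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
match_spots <- function(detected, truth, tol_px = 8) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  if (nrow(detected) > 0L && nrow(truth) > 0L) {
    for (i in seq_len(nrow(detected))) {
      d2 <- (truth$row - detected$row[i])^2 + (truth$col - detected$col[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && d2[j] <= tol_px^2) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(detected) - tp
  fn <- nrow(truth) - tp
  list(
    tp = tp, fp = fp, fn = fn,
    precision = if (nrow(detected) > 0) tp / nrow(detected) else NA_real_,
    recall = if (nrow(truth) > 0) tp / nrow(truth) else NA_real_
  )
}
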