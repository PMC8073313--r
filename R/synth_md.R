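# Synthetic coarse-grained membrane trajectories with imposed chain-angle
# and chain-extension laws, and pressure-tensor series with a known surface
# tension. These are the oracles for the MD post-processing module.

sample_law <- function(law, n) {
  if (is.function(law)) return(law(n))
  stopifnot(is.list(law), !is.null(law$type))
  switch(law$type,
    delta = rep(law$value, n),
    uniform = stats::runif(n, law$min, law$max),
    normal = stats::rnorm(n, law$mean, law$sd),
    mixture = {
      # two-component mixture of normals, e.g. compact vs expanded
      # chain-extension modes
      comp <- stats::rbinom(n, 1, law$weight1) == 1L
      out <- numeric(n)
      out[comp] <- stats::rnorm(sum(comp), law$mean1, law$sd1)
      out[!comp] <- stats::rnorm(sum(!comp), law$mean2, law$sd2)
      out
    },
    stop("unknown law type: ", law$type, call. = FALSE)
  )
}

#' Generate a synthetic membrane trajectory
#'
#' Builds a two-leaflet coarse-grained membrane whose chain first-to-last
#' vectors follow an imposed tilt-angle law (degrees from +z, sampled for
#' the upper leaflet and mirrored through the membrane plane for the lower
#' one) and an imposed first-to-last distance law (nm). Intermediate beads
#' are placed on the chain line. The imposed laws are the ground truth for
#' [angle_distribution()] and [angle_distance_histogram()].
#'
#' @param n_lipids_per_leaflet Lipids per leaflet.
#' @param angle_law List (`list(type = "delta", value = 45)`,
#'   `list(type = "uniform", min = 80, max = 100)`,
#'   `list(type = "normal", mean = , sd = )`) or a function of `n`.
#' @param distance_law Same forms, in nm (default delta at 1.5 nm). A
#'   `type = "mixture"` law imposes two modes.
#' @param beads_per_chain Beads per chain (default 6).
#' @param chains_per_lipid Chains per lipid (default 2: sn1 and sn2).
#' @param box Box `c(Lx, Ly, Lz)` in nm (default `c(30, 30, 10)`).
#' @param n_frames Frames to generate (default 10).
#' @param species Species label stored in the topology (default
#'   `"PC 38:6"`).
#' @param seed Integer seed.
#' @return List with `frames` (list of `trajectory_frame`), `topology`, and
#'   `truth` (the sampled per-chain-frame angles and distances).
#' @export
gen_trajectory <- function(n_lipids_per_leaflet = 64,
                           angle_law = list(type = "normal", mean = 30, sd = 10),
                           distance_law = list(type = "delta", value = 1.5),
                           beads_per_chain = 6L, chains_per_lipid = 2L,
                           box = c(30, 30, 10), n_frames = 10L,
                           species = "PC 38:6", seed = 1L) {
  stopifnot(beads_per_chain >= 2L, n_lipids_per_leaflet >= 1L, n_frames >= 1L)
  n_lipids <- 2L * n_lipids_per_leaflet
  n_chains <- n_lipids * chains_per_lipid
  beads_per_lipid <- beads_per_chain * chains_per_lipid
  n_beads <- n_lipids * beads_per_lipid

  leaflet <- rep(c("upper", "lower"), each = n_lipids_per_leaflet)
  topology <- do.call(rbind, lapply(seq_len(n_lipids), function(l) {
    do.call(rbind, lapply(seq_len(chains_per_lipid), function(c) {
      data.frame(
        lipid_id = l,
        species = species,
        chain = paste0("sn", c),
        sn_position = paste0("sn", c),
        bead_order = seq_len(beads_per_chain),
        bead_index = (l - 1L) * beads_per_lipid + (c - 1L) * beads_per_chain +
          seq_len(beads_per_chain),
        leaflet = leaflet[l],
        stringsAsFactors = FALSE
      )
    }))
  }))
  upper_chain <- rep(leaflet == "upper", each = chains_per_lipid)

  with_seed(seed, {
    frames <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      ang <- sample_law(angle_law, n_chains)
      ang <- pmin(pmax(ang, 0), 180)
      d <- abs(sample_law(distance_law, n_chains))
      if (any(d > min(box) / 2)) {
        stop("imposed chain extension exceeds half the box", call. = FALSE)
      }
      theta <- ang * pi / 180
      theta[!upper_chain] <- pi - theta[!upper_chain] # mirror lower leaflet
      phi <- stats::runif(n_chains, 0, 2 * pi)
      dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

      z0 <- ifelse(upper_chain, box[3] / 2 + 1, box[3] / 2 - 1)
      first <- cbind(
        stats::runif(n_chains, 0, box[1]),
        stats::runif(n_chains, 0, box[2]),
        z0
      )
      coords <- matrix(0, n_beads, 3)
      frac <- (seq_len(beads_per_chain) - 1) / (beads_per_chain - 1)
      for (c in seq_len(n_chains)) {
        idx <- (c - 1L) * beads_per_chain + seq_len(beads_per_chain)
        coords[idx, ] <- first[rep(c, beads_per_chain), ] +
          outer(frac * d[c], dir[c, ])
      }
      frames[[f]] <- trajectory_frame(coords, box = box, time = f - 1)
      truth[[f]] <- data.frame(
        frame = f, chain = seq_len(n_chains),
        angle_upper_frame = ang,
        angle = ifelse(upper_chain, ang, 180 - ang),
        distance = d
      )
    }
    list(frames = frames, topology = topology, truth = do.call(rbind, truth))
  })
}

#' Generate a pressure-tensor series with known surface tension
#'
#' Chooses the mean pressure anisotropy so the expected Kirkwood-Irving
#' per-interface tension equals `target_gamma`, then adds independent
#' Gaussian fluctuations to each diagonal component (pressure components of
#' small membrane patches fluctuate by hundreds of bar).
#'
#' @param target_gamma Target surface tension, mN/m.
#' @param Lz Box height, nm (default 10).
#' @param noise_sd Fluctuation sd per component, bar (default 100).
#' @param n Number of samples (default 1000).
#' @param dt_ns Sampling interval, ns (default 0.1).
#' @param seed Integer seed.
#' @return A `pressure_series` data frame.
#' @export
gen_pressure_series <- function(target_gamma, Lz = 10, noise_sd = 100,
                                n = 1000L, dt_ns = 0.1, seed = 1L) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  dP <- target_gamma / (0.05 * Lz) # bar
  with_seed(seed, {
    df <- data.frame(
      time_ns = seq(0, by = dt_ns, length.out = n),
      Pxx_bar = 1 + stats::rnorm(n, 0, noise_sd),
      Pyy_bar = 1 + stats::rnorm(n, 0, noise_sd),
      Pzz_bar = 1 + dP + stats::rnorm(n, 0, noise_sd),
      Lz_nm = Lz
    )
    class(df) <- c("pressure_series", "data.frame")
    df
  })
}
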