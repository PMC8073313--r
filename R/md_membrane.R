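# Post-processing of coarse-grained membrane simulations under imposed
# surface extension: extension planning, acyl-chain tilt-angle and
# chain-extension distributions, and Kirkwood-Irving surface tension from
# pressure-tensor time series.

#' Plan a stepwise membrane-plane extension series
#'
#' Each extension level e scales both in-plane box lengths by (1 + e/100),
#' so the membrane area grows by (1 + e/100)^2. Level 0 is the equilibrium
#' box.
#'
#' @param eq_box Equilibrium in-plane box `c(Lx, Ly)` in nm.
#' @param step_pct Per-step extension in percent (default 5).
#' @param max_pct Largest extension in percent (default 25).
#' @return An `extension_plan` data frame with `level_pct`, `Lx`, `Ly`,
#'   `area_ratio`.
#' @export
plan_extensions <- function(eq_box, step_pct = 5, max_pct = 25) {
  stopifnot(length(eq_box) == 2L)
  if (any(eq_box <= 0)) stop("box lengths must be positive", call. = FALSE)
  if (step_pct <= 0) stop("step_pct must be > 0", call. = FALSE)
  if (max_pct < step_pct) stop("max_pct must be >= step_pct", call. = FALSE)
  levels <- c(0, seq(step_pct, max_pct, by = step_pct))
  f <- 1 + levels / 100
  structure(
    data.frame(
      level_pct = levels,
      Lx = eq_box[1] * f,
      Ly = eq_box[2] * f,
      area_ratio = f^2
    ),
    class = c("extension_plan", "data.frame")
  )
}

#' Acyl-chain tilt angle
#'
#' Angle between the chain vector (last bead minus first bead, i.e. terminal
#' minus glycerol-proximal) and the +z membrane normal, in degrees on
#' [0, 180]. 0 means the chain points along +z (perpendicular to the
#' membrane plane, upper leaflet), 90 means in-plane, 180 along -z.
#'
#' @param first_bead,last_bead Numeric xyz coordinates (nm).
#' @return Angle in degrees.
#' @export
chain_angle <- function(first_bead, last_bead) {
  v <- as.numeric(last_bead) - as.numeric(first_bead)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length chain vector", call. = FALSE)
  acos(pmin(1, pmax(-1, v[3] / nv))) * 180 / pi
}

#' First-to-last bead distance of a chain
#'
#' Euclidean distance between the glycerol-proximal and terminal beads, the
#' chain-extension measure (nm).
#'
#' @param first_bead,last_bead Numeric xyz coordinates (nm).
#' @return Distance in nm.
#' @export
chain_extension_distance <- function(first_bead, last_bead) {
  sqrt(sum((as.numeric(last_bead) - as.numeric(first_bead))^2))
}

# Per-chain (last - first) vectors for all frames x selected chains.
# Returns a matrix with columns dx, dy, dz.
chain_vectors <- function(frames, topology, selection = NULL) {
  stopifnot(is.data.frame(topology))
  need <- c("lipid_id", "chain", "bead_order", "bead_index", "leaflet")
  miss <- setdiff(need, names(topology))
  if (length(miss)) stop("topology missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  top <- topology
  if (!is.null(selection)) {
    top <- selection(top)
    if (!is.data.frame(top) || nrow(top) == 0L) stop("empty selection", call. = FALSE)
  }
  key <- interaction(top$lipid_id, top$chain, drop = TRUE)
  first_idx <- tapply(seq_len(nrow(top)), key, function(i) i[which.min(top$bead_order[i])])
  last_idx <- tapply(seq_len(nrow(top)), key, function(i) i[which.max(top$bead_order[i])])
  fb <- top$bead_index[unlist(first_idx)]
  lb <- top$bead_index[unlist(last_idx)]
  if (length(frames) == 0L) stop("need >= 1 frame", call. = FALSE)
  out <- lapply(frames, function(fr) {
    xyz <- fr$coordinates
    d <- xyz[lb, , drop = FALSE] - xyz[fb, , drop = FALSE]
    # flag chains apparently split across the periodic boundary
    if (any(abs(d) > rep(fr$box / 2, each = nrow(d)))) {
      warning("chain vector longer than half the box: check periodic imaging",
        call. = FALSE
      )
    }
    d
  })
  do.call(rbind, out)
}

#' Tilt-angle distribution over a trajectory
#'
#' Per-bin probability mass of the chain tilt angle pooled over all selected
#' chains and frames. With both leaflets pooled in a leaflet-symmetric
#' system the distribution is symmetric about 90 degrees (two lobes);
#' `fold = TRUE` maps each angle a to min(a, 180 - a) to merge the lobes.
#'
#' @param frames List of `trajectory_frame` objects (see
#'   [read_trajectory_table()] / [gen_trajectory()]).
#' @param topology Topology data frame (`lipid_id`, `chain`, `bead_order`,
#'   `bead_index`, `leaflet`, optionally `species`, `sn_position`).
#' @param selection Optional function filtering the topology data frame
#'   (e.g. `function(t) t[t$leaflet == "upper", ]`).
#' @param bin_width Bin width in degrees (default 2.5).
#' @param fold Fold to [0, 90] (default `FALSE`, matching two-lobe plots).
#' @return An `angle_distribution`: data frame with `bin_low`, `bin_high`,
#'   `mid`, `probability` (summing to 1).
#' @export
angle_distribution <- function(frames, topology, selection = NULL,
                               bin_width = 2.5, fold = FALSE) {
  v <- chain_vectors(frames, topology, selection)
  ang <- acos(pmin(1, pmax(-1, v[, 3] / sqrt(rowSums(v^2))))) * 180 / pi
  if (fold) ang <- pmin(ang, 180 - ang)
  top <- if (fold) 90 else 180
  edges <- seq(0, top, by = bin_width)
  if (edges[length(edges)] < top) edges <- c(edges, top)
  counts <- table(cut(ang, edges, include.lowest = TRUE))
  structure(
    data.frame(
      bin_low = edges[-length(edges)],
      bin_high = edges[-1],
      mid = (edges[-1] + edges[-length(edges)]) / 2,
      probability = as.numeric(counts) / length(ang)
    ),
    class = c("angle_distribution", "data.frame"),
    n_observations = length(ang), fold = fold
  )
}

#' Joint angle-by-distance distribution
#'
#' 2D probability mass of chain tilt angle vs first-to-last bead distance
#' over all selected chains and frames. The marginals equal the matching 1D
#' distributions exactly on the same binning.
#'
#' @inheritParams angle_distribution
#' @param angle_bin_width Angle bin width in degrees (default 2.5).
#' @param dist_breaks Distance bin edges in nm; default covers [0, 3] nm in
#'   0.05-nm bins.
#' @return List with `angle_mid`, `dist_mid`, `probability` (matrix angles x
#'   distances, summing to 1).
#' @export
angle_distance_histogram <- function(frames, topology, selection = NULL,
                                     angle_bin_width = 2.5,
                                     dist_breaks = seq(0, 3, by = 0.05),
                                     fold = FALSE) {
  v <- chain_vectors(frames, topology, selection)
  d <- sqrt(rowSums(v^2))
  ang <- acos(pmin(1, pmax(-1, v[, 3] / d))) * 180 / pi
  if (fold) ang <- pmin(ang, 180 - ang)
  top <- if (fold) 90 else 180
  a_edges <- seq(0, top, by = angle_bin_width)
  if (a_edges[length(a_edges)] < top) a_edges <- c(a_edges, top)
  if (max(d) > max(dist_breaks)) {
    dist_breaks <- c(dist_breaks, max(d) + 1e-9)
  }
  ai <- cut(ang, a_edges, include.lowest = TRUE)
  di <- cut(d, dist_breaks, include.lowest = TRUE)
  tab <- table(ai, di)
  list(
    angle_mid = (a_edges[-1] + a_edges[-length(a_edges)]) / 2,
    dist_mid = (dist_breaks[-1] + dist_breaks[-length(dist_breaks)]) / 2,
    probability = unclass(tab) / length(ang)
  )
}

#' Kirkwood-Irving surface tension from a pressure-tensor series
#'
#' Per frame, gamma = (Lz/2) * (Pzz - (Pxx + Pyy)/2) in bar nm, converted to
#' mN/m (1 bar nm = 0.1 mN/m), i.e. 0.05 * Lz\[nm\] * dP\[bar\] mN/m. The
#' factor 1/2 attributes the tension to each of the bilayer's two
#' interfaces; a stretched membrane (normal pressure above lateral) yields
#' gamma > 0. The reported value is the time average over the series; the
#' error is a block-averaged standard error.
#'
#' @param series A `pressure_series` (see [read_pressure_series()] /
#'   [gen_pressure_series()]): list or data frame with `time_ns`, `Pxx_bar`,
#'   `Pyy_bar`, `Pzz_bar`, `Lz_nm` (per frame or constant).
#' @param n_blocks Number of blocks for the error estimate (default 5).
#' @param per_interface Divide by the two interfaces (default `TRUE`).
#' @param unit_label Unit string echoed in the result, `"mN/m"` by default
#'   (some reports print the label nN/m for the same numbers).
#' @return List with `gamma`, `stderr`, `unit`, `per_frame` and metadata
#'   noting the two-interface convention.
#' @export
surface_tension <- function(series, n_blocks = 5L, per_interface = TRUE,
                            unit_label = "mN/m") {
  s <- as.data.frame(unclass(series), stringsAsFactors = FALSE)
  need <- c("Pxx_bar", "Pyy_bar", "Pzz_bar", "Lz_nm")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("pressure series missing: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(s)
  if (n < 2L) stop("need >= 2 pressure samples", call. = FALSE)
  if (any(s$Lz_nm <= 0)) stop("Lz must be positive", call. = FALSE)
  dP <- s$Pzz_bar - (s$Pxx_bar + s$Pyy_bar) / 2
  g <- s$Lz_nm * dP * 0.1 # bar nm -> mN/m
  if (per_interface) g <- g / 2
  gamma <- mean(g)
  if (n < n_blocks) {
    stop(sprintf("need >= %d samples for a %d-block error estimate", n_blocks, n_blocks),
      call. = FALSE
    )
  }
  blk <- split(g, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, 0)
  structure(
    list(
      gamma = gamma,
      stderr = stats::sd(bm) / sqrt(length(bm)),
      unit = unit_label,
      n_blocks = n_blocks,
      per_frame = g,
      convention = if (per_interface) "per interface (bilayer/2)" else "whole bilayer"
    ),
    class = "surface_tension"
  )
}

#' @export
print.surface_tension <- function(x, ...) {
  cat(sprintf(
    "<surface_tension> gamma = %.3f +/- %.3f %s (%d-block error, %s)\n",
    x$gamma, x$stderr, x$unit, x$n_blocks, x$convention
  ))
  invisible(x)
}

#' Area per lipid
#'
#' In-plane box area divided by the number of lipids per leaflet.
#'
#' @param box In-plane box `c(Lx, Ly)` in nm.
#' @param n_lipids_per_leaflet Lipids per leaflet, > 0.
#' @return Area per lipid in nm^2.
#' @export
area_per_lipid <- function(box, n_lipids_per_leaflet) {
  stopifnot(length(box) == 2L)
  if (n_lipids_per_leaflet <= 0) stop("n_lipids_per_leaflet must be > 0", call. = FALSE)
  box[1] * box[2] / n_lipids_per_leaflet
}
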