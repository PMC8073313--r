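# Readers and writers for the plain-text exchange formats: tabular
# trajectories, single-frame GRO files, chain topologies, pressure-tensor
# series and per-ROI trace tables.

#' Construct a trajectory frame
#'
#' @param coordinates n_beads x 3 matrix of bead coordinates (nm).
#' @param box Box lengths `c(Lx, Ly, Lz)` in nm.
#' @param time Frame time in ns.
#' @return A `trajectory_frame` object.
#' @export
trajectory_frame <- function(coordinates, box, time = 0) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 3L, length(box) == 3L)
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  structure(
    list(coordinates = unname(coordinates), box = as.numeric(box), time = time),
    class = "trajectory_frame"
  )
}

#' Read a tabular multi-frame trajectory
#'
#' The plain-text fallback trajectory format: one row per bead per frame
#' with columns `frame`, `bead_id`, `x`, `y`, `z`, `Lx`, `Ly`, `Lz`
#' (coordinates and box in nm), comma- or tab-separated.
#'
#' @param file Path to the table.
#' @param sep Field separator; `""` auto-detects.
#' @return List of `trajectory_frame`, ordered by frame index.
#' @export
read_trajectory_table <- function(file, sep = "") {
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("frame", "bead_id", "x", "y", "z", "Lx", "Ly", "Lz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  lapply(split(df, df$frame), function(fr) {
    fr <- fr[order(fr$bead_id), ]
    trajectory_frame(
      as.matrix(fr[, c("x", "y", "z")]),
      box = c(fr$Lx[1], fr$Ly[1], fr$Lz[1]),
      time = fr$frame[1]
    )
  })
}

#' Write a list of trajectory frames as a tabular trajectory
#'
#' @param frames List of `trajectory_frame`.
#' @param file Output path (CSV).
#' @export
write_trajectory_table <- function(frames, file) {
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    data.frame(
      frame = i, bead_id = seq_len(nrow(fr$coordinates)),
      x = fr$coordinates[, 1], y = fr$coordinates[, 2], z = fr$coordinates[, 3],
      Lx = fr$box[1], Ly = fr$box[2], Lz = fr$box[3]
    )
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read a single-frame GRO coordinate file
#'
#' Minimal fixed-width GROMACS GRO reader: title line, atom count, one line
#' per atom (positions in nm, columns 21-44), final box line. Velocities,
#' if present, are ignored.
#'
#' @param file Path to a `.gro` file.
#' @return A `trajectory_frame`; atom/residue names are attached as the
#'   attribute `atoms` (data frame with `res_id`, `res_name`, `atom_name`).
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 3L) stop("not a GRO file: too few lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3L) {
    stop("not a GRO file: bad atom count", call. = FALSE)
  }
  at <- lines[3:(n + 2)]
  xyz <- t(vapply(at, function(l) {
    c(
      as.numeric(substr(l, 21, 28)),
      as.numeric(substr(l, 29, 36)),
      as.numeric(substr(l, 37, 44))
    )
  }, numeric(3)))
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  fr <- trajectory_frame(xyz, box = box, time = 0)
  attr(fr, "atoms") <- data.frame(
    res_id = as.integer(substr(at, 1, 5)),
    res_name = trimws(substr(at, 6, 10)),
    atom_name = trimws(substr(at, 11, 15)),
    stringsAsFactors = FALSE
  )
  fr
}

#' Read a chain topology table
#'
#' Columns: `lipid_id`, `chain` (sn1/sn2), `sn_position`, `bead_order`
#' (1 = glycerol-proximal), `bead_index` (row into the coordinate matrix),
#' `leaflet` (upper/lower) and optionally `species`.
#'
#' @param file Path to a CSV/TSV file.
#' @param sep Field separator; `""` auto-detects.
#' @return Topology data frame.
#' @export
read_topology <- function(file, sep = "") {
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("lipid_id", "chain", "bead_order", "bead_index", "leaflet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a pressure-tensor time series
#'
#' The tabular equivalent of an energy-file extraction: columns `time_ns`,
#' `Pxx_bar`, `Pyy_bar`, `Pzz_bar`, `Lz_nm` (the last may be constant).
#'
#' @param file Path to a CSV/TSV file.
#' @param sep Field separator; `""` auto-detects.
#' @return A `pressure_series` data frame.
#' @export
read_pressure_series <- function(file, sep = "") {
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("time_ns", "Pxx_bar", "Pyy_bar", "Pzz_bar", "Lz_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$Lz_nm <= 0)) stop("Lz must be positive", call. = FALSE)
  class(df) <- c("pressure_series", "data.frame")
  df
}

#' Read a per-ROI fluorescence trace table
#'
#' Long-format table with columns `cell_id`, `roi_id`, `channel`, `time_s`,
#' `intensity`, as written by the synthetic generators and by typical
#' time-lapse ROI exports.
#'
#' @param file Path to a CSV/TSV file.
#' @param shock_time Shock onset in s, attached to every trace.
#' @param sep Field separator; `""` auto-detects.
#' @return Data frame with the above columns and the `shock_time` attribute.
#' @export
read_trace_table <- function(file, shock_time = 0, sep = "") {
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("cell_id", "roi_id", "channel", "time_s", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  attr(df, "shock_time") <- shock_time
  df
}
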