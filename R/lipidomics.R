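# Lipidomics profiling: species parsing, exact-mass annotation of PC peaks,
# double-bond indexes, DHA/AA ratios and cross-sample PCA.

PL_CLASSES <- c("PC", "PE", "PS", "PI")

# Monoisotopic atomic masses (Da)
.MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)
PROTON_MASS <- 1.007276

#' Parse a phospholipid species name
#'
#' Names follow the field convention `"<class> <x>:<y>"`, where `x` is the
#' total number of acyl-chain carbons over both chains and `y` the total
#' number of carbon-carbon double bonds (e.g. `"PC 38:4"`: 38 carbons, four
#' double bonds).
#'
#' @param name Character scalar, e.g. `"PC 38:4"`. Surrounding/internal
#'   whitespace variants are tolerated.
#' @return A `species_id`: list with `lipid_class`, `total_carbons`,
#'   `double_bonds`.
#' @examples
#' parse_species_name("PC 38:4")
#' @export
parse_species_name <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single character string", call. = FALSE)
  }
  m <- regmatches(name, regexec("^\\s*([A-Za-z]+)\\s+(\\d+)\\s*:\\s*(\\d+)\\s*$", name))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed species name: '%s' (expected '<class> <x>:<y>')", name),
      call. = FALSE
    )
  }
  cls <- m[2]
  if (!cls %in% PL_CLASSES) {
    stop(sprintf("unknown lipid class token: '%s'", cls), call. = FALSE)
  }
  species_id(cls, as.integer(m[3]), as.integer(m[4]))
}

#' Construct a species identifier
#'
#' @param lipid_class One of `"PC"`, `"PE"`, `"PS"`, `"PI"`.
#' @param total_carbons Total acyl-chain carbons (x).
#' @param double_bonds Total acyl-chain C=C double bonds (y).
#' @return A `species_id` object.
#' @export
species_id <- function(lipid_class, total_carbons, double_bonds) {
  lipid_class <- match.arg(lipid_class, PL_CLASSES)
  total_carbons <- as.integer(total_carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(total_carbons) || total_carbons < 2L) {
    stop("total_carbons must be an integer >= 2", call. = FALSE)
  }
  if (is.na(double_bonds) || double_bonds < 0L) {
    stop("double_bonds must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(
      lipid_class = lipid_class, total_carbons = total_carbons,
      double_bonds = double_bonds
    ),
    class = "species_id"
  )
}

#' @export
format.species_id <- function(x, ...) {
  sprintf("%s %d:%d", x$lipid_class, x$total_carbons, x$double_bonds)
}

#' @export
print.species_id <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a diacyl-PC species
#'
#' Elemental composition of a diacyl phosphatidylcholine with `x` total acyl
#' carbons and `y` double bonds is C(x+8) H(2x+16-2y) N O8 P; the mass is the
#' monoisotopic elemental sum. Each additional double bond removes one H2
#' (2.0156500638 Da). Only PC is supported; other classes are accepted
#' pre-annotated and never need a computed mass here.
#'
#' @param species A `species_id` with `lipid_class == "PC"`, or a species
#'   name string parseable by [parse_species_name()].
#' @return Monoisotopic mass in Da.
#' @examples
#' pc_monoisotopic_mass("PC 32:0") # 733.5622
#' @export
pc_monoisotopic_mass <- function(species) {
  if (is.character(species)) species <- parse_species_name(species)
  stopifnot(inherits(species, "species_id"))
  if (species$lipid_class != "PC") {
    stop(sprintf(
      "mass computation is only supported for PC (got %s)",
      species$lipid_class
    ), call. = FALSE)
  }
  x <- species$total_carbons
  y <- species$double_bonds
  (x + 8) * .MASS[["C"]] + (2 * x + 16 - 2 * y) * .MASS[["H"]] +
    .MASS[["N"]] + 8 * .MASS[["O"]] + .MASS[["P"]]
}

#' Build a species table
#'
#' A species table holds one sample's phospholipid species with relative
#' abundances expressed as percent of the class total. Abundances are
#' validated to sum to 100 within each lipid class.
#'
#' @param sample_label Sample name (organ or culture condition).
#' @param species Character vector of species names (`"PC 34:1"` style).
#' @param abundance_pct Relative abundances, percent of class total.
#' @param normalize If `TRUE`, renormalize abundances to 100 per class
#'   instead of erroring on unnormalized input.
#' @return A `species_table` data frame with columns `sample`, `class`,
#'   `species` (the `"x:y"` part), `abundance_pct`.
#' @export
species_table <- function(sample_label, species, abundance_pct, normalize = FALSE) {
  ids <- lapply(species, parse_species_name)
  cls <- vapply(ids, `[[`, "", "lipid_class")
  key <- vapply(ids, format, "")
  if (anyDuplicated(key)) {
    stop("duplicate species in table: ", paste(unique(key[duplicated(key)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(abundance_pct < 0)) stop("abundances must be non-negative", call. = FALSE)
  df <- data.frame(
    sample = sample_label,
    class = cls,
    species = sub("^[A-Z]+ ", "", key),
    abundance_pct = as.numeric(abundance_pct),
    stringsAsFactors = FALSE
  )
  for (cl in unique(df$class)) {
    i <- df$class == cl
    tot <- sum(df$abundance_pct[i])
    if (abs(tot - 100) > 1e-6) {
      if (normalize) {
        if (tot <= 0) stop("cannot normalize an all-zero class: ", cl, call. = FALSE)
        df$abundance_pct[i] <- df$abundance_pct[i] / tot * 100
      } else {
        stop(sprintf(
          "class %s abundances sum to %.6f, not 100; pass normalize = TRUE",
          cl, tot
        ), call. = FALSE)
      }
    }
  }
  class(df) <- c("species_table", "data.frame")
  df
}

#' Read a species table from CSV/TSV
#'
#' Expects columns `sample`, `class`, `species` (the `"x:y"` part) and
#' `abundance_pct`. One sample per file.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator; `""` (default) auto-detects comma vs tab.
#' @param normalize Passed to [species_table()].
#' @return A `species_table`.
#' @export
read_species_table <- function(file, sep = "", normalize = FALSE) {
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample", "class", "species", "abundance_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(df$sample)) != 1L) {
    stop("a species table holds exactly one sample per file", call. = FALSE)
  }
  species_table(df$sample[1], paste(df$class, df$species), df$abundance_pct,
    normalize = normalize
  )
}

#' Annotate a peak list against candidate PC species
#'
#' Each peak is assigned to the candidate whose adduct m/z is nearest in ppm
#' within the tolerance; a peak exactly equidistant (in ppm) from two
#' candidates is left unassigned with a warning. Intensities of assigned
#' peaks are summed per species and renormalized to percent of the class
#' total. Isotopologue overlap (the M+2 isotope of a `y+1` species on the M
#' peak of a `y` species) is ignored; see the package vignette.
#'
#' @param peaks Data frame with columns `mz` (Da) and `intensity` (>= 0).
#' @param candidates List of `species_id` objects (or species name strings);
#'   PC only.
#' @param tolerance_ppm Match tolerance in ppm (default 5).
#' @param adduct `"[M+H]+"` (positive mode, default for PC) or `"[M-H]-"`.
#' @param sample_label Label for the resulting table.
#' @return A `species_table` over the candidates that received signal.
#' @export
annotate_peaks <- function(peaks, candidates, tolerance_ppm = 5,
                           adduct = c("[M+H]+", "[M-H]-"),
                           sample_label = "sample") {
  adduct <- match.arg(adduct)
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  if (tolerance_ppm < 0) stop("negative tolerance", call. = FALSE)
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0", call. = FALSE)
  candidates <- lapply(candidates, function(s) {
    if (is.character(s)) parse_species_name(s) else s
  })
  cand_mass <- vapply(candidates, pc_monoisotopic_mass, 0)
  cand_mz <- cand_mass + if (adduct == "[M+H]+") PROTON_MASS else -PROTON_MASS
  cand_name <- vapply(candidates, format, "")

  intensity <- stats::setNames(numeric(length(candidates)), cand_name)
  for (i in seq_len(nrow(peaks))) {
    ppm <- abs(peaks$mz[i] - cand_mz) / cand_mz * 1e6
    within <- which(ppm <= tolerance_ppm)
    if (length(within) == 0L) next
    # ties at < 1e-6 ppm are indistinguishable at any real mass accuracy
    best <- within[ppm[within] <= min(ppm[within]) + 1e-6]
    if (length(best) > 1L) {
      warning(sprintf(
        "peak at m/z %.4f is equidistant (ppm) from %s; left unassigned",
        peaks$mz[i], paste(cand_name[best], collapse = " and ")
      ), call. = FALSE)
      next
    }
    intensity[best] <- intensity[best] + peaks$intensity[i]
  }
  if (sum(intensity) <= 0) {
    stop("no peak matched any candidate within tolerance", call. = FALSE)
  }
  species_table(sample_label, cand_name, intensity, normalize = TRUE)
}

#' Double-bond index of a species table
#'
#' Bins the per-class relative abundances by total double bonds into the four
#' standard categories: saturated (DB = 0), monounsaturated (DB = 1),
#' diunsaturated (DB = 2) and polyunsaturated (DB > 2).
#'
#' @param table A `species_table` (single sample).
#' @param lipid_class Which class to index (default `"PC"`).
#' @return Named numeric vector `c(db0, db1, db2, dbgt2)`, percentages
#'   summing to 100.
#' @export
db_index <- function(table, lipid_class = "PC") {
  stopifnot(inherits(table, "species_table"))
  df <- table[table$class == lipid_class, , drop = FALSE]
  if (nrow(df) == 0L) stop("no species of class ", lipid_class, call. = FALSE)
  tot <- sum(df$abundance_pct)
  if (abs(tot - 100) > 1e-6) {
    stop(sprintf("table not normalized: class %s sums to %.6f", lipid_class, tot),
      call. = FALSE
    )
  }
  y <- as.integer(sub("^\\d+:", "", df$species))
  c(
    db0 = sum(df$abundance_pct[y == 0]),
    db1 = sum(df$abundance_pct[y == 1]),
    db2 = sum(df$abundance_pct[y == 2]),
    dbgt2 = sum(df$abundance_pct[y > 2])
  )
}

#' DHA to AA ratio of PC species
#'
#' Ratio of the summed abundances of the DHA-containing PC species (36:6,
#' 38:6, 40:6) to the AA-containing ones (36:4, 38:4, 40:4).
#'
#' @param table A `species_table` (single sample).
#' @return Dimensionless ratio; `0` when no DHA species is present, `Inf`
#'   (with a warning) when the AA denominator is zero.
#' @export
dha_aa_ratio <- function(table) {
  stopifnot(inherits(table, "species_table"))
  pc <- table[table$class == "PC", , drop = FALSE]
  dha <- sum(pc$abundance_pct[pc$species %in% c("36:6", "38:6", "40:6")])
  aa <- sum(pc$abundance_pct[pc$species %in% c("36:4", "38:4", "40:4")])
  if (aa == 0) {
    if (dha == 0) return(0)
    warning("AA denominator is zero; ratio is infinite", call. = FALSE)
    return(Inf)
  }
  dha / aa
}

#' PCA of double-bond indexes across samples
#'
#' Mean-centered (unscaled) principal component analysis of a samples-by-bins
#' double-bond index matrix. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param indexes A matrix or data frame with one row per sample and the four
#'   DB-index columns, or a named list of `db_index()` outputs.
#' @return List with `scores`, `loadings` and `explained_variance_pct`
#'   (non-increasing, summing to 100).
#' @export
pca_db <- function(indexes) {
  if (is.list(indexes) && !is.data.frame(indexes)) {
    indexes <- do.call(rbind, indexes)
  }
  X <- as.matrix(indexes)
  if (nrow(X) < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  if (all(apply(X, 2, stats::var) < 1e-12)) {
    warning("rank-deficient input: all samples identical; no variance to decompose",
      call. = FALSE
    )
    return(list(
      scores = X * 0, loadings = NULL,
      explained_variance_pct = rep(NA_real_, min(nrow(X) - 1L, ncol(X)))
    ))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2
  list(
    scores = p$x,
    loadings = p$rotation,
    explained_variance_pct = ev / sum(ev) * 100
  )
}
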