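# Synthetic phospholipid species tables emulating the organ- and
# culture-condition-specific PC distributions, plus matching peak lists.

# Base PC abundance profiles (percent weights, renormalized after jitter).
# Shapes encode the qualitative signatures: muscle/heart dominated by the
# DHA species 38:6/40:6; brain monounsaturated (34:1 major); lung saturated
# (32:0); pancreas/liver diunsaturated with an AA component; untreated
# myoblasts DB = 1/2 with near-zero polyunsaturated content; AA-supplemented
# myoblasts gain 36:4/38:4; DHA-supplemented gain 38:6.
.SPECIES_PRESETS <- list(
  muscle = c(
    "PC 32:0" = 6, "PC 34:1" = 12, "PC 34:2" = 8, "PC 36:2" = 6,
    "PC 36:4" = 7, "PC 38:4" = 8, "PC 36:6" = 3, "PC 38:6" = 32, "PC 40:6" = 18
  ),
  heart = c(
    "PC 32:0" = 7, "PC 34:1" = 10, "PC 34:2" = 10, "PC 36:2" = 7,
    "PC 36:4" = 8, "PC 38:4" = 12, "PC 36:6" = 2, "PC 38:6" = 28, "PC 40:6" = 16
  ),
  brain = c(
    "PC 32:0" = 16, "PC 32:1" = 8, "PC 34:1" = 38, "PC 36:1" = 10,
    "PC 34:2" = 6, "PC 36:2" = 4, "PC 36:4" = 8, "PC 38:4" = 7, "PC 38:6" = 3
  ),
  lung = c(
    "PC 30:0" = 10, "PC 32:0" = 42, "PC 34:1" = 16, "PC 34:2" = 10,
    "PC 36:2" = 6, "PC 36:4" = 9, "PC 38:4" = 5, "PC 38:6" = 2
  ),
  pancreas = c(
    "PC 32:0" = 8, "PC 34:1" = 12, "PC 34:2" = 22, "PC 36:2" = 24,
    "PC 36:4" = 14, "PC 38:4" = 12, "PC 38:6" = 8
  ),
  liver = c(
    "PC 32:0" = 8, "PC 34:1" = 10, "PC 34:2" = 20, "PC 36:2" = 16,
    "PC 36:4" = 12, "PC 38:4" = 16, "PC 38:6" = 12, "PC 40:6" = 6
  ),
  NT = c(
    "PC 32:0" = 10, "PC 32:1" = 20, "PC 34:1" = 30, "PC 34:2" = 20,
    "PC 36:2" = 16, "PC 36:4" = 2, "PC 38:4" = 1, "PC 38:6" = 1
  ),
  AA = c(
    "PC 32:0" = 6, "PC 32:1" = 8, "PC 34:1" = 14, "PC 34:2" = 12,
    "PC 36:2" = 8, "PC 36:4" = 24, "PC 38:4" = 26, "PC 38:6" = 2
  ),
  DHA = c(
    "PC 32:0" = 6, "PC 32:1" = 8, "PC 34:1" = 14, "PC 34:2" = 12,
    "PC 36:2" = 8, "PC 36:4" = 3, "PC 38:4" = 4, "PC 38:6" = 35, "PC 40:6" = 10
  )
)

#' Generate a synthetic PC species table
#'
#' Draws a normalized PC species table for an organ or culture-condition
#' preset, with multiplicative lognormal jitter on the preset weights.
#' Optionally emits the matching positive-mode peak list ([M+H]+ m/z from
#' the exact masses) so the annotation chain can be exercised end to end.
#'
#' @param preset One of `"muscle"`, `"heart"`, `"brain"`, `"lung"`,
#'   `"pancreas"`, `"liver"` (organs) or `"NT"`, `"AA"`, `"DHA"` (culture
#'   conditions).
#' @param jitter Lognormal sd of the multiplicative weight jitter
#'   (default 0.1; 0 reproduces the preset weights exactly).
#' @param seed Integer seed.
#' @param peaks Also return a peak list (default `FALSE`).
#' @param ppm_error Mass error sd applied to peak m/z, ppm (default 1).
#' @return A `species_table`, or (with `peaks = TRUE`) a list with `table`
#'   and `peaks` (`mz`, `intensity`).
#' @export
gen_species_table <- function(preset, jitter = 0.1, seed = 1L, peaks = FALSE,
                              ppm_error = 1) {
  if (!preset %in% names(.SPECIES_PRESETS)) {
    stop(
      "unknown preset: ", preset, " (use ",
      paste(names(.SPECIES_PRESETS), collapse = ", "), ")",
      call. = FALSE
    )
  }
  w <- .SPECIES_PRESETS[[preset]]
  with_seed(seed, {
    if (jitter > 0) w <- w * stats::rlnorm(length(w), 0, jitter)
    tab <- species_table(preset, names(w), w, normalize = TRUE)
    if (!peaks) return(tab)
    mz <- vapply(names(w), function(s) pc_monoisotopic_mass(s) + PROTON_MASS, 0)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, ppm_error * 1e-6))
    list(
      table = tab,
      peaks = data.frame(mz = unname(mz), intensity = unname(w) * 1e4)
    )
  })
}
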