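#' Linear HU-to-density calibration line
#'
#' Apparent density is obtained from CT attenuation as
#' `rho = a + HU * b`, clamped from below at `floor` to avoid nonphysical
#' negative densities.  The default constants reproduce the cortical-core
#' density tests of the experiments this package emulates (intercept
#' 0.48 g/cm3).  Note on the slope: the published constant pair prints
#' the slope with a positive power-of-ten exponent (4.6 x 10^4), which
#' yields absurd densities (~10^7 g/cm3 at 200 HU); the default here
#' assumes a sign-of-exponent typo and uses 4.6 x 10^-4 g/cm3 per HU.  Both
#' constants are overridable, and the discrepancy is deliberately not
#' hidden: a warning documents the assumption when the default slope is
#' requested via `default_calibration()`.
#'
#' @param a intercept, g/cm3.
#' @param b slope, g/cm3 per HU.  A warning is emitted if `b <= 0`.
#' @param floor minimum density, g/cm3 (> 0).
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(a = 0.48, b = 4.6e-4, floor = 0.01) {
  if (!is.finite(a) || !is.finite(b)) stop("'a' and 'b' must be finite")
  if (!is.finite(floor) || floor <= 0) stop("'floor' must be > 0")
  if (b <= 0) warning("calibration slope b <= 0: density decreases with HU")
  structure(list(a = a, b = b, floor = floor), class = "calibration_line")
}

#' @rdname calibration_line
#' @param quiet suppress the startup message about the assumed slope
#'   exponent.
#' @export
default_calibration <- function(quiet = FALSE) {
  if (!quiet)
    message("using calibration slope b = 4.6e-4 g/cm3 per HU ",
            "(printed constant 4.6e4 read as an exponent-sign typo)")
  calibration_line()
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("calibration_line: rho = %.6g + HU * %.6g (floor %.3g g/cm3)\n",
              x$a, x$b, x$floor))
  invisible(x)
}

#' Fit the HU-to-density line from core samples
#'
#' Ordinary least squares through `(HU, density)` pairs measured on bone
#' cores, mirroring the density tests used to calibrate the imaging chain.
#'
#' @param samples data.frame (or 2-column matrix) with columns `hu` and
#'   `density` (g/cm3); at least 2 rows with non-identical HU.
#' @param floor density floor for the resulting line, g/cm3.
#' @return A [calibration_line()].
#' @export
fit_calibration <- function(samples, floor = 0.01) {
  samples <- as.data.frame(samples)
  if (ncol(samples) < 2L) stop("'samples' needs columns hu and density")
  if (!all(c("hu", "density") %in% names(samples)))
    names(samples)[1:2] <- c("hu", "density")
  hu <- samples$hu
  rho <- samples$density
  if (length(hu) < 2L) stop("need at least 2 calibration samples")
  if (stats::var(hu) == 0)
    stop("rank-deficient calibration: all HU values identical")
  b <- stats::cov(hu, rho) / stats::var(hu)
  a <- mean(rho) - b * mean(hu)
  calibration_line(a = a, b = b, floor = floor)
}

#' Apply the calibration to a volume
#'
#' Maps in-mask HU values through `rho = max(a + HU * b, floor)`.
#'
#' @param volume a [voxel_volume()].
#' @param line a [calibration_line()].
#' @return A `density_field`: list with `values` (3-D array, g/cm3; voxels
#'   outside the mask are `NA`), `mask`, and the `line` used.
#' @export
hu_to_density <- function(volume, line = calibration_line()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(line, "calibration_line"))
  rho <- array(NA_real_, dim(volume$values))
  rho[volume$mask] <- pmax(line$a + volume$values[volume$mask] * line$b,
                           line$floor)
  structure(list(values = rho, mask = volume$mask, spacing = volume$spacing,
                 origin = volume$origin, line = line),
            class = "density_field")
}

#' Invert the calibration for phantom ground truth
#'
#' For densities above the floor this is the exact inverse of
#' [hu_to_density()].
#'
#' @param rho densities, g/cm3.
#' @param line a [calibration_line()].
#' @return HU values.
#' @export
density_to_hu <- function(rho, line = calibration_line()) {
  if (line$b == 0) stop("cannot invert a calibration with zero slope")
  (rho - line$a) / line$b
}

#' Read / write a calibration line as JSON
#'
#' @param line a [calibration_line()].
#' @param file path to a JSON file.
#' @export
write_calibration <- function(line, file) {
  jsonlite::write_json(list(a = line$a, b = line$b, floor = line$floor),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  calibration_line(a = x$a, b = x$b, floor = x$floor)
}
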