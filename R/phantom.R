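#' Voxel volume container
#'
#' A minimal CT stand-in: a 3-D array of Hounsfield-unit values with voxel
#' spacing, an origin, and a logical mask marking bone voxels.  The axis
#' convention used throughout the package is: axis 1 mediolateral, axis 2
#' anteroposterior (anterior towards increasing index), axis 3 axial
#' (cranial towards increasing index).  Voxel centres sit at
#' `origin + (index - 0.5) * spacing`.
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, position in mm of the corner of the grid.
#' @param mask logical array of the same dimension as `values`; `TRUE`
#'   marks bone voxels.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0), mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  if (!all(is.finite(values))) stop("'values' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel sizes in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must be a 3-vector in mm")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values)))
    stop("'mask' and 'values' must have identical dimensions")
  storage.mode(mask) <- "logical"
  structure(list(values = values, spacing = spacing, origin = origin,
                 mask = mask),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing %s mm, %d in mask\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

#' Coordinates of voxel centres
#'
#' @param volume a [voxel_volume()].
#' @param which `"mask"` for masked voxels only, `"all"` for the full grid.
#' @return matrix with one row per voxel, columns x/y/z in mm.
#' @export
voxel_centers <- function(volume, which = c("mask", "all")) {
  which <- match.arg(which)
  d <- dim(volume$values)
  idx <- if (which == "mask") which(volume$mask, arr.ind = TRUE)
         else as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  sweep(sweep(idx - 0.5, 2L, volume$spacing, `*`), 2L, volume$origin, `+`)
}

#' Check that the mask forms a single 6-connected component
#'
#' Flood fill from one masked voxel over face neighbours.
#'
#' @param volume a [voxel_volume()].
#' @return `TRUE` if the masked region is one 6-connected component.
#' @export
mask_is_connected <- function(volume) {
  d <- dim(volume$mask)
  n <- sum(volume$mask)
  if (n == 0L) return(FALSE)
  lin <- array(FALSE, d)
  start <- which(volume$mask)[1L]
  lin[start] <- TRUE
  visited <- 1L
  frontier <- start
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  repeat {
    ai <- arrayInd(frontier, d)
    nbr <- rbind(
      cbind(ai[, 1] - 1L, ai[, 2], ai[, 3]),
      cbind(ai[, 1] + 1L, ai[, 2], ai[, 3]),
      cbind(ai[, 1], ai[, 2] - 1L, ai[, 3]),
      cbind(ai[, 1], ai[, 2] + 1L, ai[, 3]),
      cbind(ai[, 1], ai[, 2], ai[, 3] - 1L),
      cbind(ai[, 1], ai[, 2], ai[, 3] + 1L))
    ok <- nbr[, 1] >= 1L & nbr[, 1] <= nx & nbr[, 2] >= 1L & nbr[, 2] <= ny &
          nbr[, 3] >= 1L & nbr[, 3] <= nz
    nbr <- nbr[ok, , drop = FALSE]
    li <- nbr[, 1] + nx * (nbr[, 2] - 1L) + nx * ny * (nbr[, 3] - 1L)
    li <- unique(li[volume$mask[li] & !lin[li]])
    if (length(li) == 0L) break
    lin[li] <- TRUE
    visited <- visited + length(li)
    frontier <- li
  }
  visited == n
}

#' Specification of a synthetic vertebral-body phantom
#'
#' Describes an elliptical-cylinder stand-in for an isolated vertebral body:
#' a bright cortical shell around a dimmer, heterogeneous trabecular core,
#' with a cosine-modulated concave waist.  No quantitative HU statistics are
#' published for the tissue this emulates, so the HU defaults here are
#' plausible-but-invented and should be treated as synthetic.
#'
#' @param height axial height in mm.
#' @param semi_axis_ap anteroposterior semi-axis in mm.
#' @param semi_axis_ml mediolateral semi-axis in mm.
#' @param waist_fraction in (0, 1]; mid-height radius scale (1 = straight
#'   cylinder).
#' @param shell_thickness cortical shell thickness in mm.
#' @param hu_cortical HU assigned to shell voxels.
#' @param hu_trabecular_mean,hu_trabecular_sd mean and SD of the trabecular
#'   HU field.
#' @param voxel isotropic voxel size in mm.
#' @param seed integer seed controlling the trabecular noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 22, semi_axis_ap = 14, semi_axis_ml = 18,
                         waist_fraction = 0.85, shell_thickness = 1.5,
                         hu_cortical = 1200, hu_trabecular_mean = 350,
                         hu_trabecular_sd = 60, voxel = 1, seed = 1L) {
  lens <- c(height = height, semi_axis_ap = semi_axis_ap,
            semi_axis_ml = semi_axis_ml, shell_thickness = shell_thickness,
            voxel = voxel)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths must be positive and finite")
  if (!is.finite(waist_fraction) || waist_fraction <= 0 || waist_fraction > 1)
    stop("'waist_fraction' must lie in (0, 1]")
  if (hu_cortical <= hu_trabecular_mean)
    stop("'hu_cortical' must exceed 'hu_trabecular_mean'")
  if (hu_trabecular_sd < 0) stop("'hu_trabecular_sd' must be >= 0")
  structure(list(height = height, semi_axis_ap = semi_axis_ap,
                 semi_axis_ml = semi_axis_ml, waist_fraction = waist_fraction,
                 shell_thickness = shell_thickness, hu_cortical = hu_cortical,
                 hu_trabecular_mean = hu_trabecular_mean,
                 hu_trabecular_sd = hu_trabecular_sd, voxel = voxel,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# 3^3 box smoothing of a 3-D array (edge-replicated), used to make the
# trabecular noise field smooth so per-element densities are well-posed.
smooth_box3 <- function(x) {
  d <- dim(x)
  shift1 <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    i <- idx[[axis]] - by
    i[i < 1L] <- 1L
    i[i > d[axis]] <- d[axis]
    idx[[axis]] <- i
    do.call(`[`, c(list(a), idx))
  }
  for (axis in 1:3) {
    x <- (shift1(x, axis, -1L) + x + shift1(x, axis, 1L)) / 3
  }
  x
}

#' Generate a synthetic vertebral-body HU volume
#'
#' Builds an elliptical cylinder with a cosine-modulated waist.  Voxels
#' within `shell_thickness` of the lateral boundary carry `hu_cortical`;
#' interior voxels carry a smoothed, seeded Gaussian HU field standardised
#' to the requested mean and SD; voxels outside the mask carry -1000 HU
#' (air).
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_volume()].
#' @export
make_vertebra_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- spec$voxel
  a <- spec$semi_axis_ap   # anteroposterior (axis 2)
  b <- spec$semi_axis_ml   # mediolateral (axis 1)
  if (v > a || v > b)
    stop("degenerate geometry: voxel size exceeds a semi-axis")
  nz <- max(2L, as.integer(round(spec$height / v)))
  nx <- as.integer(ceiling(2 * b / v)) + 2L   # one voxel of air padding
  ny <- as.integer(ceiling(2 * a / v)) + 2L
  cx <- nx * v / 2
  cy <- ny * v / 2
  xs <- (seq_len(nx) - 0.5) * v - cx
  ys <- (seq_len(ny) - 0.5) * v - cy
  ts <- (seq_len(nz) - 0.5) / nz
  s <- 1 - (1 - spec$waist_fraction) * sin(pi * ts)^2

  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  S <- array(rep(s, each = nx * ny), c(nx, ny, nz))
  rn <- sqrt((X / (b * S))^2 + (Y / (a * S))^2)
  mask <- rn <= 1

  values <- array(-1000, c(nx, ny, nz))
  shell <- mask & ((1 - rn) * S * min(a, b) < spec$shell_thickness)
  interior <- mask & !shell

  if (any(interior)) {
    if (spec$hu_trabecular_sd > 0) {
      noise <- withr::with_seed(spec$seed,
        array(stats::rnorm(nx * ny * nz), c(nx, ny, nz)))
      noise <- smooth_box3(noise)
      ni <- noise[interior]
      if (length(ni) > 1L && stats::sd(ni) > 0) {
        ni <- (ni - mean(ni)) / stats::sd(ni)
      } else {
        ni <- rep(0, length(ni))
      }
      values[interior] <- spec$hu_trabecular_mean + spec$hu_trabecular_sd * ni
    } else {
      values[interior] <- spec$hu_trabecular_mean
    }
  }
  values[shell] <- spec$hu_cortical

  voxel_volume(values, spacing = rep(v, 3), origin = c(0, 0, 0), mask = mask)
}

#' Generate a rectangular verification bar phantom
#'
#' A uniform-HU rectangular prism, used as an analytic verification fixture
#' (its stiffness and plastic limit load have closed forms).
#'
#' @param length_mm axial length in mm.
#' @param cross_section_mm length-2 (or scalar) cross-section edge lengths
#'   in mm (mediolateral, anteroposterior).
#' @param hu_value HU assigned to every bar voxel.
#' @param voxel isotropic voxel size in mm; all dimensions must be integer
#'   multiples of it.
#' @return A [voxel_volume()] with a one-voxel air pad around the bar.
#' @export
make_bar_phantom <- function(length_mm, cross_section_mm, hu_value = 500,
                             voxel = 1) {
  if (length(cross_section_mm) == 1L)
    cross_section_mm <- rep(cross_section_mm, 2L)
  dims <- c(cross_section_mm, length_mm)
  if (any(dims <= 0) || voxel <= 0) stop("dimensions must be positive")
  k <- dims / voxel
  if (any(abs(k - round(k)) > 1e-9))
    stop("bar dimensions must be integer multiples of the voxel size")
  k <- as.integer(round(k))
  nx <- k[1] + 2L; ny <- k[2] + 2L; nz <- k[3]
  mask <- array(FALSE, c(nx, ny, nz))
  mask[2:(k[1] + 1L), 2:(k[2] + 1L), ] <- TRUE
  values <- array(-1000, c(nx, ny, nz))
  values[mask] <- hu_value
  voxel_volume(values, spacing = rep(voxel, 3), origin = c(0, 0, 0),
               mask = mask)
}

#' Generate synthetic "experimental" compression curves
#'
#' Draws per-specimen (stiffness, strength) pairs from normal distributions
#' truncated at zero and emits one bilinear load-displacement curve per
#' specimen: load rises at the drawn stiffness until the drawn strength is
#' reached, then plateaus.  The defaults reproduce the dispersion of the
#' physical compression experiments this package emulates (stiffness
#' 9.54 +/- 1.1 kN/mm, strength 10.2 +/- 0.86 kN).
#'
#' @param n_specimens number of specimens (>= 1).
#' @param stiffness_mean,stiffness_sd mean/SD of true stiffness, kN/mm.
#' @param strength_mean,strength_sd mean/SD of true strength, kN.
#' @param seed integer seed.
#' @param d_max maximum displacement of the sampling grid, mm.
#' @param n_points number of displacement samples per curve.
#' @return An object of class `synthetic_experiment`: a list with
#'   `specimens` (data.frame of `id`, `true_stiffness`, `true_strength`)
#'   and `curves` (list of `load_displacement_curve`).
#' @export
make_synthetic_experiment <- function(n_specimens,
                                      stiffness_mean = 9.54,
                                      stiffness_sd = 1.1,
                                      strength_mean = 10.2,
                                      strength_sd = 0.86,
                                      seed = 1L,
                                      d_max = 3, n_points = 121L) {
  if (n_specimens < 1) stop("'n_specimens' must be >= 1")
  if (stiffness_sd < 0 || strength_sd < 0) stop("SDs must be >= 0")
  rtrunc0 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  draws <- withr::with_seed(seed, {
    K <- rtrunc0(n_specimens, stiffness_mean, stiffness_sd)
    F <- rtrunc0(n_specimens, strength_mean, strength_sd)
    list(K = K, F = F)
  })
  d <- seq(0, d_max, length.out = n_points)
  curves <- lapply(seq_len(n_specimens), function(i) {
    load_displacement_curve(d, pmin(draws$K[i] * d, draws$F[i]))
  })
  structure(list(
    specimens = data.frame(id = seq_len(n_specimens),
                           true_stiffness = draws$K,
                           true_strength = draws$F),
    curves = curves,
    noise = c(stiffness_sd = stiffness_sd, strength_sd = strength_sd),
    seed = as.integer(seed)),
    class = "synthetic_experiment")
}

#' Write / read a voxel volume as NIfTI
#'
#' The HU values are written to `file` and the bone mask to a companion
#' file with suffix `_mask` (0/1), both with the voxel spacing recorded in
#' the header.
#'
#' @param volume a [voxel_volume()].
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `write_volume` returns `file` invisibly; `read_volume` a
#'   [voxel_volume()].
#' @export
write_volume <- function(volume, file) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, file)
  msk <- RNifti::asNifti(array(as.integer(volume$mask), dim(volume$mask)))
  RNifti::pixdim(msk) <- volume$spacing
  RNifti::writeNifti(msk, mask_companion_path(file))
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  spacing <- RNifti::pixdim(img)[1:3]
  mfile <- mask_companion_path(file)
  mask <- if (file.exists(mfile)) {
    array(as.vector(RNifti::readNifti(mfile)) != 0, dim(img))
  } else NULL
  voxel_volume(array(as.vector(img), dim(img)), spacing = spacing,
               mask = mask)
}

mask_companion_path <- function(file) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", file)
}
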