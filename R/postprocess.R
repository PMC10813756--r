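#' Load-displacement curve
#'
#' @param displacement non-decreasing displacements starting at 0, mm.
#' @param load loads, kN, same length (>= 3 points).
#' @return An object of class `load_displacement_curve` (a data.frame
#'   with columns `displacement` and `load`).
#' @export
load_displacement_curve <- function(displacement, load) {
  if (length(displacement) != length(load))
    stop("'displacement' and 'load' must have equal length")
  if (length(displacement) < 3L) stop("a curve needs at least 3 points")
  if (displacement[1] != 0) stop("displacement must start at 0")
  if (any(diff(displacement) < 0)) stop("displacement must be non-decreasing")
  structure(data.frame(displacement = displacement, load = load),
            class = c("load_displacement_curve", "data.frame"))
}

#' Read / write curves as CSV
#'
#' Columns `displacement_mm`, `load_kN`.  Experimental and simulated
#' curves share this format and the same extractors.
#'
#' @param curve a [load_displacement_curve()].
#' @param file CSV path.
#' @export
write_curve <- function(curve, file) {
  utils::write.csv(data.frame(displacement_mm = curve$displacement,
                              load_kN = curve$load),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  x <- utils::read.csv(file)
  load_displacement_curve(x$displacement_mm, x$load_kN)
}

#' Extract stiffness from a load-displacement curve
#'
#' Stiffness is the slope of the curve's linear trajectory, realized as
#' the ordinary-least-squares slope over the ascending-branch points whose
#' load lies between `window[1]` and `window[2]` of the peak load (20-80%
#' by default; the fit window is recorded).
#'
#' @param curve a [load_displacement_curve()] with positive peak load.
#' @param window length-2 fractions of peak load bounding the fit window.
#' @return list with `stiffness` (kN/mm), `window` (indices used),
#'   `window_fractions`.
#' @export
extract_stiffness <- function(curve, window = c(0.2, 0.8)) {
  peak <- max(curve$load)
  if (peak <= 0) stop("curve has no positive load")
  ipeak <- which.max(curve$load)
  asc <- seq_len(ipeak)
  sel <- asc[curve$load[asc] >= window[1] * peak &
             curve$load[asc] <= window[2] * peak]
  if (length(sel) < 3L)
    stop("fewer than 3 points in the stiffness fit window")
  x <- curve$displacement[sel]
  y <- curve$load[sel]
  slope <- stats::cov(x, y) / stats::var(x)
  list(stiffness = slope, window = sel, window_fractions = window)
}

#' Extract strength from a load-displacement curve
#'
#' Strength is the highest load reached.  For perfectly plastic
#' simulations this coincides with the onset of the plastic plateau (the
#' highest point of elastic response); for curves with a post-peak drop it
#' is the pre-drop maximum.
#'
#' @param curve a [load_displacement_curve()].
#' @return strength in kN.
#' @export
extract_strength <- function(curve) {
  max(curve$load)
}

#' Stiffness and strength of one specimen
#'
#' @param curve a [load_displacement_curve()].
#' @param source `"simulated"` or `"experimental"`.
#' @param window stiffness fit window, see [extract_stiffness()].
#' @return An object of class `specimen_result`.
#' @export
specimen_result <- function(curve, source = c("simulated", "experimental"),
                            window = c(0.2, 0.8)) {
  source <- match.arg(source)
  st <- extract_stiffness(curve, window)
  structure(list(stiffness = st$stiffness, strength = extract_strength(curve),
                 fit_window = st$window, source = source),
            class = "specimen_result")
}

#' @export
print.specimen_result <- function(x, ...) {
  cat(sprintf("specimen_result (%s): stiffness %.3f kN/mm, strength %.3f kN\n",
              x$source, x$stiffness, x$strength))
  invisible(x)
}

#' Map plastic failure onto anatomical sectors
#'
#' Elements whose final equivalent plastic strain exceeds `peeq_threshold`
#' are flagged as yielded (threshold 0 is the literal nonzero-plastic-
#' strain rule; the default 1e-8 absorbs round-off).  Each element is
#' assigned an angular sector about the axial axis through the centre of
#' mass: anterior within +/-45 degrees of the anterior direction,
#' posterior within +/-45 degrees of its opposite, lateral-left /
#' lateral-right otherwise.
#'
#' @param solution a `solution_record` with at least one increment.
#' @param mesh the `tet_mesh` that was solved.
#' @param frame the `anatomical_frame`.
#' @param peeq_threshold yield threshold on PEEQ (>= 0).
#' @return An object of class `fracture_map`: list with `element`
#'   (data.frame: `peeq`, `sector`, `yielded`) and `sectors` (data.frame:
#'   `sector`, `n`, `fraction_yielded`, `mean_peeq`).
#' @export
fracture_map <- function(solution, mesh, frame, peeq_threshold = 1e-8) {
  if (peeq_threshold < 0) stop("'peeq_threshold' must be >= 0")
  if (solution$n_completed < 1L) stop("solution has no completed increment")
  peeq <- solution$peeq
  cent <- (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
           mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
           mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
           mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
  rel <- sweep(cent, 2L, frame$center_of_mass)
  a <- as.vector(rel %*% frame$anterior_direction)
  l <- as.vector(rel %*% frame$mediolateral_direction)
  ang <- atan2(l, a)
  sector <- ifelse(abs(ang) <= pi / 4, "anterior",
            ifelse(abs(ang) >= 3 * pi / 4, "posterior",
            ifelse(ang > 0, "lateral-right", "lateral-left")))
  yielded <- peeq > peeq_threshold
  per_sector <- do.call(rbind, lapply(
    c("anterior", "lateral-left", "lateral-right", "posterior"),
    function(s) {
      i <- sector == s
      data.frame(sector = s, n = sum(i),
                 fraction_yielded = if (any(i)) mean(yielded[i]) else NA_real_,
                 mean_peeq = if (any(i)) mean(peeq[i]) else NA_real_)
    }))
  structure(list(element = data.frame(peeq = peeq, sector = sector,
                                      yielded = yielded),
                 sectors = per_sector,
                 peeq_threshold = peeq_threshold),
            class = "fracture_map")
}

#' @export
print.fracture_map <- function(x, ...) {
  cat("fracture_map (PEEQ threshold", format(x$peeq_threshold), "):\n")
  print(x$sectors, row.names = FALSE)
  invisible(x)
}

#' Forward sagittal tilt of the loading plate
#'
#' Positive values mean the anterior edge of the (rigidly coupled) cranial
#' surface moved caudally relative to the posterior edge -- the forward
#' tilt expected when the control point sits anterior of the centre of
#' mass.
#'
#' @param solution a `solution_record` from a rigid-coupling solve.
#' @param frame the `anatomical_frame`.
#' @return tilt angle history in radians (one value per increment).
#' @export
forward_tilt <- function(solution, frame) {
  if (nrow(solution$rotation) == 0L) return(numeric(0))
  ml <- frame$mediolateral_direction
  # rotation theta about +ml moves an anterior point (+anterior lever) by
  # (theta_ml * ml) x anterior = +axial; forward (caudal) motion is -axial
  -as.vector(solution$rotation %*% ml)
}
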