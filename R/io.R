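#' Write a mesh with material cards as an Abaqus-dialect INP file
#'
#' Emits `*NODE`, `*ELEMENT, TYPE=C3D4`, `*NSET` blocks for the cranial
#' and caudal surfaces, one `*SOLID SECTION`/`*MATERIAL` per material bin
#' (with `*ELASTIC` and, for perfect plasticity, a single-row `*PLASTIC`),
#' and a comment block describing the control-point coupling.  A JSON
#' sidecar (`<file>.json`) records the load case so the mesh can be
#' round-tripped.
#'
#' @param mesh a `tet_mesh`.
#' @param cards optional `material_cards` (one row per element).
#' @param loadcase optional `load_case`, stored in the sidecar.
#' @param file output path (`.inp`).
#' @export
write_inp <- function(mesh, cards = NULL, loadcase = NULL, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*HEADING", "vertfem T4 vertebral body mesh")
  w("*NODE")
  w(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))

  if (!is.null(cards)) {
    bins <- sort(unique(cards$bin))
    for (bn in bins) {
      el <- which(cards$bin == bn)
      w(sprintf("*ELEMENT, TYPE=C3D4, ELSET=BIN%d", bn))
      w(sprintf("%d, %d, %d, %d, %d", el,
                mesh$tets[el, 1], mesh$tets[el, 2],
                mesh$tets[el, 3], mesh$tets[el, 4]))
    }
  } else {
    w("*ELEMENT, TYPE=C3D4, ELSET=ALL")
    w(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
              mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
              mesh$tets[, 4]))
  }

  for (nm in names(mesh$node_sets)) {
    w(sprintf("*NSET, NSET=%s", toupper(nm)))
    ids <- mesh$node_sets[[nm]]
    for (chunk in split(ids, ceiling(seq_along(ids) / 12)))
      w(paste(chunk, collapse = ", "))
  }

  if (!is.null(cards)) {
    bins <- sort(unique(cards$bin))
    for (bn in bins) {
      el <- which(cards$bin == bn)[1]
      w(sprintf("*SOLID SECTION, ELSET=BIN%d, MATERIAL=MAT%d", bn, bn),
        sprintf("*MATERIAL, NAME=MAT%d", bn),
        "*ELASTIC",
        sprintf("%.9g, %.9g", cards$E[el], cards$nu[el]),
        "*PLASTIC",
        sprintf("%.9g, 0.", cards$sigma_y[el]))
    }
  }
  if (!is.null(loadcase)) {
    w("** control point rigidly coupled to NSET CRANIAL (MPC equivalent);",
      sprintf("** location: %.6g, %.6g, %.6g", loadcase$control_point[1],
              loadcase$control_point[2], loadcase$control_point[3]),
      "** transverse translations locked, rotations free; CAUDAL fully fixed")
    jsonlite::write_json(
      list(control_point = loadcase$control_point,
           offset_fraction = loadcase$offset_fraction,
           prescribed_axial_displacement =
             loadcase$prescribed_axial_displacement,
           n_increments = loadcase$n_increments,
           coupling = loadcase$coupling),
      paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a mesh written by [write_inp()]
#'
#' Parses the `*NODE`, `*ELEMENT` and `*NSET` blocks of the supported INP
#' dialect (per-bin element sets are concatenated in element order).
#'
#' @param file path to the INP file.
#' @return A `tet_mesh` (element densities are not stored in INP and come
#'   back as `NA`; material bins are returned in the `inp_bins` field).
#' @export
read_inp <- function(file) {
  lines <- readLines(file)
  nodes <- NULL
  elems <- list()
  nsets <- list()
  i <- 1L
  mode <- ""
  current_set <- NULL
  acc <- list()
  flush_acc <- function() acc
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "**")) { i <- i + 1L; next }
    if (startsWith(ln, "*")) {
      up <- toupper(ln)
      if (startsWith(up, "*NODE")) {
        mode <- "node"
      } else if (startsWith(up, "*ELEMENT")) {
        mode <- "elem"
        elems[[length(elems) + 1L]] <- character(0)
      } else if (startsWith(up, "*NSET")) {
        mode <- "nset"
        nm <- sub(".*NSET=([A-Za-z0-9_]+).*", "\\1", ln)
        current_set <- tolower(nm)
        nsets[[current_set]] <- integer(0)
      } else {
        mode <- ""
      }
      i <- i + 1L
      next
    }
    if (nzchar(ln)) {
      if (mode == "node") {
        nodes <- c(nodes, ln)
      } else if (mode == "elem") {
        k <- length(elems)
        elems[[k]] <- c(elems[[k]], ln)
      } else if (mode == "nset") {
        vals <- as.integer(strsplit(ln, ",")[[1]])
        nsets[[current_set]] <- c(nsets[[current_set]],
                                  vals[!is.na(vals)])
      }
    }
    i <- i + 1L
  }
  nm <- do.call(rbind, lapply(strsplit(nodes, ","), as.numeric))
  ord <- order(nm[, 1])
  node_xyz <- nm[ord, 2:4, drop = FALSE]
  eraw <- do.call(rbind, lapply(strsplit(unlist(elems), ","), as.numeric))
  bins_raw <- rep(seq_along(elems), vapply(elems, length, 1L))
  ord2 <- order(eraw[, 1])
  etab <- eraw[ord2, , drop = FALSE]
  bins <- bins_raw[ord2]
  structure(list(nodes = node_xyz,
                 tets = matrix(as.integer(etab[, 2:5]), ncol = 4L),
                 element_density = rep(NA_real_, nrow(etab)),
                 element_voxel = rep(NA_integer_, nrow(etab)),
                 node_sets = nsets,
                 inp_bins = bins,
                 spacing = rep(NA_real_, 3)),
            class = "tet_mesh")
}

#' Export a mesh with fields as ASCII VTU
#'
#' Writes an unstructured-grid XML file readable by ParaView, with
#' optional per-node and per-element scalar fields.
#'
#' @param mesh a `tet_mesh`.
#' @param file output path (`.vtu`).
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element numeric vectors.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  da <- function(name, values, comps = 1L) {
    w('    <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
      name, comps)
    writeLines(paste(format(values, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con)
    w("    </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("  <UnstructuredGrid>")
  w('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w("   <Points>")
  da("Points", as.vector(t(mesh$nodes)), 3L)
  w("   </Points>")
  w("   <Cells>")
  w('    <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(as.vector(t(mesh$tets)) - 1L, collapse = " "), con)
  w("    </DataArray>")
  w('    <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 4L, collapse = " "), con)
  w("    </DataArray>")
  w('    <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, m), collapse = " "), con)  # VTK_TETRA
  w("    </DataArray>")
  w("   </Cells>")
  if (length(point_data)) {
    w("   <PointData>")
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      da(nm, if (is.matrix(v)) as.vector(t(v)) else v,
         if (is.matrix(v)) ncol(v) else 1L)
    }
    w("   </PointData>")
  }
  if (length(cell_data)) {
    w("   <CellData>")
    for (nm in names(cell_data)) da(nm, cell_data[[nm]])
    w("   </CellData>")
  }
  w("  </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(file)
}
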