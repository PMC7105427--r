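# Readers and writers for mesh + field files. VTK XML (.vtp polydata with
# triangles, .vtu unstructured grids with triangles or tets) in ASCII is the
# canonical dialect; a minimal legacy ASCII .vtk reader is provided for
# import. Doubles are written with 17 significant digits so a write -> read
# round trip reproduces values exactly.

.fmt_dbl <- function(x) sprintf("%.17g", x)

.da_node <- function(values, name = NULL, ncomp = 1L, type = "Float64") {
  txt <- if (type == "Float64") paste(.fmt_dbl(t(values)), collapse = " ")
         else paste(as.integer(t(values)), collapse = " ")
  attrs <- sprintf(' Name="%s"', name)
  if (is.null(name)) attrs <- ""
  sprintf('<DataArray type="%s"%s NumberOfComponents="%d" format="ascii">%s</DataArray>',
          type, attrs, ncomp, txt)
}

.coerce_data_list <- function(data, n_expected, what) {
  if (is.null(data) || !length(data)) return(list())
  stopifnot(is.list(data), !is.null(names(data)))
  out <- list()
  for (nm in names(data)) {
    v <- data[[nm]]
    if (inherits(v, "metric_map")) v <- v$values
    v <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
    if (nrow(v) != n_expected)
      stop(sprintf("%s array '%s' has %d rows, expected %d", what, nm,
                   nrow(v), n_expected))
    if (anyNA(v)) warning(sprintf("%s array '%s' contains NaN/NA; written verbatim",
                                  what, nm))
    out[[nm]] <- v
  }
  out
}

.data_block <- function(tag, arrays) {
  if (!length(arrays)) return(sprintf("<%s/>", tag))
  inner <- vapply(names(arrays), function(nm)
    .da_node(arrays[[nm]], nm, ncol(arrays[[nm]])), character(1))
  sprintf("<%s>%s</%s>", tag, paste(inner, collapse = ""), tag)
}

#' Write a surface mesh (and optional data arrays) as VTK XML PolyData
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.vtp` path.
#' @param cell_data named list of per-element vectors/matrices or
#'   `metric_map`s.
#' @param point_data named list of per-node vectors/matrices.
#' @return invisible `path`.
#' @export
write_vtp <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  np <- nrow(mesh$points); nc <- nrow(mesh$triangles)
  cd <- .coerce_data_list(cell_data, nc, "cell-data")
  pd <- .coerce_data_list(point_data, np, "point-data")
  conn <- paste(as.integer(t(mesh$triangles)), collapse = " ")
  offs <- paste(seq_len(nc) * 3L, collapse = " ")
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="1.0" byte_order="LittleEndian">',
    '<PolyData><Piece NumberOfPoints="', np, '" NumberOfVerts="0" ',
    'NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="', nc, '">',
    "<Points>", .da_node(mesh$points, "Points", 3L), "</Points>",
    "<Polys>",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>', conn),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>', offs),
    "</Polys>",
    .data_block("PointData", pd),
    .data_block("CellData", cd),
    "</Piece></PolyData></VTKFile>")
  writeLines(doc, path)
  invisible(path)
}

#' Write a mesh as VTK XML UnstructuredGrid
#'
#' Triangles (surface meshes) are written as VTK cell type 5, tetrahedra
#' (volume meshes) as type 10.
#'
#' @inheritParams write_vtp
#' @param mesh a [surface_mesh()] or [volume_mesh()].
#' @param path output `.vtu` path.
#' @return invisible `path`.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  is_surf <- inherits(mesh, "surface_mesh")
  conn_m <- if (is_surf) mesh$triangles else mesh$tets
  ctype <- if (is_surf) 5L else 10L
  nv <- ncol(conn_m)
  np <- nrow(mesh$points); nc <- nrow(conn_m)
  cd <- .coerce_data_list(cell_data, nc, "cell-data")
  pd <- .coerce_data_list(point_data, np, "point-data")
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="1.0" byte_order="LittleEndian">',
    '<UnstructuredGrid><Piece NumberOfPoints="', np, '" NumberOfCells="', nc, '">',
    "<Points>", .da_node(mesh$points, "Points", 3L), "</Points>",
    "<Cells>",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>',
            paste(as.integer(t(conn_m)), collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>',
            paste(seq_len(nc) * nv, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>',
            paste(rep(ctype, nc), collapse = " ")),
    "</Cells>",
    .data_block("PointData", pd),
    .data_block("CellData", cd),
    "</Piece></UnstructuredGrid></VTKFile>")
  writeLines(doc, path)
  invisible(path)
}

.parse_da <- function(node) {
  txt <- xml2::xml_text(node)
  vals <- scan(text = txt, what = double(), quiet = TRUE)
  ncomp <- xml2::xml_attr(node, "NumberOfComponents")
  ncomp <- if (is.na(ncomp)) 1L else as.integer(ncomp)
  matrix(vals, ncol = ncomp, byrow = TRUE)
}

.parse_data_block <- function(piece, tag) {
  out <- list()
  blk <- xml2::xml_find_first(piece, tag)
  if (inherits(blk, "xml_missing")) return(out)
  for (node in xml2::xml_find_all(blk, "DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    out[[nm]] <- .parse_da(node)
  }
  out
}

#' Read a VTK XML file (.vtp or .vtu)
#'
#' @param path file path; dialect is detected from the `VTKFile` type
#'   attribute, not the extension.
#' @return list with `mesh` (a `surface_mesh` or `volume_mesh`),
#'   `cell_data` and `point_data` (named lists of matrices).
#' @export
read_vtk_xml <- function(path) {
  doc <- xml2::read_xml(path)
  type <- xml2::xml_attr(doc, "type")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- .parse_da(xml2::xml_find_first(piece, "Points/DataArray"))
  if (type == "PolyData") {
    conn <- .parse_da(xml2::xml_find_first(
      piece, 'Polys/DataArray[@Name="connectivity"]'))
    offs <- .parse_da(xml2::xml_find_first(piece, 'Polys/DataArray[@Name="offsets"]'))
    if (any(diff(c(0, offs)) != 3L))
      stop("only triangulated PolyData is supported: ", path)
    mesh <- surface_mesh(pts, matrix(as.integer(conn), ncol = 3L, byrow = TRUE))
  } else if (type == "UnstructuredGrid") {
    conn <- as.integer(.parse_da(xml2::xml_find_first(
      piece, 'Cells/DataArray[@Name="connectivity"]')))
    types <- as.integer(.parse_da(xml2::xml_find_first(
      piece, 'Cells/DataArray[@Name="types"]')))
    if (all(types == 5L)) {
      mesh <- surface_mesh(pts, matrix(conn, ncol = 3L, byrow = TRUE))
    } else if (all(types == 10L)) {
      mesh <- volume_mesh(pts, matrix(conn, ncol = 4L, byrow = TRUE))
    } else stop("mixed or unsupported cell types in ", path)
  } else stop("unsupported VTKFile type: ", type)
  list(mesh = mesh,
       cell_data = .parse_data_block(piece, "CellData"),
       point_data = .parse_data_block(piece, "PointData"))
}

#' Read a legacy ASCII VTK file (POLYDATA or UNSTRUCTURED_GRID)
#'
#' Minimal import path for triangle / tetrahedron meshes with SCALARS or
#' VECTORS attributes in POINT_DATA / CELL_DATA sections.
#'
#' @param path `.vtk` file path.
#' @return same structure as [read_vtk_xml()].
#' @export
read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("ASCII", lines[1:4], fixed = TRUE)))
    stop("only ASCII legacy VTK is supported: ", path)
  toks <- unlist(strsplit(trimws(lines[-(1:2)]), "\\s+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  pos <- 1L
  take <- function(n) {
    out <- toks[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  mesh <- NULL; pts <- NULL; ncell <- 0L
  cd <- list(); pd <- list()
  section <- NULL # "cell" or "point" attribute section
  while (pos <= length(toks)) {
    kw <- toupper(toks[pos])
    if (kw == "POINTS") {
      np <- as.integer(toks[pos + 1L]); pos <- pos + 3L
      pts <- matrix(as.numeric(take(np * 3L)), ncol = 3L, byrow = TRUE)
    } else if (kw %in% c("POLYGONS", "CELLS")) {
      ncell <- as.integer(toks[pos + 1L]); tot <- as.integer(toks[pos + 2L])
      pos <- pos + 3L
      nums <- as.integer(take(tot))
      nv <- nums[1L] # homogeneous cells assumed
      conn <- matrix(nums, ncol = nv + 1L, byrow = TRUE)[, -1L, drop = FALSE]
      mesh <- if (nv == 3L) surface_mesh(pts, conn)
              else if (nv == 4L) volume_mesh(pts, conn)
              else stop("unsupported cell arity ", nv)
    } else if (kw == "CELL_TYPES") {
      n <- as.integer(toks[pos + 1L]); pos <- pos + 2L; take(n)
    } else if (kw == "CELL_DATA") {
      section <- "cell"; pos <- pos + 2L
    } else if (kw == "POINT_DATA") {
      section <- "point"; pos <- pos + 2L
    } else if (kw == "SCALARS") {
      nm <- toks[pos + 1L]
      ncomp <- suppressWarnings(as.integer(toks[pos + 3L]))
      if (is.na(ncomp)) ncomp <- 1L
      pos <- pos + if (is.na(suppressWarnings(as.integer(toks[pos + 3L])))) 3L else 4L
      if (toupper(toks[pos]) == "LOOKUP_TABLE") pos <- pos + 2L
      n <- if (identical(section, "cell")) ncell else nrow(pts)
      arr <- matrix(as.numeric(take(n * ncomp)), ncol = ncomp, byrow = TRUE)
      if (identical(section, "cell")) cd[[nm]] <- arr else pd[[nm]] <- arr
    } else if (kw == "VECTORS") {
      nm <- toks[pos + 1L]; pos <- pos + 3L
      n <- if (identical(section, "cell")) ncell else nrow(pts)
      arr <- matrix(as.numeric(take(n * 3L)), ncol = 3L, byrow = TRUE)
      if (identical(section, "cell")) cd[[nm]] <- arr else pd[[nm]] <- arr
    } else {
      pos <- pos + 1L
    }
  }
  if (is.null(mesh)) stop("no POLYGONS/CELLS section found in ", path)
  list(mesh = mesh, cell_data = cd, point_data = pd)
}

.read_any_vtk <- function(path) {
  if (grepl("\\.vtk$", path, ignore.case = TRUE)) read_vtk_legacy(path)
  else read_vtk_xml(path)
}

.same_topology <- function(m1, m2) {
  cls <- class(m1)[1L]
  if (cls != class(m2)[1L]) return(FALSE)
  conn1 <- if (cls == "surface_mesh") m1$triangles else m1$tets
  conn2 <- if (cls == "surface_mesh") m2$triangles else m2$tets
  identical(dim(m1$points), dim(m2$points)) && identical(dim(conn1), dim(conn2)) &&
    all(conn1 == conn2)
}

#' Read a time series of field files into a field_series
#'
#' Loads one VTK XML / legacy file per sample time, checks that the mesh
#' topology is identical across steps, extracts the named field and assembles
#' a [field_series()]. Node-attached input is averaged onto elements when
#' `attachment = "element"` is requested.
#'
#' @param paths ordered character vector of file paths, one per time step.
#' @param time_values numeric sample times (s), same length as `paths`.
#' @param attachment desired attachment of the result, "element" or "node".
#' @param field_name name of the data array to extract.
#' @param units unit string stored on the result.
#' @return list with `mesh` and `field` (the `field_series`).
#' @export
read_field_series <- function(paths, time_values, attachment = c("element", "node"),
                              field_name, units = "") {
  attachment <- match.arg(attachment)
  stopifnot(length(paths) == length(time_values), length(paths) >= 3L)
  window <- cycle_window(time_values)
  first <- .read_any_vtk(paths[1L])
  mesh <- first$mesh
  pick <- function(loaded, step) {
    src <- if (!is.null(loaded$cell_data[[field_name]])) "element"
           else if (!is.null(loaded$point_data[[field_name]])) "node"
           else stop(sprintf(
             "field '%s' not found in %s; available: cell data [%s], point data [%s]",
             field_name, paths[step],
             paste(names(loaded$cell_data), collapse = ", "),
             paste(names(loaded$point_data), collapse = ", ")))
    list(src = src,
         arr = if (src == "element") loaded$cell_data[[field_name]]
               else loaded$point_data[[field_name]])
  }
  p1 <- pick(first, 1L)
  ncomp <- ncol(p1$arr)
  kind <- names(FIELD_KINDS)[match(ncomp, FIELD_KINDS)]
  if (is.na(kind)) stop("unsupported component count ", ncomp)
  vals <- array(NA_real_, dim = c(length(paths), nrow(p1$arr), ncomp))
  vals[1L, , ] <- p1$arr
  for (s in seq_along(paths)[-1L]) {
    loaded <- .read_any_vtk(paths[s])
    if (!.same_topology(mesh, loaded$mesh))
      stop(sprintf("topology mismatch at step %d (%s) relative to step 1", s, paths[s]))
    ps <- pick(loaded, s)
    if (ps$src != p1$src || !identical(dim(ps$arr), dim(p1$arr)))
      stop(sprintf("field layout mismatch at step %d (%s)", s, paths[s]))
    vals[s, , ] <- ps$arr
  }
  field <- field_series(vals, kind = kind, attachment = p1$src,
                        window = window, units = units)
  if (attachment == "element" && field$attachment == "node")
    field <- node_to_element(field, mesh)
  list(mesh = mesh, field = field)
}

#' Write per-element metric maps as VTP cell data
#'
#' @param mesh a [surface_mesh()].
#' @param maps named list of `metric_map`s (or plain per-element vectors).
#' @param path output `.vtp` path.
#' @return invisible `path`.
#' @export
write_metric_map <- function(mesh, maps, path) {
  write_vtp(mesh, path, cell_data = maps)
}
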