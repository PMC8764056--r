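#' Read centerlines from CSV or VTK PolyData
#'
#' CSV needs columns `x,y,z` (mm, ordered proximal to distal) and optionally
#' `branch`; VTK legacy ASCII (`.vtk`) and XML (`.vtp`) PolyData polylines
#' are read one centerline per line cell. Format is auto-detected from the
#' extension unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"csv"`, `"vtk"` or `"vtp"`.
#' @return A named list of centerlines (possibly of length 1).
#' @export
read_centerline <- function(path, format = c("auto", "csv", "vtk", "vtp")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(path)
  switch(format,
         csv = read_centerline_csv(path),
         vtk = read_polyline_vtk(path),
         vtp = read_polyline_vtp(path))
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "vtk", "vtp")) return(ext)
  rlang::abort(paste0("cannot auto-detect format of '", path,
                      "' (expect .csv, .vtk or .vtp)"),
               class = "tortuometry_parse_error")
}

#' @rdname read_centerline
#' @export
read_centerline_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y", "z") %in% names(d))) {
    rlang::abort(paste0("'", path, "' lacks x,y,z columns"),
                 class = "tortuometry_parse_error")
  }
  if ("branch" %in% names(d)) {
    sp <- split(d[, c("x", "y", "z")], factor(d$branch, levels = unique(d$branch)))
    purrr::imap(sp, ~ centerline(.x, label = .y))
  } else {
    lb <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
    rlang::set_names(list(centerline(d, label = lb)), lb)
  }
}

#' Write centerlines to CSV
#'
#' One row per point with columns `x,y,z,branch`, branches concatenated in
#' order.
#'
#' @param centerlines A centerline or (named) list of centerlines.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(centerlines, path) {
  cls <- as_centerline_list(centerlines)
  d <- purrr::imap(cls, function(cl, nm) {
    tibble::tibble(x = cl$x, y = cl$y, z = cl$z, branch = nm)
  }) |> dplyr::bind_rows()
  readr::write_csv(d, path)
  invisible(path)
}

as_centerline_list <- function(x) {
  if (inherits(x, "tortuometry_centerline")) {
    x <- rlang::set_names(list(x), branch_label(x))
  }
  if (is.null(names(x))) names(x) <- purrr::map_chr(x, branch_label)
  x
}

# ---- legacy VTK ASCII -------------------------------------------------------

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write centerlines as legacy-ASCII VTK PolyData polylines
#'
#' One LINES cell per branch; branch names go into the header title and an
#' integer `branch_id` cell-data array.
#'
#' @inheritParams write_centerline_csv
#' @export
write_centerline_vtk <- function(centerlines, path) {
  cls <- as_centerline_list(centerlines)
  pts <- purrr::map(cls, as_xyz_matrix)
  npts <- vapply(pts, nrow, integer(1))
  offsets <- cumsum(c(0, npts[-length(npts)]))
  all_pts <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("tortuometry centerlines: ", paste(names(cls), collapse = ",")),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(all_pts), "double")), con)
  writeLines(apply(all_pts, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("LINES", length(cls), sum(npts + 1)), con)
  for (i in seq_along(cls)) {
    writeLines(paste(c(npts[i], offsets[i] + seq_len(npts[i]) - 1), collapse = " "), con)
  }
  writeLines(c(paste("CELL_DATA", length(cls)),
               "SCALARS branch_id int 1", "LOOKUP_TABLE default",
               paste(seq_along(cls) - 1, collapse = " ")), con)
  invisible(path)
}

tokenize_vtk <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  unlist(strsplit(trimws(lines), "\\s+"))
}

read_legacy_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1])) {
    rlang::abort(paste0("'", path, "' is not a legacy VTK file"),
                 class = "tortuometry_parse_error")
  }
  title <- lines[2]
  if (!any(grepl("^ASCII", lines))) {
    rlang::abort("only ASCII legacy VTK is supported",
                 class = "tortuometry_parse_error")
  }
  if (!any(grepl("^DATASET POLYDATA", lines))) {
    rlang::abort("only DATASET POLYDATA is supported",
                 class = "tortuometry_parse_error")
  }
  toks <- tokenize_vtk(lines[-(1:2)])
  i <- 1
  nxt <- function() { v <- toks[i]; i <<- i + 1; v }
  out <- list(title = title, points = NULL, lines = list(), polys = list(),
              point_data = list(), cell_data = list())
  n_cells_seen <- 0L
  section <- NULL
  while (i <= length(toks)) {
    tk <- nxt()
    if (tk == "POINTS") {
      n <- as.integer(nxt()); nxt()  # dtype
      vals <- as.numeric(toks[i:(i + 3 * n - 1)]); i <- i + 3 * n
      out$points <- matrix(vals, ncol = 3, byrow = TRUE)
    } else if (tk %in% c("LINES", "POLYGONS")) {
      nc <- as.integer(nxt()); sz <- as.integer(nxt())
      vals <- as.integer(toks[i:(i + sz - 1)]); i <- i + sz
      cells <- list(); j <- 1
      for (k in seq_len(nc)) {
        m <- vals[j]
        cells[[k]] <- vals[(j + 1):(j + m)] + 1L
        j <- j + m + 1
      }
      if (tk == "LINES") out$lines <- cells else out$polys <- cells
      n_cells_seen <- nc
    } else if (tk %in% c("POINT_DATA", "CELL_DATA")) {
      section <- if (tk == "POINT_DATA") "point_data" else "cell_data"
      nxt()  # count
    } else if (tk == "SCALARS") {
      nm <- nxt(); nxt()  # dtype
      if (!is.na(suppressWarnings(as.integer(toks[i]))) &&
          toks[i] %in% as.character(1:4)) i <- i + 1  # optional numComp
      if (toks[i] == "LOOKUP_TABLE") i <- i + 2
      target_n <- if (identical(section, "point_data")) nrow(out$points) else n_cells_seen
      out[[section]][[nm]] <- as.numeric(toks[i:(i + target_n - 1)])
      i <- i + target_n
    } else if (tk == "LOOKUP_TABLE") {
      i <- i + 1
    }
  }
  out
}

#' @rdname read_centerline
#' @export
read_polyline_vtk <- function(path) {
  vt <- read_legacy_vtk(path)
  if (length(vt$lines) == 0) {
    rlang::abort(paste0("'", path, "' has no LINES cells"),
                 class = "tortuometry_parse_error")
  }
  labels <- parse_title_labels(vt$title, length(vt$lines))
  purrr::map2(vt$lines, labels, function(idx, lb) {
    centerline(vt$points[idx, , drop = FALSE], label = lb)
  }) |> rlang::set_names(labels)
}

parse_title_labels <- function(title, n) {
  if (grepl("centerlines:", title, fixed = TRUE)) {
    lb <- strsplit(sub(".*centerlines:\\s*", "", title), ",")[[1]]
    lb <- trimws(lb)
    if (length(lb) == n) return(lb)
  }
  paste0("branch", seq_len(n))
}

#' Read a triangulated surface with a TAWSS field
#'
#' Supports legacy-ASCII VTK (`.vtk`) and XML (`.vtp`, ascii-encoded)
#' PolyData. The TAWSS array may sit on points or cells; a missing region
#' mask means every triangle is treated as bifurcation wall (warned, since
#' flow extensions then cannot be excluded). Non-triangle cells are refused.
#'
#' @param path Input file.
#' @param tawss_array Name of the TAWSS scalar array (default `"TAWSS"`).
#' @param mask_array Name of the integer cell array marking the bifurcation
#'   region (1) vs flow extension (0); default `"region"`.
#' @param format `"auto"`, `"vtk"` or `"vtp"`.
#' @return A [surface_field()] object.
#' @export
read_surface_field <- function(path, tawss_array = "TAWSS",
                               mask_array = "region",
                               format = c("auto", "vtk", "vtp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- detect_format(path)
    if (format == "csv") rlang::abort("surfaces must be .vtk or .vtp",
                                      class = "tortuometry_parse_error")
  }
  vt <- if (format == "vtk") read_legacy_vtk(path) else read_vtp(path)
  if (length(vt$polys) == 0) {
    rlang::abort(paste0("'", path, "' has no polygon cells"),
                 class = "tortuometry_parse_error")
  }
  sizes <- lengths(vt$polys)
  if (any(sizes != 3)) {
    rlang::abort(sprintf("non-triangle cells present (%d of %d); triangulate upstream",
                         sum(sizes != 3), length(sizes)),
                 class = "tortuometry_unsupported_geometry")
  }
  tris <- do.call(rbind, vt$polys)
  on_pt <- tawss_array %in% names(vt$point_data)
  on_cell <- tawss_array %in% names(vt$cell_data)
  if (!on_pt && !on_cell) {
    rlang::abort(paste0("no array '", tawss_array, "' in '", path,
                        "'; available: point {",
                        paste(names(vt$point_data), collapse = ", "),
                        "}, cell {", paste(names(vt$cell_data), collapse = ", "), "}"),
                 class = "tortuometry_configuration_error")
  }
  tawss <- if (on_pt) vt$point_data[[tawss_array]] else vt$cell_data[[tawss_array]]
  mask <- if (mask_array %in% names(vt$cell_data)) {
    vt$cell_data[[mask_array]] != 0
  } else NULL
  surface_field(vt$points, tris, tawss, region_mask = mask,
                tawss_on = if (on_pt) "vertex" else "triangle")
}

#' Write a surface field as legacy-ASCII VTK PolyData
#'
#' @param s A [surface_field()] object.
#' @param path Output `.vtk` file.
#' @param tawss_array,mask_array Array names to write.
#' @export
write_surface_vtk <- function(s, path, tawss_array = "TAWSS",
                              mask_array = "region") {
  con <- file(path, "w")
  on.exit(close(con))
  nt <- nrow(s$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "tortuometry surface",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(s$vertices), "double")), con)
  writeLines(apply(s$vertices, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("POLYGONS", nt, 4 * nt), con)
  writeLines(apply(s$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  if (s$tawss_on == "vertex") {
    writeLines(c(paste("POINT_DATA", nrow(s$vertices)),
                 paste("SCALARS", tawss_array, "double 1"), "LOOKUP_TABLE default",
                 paste(fmt_num(s$tawss), collapse = " "),
                 paste("CELL_DATA", nt)), con)
  } else {
    writeLines(c(paste("CELL_DATA", nt),
                 paste("SCALARS", tawss_array, "double 1"), "LOOKUP_TABLE default",
                 paste(fmt_num(s$tawss), collapse = " ")), con)
  }
  writeLines(c(paste("SCALARS", mask_array, "int 1"), "LOOKUP_TABLE default",
               paste(as.integer(s$region_mask), collapse = " ")), con)
  invisible(path)
}

# ---- XML .vtp ---------------------------------------------------------------

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    rlang::abort(paste0("'", path, "' has no PolyData Piece"),
                 class = "tortuometry_parse_error")
  }
  da_values <- function(node) {
    if (inherits(node, "xml_missing")) return(NULL)
    if (!identical(xml2::xml_attr(node, "format"), "ascii")) {
      rlang::abort("only ascii-format .vtp DataArrays are supported",
                   class = "tortuometry_parse_error")
    }
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  }
  pts <- da_values(xml2::xml_find_first(piece, "./Points/DataArray"))
  points <- matrix(pts, ncol = 3, byrow = TRUE)
  read_cells <- function(tag) {
    conn <- da_values(xml2::xml_find_first(
      piece, paste0("./", tag, "/DataArray[@Name='connectivity']")))
    offs <- da_values(xml2::xml_find_first(
      piece, paste0("./", tag, "/DataArray[@Name='offsets']")))
    if (is.null(conn) || is.null(offs) || length(offs) == 0) return(list())
    starts <- c(0, offs[-length(offs)])
    purrr::map2(starts, offs, ~ as.integer(conn[(.x + 1):.y]) + 1L)
  }
  named_arrays <- function(tag) {
    nodes <- xml2::xml_find_all(piece, paste0("./", tag, "/DataArray"))
    vals <- purrr::map(nodes, da_values)
    rlang::set_names(vals, xml2::xml_attr(nodes, "Name"))
  }
  list(title = xml2::xml_attr(piece, "Name") %||% "",
       points = points,
       lines = read_cells("Lines"), polys = read_cells("Polys"),
       point_data = named_arrays("PointData"),
       cell_data = named_arrays("CellData"))
}

#' @rdname read_centerline
#' @export
read_polyline_vtp <- function(path) {
  vt <- read_vtp(path)
  if (length(vt$lines) == 0) {
    rlang::abort(paste0("'", path, "' has no line cells"),
                 class = "tortuometry_parse_error")
  }
  labels <- paste0("branch", seq_along(vt$lines))
  nm <- attr(vt$lines, "labels", exact = TRUE)
  purrr::map2(vt$lines, labels, function(idx, lb) {
    centerline(vt$points[idx, , drop = FALSE], label = lb)
  }) |> rlang::set_names(labels)
}

vtp_array <- function(values, name = NULL, ncomp = NULL, type = "Float64") {
  attrs <- paste0(' type="', type, '"',
                  if (!is.null(name)) paste0(' Name="', name, '"') else "",
                  if (!is.null(ncomp)) paste0(' NumberOfComponents="', ncomp, '"') else "",
                  ' format="ascii"')
  paste0("<DataArray", attrs, ">\n", paste(values, collapse = " "),
         "\n</DataArray>")
}

#' Write centerlines as XML PolyData (.vtp, ascii)
#'
#' @inheritParams write_centerline_csv
#' @export
write_centerline_vtp <- function(centerlines, path) {
  cls <- as_centerline_list(centerlines)
  pts <- purrr::map(cls, as_xyz_matrix)
  npts <- vapply(pts, nrow, integer(1))
  all_pts <- do.call(rbind, pts)
  conn <- seq_len(sum(npts)) - 1L
  offs <- cumsum(npts)
  body <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    "<PolyData>\n",
    sprintf('<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">\n',
            sum(npts), length(cls)),
    "<Points>\n", vtp_array(fmt_num(t(all_pts)), ncomp = 3), "\n</Points>\n",
    "<Lines>\n",
    vtp_array(conn, name = "connectivity", type = "Int64"), "\n",
    vtp_array(offs, name = "offsets", type = "Int64"), "\n",
    "</Lines>\n",
    "<CellData>\n",
    vtp_array(seq_along(cls) - 1L, name = "branch_id", type = "Int32"),
    "\n</CellData>\n",
    "</Piece>\n</PolyData>\n</VTKFile>\n")
  writeLines(body, path)
  invisible(path)
}

#' Write a surface field as XML PolyData (.vtp, ascii)
#'
#' @inheritParams write_surface_vtk
#' @export
write_surface_vtp <- function(s, path, tawss_array = "TAWSS",
                              mask_array = "region") {
  nt <- nrow(s$triangles)
  conn <- as.integer(t(s$triangles)) - 1L
  offs <- 3L * seq_len(nt)
  tawss_block <- vtp_array(fmt_num(s$tawss), name = tawss_array)
  pd <- if (s$tawss_on == "vertex") paste0("<PointData>\n", tawss_block, "\n</PointData>\n") else "<PointData>\n</PointData>\n"
  cd <- paste0("<CellData>\n",
               if (s$tawss_on == "triangle") paste0(tawss_block, "\n") else "",
               vtp_array(as.integer(s$region_mask), name = mask_array, type = "Int32"),
               "\n</CellData>\n")
  body <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    "<PolyData>\n",
    sprintf('<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">\n',
            nrow(s$vertices), nt),
    pd, cd,
    "<Points>\n", vtp_array(fmt_num(t(s$vertices)), ncomp = 3), "\n</Points>\n",
    "<Polys>\n",
    vtp_array(conn, name = "connectivity", type = "Int64"), "\n",
    vtp_array(offs, name = "offsets", type = "Int64"), "\n",
    "</Polys>\n",
    "</Piece>\n</PolyData>\n</VTKFile>\n")
  writeLines(body, path)
  invisible(path)
}

#' Read / write a cohort table CSV
#'
#' Thin wrappers fixing the column contract of the per-branch cohort table.
#'
#' @param path CSV path.
#' @return `read_cohort_csv`: a tibble; `write_cohort_csv`: `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("case_id", "branch", "low_tawss_fraction")
  if (!all(need %in% names(d))) {
    rlang::abort(paste("cohort CSV lacks columns:",
                       paste(setdiff(need, names(d)), collapse = ", ")),
                 class = "tortuometry_parse_error")
  }
  d
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
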