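#' Read a centerline from CSV or ASCII XML PolyData (.vtp)
#'
#' CSV input is a headerless or single-header table with columns `x`, `y`, `z`
#' in mm. VTP input is an XML PolyData file whose `Points` array holds the
#' coordinates and whose `Lines` connectivity describes a single polyline; only
#' ASCII-encoded arrays are supported. Cumulative arc lengths are recomputed on
#' read and duplicate consecutive points are merged with a warning.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"vtp"`, or `"auto"` (from the file extension).
#' @return A [centerline()].
#' @export
read_centerline <- function(path, format = c("auto", "csv", "vtp")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("input file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "csv"
  }
  pts <- switch(format, csv = read_points_csv(path), vtp = read_points_vtp(path))
  centerline(pts)
}

read_points_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]", first)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(df) <- tolower(names(df))
    if (!all(c("x", "y", "z") %in% names(df))) {
      abort_io("csv header must contain columns x, y, z")
    }
    df <- df[, c("x", "y", "z")]
  } else {
    if (ncol(df) < 3) abort_io("csv must have 3 coordinate columns")
    df <- df[, 1:3]
    names(df) <- c("x", "y", "z")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) abort_io("non-numeric coordinates in csv")
  if (nrow(df) < 2) abort_io("centerline file has fewer than 2 points")
  df
}

parse_ascii_array <- function(node) {
  fmt <- xml2::xml_attr(node, "format")
  if (!is.na(fmt) && fmt != "ascii") {
    abort_io("only ascii-format .vtp DataArrays are supported")
  }
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
}

read_points_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//PolyData/Piece")
  if (inherits(piece, "xml_missing")) abort_io("not a PolyData .vtp file")
  pts_node <- xml2::xml_find_first(piece, ".//Points/DataArray")
  if (inherits(pts_node, "xml_missing")) abort_io("no Points array in .vtp")
  coords <- parse_ascii_array(pts_node)
  if (length(coords) %% 3 != 0) abort_io("malformed Points array in .vtp")
  m <- matrix(coords, ncol = 3, byrow = TRUE)
  conn_node <- xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='connectivity']")
  if (inherits(conn_node, "xml_missing")) {
    abort_io(".vtp file contains no polyline (Lines) cell")
  }
  conn <- as.integer(parse_ascii_array(conn_node)) + 1L
  if (length(conn) < 2) abort_io("polyline in .vtp has fewer than 2 points")
  df <- as.data.frame(m[conn, , drop = FALSE])
  names(df) <- c("x", "y", "z")
  df
}

#' Write a centerline to CSV or ASCII .vtp
#'
#' @param c A [centerline()].
#' @param path Output path.
#' @param format `"csv"`, `"vtp"`, or `"auto"` (from the extension).
#' @param bend_id Optional integer vector, one per point, written as the
#'   `BendId` point-data array in `.vtp` output (ignored for CSV).
#' @export
write_centerline <- function(c, path, format = c("auto", "csv", "vtp"), bend_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(as.data.frame(c)[, c("x", "y", "z")]), path)
  } else {
    write_points_vtp(as_points(c), path, bend_id = bend_id)
  }
  invisible(path)
}

num_fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

write_points_vtp <- function(p, path, bend_id = NULL) {
  n <- nrow(p)
  coords <- paste(apply(p, 1, function(r) paste(num_fmt(r), collapse = " ")),
                  collapse = "\n")
  pd <- ""
  if (!is.null(bend_id)) {
    stopifnot(length(bend_id) == n)
    pd <- paste0(
      "      <PointData Scalars=\"BendId\">\n",
      "        <DataArray type=\"Int32\" Name=\"BendId\" format=\"ascii\">\n",
      paste(as.integer(bend_id), collapse = " "), "\n",
      "        </DataArray>\n      </PointData>\n"
    )
  }
  xml <- paste0(
    "<?xml version=\"1.0\"?>\n",
    "<VTKFile type=\"PolyData\" version=\"0.1\" byte_order=\"LittleEndian\">\n",
    "  <PolyData>\n",
    sprintf("    <Piece NumberOfPoints=\"%d\" NumberOfVerts=\"0\" NumberOfLines=\"1\" NumberOfStrips=\"0\" NumberOfPolys=\"0\">\n", n),
    pd,
    "      <Points>\n",
    "        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">\n",
    coords, "\n",
    "        </DataArray>\n",
    "      </Points>\n",
    "      <Lines>\n",
    "        <DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">\n",
    paste(0:(n - 1), collapse = " "), "\n",
    "        </DataArray>\n",
    "        <DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">\n",
    sprintf("%d\n", n),
    "        </DataArray>\n",
    "      </Lines>\n",
    "    </Piece>\n",
    "  </PolyData>\n",
    "</VTKFile>\n"
  )
  ok <- tryCatch({ writeLines(xml, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write file: %s", path))
  invisible(path)
}

#' Write a landmarking result to JSON and an annotated polyline
#'
#' The JSON file records the algorithm, its effective parameters, the interface
#' positions and the bend table (label, start/peak/end arc length, length). The
#' annotated `.vtp` carries a per-point integer array `BendId`: -1 outside any
#' bend, `0..n-1` inside bend `i` (0-based, proximal to distal).
#'
#' @param result A `landmark_result` (from [landmark_piccinelli()] or
#'   [landmark_bogunovic()]).
#' @param centerline The preprocessed [centerline()] the result refers to
#'   (`result$centerline` by default).
#' @param json_path,annotated_path Output paths; either may be `NULL` to skip.
#' @export
write_result <- function(result, centerline = result$centerline,
                         json_path = NULL, annotated_path = NULL) {
  stopifnot(inherits(result, "landmark_result"))
  bends <- result$bends
  if (nrow(bends) > 0 && max(bends$end_arclength) > total_length(centerline) + 1e-6) {
    abort_config("result refers to arc lengths beyond the centerline")
  }
  if (!is.null(json_path)) {
    payload <- list(
      algorithm = result$algorithm,
      parameters = result$parameters,
      failed = result$failed,
      interfaces = result$interfaces,
      bends = bends
    )
    ok <- tryCatch({
      jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) abort_io(sprintf("cannot write file: %s", json_path))
  }
  if (!is.null(annotated_path)) {
    write_centerline(centerline, annotated_path, format = "vtp",
                     bend_id = bend_id_per_point(bends, centerline$arclength))
  }
  invisible(result)
}

bend_id_per_point <- function(bends, arclengths) {
  id <- rep(-1L, length(arclengths))
  if (nrow(bends) == 0) return(id)
  for (i in seq_len(nrow(bends))) {
    inside <- arclengths >= bends$start_arclength[i] - 1e-9 &
      arclengths <= bends$end_arclength[i] + 1e-9
    id[inside & id == -1L] <- i - 1L
  }
  id
}

#' Read a landmarking result written by [write_result()]
#' @param json_path Path to the JSON file.
#' @return A list with `algorithm`, `parameters`, `failed`, `interfaces`, and
#'   the `bends` tibble.
#' @export
read_result <- function(json_path) {
  if (!file.exists(json_path)) abort_io(sprintf("input file not found: %s", json_path))
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  bends <- tibble::as_tibble(x$bends)
  if (nrow(bends) == 0) bends <- empty_bend_table()
  x$bends <- bends
  x$interfaces <- as.numeric(x$interfaces)
  x
}
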