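#' Read and write tidy count tables
#'
#' Count tables are stored as tidy CSV with one row per subject x region
#' (`subject_id`, `sex`, `group`, `region_id`, `region_abbrev`, `count`,
#' `missing`); masked entries have an empty count and `missing = TRUE`.
#'
#' @param table A regional count table.
#' @param path File path.
#' @return `read_count_table()` returns a tibble; `write_count_table()`
#'   returns `path` invisibly.
#' @export
write_count_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$missing <- as.logical(df$missing)
  df$count <- as.integer(df$count)
  as_tibble(df)
}

#' Candidate list CSV
#'
#' @param candidates Tibble with `z`, `y`, `x` voxel indices.
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_candidates_csv <- function(candidates, path) {
  write.csv(as.data.frame(candidates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_csv
#' @export
read_candidates_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a CellCounter-style marker XML as candidates
#'
#' Parses the marker XML dialect emitted by cell-detection tools
#' (`Marker` elements with `MarkerX/Y/Z` children; X/Y/Z taken as x, y, z
#' voxel indices).
#'
#' @param path XML file path.
#' @return Tibble `z`, `y`, `x`, `source_index`.
#' @export
read_marker_xml <- function(path) {
  doc <- xml2::read_xml(path)
  markers <- xml2::xml_find_all(doc, ".//Marker")
  get_num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  tibble(
    z = vapply(markers, get_num, numeric(1), tag = "MarkerZ"),
    y = vapply(markers, get_num, numeric(1), tag = "MarkerY"),
    x = vapply(markers, get_num, numeric(1), tag = "MarkerX"),
    source_index = seq_along(markers)
  )
}

#' NIfTI volume IO
#'
#' Thin wrappers around RNifti for intensity and label volumes, carrying
#' the voxel geometry as pixdim. Arrays are (z, y, x). Requires the RNifti
#' package.
#'
#' @param volume 3-D array.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param geometry A [voxel_geometry()].
#' @return The path (write) or an array (read).
#' @export
write_volume_nifti <- function(volume, path, geometry = voxel_geometry()) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required for NIfTI IO", class = "fishmap_error_dependency")
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- unclass(geometry)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required for NIfTI IO", class = "fishmap_error_dependency")
  }
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Export a brain graph
#'
#' Writes the signed edge list as CSV and, optionally, the graph as
#' GraphML (weights and signs preserved as edge attributes).
#'
#' @param graph A `brain_graph`.
#' @param csv_path Edge-list CSV path.
#' @param graphml_path Optional GraphML path.
#' @return The CSV path, invisibly.
#' @export
write_network <- function(graph, csv_path, graphml_path = NULL) {
  write.csv(as.data.frame(tidy(graph)), csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  }
  invisible(csv_path)
}
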