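#' Assign detected cells to atlas regions
#'
#' Looks up the atlas label at each cell's voxel. Cells are assumed to be
#' in the same registered space as the label volume; assignment is
#' nearest-voxel (positions are rounded to the containing voxel).
#' Background voxels (label 0) leave the cell unassigned (`NA`).
#'
#' @param cells Data frame with 0-based voxel-index columns `z`, `y`, `x`.
#' @param labels Integer 3-D array (z, y, x) of region labels, 0 =
#'   background.
#' @return `cells` with a `region_id` column (`NA` for background).
#' @export
assign_cells_to_regions <- function(cells, labels) {
  cells <- as_tibble(cells)
  if (!all(c("z", "y", "x") %in% names(cells))) {
    abort("cells need columns z, y, x", class = "fishmap_error_validation")
  }
  dm <- dim(labels)
  idx <- cbind(round(cells$z), round(cells$y), round(cells$x)) + 1L
  if (nrow(idx) > 0 &&
      (any(idx < 1L) || any(idx[, 1] > dm[1]) || any(idx[, 2] > dm[2]) ||
       any(idx[, 3] > dm[3]))) {
    abort("cell position outside the label volume", class = "fishmap_error_bounds")
  }
  lab <- if (nrow(idx) > 0) labels[idx] else integer(0)
  cells$region_id <- ifelse(lab == 0L, NA_integer_, as.integer(lab))
  cells
}

#' Build a per-animal regional count table
#'
#' Tallies assigned cells per subject and region, keeps only gray-matter
#' regions of the ontology (white-matter and clear labels are excluded from
#' analysis), and guarantees an identical region set across subjects:
#' subject x region combinations with no cells get an explicit zero row.
#' Unassigned cells (background) are dropped.
#'
#' @param cells Data frame with `subject_id` and `region_id` (as from
#'   [assign_cells_to_regions()]); a `stain_class` column, if present, is
#'   tallied into per-class columns as well.
#' @param ontology Data frame with `region_id`, `abbreviation`,
#'   `tissue_class` (values in gray/white/clear).
#' @param subjects Optional data frame with `subject_id` plus metadata
#'   (`sex`, `group`) joined onto the result; defaults to the subjects seen
#'   in `cells`.
#' @return A tibble, one row per subject x gray region: `subject_id`,
#'   (metadata), `region_id`, `region_abbrev`, `count`, `missing = FALSE`.
#' @export
build_count_table <- function(cells, ontology, subjects = NULL) {
  cells <- as_tibble(cells)
  ontology <- as_tibble(ontology)
  stopifnot(all(c("region_id", "tissue_class") %in% names(ontology)))
  if (anyDuplicated(ontology$region_id)) {
    abort("ontology region_ids must be unique", class = "fishmap_error_validation")
  }
  seen <- unique(cells$region_id[!is.na(cells$region_id)])
  if (!all(seen %in% ontology$region_id)) {
    abort("ontology does not cover all labels seen in cells",
          class = "fishmap_error_validation")
  }
  if (!"subject_id" %in% names(cells)) cells$subject_id <- "subject1"
  if (is.null(subjects)) {
    subjects <- tibble(subject_id = unique(cells$subject_id))
  }
  subjects <- as_tibble(subjects)

  gray <- ontology[ontology$tissue_class == "gray", , drop = FALSE]
  assigned <- cells[!is.na(cells$region_id) &
                      cells$region_id %in% gray$region_id, , drop = FALSE]

  grid <- tidyr::expand_grid(subject_id = subjects$subject_id,
                             region_id = gray$region_id)
  tallies <- assigned |>
    dplyr::count(.data$subject_id, .data$region_id, name = "count")
  out <- grid |>
    dplyr::left_join(tallies, by = c("subject_id", "region_id")) |>
    dplyr::mutate(count = as.integer(ifelse(is.na(.data$count), 0L, .data$count)))

  if ("stain_class" %in% names(assigned)) {
    by_class <- assigned |>
      dplyr::count(.data$subject_id, .data$region_id, .data$stain_class) |>
      tidyr::pivot_wider(names_from = "stain_class", values_from = "n",
                         names_prefix = "count_", values_fill = 0L)
    out <- dplyr::left_join(out, by_class, by = c("subject_id", "region_id"))
    cls_cols <- grep("^count_", names(out), value = TRUE)
    out[cls_cols] <- lapply(out[cls_cols],
                            function(v) as.integer(ifelse(is.na(v), 0L, v)))
  }

  abbr <- setNames(
    as.character(gray$abbreviation %||% sprintf("R%03d", gray$region_id)),
    as.character(gray$region_id))
  out$region_abbrev <- abbr[as.character(out$region_id)]
  out$missing <- FALSE
  out <- dplyr::left_join(out, subjects, by = "subject_id")
  meta <- setdiff(names(subjects), "subject_id")
  dplyr::relocate(out, dplyr::all_of(c("subject_id", meta, "region_id",
                                       "region_abbrev", "count", "missing")))
}

#' Flag failed-registration entries as missing
#'
#' Marks named subject x region entries as missing (count set to `NA`,
#' `missing = TRUE`), the treatment given to regions whose registration
#' failed (e.g. olfactory bulbs of individual brains). Downstream
#' correlation uses pairwise-complete observations, so flagged entries are
#' simply absent from the affected pairs rather than contributing zeros.
#'
#' @param table A regional count table.
#' @param mask Data frame with columns `subject_id` and `region_id` naming
#'   entries to mask. An empty mask returns the table unchanged.
#' @return The table with masked entries flagged.
#' @export
mask_failed_regions <- function(table, mask) {
  table <- as_tibble(table)
  mask <- as_tibble(mask)
  if (nrow(mask) == 0) return(table)
  stopifnot(all(c("subject_id", "region_id") %in% names(mask)))
  if (!all(mask$subject_id %in% table$subject_id) ||
      !all(mask$region_id %in% table$region_id)) {
    abort("mask names subjects or regions not in the table",
          class = "fishmap_error_validation")
  }
  key <- paste(table$subject_id, table$region_id)
  hit <- key %in% paste(mask$subject_id, mask$region_id)
  table$missing[hit] <- TRUE
  table$count[hit] <- NA_integer_
  table
}

#' Whole-brain c-fos cell density per subject
#'
#' Total gray-matter count divided by brain volume in cubic millimetres.
#' Missing (masked) entries are excluded from the total.
#'
#' @param table A regional count table.
#' @param brain_volume_mm3 Named numeric vector (names = subject ids) or
#'   data frame with `subject_id`, `volume_mm3`.
#' @return A tibble `subject_id`, (metadata), `total_count`,
#'   `volume_mm3`, `density` (cells per mm^3).
#' @export
whole_brain_density <- function(table, brain_volume_mm3) {
  table <- as_tibble(table)
  if (is.data.frame(brain_volume_mm3)) {
    vols <- setNames(brain_volume_mm3$volume_mm3, brain_volume_mm3$subject_id)
  } else {
    vols <- brain_volume_mm3
  }
  subs <- unique(table$subject_id)
  if (!all(subs %in% names(vols))) {
    abort("missing brain volume for some subjects", class = "fishmap_error_validation")
  }
  if (any(vols[subs] <= 0)) {
    abort("brain volumes must be positive", class = "fishmap_error_validation")
  }
  meta_cols <- intersect(c("sex", "group"), names(table))
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", meta_cols)))) |>
    dplyr::summarise(total_count = sum(.data$count, na.rm = TRUE),
                     .groups = "drop")
  out$volume_mm3 <- unname(vols[out$subject_id])
  out$density <- out$total_count / out$volume_mm3
  out
}

#' Brain volume implied by a label volume
#'
#' Number of nonzero-label voxels times the physical voxel volume.
#'
#' @param labels Integer 3-D label array.
#' @param geometry A [voxel_geometry()].
#' @return Volume in mm^3.
#' @export
label_volume_mm3 <- function(labels, geometry = voxel_geometry()) {
  sum(labels != 0L) * prod(unclass(geometry)) / 1e9
}
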