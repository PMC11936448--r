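#' Voxel geometry of an image stack
#'
#' Physical size of one voxel along each axis, in micrometres. Light-sheet
#' stacks of cleared adult zebrafish brains are strongly anisotropic: the
#' axial (z) step is several times the in-plane (y, x) pixel pitch, so any
#' distance rule expressed in micrometres must rescale voxel indices per
#' axis before computing Euclidean distance. The default matches a 4x/0.943
#' um-pixel acquisition with a 3.99 um z step.
#'
#' @param z,y,x Physical voxel size along each axis, in um. All must be
#'   positive.
#' @return A `voxel_geometry` object (named numeric vector of length 3,
#'   order z, y, x).
#' @examples
#' voxel_geometry()
#' voxel_geometry(z = 2, y = 1, x = 1)
#' @export
voxel_geometry <- function(z = 3.990, y = 0.943, x = 0.943) {
  sizes <- c(z = z, y = y, x = x)
  if (!is.numeric(sizes) || length(sizes) != 3L || anyNA(sizes) || any(sizes <= 0)) {
    abort("voxel sizes must be positive finite numbers", class = "fishmap_error_validation")
  }
  structure(sizes, class = c("voxel_geometry", "numeric"))
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> z = %.3f um, y = %.3f um, x = %.3f um\n",
              x[["z"]], x[["y"]], x[["x"]]))
  invisible(x)
}

#' Physical distance between voxel positions
#'
#' Euclidean distance in micrometres between two positions given in voxel
#' indices, after per-axis scaling by the voxel size. Vectorised: `a` and
#' `b` may be data frames with columns `z`, `y`, `x` (recycled row-wise) or
#' numeric vectors of length 3 in (z, y, x) order.
#'
#' @param a,b Positions in voxel indices: numeric length-3 vectors (z, y, x)
#'   or data frames with columns `z`, `y`, `x`.
#' @param geometry A [voxel_geometry()].
#' @return Numeric vector of distances in um.
#' @examples
#' physical_distance(c(0, 0, 0), c(0, 0, 10), voxel_geometry())  # 9.43
#' @export
physical_distance <- function(a, b, geometry = voxel_geometry()) {
  pa <- as_position_matrix(a)
  pb <- as_position_matrix(b)
  g <- unclass(voxel_geometry(geometry[[1]], geometry[[2]], geometry[[3]]))
  d <- sweep(pa, 2, g, `*`) - sweep(pb, 2, g, `*`)
  unname(sqrt(rowSums(d * d)))
}

as_position_matrix <- function(p) {
  if (is.data.frame(p)) {
    if (!all(c("z", "y", "x") %in% names(p))) {
      abort("positions need columns z, y, x", class = "fishmap_error_validation")
    }
    return(cbind(z = p$z, y = p$y, x = p$x))
  }
  if (is.numeric(p) && length(p) == 3L) {
    return(matrix(p, nrow = 1, dimnames = list(NULL, c("z", "y", "x"))))
  }
  abort("positions must be a data frame with z,y,x or a length-3 numeric", class = "fishmap_error_validation")
}

#' Remove near-duplicate cell candidates
#'
#' Automated cell detection on overlapping image chunks can report the same
#' soma more than once. This filter removes candidates that lie within
#' `min_dist_um` of an already-retained candidate, measured as physical
#' (per-axis scaled) Euclidean distance. The scan is greedy in input order:
#' the first candidate of a close pair is kept, later ones are dropped, so
#' the result is deterministic for a fixed input order. With
#' `keep = "intensity"` candidates are visited in decreasing intensity
#' instead, so the brighter member of each close pair survives; output order
#' still follows the original input.
#'
#' The boundary is strict: a pair at exactly `min_dist_um` is retained.
#'
#' @param candidates Data frame with voxel-index columns `z`, `y`, `x`;
#'   optional `intensity` (needed for `keep = "intensity"`).
#' @param geometry A [voxel_geometry()].
#' @param min_dist_um Minimum allowed pairwise distance in um (default 9).
#' @param keep `"first"` (default) keeps the earlier candidate of a close
#'   pair; `"intensity"` keeps the brighter one.
#' @return A tibble: the retained subset of `candidates`, original order,
#'   with a `source_index` column giving each row's position in the input.
#' @examples
#' cands <- tibble::tibble(z = c(0, 0, 5), y = c(0, 0, 5), x = c(0, 4, 5))
#' dedup_candidates(cands, voxel_geometry())
#' @export
dedup_candidates <- function(candidates, geometry = voxel_geometry(),
                             min_dist_um = 9, keep = c("first", "intensity")) {
  keep <- match.arg(keep)
  if (!is.numeric(min_dist_um) || length(min_dist_um) != 1L || min_dist_um <= 0) {
    abort("min_dist_um must be a single positive number", class = "fishmap_error_validation")
  }
  candidates <- as_tibble(candidates)
  if (!all(c("z", "y", "x") %in% names(candidates))) {
    abort("candidates need columns z, y, x", class = "fishmap_error_validation")
  }
  n <- nrow(candidates)
  if (!"source_index" %in% names(candidates)) {
    candidates$source_index <- seq_len(n)
  }
  if (n <= 1L) return(candidates)

  if (keep == "intensity") {
    if (!"intensity" %in% names(candidates)) {
      abort("keep = \"intensity\" needs an intensity column", class = "fishmap_error_validation")
    }
    visit <- order(-candidates$intensity, candidates$source_index)
  } else {
    visit <- seq_len(n)
  }

  g <- unclass(voxel_geometry(geometry[[1]], geometry[[2]], geometry[[3]]))
  pos <- cbind(candidates$z * g["z"], candidates$y * g["y"], candidates$x * g["x"])

  keep_mask <- rep(FALSE, n)
  kept_pos <- matrix(numeric(0), ncol = 3)
  for (i in visit) {
    if (nrow(kept_pos) > 0L) {
      d2 <- (kept_pos[, 1] - pos[i, 1])^2 + (kept_pos[, 2] - pos[i, 2])^2 +
        (kept_pos[, 3] - pos[i, 3])^2
      if (any(d2 < min_dist_um^2)) next
    }
    keep_mask[i] <- TRUE
    kept_pos <- rbind(kept_pos, pos[i, , drop = FALSE])
  }
  out <- candidates[keep_mask, , drop = FALSE]
  out[order(out$source_index), , drop = FALSE]
}
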