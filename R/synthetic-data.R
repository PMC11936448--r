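#' Default experimental design for simulated count tables
#'
#' Group labels and per-sex animal counts for the novel-tank time course:
#' two controls (animals taken straight off the housing rack, and home-tank
#' animals habituated to the behaviour room) plus five post-behaviour kill
#' times. Cell sizes are 3-7 animals per sex, typical of whole-brain
#' clearing studies.
#'
#' @return A tibble with columns `label`, `n_female`, `n_male`.
#' @export
default_groups <- function() {
  tibble(
    label    = c("rack", "HT", "5min", "15min", "30min", "60min", "120min"),
    n_female = c(4L, 5L, 6L, 7L, 5L, 4L, 5L),
    n_male   = c(4L, 4L, 5L, 6L, 5L, 4L, 3L)
  )
}

#' Default time-course fold changes
#'
#' Multiplicative change in regional c-fos rate per group, relative to the
#' rack control. Induction peaks at 15 min (about 3.5-fold, the scale seen
#' for immediate-early-gene induction shortly after behaviour) and decays
#' back to baseline by 60-120 min.
#'
#' @return Named numeric vector, one entry per default group.
#' @export
default_fold_change <- function() {
  c(rack = 1, HT = 1, "5min" = 1.8, "15min" = 3.5, "30min" = 1.6,
    "60min" = 1.1, "120min" = 1)
}

#' Specification of a simulated regional count table
#'
#' Defines the generative model for per-animal, per-region c-fos counts:
#' a log-normal latent rate per animal x region, Poisson-sampled into
#' counts. The latent log-rate is
#' `baseline_r + log(fold_change[group, r]) + loading * f[animal, comm(r)]
#'  + dispersion * noise`,
#' where `f` are per-animal standard-normal community factors. The shared
#' factor induces cross-animal correlation between regions of the same
#' community -- the knob the network stage needs. Designated hub regions
#' instead load on the (variance-normalised) sum of all community factors,
#' so they correlate with every community and acquire high degree in the
#' thresholded network.
#'
#' @param n_regions Number of brain regions.
#' @param n_communities Number of planted communities.
#' @param community_assignment Optional integer vector of length
#'   `n_regions` mapping each region to a community in
#'   `1:n_communities`; default splits regions into contiguous blocks.
#' @param hub_regions Integer vector of region ids planted as hubs
#'   (default none).
#' @param hub_loading Latent loading of hub regions on the pooled
#'   community factor.
#' @param groups Design tibble as from [default_groups()].
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-region
#'   log baseline rate (drawn once per region).
#' @param fold_change Either a named numeric vector (one multiplier per
#'   group label, shared by all regions) or a groups x regions matrix with
#'   rownames matching group labels. All entries must be positive.
#' @param latent_loading Loading of non-hub regions on their community
#'   factor; 0 removes all planted correlation.
#' @param dispersion SD of the per-entry log-normal noise on the latent
#'   rate (over-dispersion beyond Poisson).
#' @param missing_spec List of `list(group =, regions =, n_animals =)`
#'   entries planting missing observations (e.g. regions lost to failed
#'   registration) for the first `n_animals` animals of `group`.
#' @param seed Integer RNG seed; identical spec + seed reproduces the
#'   table bit-for-bit.
#' @return A `count_table_spec` object.
#' @seealso [simulate_count_table()]
#' @export
count_table_spec <- function(n_regions = 60,
                             n_communities = 4,
                             community_assignment = NULL,
                             hub_regions = integer(0),
                             hub_loading = 1,
                             groups = default_groups(),
                             baseline_log_mean = log(200),
                             baseline_log_sd = 0.7,
                             fold_change = default_fold_change(),
                             latent_loading = 0.4,
                             dispersion = 0.9,
                             missing_spec = list(),
                             seed = 1L) {
  if (n_regions < 1 || n_communities < 1) {
    abort("n_regions and n_communities must be positive", class = "fishmap_error_validation")
  }
  groups <- as_tibble(groups)
  stopifnot(all(c("label", "n_female", "n_male") %in% names(groups)))
  if (any(groups$n_female + groups$n_male < 1)) {
    abort("every group needs at least one animal", class = "fishmap_error_validation")
  }
  if (is.null(community_assignment)) {
    community_assignment <- sort(rep_len(seq_len(n_communities), n_regions))
  }
  if (length(community_assignment) != n_regions ||
      anyNA(community_assignment) ||
      !all(community_assignment %in% seq_len(n_communities))) {
    abort("community_assignment must map every region to a community",
          class = "fishmap_error_validation")
  }
  if (is.matrix(fold_change)) {
    if (!identical(dim(fold_change), c(nrow(groups), as.integer(n_regions))) &&
        !identical(dim(fold_change), c(nrow(groups), n_regions))) {
      abort("fold_change matrix must be groups x regions", class = "fishmap_error_validation")
    }
    fc <- fold_change
    if (is.null(rownames(fc))) rownames(fc) <- groups$label
  } else {
    if (is.null(names(fold_change)) || !all(groups$label %in% names(fold_change))) {
      abort("fold_change vector must be named with every group label",
            class = "fishmap_error_validation")
    }
    fc <- matrix(rep(fold_change[groups$label], n_regions),
                 nrow = nrow(groups), dimnames = list(groups$label, NULL))
  }
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    abort("all fold_change entries must be positive and finite",
          class = "fishmap_error_validation")
  }
  if (!all(hub_regions %in% seq_len(n_regions))) {
    abort("hub_regions outside 1:n_regions", class = "fishmap_error_validation")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         n_communities = as.integer(n_communities),
         community_assignment = as.integer(community_assignment),
         hub_regions = as.integer(hub_regions),
         hub_loading = hub_loading,
         groups = groups,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         fold_change = fc,
         latent_loading = latent_loading,
         dispersion = dispersion,
         missing_spec = missing_spec,
         seed = as.integer(seed)),
    class = "count_table_spec"
  )
}

#' Simulate a per-animal, per-region count table
#'
#' Draws a tidy count table under a [count_table_spec()]. Planted missing
#' entries (from `missing_spec`) are flagged with `missing = TRUE` and an
#' `NA` count -- never zero-filled, since zeros would corrupt downstream
#' correlations. Ground truth (region communities, hub flags, baselines)
#' travels in the `"planted"` attribute; see [planted_structure()].
#'
#' @param spec A [count_table_spec()].
#' @return A tibble with columns `subject_id`, `sex`, `group`, `region_id`,
#'   `region_abbrev`, `count`, `missing`.
#' @examples
#' tbl <- simulate_count_table(count_table_spec(n_regions = 8, seed = 42))
#' dplyr::count(tbl, group)
#' @export
simulate_count_table <- function(spec) {
  stopifnot(inherits(spec, "count_table_spec"))
  set.seed(spec$seed)
  R <- spec$n_regions
  comm <- spec$community_assignment
  is_hub <- seq_len(R) %in% spec$hub_regions

  baseline <- rnorm(R, spec$baseline_log_mean, spec$baseline_log_sd)

  subjects <- purrr::pmap_dfr(spec$groups, function(label, n_female, n_male) {
    tibble(group = label,
           sex = rep(c("F", "M"), c(n_female, n_male)))
  })
  subjects$subject_id <- sprintf("fish%03d", seq_len(nrow(subjects)))
  n_sub <- nrow(subjects)

  # per-animal community factors and the pooled hub factor
  f <- matrix(rnorm(n_sub * spec$n_communities), n_sub, spec$n_communities)
  hub_factor <- rowSums(f) / sqrt(spec$n_communities)

  rows <- vector("list", n_sub)
  for (a in seq_len(n_sub)) {
    g <- subjects$group[a]
    latent <- ifelse(is_hub,
                     spec$hub_loading * hub_factor[a],
                     spec$latent_loading * f[a, comm])
    eta <- baseline + log(spec$fold_change[g, ]) + latent +
      spec$dispersion * rnorm(R)
    rows[[a]] <- tibble(
      subject_id = subjects$subject_id[a],
      sex = subjects$sex[a],
      group = g,
      region_id = seq_len(R),
      region_abbrev = sprintf("R%03d", seq_len(R)),
      count = rpois(R, exp(eta)),
      missing = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)

  for (ms in spec$missing_spec) {
    subj <- subjects$subject_id[subjects$group == ms$group]
    subj <- head(subj, ms$n_animals)
    hit <- out$subject_id %in% subj & out$region_id %in% ms$regions
    out$missing[hit] <- TRUE
    out$count[hit] <- NA_integer_
  }

  attr(out, "planted") <- list(
    spec = spec,
    regions = tibble(region_id = seq_len(R),
                     region_abbrev = sprintf("R%03d", seq_len(R)),
                     community = comm,
                     is_hub = is_hub,
                     baseline_log_rate = baseline),
    subjects = subjects[, c("subject_id", "sex", "group")]
  )
  out
}

#' Ground truth planted in a simulated table
#'
#' @param table A tibble produced by [simulate_count_table()].
#' @return A list with `spec`, `regions` (community / hub ground truth) and
#'   `subjects`.
#' @export
planted_structure <- function(table) {
  p <- attr(table, "planted")
  if (is.null(p)) abort("no planted structure attached to this table",
                        class = "fishmap_error_validation")
  p
}

#' Specification of a simulated cell-candidate point cloud
#'
#' Base points are scattered with a guaranteed mutual physical separation,
#' then a fraction receive a planted duplicate at a controlled physical
#' offset -- below or above the deduplication radius -- so the filter's
#' hit/miss behaviour has exact ground truth.
#'
#' @param n_points Number of base points.
#' @param duplicate_fraction Fraction of base points duplicated.
#' @param duplicate_offset_um Numeric vector of physical offsets (um) from
#'   which each planted duplicate's displacement is drawn uniformly.
#' @param bounds Volume extent in voxels, `(z, y, x)`.
#' @param geometry A [voxel_geometry()].
#' @param seed Integer RNG seed.
#' @return A `point_cloud_spec` object.
#' @export
point_cloud_spec <- function(n_points = 200,
                             duplicate_fraction = 0.2,
                             duplicate_offset_um = c(4, 12),
                             bounds = c(100, 400, 400),
                             geometry = voxel_geometry(),
                             seed = 1L) {
  if (n_points < 1 || duplicate_fraction < 0 || duplicate_fraction > 1) {
    abort("invalid point-cloud spec", class = "fishmap_error_validation")
  }
  if (any(duplicate_offset_um <= 0)) {
    abort("duplicate offsets must be positive", class = "fishmap_error_validation")
  }
  structure(
    list(n_points = as.integer(n_points),
         duplicate_fraction = duplicate_fraction,
         duplicate_offset_um = duplicate_offset_um,
         bounds = bounds, geometry = geometry, seed = as.integer(seed)),
    class = "point_cloud_spec"
  )
}

#' Simulate a candidate point cloud with planted duplicates
#'
#' @param spec A [point_cloud_spec()].
#' @return A list: `candidates` (tibble `z`, `y`, `x`, `source_index`,
#'   `intensity`, `is_duplicate`) and `pairs` (tibble `original`,
#'   `duplicate`, `offset_um` of planted pairs, indices into `candidates`).
#'   Base points are at least `9 + max(offset) + 1` um apart, so the only
#'   sub-threshold pairs are the planted ones.
#' @export
simulate_point_cloud <- function(spec) {
  stopifnot(inherits(spec, "point_cloud_spec"))
  set.seed(spec$seed)
  g <- unclass(spec$geometry)
  min_sep <- 9 + max(spec$duplicate_offset_um) + 1

  pos <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(pos) < spec$n_points) {
    tries <- tries + 1L
    if (tries > 200L * spec$n_points) {
      abort("could not place points at required separation; enlarge bounds",
            class = "fishmap_error_validation")
    }
    cand <- runif(3, 0, spec$bounds - 1)
    phys <- cand * g
    if (nrow(pos) > 0) {
      d2 <- colSums((t(pos) * g - phys)^2)
      if (min(d2) < min_sep^2) next
    }
    pos <- rbind(pos, cand)
  }

  n_dup <- round(spec$duplicate_fraction * spec$n_points)
  dup_of <- sample.int(spec$n_points, n_dup)
  dup_rows <- matrix(numeric(0), ncol = 3)
  offsets <- numeric(0)
  for (i in dup_of) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      off_um <- sample(rep(spec$duplicate_offset_um, 2), 1)  # rep: length-1 safe
      p <- pos[i, ] + (u * off_um) / g
      if (all(p >= 0) && all(p <= spec$bounds - 1)) break
    }
    dup_rows <- rbind(dup_rows, p)
    offsets <- c(offsets, off_um)
  }

  all_pos <- rbind(pos, dup_rows)
  n_all <- nrow(all_pos)
  candidates <- tibble(
    z = all_pos[, 1], y = all_pos[, 2], x = all_pos[, 3],
    source_index = seq_len(n_all),
    intensity = runif(n_all, 1, 10),
    is_duplicate = c(rep(FALSE, spec$n_points), rep(TRUE, n_dup))
  )
  pairs <- tibble(original = dup_of,
                  duplicate = spec$n_points + seq_len(n_dup),
                  offset_um = offsets)
  list(candidates = candidates, pairs = pairs)
}

#' Specification of a simulated labeled volume
#'
#' A 3-D intensity stack over a toy atlas: the volume is partitioned into
#' axial slabs, each slab one region with a tissue class (gray, white or
#' clear), and cells of two stain morphologies are rendered at separated
#' positions. Punctate cells are compact bright Gaussian cores (recent
#' nuclear transcription); diffuse cells are dimmer filled somata with a
#' slightly darker centre (older cytoplasmic signal). With the default
#' parameters the two classes are separable by construction: the punctate
#' peak (~12) is three times the diffuse plateau (~4), both far above the
#' background noise SD.
#'
#' @param shape Volume extent `(z, y, x)` in voxels; each axis >= 11.
#' @param voxel_size_um Physical voxel sizes, a [voxel_geometry()].
#' @param n_cells Number of cells to render.
#' @param fraction_punctate Fraction of cells rendered punctate.
#' @param punctate_params `list(sigma_px =, peak =)` Gaussian core shape.
#' @param diffuse_params `list(radius_px =, plateau =)` soma shape.
#' @param background_sd SD of background noise around mean 1.
#' @param n_regions Number of atlas slabs.
#' @param white_matter_labels,clear_labels Region ids classed as white
#'   matter / clear (excluded from gray-matter analyses).
#' @param seed Integer RNG seed.
#' @return A `volume_spec` object.
#' @export
volume_spec <- function(shape = c(40, 60, 60),
                        voxel_size_um = voxel_geometry(1, 1, 1),
                        n_cells = 30,
                        fraction_punctate = 0.5,
                        punctate_params = list(sigma_px = 2, peak = 12),
                        diffuse_params = list(radius_px = 4, plateau = 4),
                        background_sd = 0.3,
                        n_regions = 4,
                        white_matter_labels = integer(0),
                        clear_labels = integer(0),
                        seed = 1L) {
  if (any(shape < 11)) {
    abort("volume must be at least 11 voxels along every axis",
          class = "fishmap_error_validation")
  }
  if (fraction_punctate < 0 || fraction_punctate > 1) {
    abort("fraction_punctate must be in [0,1]", class = "fishmap_error_validation")
  }
  structure(
    list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
         n_cells = as.integer(n_cells), fraction_punctate = fraction_punctate,
         punctate_params = punctate_params, diffuse_params = diffuse_params,
         background_sd = background_sd, n_regions = as.integer(n_regions),
         white_matter_labels = as.integer(white_matter_labels),
         clear_labels = as.integer(clear_labels), seed = as.integer(seed)),
    class = "volume_spec"
  )
}

#' Simulate an intensity volume over a toy labeled atlas
#'
#' @param spec A [volume_spec()].
#' @return A list: `intensity` (3-D array, z-y-x), `labels` (integer 3-D
#'   array partitioning the volume into `n_regions` slabs), `cells`
#'   (ground-truth tibble `z`, `y`, `x`, `stain_class`, `region_id`) and
#'   `ontology` (tibble `region_id`, `abbreviation`, `name`,
#'   `tissue_class`).
#' @export
simulate_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  set.seed(spec$seed)
  dz <- spec$shape[1]; dy <- spec$shape[2]; dx <- spec$shape[3]

  intensity <- array(pmax(rnorm(dz * dy * dx, 1, spec$background_sd), 0),
                     dim = spec$shape)

  # atlas: slabs along y
  breaks <- floor(seq(0, dy, length.out = spec$n_regions + 1))
  slab <- findInterval(seq_len(dy) - 1, breaks, rightmost.closed = TRUE)
  slab <- pmin(slab, spec$n_regions)
  labels <- array(0L, dim = spec$shape)
  for (j in seq_len(dy)) labels[, j, ] <- slab[j]

  tissue <- rep("gray", spec$n_regions)
  tissue[spec$white_matter_labels] <- "white"
  tissue[spec$clear_labels] <- "clear"
  ontology <- tibble(region_id = seq_len(spec$n_regions),
                     abbreviation = sprintf("R%02d", seq_len(spec$n_regions)),
                     name = sprintf("toy region %d", seq_len(spec$n_regions)),
                     tissue_class = tissue)

  margin <- 5L
  min_sep_px <- 9
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(centers) < spec$n_cells) {
    tries <- tries + 1L
    if (tries > 500L * max(spec$n_cells, 1L)) {
      abort("cell count infeasible for volume size", class = "fishmap_error_validation")
    }
    p <- c(sample(margin:(dz - 1 - margin), 1),
           sample(margin:(dy - 1 - margin), 1),
           sample(margin:(dx - 1 - margin), 1))
    if (nrow(centers) > 0 && min(colSums((t(centers) - p)^2)) < min_sep_px^2) next
    centers <- rbind(centers, p)
  }

  n_punct <- round(spec$fraction_punctate * spec$n_cells)
  classes <- c(rep("punctate", n_punct),
               rep("diffuse", spec$n_cells - n_punct))

  for (i in seq_len(spec$n_cells)) {
    ctr <- centers[i, ]
    if (classes[i] == "punctate") {
      s <- spec$punctate_params$sigma_px
      r <- ceiling(3 * s)
      pk <- spec$punctate_params$peak
    } else {
      r <- spec$diffuse_params$radius_px
      pk <- spec$diffuse_params$plateau
    }
    zr <- max(1, ctr[1] + 1 - r):min(dz, ctr[1] + 1 + r)
    yr <- max(1, ctr[2] + 1 - r):min(dy, ctr[2] + 1 + r)
    xr <- max(1, ctr[3] + 1 - r):min(dx, ctr[3] + 1 + r)
    dzv <- zr - 1 - ctr[1]; dyv <- yr - 1 - ctr[2]; dxv <- xr - 1 - ctr[3]
    dist <- sqrt(outer(outer(dzv^2, dyv^2, `+`), dxv^2, `+`))
    if (classes[i] == "punctate") {
      blob <- pk * exp(-dist^2 / (2 * spec$punctate_params$sigma_px^2))
    } else {
      # filled soma, centre slightly dimmer than the rim
      blob <- ifelse(dist <= r, pk * (0.75 + 0.25 * dist / r), 0)
    }
    intensity[zr, yr, xr] <- intensity[zr, yr, xr] + blob
  }

  cells <- tibble(
    z = as.integer(centers[, 1]), y = as.integer(centers[, 2]),
    x = as.integer(centers[, 3]),
    stain_class = classes,
    region_id = labels[centers + 1L]
  )
  list(intensity = intensity, labels = labels, cells = cells,
       ontology = ontology)
}
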