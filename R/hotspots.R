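# Hotspot extraction: per-patient top-decile PS voxels inside the eroded WM
# mask, connected components, minimum-size filter, atlas assignment and a
# semiquantitative regional load. The threshold is rank-based and relative to
# each patient's own PS distribution, so hotspot counts are invariant under
# any strictly monotone transform of the map.

#' Top-decile threshold of a PS map within a mask
#'
#' Nearest-rank percentile: with `N` mask voxels, `k = round(fraction * N)`
#' (at least 1) and the threshold is the k-th largest PS value in the mask.
#' All voxels at or above the threshold are selected, so ties at the threshold
#' can push the selected count above `k`; with all mask values equal the
#' degenerate selection is the whole mask.
#'
#' @param ps_map Numeric 3D array.
#' @param mask Logical 3D array, nonempty.
#' @param fraction Upper tail fraction in (0, 1); default 0.10 (highest decile).
#' @return List with `threshold_value`, `selected` (logical 3D array),
#'   `n_mask_voxels`, `n_selected_voxels`, `ties_at_threshold`.
#' @export
#' @examples
#' m <- array(TRUE, c(10, 10, 1))
#' ps <- array(1:100, c(10, 10, 1))
#' decile_threshold(ps, m)$threshold_value  # 91
decile_threshold <- function(ps_map, mask, fraction = 0.10) {
  check_mask3d(mask)
  stopifnot_scalar_number(fraction, "fraction",
                          lower = .Machine$double.xmin, upper = 1 - 1e-12)
  vals <- ps_map[mask]
  n <- length(vals)
  if (n == 0L) stop("empty mask", call. = FALSE)
  k <- max(1L, as.integer(round(fraction * n)))
  threshold <- sort(vals, decreasing = TRUE, method = "radix")[k]
  selected <- mask & !is.na(ps_map) & ps_map >= threshold
  list(threshold_value = threshold,
       selected = selected,
       n_mask_voxels = n,
       n_selected_voxels = sum(selected),
       ties_at_threshold = sum(vals == threshold) - 1L)
}

#' Assign a hotspot to an atlas region by majority vote
#'
#' Majority vote over the atlas codes of the hotspot's voxels; exact ties are
#' broken toward the lowest code so assignment is deterministic. Voxels with
#' atlas code 0 do not vote; a hotspot entirely on unlabeled voxels is
#' `"unassigned"`.
#'
#' @param voxels Integer flat voxel indices of one hotspot.
#' @param atlas Integer 3D atlas array (`10 * region + side`).
#' @return List with `code`, `region`, `side`.
#' @export
assign_region <- function(voxels, atlas) {
  codes <- atlas[voxels]
  codes <- codes[codes > 0L]
  if (length(codes) == 0L) {
    return(list(code = 0L, region = "unassigned", side = "unassigned"))
  }
  tab <- table(codes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  code <- min(winners)
  dec <- atlas_decode(code)
  list(code = code, region = dec$region, side = dec$side)
}

#' Filter labeled components into a hotspot set
#'
#' Keeps components of at least `min_size` voxels and computes per-hotspot
#' size, centroid (mm, from 0-based voxel indices), mean PS and atlas region.
#'
#' @param components Integer 3D labeled component array (from
#'   [label_components()]).
#' @param min_size Minimum component size in voxels (default 5).
#' @param ps_map Numeric 3D PS array.
#' @param atlas Integer 3D region atlas, or `NULL` to skip region assignment.
#' @param voxel_mm Per-axis voxel size (mm) for centroids.
#' @return A tibble with one row per retained hotspot: `hotspot_id`, `size`,
#'   `centroid_x/y/z_mm`, `region`, `side`, `region_code`, `mean_ps`,
#'   `voxels` (list-column of flat indices).
#' @export
filter_min_size <- function(components, min_size = 5L, ps_map = NULL,
                            atlas = NULL, voxel_mm = c(1, 1, 1)) {
  stopifnot_scalar_number(min_size, "min_size", lower = 1)
  shape <- dim(components)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  labs <- components[components > 0L]
  if (length(labs) == 0L) return(empty_hotspot_tibble())
  sizes <- tabulate(labs)
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(empty_hotspot_tibble())

  vox_all <- which(components > 0L)
  by_label <- split(vox_all, components[vox_all])
  rows <- lapply(seq_along(keep), function(i) {
    vox <- by_label[[as.character(keep[i])]]
    cc <- flat_to_coord(vox, shape)
    reg <- if (is.null(atlas)) {
      list(code = 0L, region = "unassigned", side = "unassigned")
    } else {
      assign_region(vox, atlas)
    }
    tibble::tibble(
      hotspot_id = i,
      size = length(vox),
      centroid_x_mm = mean(cc[, 1L] - 1L) * voxel_mm[1L],
      centroid_y_mm = mean(cc[, 2L] - 1L) * voxel_mm[2L],
      centroid_z_mm = mean(cc[, 3L] - 1L) * voxel_mm[3L],
      region = reg$region, side = reg$side, region_code = reg$code,
      mean_ps = if (is.null(ps_map)) NA_real_ else mean(ps_map[vox]),
      voxels = list(vox)
    )
  })
  dplyr::bind_rows(rows)
}

empty_hotspot_tibble <- function() {
  tibble::tibble(hotspot_id = integer(), size = integer(),
                 centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                 centroid_z_mm = numeric(), region = character(),
                 side = character(), region_code = integer(),
                 mean_ps = numeric(), voxels = list())
}

#' Detect BBB-leakage hotspots in a PS map
#'
#' End-to-end hotspot extraction for one patient: top-decile threshold inside
#' the analysis mask, connected components under the configured contiguity,
#' and the minimum-size filter. The hotspot count is the number of retained
#' components.
#'
#' @param ps_map Numeric 3D PS array (1/min).
#' @param mask Logical 3D analysis mask (typically the eroded WM mask).
#' @param atlas Optional integer 3D region atlas for regional assignment.
#' @param voxel_mm Per-axis voxel size in mm.
#' @param fraction Upper-tail fraction (default 0.10).
#' @param min_size Minimum cluster size in voxels (default 5).
#' @param connectivity Contiguity rule, 26 (default) or 6.
#' @return Object of class `bbb_hotspots`: list with `hotspots` (tibble, see
#'   [filter_min_size()]), `threshold_value`, `n_mask_voxels`,
#'   `n_selected_voxels`, `n_hotspots`, `selected` and `component_labels`
#'   arrays, and the parameters used.
#' @export
#' @examples
#' ps <- array(stats::rnorm(27e3), c(30, 30, 30))
#' mask <- array(TRUE, c(30, 30, 30))
#' hs <- detect_hotspots(ps, mask)
#' hs$n_hotspots
detect_hotspots <- function(ps_map, mask, atlas = NULL, voxel_mm = c(1, 1, 1),
                            fraction = 0.10, min_size = 5L,
                            connectivity = 26L) {
  thr <- decile_threshold(ps_map, mask, fraction)
  comp <- label_components(thr$selected, connectivity)
  hotspots <- filter_min_size(comp, min_size, ps_map, atlas, voxel_mm)
  hotspot_labels <- array(0L, dim = dim(comp))
  for (i in seq_len(nrow(hotspots))) {
    hotspot_labels[hotspots$voxels[[i]]] <- hotspots$hotspot_id[i]
  }
  structure(
    list(hotspots = hotspots,
         threshold_value = thr$threshold_value,
         n_mask_voxels = thr$n_mask_voxels,
         n_selected_voxels = thr$n_selected_voxels,
         ties_at_threshold = thr$ties_at_threshold,
         n_hotspots = nrow(hotspots),
         selected = thr$selected,
         component_labels = comp,
         hotspot_labels = hotspot_labels,
         params = list(fraction = fraction, min_size = min_size,
                       connectivity = connectivity)),
    class = "bbb_hotspots"
  )
}

#' @export
print.bbb_hotspots <- function(x, ...) {
  cat(sprintf(
    "<bbb_hotspots> %d hotspots (>= %d voxels, %d-connectivity) from %d/%d selected voxels; threshold %.3g\n",
    x$n_hotspots, x$params$min_size, x$params$connectivity,
    x$n_selected_voxels, x$n_mask_voxels, x$threshold_value))
  invisible(x)
}

#' @export
tidy.bbb_hotspots <- function(x, ...) {
  dplyr::select(x$hotspots, -"voxels")
}

#' @export
glance.bbb_hotspots <- function(x, ...) {
  tibble::tibble(n_hotspots = x$n_hotspots,
                 threshold_value = x$threshold_value,
                 n_mask_voxels = x$n_mask_voxels,
                 n_selected_voxels = x$n_selected_voxels,
                 selected_fraction = x$n_selected_voxels / x$n_mask_voxels,
                 min_size = x$params$min_size,
                 connectivity = x$params$connectivity)
}

#' Plot an axial slice of a hotspot map
#'
#' @param object A `bbb_hotspots` object.
#' @param slice Axial (third-axis) slice index; default the middle slice.
#' @param ... Unused.
#' @export
autoplot.bbb_hotspots <- function(object, slice = NULL, ...) {
  dims <- dim(object$hotspot_labels)
  if (is.null(slice)) slice <- ceiling(dims[3L] / 2)
  df <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]))
  df$selected <- as.vector(object$selected[, , slice])
  df$hotspot <- as.vector(object$hotspot_labels[, , slice]) > 0L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$selected), show.legend = FALSE) +
    ggplot2::geom_point(data = df[df$hotspot, , drop = FALSE],
                        colour = "red", size = 0.6) +
    ggplot2::scale_fill_manual(values = c("grey90", "grey40")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Top-decile PS voxels and hotspots, slice %d", slice))
}

#' Semiquantitative regional hotspot load
#'
#' Per region and side, the hotspot count maps to an ordinal load: 0 hotspots
#' is absence (0), counts up to the first cut-off are low (1), up to the
#' second are medium (2), and at or above the third are high (3). Left and
#' right loads are summed to the 0-6 scale used to describe regional
#' distribution.
#'
#' @param hotspots A `bbb_hotspots` object or its `hotspots` tibble (needs
#'   `region` and `side` columns).
#' @param cut_offs Increasing integer vector of length 3: the minimum counts
#'   for low, medium and high (default `c(1, 3, 6)`, i.e. 1-2 low, 3-5
#'   medium, >= 6 high). These cut-offs are this package's own convention and
#'   are recorded in the output.
#' @return A tibble with one row per region: `region`, `n_left`, `n_right`,
#'   `load_left`, `load_right`, `load_total` (0-6); attribute `cut_offs`.
#' @export
regional_load <- function(hotspots, cut_offs = c(1L, 3L, 6L)) {
  if (inherits(hotspots, "bbb_hotspots")) hotspots <- hotspots$hotspots
  if (length(cut_offs) != 3L || any(diff(cut_offs) <= 0) || cut_offs[1L] < 1L) {
    stop("`cut_offs` must be 3 increasing positive counts", call. = FALSE)
  }
  count_to_load <- function(n) {
    findInterval(n, c(cut_offs[1L], cut_offs[2L], cut_offs[3L]))
  }
  regions <- atlas_regions()$region
  counts <- tidyr::complete(
    dplyr::count(dplyr::filter(hotspots, .data$region != "unassigned"),
                 .data$region, .data$side),
    region = regions, side = c("left", "right"), fill = list(n = 0L)
  )
  out <- tidyr::pivot_wider(counts, names_from = "side", values_from = "n",
                            names_prefix = "n_", values_fill = 0L)
  if (!"n_left" %in% names(out)) out$n_left <- 0L
  if (!"n_right" %in% names(out)) out$n_right <- 0L
  out <- dplyr::mutate(
    dplyr::select(out, "region", "n_left", "n_right"),
    load_left = count_to_load(.data$n_left),
    load_right = count_to_load(.data$n_right),
    load_total = .data$load_left + .data$load_right
  )
  out <- out[match(regions, out$region), ]
  attr(out, "cut_offs") <- cut_offs
  out
}
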