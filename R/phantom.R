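# Synthetic brain phantom: a co-registered label volume, region atlas and
# lesion inventory with STRIVE-style lesion classes (lacunes as CSF-filled
# cavities in white matter, periventricular/confluent WMH, 1-2 voxel microbleeds).
# Geometry is deliberately schematic: nested ellipsoids for cortex/WM, paired
# ellipsoidal ventricles, a brainstem cylinder and a posterior-inferior
# cerebellum, enough to give every downstream mask/atlas operation realistic
# topology (holes, boundaries, left/right structure) at desk scale.

#' Lesion specification for the phantom generator
#'
#' Counts and radius ranges (in voxels) per lesion class. WMH blobs are grown
#' around periventricular seeds (plus a configurable fraction of deep-WM
#' seeds) and relabel white matter; lacunes are carved out as CSF-filled
#' cavities; microbleeds are small spheres left inside normal-appearing WM.
#'
#' @param n_lacunes,lacune_radius Number of lacunes and radius range (voxels).
#' @param n_wmh_blobs,wmh_radius Number of WMH blobs and radius range.
#' @param wmh_deep_fraction Fraction of WMH seeds placed in deep WM rather
#'   than adjacent to the ventricles.
#' @param n_cmb,cmb_radius Number of microbleeds and radius range (1-2 voxels).
#' @return A list of class `bbb_lesion_spec`.
#' @export
#' @examples
#' lesion_spec(n_lacunes = 2, n_wmh_blobs = 3, n_cmb = 1)
lesion_spec <- function(n_lacunes = 3, lacune_radius = c(1, 2),
                        n_wmh_blobs = 4, wmh_radius = c(2, 4),
                        wmh_deep_fraction = 0.25,
                        n_cmb = 2, cmb_radius = c(1, 2)) {
  spec <- list(
    n_lacunes = as.integer(n_lacunes), lacune_radius = lacune_radius,
    n_wmh_blobs = as.integer(n_wmh_blobs), wmh_radius = wmh_radius,
    wmh_deep_fraction = wmh_deep_fraction,
    n_cmb = as.integer(n_cmb), cmb_radius = cmb_radius
  )
  for (f in c("n_lacunes", "n_wmh_blobs", "n_cmb")) {
    stopifnot_scalar_number(spec[[f]], f, lower = 0)
  }
  stopifnot_scalar_number(wmh_deep_fraction, "wmh_deep_fraction", 0, 1)
  structure(spec, class = "bbb_lesion_spec")
}

# normalized coordinate grids in [-1, 1] per axis
norm_grids <- function(shape) {
  ax <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  list(
    x = array(rep(ax[[1L]], times = shape[2L] * shape[3L]), dim = shape),
    y = aperm(array(rep(ax[[2L]], times = shape[1L] * shape[3L]),
                    dim = shape[c(2L, 1L, 3L)]), c(2L, 1L, 3L)),
    z = aperm(array(rep(ax[[3L]], times = shape[1L] * shape[2L]),
                    dim = shape[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  )
}

inside_ellipsoid <- function(g, centre, radii) {
  ((g$x - centre[1L]) / radii[1L])^2 +
    ((g$y - centre[2L]) / radii[2L])^2 +
    ((g$z - centre[3L]) / radii[3L])^2 <= 1
}

# flat indices of the voxel ball of radius r (voxels) around centre coord
ball_indices <- function(centre, radius, shape) {
  rng <- lapply(1:3, function(a) {
    max(1L, centre[a] - ceiling(radius)):min(shape[a], centre[a] + ceiling(radius))
  })
  g <- as.matrix(expand.grid(i = rng[[1L]], j = rng[[2L]], k = rng[[3L]]))
  d2 <- (g[, 1L] - centre[1L])^2 + (g[, 2L] - centre[2L])^2 + (g[, 3L] - centre[3L])^2
  coord_to_flat(g[d2 <= radius^2, , drop = FALSE], shape)
}

sample_radius <- function(range) {
  if (length(range) == 1L) return(range)
  stats::runif(1L, range[1L], range[2L])
}

# rejection-sample a lesion centre whose ball fits inside `host` and keeps
# `separation` voxels of distance from previously used centres
place_ball <- function(host_idx, host_mask, shape, radius, prev_centres,
                       separation, what, n_attempts = 2000L) {
  for (attempt in seq_len(n_attempts)) {
    centre <- flat_to_coord(host_idx[sample.int(length(host_idx), 1L)], shape)[1L, ]
    idx <- ball_indices(centre, radius, shape)
    if (!all(host_mask[idx])) next
    if (length(prev_centres)) {
      d <- vapply(prev_centres, function(p) sqrt(sum((p - centre)^2)), numeric(1))
      if (any(d < separation)) next
    }
    return(list(centre = centre, idx = idx))
  }
  stop(sprintf("phantom too small to place a %s of radius %.1f voxels; ",
               what, radius),
       "enlarge `shape` or reduce the lesion specification", call. = FALSE)
}

#' Generate a synthetic brain phantom with SVD lesions
#'
#' Builds a 3D label volume (see [label_codes()]), a left/right region atlas
#' covering all white-matter-class voxels (see [atlas_regions()]) and a
#' per-lesion inventory. Lacunes are CSF-labeled cavities strictly inside WM,
#' WMH blobs relabel WM around periventricular (and some deep) seeds, and
#' microbleeds are 1-2-voxel-radius spheres in normal-appearing WM. The result
#' is bit-reproducible for a fixed seed.
#'
#' @param shape Integer vector of 3 axis sizes, each >= 32.
#' @param voxel_mm Per-axis voxel size in mm (positive).
#' @param lesion_spec A [lesion_spec()] object.
#' @param seed Integer seed.
#' @return An object of class `bbb_phantom`: list with `labels` (integer 3D),
#'   `atlas` (integer 3D, `10*region + side`), `voxel_mm`, `lesion_index`
#'   (tibble: `lesion_id`, `class`, `n_voxels`, `centre`, `voxels` list-column
#'   of flat indices) and `shape`.
#' @export
#' @examples
#' ph <- generate_phantom(shape = c(36, 36, 36), lesion_spec = lesion_spec(
#'   n_lacunes = 1, n_wmh_blobs = 1, n_cmb = 0), seed = 1)
#' table(ph$labels)[1:4]
generate_phantom <- function(shape = c(48, 48, 48), voxel_mm = c(2, 2, 2),
                             lesion_spec = bbbhotspots::lesion_spec(),
                             seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    stop("`shape` must give 3 axis sizes, each >= 32", call. = FALSE)
  }
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (any(voxel_mm <= 0)) stop("`voxel_mm` must be > 0 on all axes", call. = FALSE)
  codes <- label_codes()
  g <- norm_grids(shape)

  labels <- array(codes[["background"]], dim = shape)
  cerebrum <- inside_ellipsoid(g, c(0, 0.05, 0.1), c(0.85, 0.88, 0.78))
  wm_core <- inside_ellipsoid(g, c(0, 0.05, 0.12), c(0.62, 0.68, 0.56))
  vent_l <- inside_ellipsoid(g, c(-0.16, 0.05, 0.12), c(0.09, 0.4, 0.11))
  vent_r <- inside_ellipsoid(g, c(0.16, 0.05, 0.12), c(0.09, 0.4, 0.11))
  cereb <- inside_ellipsoid(g, c(0, -0.55, -0.5), c(0.4, 0.3, 0.26))
  cereb_wm <- inside_ellipsoid(g, c(0, -0.55, -0.5), c(0.26, 0.19, 0.16))
  stem <- (g$x^2 + (g$y + 0.15)^2) <= 0.13^2 & g$z > -0.85 & g$z < -0.25

  labels[cerebrum] <- codes[["gm"]]
  labels[wm_core] <- codes[["wm"]]
  labels[cereb] <- codes[["cerebellum_cortex"]]
  labels[cereb_wm] <- codes[["wm"]]
  labels[stem] <- codes[["brainstem"]]
  labels[vent_l | vent_r] <- codes[["csf"]]

  # region atlas over brain voxels; decided by geometry so that relabelled WMH
  # voxels keep their region
  region <- array(0L, dim = shape)
  brain <- labels != codes[["background"]]
  region[brain] <- 6L  # centrum semiovale fallback
  region[brain & g$y > 0.5] <- 4L                         # anterior-horn WM
  region[brain & g$y < -0.38 & !cereb] <- 5L              # posterior-horn WM
  region[brain & g$z < -0.1 & abs(g$x) > 0.35] <- 3L      # temporal
  ic <- brain & abs(g$x) > 0.25 & abs(g$x) < 0.42 &
    g$y > -0.3 & g$y < 0.35 & g$z > -0.1 & g$z < 0.35
  region[ic] <- 2L                                        # internal capsule
  region[cereb | cereb_wm] <- 1L                          # cerebellum
  side <- ifelse(g$x < 0, 1L, 2L)
  atlas <- ifelse(region > 0L, region * 10L + side, 0L)
  storage.mode(atlas) <- "integer"

  # lesion placement
  lesions <- list()
  with_seed(seed, {
    wm_mask <- labels == codes[["wm"]]
    wm_idx <- which(wm_mask & !cereb_wm)
    centres <- list()

    for (i in seq_len(lesion_spec$n_lacunes)) {
      r <- sample_radius(lesion_spec$lacune_radius)
      p <- place_ball(wm_idx, wm_mask, shape, r, centres,
                      separation = 2 * max(lesion_spec$lacune_radius) + 3,
                      what = "lacune")
      labels[p$idx] <- codes[["lacune"]]
      centres <- c(centres, list(p$centre))
      lesions[[length(lesions) + 1L]] <-
        list(class = "lacune", centre = p$centre, voxels = p$idx)
    }

    # WMH: seeds adjacent to the ventricles (or deep WM), balls clipped to WM
    wm_mask <- labels == codes[["wm"]]
    pv_band <- outer_band(vent_l | vent_r, radius = 2L) & wm_mask
    pv_idx <- which(pv_band)
    deep_idx <- which(wm_mask & !cereb_wm)
    for (i in seq_len(lesion_spec$n_wmh_blobs)) {
      deep <- stats::runif(1) < lesion_spec$wmh_deep_fraction
      host <- if (deep || length(pv_idx) == 0L) deep_idx else pv_idx
      if (length(host) == 0L) {
        stop("phantom too small to seed the requested WMH blobs", call. = FALSE)
      }
      centre <- flat_to_coord(host[sample.int(length(host), 1L)], shape)[1L, ]
      r <- sample_radius(lesion_spec$wmh_radius)
      idx <- ball_indices(centre, r, shape)
      idx <- idx[labels[idx] %in% c(codes[["wm"]], codes[["wmh"]])]
      if (length(idx) == 0L) next
      labels[idx] <- codes[["wmh"]]
      lesions[[length(lesions) + 1L]] <-
        list(class = "wmh", centre = centre, voxels = idx)
    }

    # CMBs inside normal-appearing WM, separated from lacunes
    nawm_mask <- labels == codes[["wm"]]
    nawm_idx <- which(nawm_mask & !cereb_wm)
    for (i in seq_len(lesion_spec$n_cmb)) {
      r <- sample_radius(lesion_spec$cmb_radius)
      p <- place_ball(nawm_idx, nawm_mask, shape, r, centres,
                      separation = 2 * max(lesion_spec$cmb_radius) + 3,
                      what = "microbleed")
      labels[p$idx] <- codes[["cmb"]]
      centres <- c(centres, list(p$centre))
      lesions[[length(lesions) + 1L]] <-
        list(class = "cmb", centre = p$centre, voxels = p$idx)
    }
  })

  lesion_index <- if (length(lesions)) {
    tibble::tibble(
      lesion_id = seq_along(lesions),
      class = vapply(lesions, `[[`, character(1), "class"),
      n_voxels = vapply(lesions, function(l) length(l$voxels), integer(1)),
      centre = lapply(lesions, `[[`, "centre"),
      voxels = lapply(lesions, `[[`, "voxels")
    )
  } else {
    tibble::tibble(lesion_id = integer(), class = character(),
                   n_voxels = integer(), centre = list(), voxels = list())
  }

  structure(
    list(labels = labels, atlas = atlas, voxel_mm = as.numeric(voxel_mm),
         lesion_index = lesion_index, shape = shape, seed = seed),
    class = "bbb_phantom"
  )
}

#' @export
print.bbb_phantom <- function(x, ...) {
  codes <- label_codes()
  cat(sprintf("<bbb_phantom> %s voxels @ %s mm; WM %d, WMH %d voxels; lesions: %s\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_mm, collapse = "x"),
              sum(x$labels == codes[["wm"]]), sum(x$labels == codes[["wmh"]]),
              if (nrow(x$lesion_index)) {
                paste(sprintf("%s=%d", names(table(x$lesion_index$class)),
                              table(x$lesion_index$class)), collapse = ", ")
              } else "none"))
  invisible(x)
}
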