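# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# flat index <-> voxel coordinate conversions for 3D arrays
flat_to_coord <- function(idx, dim3) {
  arrayInd(idx, .dim = dim3)
}

coord_to_flat <- function(coords, dim3) {
  coords[, 1L] + (coords[, 2L] - 1L) * dim3[1L] +
    (coords[, 3L] - 1L) * dim3[1L] * dim3[2L]
}

#' Tissue label codes used by the phantom generator
#'
#' Integer codes for the voxel labels in a synthetic phantom: background,
#' cortical grey matter, white matter, white matter hyperintensity (WMH),
#' lacune interior (CSF-filled cavity), cerebral microbleed (CMB),
#' ventricle/CSF, brainstem and cerebellar cortex.
#'
#' @return A named integer vector of label codes.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(background = 0L, gm = 1L, wm = 2L, wmh = 3L, lacune = 4L,
    cmb = 5L, csf = 6L, brainstem = 7L, cerebellum_cortex = 8L)
}

#' Atlas region vocabulary
#'
#' The six white-matter regions used to describe hotspot distribution, each
#' present on the left and right side. Atlas volumes store
#' `10 * region + side` with side 1 = left, 2 = right, and 0 for unlabeled
#' voxels.
#'
#' @return A tibble with columns `region_code`, `region` and full left/right
#'   atlas codes.
#' @export
#' @examples
#' atlas_regions()
atlas_regions <- function() {
  tibble::tibble(
    region_code = 1:6,
    region = c("cerebellum", "internal_capsule", "temporal",
               "anterior_horn_wm", "posterior_horn_wm", "centrum_semiovale"),
    code_left = 1:6 * 10L + 1L,
    code_right = 1:6 * 10L + 2L
  )
}

atlas_decode <- function(code) {
  region_code <- code %/% 10L
  side <- code %% 10L
  regions <- atlas_regions()
  list(
    region_code = region_code,
    region = ifelse(region_code %in% regions$region_code,
                    regions$region[match(region_code, regions$region_code)],
                    "unassigned"),
    side = c("left", "right", "unassigned")[ifelse(side %in% 1:2, side, 3L)]
  )
}
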