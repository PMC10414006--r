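# Ground-truth permeability maps: piecewise-constant tissue baselines plus
# planted high-PS foci attached to lesion geometry (at lacune rims, within or
# at WMH rims, at CMB rims, or at random WM locations). The focus index keeps
# the planted attachment so recovery can be scored later.

#' Specification of planted high-PS foci
#'
#' Each attachment rule gets a count, an amplitude added to the baseline PS
#' inside the focus ball (1/min), and a ball radius in voxels. Foci are always
#' clipped to white-matter-class voxels (WM or WMH).
#'
#' @param at_lacune_rim,inside_wmh,at_wmh_rim,at_cmb_rim,random_wm Number of
#'   foci per attachment rule.
#' @param amplitude PS elevation inside a focus (1/min). The default (5e-4)
#'   puts focus voxels far above the white-matter baseline so that planted
#'   foci land in the top PS decile under the default noise level.
#' @param radius Focus ball radius (voxels).
#' @return A list of class `bbb_focus_spec`.
#' @export
#' @examples
#' focus_spec(at_lacune_rim = 2, random_wm = 5)
focus_spec <- function(at_lacune_rim = 0L, inside_wmh = 0L, at_wmh_rim = 0L,
                       at_cmb_rim = 0L, random_wm = 0L,
                       amplitude = 5e-4, radius = 2) {
  counts <- c(at_lacune_rim = as.integer(at_lacune_rim),
              inside_wmh = as.integer(inside_wmh),
              at_wmh_rim = as.integer(at_wmh_rim),
              at_cmb_rim = as.integer(at_cmb_rim),
              random_wm = as.integer(random_wm))
  if (any(counts < 0L)) stop("focus counts must be >= 0", call. = FALSE)
  stopifnot_scalar_number(amplitude, "amplitude", lower = 0)
  stopifnot_scalar_number(radius, "radius", lower = 1)
  structure(list(counts = counts, amplitude = amplitude, radius = radius),
            class = "bbb_focus_spec")
}

focus_attachment_host <- function(attachment, phantom, wm_class) {
  codes <- label_codes()
  shape <- phantom$shape
  li <- phantom$lesion_index
  lesion_of_class <- function(cls) li[li$class == cls, , drop = FALSE]
  switch(
    attachment,
    at_lacune_rim = {
      les <- lesion_of_class("lacune")
      if (nrow(les) == 0L) {
        stop("focus attachment 'at_lacune_rim' requested but the phantom has no lacunes",
             call. = FALSE)
      }
      les
    },
    at_cmb_rim = {
      les <- lesion_of_class("cmb")
      if (nrow(les) == 0L) {
        stop("focus attachment 'at_cmb_rim' requested but the phantom has no microbleeds",
             call. = FALSE)
      }
      les
    },
    inside_wmh = ,
    at_wmh_rim = {
      if (!any(phantom$labels == codes[["wmh"]])) {
        stop(sprintf("focus attachment '%s' requested but the phantom has no WMH",
                     attachment), call. = FALSE)
      }
      NULL
    },
    random_wm = NULL
  )
}

#' Generate ground-truth PS and vP maps with planted leakage foci
#'
#' Outside foci, the permeability surface area product (PS) and plasma volume
#' fraction (vP) maps are piecewise-constant over tissue classes, with
#' defaults emulating white-matter values reported for small-vessel-disease
#' cohorts (PS around 0.4e-4/min in normal-appearing WM, 0.9e-4/min in WMH;
#' vP around 0.004 and 0.006). Each planted focus raises PS by a constant
#' amplitude inside a ball clipped to WM-class voxels, seeded at a location
#' determined by its attachment rule.
#'
#' @param phantom A [generate_phantom()] result.
#' @param base_ps Named numeric: baseline PS (1/min) for `nawm`, `wmh` and
#'   optionally `gm`, `other`.
#' @param base_vp Named numeric: baseline vP (fraction) for the same classes.
#' @param focus_spec A [focus_spec()] object.
#' @param seed Integer seed for focus placement.
#' @return Object of class `bbb_truth`: list with `ps_true`, `vp_true`
#'   (3D arrays), and `focus_index` (tibble: `focus_id`, `attachment`,
#'   `lesion_id`, `seed_voxel`, `radius`, `amplitude`, `voxels` list-column).
#' @export
#' @examples
#' ph <- generate_phantom(shape = c(36, 36, 36),
#'                        lesion_spec = lesion_spec(n_lacunes = 1, n_cmb = 0),
#'                        seed = 2)
#' tr <- generate_truth_maps(ph, focus_spec = focus_spec(at_lacune_rim = 1), seed = 3)
#' nrow(tr$focus_index)
generate_truth_maps <- function(phantom,
                                base_ps = c(nawm = 0.43e-4, wmh = 0.91e-4,
                                            gm = 1e-4, other = 0),
                                base_vp = c(nawm = 41.42e-4, wmh = 62.30e-4,
                                            gm = 0.02, other = 0),
                                focus_spec = bbbhotspots::focus_spec(),
                                seed = 1L) {
  stopifnot(inherits(phantom, "bbb_phantom"))
  for (nm in c("nawm", "wmh")) {
    if (is.na(base_ps[nm]) || is.na(base_vp[nm])) {
      stop(sprintf("base PS and vP values must be given for '%s'", nm),
           call. = FALSE)
    }
  }
  codes <- label_codes()
  labels <- phantom$labels
  shape <- phantom$shape
  gm_ps <- if (!is.na(base_ps["gm"])) base_ps[["gm"]] else base_ps[["nawm"]]
  gm_vp <- if (!is.na(base_vp["gm"])) base_vp[["gm"]] else base_vp[["nawm"]]
  other_ps <- if (!is.na(base_ps["other"])) base_ps[["other"]] else 0
  other_vp <- if (!is.na(base_vp["other"])) base_vp[["other"]] else 0

  ps <- array(other_ps, dim = shape)
  vp <- array(other_vp, dim = shape)
  gm_like <- labels %in% c(codes[["gm"]], codes[["cerebellum_cortex"]],
                           codes[["brainstem"]])
  ps[gm_like] <- gm_ps
  vp[gm_like] <- gm_vp
  ps[labels == codes[["wm"]]] <- base_ps[["nawm"]]
  vp[labels == codes[["wm"]]] <- base_vp[["nawm"]]
  ps[labels == codes[["wmh"]]] <- base_ps[["wmh"]]
  vp[labels == codes[["wmh"]]] <- base_vp[["wmh"]]

  wm_class <- labels %in% c(codes[["wm"]], codes[["wmh"]])
  wmh_mask <- labels == codes[["wmh"]]
  foci <- list()

  with_seed(seed, {
    for (attachment in names(focus_spec$counts)) {
      n_foci <- focus_spec$counts[[attachment]]
      if (n_foci == 0L) next
      lesions <- focus_attachment_host(attachment, phantom, wm_class)
      for (i in seq_len(n_foci)) {
        lesion_id <- NA_integer_
        host_idx <- switch(
          attachment,
          at_lacune_rim = ,
          at_cmb_rim = {
            row <- ((i - 1L) %% nrow(lesions)) + 1L  # cycle through lesions
            lesion_id <- lesions$lesion_id[row]
            lmask <- array(FALSE, dim = shape)
            lmask[lesions$voxels[[row]]] <- TRUE
            which(outer_band(lmask) & wm_class)
          },
          inside_wmh = {
            inner <- erode_one_voxel(wmh_mask)
            which(if (any(inner)) inner else wmh_mask)
          },
          at_wmh_rim = which(outer_band(wmh_mask) & wm_class),
          random_wm = which(wm_class)
        )
        if (length(host_idx) == 0L) {
          stop(sprintf("no eligible WM voxels to seed a '%s' focus", attachment),
               call. = FALSE)
        }
        seed_voxel <- host_idx[sample.int(length(host_idx), 1L)]
        centre <- flat_to_coord(seed_voxel, shape)[1L, ]
        idx <- ball_indices(centre, focus_spec$radius, shape)
        idx <- idx[wm_class[idx]]
        ps[idx] <- ps[idx] + focus_spec$amplitude
        foci[[length(foci) + 1L]] <- list(
          attachment = attachment, lesion_id = lesion_id,
          seed_voxel = seed_voxel, voxels = idx
        )
      }
    }
  })

  focus_index <- if (length(foci)) {
    tibble::tibble(
      focus_id = seq_along(foci),
      attachment = vapply(foci, `[[`, character(1), "attachment"),
      lesion_id = vapply(foci, `[[`, integer(1), "lesion_id"),
      seed_voxel = vapply(foci, `[[`, integer(1), "seed_voxel"),
      radius = focus_spec$radius,
      amplitude = focus_spec$amplitude,
      voxels = lapply(foci, `[[`, "voxels")
    )
  } else {
    tibble::tibble(focus_id = integer(), attachment = character(),
                   lesion_id = integer(), seed_voxel = integer(),
                   radius = numeric(), amplitude = numeric(), voxels = list())
  }

  structure(list(ps_true = ps, vp_true = vp, focus_index = focus_index,
                 base_ps = base_ps, base_vp = base_vp),
            class = "bbb_truth")
}

#' Synthesize a Patlak-consistent DCE concentration series
#'
#' Per voxel, the tissue concentration follows the Patlak forward model
#' \deqn{C_t(t) = v_P C_p(t) + PS \int_0^t C_p \, d\tau + \varepsilon,}
#' with \eqn{\varepsilon \sim N(0, \sigma^2)} independent across voxels and
#' time points. With `noise_sd = 0` the series is exactly noise-free and
#' Patlak fitting recovers the truth to numerical precision.
#'
#' @param truth A [generate_truth_maps()] result.
#' @param vif A [generate_vif()] result.
#' @param times Sample times (s); must equal `vif$times`.
#' @param noise_sd Gaussian noise SD in concentration units (mM), >= 0.
#' @param seed Integer seed for the noise draw.
#' @return Object of class `bbb_dce`: list with `times`, `conc` (4D array,
#'   one volume per time point) and `noise_sd`.
#' @export
#' @examples
#' ph <- generate_phantom(shape = c(36, 36, 36),
#'                        lesion_spec = lesion_spec(0, n_wmh_blobs = 0, n_cmb = 0))
#' tr <- generate_truth_maps(ph, focus_spec = focus_spec())
#' vif <- generate_vif(times = seq(0, 300, 30))
#' dce <- synthesize_dce(tr, vif, noise_sd = 0)
#' dim(dce$conc)
synthesize_dce <- function(truth, vif, times = vif$times, noise_sd = 0.002,
                           seed = 1L) {
  stopifnot(inherits(truth, "bbb_truth"))
  if (!isTRUE(all.equal(as.numeric(times), vif$times))) {
    stop("`times` must match the VIF time axis", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  shape <- dim(truth$ps_true)
  n_t <- length(times)
  cumint <- cumulative_vif_integral(vif)  # mM.min

  nvox <- prod(shape)
  # conc as nvox x n_t, then reshaped; outer products keep this vectorised
  conc <- as.vector(truth$vp_true) %o% vif$cp +
    as.vector(truth$ps_true) %o% cumint
  if (noise_sd > 0) {
    with_seed(seed, {
      conc <- conc + stats::rnorm(length(conc), sd = noise_sd)
    })
  }
  structure(list(times = as.numeric(times),
                 conc = array(conc, dim = c(shape, n_t)),
                 noise_sd = noise_sd),
            class = "bbb_dce")
}
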